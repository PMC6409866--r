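# Synthetic falciform nuclei with planted FISH signals and full ground
# truth. The silhouette is a parametric midline with varying half-width:
# the heading angle relaxes exponentially from a strongly curled apical
# hook to a straight body, and the half-width profile pinches to a point at
# both the hook tip and the tail-attachment end so both landmarks exist by
# construction. Planted signal addresses use midline coordinates (u, v):
# u = fractional arc position from hook tip to base, v = signed fractional
# offset toward the dorsal (+) or ventral (-) boundary. These addresses
# transfer across differently shaped strains exactly as the mesh does.

#' Falciform shape parameters
#'
#' Defaults emulate a DTT-swelled mouse sperm nucleus: roughly 10 um long,
#' 4.5 um wide, area in the low tens of um^2. `hook_curl` scales the total
#' turning of the apical hook (1 corresponds to about 140 degrees); it must
#' be positive, since a hook-free ellipse has no orientable landmarks and
#' is rejected as non-falciform.
#'
#' @param length_um Midline length.
#' @param width_um Maximum full width.
#' @param hook_curl Dimensionless hook curvature scale, > 0.
#' @param boundary_noise_sd Gaussian boundary displacement, in pixels.
#' @param strain_label Strain name carried into manifests.
#' @export
falciform_params <- function(length_um = 10, width_um = 4.5, hook_curl = 1,
                             boundary_noise_sd = 0.5, strain_label = "strainA") {
  if (length_um <= 0 || width_um <= 0) stop("dimensions must be positive")
  if (hook_curl <= 0) stop("hook_curl must be > 0: a hook-free outline is not falciform")
  list(length_um = length_um, width_um = width_um, hook_curl = hook_curl,
       boundary_noise_sd = boundary_noise_sd, strain_label = strain_label)
}

#' Planted FISH signal specification
#'
#' @param probe_label Probe name (e.g. "chrX").
#' @param address Either a named nuclear region (`"dorsal_apical"`,
#'   `"ventral_basal"`, `"centre"`) or a numeric `c(u, v)` midline address.
#' @param spread_um Gaussian blob sigma.
#' @param placement_noise Probability that the signal is planted at a
#'   uniform-random in-nucleus position instead of its address.
#' @param address_jitter SD of biological scatter added to (u, v) per
#'   nucleus, in address units.
#' @export
planted_signal <- function(probe_label, address = "centre", spread_um = 0.45,
                           placement_noise = 0, address_jitter = 0.04) {
  named <- c(dorsal_apical = NA, ventral_basal = NA, centre = NA)
  if (is.character(address)) {
    address <- switch(address,
      dorsal_apical = c(0.30, 0.45),
      ventral_basal = c(0.75, -0.40),
      centre = c(0.55, 0),
      stop("unknown named address: ", address))
  }
  if (length(address) != 2 || address[1] < 0 || address[1] > 1 ||
      abs(address[2]) > 1) {
    stop("address must be (u in [0,1], v in [-1,1])")
  }
  if (spread_um <= 0) stop("spread_um must be positive")
  list(probe_label = probe_label, address = address, spread_um = spread_um,
       placement_noise = placement_noise, address_jitter = address_jitter)
}

# Midline geometry in microns, canonical pose (hook tip near origin, body
# running rightward, hook curling toward smaller y = dorsal up).
falciform_geometry <- function(params, n_mid = 160) {
  s <- seq(0, 1, length.out = n_mid)
  delta <- 2.45 * params$hook_curl          # total hook turning, radians
  theta <- -delta * exp(-s / 0.22)
  ds <- params$length_um / (n_mid - 1)
  dx <- cos(theta) * ds
  dy <- sin(theta) * ds
  mid <- cbind(cumsum(dx) - dx[1], cumsum(dy) - dy[1])
  tang <- cbind(cos(theta), sin(theta))
  # dorsal = the convex (acrosomal) edge; lands "up" after orientation
  normal <- cbind(tang[, 2], -tang[, 1])
  wraw <- s^0.62 * (1 - s^4)^0.62
  halfw <- wraw / max(wraw) * params$width_um / 2
  arc <- c(0, cumsum(sqrt(diff(mid[, 1])^2 + diff(mid[, 2])^2)))
  list(mid = mid, normal = normal, halfw = halfw, u = arc / max(arc))
}

# Closed polygon (microns) from geometry: tip, dorsal side, base, ventral.
falciform_polygon <- function(geom) {
  n <- nrow(geom$mid)
  inner <- 2:(n - 1)
  dorsal <- geom$mid[inner, ] + geom$normal[inner, ] * geom$halfw[inner]
  ventral <- geom$mid[inner, ] - geom$normal[inner, ] * geom$halfw[inner]
  rbind(geom$mid[1, , drop = FALSE], dorsal, geom$mid[n, , drop = FALSE],
        ventral[rev(seq_len(nrow(ventral))), , drop = FALSE])
}

# Convert a (u, v) midline address to a point (microns, canonical pose).
address_point <- function(geom, u, v) {
  m <- c(stats::approx(geom$u, geom$mid[, 1], u)$y,
         stats::approx(geom$u, geom$mid[, 2], u)$y)
  nr <- c(stats::approx(geom$u, geom$normal[, 1], u)$y,
          stats::approx(geom$u, geom$normal[, 2], u)$y)
  w <- stats::approx(geom$u, geom$halfw, u)$y
  m + v * w * nr / max(sqrt(sum(nr^2)), 1e-9)
}

#' Generate one synthetic falciform nucleus
#'
#' Builds the parametric silhouette, perturbs the boundary with Gaussian
#' noise, and renders an 8-bit counterstain raster (bright interior over a
#' dim noisy background) in the nucleus's own frame.
#'
#' @param params A [falciform_params] list.
#' @param seed Integer seed; the same seed reproduces the raster exactly.
#' @param mpp Microns per pixel.
#' @return List: `outline` ([nucleus_outline] of the true noisy polygon),
#'   `raster` ([channel_raster], counterstain), `truth` (list with `apex`,
#'   `base` ground-truth landmark points, the polygon, the midline
#'   geometry in pixel units, and the analytic polygon area in um^2).
#' @export
generate_nucleus <- function(params, seed = 1, mpp = 0.1) {
  withr::local_seed(seed)
  geom <- falciform_geometry(params)
  poly_um <- falciform_polygon(geom)
  analytic_area <- poly_area(poly_um)
  poly <- poly_um / mpp
  if (params$boundary_noise_sd > 0) {
    noise <- stats::rnorm(nrow(poly), 0, params$boundary_noise_sd)
    # displace along the local outward direction, then lightly smooth
    ctr <- poly_centroid(poly)
    dirs <- sweep(poly, 2, ctr)
    dirs <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-9)
    poly <- poly + dirs * noise
    poly <- smooth_closed(poly, 3)
  }
  shift <- c(4, 4) - c(min(poly[, 1]), min(poly[, 2]))
  poly <- sweep(poly, 2, shift, "+")
  geom_px <- list(mid = sweep(geom$mid / mpp, 2, shift, "+"),
                  normal = geom$normal, halfw = geom$halfw / mpp, u = geom$u)
  outline <- nucleus_outline(poly, mpp = mpp,
                             id = sprintf("%s_seed%d", params$strain_label, seed),
                             source = "synthetic")
  mask <- outline$mask
  px <- matrix(stats::rnorm(length(mask), 10, 3), nrow(mask), ncol(mask))
  px[mask] <- stats::rnorm(sum(mask), 170, 8)
  px <- matrix(as.integer(pmin(255, pmax(0, round(px)))), nrow(mask), ncol(mask))
  raster <- channel_raster(px, bit_depth = 8L, channel_role = "counterstain")
  truth <- list(apex = geom_px$mid[1, ], base = geom_px$mid[nrow(geom_px$mid), ],
                polygon = poly, geom = geom_px, analytic_area_um2 = analytic_area)
  list(outline = outline, raster = raster, truth = truth)
}

smooth_closed <- function(poly, w = 3) {
  n <- nrow(poly)
  half <- (w - 1) / 2
  out <- poly
  for (d in seq_len(half)) {
    prev <- poly[((seq_len(n) - 1 - d) %% n) + 1, , drop = FALSE]
    nxt <- poly[((seq_len(n) - 1 + d) %% n) + 1, , drop = FALSE]
    out <- out + prev + nxt
  }
  out / (2 * half + 1)
}

#' Plant FISH signals into a synthetic nucleus
#'
#' Each probe becomes a Gaussian intensity blob at its (u, v) address (or,
#' with probability `placement_noise`, at a uniform-random in-nucleus
#' position) over a dim noisy background, rendered in the nucleus frame.
#'
#' @param nucleus A [generate_nucleus] result.
#' @param signals List of [planted_signal] specs (at most 2: the raster
#'   container supports signal_A and signal_B).
#' @param seed Integer seed.
#' @return List with `channels` (list of [channel_raster]) and `truth`
#'   (per-probe planted centre, pixel coords, and whether it was displaced).
#' @export
plant_signals <- function(nucleus, signals, seed = 1) {
  if (length(signals) > 2) stop("at most two signal channels per field")
  withr::local_seed(seed)
  mask <- nucleus$outline$mask
  geom <- nucleus$truth$geom
  mpp <- nucleus$outline$mpp
  h <- nrow(mask); w <- ncol(mask)
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  channels <- list()
  truth <- list()
  roles <- c("signal_A", "signal_B")
  for (i in seq_along(signals)) {
    sg <- signals[[i]]
    uv <- sg$address + stats::rnorm(2, 0, sg$address_jitter)
    uv[1] <- min(0.95, max(0.05, uv[1]))
    uv[2] <- min(0.85, max(-0.85, uv[2]))
    displaced <- stats::runif(1) < sg$placement_noise
    if (displaced) {
      inpix <- which(mask)
      pick <- sample(length(inpix), 1)
      ctr <- c((inpix[pick] - 1L) %/% h, (inpix[pick] - 1L) %% h)
    } else {
      ctr <- address_point(geom_um_to_px(geom), uv[1], uv[2])
    }
    if (!points_in_mask(mask, matrix(ctr, 1))) {
      # jittered address slipped outside the noisy boundary; pull to centre
      ctr <- address_point(geom_um_to_px(geom), uv[1], uv[2] * 0.5)
      if (!points_in_mask(mask, matrix(ctr, 1))) {
        stop("planted address lies outside the nucleus")
      }
    }
    sig_px <- sg$spread_um / mpp
    blob <- 190 * exp(-((xs - ctr[1])^2 + (ys - ctr[2])^2) / (2 * sig_px^2))
    px <- blob + stats::rnorm(h * w, 6, 2.5)
    px <- matrix(as.integer(pmin(255, pmax(0, round(px)))), h, w)
    channels[[i]] <- channel_raster(px, 8L, roles[i])
    truth[[sg$probe_label]] <- list(centre = ctr, address = uv,
                                    displaced = displaced)
  }
  list(channels = channels, truth = truth)
}

# geometry already stored in px units; identity helper kept for clarity
geom_um_to_px <- function(geom) geom

#' Generate a population of synthetic field images
#'
#' Places `nuclei_per_field` nuclei per field on a grid of non-overlapping
#' cells with random rotation, mirroring and jitter, renders counterstain
#' and signal channels, and returns the fields with a complete ground-truth
#' manifest. With `out_dir` set, fields are written as multi-plane TIFFs
#' and the manifest as JSON.
#'
#' @param strains List of strain specs: each
#'   `list(params = falciform_params(...), signals = list(planted_signal(...)))`.
#' @param n_per_strain Nuclei per strain.
#' @param seed Integer seed for the whole population.
#' @param mpp Microns per pixel.
#' @param nuclei_per_field Nuclei placed in each field.
#' @param out_dir Optional output directory.
#' @return List: `fields` (list of [field_image]), `manifest` (per-nucleus
#'   ground truth: strain, field, polygon, apex/base, signal centres,
#'   probe-role mapping), `probe_map` (per-field role -> probe labels).
#' @export
generate_population <- function(strains, n_per_strain, seed = 1, mpp = 0.1,
                                nuclei_per_field = 4, out_dir = NULL) {
  if (n_per_strain < 1) stop("n_per_strain must be >= 1")
  withr::local_seed(seed)
  fields <- list()
  manifest <- list()
  probe_map <- list()
  nuc_global <- 0
  for (si in seq_along(strains)) {
    sp <- strains[[si]]
    roles <- c("signal_A", "signal_B")[seq_along(sp$signals)]
    labels <- vapply(sp$signals, function(s) s$probe_label, character(1))
    n_fields <- ceiling(n_per_strain / nuclei_per_field)
    placed <- 0
    for (fi in seq_len(n_fields)) {
      n_here <- min(nuclei_per_field, n_per_strain - placed)
      nuclei <- lapply(seq_len(n_here), function(j) {
        s_nuc <- sample.int(2^31 - 1, 1)
        nuc <- generate_nucleus(sp$params, seed = s_nuc, mpp = mpp)
        sig <- plant_signals(nuc, sp$signals, seed = sample.int(2^31 - 1, 1))
        list(nuc = nuc, sig = sig)
      })
      cell <- max(vapply(nuclei, function(z) max(dim(z$nuc$outline$mask)),
                         numeric(1))) + 30L
      ncol_grid <- ceiling(sqrt(nuclei_per_field))
      nrow_grid <- ceiling(nuclei_per_field / ncol_grid)
      W <- as.integer(ncol_grid * cell + 20L)
      H <- as.integer(nrow_grid * cell + 20L)
      cs <- matrix(stats::rnorm(H * W, 10, 3), H, W)
      sigs <- lapply(roles, function(r) matrix(stats::rnorm(H * W, 6, 2.5), H, W))
      field_truth <- list()
      for (j in seq_len(n_here)) {
        z <- nuclei[[j]]
        gi <- (j - 1) %% ncol_grid
        gj <- (j - 1) %/% ncol_grid
        theta <- stats::runif(1, 0, 2 * pi)
        mirrored <- stats::runif(1) < 0.5
        poly <- z$nuc$truth$polygon
        ctr <- poly_centroid(poly)
        M <- rot2(theta)
        if (mirrored) M <- M %*% matrix(c(-1, 0, 0, 1), 2, 2)
        rp <- sweep(sweep(poly, 2, ctr) %*% t(M), 2, ctr, "+")
        ext <- rbind(c(min(rp[, 1]), min(rp[, 2])), c(max(rp[, 1]), max(rp[, 2])))
        slack_x <- cell - (ext[2, 1] - ext[1, 1]) - 8
        slack_y <- cell - (ext[2, 2] - ext[1, 2]) - 8
        if (slack_x < 0 || slack_y < 0) stop("cannot place nucleus without overlap")
        off <- c(10 + gi * cell + stats::runif(1, 0, slack_x) - ext[1, 1],
                 10 + gj * cell + stats::runif(1, 0, slack_y) - ext[1, 2])
        tf <- list(A = M, b = as.numeric(-M %*% ctr) + ctr + off)
        fp <- sweep(rp, 2, off, "+")
        fmask <- rasterize_polygon(fp, W, H)
        cs[fmask] <- stats::rnorm(sum(fmask), 170, 8)
        for (ri in seq_along(roles)) {
          sc <- apply_affine(tf, matrix(z$sig$truth[[ri]]$centre, 1))
          sig_px <- sp$signals[[ri]]$spread_um / mpp
          x0 <- max(1, floor(sc[1] - 4 * sig_px)); x1 <- min(W, ceiling(sc[1] + 4 * sig_px))
          y0 <- max(1, floor(sc[2] - 4 * sig_px)); y1 <- min(H, ceiling(sc[2] + 4 * sig_px))
          if (x1 >= x0 && y1 >= y0) {
            xs <- matrix(rep((x0:x1) - 1, each = y1 - y0 + 1), y1 - y0 + 1)
            ys <- matrix(rep((y0:y1) - 1, x1 - x0 + 1), y1 - y0 + 1)
            blob <- 190 * exp(-((xs - sc[1])^2 + (ys - sc[2])^2) / (2 * sig_px^2))
            sigs[[ri]][y0:y1, x0:x1] <- sigs[[ri]][y0:y1, x0:x1] + blob
          }
        }
        nuc_global <- nuc_global + 1
        field_truth[[j]] <- list(
          id = sprintf("nuc%04d", nuc_global),
          strain = sp$params$strain_label,
          field = length(fields) + 1L,
          polygon = fp,
          apex = as.numeric(apply_affine(tf, matrix(z$nuc$truth$apex, 1))),
          base = as.numeric(apply_affine(tf, matrix(z$nuc$truth$base, 1))),
          mirrored = mirrored,
          area_um2 = z$nuc$outline$area_um2,
          signals = stats::setNames(lapply(seq_along(roles), function(ri) {
            list(centre = as.numeric(apply_affine(tf,
                   matrix(z$sig$truth[[ri]]$centre, 1))),
                 displaced = z$sig$truth[[ri]]$displaced,
                 role = roles[ri])
          }), labels))
      }
      to_int <- function(m) matrix(as.integer(pmin(255, pmax(0, round(m)))),
                                   nrow(m), ncol(m))
      chans <- c(list(channel_raster(to_int(cs), 8L, "counterstain")),
                 lapply(seq_along(roles), function(ri)
                   channel_raster(to_int(sigs[[ri]]), 8L, roles[ri])))
      fid <- sprintf("field%03d_%s", length(fields) + 1L, sp$params$strain_label)
      fields[[length(fields) + 1L]] <- field_image(chans, calibration(mpp),
                                                   source_path = fid)
      probe_map[[length(fields)]] <- stats::setNames(labels, roles)
      manifest <- c(manifest, field_truth)
      placed <- placed + n_here
    }
  }
  res <- list(fields = fields, manifest = manifest, probe_map = probe_map)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      planes <- lapply(f$channels, function(ch) ch$pixels / 255)
      tiff::writeTIFF(planes, file.path(out_dir, paste0(f$source_path, ".tif")),
                      bits.per.sample = 8L)
    }
    jsonlite::write_json(
      list(mpp = mpp, seed = seed,
           probe_map = probe_map,
           nuclei = manifest),
      file.path(out_dir, "truth_manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
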