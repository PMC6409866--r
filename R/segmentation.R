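# Nucleus detection on the counterstain channel: global Otsu threshold,
# hole filling, connected components, then size/solidity/border filters.
# Clumped or misshapen objects are rejected rather than split, since the
# downstream composites aggregate over populations and can afford the loss.

#' Nucleus outline
#'
#' An ordered closed boundary polygon for one segmented nucleus, together
#' with its interior mask, area, centre of mass and orientation metadata.
#' Boundary coordinates are local to the outline's own frame; `offset` gives
#' the position of local pixel (0,0) in the source image.
#'
#' @param boundary n x 2 matrix of (x, y) boundary points, ordered, closed
#'   implicitly (first point is not repeated).
#' @param mpp Microns per pixel.
#' @param mask Optional logical interior mask; rasterised from the polygon
#'   when omitted.
#' @param offset Length-2 origin of the local frame in source-image pixels.
#' @param id,source Identifiers for provenance.
#' @param flipped Whether a horizontal mirror was applied during orientation.
#' @return Object of class `nucleus_outline`.
#' @export
nucleus_outline <- function(boundary, mpp, mask = NULL, offset = c(0, 0),
                            id = "nucleus", source = "<unknown>",
                            flipped = FALSE) {
  boundary <- as.matrix(boundary)
  if (nrow(boundary) < 3) stop("boundary needs at least 3 points")
  if (is.null(mask)) {
    w <- ceiling(max(boundary[, 1])) + 2L
    h <- ceiling(max(boundary[, 2])) + 2L
    if (min(boundary) < 0) stop("local boundary coordinates must be non-negative")
    mask <- rasterize_polygon(boundary, w, h)
  }
  npix <- sum(mask)
  idx <- which(mask)
  com <- c(mean((idx - 1L) %/% nrow(mask)), mean((idx - 1L) %% nrow(mask)))
  structure(list(boundary = boundary, mask = mask, mpp = mpp,
                 offset = as.numeric(offset),
                 area_um2 = npix * mpp^2,
                 centre_of_mass = com,
                 flipped = flipped, id = id, source = source),
            class = "nucleus_outline")
}

#' @export
print.nucleus_outline <- function(x, ...) {
  cat(sprintf("<nucleus_outline> %s: %d boundary pts, %.1f um^2, flipped=%s\n",
              x$id, nrow(x$boundary), x$area_um2, x$flipped))
  invisible(x)
}

#' Segmentation parameters
#'
#' Defaults bracket the area range of DTT-swelled mouse sperm nuclei
#' (roughly 20-40 um^2 after swelling) with generous margins, and reject
#' clumps and debris through a convexity (solidity) floor low enough to
#' retain strongly hooked shapes.
#'
#' @param min_area_um2,max_area_um2 Area acceptance window.
#' @param min_solidity Minimum ratio of object area to convex hull area.
#' @export
segmentation_params <- function(min_area_um2 = 10, max_area_um2 = 60,
                                min_solidity = 0.7) {
  if (min_area_um2 > max_area_um2) {
    stop("configuration error: min_area_um2 exceeds max_area_um2")
  }
  list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
       min_solidity = min_solidity)
}

trace_boundary <- function(submask) {
  img <- EBImage::Image(t(submask * 1))
  oc <- EBImage::ocontour(img)
  if (length(oc) == 0) return(NULL)
  b <- oc[[1]]
  if (nrow(b) < 3) return(NULL)
  b
}

#' Detect nuclei in a field image
#'
#' Otsu-thresholds the counterstain channel, fills holes, labels connected
#' components (8-connected) and returns an outline for every object that
#' passes the area and solidity filters and does not touch the image border.
#' A blank channel yields an empty list.
#'
#' @param field A [field_image].
#' @param params A [segmentation_params] list.
#' @return List of [nucleus_outline] objects.
#' @export
detect_nuclei <- function(field, params = segmentation_params()) {
  if (is.null(field$channels$counterstain)) stop("field has no counterstain channel")
  px <- field$channels$counterstain$pixels
  mpp <- field$calibration$microns_per_pixel
  mx <- max(px)
  if (mx == 0) return(list())
  thr <- EBImage::otsu(EBImage::Image(px / mx), range = c(0, 1), levels = 256)
  mask <- px / mx > thr
  mask <- t(EBImage::fillHull(EBImage::Image(t(mask) * 1)) > 0)
  lab <- label_components(mask, connectivity = 8)
  ncomp <- max(lab)
  if (ncomp == 0) return(list())
  h <- nrow(mask); w <- ncol(mask)
  out <- list()
  for (k in seq_len(ncomp)) {
    idx <- which(lab == k)
    rows <- (idx - 1L) %% h + 1L
    cols <- (idx - 1L) %/% h + 1L
    # border contact
    if (min(rows) == 1L || max(rows) == h || min(cols) == 1L || max(cols) == w) next
    area <- length(idx) * mpp^2
    if (area < params$min_area_um2 || area > params$max_area_um2) next
    hull <- grDevices::chull(cols, rows)
    hull_area <- poly_area(cbind(cols[hull], rows[hull]))
    solidity <- length(idx) / max(hull_area, 1)
    if (solidity < params$min_solidity) next
    r0 <- min(rows) - 2L; c0 <- min(cols) - 2L
    sub <- matrix(FALSE, max(rows) - r0 + 2L, max(cols) - c0 + 2L)
    sub[cbind(rows - r0, cols - c0)] <- TRUE
    b <- trace_boundary(sub)
    if (is.null(b)) next
    out[[length(out) + 1L]] <- nucleus_outline(
      boundary = b, mpp = mpp, mask = sub,
      offset = c(c0, r0),  # (x0, y0): local (0,0) sits at source col c0+1 etc.
      id = sprintf("%s_n%02d", basename(field$source_path), k),
      source = field$source_path)
  }
  out
}

#' Crop a channel to a nucleus's local frame
#'
#' @param field A [field_image].
#' @param outline A [nucleus_outline] detected in that field.
#' @param role Channel role to crop.
#' @return Integer matrix with the outline's mask dimensions.
#' @export
crop_channel <- function(field, outline, role = "signal_A") {
  ch <- field$channels[[role]]
  if (is.null(ch)) stop("field has no channel with role ", role)
  px <- ch$pixels
  h <- nrow(outline$mask); w <- ncol(outline$mask)
  x0 <- outline$offset[1]; y0 <- outline$offset[2]
  out <- matrix(0L, h, w)
  rows <- seq_len(h) + y0
  cols <- seq_len(w) + x0
  ok_r <- rows >= 1 & rows <= nrow(px)
  ok_c <- cols >= 1 & cols <= ncol(px)
  out[ok_r, ok_c] <- px[rows[ok_r], cols[ok_c]]
  out
}

#' Export outlines as CSV files plus a run-level JSON manifest
#'
#' One CSV of boundary coordinates per nucleus, and a manifest recording
#' nucleus id, source image, landmark indices, flip state and area.
#'
#' @param outlines List of [nucleus_outline]s.
#' @param landmark_sets Optional list of [landmark_set]s, parallel to
#'   `outlines`.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest JSON, invisibly.
#' @export
export_outlines <- function(outlines, landmark_sets = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(seq_along(outlines), function(i) {
    o <- outlines[[i]]
    f <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", o$id), ".csv"))
    utils::write.csv(data.frame(x = o$boundary[, 1], y = o$boundary[, 2]),
                     f, row.names = FALSE)
    lm <- if (!is.null(landmark_sets)) as.list(landmark_sets[[i]]$indices) else NULL
    list(id = o$id, source = o$source, outline_csv = basename(f),
         landmarks = lm, flipped = o$flipped, area_um2 = o$area_um2)
  })
  mpath <- file.path(dir, "nuclei_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
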