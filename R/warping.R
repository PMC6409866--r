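# Signal binarisation and forward piecewise-affine warping. Warping is
# source -> target: every ON pixel centre is moved by the affine map of its
# mesh face and rasterised to the nearest target pixel; the gap-filling
# kernel then closes the holes that forward mapping leaves when a source
# face is smaller than its target face. FISH rasters are binarised before
# warping so bright and dim hybridisations contribute equally.

#' Binarise a signal channel within a nucleus mask
#'
#' The threshold is computed from in-mask pixels only, so neighbouring
#' nuclei or background structure cannot bias it.
#'
#' @param channel Integer matrix (or [channel_raster]) of signal intensities.
#' @param mask Logical nucleus mask with the same dimensions.
#' @param method Threshold spec: `"otsu"` (Otsu on the in-mask histogram),
#'   `"fixed:<v>"` (absolute intensity), or `"fraction:<f>"` (fraction of
#'   the in-mask maximum).
#' @return Logical matrix; TRUE only inside the mask where intensity
#'   exceeds the threshold. An all-zero channel yields an all-FALSE raster.
#' @export
binarise_signal <- function(channel, mask, method = "otsu") {
  if (inherits(channel, "channel_raster")) channel <- channel$pixels
  if (!all(dim(channel) == dim(mask))) stop("channel and mask dimensions differ")
  vals <- channel[mask]
  if (length(vals) == 0 || max(vals) == 0) {
    return(matrix(FALSE, nrow(channel), ncol(channel)))
  }
  thr <- resolve_threshold(method, vals)
  out <- channel > thr & mask
  out
}

resolve_threshold <- function(method, vals) {
  if (is.numeric(method)) return(method)
  if (identical(method, "otsu")) {
    mx <- max(vals)
    # EBImage's Otsu accepts any image shape; feed it the in-mask values
    img <- EBImage::Image(matrix(vals / mx, nrow = 1))
    return(EBImage::otsu(img, range = c(0, 1), levels = 256) * mx)
  }
  if (grepl("^fixed:", method)) return(as.numeric(sub("^fixed:", "", method)))
  if (grepl("^fraction:", method)) {
    return(as.numeric(sub("^fraction:", "", method)) * max(vals))
  }
  stop("unknown threshold method: ", method)
}

#' Raster frame of a target mesh
#'
#' Bounding box of the target polygon plus a 2-pixel margin. All warps onto
#' the same template share this frame, which is what makes their rasters
#' directly compositable.
#'
#' @param mesh Target [build_mesh] result.
#' @return List: `offset` (pixel coords of frame origin in mesh coords),
#'   `width`, `height`, `mask` (rasterised target polygon).
#' @export
target_frame <- function(mesh) {
  v <- mesh$polygon
  x0 <- floor(min(v[, 1])) - 2L
  y0 <- floor(min(v[, 2])) - 2L
  w <- ceiling(max(v[, 1])) + 2L - x0 + 1L
  h <- ceiling(max(v[, 2])) + 2L - y0 + 1L
  poly <- sweep(v, 2, c(x0, y0))
  list(offset = c(x0, y0), width = as.integer(w), height = as.integer(h),
       mask = rasterize_polygon(poly, as.integer(w), as.integer(h)))
}

#' Assign points to mesh faces
#'
#' @param mesh A [build_mesh] result.
#' @param pts n x 2 point matrix in mesh coordinates.
#' @return Integer vector of face indices (0 = in no face). Points on a
#'   shared edge go to the lower face index.
#' @export
assign_points_to_faces <- function(mesh, pts) {
  n <- nrow(pts)
  assigned <- integer(n)
  v <- mesh$vertices
  for (f in seq_len(nrow(mesh$faces))) {
    open <- assigned == 0L
    if (!any(open)) break
    tri <- v[mesh$faces[f, ], , drop = FALSE]
    cand <- open &
      pts[, 1] >= min(tri[, 1]) - 1e-9 & pts[, 1] <= max(tri[, 1]) + 1e-9 &
      pts[, 2] >= min(tri[, 2]) - 1e-9 & pts[, 2] <= max(tri[, 2]) + 1e-9
    if (!any(cand)) next
    hit <- points_in_triangle(pts[cand, , drop = FALSE], tri)
    assigned[which(cand)[hit]] <- f
  }
  assigned
}

#' Per-pixel face index map for a raster
#'
#' @param mesh A [build_mesh] result.
#' @param dims c(height, width) of the raster, in the mesh's own frame.
#' @return Integer matrix of face indices; 0 where the pixel lies outside
#'   every face.
#' @export
assign_pixels_to_faces <- function(mesh, dims) {
  h <- dims[1]; w <- dims[2]
  pts <- cbind(rep(0:(w - 1), each = h), rep(0:(h - 1), w))
  matrix(assign_points_to_faces(mesh, pts), h, w)
}

#' Gap-filling kernel
#'
#' Single pass over a frozen copy of the input: any zero pixel with at
#' least `min_neighbors` non-zero 8-connected neighbours is set to the mean
#' of those non-zero neighbours (hence to 1 for binary rasters). All other
#' pixels are unchanged.
#'
#' @param raster Numeric or logical matrix.
#' @param min_neighbors Minimum count of non-zero neighbours required to
#'   fill; default 4.
#' @param passes Number of passes; each pass reads the previous result.
#' @return Matrix of the same type semantics (logical in, logical out).
#' @export
fill_gaps <- function(raster, min_neighbors = 4, passes = 1) {
  was_logical <- is.logical(raster)
  r <- raster * 1
  for (p in seq_len(passes)) {
    h <- nrow(r); w <- ncol(r)
    pad <- matrix(0, h + 2, w + 2)
    pad[2:(h + 1), 2:(w + 1)] <- r
    nz_sum <- matrix(0, h, w)
    nz_cnt <- matrix(0, h, w)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      sh <- pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
      nz_sum <- nz_sum + sh
      nz_cnt <- nz_cnt + (sh != 0)
    }
    fill <- r == 0 & nz_cnt >= min_neighbors
    r[fill] <- nz_sum[fill] / nz_cnt[fill]
  }
  if (was_logical) r != 0 else r
}

#' Warp a binarised signal raster onto a target mesh
#'
#' For every ON pixel, the unique affine map sending its source face onto
#' the corresponding target face moves the pixel centre into the target
#' frame; nearest-pixel rasterisation, one pass of the gap filler, and a
#' clip to the target polygon follow. Degenerate (zero-area) source faces
#' contribute nothing, with a warning.
#'
#' @param source_mesh Mesh built on the source nucleus.
#' @param target_mesh Structurally equivalent mesh on the template shape.
#' @param binary Logical/0-1 matrix in the source nucleus frame.
#' @param pre_transform Optional affine `list(A, b)` applied to ON pixel
#'   coordinates before face lookup — pass the `transform` stored by
#'   [orient_nucleus] when `binary` lives in the unoriented frame.
#' @param frame Optional precomputed [target_frame] (shared across a run).
#' @param fill_passes Gap-filling passes (default 1).
#' @return Object of class `warped_signal`: `raster` (logical, target
#'   frame), `frame`, `source_nucleus`, `target_signature`.
#' @export
warp_signal <- function(source_mesh, target_mesh, binary,
                        pre_transform = NULL, frame = NULL,
                        fill_passes = 1, source_nucleus = "nucleus") {
  if (!mesh_isomorphic(source_mesh, target_mesh)) {
    stop("structural mismatch: source and target meshes are not isomorphic")
  }
  if (is.null(frame)) frame <- target_frame(target_mesh)
  out <- matrix(FALSE, frame$height, frame$width)
  on_idx <- which(binary != 0)
  if (length(on_idx) > 0) {
    h <- nrow(binary)
    pts <- cbind((on_idx - 1L) %/% h, (on_idx - 1L) %% h)  # (x, y)
    if (!is.null(pre_transform)) pts <- apply_affine(pre_transform, pts)
    fidx <- assign_points_to_faces(source_mesh, pts)
    vs <- source_mesh$vertices; vt <- target_mesh$vertices
    for (f in unique(fidx[fidx > 0])) {
      src <- vs[source_mesh$faces[f, ], , drop = FALSE]
      dst <- vt[target_mesh$faces[f, ], , drop = FALSE]
      if (abs(poly_signed_area(src)) < 1e-9) {
        warning("degenerate source face ", f, " skipped")
        next
      }
      tf <- affine_from_triangles(src, dst)
      mapped <- apply_affine(tf, pts[fidx == f, , drop = FALSE])
      xs <- round(mapped[, 1]) - frame$offset[1] + 1L
      ys <- round(mapped[, 2]) - frame$offset[2] + 1L
      ok <- xs >= 1 & xs <= frame$width & ys >= 1 & ys <= frame$height
      out[cbind(ys[ok], xs[ok])] <- TRUE
    }
    if (fill_passes > 0) out <- fill_gaps(out, passes = fill_passes)
    out <- out & frame$mask
  }
  structure(list(raster = out, frame = frame,
                 source_nucleus = source_nucleus,
                 target_signature = target_mesh$structure_signature),
            class = "warped_signal")
}

#' Composite map
#'
#' @param frequencies Matrix of per-pixel signal frequencies in \[0,1\].
#' @param n_nuclei Number of nuclei aggregated.
#' @param probe_label Probe name.
#' @param target_signature Structure signature of the template mesh.
#' @param validate_counts Check that frequency x n is integral.
#' @export
composite_map <- function(frequencies, n_nuclei, probe_label = "",
                          target_signature = "", validate_counts = TRUE) {
  if (any(frequencies < -1e-9 | frequencies > 1 + 1e-9)) {
    stop("frequencies must lie in [0,1]")
  }
  if (validate_counts &&
      any(abs(frequencies * n_nuclei - round(frequencies * n_nuclei)) > 1e-6)) {
    stop("frequencies x n_nuclei must be integral counts")
  }
  structure(list(frequencies = frequencies, n_nuclei = as.integer(n_nuclei),
                 probe_label = probe_label,
                 target_signature = target_signature),
            class = "composite_map")
}

#' @export
print.composite_map <- function(x, ...) {
  cat(sprintf("<composite_map> %s: %dx%d px, n=%d, max freq %.3f\n",
              x$probe_label, ncol(x$frequencies), nrow(x$frequencies),
              x$n_nuclei, max(x$frequencies)))
  invisible(x)
}

#' Aggregate warped signals into a composite map
#'
#' Per-pixel mean of the binary warped rasters: random mispositioned signal
#' averages out while consistent nuclear addresses reinforce.
#'
#' @param warps Non-empty list of [warp_signal] results sharing a template.
#' @param probe_label Probe name recorded on the composite.
#' @return A [composite_map].
#' @export
composite <- function(warps, probe_label = "") {
  if (length(warps) == 0) stop("cannot composite an empty list of warps")
  sig <- unique(vapply(warps, function(w) w$target_signature, character(1)))
  if (length(sig) != 1) stop("structural mismatch: warps have different templates")
  dims <- vapply(warps, function(w) dim(w$raster), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("structural mismatch: warp raster dimensions differ")
  }
  acc <- Reduce(`+`, lapply(warps, function(w) w$raster * 1))
  composite_map(acc / length(warps), n_nuclei = length(warps),
                probe_label = probe_label, target_signature = sig)
}
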