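# Consensus-shape construction and the structurally equivalent triangular
# mesh. Peripheral vertices are the landmarks plus a fixed number of
# arc-length-equidistant semi-landmarks per inter-landmark segment; internal
# vertices are chord midpoints of peripheral vertex pairs walked out from
# the hook tip; faces triangulate the bands between consecutive pairs plus
# the caps at tip and base. The mesh's graph structure depends only on the
# landmark/semi-landmark counts, never on geometry, which is what makes
# cross-nucleus (and cross-strain) warping well defined.

#' Consensus nuclear shape
#'
#' Pointwise arithmetic mean of oriented, per-segment-resampled outlines.
#' No Procrustes scaling is applied: nuclei are already rigidly oriented and
#' size differences are biological signal worth preserving.
#'
#' @param outlines List of oriented [nucleus_outline]s (see
#'   [orient_nucleus]), all with the same landmark structure.
#' @param landmark_sets List of [landmark_set]s parallel to `outlines`.
#' @param points_per_segment Number of resampled points per inter-landmark
#'   segment used for averaging.
#' @return Object of class `consensus_shape`: `boundary`, `landmarks`
#'   (a [landmark_set] on the consensus boundary), `n_contributing`, `mpp`.
#' @export
build_consensus <- function(outlines, landmark_sets,
                            points_per_segment = 100) {
  if (length(outlines) < 1) stop("need at least one outline")
  nlm <- vapply(landmark_sets, function(l) length(l$indices), integer(1))
  if (length(unique(nlm)) != 1 ||
      length(unique(vapply(landmark_sets, function(l)
        paste(sort(names(l$indices)), collapse = ","), character(1)))) != 1) {
    stop("structural mismatch: outlines have different landmark structures")
  }
  res <- lapply(seq_along(outlines), function(i) {
    resample_by_segments(outlines[[i]]$boundary, landmark_sets[[i]],
                         points_per_segment)
  })
  pts <- Reduce(`+`, lapply(res, function(r) r$points)) / length(res)
  shift <- c(2, 2) - c(min(pts[, 1]), min(pts[, 2]))
  pts <- sweep(pts, 2, shift, "+")
  structure(list(boundary = pts,
                 landmarks = landmark_set(res[[1]]$landmark_idx, nrow(pts)),
                 n_contributing = length(outlines),
                 mpp = outlines[[1]]$mpp),
            class = "consensus_shape")
}

#' @export
print.consensus_shape <- function(x, ...) {
  cat(sprintf("<consensus_shape> %d boundary pts, %d landmarks, n=%d\n",
              nrow(x$boundary), length(x$landmarks$indices), x$n_contributing))
  invisible(x)
}

# Resample each inter-landmark segment (in boundary traversal order starting
# at hook_tip) to `k` arc-equidistant points; segment joins are the
# landmarks. Returns the stacked points and the landmark indices therein.
resample_by_segments <- function(boundary, lms, k) {
  n <- nrow(boundary)
  idx <- lms$indices
  ord <- order((idx - idx[["hook_tip"]]) %% n)
  idx <- idx[ord]
  m <- length(idx)
  pts_list <- vector("list", m)
  for (s in seq_len(m)) {
    from <- idx[[s]]
    to <- idx[[if (s == m) 1 else s + 1]]
    # exactly one segment wraps past the end of the boundary index range
    seg_idx <- if (from < to) from:to else c(from:n, 1:to)
    seg <- boundary[seg_idx, , drop = FALSE]
    pts_list[[s]] <- resample_polyline(seg, k + 1)[seq_len(k), , drop = FALSE]
  }
  pts <- do.call(rbind, pts_list)
  lm_idx <- stats::setNames(as.integer(1 + (seq_len(m) - 1) * k), names(idx))
  list(points = pts, landmark_idx = lm_idx)
}

#' Build the structural mesh on a boundary
#'
#' Peripheral vertices are the landmarks plus `semilandmarks_per_segment`
#' arc-length-equidistant semi-landmarks on each inter-landmark segment.
#' Walking out pairwise from the hook tip, the i-th vertex along the dorsal
#' side is paired with the i-th vertex along the ventral side and each pair
#' contributes one internal vertex at its chord midpoint. Faces are the two
#' tip-cap triangles, two quads per band (each split along the diagonal
#' toward the tip-ward internal vertex) and a fan over the base cap. When
#' side counts differ the excess basal vertices join the base fan.
#'
#' @param boundary Closed polygon (n x 2), or a [consensus_shape] /
#'   [nucleus_outline] (in which case `landmarks` may be omitted for a
#'   consensus).
#' @param landmarks A [landmark_set] on that boundary.
#' @param semilandmarks_per_segment Semi-landmark count per segment
#'   (scalar, recycled). Must be >= 1.
#' @return Object of class `nucleus_mesh`: `vertices` (V x 2),
#'   `faces` (F x 3 vertex indices, positively oriented),
#'   `peripheral_idx`, `internal_idx`, `polygon` (peripheral polygon),
#'   `structure_signature`.
#' @export
build_mesh <- function(boundary, landmarks = NULL,
                       semilandmarks_per_segment = 20) {
  if (inherits(boundary, "consensus_shape")) {
    landmarks <- boundary$landmarks
    boundary <- boundary$boundary
  } else if (inherits(boundary, "nucleus_outline")) {
    boundary <- boundary$boundary
  }
  if (is.null(landmarks)) stop("landmarks required")
  k <- semilandmarks_per_segment
  if (any(k < 1)) stop("each segment needs at least one semi-landmark")
  n <- nrow(boundary)
  idx <- landmarks$indices
  ordn <- order((idx - idx[["hook_tip"]]) %% n)
  idx <- idx[ordn]
  m <- length(idx)
  k <- rep_len(k, m)

  peripheral <- NULL
  lm_pos <- integer(m)
  for (s in seq_len(m)) {
    from <- idx[[s]]
    to <- idx[[if (s == m) 1 else s + 1]]
    seg_idx <- if (from < to) from:to else c(from:n, 1:to)
    seg <- boundary[seg_idx, , drop = FALSE]
    rs <- resample_polyline(seg, k[s] + 2)
    lm_pos[s] <- if (is.null(peripheral)) 1L else nrow(peripheral) + 1L
    peripheral <- rbind(peripheral, rs[seq_len(k[s] + 1), , drop = FALSE])
  }
  P <- nrow(peripheral)
  tip <- 1L
  base <- lm_pos[which(names(idx) == "tail_attachment")]

  dorsal <- if (base > 2) 2:(base - 1) else integer(0)
  ventral <- if (base < P) rev((base + 1):P) else integer(0)
  p <- length(dorsal); q <- length(ventral)
  npair <- min(p, q)
  if (npair < 1) stop("mesh degenerate: no peripheral pairs")

  internal <- (peripheral[dorsal[seq_len(npair)], , drop = FALSE] +
               peripheral[ventral[seq_len(npair)], , drop = FALSE]) / 2
  inside <- points_in_polygon(internal, peripheral)
  if (!all(inside)) {
    stop(structure(class = c("nc_degenerate_mesh", "error", "condition"),
                   list(message = "chord midpoint falls outside polygon; mesh degenerate",
                        call = sys.call(-1))))
  }
  vertices <- rbind(peripheral, internal)
  I <- P + seq_len(npair)

  faces <- list()
  add <- function(a, b, c) faces[[length(faces) + 1L]] <<- c(a, b, c)
  # tip cap
  add(I[1], ventral[1], tip)
  add(I[1], tip, dorsal[1])
  # bands
  if (npair > 1) {
    for (i in seq_len(npair - 1)) {
      add(dorsal[i], dorsal[i + 1], I[i])
      add(dorsal[i + 1], I[i + 1], I[i])
      add(ventral[i], ventral[i + 1], I[i])
      add(ventral[i + 1], I[i + 1], I[i])
    }
  }
  # base fan: peripheral chain from last paired dorsal vertex through the
  # base vertex to the last paired ventral vertex, fanned around the last
  # internal vertex (absorbs any unpaired excess on either side)
  chain <- dorsal[npair]:ventral[npair]
  for (j in seq_len(length(chain) - 1)) add(I[npair], chain[j], chain[j + 1])

  faces <- do.call(rbind, faces)
  # orient all faces positively
  for (f in seq_len(nrow(faces))) {
    tri <- vertices[faces[f, ], , drop = FALSE]
    a <- poly_signed_area(tri)
    if (abs(a) < 1e-9) {
      warning("zero-area face ", f, " in mesh")
    } else if (a < 0) {
      faces[f, ] <- faces[f, c(1, 3, 2)]
    }
  }
  sig <- sprintf("L%d|S%s|P%d,%d", m, paste(k, collapse = ","), p, q)
  structure(list(vertices = vertices, faces = faces,
                 peripheral_idx = seq_len(P), internal_idx = I,
                 tip = tip, base = base,
                 polygon = peripheral,
                 structure_signature = sig),
            class = "nucleus_mesh")
}

#' @export
print.nucleus_mesh <- function(x, ...) {
  cat(sprintf("<nucleus_mesh> %d vertices (%d peripheral), %d faces, sig=%s\n",
              nrow(x$vertices), length(x$peripheral_idx), nrow(x$faces),
              x$structure_signature))
  invisible(x)
}

#' Are two meshes structurally equivalent?
#'
#' True iff the structure signatures match, i.e. same landmark count, same
#' semi-landmark counts per segment and hence identical face connectivity.
#' Geometry plays no role, so any nucleus can be warped onto any template
#' built with the same counts.
#'
#' @param a,b [build_mesh] results.
#' @export
mesh_isomorphic <- function(a, b) {
  identical(a$structure_signature, b$structure_signature)
}

#' Total overlap area between distinct mesh faces
#'
#' Quality-control helper: sums the pairwise intersection areas of all face
#' pairs whose bounding boxes overlap (shared edges have zero area and do
#' not count). A valid mesh returns 0 up to floating-point noise.
#'
#' @param mesh A [build_mesh] result.
#' @export
mesh_overlap_area <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  v <- mesh$vertices
  bb <- t(vapply(seq_len(nf), function(i) {
    tri <- v[f[i, ], ]
    c(min(tri[, 1]), max(tri[, 1]), min(tri[, 2]), max(tri[, 2]))
  }, numeric(4)))
  total <- 0
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      if (bb[i, 2] < bb[j, 1] || bb[j, 2] < bb[i, 1] ||
          bb[i, 4] < bb[j, 3] || bb[j, 4] < bb[i, 3]) next
      total <- total + triangle_intersection_area(v[f[i, ], ], v[f[j, ], ])
    }
  }
  total
}

#' Export a mesh as JSON or OFF
#'
#' @param mesh A [build_mesh] result.
#' @param path Output path; format chosen by extension (`.json` or `.off`).
#' @export
export_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(list(vertices = mesh$vertices, faces = mesh$faces,
                              signature = mesh$structure_signature),
                         path, digits = NA)
  } else if (ext == "off") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
    writeLines(sprintf("%.6f %.6f 0", mesh$vertices[, 1], mesh$vertices[, 2]), con)
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  } else {
    stop("unsupported mesh format: ", ext)
  }
  invisible(path)
}

#' Read a mesh written by [export_mesh] (JSON form)
#' @param path JSON mesh path.
#' @export
read_mesh <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(vertices = j$vertices, faces = j$faces,
                 peripheral_idx = NULL, internal_idx = NULL,
                 polygon = NULL, structure_signature = j$signature),
            class = "nucleus_mesh")
}
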