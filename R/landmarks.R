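# Landmark discovery on nucleus outlines. The curvature functional is a
# windowed interior angle: at each boundary point the angle subtended by the
# points half a window behind and ahead, assigned to the interior side by
# testing the chord midpoint against the nucleus mask. Sharp convex
# protrusions (the apical hook tip, the tail attachment point) appear as
# deep minima of this profile.

#' Windowed interior-angle profile of an outline
#'
#' @param outline A [nucleus_outline].
#' @param window_fraction Fraction of the perimeter used as the sliding
#'   window (half ahead, half behind); must lie in (0, 0.5). The default 5%
#'   suppresses pixel-level boundary noise while preserving landmark minima.
#' @return Object of class `angle_profile`: `values` (degrees, one per
#'   boundary point, cyclic), `window_fraction`, `index_zero`.
#' @export
compute_angle_profile <- function(outline, window_fraction = 0.05) {
  if (window_fraction <= 0 || window_fraction >= 0.5) {
    stop("configuration error: window_fraction must be in (0, 0.5)")
  }
  b <- outline$boundary
  n <- nrow(b)
  w <- max(1L, round(window_fraction * n))
  if (n < 3 / window_fraction && n < 3 * w) stop("boundary too short for window")
  ia <- ((seq_len(n) - 1L - w) %% n) + 1L
  ic <- ((seq_len(n) - 1L + w) %% n) + 1L
  v1 <- b[ia, , drop = FALSE] - b
  v2 <- b[ic, , drop = FALSE] - b
  dot <- rowSums(v1 * v2)
  nrm <- sqrt(rowSums(v1^2) * rowSums(v2^2))
  raw <- acos(pmin(1, pmax(-1, dot / pmax(nrm, 1e-12)))) * 180 / pi
  # interior side: is the chord midpoint (pulled slightly toward the vertex)
  # inside the boundary polygon? Exact test; on-boundary counts as inside,
  # which resolves the collinear (raw = 180) case either way.
  mid <- (b[ia, , drop = FALSE] + b[ic, , drop = FALSE]) / 2
  test <- b + 0.8 * (mid - b)
  inside <- points_in_polygon(test, b)
  vals <- ifelse(inside, raw, 360 - raw)
  structure(list(values = vals, window_fraction = window_fraction,
                 index_zero = 1L),
            class = "angle_profile")
}

points_in_mask <- function(mask, pts) {
  r <- round(pts[, 2]) + 1L
  c <- round(pts[, 1]) + 1L
  ok <- r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask)
  res <- rep(FALSE, nrow(pts))
  res[ok] <- mask[cbind(r[ok], c[ok])]
  res
}

#' Landmark set
#'
#' Named boundary indices. `hook_tip` and `tail_attachment` are required;
#' auxiliary curvature extrema are named `aux1`, `aux2`, ... in arc order
#' from the hook tip.
#'
#' @param indices Named integer vector of boundary indices.
#' @param n_boundary Boundary length the indices refer to.
#' @export
landmark_set <- function(indices, n_boundary) {
  if (!all(c("hook_tip", "tail_attachment") %in% names(indices))) {
    stop("hook_tip and tail_attachment are required landmarks")
  }
  if (anyDuplicated(indices)) stop("landmark indices must be distinct")
  if (any(indices < 1 | indices > n_boundary)) stop("landmark index out of range")
  structure(list(indices = indices, n_boundary = as.integer(n_boundary)),
            class = "landmark_set")
}

#' Landmark detection parameters
#'
#' @param hook_angle_max Maximum windowed interior angle (degrees) for the
#'   hook tip; profiles whose global minimum is blunter than this mark the
#'   nucleus unanalyzable (e.g. circles or heavily over-swelled nuclei).
#' @param tail_angle_max Same ceiling for the tail-attachment minimum.
#' @param min_tail_arc Minimum arc separation (fraction of perimeter)
#'   between hook tip and tail attachment.
#' @param n_auxiliary Number of auxiliary curvature extrema to record.
#'   Swelled nuclei present few reliable extrema, so the default is 0.
#' @param min_aux_arc Minimum arc separation between auxiliary landmarks
#'   and any previously placed landmark.
#' @export
landmark_params <- function(hook_angle_max = 150, tail_angle_max = 170,
                            min_tail_arc = 0.25, n_auxiliary = 0,
                            min_aux_arc = 0.10) {
  list(hook_angle_max = hook_angle_max, tail_angle_max = tail_angle_max,
       min_tail_arc = min_tail_arc, n_auxiliary = n_auxiliary,
       min_aux_arc = min_aux_arc)
}

cyclic_arc_dist <- function(cum, per, i, j) {
  d <- abs(cum[i] - cum[j])
  pmin(d, per - d)
}

local_minima_cyclic <- function(v, w) {
  n <- length(v)
  is_min <- rep(TRUE, n)
  for (k in seq_len(w)) {
    fwd <- c(v[(k + 1):n], v[1:k])
    bwd <- c(v[(n - k + 1):n], v[1:(n - k)])
    is_min <- is_min & (v <= fwd) & (v <= bwd)
  }
  which(is_min)
}

#' Detect named landmarks on an angle profile
#'
#' The hook tip is the global minimum of the interior-angle profile (the
#' sharpest convex protrusion). The tail attachment is the lowest-angle
#' remaining local minimum at least `min_tail_arc` of the perimeter away
#' from the hook tip. Further local extrema become auxiliary landmarks.
#' Equal-angle ties are broken toward the smallest boundary index after the
#' hook tip, so detection is deterministic.
#'
#' @param profile An [compute_angle_profile] result for `outline`.
#' @param outline The [nucleus_outline] the profile was computed from.
#' @param params A [landmark_params] list.
#' @return A [landmark_set], or an error of class `nc_unanalyzable` when the
#'   outline lacks the required distinct extrema.
#' @export
detect_landmarks <- function(profile, outline, params = landmark_params()) {
  v <- profile$values
  n <- length(v)
  if (n != nrow(outline$boundary)) stop("profile does not match outline")
  arc <- poly_arclength(outline$boundary)
  w <- max(2L, round(profile$window_fraction * n))
  hook <- which.min(v)  # which.min takes the first (smallest index) on ties
  if (v[hook] > params$hook_angle_max) {
    stop(structure(class = c("nc_unanalyzable", "error", "condition"),
                   list(message = "no distinct hook-tip extremum; nucleus unanalyzable",
                        call = sys.call(-1))))
  }
  mins <- local_minima_cyclic(v, w)
  mins <- mins[mins != hook]
  cand <- mins[cyclic_arc_dist(arc$cum, arc$perimeter, mins, hook) >
                 params$min_tail_arc * arc$perimeter]
  cand <- cand[v[cand] <= params$tail_angle_max]
  if (length(cand) == 0) {
    stop(structure(class = c("nc_unanalyzable", "error", "condition"),
                   list(message = "no tail-attachment extremum; nucleus unanalyzable",
                        call = sys.call(-1))))
  }
  # order by angle, then by index measured forward from the hook tip
  after <- ((cand - hook) %% n)
  cand <- cand[order(v[cand], after)]
  tail_idx <- cand[1]
  chosen <- c(hook_tip = hook, tail_attachment = tail_idx)
  if (params$n_auxiliary > 0) {
    pool <- mins[!mins %in% chosen]
    pool <- pool[order(v[pool], (pool - hook) %% n)]
    for (p in pool) {
      if (length(chosen) >= 2 + params$n_auxiliary) break
      if (all(cyclic_arc_dist(arc$cum, arc$perimeter, p, chosen) >
              params$min_aux_arc * arc$perimeter)) {
        chosen <- c(chosen, stats::setNames(p, paste0("aux", length(chosen) - 1)))
      }
    }
    if (length(chosen) < 2 + params$n_auxiliary) {
      stop(structure(class = c("nc_unanalyzable", "error", "condition"),
                     list(message = "fewer distinct extrema than requested landmarks",
                          call = sys.call(-1))))
    }
  }
  landmark_set(chosen, n)
}

#' Orient a nucleus into the canonical pose
#'
#' Rotates the outline so the hook-tip to tail-attachment chord is
#' horizontal with the hook on the left, mirrors it if needed so the hook
#' curves upward (dorsal side up, i.e. toward smaller y in the pixel frame),
#' translates it into a tight non-negative frame, and re-indexes the
#' boundary to start at the hook tip and traverse the dorsal side first.
#' The applied affine map is stored in the `transform` field so signal
#' rasters in the original frame can be carried along exactly.
#'
#' Orientation is idempotent: applying it to an already oriented nucleus
#' only re-indexes the boundary.
#'
#' @param outline A [nucleus_outline].
#' @param landmarks Its [landmark_set].
#' @return List with elements `outline` (oriented [nucleus_outline], with
#'   `transform` = list(A, b) mapping original local coords to oriented
#'   coords), `landmarks` (re-indexed [landmark_set]).
#' @export
orient_nucleus <- function(outline, landmarks) {
  b <- outline$boundary
  n <- nrow(b)
  hook <- landmarks$indices[["hook_tip"]]
  tail <- landmarks$indices[["tail_attachment"]]
  chord <- b[tail, ] - b[hook, ]
  theta <- atan2(chord[2], chord[1])
  R <- rot2(-theta)
  tf <- list(A = R, b = as.numeric(-R %*% b[hook, ]))
  bb <- apply_affine(tf, b)
  # mirror so the nucleus body (polygon centroid) lies above the chord
  # (smaller y = visually up): the crescent arcs dorsally over the
  # hook-to-tail chord, with the hook curling up at the left
  cen <- poly_centroid(bb)
  flipped <- cen[2] > 0
  if (flipped) {
    Fm <- matrix(c(1, 0, 0, -1), 2, 2)
    tf <- compose_affine(list(A = Fm, b = c(0, 0)), tf)
    bb <- apply_affine(tf, b)
  }
  # translate into a non-negative frame with a 2 px margin
  shift <- c(2, 2) - c(min(bb[, 1]), min(bb[, 2]))
  tf <- compose_affine(list(A = diag(2), b = shift), tf)
  bb <- apply_affine(tf, b)
  # re-index from the hook tip; dorsal side (smaller mean y than the chord,
  # i.e. the side the hook curls toward) is traversed first
  ord <- c(hook:n, if (hook > 1) 1:(hook - 1))
  bb <- bb[ord, , drop = FALSE]
  tail_new <- ((tail - hook) %% n) + 1L
  first_half <- bb[seq(2, max(2, tail_new - 1)), , drop = FALSE]
  chord_y <- (bb[1, 2] + bb[tail_new, 2]) / 2
  if (mean(first_half[, 2]) > chord_y) {
    bb <- bb[c(1, n:2), , drop = FALSE]
    tail_new <- n - tail_new + 2L
  }
  out <- nucleus_outline(bb, mpp = outline$mpp, offset = outline$offset,
                         id = outline$id, source = outline$source,
                         flipped = xor(outline$flipped, flipped))
  out$transform <- tf
  new_idx <- c(hook_tip = 1L, tail_attachment = as.integer(tail_new))
  aux <- setdiff(names(landmarks$indices), c("hook_tip", "tail_attachment"))
  if (length(aux) > 0) {
    # recover auxiliary positions by nearest boundary point after transform
    for (a in aux) {
      p <- apply_affine(tf, b[landmarks$indices[[a]], , drop = FALSE])
      d2 <- rowSums(sweep(bb, 2, as.numeric(p))^2)
      new_idx[[a]] <- which.min(d2)
    }
  }
  list(outline = out, landmarks = landmark_set(new_idx, n))
}
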