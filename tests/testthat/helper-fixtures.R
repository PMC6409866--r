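# Shared fixtures, all generated in code.

# Discretised circle outline (constant curvature; no landmarks).
circle_outline <- function(n = 360, r = 50, mpp = 0.1) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  nucleus_outline(cbind(r + 4 + r * cos(t), r + 4 + r * sin(t)), mpp = mpp)
}

# Axis-aligned square outline sampled at ~1 px spacing.
square_outline <- function(side = 40, mpp = 0.1) {
  s <- seq(0, side - 1)
  b <- rbind(cbind(4 + s, 4),
             cbind(4 + side, 4 + s),
             cbind(4 + side - s, 4 + side),
             cbind(4, 4 + side - s))
  nucleus_outline(b, mpp = mpp)
}

# Rigidly transform an outline (rotation about centroid, optional mirror,
# shift back into a positive frame); returns a fresh nucleus_outline.
transform_outline <- function(o, theta = 0, mirror = FALSE, shift = c(0, 0)) {
  b <- o$boundary
  ctr <- colMeans(b)
  M <- nucleocarta:::rot2(theta)
  if (mirror) M <- M %*% matrix(c(-1, 0, 0, 1), 2, 2)
  b2 <- sweep(sweep(b, 2, ctr) %*% t(M), 2, ctr + shift, "+")
  b2 <- sweep(b2, 2, c(4, 4) - c(min(b2[, 1]), min(b2[, 2])), "+")
  nucleus_outline(b2, mpp = o$mpp)
}

# Arc distance (fraction of perimeter) between a boundary index and the
# boundary point nearest to a query point.
arc_frac_to_point <- function(b, i, q) {
  a <- cumsum(c(0, sqrt(rowSums(diff(rbind(b, b[1, ]))^2))))
  per <- a[length(a)]
  qi <- which.min(rowSums(sweep(b, 2, as.numeric(q))^2))
  d <- abs(a[i] - a[qi]) / per
  min(d, 1 - d)
}

# Landmark detection shorthand.
find_landmarks <- function(o, wf = 0.05, ...) {
  detect_landmarks(compute_angle_profile(o, wf), o, landmark_params(...))
}

# A small two-probe population: X/Y-style dorsal-apical batch and
# 11/19-style ventral-basal batch, same strain shape.
two_batch_population <- function(n_per_batch, seed, placement_noise = 0.05,
                                 params = falciform_params()) {
  strains <- list(
    list(params = params,
         signals = list(
           planted_signal("chrX", "dorsal_apical", placement_noise = placement_noise),
           planted_signal("chrY", "dorsal_apical", placement_noise = placement_noise))),
    list(params = params,
         signals = list(
           planted_signal("chr11", "ventral_basal", placement_noise = placement_noise),
           planted_signal("chr19", "ventral_basal", placement_noise = placement_noise))))
  generate_population(strains, n_per_strain = n_per_batch, seed = seed)
}
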