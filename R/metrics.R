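# Signal detection, centre-of-mass distances, MS-SSIM* similarity scoring
# and the population-level statistics built on them.

#' Detect discrete FISH signals in a nucleus
#'
#' Thresholds the channel within the nucleus mask, labels 8-connected
#' components, discards components below the minimum area, and returns each
#' surviving component with its intensity-weighted centre of mass.
#'
#' @param channel Integer matrix (or [channel_raster]) of signal intensity.
#' @param mask Logical nucleus mask, same dimensions.
#' @param method Threshold spec as in [binarise_signal]; the default takes
#'   half of the in-mask maximum, in the spirit of fraction-of-peak signal
#'   segmentation.
#' @param min_area_um2 Minimum signal area; sub-resolution specks are noise.
#' @param mpp Microns per pixel.
#' @param probe_label,nucleus_id Metadata attached to each detection.
#' @return List of `signal_detection` objects: `component_pixels` (n x 2
#'   matrix of x, y), `centre_of_mass`, `area_um2`, `probe_label`,
#'   `nucleus_id`.
#' @export
detect_signals <- function(channel, mask, method = "fraction:0.5",
                           min_area_um2 = 0.3, mpp,
                           probe_label = "", nucleus_id = "") {
  if (inherits(channel, "channel_raster")) channel <- channel$pixels
  bin <- binarise_signal(channel, mask, method)
  lab <- label_components(bin, connectivity = 8)
  ncomp <- max(lab)
  if (ncomp == 0) return(list())
  h <- nrow(bin)
  out <- list()
  for (k in seq_len(ncomp)) {
    idx <- which(lab == k)
    area <- length(idx) * mpp^2
    if (area < min_area_um2) next
    x <- (idx - 1L) %/% h
    y <- (idx - 1L) %% h
    wgt <- as.numeric(channel[idx])
    if (sum(wgt) <= 0) wgt <- rep(1, length(idx))
    com <- c(sum(x * wgt), sum(y * wgt)) / sum(wgt)
    out[[length(out) + 1L]] <- structure(
      list(component_pixels = cbind(x = x, y = y), centre_of_mass = com,
           area_um2 = area, probe_label = probe_label, nucleus_id = nucleus_id),
      class = "signal_detection")
  }
  out
}

#' Centre-of-mass distance between two co-hybridised signals
#'
#' @param a,b `signal_detection` objects from the same nucleus.
#' @param cal A [calibration].
#' @return Object of class `pairwise_distance`: `nucleus_id`, `probe_pair`,
#'   `distance_um`.
#' @export
com_distance <- function(a, b, cal) {
  if (!identical(a$nucleus_id, b$nucleus_id)) {
    stop("contract violation: signals come from different nuclei")
  }
  d <- sqrt(sum((a$centre_of_mass - b$centre_of_mass)^2)) * cal$microns_per_pixel
  structure(list(nucleus_id = a$nucleus_id,
                 probe_pair = c(a$probe_label, b$probe_label),
                 distance_um = d),
            class = "pairwise_distance")
}

gaussian_kernel_1d <- function(size = 11, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Valid-mode separable convolution via banded matrices: for an h x w image
# and window n, returns an (h-n+1) x (w-n+1) matrix of window means.
conv_valid <- function(img, k) {
  n <- length(k)
  h <- nrow(img); w <- ncol(img)
  if (h < n || w < n) stop("image smaller than filter window")
  Rm <- matrix(0, h - n + 1, h)
  for (i in seq_len(h - n + 1)) Rm[i, i:(i + n - 1)] <- k
  Cm <- matrix(0, w, w - n + 1)
  for (i in seq_len(w - n + 1)) Cm[i:(i + n - 1), i] <- k
  Rm %*% img %*% Cm
}

downsample2 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  if (h %% 2 == 1) img <- rbind(img, img[h, ])
  if (w %% 2 == 1) img <- cbind(img, img[, w])
  h2 <- nrow(img) / 2; w2 <- ncol(img) / 2
  (img[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2)] +
   img[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2)] +
   img[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2)] +
   img[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2)]) / 4
}

#' Multi-scale structural similarity (MS-SSIM*)
#'
#' Standard multi-scale SSIM: contrast/structure terms are computed on
#' progressively low-pass downsampled image pairs, the luminance term at the
#' coarsest scale only, and the terms are combined as a weighted geometric
#' product with the canonical five-scale exponents. The `*` refinement
#' concerns windows where both images have zero variance and equal means
#' (ubiquitous in binarised or composited FISH rasters, whose backgrounds
#' are exactly constant): such windows contribute a component value of 1
#' rather than an indeterminate 0/0.
#'
#' Identical images score exactly 1; the result is clamped to \[0,1\].
#'
#' @param a,b Numeric matrices of equal dimensions (any common intensity
#'   scale; the dynamic range is taken as the maximum over the pair).
#' @param scales Requested number of scales (default 5). If the images
#'   cannot support the 11x11 window at the smallest scale the count is
#'   reduced with a warning, and the retained exponents are renormalised.
#' @param weights Per-scale exponents.
#' @param K Stabilising constants `c(K1, K2)`.
#' @param window,sigma Gaussian window size and width.
#' @return Object of class `similarity_score`: `value`, `scales_used`,
#'   `weights`.
#' @export
ms_ssim <- function(a, b, scales = 5,
                    weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333),
                    K = c(0.01, 0.03), window = 11, sigma = 1.5) {
  if (inherits(a, "composite_map")) a <- a$frequencies
  if (inherits(b, "composite_map")) b <- b$frequencies
  a <- a * 1; b <- b * 1
  if (!all(dim(a) == dim(b))) stop("image dimensions differ")
  L <- max(a, b)
  if (L <= 0) {
    # both images identically zero: zero variance, equal means -> identical
    return(structure(list(value = 1, scales_used = 0L, weights = numeric(0)),
                     class = "similarity_score"))
  }
  max_scales <- floor(log2(min(dim(a)) / window)) + 1
  if (max_scales < 1) stop("image too small for an 11x11 window")
  M <- min(scales, max_scales)
  if (M < scales) {
    warning(sprintf("image supports only %d of %d requested scales", M, scales))
  }
  wts <- weights[seq_len(M)]
  if (M < length(weights)) wts <- wts / sum(wts)
  C1 <- (K[1] * L)^2
  C2 <- (K[2] * L)^2
  k <- gaussian_kernel_1d(window, sigma)
  eps <- 1e-12
  val <- 1
  for (s in seq_len(M)) {
    mu_a <- conv_valid(a, k); mu_b <- conv_valid(b, k)
    var_a <- conv_valid(a * a, k) - mu_a^2
    var_b <- conv_valid(b * b, k) - mu_b^2
    cov_ab <- conv_valid(a * b, k) - mu_a * mu_b
    num <- 2 * cov_ab + C2
    den <- var_a + var_b + C2
    cs <- ifelse(abs(den) < eps,
                 ifelse(var_a < eps & var_b < eps & abs(mu_a - mu_b) < eps, 1, 0),
                 num / den)
    if (s == M) {
      lnum <- 2 * mu_a * mu_b + C1
      lden <- mu_a^2 + mu_b^2 + C1
      lum <- ifelse(abs(lden) < eps, 1, lnum / lden)
      val <- val * max(0, mean(lum))^wts[s] * max(0, mean(cs))^wts[s]
    } else {
      val <- val * max(0, mean(cs))^wts[s]
      a <- downsample2(a); b <- downsample2(b)
    }
  }
  structure(list(value = min(1, max(0, val)), scales_used = M, weights = wts),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("<similarity_score> %.4f (%d scales)\n", x$value, x$scales_used))
  invisible(x)
}

#' Compare two sets of centre-of-mass distances
#'
#' Two-sided Wilcoxon rank sum test on the distance values, as used for the
#' per-nucleus colocalisation comparisons.
#'
#' @param d1,d2 Lists of `pairwise_distance` objects, or numeric vectors of
#'   distances. Each group needs at least 3 values.
#' @return List: `n1`, `n2`, `median1`, `median2`, `statistic`, `p_value`.
#' @export
compare_distance_sets <- function(d1, d2) {
  x <- distances_as_numeric(d1)
  y <- distances_as_numeric(d2)
  if (length(x) < 3 || length(y) < 3) {
    stop("refusing to test: need at least 3 distances per group")
  }
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                           correct = TRUE)
  list(n1 = length(x), n2 = length(y),
       median1 = stats::median(x), median2 = stats::median(y),
       statistic = unname(wt$statistic), p_value = wt$p.value)
}

distances_as_numeric <- function(d) {
  if (is.numeric(d)) return(d)
  vapply(d, function(z) z$distance_um, numeric(1))
}

#' Pairwise MS-SSIM* matrix over composite maps
#'
#' All composites must share a template (cross-strain comparisons require
#' warping every population onto one template first).
#'
#' @param composites Named list of [composite_map]s (names become labels),
#'   or unnamed (probe labels are used).
#' @param ... Passed to [ms_ssim].
#' @return Labelled symmetric numeric matrix with unit diagonal.
#' @export
similarity_matrix <- function(composites, ...) {
  n <- length(composites)
  sig <- unique(vapply(composites, function(cm) cm$target_signature, character(1)))
  if (length(sig) != 1) stop("structural mismatch: composites from different templates")
  dims <- vapply(composites, function(cm) dim(cm$frequencies), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("structural mismatch: composite dimensions differ")
  }
  labels <- names(composites)
  if (is.null(labels)) {
    labels <- vapply(composites, function(cm) cm$probe_label, character(1))
  }
  m <- diag(1, n)
  dimnames(m) <- list(labels, labels)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- ms_ssim(composites[[i]]$frequencies, composites[[j]]$frequencies, ...)$value
        m[i, j] <- s
        m[j, i] <- s
      }
    }
  }
  m
}
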