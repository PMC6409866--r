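test_that("MS-SSIM* scores identical images as exactly 1", {
  set.seed(21)
  rasters <- list(
    matrix(0.4, 96, 96),
    matrix(runif(96 * 96), 96, 96),
    outer(1:96, 1:96, function(i, j) exp(-((i - 30)^2 + (j - 60)^2) / 50)))
  for (x in rasters) {
    expect_identical(suppressWarnings(ms_ssim(x, x))$value, 1)
  }
  # binary and all-zero rasters too
  b <- matrix(FALSE, 64, 64); b[20:25, 30:40] <- TRUE
  expect_identical(suppressWarnings(ms_ssim(b, b))$value, 1)
  expect_identical(ms_ssim(matrix(0, 48, 48), matrix(0, 48, 48))$value, 1)
})

test_that("MS-SSIM* is symmetric, bounded, and scale-adaptive", {
  set.seed(22)
  for (rep in 1:5) {
    a <- matrix(runif(60 * 60), 60, 60)
    b <- matrix(runif(60 * 60), 60, 60)
    sab <- suppressWarnings(ms_ssim(a, b))
    sba <- suppressWarnings(ms_ssim(b, a))
    expect_equal(sab$value, sba$value)
    expect_gte(sab$value, 0)
    expect_lte(sab$value, 1)
  }
  # 60 px supports 3 of the 5 canonical scales
  expect_warning(s <- ms_ssim(matrix(runif(3600), 60, 60),
                              matrix(runif(3600), 60, 60)),
                 "scales")
  expect_equal(s$scales_used, 3)
  expect_error(ms_ssim(matrix(0, 8, 8), matrix(0, 8, 9)), "differ")
  expect_error(ms_ssim(matrix(1, 8, 8), matrix(0, 8, 8)), "small")
})

test_that("similar signal distributions outscore dissimilar ones", {
  # two disjoint halves of one population vs a different nuclear address
  pop <- two_batch_population(24, seed = 61, placement_noise = 0)
  rec <- detect_and_orient(pop$fields)
  res <- warp_population(rec, pop$fields, pop$probe_map)
  same_addr <- suppressWarnings(ms_ssim(res$composites$chrX, res$composites$chrY))$value
  diff_addr <- suppressWarnings(ms_ssim(res$composites$chrX, res$composites$chr19))$value
  expect_gt(same_addr, diff_addr)
})

test_that("signal detection recovers planted blobs with weighted centroids", {
  nuc <- generate_nucleus(falciform_params(), seed = 17)
  sig <- plant_signals(nuc, list(planted_signal("p", "centre",
                                                address_jitter = 0)),
                       seed = 170)
  dets <- detect_signals(sig$channels[[1]], nuc$outline$mask,
                         mpp = 0.1, probe_label = "p", nucleus_id = "n1")
  expect_length(dets, 1)
  expect_lt(sqrt(sum((dets[[1]]$centre_of_mass - sig$truth$p$centre)^2)), 1)
  # min-area filter drops specks
  chan <- sig$channels[[1]]$pixels
  chan[5, 5] <- 255L  # single bright pixel outside... inside frame, tiny area
  dets2 <- detect_signals(chan, nuc$outline$mask, mpp = 0.1,
                          min_area_um2 = 0.3)
  expect_length(dets2, 1)
  # symmetric blob: centre of mass at symmetry centre
  sym <- matrix(0L, 41, 41)
  d2 <- outer(-20:20, -20:20, function(i, j) i^2 + j^2)
  sym[d2 <= 36] <- 200L
  dsym <- detect_signals(sym, matrix(TRUE, 41, 41), mpp = 0.1)
  expect_equal(dsym[[1]]$centre_of_mass, c(20, 20), tolerance = 1e-9)
})

test_that("centre-of-mass distances are Euclidean in microns", {
  mk <- function(com, id = "n1", label = "p") {
    structure(list(component_pixels = matrix(com, 1), centre_of_mass = com,
                   area_um2 = 1, probe_label = label, nucleus_id = id),
              class = "signal_detection")
  }
  cal <- calibration(0.1)
  expect_equal(com_distance(mk(c(5, 5)), mk(c(5, 5), label = "q"), cal)$distance_um, 0)
  expect_equal(com_distance(mk(c(0, 0)), mk(c(3, 4), label = "q"), cal)$distance_um, 0.5)
  expect_error(com_distance(mk(c(0, 0)), mk(c(1, 1), id = "n2"), cal),
               "different nuclei")
  # brute-force agreement on random pairs
  set.seed(23)
  for (rep in 1:10) {
    a <- runif(2, 0, 100); b <- runif(2, 0, 100)
    expect_equal(com_distance(mk(a), mk(b, label = "q"), cal)$distance_um,
                 sqrt(sum((a - b)^2)) * 0.1)
  }
})

test_that("Wilcoxon comparisons behave at the extremes and refuse tiny groups", {
  res <- compare_distance_sets(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gt(res$p_value, 0.95)
  sep <- compare_distance_sets(1:5, 101:105)
  expect_lt(sep$p_value, 0.05)
  expect_equal(sep$n1, 5)
  expect_equal(sep$median2, 103)
  expect_error(compare_distance_sets(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("similarity matrices are symmetric with unit diagonal", {
  mkcm <- function(seed) {
    set.seed(seed)
    composite_map(matrix(sample(0:4, 48 * 48, TRUE) / 4, 48, 48), 4L,
                  probe_label = paste0("p", seed), target_signature = "s")
  }
  cms <- list(a = mkcm(1), b = mkcm(2), c = mkcm(3))
  m <- suppressWarnings(similarity_matrix(cms))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 1))
  # single composite -> 1x1 unit matrix
  m1 <- similarity_matrix(cms[1])
  expect_equal(unname(m1), matrix(1))
  bad <- mkcm(4); bad$target_signature <- "other"
  expect_error(similarity_matrix(list(cms$a, bad)), "structural mismatch")
})
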