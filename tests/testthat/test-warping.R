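signal_fixture <- function(seed = 3, address = "centre", spread = 0.45) {
  nuc <- generate_nucleus(falciform_params(), seed = seed)
  sig <- plant_signals(nuc, list(planted_signal("p", address,
                                                spread_um = spread,
                                                address_jitter = 0)),
                       seed = seed + 100)
  list(nuc = nuc, chan = sig$channels[[1]], truth = sig$truth$p)
}

test_that("binarisation is confined to the mask and recovers planted blobs", {
  fx <- signal_fixture()
  mask <- fx$nuc$outline$mask
  # fixed threshold on a uniform channel
  uni <- matrix(100L, nrow(mask), ncol(mask))
  bin <- binarise_signal(uni, mask, "fixed:50")
  expect_true(all(bin[mask]))
  expect_true(all(!bin[!mask]))
  # Otsu-within-mask on the planted blob
  bin2 <- binarise_signal(fx$chan, mask, "otsu")
  expect_gt(sum(bin2), 0)
  idx <- which(bin2)
  h <- nrow(bin2)
  ctr <- c(mean((idx - 1) %/% h), mean((idx - 1) %% h))
  expect_lt(sqrt(sum((ctr - fx$truth$centre)^2)), 1)
  # signal outside the mask contributes nothing
  outside <- fx$chan$pixels
  outside[!mask] <- 255L
  bin3 <- binarise_signal(outside, mask, "fixed:200")
  expect_true(all(!bin3[!mask]))
  # all-zero channel is silent, not an error
  expect_true(all(!binarise_signal(matrix(0L, nrow(mask), ncol(mask)), mask)))
})

test_that("the gap filler follows the at-least-4-neighbours rule", {
  base <- matrix(0, 3, 3)
  neighbours <- cbind(row = c(1, 1, 1, 2, 2, 3, 3, 3),
                      col = c(1, 2, 3, 1, 3, 1, 2, 3))
  for (k in 0:8) {
    r <- base
    if (k > 0) r[neighbours[seq_len(k), , drop = FALSE]] <- 1
    filled <- fill_gaps(r)
    expect_identical(filled[2, 2] != 0, k >= 4)
  }
  # mean-of-neighbours for intensity rasters
  r <- matrix(0, 3, 3)
  r[1, 1] <- 10; r[1, 3] <- 20; r[3, 1] <- 30; r[3, 3] <- 40
  expect_equal(fill_gaps(r)[2, 2], 25)
  # filled from a frozen copy: already-nonzero pixels unchanged
  expect_equal(fill_gaps(r)[1, 1], 10)
})

test_that("pixel-to-face assignment covers the interior consistently", {
  nuc <- generate_nucleus(falciform_params(), seed = 4)
  ori <- orient_nucleus(nuc$outline, find_landmarks(nuc$outline))
  mesh <- build_mesh(ori$outline$boundary, ori$landmarks, 15)
  dims <- dim(ori$outline$mask)
  fmap <- assign_pixels_to_faces(mesh, dims)
  poly_px <- sum(nucleocarta:::rasterize_polygon(mesh$polygon, dims[2], dims[1]))
  assigned <- sum(fmap > 0)
  expect_lt(abs(assigned - poly_px) / poly_px, 0.01)
  # a pixel strictly inside a face maps to it
  tri <- mesh$vertices[mesh$faces[5, ], ]
  ctr <- colMeans(tri)
  expect_equal(assign_points_to_faces(mesh, matrix(ctr, 1)), 5L)
  # shared-edge points take the lower face index
  e <- (mesh$vertices[mesh$faces[5, 1], ] + mesh$vertices[mesh$faces[5, 2], ]) / 2
  f <- assign_points_to_faces(mesh, matrix(e, 1))
  shared <- which(apply(mesh$faces, 1, function(fc)
    all(mesh$faces[5, 1:2] %in% fc)))
  expect_equal(f, min(shared))
})

test_that("identity warp preserves at least 99% of ON pixels", {
  for (sd in c(2, 9)) {
    fx <- signal_fixture(seed = sd)
    o <- fx$nuc$outline
    lms <- find_landmarks(o)
    mesh <- build_mesh(o$boundary, lms, 20)
    bin <- binarise_signal(fx$chan, o$mask, "otsu")
    w <- warp_signal(mesh, mesh, bin)
    # map input ON pixels into the frame and compare
    idx <- which(bin)
    h <- nrow(bin)
    xs <- (idx - 1) %/% h - w$frame$offset[1] + 1
    ys <- (idx - 1) %% h - w$frame$offset[2] + 1
    ok <- xs >= 1 & xs <= w$frame$width & ys >= 1 & ys <= w$frame$height
    kept <- sum(w$raster[cbind(ys[ok], xs[ok])])
    expect_gte(kept / sum(bin), 0.99)
  }
})

test_that("a blob planted at the hook tip warps into the consensus tip region", {
  pop <- generate_population(
    list(list(params = falciform_params(),
              signals = list(planted_signal("tip", c(0.08, 0),
                                            address_jitter = 0)))),
    n_per_strain = 8, seed = 31)
  rec <- detect_and_orient(pop$fields)
  res <- warp_population(rec, pop$fields, pop$probe_map)
  cm <- res$composites$tip
  idx <- which(cm$frequencies >= 0.5 * max(cm$frequencies))
  h <- nrow(cm$frequencies)
  ctr <- c(mean((idx - 1) %/% h), mean((idx - 1) %% h))
  tip_px <- res$template_mesh$vertices[res$template_mesh$tip, ] -
    res$frame$offset
  per <- sum(sqrt(rowSums(diff(rbind(res$template_mesh$polygon,
                                     res$template_mesh$polygon[1, ]))^2)))
  expect_lt(sqrt(sum((ctr - tip_px)^2)), 0.05 * per + 5)
})

test_that("empty rasters warp to empty and mismatched meshes error", {
  nuc <- generate_nucleus(falciform_params(), seed = 5)
  o <- nuc$outline
  lms <- find_landmarks(o)
  m1 <- build_mesh(o$boundary, lms, 10)
  m2 <- build_mesh(o$boundary, lms, 11)
  empty <- matrix(FALSE, nrow(o$mask), ncol(o$mask))
  expect_equal(sum(warp_signal(m1, m1, empty)$raster), 0)
  expect_error(warp_signal(m1, m2, empty), "structural mismatch")
})

test_that("composites are means: arithmetic, permutation invariance, count integrality", {
  frame <- list(offset = c(0, 0), width = 10L, height = 10L,
                mask = matrix(TRUE, 10, 10))
  mk <- function(px) {
    r <- matrix(FALSE, 10, 10)
    r[px] <- TRUE
    structure(list(raster = r, frame = frame, source_nucleus = "x",
                   target_signature = "s"), class = "warped_signal")
  }
  w1 <- mk(15); w2 <- mk(77)
  cm <- composite(list(w1, w2))
  expect_equal(sum(cm$frequencies == 0.5), 2)
  expect_equal(sum(cm$frequencies), 1)
  # permutation invariance
  cm2 <- composite(list(w2, w1))
  expect_identical(cm$frequencies, cm2$frequencies)
  # n identical warps -> composite equals any one of them
  cm3 <- composite(list(w1, w1, w1))
  expect_identical(cm3$frequencies != 0, w1$raster)
  expect_true(all(abs(cm$frequencies * cm$n_nuclei -
                        round(cm$frequencies * cm$n_nuclei)) < 1e-9))
  expect_error(composite(list()), "empty")
  w3 <- mk(20); w3$target_signature <- "other"
  expect_error(composite(list(w1, w3)), "structural mismatch")
})
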