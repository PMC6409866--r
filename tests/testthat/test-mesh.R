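oriented_fixture <- function(seed, params = falciform_params()) {
  nuc <- generate_nucleus(params, seed = seed)
  orient_nucleus(nuc$outline, find_landmarks(nuc$outline))
}

test_that("consensus of a single outline is that outline's resampling", {
  ori <- oriented_fixture(2)
  cons <- build_consensus(list(ori$outline), list(ori$landmarks), 80)
  rs <- nucleocarta:::resample_by_segments(ori$outline$boundary,
                                           ori$landmarks, 80)$points
  # both are shifted into a margin-2 frame; align centroids before comparing
  a <- sweep(cons$boundary, 2, colMeans(cons$boundary))
  b <- sweep(rs, 2, colMeans(rs))
  expect_lt(max(sqrt(rowSums((a - b)^2))), 1e-6)
  expect_equal(cons$n_contributing, 1L)
})

test_that("consensus of translated copies equals the common shape", {
  ori <- oriented_fixture(3)
  o2 <- ori$outline
  o2$boundary <- sweep(o2$boundary, 2, c(5, 7), "+")
  cons <- build_consensus(list(ori$outline, o2),
                          list(ori$landmarks, ori$landmarks), 60)
  rs <- nucleocarta:::resample_by_segments(ori$outline$boundary,
                                           ori$landmarks, 60)$points
  a <- sweep(cons$boundary, 2, colMeans(cons$boundary))
  b <- sweep(rs, 2, colMeans(rs))
  expect_lt(max(sqrt(rowSums((a - b)^2))), 1e-6)
})

test_that("consensus averages away i.i.d. boundary noise", {
  set.seed(77)
  base <- oriented_fixture(4, falciform_params(boundary_noise_sd = 0))
  # uniformly spaced template, as traced pixel-chain boundaries are
  ub <- nucleocarta:::resample_by_segments(base$outline$boundary,
                                           base$landmarks, 200)
  template <- nucleus_outline(ub$points, mpp = 0.1)
  lms <- landmark_set(ub$landmark_idx, nrow(ub$points))
  noisy <- lapply(1:50, function(i) {
    o <- template
    o$boundary <- o$boundary + matrix(rnorm(length(o$boundary), 0, 1),
                                      ncol = 2)
    o
  })
  cons <- build_consensus(noisy, rep(list(lms), 50), 80)
  rs <- nucleocarta:::resample_by_segments(template$boundary, lms, 80)$points
  a <- sweep(cons$boundary, 2, colMeans(cons$boundary))
  b <- sweep(rs, 2, colMeans(rs))
  expect_lt(mean(sqrt(rowSums((a - b)^2))), 0.5)
})

test_that("mixed landmark structures cannot be averaged", {
  ori <- oriented_fixture(5)
  lm3 <- landmark_set(c(hook_tip = 1L, tail_attachment = 100L, aux1 = 200L),
                      nrow(ori$outline$boundary))
  expect_error(build_consensus(list(ori$outline, ori$outline),
                               list(ori$landmarks, lm3)),
               "structural mismatch")
})

test_that("internal vertices of a symmetric lens lie on its symmetry axis", {
  x <- seq(0, 60, length.out = 121)
  bulge <- 18 * sin(pi * x / 60)
  lens <- rbind(cbind(x, 30 - bulge)[-c(1, 121), ],
                c(60, 30),
                cbind(rev(x), 30 + rev(bulge))[-c(1, 121), ],
                c(0, 30))
  lens <- lens[nrow(lens):1, ]  # start at (0,30)
  lm <- landmark_set(c(hook_tip = 1L,
                       tail_attachment = which(lens[, 1] == 60 & lens[, 2] == 30)),
                     nrow(lens))
  mesh <- build_mesh(lens, lm, 5)
  internal <- mesh$vertices[mesh$internal_idx, , drop = FALSE]
  expect_true(all(abs(internal[, 2] - 30) < 1e-6))
})

test_that("mesh faces tile the polygon without overlap", {
  for (sd in c(1, 6, 11)) {
    ori <- oriented_fixture(sd)
    mesh <- build_mesh(ori$outline$boundary, ori$landmarks, 20)
    pa <- nucleocarta:::poly_area(mesh$polygon)
    fa <- sum(apply(mesh$faces, 1, function(f)
      nucleocarta:::poly_area(mesh$vertices[f, ])))
    expect_lt(abs(fa - pa) / pa, 0.01)
    expect_lt(mesh_overlap_area(mesh) / pa, 1e-6)
    # all faces positively oriented
    signs <- apply(mesh$faces, 1, function(f)
      nucleocarta:::poly_signed_area(mesh$vertices[f, ]))
    expect_true(all(signs > 0))
  }
})

test_that("structure signature depends on counts, not geometry", {
  a <- oriented_fixture(7)
  b <- oriented_fixture(8, falciform_params(length_um = 8.5, width_um = 5.2,
                                            strain_label = "STF"))
  m1 <- build_mesh(a$outline$boundary, a$landmarks, 20)
  m2 <- build_mesh(b$outline$boundary, b$landmarks, 20)
  m3 <- build_mesh(a$outline$boundary, a$landmarks, 21)
  expect_true(mesh_isomorphic(m1, m1))
  expect_true(mesh_isomorphic(m1, m2))
  expect_false(mesh_isomorphic(m1, m3))
})

test_that("mesh exports round-trip through JSON and write OFF", {
  ori <- oriented_fixture(9)
  mesh <- build_mesh(ori$outline$boundary, ori$landmarks, 8)
  fj <- file.path(tempdir(), "mesh.json")
  export_mesh(mesh, fj)
  back <- read_mesh(fj)
  expect_equal(back$structure_signature, mesh$structure_signature)
  expect_equal(dim(back$faces), dim(mesh$faces))
  fo <- file.path(tempdir(), "mesh.off")
  export_mesh(mesh, fo)
  expect_identical(readLines(fo, n = 1), "OFF")
})
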