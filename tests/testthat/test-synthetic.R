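test_that("generation is seed-deterministic and seeds differ", {
  a <- generate_nucleus(falciform_params(), seed = 8)
  b <- generate_nucleus(falciform_params(), seed = 8)
  c <- generate_nucleus(falciform_params(), seed = 9)
  expect_identical(a$raster$pixels, b$raster$pixels)
  expect_identical(a$outline$boundary, b$outline$boundary)
  expect_false(identical(a$raster$pixels, c$raster$pixels))
})

test_that("wider strains are larger and squatter", {
  narrow <- generate_nucleus(falciform_params(width_um = 4.5), seed = 2)
  wide <- generate_nucleus(falciform_params(width_um = 5.4), seed = 2)
  expect_gt(wide$outline$area_um2, narrow$outline$area_um2)
  aspect <- function(n) {
    bb <- apply(n$truth$polygon, 2, range)
    (bb[2, 1] - bb[1, 1]) / (bb[2, 2] - bb[1, 2])
  }
  expect_lt(aspect(wide), aspect(narrow))
})

test_that("rendered mask area matches the analytic polygon area", {
  for (sd in c(1, 4, 9)) {
    nuc <- generate_nucleus(falciform_params(), seed = sd)
    expect_lt(abs(nuc$outline$area_um2 - nuc$truth$analytic_area_um2) /
                nuc$truth$analytic_area_um2, 0.05)
  }
})

test_that("hook-free shapes are rejected as non-falciform", {
  expect_error(falciform_params(hook_curl = 0), "falciform")
  expect_error(falciform_params(length_um = -1), "positive")
})

test_that("noise-free planting puts the blob at its address", {
  nuc <- generate_nucleus(falciform_params(), seed = 13)
  sig <- plant_signals(nuc, list(planted_signal("p", c(0.55, 0.2),
                                                placement_noise = 0,
                                                address_jitter = 0)),
                       seed = 14)
  expected <- nucleocarta:::address_point(nuc$truth$geom, 0.55, 0.2)
  expect_lt(sqrt(sum((sig$truth$p$centre - expected)^2)), 1)
  expect_false(sig$truth$p$displaced)
  # brightest raster pixel sits on the planted centre
  px <- sig$channels[[1]]$pixels
  top <- which(px == max(px), arr.ind = TRUE)[1, ]
  expect_lt(sqrt(sum((c(top[2] - 1, top[1] - 1) - sig$truth$p$centre)^2)), 2)
})

test_that("per-nucleus distances match a direct resampling of the generator", {
  # two probes drawn independently around one shared address: the measured
  # centre-of-mass distances should match the generator's own distribution
  set.seed(99)
  jit <- 0.06
  n <- 50
  measured <- replicate(n, {
    sd <- sample.int(1e6, 1)
    nuc <- generate_nucleus(falciform_params(boundary_noise_sd = 0), seed = sd)
    sig <- plant_signals(nuc, list(
      planted_signal("a", "ventral_basal", address_jitter = jit),
      planted_signal("b", "ventral_basal", address_jitter = jit)), seed = sd + 1)
    sqrt(sum((sig$truth$a$centre - sig$truth$b$centre)^2)) * 0.1
  })
  nuc0 <- generate_nucleus(falciform_params(boundary_noise_sd = 0), seed = 1)
  oracle <- replicate(2000, {
    uv <- matrix(rep(c(0.75, -0.40), 2), 2, byrow = TRUE) +
      matrix(rnorm(4, 0, jit), 2)
    p1 <- nucleocarta:::address_point(nuc0$truth$geom, uv[1, 1], uv[1, 2])
    p2 <- nucleocarta:::address_point(nuc0$truth$geom, uv[2, 1], uv[2, 2])
    sqrt(sum((p1 - p2)^2)) * 0.1
  })
  expect_lt(abs(mean(measured) - mean(oracle)), 0.25 * mean(oracle) + 0.05)
  expect_gt(stats::ks.test(measured, oracle)$p.value, 0.001)
})

test_that("population manifests enumerate every nucleus with its truth", {
  strains <- list(
    list(params = falciform_params(strain_label = "PWK"),
         signals = list(planted_signal("chrX", "dorsal_apical"))),
    list(params = falciform_params(strain_label = "LEWES"),
         signals = list(planted_signal("chrX", "dorsal_apical"))),
    list(params = falciform_params(length_um = 8.5, width_um = 5.2,
                                   strain_label = "STF"),
         signals = list(planted_signal("chrX", "dorsal_apical"))))
  pop <- generate_population(strains, n_per_strain = 4, seed = 55)
  expect_length(pop$manifest, 12)
  expect_equal(sort(unique(vapply(pop$manifest, `[[`, character(1), "strain"))),
               c("LEWES", "PWK", "STF"))
  ids <- vapply(pop$manifest, `[[`, character(1), "id")
  expect_false(anyDuplicated(ids) > 0)
  # truth centres lie inside their field
  d <- dim(pop$fields[[1]]$channels[[1]]$pixels)
  for (m in pop$manifest[1:4]) {
    expect_true(all(m$signals$chrX$centre >= 0))
  }
  # distinct seeds give distinct fields
  pop2 <- generate_population(strains, n_per_strain = 4, seed = 56)
  expect_false(identical(pop$fields[[1]]$channels[[1]]$pixels,
                         pop2$fields[[1]]$channels[[1]]$pixels))
})

test_that("written populations round-trip from disk", {
  d <- file.path(tempdir(), "popdisk")
  strains <- list(list(params = falciform_params(),
                       signals = list(planted_signal("chrX", "dorsal_apical"),
                                      planted_signal("chrY", "dorsal_apical"))))
  pop <- generate_population(strains, n_per_strain = 2, seed = 77,
                             nuclei_per_field = 2, out_dir = d)
  tifs <- list.files(file.path(d), pattern = "\\.tif$", recursive = TRUE,
                     full.names = TRUE)
  expect_length(tifs, 1)
  fi <- read_field(tifs[1], c("counterstain", "signal_A", "signal_B"),
                   calibration(0.1))
  expect_identical(fi$channels$counterstain$pixels,
                   pop$fields[[1]]$channels$counterstain$pixels)
  man <- jsonlite::read_json(file.path(d, "truth_manifest.json"))
  expect_length(man$nuclei, 2)
})
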