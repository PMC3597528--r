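test_that("space constant matches the closed form and sets compartment count", {
  # lambda = sqrt(d * Rm / (4 * Ri)), d = 1 um, Rm = 28000, Ri = 200
  lam <- space_constant(1, 28000, 200)
  expect_equal(lam, sqrt(1e-4 * 28000 / 800) * 1e4, tolerance = 1e-12)
  expect_equal(round(lam), 592)

  m <- build_unbranched_cable(300, diameter = 1, max_electrotonic_step = 0.1)
  n_dend <- nrow(m$compartments) - 1
  expect_gte(n_dend, 6)
  expect_equal(n_dend, ceiling(300 / (0.1 * lam)))
})

test_that("degenerate and invalid geometries are handled", {
  m0 <- build_unbranched_cable(0)
  expect_equal(nrow(m0$compartments), 1)
  expect_equal(m0$compartments$region, "soma")
  expect_error(build_unbranched_cable(100, diameter = -0.5), "diameter")
})

test_that("region labelling is total and follows the boundaries", {
  expect_equal(region_of(c(30, 75, 150), c(50, 100)),
               c("proximal", "dendrite", "distal"))
  m <- build_unbranched_cable(300, region_boundaries = c(50, 100))
  expect_false(any(is.na(m$compartments$region)))
  cc <- m$compartments[-1, ]
  expect_equal(cc$region, region_of(cc$path_distance, c(50, 100)))
})

test_that("halving the electrotonic step refines the mesh", {
  n1 <- nrow(build_unbranched_cable(300, 1)$compartments) - 1
  n2 <- nrow(build_unbranched_cable(300, 1,
                                    max_electrotonic_step = 0.05)$compartments) - 1
  expect_gte(n2, 2 * n1 - 1)
})

test_that("SWC parsing preserves 3-D path geometry", {
  swc <- c("1 1 0 0 0 10 -1",
           "2 3 100 0 0 0.5 1")
  m <- load_swc(swc)
  expect_equal(total_dendrite_length(m), 100)

  swc2 <- c("1 1 0 0 0 10 -1",
            "2 3 3 4 0 0.5 1")
  m2 <- load_swc(swc2)
  expect_equal(total_dendrite_length(m2), 5)
})

test_that("malformed SWC inputs are rejected with the offending line", {
  expect_error(load_swc(c("1 1 0 0 0 10 -1", "2 3 1 0 0 -1 1")),
               "negative radius.*line 2")
  expect_error(load_swc(c("1 1 0 0 0 10 2", "2 3 1 0 0 1 1")),
               "root")
  # parent listed after its child
  expect_error(load_swc(c("1 1 0 0 0 10 -1",
                          "2 3 5 0 0 1 3",
                          "3 3 2 0 0 1 1")),
               "precede.*line 2")
})

test_that("morphologies round-trip through SWC and the tabular format", {
  m <- build_unbranched_cable(213, diameter = c(1.2, 0.4))
  m2 <- load_swc(write_swc(m))
  expect_equal(total_dendrite_length(m2), total_dendrite_length(m),
               tolerance = 1e-9)
  tips <- function(x) max(x$compartments$path_distance +
                          x$compartments$length / 2)
  expect_equal(tips(m2), tips(m), tolerance = 1e-6)

  tf <- withr::local_tempfile(fileext = ".tsv")
  write_morphology_table(m, tf)
  m3 <- read_morphology_table(tf)
  expect_equal(m3$compartments$path_distance, m$compartments$path_distance)
  expect_equal(m3$compartments$diameter, m$compartments$diameter)
})

test_that("synapse placement reproduces the configured interval statistics", {
  m <- build_unbranched_cable(100, diameter = 1)
  s <- place_synapses(m, mean_spacing = 10, regularity = 8, seed = 7)
  expect_gte(nrow(s), 6)
  expect_lte(nrow(s), 15)
  expect_true(!is.unsorted(s$path_distance))

  # aggregate interval statistics on a long cable
  long <- build_unbranched_cable(30000, diameter = 1)
  sl <- place_synapses(long, 10, 8, seed = 11)
  iv <- diff(sl$path_distance)
  expect_equal(mean(iv), 10, tolerance = 0.02)          # +-0.2 um
  expect_equal(mean(iv) / sd(iv), 8, tolerance = 0.0625) # +-0.5

  ks <- suppressWarnings(
    stats::ks.test(iv, stats::pgamma, shape = 64, scale = 10 / 64))
  expect_gt(ks$p.value, 0.01)
})

test_that("placement is deterministic per seed and regularizes in the limit", {
  m <- build_unbranched_cable(500, diameter = 1)
  a <- place_synapses(m, 10, 8, seed = 3)
  b <- place_synapses(m, 10, 8, seed = 3)
  expect_identical(a, b)

  reg <- place_synapses(m, 10, regularity = 1e4, seed = 3)
  expect_true(all(abs(diff(reg$path_distance) - 10) < 0.1))

  short <- build_unbranched_cable(0.5, diameter = 1)
  expect_equal(nrow(place_synapses(short, 10, 8, seed = 1)), 0)
})
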