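test_that("inversion and width are exact inverses with the stated constant", {
  # published TAIL-OH3 bond: k = 93.0 kcal/(mol A^2) at 305 K
  expect_equal(boltzmann_invert(0.080726, 305), 93.0, tolerance = 2e-4)
  # algebraic round trip at the TAIL-OH4 stiffness
  sg <- harmonic_width(542.0, 305)
  expect_equal(boltzmann_invert(sg, 305), 542.0, tolerance = 1e-12)
  # strictly decreasing in sigma, linear in temperature
  sgs <- seq(0.02, 0.2, by = 0.02)
  expect_true(all(diff(boltzmann_invert(sgs, 305)) < 0))
  expect_equal(boltzmann_invert(0.05, 610), 2 * boltzmann_invert(0.05, 305))
  # k -> 0 as sigma grows without bound
  expect_lt(boltzmann_invert(1e6, 305), 1e-9)
  expect_error(boltzmann_invert(-1, 305), "positive")
  expect_error(harmonic_width(0, 305), "positive")
})

test_that("gaussian fits recover the center and width of sampled normals", {
  x <- sample_term(2.50, boltzmann_invert(0.0334, 305), 305, 1e5, seed = 11)
  ft <- fit_gaussian(distribution_histogram(x, "bond", temperature = 305))
  expect_equal(ft$x0, 2.50, tolerance = 5e-3)
  expect_equal(ft$sigma, 0.0334, tolerance = 0.03)
  expect_false(ft$multimodal)
  # bin-width halving moves the estimates by < 1%
  ft2 <- fit_gaussian(distribution_histogram(x, "bond", bin_width = 0.005,
                                             temperature = 305))
  expect_lt(abs(ft2$x0 - ft$x0) / ft$x0, 0.01)
  expect_lt(abs(ft2$sigma - ft$sigma) / ft$sigma, 0.01)
})

test_that("a symmetric two-peak mixture is flagged multimodal with a fit between the peaks", {
  x <- withr::with_seed(5, c(rnorm(5e4, 60, 4), rnorm(5e4, 80, 4)))
  ft <- fit_gaussian(distribution_histogram(x, "angle"))
  expect_true(ft$multimodal)
  expect_gt(ft$x0, 62)
  expect_lt(ft$x0, 78)
})

test_that("degenerate samples are rejected", {
  expect_error(distribution_histogram(rep(2.4, 500), "bond"), "zero-variance")
  expect_error(fit_gaussian(structure(tibble::tibble(x = 1, density = 1),
                                      kind = "bond", bin_width = 0.01, n = 1,
                                      temperature = 305,
                                      class = c("distribution_histogram",
                                                class(tibble::tibble())))),
               "histogram")
})

test_that("sampling is reproducible per seed and concentrates in the stiff limit", {
  a <- sample_term(2.4, 93, 305, 5, seed = 99)
  b <- sample_term(2.4, 93, 305, 5, seed = 99)
  expect_identical(a, b)
  stiff <- sample_term(2.4, 1e9, 305, 1000, seed = 1)
  expect_lt(max(abs(stiff - 2.4)), 1e-3)
  # CLT bound on the sample mean
  n <- 1e5
  sg <- harmonic_width(93, 305)
  xs <- sample_term(2.4, 93, 305, n, seed = 7)
  expect_lt(abs(mean(xs) - 2.4), 5 * sg / sqrt(n))
})

test_that("derive_bonded_table recovers parameters and applies exclusions", {
  truth <- tibble::tibble(term = c("TAIL-OH3", "TAIL-OH4"), kind = "bond",
                          x0 = c(2.40, 2.50), k = c(93, 542))
  ds <- gen_bonded_dataset(truth, n = 2e5, seed = 21)
  tab <- derive_bonded_table(ds$samples, temperature = 305)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$x0[match("TAIL-OH3", tab$term)], 2.40, tolerance = 0.005)
  expect_equal(tab$k[match("TAIL-OH3", tab$term)], 93, tolerance = 0.02)
  expect_equal(tab$x0[match("TAIL-OH4", tab$term)], 2.50, tolerance = 0.005)
  expect_equal(tab$k[match("TAIL-OH4", tab$term)], 542, tolerance = 0.02)
  # a term with < 100 samples is excluded with a warning
  thin <- dplyr::bind_rows(ds$samples,
                           tibble::tibble(term = "X-Y", kind = "bond",
                                          value = rnorm(50, 3, 0.05)))
  expect_warning(tab2 <- derive_bonded_table(thin, 305), "100 samples")
  expect_equal(nrow(tab2), 2)
  # an angle term in degrees inverts through radians
  ang <- tibble::tibble(term = "TAIL-TAIL-OH3", kind = "angle",
                        x0 = 144, k = 80)
  da <- gen_bonded_dataset(ang, n = 2e5, seed = 5)
  ta <- derive_bonded_table(da$samples, 305)
  expect_equal(ta$x0, 144, tolerance = 0.005)
  expect_equal(ta$k, 80, tolerance = 0.03)
  # a bimodal synthetic angle term is flagged and centered between the modes
  bim <- tibble::tibble(term = "MHEAD2-TAIL-OH3", kind = "angle",
                        value = withr::with_seed(8, c(rnorm(5e4, 60, 4),
                                                      rnorm(5e4, 85, 4))))
  tb <- derive_bonded_table(bim, 305)
  expect_true(tb$multimodal)
  expect_gt(tb$x0, 62)
  expect_lt(tb$x0, 83)
})

test_that("round-trip recovery holds across the stiffness range", {
  # sample -> histogram fit -> invert recovers x0 within 0.5% and k within 3%
  grid <- expand.grid(k = c(15, 120, 900), seed = c(101, 202))
  for (i in seq_len(nrow(grid))) {
    k <- grid$k[i]
    x <- sample_term(2.0, k, 305, 1e5, seed = grid$seed[i])
    ft <- fit_gaussian(distribution_histogram(x, "bond", temperature = 305))
    expect_equal(ft$x0, 2.0, tolerance = 0.005)
    expect_equal(boltzmann_invert(ft$sigma, 305), k, tolerance = 0.03)
  }
})

test_that("bonded tables survive the text round trip", {
  truth <- oh_bead_reference()[1:2, ]
  ds <- gen_bonded_dataset(truth, n = 1e4, seed = 2)
  tab <- derive_bonded_table(ds$samples, 305)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bonded_table(tab, path)
  expect_equal(as.data.frame(read_bonded_table(path)), as.data.frame(tab),
               tolerance = 1e-6)
})
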