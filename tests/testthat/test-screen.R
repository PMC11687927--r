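test_that("structural grid enumerates exactly 162 configurations", {
  g <- enumerate_structural_grid()
  expect_equal(nrow(g), 162)
  expect_equal(sum(g$family == "constant"), 81)
  expect_equal(sum(g$family == "dependent"), 81)
  # the all-zero configuration appears exactly once in each family
  zc <- g$family == "constant" & g$epsA1 == 0 & g$epsB1 == 0 &
    g$epsA2 == 0 & g$epsB2 == 0
  expect_equal(sum(zc), 1)
  # push-n-pull mirror families: 9 configurations each
  pp <- g$family == "constant" & g$epsB1 > 0 & g$epsA2 > 0
  mir <- g$family == "constant" & g$epsA1 > 0 & g$epsB2 > 0
  expect_equal(sum(pp), 9)
  expect_equal(sum(pp) + sum(mir), 18)
})

test_that("biochemical grid has the closed-form cardinality", {
  g <- enumerate_biochemical_grid(gammas = c(1, 10, 100, 1000))
  expect_equal(nrow(g), (1 + 4 * 3)^2)      # none + 4 slots x 3 factors, squared
  g1 <- enumerate_biochemical_grid(gammas = 1)
  expect_equal(nrow(g1), 1)                 # only the uncoupled configuration
  expect_true(is.na(g1$cell1_species))
  # the four asymmetric gamma = 1000 motifs are present
  find <- function(s1, r1, s2, r2) {
    any(g$cell1_species == s1 & g$cell1_rate == r1 & g$cell1_gamma == 1000 &
        g$cell2_species == s2 & g$cell2_rate == r2 & g$cell2_gamma == 1000,
        na.rm = TRUE)
  }
  expect_true(find("rac", "on", "rho", "on"))
  expect_true(find("rac", "off", "rho", "off"))
  expect_true(find("rac", "on", "rac", "off"))
  expect_true(find("rho", "on", "rho", "off"))
  gc <- enumerate_biochemical_grid(collapse_symmetric = TRUE)
  expect_lt(nrow(gc), nrow(g))
})

test_that("screens aggregate exact fractions that sum to one", {
  p <- fast_params()
  grid <- enumerate_structural_grid()[c(1, 41), ]
  res <- run_screen(grid, n_realizations = 6, base_seed = 5, params = p)
  expect_equal(nrow(res), 2)
  psum <- res$p_coalign + res$p_collision + res$p_misalign + res$p_nonpolar
  expect_equal(psum, rep(1, 2))
  lab <- res$labels[[1]]
  expect_equal(res$p_coalign[1], mean(lab$outcome == "co-alignment"))
  # deterministic given the base seed
  res2 <- run_screen(grid, n_realizations = 6, base_seed = 5, params = p)
  expect_identical(res$labels, res2$labels)
})

test_that("screen cache resumes without recomputation", {
  p <- fast_params()
  grid <- enumerate_structural_grid()[1, ]
  cache <- tempfile(fileext = ".csv")
  res <- run_screen(grid, n_realizations = 4, base_seed = 2, params = p,
                    cache = cache)
  expect_true(file.exists(cache))
  t0 <- Sys.time()
  res2 <- run_screen(grid, n_realizations = 4, base_seed = 2, params = p,
                     cache = cache)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_equal(res$p_coalign, res2$p_coalign)
})

test_that("Wilson interval matches the textbook case", {
  # frozen from an independent implementation
  # (statsmodels proportion_confint, method = "wilson")
  ci <- wilson_ci(25, 100)
  expect_equal(unname(ci), c(0.1754521, 0.3430446), tolerance = 1e-6)
  expect_true(all(wilson_ci(0, 10) >= 0) && all(wilson_ci(10, 10) <= 1))
})

test_that("summary table is long-form with one row per outcome", {
  p <- fast_params()
  res <- run_screen(enumerate_structural_grid()[1, ], n_realizations = 4,
                    base_seed = 2, params = p)
  s <- summarize_screen(res)
  expect_equal(nrow(s), 5)
  expect_true(all(s$ci_lower <= s$probability & s$probability <= s$ci_upper))
  empty <- summarize_screen(res[0, ])
  expect_equal(nrow(empty), 0)
})
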