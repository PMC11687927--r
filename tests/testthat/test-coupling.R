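map <- build_junction_map("doublet")
jn <- map$junctions[[1]]

test_that("empty regulation leaves unit rate factors everywhere", {
  f <- junction_rate_fields(map, list(), cell = 1)
  expect_true(all(f$kon_factor == 1) && all(f$koff_factor == 1))
})

test_that("constant gamma acts only on the target cell's junction arc", {
  reg <- list(gtpase_regulation(c(1, 2), 1, "rac", "on", 1000))
  f1 <- junction_rate_fields(map, reg, cell = 1)
  f2 <- junction_rate_fields(map, reg, cell = 2)
  expect_equal(sort(which(f1$kon_factor[, 1] == 1000)), sort(jn$idx_i))
  expect_true(all(f1$kon_factor[-jn$idx_i, 1] == 1))
  expect_true(all(f1$kon_factor[, 2] == 1))   # rho untouched
  expect_true(all(f1$koff_factor == 1))
  expect_true(all(f2$kon_factor == 1))        # cell 2 unchanged
})

test_that("gamma below one is rejected at construction", {
  expect_error(gtpase_regulation(c(1, 2), 1, "rac", "on", 0.5), "gamma >= 1")
})

test_that("concentration-dependent factor reduces to baseline with no neighbour molecules", {
  reg <- list(gtpase_regulation(c(1, 2), 1, "rac", "on", 1000,
                                conc_dependent = TRUE))
  nb <- list(NULL, list(rac = numeric(0), rho = numeric(0)))
  f <- junction_rate_fields(map, reg, cell = 1, neighbour_positions = nb)
  expect_true(all(f$kon_factor == 1))

  # one neighbour molecule at the mirror of the junction center
  nb2 <- list(NULL, list(rac = 5.0, rho = numeric(0)))  # s = 5 is theta 180
  f2 <- junction_rate_fields(map, reg, cell = 1, neighbour_positions = nb2)
  center_site <- jn$idx_i[(length(jn$idx_i) + 1) / 2]
  expect_equal(f2$kon_factor[center_site, 1], 1000)
  expect_error(junction_rate_fields(map, reg, cell = 1), "neighbour state")
})

test_that("growth fields are zero outside the junction arc", {
  reg <- list(actin_regulation(c(1, 2), 1, eps_A = 0.5, eps_B = -0.25))
  g <- junction_growth_fields(map, reg, cell = 1)
  expect_equal(unique(g$eps_A[jn$idx_i]), 0.5)
  expect_equal(unique(g$eps_B[jn$idx_i]), -0.25)
  expect_true(all(g$eps_A[-jn$idx_i] == 0) && all(g$eps_B[-jn$idx_i] == 0))
  g2 <- junction_growth_fields(map, list(), cell = 1)
  expect_true(all(g2$eps_A == 0) && all(g2$eps_B == 0))
})

test_that("dependent growth fields read the neighbour's mirrored densities", {
  reg <- list(actin_crosstalk(c(1, 2), c(AA = 0, AB = 1, BA = 1, BB = 0)))
  n <- map$domain$n_grid
  zero <- list(A = rep(0, n), B = rep(0, n))
  g0 <- junction_growth_fields(map, reg, cell = 1,
                               neighbour_fields = list(NULL, zero))
  expect_true(all(g0$eps_A == 0) && all(g0$eps_B == 0))

  nbB <- list(NULL, list(A = rep(0, n), B = rep(2, n)))
  g <- junction_growth_fields(map, reg, cell = 1, neighbour_fields = nbB)
  expect_equal(unique(g$eps_A[jn$idx_i]), 2)  # eps_A = eAB * B(cell 2)
  expect_true(all(g$eps_B == 0))              # eBB = 0, A(cell 2) = 0
})

test_that("push-n-pull motif raises complementary networks across the pair", {
  cp <- coupling_motif(map, "pushpull_actin", eps = 1)
  g1 <- junction_growth_fields(map, cp$actin, cell = 1)
  g2 <- junction_growth_fields(map, cp$actin, cell = 2)
  expect_equal(unique(g1$eps_B[jn$idx_i]), 1)   # bundled up in cell 1
  expect_true(all(g1$eps_A == 0))
  expect_equal(unique(g2$eps_A[jn$idx_j]), 1)   # branched up in cell 2
  expect_true(all(g2$eps_B == 0))
})
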