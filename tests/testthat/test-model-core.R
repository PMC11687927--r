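test_that("initialization binds exactly 10% of each species at random", {
  p <- frozen_params(T_end = 0.1, N_rac = 100L, N_rho = 70L)
  tr <- simulate_cell(params = p, seed = 5)
  expect_length(tr$bound[[1]]$rac, 10)
  expect_length(tr$bound[[1]]$rho, 7)
  expect_true(all(tr$bound[[1]]$rac >= 0 & tr$bound[[1]]$rac < 10))
})

test_that("identical seeds reproduce bitwise-identical states", {
  a <- simulate_cell(params = fast_params(), seed = 9)
  b <- simulate_cell(params = fast_params(), seed = 9)
  expect_identical(a$axis, b$axis)
  expect_identical(a$A, b$A)
  expect_identical(a$bound, b$bound)
  c <- simulate_cell(params = fast_params(), seed = 10)
  expect_false(identical(a$bound, c$bound))
})

test_that("initial bound positions are uniform on the perimeter", {
  # frozen kinetics: final positions equal the initial draw
  p <- frozen_params(T_end = 0.1, N_rac = 40L)
  pos <- unlist(lapply(1:300, function(s)
    simulate_cell(params = p, seed = s)$bound[[1]]$rac))
  ks <- suppressWarnings(stats::ks.test(pos / 10, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a lone bound molecule decays exponentially under k_off", {
  # survival over many seeds matches exp(-k*t) within Monte-Carlo tolerance
  r <- 1; Tend <- 1; n <- 2000
  p <- cell_params(k_on = 0, k_fb = 0, k_off = r, T_end = Tend,
                   N_rac = 10L, N_rho = 10L)   # one bound molecule per species
  surv <- vapply(seq_len(n), function(s) {
    tr <- simulate_cell(params = p, seed = s,
                        domain = periodic_domain(10, 20), stride = 50L)
    length(tr$bound[[1]]$rac)
  }, numeric(1))
  expected <- exp(-r * Tend)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(surv) - expected), 4 * se)
})

test_that("zero kinetic rates leave the GTPase state unchanged", {
  p <- frozen_params(T_end = 1)
  tr <- simulate_cell(params = p, seed = 2, check = TRUE)
  tr2 <- simulate_cell(params = frozen_params(T_end = 5), seed = 2)
  expect_identical(tr$bound, tr2$bound)  # positions frozen in time
})

test_that("total inhibition blocks all binding of the vetoed species", {
  # rho occupies every site; rac can never bind or be recruited
  n <- 20
  dom <- periodic_domain(10, n)
  rho_everywhere <- (seq_len(n) - 0.5) * dom$ds
  p <- cell_params(k_off = 0, k_fb = 0, k_on = 5, T_end = 2,
                   N_rac = 50L, N_rho = 20L)
  tr <- simulate_cell(params = p, seed = 4, domain = dom,
                      init_pos = list(list(rac = numeric(0),
                                           rho = rho_everywhere)))
  expect_length(tr$bound[[1]]$rac, 0)
  expect_length(tr$bound[[1]]$rho, n)
})

test_that("mass is conserved at every step of stochastic runs", {
  for (s in 1:5) {
    tr <- simulate_cell(params = fast_params(), seed = s, check = TRUE)
    nb <- lengths(tr$bound[[1]])
    expect_equal(unname(nb + tr$inactive[, 1]), c(60, 60))
  }
})

test_that("actin fields stay nonnegative throughout", {
  tr <- simulate_cell(params = fast_params(eps_A0 = -3, eps_B0 = -3),
                      seed = 1, record_fields = TRUE)
  expect_gte(min(unlist(tr$A_snapshots)), 0)
  expect_gte(min(unlist(tr$B_snapshots)), 0)
})

test_that("zero fields are a fixed point of the actin dynamics", {
  n <- 100
  p <- frozen_params(T_end = 2)
  tr <- simulate_cell(params = p, seed = 1,
                      init_pos = list(list(rac = numeric(0),
                                           rho = numeric(0))),
                      init_fields = list(list(A = rep(0, n), B = rep(0, n))))
  expect_true(all(tr$A == 0) && all(tr$B == 0))
})

test_that("homogeneous steady states match the closed-form roots", {
  # uniform local counts: one molecule of each species per grid cell gives
  # n = 2h + 1 inside every inhibition window
  n <- 100
  dom <- periodic_domain(10, n)
  pos <- (seq_len(n) - 0.5) * dom$ds
  p <- frozen_params(T_end = 60)
  h <- round(p$inhibition_radius / dom$ds)
  nloc <- 2 * h + 1

  # symmetric coexistence branch: A = B = (1 + alpha n) / (1 + m0)
  tr <- simulate_cell(params = p, seed = 1, domain = dom,
                      init_pos = list(list(rac = pos, rho = pos)),
                      init_fields = list(list(A = rep(1, n), B = rep(1, n))))
  astar <- (1 + p$alpha * nloc) / (1 + p$m0)
  expect_lt(max(abs(tr$A - astar)), 1e-6)
  expect_lt(max(abs(tr$B - astar)), 1e-6)

  # single-network logistic branch: B = 0, A = 1 + alpha n + eps_A
  p2 <- frozen_params(T_end = 60, eps_A0 = 0.5)
  tr2 <- simulate_cell(params = p2, seed = 1, domain = dom,
                       init_pos = list(list(rac = pos, rho = pos)),
                       init_fields = list(list(A = rep(1, n), B = rep(0, n))))
  expect_lt(max(abs(tr2$A - (1 + p2$alpha * nloc + 0.5))), 1e-6)
  expect_true(all(tr2$B == 0))
})

test_that("deterministic field dynamics are rotation-equivariant", {
  n <- 100
  dom <- periodic_domain(10, n)
  set.seed(7)
  A0 <- 1 + 0.2 * sin(2 * pi * (1:n) / n) + 0.01 * runif(n)
  B0 <- 1 + 0.2 * cos(2 * pi * (1:n) / n)
  p <- frozen_params(T_end = 5)
  base <- simulate_cell(params = p, seed = 1, domain = dom,
                        init_pos = list(list(rac = numeric(0), rho = numeric(0))),
                        init_fields = list(list(A = A0, B = B0)))
  k <- 30
  rot <- simulate_cell(params = p, seed = 1, domain = dom,
                       init_pos = list(list(rac = numeric(0), rho = numeric(0))),
                       init_fields = list(list(A = c(A0[-(1:k)], A0[1:k]),
                                               B = c(B0[-(1:k)], B0[1:k]))))
  expect_equal(rot$A[, 1], c(base$A[-(1:k), 1], base$A[1:k, 1]), tolerance = 1e-12)
})

test_that("numerical blow-up is reported with the failing step", {
  p <- cell_params(T_end = 5, eps_A0 = 1e300)
  expect_error(simulate_cell(params = p, seed = 1), "non-finite")
})

test_that("uncoupled doublet equals two independent single-cell runs bit-for-bit", {
  p <- fast_params()
  du <- simulate_group("doublet", params = p, seed = 42)
  for (i in 1:2) {
    si <- simulate_cell(params = p, cell_seeds = derive_cell_seed(42, i - 1))
    expect_identical(du$axis[, i], si$axis[, 1])
    expect_identical(du$A[, i], si$A[, 1])
    expect_identical(du$B[, i], si$B[, 1])
    expect_identical(du$bound[[i]], si$bound[[1]])
  }
})

test_that("doublet with explicit zero couplings equals the uncoupled doublet", {
  p <- fast_params()
  cp <- list(gtpase = list(gtpase_regulation(c(1, 2), 1, "rac", "on", 1)),
             actin = list(actin_regulation(c(1, 2), 2, eps_A = 0, eps_B = 0)))
  a <- simulate_group("doublet", params = p, coupling = cp, seed = 3)
  b <- simulate_group("doublet", params = p, seed = 3)
  expect_identical(a$axis, b$axis)
  expect_identical(a$A, b$A)
})

test_that("the time-step stability bound is enforced", {
  p <- cell_params(dt = 0.05, D_actin = 0.1)
  expect_error(simulate_cell(params = p), "stability")
})
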