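dom <- periodic_domain()

test_that("zero-amplitude stimulus gives uniform baseline profiles", {
  sp <- stimulus_spec(1, 275, amplitude = 0)
  prof <- stimulus_rate_profile(sp, dom, k0 = 0.8)
  expect_true(all(prof == 0.8))
})

test_that("Rac profile peaks at the center and Rho is its complement", {
  sp <- stimulus_spec(2, 275)
  prof <- stimulus_rate_profile(sp, dom, k0 = 1)
  peak <- which.max(prof[, "rac"])
  expect_lt(angle_diff(dom$theta_deg[peak], 275), 4)
  expect_equal(which.min(prof[, "rho"]), peak)
  # pointwise sum held fixed, exactly
  s <- prof[, "rac"] + prof[, "rho"]
  expect_equal(max(abs(s - s[1])), 0)
})

test_that("stimulus outside its activity window returns the baseline", {
  sp <- stimulus_spec(1, 90, t_on = 2, t_off = 4)
  prof <- stimulus_rate_profile(sp, dom, k0 = 1, t = 5)
  expect_true(all(prof == 1))
})

test_that("neutralization rebinds exactly 10% of a depleted species", {
  expect_identical(neutralize_if_depleted(c(1, 2), 100), c(1, 2))
  set.seed(1)
  nb <- neutralize_if_depleted(numeric(0), 100, perimeter = 10)
  expect_length(nb, 10)
  expect_true(all(nb >= 0 & nb < 10))
})

test_that("a stimulated cell polarizes toward the cue", {
  st <- stimulus_spec(1, 275)
  dev <- vapply(1:10, function(s) {
    ax <- final_axes(simulate_cell(seed = s, stimulus = st))
    circ_dev(ax, 275)
  }, numeric(1))
  expect_gte(mean(dev < 45, na.rm = TRUE), 0.8)
})

test_that("neutralization inside the simulator preserves conservation", {
  # all molecules forced off the membrane; neutralization must rebind 10%
  p <- cell_params(T_end = 2, k_on = 0, k_fb = 0, k_off = 5000,
                   N_rac = 100L, N_rho = 100L)
  tr <- simulate_cell(params = p, seed = 3, neutralize = TRUE, check = TRUE)
  nb <- lengths(tr$bound[[1]])
  expect_true(all(nb == 10))   # exactly 10% rebound after full unbinding
  expect_equal(unname(nb + tr$inactive[, 1]), c(100, 100))
})
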