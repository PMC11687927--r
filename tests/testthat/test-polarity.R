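mk_fields <- function(arc_deg, n = 100, hi = 3, lo = 0.5, B_hi = TRUE) {
  th <- 360 * (seq_len(n) - 1) / n
  inarc <- if (arc_deg[1] <= arc_deg[2]) th >= arc_deg[1] & th <= arc_deg[2]
           else th >= arc_deg[1] | th <= arc_deg[2]
  A <- ifelse(inarc, hi, lo)
  B <- if (B_hi) ifelse(inarc, lo, hi) else rep(lo, n)
  list(A = A, B = B)
}

test_that("axis is the circular midpoint of the supra-threshold arc", {
  f <- mk_fields(c(0, 40))
  ax <- compute_axis(f$A, f$B, C_crit = 1.8)
  expect_true(ax$defined)
  expect_equal(ax$angle_deg, 18, tolerance = 3)  # midpoint of [0, 40] on grid

  # wrap across the seam: arc [350, 10] has midpoint 0
  f2 <- mk_fields(c(350, 10))
  ax2 <- compute_axis(f2$A, f2$B, C_crit = 1.8)
  expect_lt(min(ax2$angle_deg, 360 - ax2$angle_deg), 4)
})

test_that("axis is undefined when either network stays below threshold", {
  f <- mk_fields(c(0, 40), B_hi = FALSE)    # B never exceeds C_crit
  expect_false(compute_axis(f$A, f$B, C_crit = 1.8)$defined)
  expect_false(compute_axis(rep(0.5, 100), rep(3, 100), C_crit = 1.8)$defined)
})

test_that("tied arcs break by integrated density, then start index", {
  n <- 100
  A <- rep(0.5, n); B <- rep(3, n)
  A[11:20] <- 2; A[61:70] <- 2.5            # equal length, second denser
  ax <- compute_axis(A, B, C_crit = 1.8)
  expect_equal(ax$angle_deg, (65 - 1) * 3.6, tolerance = 2)
})

test_that("doublet classification follows the cone rules", {
  expect_equal(classify_doublet(10, 40), "co-alignment")
  expect_equal(classify_doublet(0, 180), "collision")
  expect_equal(classify_doublet(90, 270), "misalignment")
  expect_equal(classify_doublet(NA, 90), "non-polarized")
  expect_equal(classify_doublet(10, 170), "collision")   # inside both cones
  expect_equal(classify_doublet(25, 155), "misalignment")
})

test_that("supracellular overlay follows the leader-follower cones", {
  # cell 2 leads away from its junction, cell 1 follows toward cell 2
  expect_true(classify_supracellular(5, 10))
  expect_true(classify_supracellular(5, 10) &&
              classify_doublet(5, 10) == "co-alignment")
  # both axes toward the junction: not supracellular
  expect_false(classify_supracellular(0, 180))
  expect_false(classify_supracellular(NA, 10))
})

test_that("primary doublet labels are exhaustive and mutually exclusive", {
  grid <- expand.grid(a1 = seq(0, 359, by = 1), a2 = seq(0, 359, by = 1))
  lab <- mapply(classify_doublet, grid$a1, grid$a2)
  expect_true(all(lab %in% c("co-alignment", "collision", "misalignment")))
  # collision and co-alignment cones are geometrically disjoint
  coll <- lab == "collision"
  codiff <- angle_diff(grid$a1, grid$a2) < 45
  expect_false(any(coll & codiff))
  # supracellular never co-occurs with collision
  sup <- mapply(classify_supracellular, grid$a1, grid$a2)
  expect_false(any(sup & coll))
})

test_that("co-alignment and misalignment are rotation-equivariant", {
  set.seed(3)
  a1 <- runif(200, 0, 360); a2 <- runif(200, 0, 360); rot <- runif(200, 0, 360)
  base <- mapply(classify_doublet, a1, a2)
  keep <- base %in% c("co-alignment", "misalignment")
  rotated <- mapply(classify_doublet, (a1 + rot) %% 360, (a2 + rot) %% 360)
  # rotation can move axes into the (layout-anchored) collision cones, but
  # co-alignment can never rotate into misalignment or vice versa
  expect_false(any(base[keep] == "co-alignment" &
                   rotated[keep] == "misalignment"))
  expect_false(any(base[keep] == "misalignment" &
                   rotated[keep] == "co-alignment"))
})

test_that("quadruplet labels cover the five square arrangements", {
  expect_equal(classify_quadruplet(c(90, 90, 90, 90)), "co-alignment")
  expect_equal(classify_quadruplet(c(45, 315, 225, 135)), "circular-CW")
  expect_equal(classify_quadruplet(c(225, 135, 45, 315)), "circular-CCW")
  expect_equal(classify_quadruplet(c(0, 0, 180, 180)), "paired")
  expect_equal(classify_quadruplet(c(0, 90, 200, 330)), "misalignment")
  expect_equal(classify_quadruplet(c(0, NA, 90, 90)), "non-polarized")
  expect_error(classify_quadruplet(c(0, 90)), "four")
})

test_that("chain groups use the all-pairwise co-alignment rule", {
  expect_equal(classify_quadruplet(c(170, 180, 190, 200), "chain4"),
               "co-alignment")
  expect_equal(classify_quadruplet(c(170, 180, 190, 220), "chain4"),
               "misalignment")
})

test_that("time to polarize finds the earliest stable window", {
  # constant, defined from the start
  expect_equal(time_to_polarize(rep(90, 150), dt_out = 0.2), 0)
  # rotating 20 degrees per step never stabilises (threshold is 15)
  rot <- (20 * seq_len(300)) %% 360
  expect_true(is.na(time_to_polarize(rot, dt_out = 0.2)))
  # noisy for 50 steps, frozen afterwards: onset at entry 51
  set.seed(1)
  noisy <- c(runif(50, 0, 360), rep(123, 150))
  expect_equal(time_to_polarize(noisy, dt_out = 0.5), 50 * 0.5)
  # undefined stretches postpone the onset
  gap <- c(rep(NA, 30), rep(45, 120))
  expect_equal(time_to_polarize(gap, dt_out = 1), 30)
  expect_true(is.na(time_to_polarize(rep(7, 50), dt_out = 1)))  # too short
})
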