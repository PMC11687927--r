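#' Polarity axis from the actin fields
#'
#' The front-rear axis points from the cell center to the circular midpoint
#' of the largest contiguous arc where the branched network `A` exceeds
#' `C_crit`. The axis is undefined (cell non-polarized) if either network
#' never exceeds `C_crit`. When several disjoint supra-threshold arcs tie in
#' length, the one with the larger integrated density wins, then the smaller
#' start index. If `A` is above threshold on the whole membrane the peak
#' location of `A` is used.
#'
#' @param A,B density vectors on the periodic grid.
#' @param C_crit polarization threshold.
#' @param domain a [periodic_domain()] matching `length(A)`.
#' @return list with `defined` (logical) and `angle_deg`
#'   (degrees in `[0, 360)`, `NA` when undefined).
#' @export
compute_axis <- function(A, B, C_crit, domain = periodic_domain(n_grid = length(A))) {
  n <- length(A)
  stopifnot(length(B) == n, domain$n_grid == n)
  if (!(max(A) > C_crit && max(B) > C_crit))
    return(list(defined = FALSE, angle_deg = NA_real_))
  ab <- A > C_crit
  if (all(ab))
    return(list(defined = TRUE, angle_deg = (which.max(A) - 1) * 360 / n))
  starts <- which(ab & !ab[c(n, seq_len(n - 1))])
  best <- NULL
  for (st in starts) {
    len <- 0L; j <- st; den <- 0
    while (ab[(j - 1L) %% n + 1L] && len < n) {
      den <- den + A[(j - 1L) %% n + 1L]; len <- len + 1L; j <- j + 1L
    }
    cand <- c(len, den, -st)
    if (is.null(best) || len > best[1] ||
        (len == best[1] && (den > best[2] + 1e-12 ||
         (abs(den - best[2]) <= 1e-12 && st < -best[3]))))
      best <- cand
  }
  mid <- (-best[3] - 1) + (best[1] - 1) / 2
  list(defined = TRUE, angle_deg = (mid %% n) * 360 / n)
}

#' Classify the arrangement of a doublet's polarity axes
#'
#' Primary outcome labels:
#' \describe{
#'   \item{non-polarized}{either axis undefined.}
#'   \item{collision}{both axes point toward the cell-cell junction: each
#'     axis within an 18-degree half-angle (36-degree opening) of its cell's
#'     junction direction.}
#'   \item{co-alignment}{circular angle difference below 45 degrees.}
#'   \item{misalignment}{anything else.}
#' }
#' Collision is checked before co-alignment; under these cone widths the two
#' are geometrically exclusive, so the precedence is a safety choice only.
#'
#' @param axis1,axis2 axis angles in degrees (`NA` when undefined).
#' @param junction_dir junction facing direction of each cell (degrees);
#'   `c(0, 180)` for the standard left/right doublet.
#' @return one of `"co-alignment"`, `"collision"`, `"misalignment"`,
#'   `"non-polarized"`.
#' @export
classify_doublet <- function(axis1, axis2, junction_dir = c(0, 180)) {
  if (is.na(axis1) || is.na(axis2)) return("non-polarized")
  if (angle_diff(axis1, junction_dir[1]) <= 18 &&
      angle_diff(axis2, junction_dir[2]) <= 18) return("collision")
  if (angle_diff(axis1, axis2) < 45) return("co-alignment")
  "misalignment"
}

#' Supracellular (leader-follower) overlay label for a doublet
#'
#' TRUE when, for either assignment of leader and follower, the leader's
#' axis points away from its junction (outside a 45-degree opening, i.e.
#' more than 22.5 degrees from the junction direction) while the follower's
#' axis points toward the leader's center (within a 45-degree opening).
#' The overlay may co-occur with co-alignment or misalignment; it is
#' geometrically exclusive with collision.
#'
#' @param axis1,axis2 axis angles in degrees (`NA` when undefined).
#' @param junction_dir per-cell junction directions, default `c(0, 180)`.
#' @param toward_dir per-cell direction toward the other cell's center;
#'   defaults to `junction_dir` (coincident for a doublet).
#' @return logical flag.
#' @export
classify_supracellular <- function(axis1, axis2, junction_dir = c(0, 180),
                                   toward_dir = junction_dir) {
  if (is.na(axis1) || is.na(axis2)) return(FALSE)
  lead2 <- angle_diff(axis2, junction_dir[2]) > 22.5 &&
    angle_diff(axis1, toward_dir[1]) <= 22.5
  lead1 <- angle_diff(axis1, junction_dir[1]) > 22.5 &&
    angle_diff(axis2, toward_dir[2]) <= 22.5
  lead1 || lead2
}

#' Classify the polarity-axis arrangement of a 4-cell group
#'
#' For the square layout (cells placed clockwise from the top-left corner)
#' the possible labels are `"non-polarized"` (any axis undefined),
#' `"co-alignment"` (all pairwise circular differences below 45 degrees),
#' `"circular-CW"` / `"circular-CCW"` (each axis within 45 degrees of the
#' tangential direction of a common rotation sense around the group center),
#' `"paired"` (a partition into two pairs, each internally co-aligned, whose
#' mean directions differ by at least 45 degrees), and `"misalignment"`.
#' For the chain layout the labels are `"non-polarized"`, `"co-alignment"`
#' (all four axes mutually within 45 degrees) and `"misalignment"`.
#'
#' @param axes numeric vector of four axis angles (degrees, `NA` when
#'   undefined).
#' @param layout `"square4"` or `"chain4"`.
#' @return the outcome label.
#' @export
classify_quadruplet <- function(axes, layout = c("square4", "chain4")) {
  layout <- match.arg(layout)
  if (length(axes) != 4L) stop("need exactly four axes")
  if (anyNA(axes)) return("non-polarized")
  pw <- utils::combn(4, 2)
  alldiff <- apply(pw, 2, function(ij) angle_diff(axes[ij[1]], axes[ij[2]]))
  if (all(alldiff < 45)) return("co-alignment")
  if (layout == "chain4") return("misalignment")

  posang <- c(135, 45, 315, 225)            # cell position angles from center
  cw <- (posang - 90) %% 360
  ccw <- (posang + 90) %% 360
  if (all(angle_diff(axes, cw) < 45)) return("circular-CW")
  if (all(angle_diff(axes, ccw) < 45)) return("circular-CCW")

  pairings <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                   list(c(1, 4), c(2, 3)))
  for (pp in pairings) {
    d1 <- angle_diff(axes[pp[[1]][1]], axes[pp[[1]][2]])
    d2 <- angle_diff(axes[pp[[2]][1]], axes[pp[[2]][2]])
    if (d1 < 45 && d2 < 45) {
      m1 <- circ_mean(axes[pp[[1]]])
      m2 <- circ_mean(axes[pp[[2]]])
      if (angle_diff(m1, m2) >= 45) return("paired")
    }
  }
  "misalignment"
}

circ_mean <- function(deg) {
  r <- deg * pi / 180
  (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
}

#' Classify a simulated trajectory at its final time
#'
#' Applies the layout-appropriate outcome classifier to the final recorded
#' axes of a [simulate_group()] trajectory.
#'
#' @param traj a `copol_traj`.
#' @return for a single cell, `list(outcome = "polarized"|"non-polarized")`;
#'   for a doublet, `list(outcome, supracellular, axes)`; for a 4-cell
#'   layout, `list(outcome, axes)`.
#' @export
classify_trajectory <- function(traj) {
  ax <- final_axes(traj)
  layout <- traj$map$layout
  if (layout == "single") {
    return(list(outcome = if (is.na(ax[1])) "non-polarized" else "polarized",
                axes = ax))
  }
  if (layout == "doublet") {
    jd <- vapply(junction_directions(traj$map), `[`, numeric(1), 1)
    return(list(outcome = classify_doublet(ax[1], ax[2], jd),
                supracellular = classify_supracellular(ax[1], ax[2], jd),
                axes = ax))
  }
  list(outcome = classify_quadruplet(ax, layout), axes = ax)
}

#' Time to reach a stable polarized axis
#'
#' The earliest time at which the axis is defined throughout a window of
#' `window` consecutive recorded steps and every consecutive angular change
#' within the window stays below `tol_deg` (pi/12 radians = 15 degrees by
#' default). `NA` if the condition is never met.
#'
#' @param axis_deg numeric vector of recorded axis angles (`NA` when
#'   undefined), sampled at the simulation stride.
#' @param dt_out time between recorded entries (seconds).
#' @param window number of recorded steps the axis must stay stable.
#' @param tol_deg maximum consecutive angular change (degrees).
#' @return time in seconds, or `NA`.
#' @export
time_to_polarize <- function(axis_deg, dt_out, window = 100L, tol_deg = 15) {
  n <- length(axis_deg)
  if (n < window + 1L) return(NA_real_)
  ok <- !is.na(axis_deg)
  small <- c(ok[-1] & ok[-n] &
               angle_diff(axis_deg[-1], axis_deg[-n]) < tol_deg, FALSE)
  run <- 0L
  # scan from the end: run[i] = consecutive TRUE entries of `small` from i
  runs <- integer(n)
  for (i in n:1) {
    run <- if (small[i]) run + 1L else 0L
    runs[i] <- run
  }
  idx <- which(ok & runs >= window)
  if (length(idx) == 0L) return(NA_real_)
  (idx[1] - 1L) * dt_out
}
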