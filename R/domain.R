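#' Periodic membrane domain
#'
#' The plasma membrane of each model cell is a static circular 1D periodic
#' domain of arclength `perimeter`, discretised into `n_grid` points.
#' Grid point `i` (1-based) sits at arclength `s = (i-1) * ds` and angle
#' `theta = 360 * (i-1) / n_grid` degrees, measured counterclockwise from the
#' positive horizontal axis.
#'
#' @param perimeter total membrane arclength (model length units).
#' @param n_grid number of grid points (at least 16).
#' @return an object of class `copol_domain` with fields `perimeter`,
#'   `n_grid`, `ds`, and the grid angles `theta_deg`.
#' @export
periodic_domain <- function(perimeter = 10, n_grid = 100) {
  stopifnot(perimeter > 0, n_grid >= 16)
  structure(
    list(perimeter = perimeter, n_grid = as.integer(n_grid),
         ds = perimeter / n_grid,
         theta_deg = 360 * (seq_len(n_grid) - 1) / n_grid),
    class = "copol_domain")
}

#' Angle (degrees) of an arclength position on the domain
#' @param domain a [periodic_domain()].
#' @param s arclength position(s).
#' @export
arc_to_angle <- function(domain, s) {
  (s %% domain$perimeter) / domain$perimeter * 360
}

#' Count membrane-bound molecules near a position
#'
#' Number of bound molecules within the open periodic arc
#' `(s - radius, s + radius)`. This is the local count `n` that enters the
#' actin growth terms `A(1 + alpha * n_Rac)` and the mutual-inhibition /
#' recruitment neighbourhoods.
#'
#' @param positions numeric vector of bound-molecule arclength positions.
#' @param s query arclength.
#' @param radius neighbourhood half-width (arclength), positive.
#' @param perimeter domain perimeter.
#' @return integer count.
#' @export
local_count <- function(positions, s, radius, perimeter) {
  stopifnot(radius > 0, perimeter > 0)
  if (length(positions) == 0L) return(0L)
  d <- abs((positions - s) %% perimeter)
  d <- pmin(d, perimeter - d)
  sum(d < radius)
}

#' Smallest circular difference between two angles, in degrees
#' @param a,b angles in degrees.
#' @return value in `[0, 180]`.
#' @export
angle_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}
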