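#' External stimulus specification
#'
#' A directional external cue applied to one cell. While active, the cue
#' replaces the cell's actin-dependent GTPase binding rates with spatially
#' fixed profiles: the Rac binding rate is a smooth raised-cosine bump
#' peaked at `center_deg`, and the Rho binding rate is its spatial
#' complement, so that the pointwise sum of the two rates is constant around
#' the membrane.
#'
#' @param cell index of the exposed cell.
#' @param center_deg peak direction of the Rac-binding profile (degrees,
#'   counterclockwise from horizontal).
#' @param amplitude relative bump amplitude `a`: the Rac rate rises to
#'   `k0 * (1 + a)` at the peak while the Rho rate falls to `k0` there;
#'   `amplitude = 0` gives uniform baseline profiles.
#' @param width_deg half-width of the raised-cosine bump (degrees).
#' @param t_on,t_off activity window in seconds (`t_on <= t < t_off`).
#' @return an object of class `copol_stimulus`.
#' @export
stimulus_spec <- function(cell, center_deg, amplitude = 5, width_deg = 90,
                          t_on = 0, t_off = Inf) {
  stopifnot(amplitude >= 0, width_deg > 0, t_off > t_on)
  structure(list(cell = as.integer(cell), center_deg = center_deg,
                 amplitude = amplitude, width_deg = width_deg,
                 t_on = t_on, t_off = t_off),
            class = "copol_stimulus")
}

#' Stimulus binding-rate profiles around the membrane
#'
#' Evaluates the spatially fixed binding-rate profiles imposed by an active
#' stimulus. With bump `b(delta) = (1 + cos(pi * delta / w)) / 2` for
#' `|delta| < w` (zero outside),
#' `k_on_rac(theta) = k0 * (1 + a * b(theta - center))` and
#' `k_on_rho(theta) = k0 * (1 + a * (1 - b(theta - center)))`, so
#' `k_on_rac + k_on_rho = k0 * (2 + a)` everywhere.
#'
#' @param spec a [stimulus_spec()].
#' @param domain a [periodic_domain()].
#' @param k0 baseline binding rate the profiles are built on.
#' @param t time (seconds); outside the activity window the baseline
#'   (uniform `k0`) profiles are returned.
#' @return an `n_grid x 2` matrix, columns `rac` and `rho`.
#' @export
stimulus_rate_profile <- function(spec, domain, k0, t = spec$t_on) {
  th <- domain$theta_deg
  if (t < spec$t_on || t >= spec$t_off) {
    out <- cbind(rac = rep(k0, domain$n_grid), rho = rep(k0, domain$n_grid))
    return(out)
  }
  d <- angle_diff(th, spec$center_deg)
  b <- ifelse(d < spec$width_deg, (1 + cos(pi * d / spec$width_deg)) / 2, 0)
  cbind(rac = k0 * (1 + spec$amplitude * b),
        rho = k0 * (1 + spec$amplitude * (1 - b)))
}

#' Rebind a fraction of a fully unbound species
#'
#' Neutralization step used in signal-switch experiments: if every molecule
#' of a species has dissociated from the membrane, a fraction of the pool is
#' rebound at independent uniform positions (mirroring the initialization
#' rule). Species with at least one bound molecule are left unchanged.
#'
#' @param bound numeric vector of bound positions for one species.
#' @param n_total total molecule count of the species.
#' @param frac fraction to rebind (default 0.1).
#' @param perimeter membrane perimeter.
#' @return numeric vector of bound positions after the (possible) reset.
#' @export
neutralize_if_depleted <- function(bound, n_total, frac = 0.1, perimeter = 10) {
  if (length(bound) > 0L || n_total <= 0L) return(bound)
  stats::runif(round(frac * n_total), 0, perimeter)
}
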