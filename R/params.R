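#' Kinetic and network parameters for one model cell
#'
#' Bundles all per-cell constants of the mechanochemical polarity model:
#' GTPase cycling rates, the actin reaction-diffusion coefficients, the
#' bidirectional coupling strengths, and the numerical step sizes.
#'
#' Parameter meanings (units are model units: arclength `u`, seconds `s`):
#' \describe{
#'   \item{k_on}{baseline membrane association rate of an inactive GTPase
#'     molecule (1/s). The effective rate is actin-dependent, see
#'     [effective_kon()].}
#'   \item{k_off}{membrane dissociation rate of a bound molecule (1/s).}
#'   \item{k_fb}{autocatalytic recruitment rate: each bound molecule recruits
#'     inactive molecules of its own species to within
#'     `inhibition_radius` of itself (1/s).}
#'   \item{D_actin}{diffusion coefficient of both F-actin density fields
#'     (u^2/s).}
#'   \item{D_membrane}{lateral diffusion coefficient of membrane-bound
#'     GTPase molecules (u^2/s); 0 gives immobile bound molecules.}
#'   \item{alpha}{coupling of local bound-GTPase counts into the actin growth
#'     rates (per molecule).}
#'   \item{beta_rev}{reverse coupling: local actin density multiplies the
#'     GTPase binding rate as `k_on * (1 + beta_rev * density)`.}
#'   \item{m0}{competition strength between the branched and bundled
#'     networks.}
#'   \item{N_rac, N_rho}{total molecule numbers per species (bound +
#'     inactive; conserved).}
#'   \item{C_crit}{density threshold defining a polarized network region.}
#'   \item{inhibition_radius}{arclength half-width of the neighbourhood used
#'     for mutual inhibition, recruitment and local counts (u).}
#'   \item{dt, T_end}{time step and simulated duration (s).}
#'   \item{init_frac}{fraction of molecules bound at random positions at
#'     t = 0 (and after neutralization).}
#'   \item{init_noise}{relative amplitude of the uniform perturbation applied
#'     to the homogeneous unit actin baseline at t = 0.}
#'   \item{eps_A0, eps_B0}{whole-domain additive growth offsets (cell
#'     variability experiments; zero by default).}
#' }
#'
#' @param ... named overrides of any default listed above; per-species rate
#'   overrides are available as `k_on_rac`, `k_on_rho`, `k_off_rac`,
#'   `k_off_rho` (defaulting to the shared `k_on` / `k_off`).
#' @return an object of class `copol_params`.
#' @export
cell_params <- function(...) {
  p <- params_default()
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  validate_params(p)
}

#' Default calibrated parameter profile
#'
#' The profile is calibrated so that (a) a single cell spontaneously
#' polarizes in at least 90 of 100 realizations by `T_end`, and (b) an
#' uncoupled doublet co-aligns in roughly a quarter of realizations (the
#' value implied by independent, uniformly oriented axes). See the methods
#' vignette for the calibration procedure.
#'
#' @return a `copol_params` object.
#' @export
params_default <- function() {
  structure(list(
    k_on = 0.8, k_off = 3.0, k_fb = 2.0,
    k_on_rac = NA_real_, k_on_rho = NA_real_,
    k_off_rac = NA_real_, k_off_rho = NA_real_,
    D_actin = 0.1, D_membrane = 0, alpha = 0.03, beta_rev = 4.0, m0 = 2.0,
    N_rac = 300L, N_rho = 300L,
    C_crit = 1.8, inhibition_radius = 0.3,
    dt = 0.02, T_end = 100,
    init_frac = 0.1, init_noise = 0.01,
    eps_A0 = 0, eps_B0 = 0),
    class = "copol_params")
}

validate_params <- function(p) {
  num <- c("k_on", "k_off", "k_fb", "D_actin", "D_membrane", "alpha",
           "beta_rev", "m0",
           "C_crit", "inhibition_radius", "dt", "T_end", "init_frac",
           "init_noise")
  for (nm in num)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop("parameter '", nm, "' must be a nonnegative scalar")
  if (p$dt <= 0 || p$T_end <= 0) stop("dt and T_end must be positive")
  if (p$N_rac < 0 || p$N_rho < 0) stop("molecule counts must be nonnegative")
  if (p$N_rac + p$N_rho <= 0) stop("configuration error: no molecules (N <= 0)")
  p$N_rac <- as.integer(p$N_rac); p$N_rho <- as.integer(p$N_rho)
  class(p) <- "copol_params"
  p
}

# resolve per-species rates
species_rates <- function(p) {
  kon <- c(ifelse(is.na(p$k_on_rac), p$k_on, p$k_on_rac),
           ifelse(is.na(p$k_on_rho), p$k_on, p$k_on_rho))
  koff <- c(ifelse(is.na(p$k_off_rac), p$k_off, p$k_off_rac),
            ifelse(is.na(p$k_off_rho), p$k_off, p$k_off_rho))
  list(kon = kon, koff = koff)
}

#' Effective actin-dependent, junction-amplified binding rate
#'
#' The GTPase binding affinity is not fixed: it grows linearly with the local
#' density of the corresponding F-actin network (branched for Rac, bundled
#' for Rho) and is multiplied by any junction amplification factor.
#'
#' @param base_kon baseline binding rate (1/s).
#' @param actin_local_density local density of the respective network.
#' @param beta_rev reverse-coupling strength.
#' @param junction_factor multiplicative junction amplification (>= 1 inside
#'   the intercellular region, 1 elsewhere).
#' @return the effective rate
#'   `junction_factor * base_kon * (1 + beta_rev * actin_local_density)`.
#' @export
effective_kon <- function(base_kon, actin_local_density, beta_rev,
                          junction_factor = 1) {
  stopifnot(all(base_kon >= 0), all(actin_local_density >= 0),
            all(beta_rev >= 0), all(junction_factor >= 0))
  junction_factor * base_kon * (1 + beta_rev * actin_local_density)
}

#' Apply whole-cell baseline variability to a parameter set
#'
#' Cell-to-cell variability experiments elevate a cell's baseline kinetics or
#' network growth over its entire domain: multiplicative factors on the
#' binding/unbinding rates (e.g. a 10-fold Rac binding rate) or additive
#' whole-domain growth offsets (e.g. `eps_A0 = 1`). Junction regulation later
#' composes multiplicatively on top of these baselines.
#'
#' @param params a `copol_params` object.
#' @param overrides named list; recognised names are `k_on_rac_mult`,
#'   `k_on_rho_mult`, `k_off_rac_mult`, `k_off_rho_mult`, `k_fb_mult`,
#'   `eps_A0`, `eps_B0`.
#' @return modified `copol_params`.
#' @export
apply_cell_variability <- function(params, overrides = list()) {
  if (length(overrides) == 0L) return(params)
  known <- c("k_on_rac_mult", "k_on_rho_mult", "k_off_rac_mult",
             "k_off_rho_mult", "k_fb_mult", "eps_A0", "eps_B0")
  unknown <- setdiff(names(overrides), known)
  if (length(unknown))
    stop("unknown variability override(s): ", paste(unknown, collapse = ", "))
  mults <- overrides[grepl("_mult$", names(overrides))]
  if (any(unlist(mults) < 0)) stop("variability factors must be nonnegative")
  r <- species_rates(params)
  g <- function(nm) if (is.null(overrides[[nm]])) 1 else overrides[[nm]]
  params$k_on_rac <- r$kon[1] * g("k_on_rac_mult")
  params$k_on_rho <- r$kon[2] * g("k_on_rho_mult")
  params$k_off_rac <- r$koff[1] * g("k_off_rac_mult")
  params$k_off_rho <- r$koff[2] * g("k_off_rho_mult")
  params$k_fb <- params$k_fb * g("k_fb_mult")
  if (!is.null(overrides$eps_A0)) params$eps_A0 <- overrides$eps_A0
  if (!is.null(overrides$eps_B0)) params$eps_B0 <- overrides$eps_B0
  params
}
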