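#' Simulate a cell group
#'
#' Steps the coupled stochastic-GTPase / reaction-diffusion model for a
#' single cell, a doublet, or a 4-cell group (chain or square), with any
#' combination of junction couplings, whole-cell variability and external
#' stimuli. All cells advance jointly; every intercellular term reads the
#' neighbour's previous-step state, so with all couplings disabled the group
#' is exactly a set of independent single-cell simulations (bit-for-bit,
#' given matched per-cell seeds).
#'
#' @param layout `"single"`, `"doublet"`, `"chain4"` or `"square4"` (or a
#'   prebuilt [build_junction_map()] via `map`).
#' @param params a [cell_params()] object, or a list of one per cell for
#'   variability experiments.
#' @param coupling `list(gtpase = ..., actin = ...)` of regulation entries,
#'   e.g. from [coupling_motif()]; `NULL` for an uncoupled group.
#' @param stimulus a [stimulus_spec()] or list of them (a switch schedule).
#' @param f_cc junction fraction of the perimeter.
#' @param seed integer root seed; per-cell independent substreams are derived
#'   deterministically from `(seed, cell index)`.
#' @param cell_seeds optional explicit per-cell stream seeds (overrides
#'   `seed`); used to match a group run against single-cell runs.
#' @param domain a [periodic_domain()].
#' @param map optional prebuilt junction map (overrides `layout`, `f_cc`,
#'   `domain`).
#' @param stride record the axis every `stride` steps.
#' @param record_fields keep full A/B and binned GTPase snapshots at the
#'   recording stride (needed for kymographs).
#' @param neutralize enable the neutralization rule (signal-switch
#'   experiments).
#' @param veto mutual-inhibition veto probability in `[0, 1]`; 1 is the
#'   default hard veto.
#' @param check assert mass conservation at every step.
#' @param init_pos,init_fields optional explicit initial conditions (lists
#'   indexed by cell), used by tests.
#' @return an object of class `copol_traj`: recorded `time`, per-cell `axis`
#'   (degrees; `NA` while undefined) and `polarized` matrices, final fields
#'   and bound positions, and the layout/classification geometry.
#' @export
simulate_group <- function(layout = "doublet", params = cell_params(),
                           coupling = NULL, stimulus = NULL, f_cc = 0.25,
                           seed = 1, cell_seeds = NULL,
                           domain = periodic_domain(), map = NULL,
                           stride = 10L, record_fields = FALSE,
                           neutralize = FALSE, veto = 1, check = FALSE,
                           init_pos = NULL, init_fields = NULL) {
  if (is.null(map)) map <- build_junction_map(layout, f_cc, domain)
  domain <- map$domain
  nc <- map$n_cells
  if (inherits(params, "copol_params")) params <- rep(list(params), nc)
  if (length(params) != nc) stop("need one parameter set per cell")

  p1 <- params[[1]]
  dt <- p1$dt
  n_steps <- as.integer(round(p1$T_end / dt))
  stride <- as.integer(stride)
  if (n_steps %% stride != 0L)
    n_steps <- as.integer(ceiling(n_steps / stride) * stride)
  for (p in params) {
    if (abs(p$dt - dt) > 1e-12)
      stop("all cells must share the same time step")
    if (p$dt > domain$ds^2 / (4 * p$D_actin) + 1e-12)
      stop("dt violates the diffusion stability bound ds^2 / (4 * D)")
  }

  if (is.null(coupling)) coupling <- list(gtpase = list(), actin = list())
  if (is.null(coupling$gtpase)) coupling$gtpase <- list()
  if (is.null(coupling$actin)) coupling$actin <- list()
  cc <- compile_coupling(map, coupling)

  if (inherits(stimulus, "copol_stimulus")) stimulus <- list(stimulus)
  stim <- lapply(stimulus, function(s) {
    k0 <- species_rates(params[[s$cell]])$kon[1]
    list(cell = s$cell,
         step_on = as.integer(max(0, floor(s$t_on / dt))),
         step_off = as.integer(min(n_steps, ceiling(
           if (is.finite(s$t_off)) s$t_off / dt else n_steps))),
         prof = stimulus_rate_profile(s, domain, k0, t = s$t_on))
  })

  if (is.null(cell_seeds))
    cell_seeds <- vapply(seq_len(nc) - 1L, function(i)
      derive_cell_seed_cpp(as.double(seed), i), numeric(1))

  cells <- lapply(seq_len(nc), function(i) {
    p <- params[[i]]
    r <- species_rates(p)
    cl <- list(kon = r$kon, koff = r$koff, kfb = p$k_fb, alpha = p$alpha,
               beta = p$beta_rev, m0 = p$m0, D = p$D_actin,
               Dmem = p$D_membrane,
               rinh = p$inhibition_radius, Ccrit = p$C_crit,
               N = c(p$N_rac, p$N_rho), eps0 = c(p$eps_A0, p$eps_B0),
               init_frac = p$init_frac, init_noise = p$init_noise,
               seed = cell_seeds[i])
    if (!is.null(init_pos) && !is.null(init_pos[[i]]))
      cl$init_pos <- list(init_pos[[i]]$rac, init_pos[[i]]$rho)
    if (!is.null(init_fields) && !is.null(init_fields[[i]])) {
      cl$initA <- init_fields[[i]]$A
      cl$initB <- init_fields[[i]]$B
    }
    cl
  })

  cfg <- list(n_grid = domain$n_grid, ds = domain$ds, dt = dt,
              n_steps = n_steps, stride = stride,
              cells = cells, konfac = cc$konfac, kofffac = cc$kofffac,
              epsc = cc$epsc, dyn_rate = cc$dyn_rate, dyn_eps = cc$dyn_eps,
              stim = stim, neutralize = neutralize, veto = veto,
              check = check, record_fields = record_fields)
  out <- sim_group_cpp(cfg)

  structure(list(
    time = out$time, axis = out$axis, polarized = out$polarized,
    A = out$A, B = out$B, bound = out$bound, inactive = out$inactive,
    A_snapshots = out$A_snapshots, B_snapshots = out$B_snapshots,
    rac_snapshots = out$rac_snapshots, rho_snapshots = out$rho_snapshots,
    map = map, params = params, seed = seed, cell_seeds = cell_seeds,
    dt = dt, stride = stride),
    class = "copol_traj")
}

#' Deterministic per-cell RNG stream seed
#'
#' The independent RNG substream of cell `cell_index` (0-based) in a group
#' run with root seed `seed`. Passing this value as `cell_seeds` to a
#' single-cell run reproduces that cell of the group bit-for-bit when all
#' couplings are disabled.
#'
#' @param seed integer root seed; `cell_index` 0-based cell position.
#' @return numeric stream seed (an integer below 2^53).
#' @export
derive_cell_seed <- function(seed, cell_index) {
  derive_cell_seed_cpp(as.double(seed), as.integer(cell_index))
}

#' Simulate a single cell
#'
#' Convenience wrapper around [simulate_group()] with `layout = "single"`.
#' @inheritParams simulate_group
#' @param ... passed on to [simulate_group()].
#' @return a `copol_traj` with one cell.
#' @export
simulate_cell <- function(params = cell_params(), seed = 1, ...) {
  simulate_group(layout = "single", params = params, seed = seed, ...)
}

#' Final per-cell polarity axes of a trajectory
#' @param traj a `copol_traj`.
#' @return numeric vector of axis angles in degrees (`NA` when undefined).
#' @export
final_axes <- function(traj) {
  traj$axis[nrow(traj$axis), ]
}

#' @export
print.copol_traj <- function(x, ...) {
  ax <- final_axes(x)
  cat("<copol_traj> ", x$map$layout, ", ", ncol(x$axis), " cell(s), T = ",
      max(x$time), " s\n", sep = "")
  cat("final axes (deg):",
      paste(ifelse(is.na(ax), "undefined", sprintf("%.1f", ax)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Tidy axis track of a trajectory
#' @param x a `copol_traj`.
#' @param ... unused.
#' @return a tibble with columns `time`, `cell`, `axis_angle_deg`,
#'   `polarized`.
#' @export
as_tibble.copol_traj <- function(x, ...) {
  nc <- ncol(x$axis)
  tibble::tibble(
    time = rep(x$time, nc),
    cell = rep(seq_len(nc), each = length(x$time)),
    axis_angle_deg = as.vector(x$axis),
    polarized = as.vector(x$polarized))
}

#' Write the axis track of a trajectory to CSV
#' @param traj a `copol_traj`; `path` output file.
#' @return `path`, invisibly.
#' @export
export_trajectory_csv <- function(traj, path) {
  utils::write.csv(as_tibble.copol_traj(traj), path, row.names = FALSE)
  invisible(path)
}
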