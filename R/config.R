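#' Load and validate a run configuration
#'
#' Run configurations are flat YAML files describing a simulation or screen:
#' layout, parameter overrides, coupling motif, stimulus schedule,
#' realization counts and seeds. Unknown keys are rejected (with the
#' offending key named), defaults are filled in explicitly, and the
#' resolved configuration round-trips losslessly through [save_config()].
#'
#' Recognised keys: `layout`, `f_cc`, `n_realizations`, `seed`, `stride`,
#' `neutralize`, `params` (named list of [cell_params()] overrides),
#' `coupling` (named list with `motif`, `gamma`, `eps`, `conc_dependent`),
#' `stimulus` (list of blocks with `cell`, `center_deg`, `amplitude`,
#' `width_deg`, `t_on`, `t_off`), `out_dir`.
#'
#' @param path YAML file path.
#' @return a validated `copol_config` list with all defaults resolved.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' @rdname load_config
#' @param config a named list of configuration values (possibly partial).
#' @export
as_run_config <- function(config) {
  known <- c("layout", "f_cc", "n_realizations", "seed", "stride",
             "neutralize", "params", "coupling", "stimulus", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(layout = "doublet", f_cc = 0.25, n_realizations = 100L,
                   seed = 1L, stride = 10L, neutralize = FALSE,
                   params = list(), coupling = NULL, stimulus = NULL,
                   out_dir = NULL)
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (!cfg$layout %in% c("single", "doublet", "chain4", "square4"))
    stop("layout: must be single, doublet, chain4 or square4")
  if (!(cfg$f_cc > 0 && cfg$f_cc < 1)) stop("f_cc: must be in (0, 1)")
  if (cfg$n_realizations < 1) stop("n_realizations: must be positive")
  if (!is.null(cfg$coupling)) {
    cu <- setdiff(names(cfg$coupling),
                  c("motif", "gamma", "eps", "conc_dependent"))
    if (length(cu)) stop("coupling: unknown key(s): ",
                         paste(cu, collapse = ", "))
  }
  for (s in cfg$stimulus) {
    su <- setdiff(names(s), c("cell", "center_deg", "amplitude",
                              "width_deg", "t_on", "t_off"))
    if (length(su)) stop("stimulus: unknown key(s): ",
                         paste(su, collapse = ", "))
  }
  do.call(cell_params, cfg$params)  # validates overrides
  structure(cfg, class = "copol_config")
}

#' Write a run configuration to YAML
#' @param config a `copol_config` (or compatible list).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Materialise a run configuration into simulator arguments
#'
#' Expands a validated configuration into the argument list used by
#' [simulate_group()] / [run_screen()]: the junction map, parameter set,
#' coupling block and stimulus schedule.
#'
#' @param config a `copol_config`.
#' @return a named list with `map`, `params`, `coupling`, `stimulus`,
#'   `n_realizations`, `seed`, `neutralize`, `stride`.
#' @export
build_run <- function(config) {
  map <- build_junction_map(config$layout, config$f_cc)
  params <- do.call(cell_params, config$params)
  coupling <- NULL
  if (!is.null(config$coupling)) {
    cu <- config$coupling
    coupling <- coupling_motif(
      map, motif = cu$motif,
      gamma = if (is.null(cu$gamma)) 1000 else cu$gamma,
      eps = if (is.null(cu$eps)) 1 else cu$eps,
      conc_dependent = isTRUE(cu$conc_dependent))
  }
  stimulus <- lapply(config$stimulus, function(s) do.call(stimulus_spec, s))
  if (length(stimulus) == 0L) stimulus <- NULL
  list(map = map, params = params, coupling = coupling, stimulus = stimulus,
       n_realizations = config$n_realizations, seed = config$seed,
       neutralize = config$neutralize, stride = config$stride)
}
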