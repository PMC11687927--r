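#' Space-time kymographs from a trajectory
#'
#' Extracts space (rows) by time (columns) arrays of the branched and
#' bundled network densities and of the binned bound-GTPase counts from a
#' trajectory recorded with `record_fields = TRUE`, optionally averaging
#' several realizations, and can write them as plain CSV.
#'
#' @param trajectories a `copol_traj`, or a list of them to average (all
#'   from the same configuration).
#' @param cell which cell's fields to extract.
#' @param path optional directory; when given, writes `A.csv`, `B.csv`,
#'   `rac.csv`, `rho.csv` there.
#' @return a list of matrices `A`, `B`, `rac`, `rho` (`n_grid` rows,
#'   one column per recorded time), with the recorded times as `time`.
#' @export
export_kymograph <- function(trajectories, cell = 1, path = NULL) {
  if (inherits(trajectories, "copol_traj"))
    trajectories <- list(trajectories)
  if (is.null(trajectories[[1]]$A_snapshots))
    stop("no snapshots recorded; rerun with record_fields = TRUE")
  get <- function(tr, what) tr[[what]][[cell]]
  avg <- function(what) {
    acc <- get(trajectories[[1]], what) * 1.0
    if (length(trajectories) > 1)
      for (tr in trajectories[-1]) acc <- acc + get(tr, what)
    acc / length(trajectories)
  }
  out <- list(A = avg("A_snapshots"), B = avg("B_snapshots"),
              rac = avg("rac_snapshots"), rho = avg("rho_snapshots"),
              time = trajectories[[1]]$time)
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("A", "B", "rac", "rho"))
      utils::write.csv(out[[nm]], file.path(path, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  out
}
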