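#' Enumerate the biochemical (GTPase rate) coupling grid
#'
#' All combinations of one up-regulation per cell: each cell is assigned
#' either no modification or one `(species, rate)` slot amplified by a
#' factor from `gammas` at the junction. With the default four factor
#' choices this is the systematic doublet screen of binding/unbinding
#' amplifications.
#'
#' @param gammas amplification factors to enumerate; values equal to 1 mean
#'   "no modification".
#' @param conc_dependent enumerate the concentration-dependent variant.
#' @param collapse_symmetric drop configurations that duplicate another under
#'   exchange of the two cell labels.
#' @return a tibble with one row per configuration: `config_id`,
#'   `cell1_species`, `cell1_rate`, `cell1_gamma` (and the cell-2
#'   counterparts; `NA` species/rate means unmodified) plus
#'   `conc_dependent`.
#' @export
enumerate_biochemical_grid <- function(gammas = c(1, 10, 100, 1000),
                                       conc_dependent = FALSE,
                                       collapse_symmetric = FALSE) {
  slots <- expand.grid(species = c("rac", "rho"), rate = c("on", "off"),
                       gamma = gammas[gammas > 1], stringsAsFactors = FALSE)
  opts <- rbind(data.frame(species = NA_character_, rate = NA_character_,
                           gamma = 1), slots)
  idx <- expand.grid(i1 = seq_len(nrow(opts)), i2 = seq_len(nrow(opts)))
  g <- tibble::tibble(
    cell1_species = opts$species[idx$i1], cell1_rate = opts$rate[idx$i1],
    cell1_gamma = opts$gamma[idx$i1],
    cell2_species = opts$species[idx$i2], cell2_rate = opts$rate[idx$i2],
    cell2_gamma = opts$gamma[idx$i2],
    conc_dependent = conc_dependent)
  if (collapse_symmetric) {
    key <- function(s1, r1, g1, s2, r2, g2) {
      a <- paste(s1, r1, g1); b <- paste(s2, r2, g2)
      paste(pmin(a, b), pmax(a, b))
    }
    k <- key(g$cell1_species, g$cell1_rate, g$cell1_gamma,
             g$cell2_species, g$cell2_rate, g$cell2_gamma)
    g <- g[!duplicated(k), ]
  }
  g$config_id <- seq_len(nrow(g))
  g[, c("config_id", setdiff(names(g), "config_id"))]
}

#' Enumerate the structural (F-actin growth) coupling grid
#'
#' The full three-level screen of junction growth modifications: the
#' concentration-independent family varies the four constants
#' `eps_A`, `eps_B` in each cell over `{-e, 0, +e}` (81 configurations), and
#' the concentration-dependent family varies the four crosstalk coefficients
#' `eps_AA`, `eps_AB`, `eps_BA`, `eps_BB` over the same three levels
#' (81 more), for 162 configurations in total.
#'
#' @param e_magnitude positive modification magnitude `e`.
#' @return a tibble with `config_id`, `family`
#'   (`"constant"`/`"dependent"`) and the four coefficient columns
#'   (`epsA1`, `epsB1`, `epsA2`, `epsB2` for the constant family;
#'   `eAA`, `eAB`, `eBA`, `eBB` for the dependent family, `NA` otherwise).
#' @export
enumerate_structural_grid <- function(e_magnitude = 1) {
  stopifnot(e_magnitude > 0)
  lv <- c(-e_magnitude, 0, e_magnitude)
  const <- expand.grid(epsA1 = lv, epsB1 = lv, epsA2 = lv, epsB2 = lv)
  dep <- expand.grid(eAA = lv, eAB = lv, eBA = lv, eBB = lv)
  g <- dplyr::bind_rows(
    tibble::tibble(family = "constant", const,
                   eAA = NA_real_, eAB = NA_real_, eBA = NA_real_,
                   eBB = NA_real_),
    tibble::tibble(family = "dependent",
                   epsA1 = NA_real_, epsB1 = NA_real_, epsA2 = NA_real_,
                   epsB2 = NA_real_, dep))
  g$config_id <- seq_len(nrow(g))
  g[, c("config_id", setdiff(names(g), "config_id"))]
}

# build a coupling block from one grid row (doublet junction = cells 1, 2)
coupling_from_config <- function(map, cfg) {
  g <- list(); a <- list()
  if (!is.null(cfg$family)) {                      # structural grid row
    if (cfg$family == "constant") {
      for (j in map$junctions) {
        a <- c(a, list(
          actin_regulation(j$cells, j$cells[1], cfg$epsA1, cfg$epsB1),
          actin_regulation(j$cells, j$cells[2], cfg$epsA2, cfg$epsB2)))
      }
    } else {
      for (j in map$junctions)
        a <- c(a, list(actin_crosstalk(j$cells, c(
          AA = cfg$eAA, AB = cfg$eAB, BA = cfg$eBA, BB = cfg$eBB))))
    }
  } else {                                          # biochemical grid row
    for (j in map$junctions) {
      for (side in 1:2) {
        sp <- cfg[[paste0("cell", side, "_species")]]
        rt <- cfg[[paste0("cell", side, "_rate")]]
        gm <- cfg[[paste0("cell", side, "_gamma")]]
        if (!is.na(sp) && gm > 1)
          g <- c(g, list(gtpase_regulation(
            j$cells, j$cells[side], sp, rt, gm,
            conc_dependent = isTRUE(cfg$conc_dependent))))
      }
    }
  }
  list(gtpase = g, actin = a)
}

#' Run an outcome-probability screen
#'
#' Runs `n_realizations` independent group simulations for every
#' configuration of a coupling grid, classifies each realization, and
#' aggregates outcome probabilities. Deterministic for a given `base_seed`:
#' realization `r` of configuration `c` uses root seed
#' `(base_seed + 100003 * c + r) mod (2^31 - 1)`, so the same seeds recur
#' across configurations (common random numbers).
#'
#' @param grid a tibble of configurations (from
#'   [enumerate_biochemical_grid()], [enumerate_structural_grid()], or a
#'   compatible hand-built tibble with a `config_id` column). May also be a
#'   list of prebuilt coupling blocks (named, one per configuration).
#' @param layout group layout.
#' @param n_realizations realizations per configuration.
#' @param base_seed integer.
#' @param params a [cell_params()] object or per-cell list.
#' @param stimulus optional [stimulus_spec()] (or list) applied in every run.
#' @param f_cc junction fraction.
#' @param neutralize passed to [simulate_group()].
#' @param success_threshold co-alignment probability declaring a
#'   configuration successful (default 0.70).
#' @param cache optional CSV path; per-realization labels are appended there
#'   and completed (configuration, realization) pairs are skipped on rerun.
#' @return a `copol_screen` tibble: one row per configuration with outcome
#'   probabilities (`p_coalign`, `p_collision`, `p_misalign`,
#'   `p_nonpolar`, `p_supra`), `n`, `success`, and a list-column `labels`
#'   of per-realization outcomes (with seeds).
#' @export
run_screen <- function(grid, layout = "doublet", n_realizations = 100,
                       base_seed = 1, params = cell_params(),
                       stimulus = NULL, f_cc = 0.25, neutralize = FALSE,
                       success_threshold = 0.70, cache = NULL) {
  map <- build_junction_map(layout, f_cc)
  prebuilt <- !is.data.frame(grid)
  ids <- if (prebuilt) seq_along(grid) else grid$config_id

  done <- NULL
  if (!is.null(cache)) {
    dir.create(dirname(cache), showWarnings = FALSE, recursive = TRUE)
    if (file.exists(cache))
      done <- utils::read.csv(cache, stringsAsFactors = FALSE)
  }

  rows <- lapply(seq_along(ids), function(k) {
    cfg_id <- ids[k]
    coupling <- if (prebuilt) grid[[k]]
                else coupling_from_config(map, grid[grid$config_id == cfg_id, ])
    lab <- character(n_realizations)
    sup <- logical(n_realizations)
    seeds <- (base_seed + 100003 * cfg_id + seq_len(n_realizations)) %%
      2147483647
    for (r in seq_len(n_realizations)) {
      if (!is.null(done)) {
        hit <- done$config_id == cfg_id & done$realization == r
        if (any(hit)) {
          lab[r] <- done$outcome[hit][1]
          sup[r] <- as.logical(done$supracellular[hit][1])
          next
        }
      }
      traj <- simulate_group(map = map, params = params, coupling = coupling,
                             stimulus = stimulus, seed = seeds[r],
                             neutralize = neutralize)
      cls <- classify_trajectory(traj)
      lab[r] <- cls$outcome
      sup[r] <- isTRUE(cls$supracellular)
      if (!is.null(cache)) {
        row <- data.frame(config_id = cfg_id, realization = r,
                          seed = seeds[r], outcome = lab[r],
                          supracellular = sup[r])
        new <- !file.exists(cache)
        suppressWarnings(utils::write.table(
          row, cache, sep = ",", row.names = FALSE,
          col.names = new, append = !new))
      }
    }
    tibble::tibble(
      config_id = cfg_id,
      n = n_realizations,
      p_coalign = mean(lab == "co-alignment"),
      p_collision = mean(lab == "collision"),
      p_misalign = mean(lab == "misalignment"),
      p_nonpolar = mean(lab == "non-polarized"),
      p_circular = mean(lab %in% c("circular-CW", "circular-CCW")),
      p_paired = mean(lab == "paired"),
      p_supra = mean(sup),
      success = mean(lab == "co-alignment") >= success_threshold,
      labels = list(tibble::tibble(realization = seq_len(n_realizations),
                                   seed = seeds, outcome = lab,
                                   supracellular = sup)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("copol_screen", class(out))
  out
}

#' Wilson score confidence interval for a binomial proportion
#' @param x successes; `n` trials; `conf` confidence level.
#' @return named numeric `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = center - half, upper = center + half)
}

#' Long-form summary table of a screen
#'
#' One row per (configuration, outcome) with the outcome probability, the
#' number of realizations, and a Wilson 95% confidence interval.
#'
#' @param result a `copol_screen` from [run_screen()].
#' @return a tibble with columns `config_id`, `outcome`, `probability`,
#'   `n`, `ci_lower`, `ci_upper`.
#' @export
summarize_screen <- function(result) {
  if (nrow(result) == 0L)
    return(tibble::tibble(config_id = integer(), outcome = character(),
                          probability = numeric(), n = integer(),
                          ci_lower = numeric(), ci_upper = numeric()))
  outcomes <- c(p_coalign = "co-alignment", p_collision = "collision",
                p_misalign = "misalignment", p_nonpolar = "non-polarized",
                p_supra = "supracellular")
  rows <- lapply(seq_len(nrow(result)), function(i) {
    p <- unlist(result[i, names(outcomes)])
    ci <- vapply(p, function(pp)
      wilson_ci(round(pp * result$n[i]), result$n[i]), numeric(2))
    tibble::tibble(config_id = result$config_id[i],
                   outcome = unname(outcomes),
                   probability = unname(p), n = result$n[i],
                   ci_lower = ci[1, ], ci_upper = ci[2, ])
  })
  dplyr::bind_rows(rows)
}
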