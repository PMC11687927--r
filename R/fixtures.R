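#' Synthetic axis-track fixtures for the outcome classifiers
#'
#' Generates axis-angle time series that satisfy a named arrangement by
#' construction, so the classifiers can be unit-tested without running the
#' simulator. Jitter is kept small enough that the final axes provably stay
#' inside (or outside) the relevant cones.
#'
#' @param scenario one of `"coalign"`, `"collide"`, `"misalign"`,
#'   `"supracellular"`, `"nonpolar"`, `"paired4"`, `"circular4_cw"`,
#'   `"circular4_ccw"`.
#' @param n number of independent tracks (realizations).
#' @param seed integer seed (R RNG).
#' @param n_time recorded time points per track.
#' @param jitter_deg half-range of the uniform angular jitter.
#' @return a tibble with columns `track`, `time`, `cell`, `angle_deg`,
#'   `defined`.
#' @export
generate_axis_fixtures <- function(scenario = c("coalign", "collide",
                                                "misalign", "supracellular",
                                                "nonpolar", "paired4",
                                                "circular4_cw",
                                                "circular4_ccw"),
                                   n = 10, seed = 1, n_time = 20,
                                   jitter_deg = 5) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  jit <- function(k) stats::runif(k, -jitter_deg, jitter_deg)
  quad <- scenario %in% c("paired4", "circular4_cw", "circular4_ccw")
  ncell <- if (quad) 4L else 2L

  one <- function(track) {
    base <- switch(scenario,
      coalign = {                      # common direction off both cones
        mu <- stats::runif(1, 45, 135) + sample(c(0, 180), 1)
        c(mu + jit(1), mu + jit(1)) %% 360
      },
      collide = c(jit(1) * 2, 180 + jit(1) * 2) %% 360,
      misalign = {
        mu <- stats::runif(1, 60, 120)
        c(mu + jit(1), mu + 180 + 90 + jit(1)) %% 360
      },
      supracellular = {                # follower (cell 1) toward leader
        c(jit(1) * 2, 45 + jit(1)) %% 360
      },
      nonpolar = c(NA_real_, stats::runif(1, 0, 360)),
      paired4 = {
        mu <- stats::runif(1, 0, 360)
        (c(mu, mu, mu + 180, mu + 180) + jit(4)) %% 360
      },
      circular4_cw = (c(45, 315, 225, 135) + jit(4)) %% 360,
      circular4_ccw = (c(225, 135, 45, 315) + jit(4)) %% 360)
    ang <- outer(rep(1, n_time), base)
    ok <- !is.na(base)
    ang[, ok] <- (ang[, ok] + matrix(jit(n_time * sum(ok)), n_time)) %% 360
    # hold the final recorded value exactly at the constructed axis
    ang[n_time, ] <- base
    tibble::tibble(track = track,
                   time = rep(seq_len(n_time) - 1, ncell),
                   cell = rep(seq_len(ncell), each = n_time),
                   angle_deg = as.vector(ang),
                   defined = !is.na(as.vector(ang)))
  }
  dplyr::bind_rows(lapply(seq_len(n), one))
}

#' Classify fixture (or exported) axis tracks
#'
#' Applies the doublet or quadruplet classifier to the final time point of
#' each track in a long-format axis table, e.g. from
#' [generate_axis_fixtures()] or a CSV written by
#' [export_trajectory_csv()].
#'
#' @param tracks tibble with columns `track` (optional), `time`, `cell`,
#'   `angle_deg`, `defined`.
#' @param layout `"doublet"`, `"chain4"` or `"square4"`.
#' @return a tibble with one row per track: `track`, `outcome`,
#'   `supracellular` (`NA` for quadruplets).
#' @export
classify_axis_tracks <- function(tracks, layout = "doublet") {
  if (is.null(tracks$track)) tracks$track <- 1L
  res <- lapply(split(tracks, tracks$track), function(tr) {
    fin <- tr[tr$time == max(tr$time), ]
    fin <- fin[order(fin$cell), ]
    ax <- ifelse(fin$defined, fin$angle_deg, NA_real_)
    if (layout == "doublet")
      tibble::tibble(track = fin$track[1],
                     outcome = classify_doublet(ax[1], ax[2]),
                     supracellular = classify_supracellular(ax[1], ax[2]))
    else
      tibble::tibble(track = fin$track[1],
                     outcome = classify_quadruplet(ax, layout),
                     supracellular = NA)
  })
  dplyr::bind_rows(res)
}
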