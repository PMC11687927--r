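#' GTPase junction regulation entry
#'
#' One multiplicative up-regulation of a GTPase kinetic rate at the
#' intercellular region: the target cell's binding or unbinding rate of one
#' species is multiplied by `gamma >= 1` on its junction arc. In the
#' concentration-dependent variant the factor is
#' `max(1, gamma * n)`, where `n` is the neighbour's bound-molecule count of
#' `source_species` near the mirror-mapped membrane point (so the
#' up-regulation vanishes to baseline where the neighbour has no molecules).
#'
#' @param pair the junction, as `c(i, j)` cell indices.
#' @param target which cell's rate is modified (must be in `pair`).
#' @param species `"rac"` or `"rho"`.
#' @param rate `"on"` or `"off"`.
#' @param gamma amplification factor, `>= 1`.
#' @param conc_dependent logical; concentration-dependent amplification.
#' @param source_species species read in the neighbour cell when
#'   `conc_dependent = TRUE` (defaults to `species`).
#' @return a regulation entry (list), to be passed in
#'   `coupling = list(gtpase = list(...))` of [simulate_group()].
#' @export
gtpase_regulation <- function(pair, target, species = c("rac", "rho"),
                              rate = c("on", "off"), gamma,
                              conc_dependent = FALSE, source_species = NULL) {
  species <- match.arg(species); rate <- match.arg(rate)
  if (gamma < 1) stop("amplification factor must satisfy gamma >= 1")
  if (!target %in% pair) stop("target cell must belong to the junction pair")
  if (conc_dependent && is.null(source_species)) source_species <- species
  structure(list(pair = as.integer(pair), target = as.integer(target),
                 species = species, rate = rate, gamma = gamma,
                 conc_dependent = conc_dependent,
                 source_species = source_species),
            class = "copol_gtpase_reg")
}

#' Constant F-actin growth regulation at a junction
#'
#' Adds constant terms `eps_A`, `eps_B` to the growth rates of the target
#' cell's branched/bundled networks, nonzero only on its junction arc.
#'
#' @param pair junction cell pair `c(i, j)`.
#' @param target cell whose growth rates are modified.
#' @param eps_A,eps_B additive growth constants (may be negative).
#' @return a regulation entry for `coupling = list(actin = list(...))`.
#' @export
actin_regulation <- function(pair, target, eps_A = 0, eps_B = 0) {
  if (!target %in% pair) stop("target cell must belong to the junction pair")
  structure(list(pair = as.integer(pair), target = as.integer(target),
                 eps_A = eps_A, eps_B = eps_B, conc_dependent = FALSE),
            class = "copol_actin_reg")
}

#' Concentration-dependent F-actin crosstalk at a junction
#'
#' Growth modifications proportional to the neighbour's network densities at
#' the mirror-mapped point, applied symmetrically in both junction cells:
#' `eps_A = eAA * A' + eAB * B'` and `eps_B = eBA * A' + eBB * B'`, where
#' primes denote the neighbour's previous-step fields.
#'
#' @param pair junction cell pair `c(i, j)`.
#' @param coef named numeric vector `c(AA=, AB=, BA=, BB=)`.
#' @return a regulation entry for `coupling = list(actin = list(...))`.
#' @export
actin_crosstalk <- function(pair, coef) {
  coef <- coef[c("AA", "AB", "BA", "BB")]
  if (any(is.na(coef))) stop("coef must name AA, AB, BA, BB")
  structure(list(pair = as.integer(pair), coef = as.numeric(coef),
                 conc_dependent = TRUE),
            class = "copol_actin_reg")
}

#' Named intercellular coupling motifs
#'
#' Builds the full coupling block for a layout by applying one of the named
#' motifs at every junction of the map, oriented by the junction's stored
#' cell order (left-to-right for doublet/chain, clockwise around the ring
#' for the square):
#' \describe{
#'   \item{asym_bind_complementary}{Rac binding up in the first cell, Rho
#'     binding up in the second.}
#'   \item{asym_unbind_complementary}{Rac unbinding up in the first cell,
#'     Rho unbinding up in the second.}
#'   \item{asym_bind_unbind_rac}{Rac binding up in the first cell, Rac
#'     unbinding up in the second.}
#'   \item{asym_bind_unbind_rho}{Rho binding up in the first cell, Rho
#'     unbinding up in the second.}
#'   \item{pushpull_actin}{bundled growth up in the first cell, branched
#'     growth up in the second (`eps_B`, then `eps_A`, `= eps`).}
#'   \item{actin_crosstalk}{concentration-dependent reciprocal excitation of
#'     complementary networks, `eAB = eBA = eps`, `eAA = eBB = 0`.}
#' }
#'
#' @param map a [build_junction_map()] result.
#' @param motif motif name.
#' @param gamma amplification factor for the GTPase motifs.
#' @param eps growth-modification magnitude for the actin motifs.
#' @param conc_dependent use concentration-dependent amplification for the
#'   GTPase motifs.
#' @return `list(gtpase = ..., actin = ...)` suitable for
#'   [simulate_group()]'s `coupling` argument.
#' @export
coupling_motif <- function(map,
                           motif = c("asym_bind_complementary",
                                     "asym_unbind_complementary",
                                     "asym_bind_unbind_rac",
                                     "asym_bind_unbind_rho",
                                     "pushpull_actin",
                                     "actin_crosstalk"),
                           gamma = 1000, eps = 1, conc_dependent = FALSE) {
  motif <- match.arg(motif)
  g <- list(); a <- list()
  for (j in map$junctions) {
    i1 <- j$cells[1]; i2 <- j$cells[2]; pr <- j$cells
    if (motif == "asym_bind_complementary") {
      g <- c(g, list(
        gtpase_regulation(pr, i1, "rac", "on", gamma, conc_dependent,
                          if (conc_dependent) "rho" else NULL),
        gtpase_regulation(pr, i2, "rho", "on", gamma, conc_dependent,
                          if (conc_dependent) "rac" else NULL)))
    } else if (motif == "asym_unbind_complementary") {
      g <- c(g, list(
        gtpase_regulation(pr, i1, "rac", "off", gamma, conc_dependent,
                          if (conc_dependent) "rho" else NULL),
        gtpase_regulation(pr, i2, "rho", "off", gamma, conc_dependent,
                          if (conc_dependent) "rac" else NULL)))
    } else if (motif == "asym_bind_unbind_rac") {
      g <- c(g, list(
        gtpase_regulation(pr, i1, "rac", "on", gamma, conc_dependent),
        gtpase_regulation(pr, i2, "rac", "off", gamma, conc_dependent)))
    } else if (motif == "asym_bind_unbind_rho") {
      g <- c(g, list(
        gtpase_regulation(pr, i1, "rho", "on", gamma, conc_dependent),
        gtpase_regulation(pr, i2, "rho", "off", gamma, conc_dependent)))
    } else if (motif == "pushpull_actin") {
      a <- c(a, list(actin_regulation(pr, i1, eps_B = eps),
                     actin_regulation(pr, i2, eps_A = eps)))
    } else if (motif == "actin_crosstalk") {
      a <- c(a, list(actin_crosstalk(pr, c(AA = 0, AB = eps, BA = eps, BB = 0))))
    }
  }
  list(gtpase = g, actin = a)
}

# ---- internal: turn regulation entries into the C++ coupling spec ----------

# find the junction object in `map` matching an unordered cell pair
find_junction <- function(map, pair) {
  for (j in map$junctions)
    if (setequal(j$cells, pair)) return(j)
  stop("no junction between cells ", pair[1], " and ", pair[2],
       " in layout '", map$layout, "'")
}

sp_idx <- function(s) if (s == "rac") 1L else 2L

# returns list(konfac, kofffac, epsc, dyn_rate, dyn_eps) in C++ layout
compile_coupling <- function(map, coupling) {
  n <- map$domain$n_grid; nc <- map$n_cells
  konfac <- lapply(seq_len(nc), function(i) matrix(1, n, 2))
  kofffac <- lapply(seq_len(nc), function(i) matrix(1, n, 2))
  epsc <- lapply(seq_len(nc), function(i) matrix(0, n, 2))
  dyn_rate <- list(); dyn_eps <- list()

  for (e in coupling$gtpase) {
    j <- find_junction(map, e$pair)
    tgt_first <- e$target == j$cells[1]
    idx <- if (tgt_first) j$idx_i else j$idx_j
    mir <- if (tgt_first) j$idx_j else j$idx_i
    src <- setdiff(j$cells, e$target)
    if (!e$conc_dependent) {
      m <- if (e$rate == "on") konfac else kofffac
      m[[e$target]][idx, sp_idx(e$species)] <-
        m[[e$target]][idx, sp_idx(e$species)] * e$gamma
      if (e$rate == "on") konfac <- m else kofffac <- m
    } else {
      dyn_rate[[length(dyn_rate) + 1L]] <- list(
        cell = e$target, species = sp_idx(e$species),
        rate = if (e$rate == "on") 1L else 2L, gamma = e$gamma,
        src_cell = src, src_species = sp_idx(e$source_species),
        idx = as.integer(idx), mir = as.integer(mir))
    }
  }

  for (e in coupling$actin) {
    j <- find_junction(map, e$pair)
    if (!e$conc_dependent) {
      tgt_first <- e$target == j$cells[1]
      idx <- if (tgt_first) j$idx_i else j$idx_j
      epsc[[e$target]][idx, 1] <- epsc[[e$target]][idx, 1] + e$eps_A
      epsc[[e$target]][idx, 2] <- epsc[[e$target]][idx, 2] + e$eps_B
    } else {
      dyn_eps[[length(dyn_eps) + 1L]] <- list(
        cell = j$cells[1], src_cell = j$cells[2],
        idx = as.integer(j$idx_i), mir = as.integer(j$idx_j), coef = e$coef)
      dyn_eps[[length(dyn_eps) + 1L]] <- list(
        cell = j$cells[2], src_cell = j$cells[1],
        idx = as.integer(j$idx_j), mir = as.integer(j$idx_i), coef = e$coef)
    }
  }
  list(konfac = konfac, kofffac = kofffac, epsc = epsc,
       dyn_rate = dyn_rate, dyn_eps = dyn_eps)
}

#' Per-location junction rate-factor fields
#'
#' Evaluates the multiplicative rate-modification field that a set of GTPase
#' regulation entries produces for one cell, given the neighbour's
#' previous-step bound-molecule positions (needed for
#' concentration-dependent entries). Mainly a testing/inspection surface:
#' the group simulator evaluates the same quantities internally each step.
#'
#' @param map a `copol_map`; `coupling` a list of [gtpase_regulation()]
#'   entries; `cell` the cell whose fields are requested.
#' @param neighbour_positions list (indexed by cell) of
#'   `list(rac=, rho=)` bound positions used by concentration-dependent
#'   entries; may be `NULL` when all entries are constant.
#' @param inhibition_radius neighbourhood half-width for neighbour counts.
#' @return list of two `n_grid x 2` matrices `kon_factor`, `koff_factor`
#'   (columns Rac, Rho).
#' @export
junction_rate_fields <- function(map, coupling, cell,
                                 neighbour_positions = NULL,
                                 inhibition_radius = 0.5) {
  cc <- compile_coupling(map, list(gtpase = coupling, actin = list()))
  n <- map$domain$n_grid; L <- map$domain$perimeter
  kon <- cc$konfac[[cell]]; koff <- cc$kofffac[[cell]]
  for (d in cc$dyn_rate) {
    if (d$cell != cell) next
    if (is.null(neighbour_positions))
      stop("configuration error: concentration-dependent entry needs ",
           "neighbour state")
    pos <- neighbour_positions[[d$src_cell]][[c("rac", "rho")[d$src_species]]]
    s_mir <- (d$mir - 1) * map$domain$ds
    nloc <- vapply(s_mir, function(s)
      local_count(pos, s, inhibition_radius, L), integer(1))
    f <- pmax(1, d$gamma * nloc)
    m <- if (d$rate == 1L) kon else koff
    m[d$idx, d$species] <- m[d$idx, d$species] * f
    if (d$rate == 1L) kon <- m else koff <- m
  }
  list(kon_factor = kon, koff_factor = koff)
}

#' Per-location junction growth-modification fields
#'
#' Evaluates the additive `eps_A`, `eps_B` fields for one cell from a set of
#' actin regulation entries, given the neighbour's previous-step fields for
#' concentration-dependent crosstalk. Zero outside the junction arcs.
#'
#' @param map a `copol_map`; `coupling` a list of [actin_regulation()] /
#'   [actin_crosstalk()] entries; `cell` the target cell.
#' @param neighbour_fields list (indexed by cell) of `list(A=, B=)` density
#'   vectors; may be `NULL` when all entries are constant.
#' @return list of numeric vectors `eps_A`, `eps_B` of length `n_grid`.
#' @export
junction_growth_fields <- function(map, coupling, cell,
                                   neighbour_fields = NULL) {
  cc <- compile_coupling(map, list(gtpase = list(), actin = coupling))
  epsA <- cc$epsc[[cell]][, 1]; epsB <- cc$epsc[[cell]][, 2]
  for (d in cc$dyn_eps) {
    if (d$cell != cell) next
    A <- neighbour_fields[[d$src_cell]]$A[d$mir]
    B <- neighbour_fields[[d$src_cell]]$B[d$mir]
    epsA[d$idx] <- epsA[d$idx] + d$coef[1] * A + d$coef[2] * B
    epsB[d$idx] <- epsB[d$idx] + d$coef[3] * A + d$coef[4] * B
  }
  list(eps_A = epsA, eps_B = epsB)
}
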