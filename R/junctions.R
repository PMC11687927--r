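#' Construct the junction map for a cell-group layout
#'
#' Builds the intercellular junction geometry: for every adjacent cell pair,
#' the arc (a fixed fraction `f_cc` of each perimeter) over which junction
#' couplings act, and the mirror correspondence pairing juxtaposed membrane
#' points of the two cells. A point at angle `center_i + delta` in cell `i`
#' is juxtaposed with `center_j - delta` in its neighbour, so the mapping
#' reverses orientation and is an involution.
#'
#' Layouts:
#' \describe{
#'   \item{single}{one cell, no junctions.}
#'   \item{doublet}{cell 1 left, cell 2 right; junction centers at 0 and
#'     180 degrees.}
#'   \item{chain4}{four cells in single file; three junctions, interior cells
#'     carry two disjoint junction arcs.}
#'   \item{square4}{cells 1-4 placed clockwise from the top-left corner;
#'     four lateral junctions between edge-adjacent cells (no diagonal
#'     contact).}
#' }
#'
#' @param layout one of `"single"`, `"doublet"`, `"chain4"`, `"square4"`.
#' @param f_cc junction fraction of the perimeter, in (0, 1); default 0.25.
#' @param domain a [periodic_domain()].
#' @return an object of class `copol_map`: `n_cells`, `positions` (cell
#'   center coordinates), and `junctions`, a list with elements
#'   `cells = c(i, j)`, `center = c(deg_i, deg_j)`, and aligned index
#'   vectors `idx_i`, `idx_j` (1-based grid indices; `idx_j[k]` is the mirror
#'   of `idx_i[k]`).
#' @export
build_junction_map <- function(layout = c("single", "doublet", "chain4", "square4"),
                               f_cc = 0.25, domain = periodic_domain()) {
  layout <- match.arg(layout)
  stopifnot(f_cc > 0, f_cc < 1)
  n <- domain$n_grid
  step <- 360 / n

  jn <- switch(layout,
    single = list(),
    doublet = list(list(cells = c(1L, 2L), center = c(0, 180))),
    chain4 = list(
      list(cells = c(1L, 2L), center = c(0, 180)),
      list(cells = c(2L, 3L), center = c(0, 180)),
      list(cells = c(3L, 4L), center = c(0, 180))),
    square4 = list(
      list(cells = c(1L, 2L), center = c(0, 180)),
      list(cells = c(2L, 3L), center = c(270, 90)),
      list(cells = c(3L, 4L), center = c(180, 0)),
      list(cells = c(4L, 1L), center = c(90, 270))))

  positions <- switch(layout,
    single = matrix(c(0, 0), 1, 2),
    doublet = rbind(c(0, 0), c(2, 0)),
    chain4 = cbind(2 * (0:3), 0),
    square4 = rbind(c(-1, 1), c(1, 1), c(1, -1), c(-1, -1)))

  half <- f_cc * 360 / 2
  jn <- lapply(jn, function(j) {
    for (ci in 1:2) {
      if (abs(j$center[ci] / step - round(j$center[ci] / step)) > 1e-9)
        stop("junction center must lie on the grid")
    }
    kmax <- floor(half / step + 1e-9)
    offs <- (-kmax):kmax                       # signed offsets in grid steps
    c_i <- round(j$center[1] / step); c_j <- round(j$center[2] / step)
    j$idx_i <- ((c_i + offs) %% n) + 1L
    j$idx_j <- ((c_j - offs) %% n) + 1L
    j
  })

  n_cells <- switch(layout, single = 1L, doublet = 2L, chain4 = 4L, square4 = 4L)
  structure(list(layout = layout, f_cc = f_cc, domain = domain,
                 n_cells = n_cells, positions = positions, junctions = jn),
            class = "copol_map")
}

#' Per-cell junction facing direction(s), in degrees
#'
#' For each cell, the angles at which its junction arcs are centered (one
#' angle for end/doublet cells, two for interior chain cells and square
#' cells).
#' @param map a `copol_map`.
#' @return list of numeric vectors, one per cell.
#' @export
junction_directions <- function(map) {
  out <- vector("list", map$n_cells)
  for (j in map$junctions) {
    out[[j$cells[1]]] <- c(out[[j$cells[1]]], j$center[1])
    out[[j$cells[2]]] <- c(out[[j$cells[2]]], j$center[2])
  }
  out
}

#' Mirror map of a junction point
#'
#' Grid index in the neighbour cell juxtaposed to grid index `idx` of cell
#' `cell` across the given junction (an involution).
#' @param map a `copol_map`; `junction` the junction number; `cell` which of
#'   the two junction cells `idx` refers to; `idx` 1-based grid index.
#' @return the paired 1-based grid index in the other cell.
#' @export
mirror_index <- function(map, junction, cell, idx) {
  j <- map$junctions[[junction]]
  if (cell == j$cells[1]) {
    pos <- match(idx, j$idx_i); j$idx_j[pos]
  } else if (cell == j$cells[2]) {
    pos <- match(idx, j$idx_j); j$idx_i[pos]
  } else stop("cell is not part of this junction")
}
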