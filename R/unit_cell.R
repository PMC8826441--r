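# Parametric truss unit cells and the clinical/manufacturing design window.
#
# Morphology convention: struts are circular cylinders of radius `t`. For the
# octet-truss cell the relative density follows the stretching-dominated
# closed form rho = 6*sqrt(2)*pi*(t/l)^2, where `l` is the STRUT length; the
# cubic cell edge is sqrt(2)*l. `unit_cell_spec()` stores the cell edge and
# converts internally.

OCTET_RHO_COEF <- 6 * sqrt(2) * pi

#' Relative density of an octet-truss cell from strut size
#'
#' Applies the stretching-dominated octet-truss relation
#' \eqn{\rho = 6\sqrt{2}\pi (t/l)^2} (clipped to 1), where `t` is the strut
#' radius and `l` the strut length. Porosity is `1 - rho`.
#'
#' @param t strut radius (mm); use `strut_size_is_diameter = TRUE` if `t`
#'   is a diameter.
#' @param l strut length (mm); for a cubic octet cell of edge `a`,
#'   `l = a / sqrt(2)`.
#' @param strut_size_is_diameter interpret `t` as the strut diameter.
#' @return relative density in `[0, 1]`.
#' @seealso [strut_for_density()], [unit_cell_spec()]
#' @export
#' @examples
#' density_from_strut(0.1, 1.5)   # ~0.1185
density_from_strut <- function(t, l, strut_size_is_diameter = FALSE) {
  if (any(!is.finite(l)) || any(l <= 0)) {
    stop("strut length `l` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("strut radius `t` must be non-negative and finite", call. = FALSE)
  }
  if (strut_size_is_diameter) t <- t / 2
  pmin(OCTET_RHO_COEF * (t / l)^2, 1)
}

#' Strut radius giving a target octet-truss relative density
#'
#' Inverts the density--strut relation of [density_from_strut()]:
#' \eqn{t = l \sqrt{\rho / (6\sqrt{2}\pi)}}.
#'
#' @param rho relative density, in `(0, 1]`.
#' @param l strut length (mm).
#' @inheritParams density_from_strut
#' @return strut radius (mm), or diameter if `strut_size_is_diameter`.
#' @export
strut_for_density <- function(rho, l, strut_size_is_diameter = FALSE) {
  if (any(!is.finite(rho)) || any(rho <= 0) || any(rho > 1)) {
    stop("`rho` must lie in (0, 1]", call. = FALSE)
  }
  if (any(!is.finite(l)) || any(l <= 0)) {
    stop("strut length `l` must be positive and finite", call. = FALSE)
  }
  t <- l * sqrt(rho / OCTET_RHO_COEF)
  if (strut_size_is_diameter) 2 * t else t
}

#' Pore size of a truss cell
#'
#' The pore size is taken as the face-diagonal opening between parallel
#' struts, `pore = a/sqrt(2) - 2 t` = strut length minus one strut diameter,
#' floored at zero. This is the aperture limiting bone ingrowth.
#'
#' @param t strut radius (mm).
#' @param edge cubic cell edge length (mm).
#' @return pore size (mm).
#' @export
pore_size <- function(t, edge) {
  pmax(edge / sqrt(2) - 2 * t, 0)
}

## density prefactor k in rho = k * (t/edge)^2 per cell type, from summing
## strut volumes with face-sharing weights (face-plane struts count 1/2)
cell_rho_coef <- function(cell_type) {
  switch(cell_type,
    octet = 12 * sqrt(2) * pi,  # == 6*sqrt(2)*pi in strut-length form
    bcc   = 4 * sqrt(3) * pi,
    fcc   = 6 * sqrt(2) * pi,
    stop("unsupported cell type: ", cell_type, call. = FALSE)
  )
}

#' Specify a parametric truss unit cell
#'
#' A cell is defined by its type, cubic edge length `l`, and either the strut
#' radius `t` or the relative density `rho` (the third quantity is computed
#' from the other two). For octet cells the density relation is the
#' stretching-dominated closed form of [density_from_strut()] evaluated at
#' strut length `l / sqrt(2)`.
#'
#' @param cell_type one of `"octet"`, `"bcc"`, `"fcc"`.
#' @param l cubic cell edge length (mm), positive.
#' @param t strut radius (mm), or `NULL` to derive from `rho`.
#' @param rho relative density in `(0, 1]`, or `NULL` to derive from `t`.
#' @param strut_size_is_diameter interpret a supplied `t` as a diameter.
#' @return an object of class `unit_cell_spec` with fields `cell_type`, `l`
#'   (cell edge, mm), `t` (strut radius, mm), `rho`, and `pore` (mm).
#' @export
#' @examples
#' unit_cell_spec("octet", l = 1.35, rho = 0.4)
unit_cell_spec <- function(cell_type = c("octet", "bcc", "fcc"), l,
                           t = NULL, rho = NULL,
                           strut_size_is_diameter = FALSE) {
  cell_type <- match.arg(cell_type)
  if (!is.numeric(l) || length(l) != 1L || !is.finite(l) || l <= 0) {
    stop("cell edge `l` must be a positive number", call. = FALSE)
  }
  if (is.null(t) && is.null(rho)) {
    stop("supply one of `t` (strut radius) or `rho` (relative density)",
         call. = FALSE)
  }
  k <- cell_rho_coef(cell_type)
  if (is.null(t)) {
    if (rho <= 0 || rho > 1) stop("`rho` must lie in (0, 1]", call. = FALSE)
    t <- l * sqrt(rho / k)
  } else {
    if (strut_size_is_diameter) t <- t / 2
    if (t < 0) stop("strut radius `t` must be non-negative", call. = FALSE)
    rho_geom <- min(k * (t / l)^2, 1)
    if (!is.null(rho) && abs(rho - rho_geom) > 1e-8 * max(1, rho)) {
      stop("`t` and `rho` are inconsistent for this cell type", call. = FALSE)
    }
    rho <- rho_geom
  }
  structure(
    list(cell_type = cell_type, l = l, t = t, rho = rho,
         pore = pore_size(t, l)),
    class = "unit_cell_spec"
  )
}

#' @export
print.unit_cell_spec <- function(x, ...) {
  cat(sprintf("%s unit cell: edge %.4g mm, strut radius %.4g mm, rho %.4g, pore %.4g mm\n",
              x$cell_type, x$l, x$t, x$rho, x$pore))
  invisible(x)
}

## node/strut tables for the three supported cells, on the unit cube [0,1]^3.
## weight = fraction of the strut volume belonging to this cell (struts lying
## in a face plane are shared by two adjacent cells).
cell_topology <- function(cell_type) {
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  faces <- rbind(c(.5, .5, 0), c(.5, .5, 1), c(.5, 0, .5),
                 c(.5, 1, .5), c(0, .5, .5), c(1, .5, .5))
  pair_within <- function(P, Q, d2) {
    # index pairs (i in P, j in Q) at squared distance d2
    out <- NULL
    for (i in seq_len(nrow(P))) {
      dd <- rowSums((Q - matrix(P[i, ], nrow(Q), 3, byrow = TRUE))^2)
      j <- which(abs(dd - d2) < 1e-12)
      if (length(j)) out <- rbind(out, cbind(i, j))
    }
    out
  }
  if (cell_type == "octet") {
    nodes <- rbind(corners, faces)
    # octahedral core: edges between adjacent face centres
    oct <- pair_within(faces, faces, 0.5)
    oct <- oct[oct[, 1] < oct[, 2], , drop = FALSE]
    core <- cbind(oct[, 1] + 8L, oct[, 2] + 8L)
    # corner-to-face-centre tetrahedral struts (lie in the face planes)
    tet <- pair_within(corners, faces, 0.5)
    tets <- cbind(tet[, 1], tet[, 2] + 8L)
    struts <- rbind(core, tets)
    weight <- c(rep(1, nrow(core)), rep(0.5, nrow(tets)))
    core_ids <- seq_len(nrow(core))
  } else if (cell_type == "bcc") {
    nodes <- rbind(corners, c(.5, .5, .5))
    struts <- cbind(1:8, 9L)
    weight <- rep(1, 8)
    core_ids <- integer(0)
  } else if (cell_type == "fcc") {
    nodes <- rbind(corners, faces)
    tet <- pair_within(corners, faces, 0.5)
    struts <- cbind(tet[, 1], tet[, 2] + 8L)
    weight <- rep(0.5, nrow(struts))
    core_ids <- integer(0)
  } else {
    stop("unsupported cell type: ", cell_type, call. = FALSE)
  }
  dimnames(nodes) <- NULL
  list(nodes = nodes, struts = struts, weight = weight, core = core_ids)
}

#' Build the strut network of a unit cell
#'
#' Instantiates the node coordinates and strut connectivity of the cell on
#' `[0, l]^3`. The octet cell consists of an octahedral core (6 nodes, 12
#' struts between face centres) plus corner tetrahedral struts; `bcc` and
#' `fcc` follow the standard body-/face-centred connectivity.
#'
#' @param spec a [unit_cell_spec()].
#' @return an object of class `cell_geometry`: `nodes` (matrix, mm), `struts`
#'   (two-column index matrix), `t` (strut radius, mm), `l` (cell edge, mm),
#'   `weight` (per-strut volume share of this cell), `core` (row indices of
#'   the octahedral-core struts, octet only), `cell_type`.
#' @export
build_cell <- function(spec) {
  stopifnot(inherits(spec, "unit_cell_spec"))
  topo <- cell_topology(spec$cell_type)
  structure(
    list(nodes = topo$nodes * spec$l, struts = topo$struts,
         weight = topo$weight, core = topo$core,
         t = spec$t, l = spec$l, cell_type = spec$cell_type),
    class = "cell_geometry"
  )
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("%s cell geometry: %d nodes, %d struts, edge %.4g mm, strut radius %.4g mm\n",
              x$cell_type, nrow(x$nodes), nrow(x$struts), x$l, x$t))
  invisible(x)
}

## analytic solid fraction of the cell from strut volumes (junction overlap
## ignored, face struts half-weighted) -- the closed-form density bookkeeping
cell_volume_fraction <- function(cell) {
  a <- cell$nodes[cell$struts[, 1], , drop = FALSE]
  b <- cell$nodes[cell$struts[, 2], , drop = FALSE]
  len <- sqrt(rowSums((a - b)^2))
  min(sum(cell$weight * pi * cell$t^2 * len) / cell$l^3, 1)
}

#' Clinical and manufacturing design window for lattice cells
#'
#' Bounds on the admissible cell morphology: a minimum printable strut size
#' (`t_min`, compared against the strut diameter), a maximum pore size
#' compatible with bone ingrowth (`pore_max`), the admissible cell edge
#' lengths and relative-density interval.
#'
#' @param t_min minimum manufacturable strut size (diameter, mm).
#' @param pore_max maximum pore size for bone ingrowth (mm).
#' @param l_range admissible cell edge lengths (mm), length-2.
#' @param rho_bounds admissible relative density interval, within (0, 1).
#' @return an object of class `design_window`.
#' @export
design_window <- function(t_min = 0.2, pore_max = 0.8,
                          l_range = c(1.2, 1.5), rho_bounds = c(0.2, 0.7)) {
  stopifnot(t_min > 0, pore_max > 0, length(l_range) == 2L,
            l_range[1] > 0, diff(l_range) >= 0,
            length(rho_bounds) == 2L,
            rho_bounds[1] > 0, rho_bounds[2] < 1,
            rho_bounds[1] <= rho_bounds[2])
  structure(list(t_min = t_min, pore_max = pore_max,
                 l_range = l_range, rho_bounds = rho_bounds),
            class = "design_window")
}

#' Admissible density interval for a given cell size
#'
#' Intersects the window's density bounds with the manufacturing constraint
#' (strut diameter at least `t_min`) and the ingrowth constraint (pore size
#' at most `pore_max`). Both constraints bind at the low-density end: thin
#' struts and large pores belong to sparse cells. The interval may be empty
#' (returned as `numeric(0)`).
#'
#' @param win a [design_window()].
#' @param l cell edge length (mm), inside `win$l_range`.
#' @return `c(rho_lo, rho_hi)` or `numeric(0)` if no density is admissible.
#' @export
admissible_window <- function(win, l) {
  stopifnot(inherits(win, "design_window"))
  if (l < win$l_range[1] - 1e-9 || l > win$l_range[2] + 1e-9) {
    stop("cell size `l` outside the window's l_range", call. = FALSE)
  }
  ls <- l / sqrt(2)  # strut length
  # manufacturing: 2 t(rho) >= t_min  =>  rho >= rho at radius t_min/2
  rho_manuf <- density_from_strut(win$t_min / 2, ls)
  # ingrowth: pore(rho) <= pore_max => t >= (ls - pore_max)/2
  t_pore <- max((ls - win$pore_max) / 2, 0)
  rho_pore <- density_from_strut(t_pore, ls)
  lo <- max(win$rho_bounds[1], rho_manuf, rho_pore)
  hi <- win$rho_bounds[2]
  if (lo > hi) numeric(0) else c(lo, hi)
}

#' Write a cell or lattice wireframe as CSV node/strut tables
#'
#' @param x a `cell_geometry` or `lattice_model`.
#' @param nodes_csv,struts_csv output paths.
#' @return invisibly, the two paths.
#' @export
export_wireframe <- function(x, nodes_csv, struts_csv) {
  if (inherits(x, "cell_geometry")) {
    nodes <- data.frame(id = seq_len(nrow(x$nodes)),
                        x = x$nodes[, 1], y = x$nodes[, 2], z = x$nodes[, 3])
    struts <- data.frame(n1 = x$struts[, 1], n2 = x$struts[, 2], radius = x$t)
  } else if (inherits(x, "lattice_model")) {
    nodes <- data.frame(id = seq_len(nrow(x$nodes)),
                        x = x$nodes[, 1], y = x$nodes[, 2], z = x$nodes[, 3])
    struts <- data.frame(n1 = x$struts$n1, n2 = x$struts$n2,
                         radius = x$struts$radius)
  } else {
    stop("`x` must be a cell_geometry or lattice_model", call. = FALSE)
  }
  utils::write.csv(nodes, nodes_csv, row.names = FALSE)
  utils::write.csv(struts, struts_csv, row.names = FALSE)
  invisible(c(nodes_csv, struts_csv))
}
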