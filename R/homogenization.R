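# Effective elasticity of periodic lattice materials by the unit-test-strain
# homogenization method on a voxelized representative volume element (RVE).
#
# Six cell problems are solved, one per unit macroscopic strain (the other
# five components zero), with periodic displacement-fluctuation boundary
# conditions on a regular voxel grid of 8-node hexahedra. The effective
# tensor is the energy average
#   C_pq = (1/|Y|) sum_e (u0_p - chi_p)' ke (u0_q - chi_q),
# which is symmetric and energy-consistent by construction.
#
# Void voxels carry no stiffness and are removed from the linear system
# (the solid phase must be periodically connected); rigid translations are
# removed by pinning one solid node. The six load cases share one Jacobi
# preconditioned conjugate-gradient solve advanced in lockstep.

## squared distance of points P (m x 3, unit-cell coords) to the nearest
## strut axis of `cell`, including periodic images; early bounding-box culls
strut_dist2 <- function(P, cell, pad) {
  A0 <- cell$nodes[cell$struts[, 1], , drop = FALSE] / cell$l
  B0 <- cell$nodes[cell$struts[, 2], , drop = FALSE] / cell$l
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d2min <- rep(Inf, nrow(P))
  for (s in seq_len(nrow(A0))) {
    for (o in seq_len(nrow(offs))) {
      A <- A0[s, ] + offs[o, ]
      B <- B0[s, ] + offs[o, ]
      lo <- pmin(A, B) - pad; hi <- pmax(A, B) + pad
      if (any(lo > 1) || any(hi < 0)) next
      AB <- B - A
      L2 <- sum(AB^2)
      if (L2 == 0) next
      ss <- ((P[, 1] - A[1]) * AB[1] + (P[, 2] - A[2]) * AB[2] +
               (P[, 3] - A[3]) * AB[3]) / L2
      ss <- pmin(pmax(ss, 0), 1)
      d2 <- (P[, 1] - A[1] - ss * AB[1])^2 + (P[, 2] - A[2] - ss * AB[2])^2 +
        (P[, 3] - A[3] - ss * AB[3])^2
      d2min <- pmin(d2min, d2)
    }
  }
  d2min
}

#' Voxelize a truss cell into a periodic RVE grid
#'
#' The binary `indicator` marks voxels whose centre lies within one strut
#' radius of a strut axis (with periodic wrap-around of the cell). With
#' `subsamples > 1` a composite-voxel `fraction` field is also computed:
#' voxels cut by the strut surface are sub-sampled on a
#' `subsamples^3` grid and carry the fractional solid volume, which removes
#' most of the staircase error of the binary rule; voxels clearly inside or
#' outside are not refined. The solid fraction converges (up to the
#' strut-junction overlap neglected by the closed-form density relation) as
#' `n` grows.
#'
#' @param cell a [build_cell()] geometry.
#' @param n voxels per cell edge (>= 8).
#' @param Es solid Young's modulus (MPa).
#' @param nus solid Poisson ratio, in (0, 0.5).
#' @param subsamples per-axis sub-sampling of surface-cut voxels; `1`
#'   reduces to the pure binary centre rule.
#' @return an object of class `homog_problem`: logical `n x n x n` array
#'   `indicator`, numeric array `fraction` (equal to `indicator` when
#'   `subsamples = 1`), `Es`, `nus`, `n`, and the cell edge `l` (mm).
#' @export
voxelize <- function(cell, n, Es = 110000, nus = 0.3, subsamples = 3L) {
  stopifnot(inherits(cell, "cell_geometry"))
  if (n < 8) stop("resolution `n` must be at least 8", call. = FALSE)
  if (Es <= 0) stop("`Es` must be positive", call. = FALSE)
  if (nus <= 0 || nus >= 0.5) stop("`nus` must lie in (0, 0.5)", call. = FALSE)
  subsamples <- max(1L, as.integer(subsamples))
  h <- cell$l / n
  if (cell$t < h) {
    warning(sprintf(
      "fewer than 2 voxels across a strut (t = %.4g mm, voxel = %.4g mm); increase `n`",
      cell$t, h), call. = FALSE)
  }
  tr <- cell$t / cell$l                      # radius in unit-cell coords
  hr <- 1 / n                                # voxel edge in unit coords
  xc <- (seq_len(n) - 0.5) / n
  P <- as.matrix(expand.grid(x = xc, y = xc, z = xc))
  d2 <- strut_dist2(P, cell, pad = tr + hr)
  solid <- d2 <= tr^2
  if (!any(solid)) stop("voxelization produced an empty solid phase", call. = FALSE)
  frac <- as.numeric(solid)
  if (subsamples > 1L) {
    half_diag <- sqrt(3) / 2 * hr
    shell <- which(abs(sqrt(d2) - tr) <= half_diag)
    if (length(shell)) {
      s1 <- ((seq_len(subsamples) - 0.5) / subsamples - 0.5) * hr
      sub <- as.matrix(expand.grid(s1, s1, s1))
      m <- nrow(sub)
      Ps <- P[rep(shell, m), , drop = FALSE] + sub[rep(seq_len(m), each = length(shell)), ]
      inside <- strut_dist2(Ps, cell, pad = tr) <= tr^2
      frac[shell] <- rowSums(matrix(inside, length(shell), m)) / m
    }
  }
  structure(
    list(indicator = array(solid, dim = c(n, n, n)),
         fraction = array(frac, dim = c(n, n, n)),
         Es = Es, nus = nus, n = as.integer(n), l = cell$l),
    class = "homog_problem"
  )
}

#' @export
print.homog_problem <- function(x, ...) {
  cat(sprintf("homogenization RVE: %d^3 voxels, solid fraction %.4f, Es = %g MPa, nus = %g\n",
              x$n, mean(x$indicator), x$Es, x$nus))
  invisible(x)
}

## periodic linear node index for voxel-corner (i, j, k) in 0..n-1 (wrapped)
periodic_nid <- function(i, j, k, n) {
  ((i %% n) + (j %% n) * n + (k %% n) * n * n) + 1L
}

## nel x 8 node table for all n^3 elements of the periodic grid,
## ordering consistent with HEX_XI
periodic_grid_nodes <- function(n) {
  el <- expand.grid(i = 0:(n - 1), j = 0:(n - 1), k = 0:(n - 1))
  cbind(
    periodic_nid(el$i,     el$j,     el$k,     n),
    periodic_nid(el$i + 1, el$j,     el$k,     n),
    periodic_nid(el$i + 1, el$j + 1, el$k,     n),
    periodic_nid(el$i,     el$j + 1, el$k,     n),
    periodic_nid(el$i,     el$j,     el$k + 1, n),
    periodic_nid(el$i + 1, el$j,     el$k + 1, n),
    periodic_nid(el$i + 1, el$j + 1, el$k + 1, n),
    periodic_nid(el$i,     el$j + 1, el$k + 1, n)
  )
}

## check the solid phase is one periodically connected component and spans
## the cell across every axis; on failure, error naming the axis/axes
check_periodic_connectivity <- function(ind) {
  n <- dim(ind)[1]
  idx <- which(ind)
  if (!length(idx)) stop("empty solid phase", call. = FALSE)
  k0 <- idx - 1L
  ix <- k0 %% n; iy <- (k0 %/% n) %% n; iz <- k0 %/% (n * n)
  lin <- function(x, y, z) (x %% n) + (y %% n) * n + (z %% n) * n * n + 1L
  sel <- logical(n^3); sel[idx] <- TRUE
  edges <- NULL
  wrap <- c(x = FALSE, y = FALSE, z = FALSE)
  for (ax in 1:3) {
    nb <- switch(ax, lin(ix + 1L, iy, iz), lin(ix, iy + 1L, iz), lin(ix, iy, iz + 1L))
    keep <- sel[nb]
    edges <- rbind(edges, cbind(idx[keep], nb[keep]))
    # does any solid pair join across the periodic face of this axis?
    onface <- switch(ax, ix == n - 1L, iy == n - 1L, iz == n - 1L)
    wrap[ax] <- any(keep & onface)
  }
  g <- igraph::graph_from_edgelist(
    matrix(match(as.vector(edges), idx), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  ncomp <- igraph::components(g)$no
  bad <- names(wrap)[!wrap]
  if (ncomp > 1L || length(bad)) {
    axes <- if (length(bad)) paste(bad, collapse = ", ") else "none"
    stop(sprintf(
      "solid phase is not periodically connected (%d components; axes lacking periodic continuity: %s)",
      ncomp, axes), call. = FALSE)
  }
  invisible(TRUE)
}

## nodal displacements (24-vector) of a unit macroscopic strain over one
## voxel of edge h; Voigt order (11,22,33,12,13,23), engineering shears
unit_strain_disp <- function(h) {
  corners <- (HEX_XI + 1) / 2 * h            # 8x3
  U0 <- matrix(0, 24, 6)
  voigt <- diag(6)
  for (q in 1:6) {
    v <- voigt[, q]
    eps <- matrix(c(v[1], v[4] / 2, v[5] / 2,
                    v[4] / 2, v[2], v[6] / 2,
                    v[5] / 2, v[6] / 2, v[3]), 3, 3)
    U0[, q] <- as.vector(t(corners %*% eps))  # (u1x,u1y,u1z,...)
  }
  U0
}

#' Effective elasticity tensor of a voxelized RVE
#'
#' Solves the six periodic cell problems (one per unit test strain) and
#' returns the energy-averaged 6x6 stiffness in Voigt order
#' (11, 22, 33, 12, 13, 23). Element stiffness scales with the voxel solid
#' fraction (composite voxels); with a binary problem this is the classic
#' solid/void discretization. Voxels with zero fraction carry no stiffness
#' and are removed from the system.
#'
#' @param p a [voxelize()] problem.
#' @param tol relative residual of the conjugate-gradient solver.
#' @param use_fraction use the composite-voxel `fraction` field (default);
#'   `FALSE` forces the binary indicator.
#' @return a symmetric positive semi-definite 6x6 matrix (MPa) of class
#'   `elasticity_tensor`, with attributes `solid_fraction` (of the binary
#'   indicator), `volume_fraction` (of the field used), and `cg_iters`.
#' @export
effective_tensor <- function(p, tol = 1e-8, use_fraction = TRUE) {
  stopifnot(inherits(p, "homog_problem"))
  n <- p$n
  f <- if (use_fraction && !is.null(p$fraction)) p$fraction else
    array(as.numeric(p$indicator), dim = dim(p$indicator))
  check_periodic_connectivity(f > 0)
  h <- p$l / n
  ke <- hex_stiffness(((HEX_XI + 1) / 2) * h, p$Es, p$nus)
  sel <- which(as.vector(f) > 0)
  scale <- as.vector(f)[sel]                 # per-element stiffness share
  nodes8 <- periodic_grid_nodes(n)[sel, , drop = FALSE]
  # renumber to active nodes only
  act_nodes <- sort(unique(as.vector(nodes8)))
  nodes8 <- matrix(match(nodes8, act_nodes), nrow = nrow(nodes8))
  edof <- edof_from_nodes(nodes8)
  ndof <- 3L * length(act_nodes)
  K <- assemble_sparse(edof, ke, scale = scale, ndof = ndof)

  nel <- length(sel)
  U0 <- unit_strain_disp(h)                  # 24x6
  Fe <- ke %*% U0                            # 24x6, scaled per element
  Frhs <- matrix(0, ndof, 6)
  for (a in 1:24) {
    acc <- rowsum(outer(scale, Fe[a, ]), edof[, a])
    rows <- as.integer(rownames(acc))
    Frhs[rows, ] <- Frhs[rows, ] + acc
  }

  # pin the three dofs of the first active node (rigid translations)
  keep <- 4:ndof
  sol <- block_pcg(K[keep, keep, drop = FALSE], Frhs[keep, , drop = FALSE],
                   tol = tol)
  Chi <- matrix(0, ndof, 6)
  Chi[keep, ] <- sol$X

  # energy average: C_pq = (1/V) sum_e f_e (U0_p - chi_p)' ke (U0_q - chi_q)
  V <- (n * h)^3
  C <- matrix(0, 6, 6)
  W <- vector("list", 6)
  for (q in 1:6) {
    Xe <- matrix(Chi[edof, q], nrow = nel)   # nel x 24
    W[[q]] <- sweep(-Xe, 2, U0[, q], `+`)    # U0 - chi, per element
  }
  for (q in 1:6) {
    KW <- (W[[q]] %*% ke) * scale            # nel x 24
    for (r in q:6) {
      C[q, r] <- sum(KW * W[[r]]) / V
      C[r, q] <- C[q, r]
    }
  }
  structure(C, class = c("elasticity_tensor", "matrix"),
            solid_fraction = mean(p$indicator), volume_fraction = mean(f),
            cg_iters = sol$iters)
}

#' @export
print.elasticity_tensor <- function(x, digits = 5, ...) {
  cat("effective elasticity tensor (MPa), Voigt order (11,22,33,12,13,23):\n")
  print(round(unclass(x)[1:6, 1:6], digits))
  invisible(x)
}

#' Compliance tensor (inverse of a 6x6 stiffness)
#'
#' @param C 6x6 elasticity matrix (MPa), Voigt order.
#' @return 6x6 compliance matrix (1/MPa).
#' @export
compliance_tensor <- function(C) {
  C <- unclass(C)
  stopifnot(is.matrix(C), all(dim(C) == c(6, 6)))
  rc <- rcond(C)
  if (!is.finite(rc) || rc < 1e-14) {
    stop("degenerate material: elasticity tensor is numerically singular",
         call. = FALSE)
  }
  solve(C)
}

#' Orthotropic engineering constants from a compliance matrix
#'
#' Reads the engineering constants off the orthotropic compliance layout:
#' `E_i = 1/S_ii`, `G_ij = 1/S_kk` (k = 4..6 for 12, 13, 23), and
#' `nu_ij = -S_ij * E_i`.
#'
#' @param S 6x6 compliance matrix (1/MPa).
#' @return an object of class `eng_constants`: list with `E1,E2,E3` (MPa),
#'   `nu12,nu13,nu23`, `G12,G13,G23` (MPa).
#' @export
engineering_constants <- function(S) {
  S <- unclass(S)
  stopifnot(is.matrix(S), all(dim(S) == c(6, 6)))
  if (any(diag(S) <= 0)) {
    stop("invalid compliance: non-positive diagonal", call. = FALSE)
  }
  E <- 1 / diag(S)[1:3]
  structure(list(
    E1 = E[1], E2 = E[2], E3 = E[3],
    nu12 = -S[1, 2] * E[1], nu13 = -S[1, 3] * E[1], nu23 = -S[2, 3] * E[2],
    G12 = 1 / S[4, 4], G13 = 1 / S[5, 5], G23 = 1 / S[6, 6]
  ), class = "eng_constants")
}

#' @export
print.eng_constants <- function(x, ...) {
  cat(sprintf("E = (%.5g, %.5g, %.5g) MPa; nu = (%.4f, %.4f, %.4f); G = (%.5g, %.5g, %.5g) MPa\n",
              x$E1, x$E2, x$E3, x$nu12, x$nu13, x$nu23, x$G12, x$G13, x$G23))
  invisible(x)
}

## re-assemble an orthotropic compliance matrix from engineering constants
compliance_from_constants <- function(ec) {
  S <- matrix(0, 6, 6)
  diag(S) <- c(1 / ec$E1, 1 / ec$E2, 1 / ec$E3, 1 / ec$G12, 1 / ec$G13, 1 / ec$G23)
  S[1, 2] <- S[2, 1] <- -ec$nu12 / ec$E1
  S[1, 3] <- S[3, 1] <- -ec$nu13 / ec$E1
  S[2, 3] <- S[3, 2] <- -ec$nu23 / ec$E2
  S
}

#' Homogenize a cell type over a range of relative densities
#'
#' Runs one voxel homogenization per density and tabulates the effective
#' stiffness entries and engineering constants. This is the data the
#' polynomial surrogate is fitted to.
#'
#' @param cell_type `"octet"`, `"bcc"` or `"fcc"`.
#' @param rho_list relative densities in (0, 1).
#' @param Es,nus solid material constants (MPa, -).
#' @param n voxel resolution per cell edge.
#' @param l cell edge (mm); the effective tensor is scale-invariant, so this
#'   only sets units.
#' @param verbose print progress per density.
#' @return a `data.frame` with columns `rho`, `solid_fraction` (binary
#'   indicator), `volume_fraction` (composite voxels), `C11 ... C66` (upper
#'   triangle), `E1 ... G23`, plus the list of tensors in
#'   `attr(, "tensors")`.
#' @export
density_sweep <- function(cell_type = "octet", rho_list = seq(0.1, 0.8, by = 0.1),
                          Es = 110000, nus = 0.3, n = 48, l = 1.35,
                          verbose = FALSE) {
  stopifnot(all(rho_list > 0), all(rho_list < 1))
  rows <- vector("list", length(rho_list))
  tensors <- vector("list", length(rho_list))
  vnames <- c("11", "22", "33", "12", "13", "23")
  for (i in seq_along(rho_list)) {
    rho <- rho_list[i]
    res <- tryCatch({
      spec <- unit_cell_spec(cell_type, l = l, rho = rho)
      prob <- voxelize(build_cell(spec), n = n, Es = Es, nus = nus)
      C <- effective_tensor(prob)
      ec <- engineering_constants(compliance_tensor(C))
      list(C = C, ec = ec, sf = attr(C, "solid_fraction"),
           vf = attr(C, "volume_fraction"))
    }, error = function(e) {
      stop(sprintf("homogenization failed at rho = %g: %s", rho,
                   conditionMessage(e)), call. = FALSE)
    })
    tensors[[i]] <- res$C
    cu <- unclass(res$C)
    ut <- which(upper.tri(cu, diag = TRUE), arr.ind = TRUE)
    cvals <- cu[ut]
    names(cvals) <- paste0("C", vnames[ut[, 1]], "_", vnames[ut[, 2]])
    rows[[i]] <- c(rho = rho, solid_fraction = res$sf,
                   volume_fraction = res$vf, cvals, unlist(res$ec))
    if (verbose) {
      message(sprintf("rho = %.2f: solid fraction %.4f, E1/Es = %.5f",
                      rho, res$sf, res$ec$E1 / Es))
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "tensors") <- tensors
  attr(out, "Es") <- Es
  attr(out, "nus") <- nus
  attr(out, "cell_type") <- cell_type
  attr(out, "resolution") <- n
  out
}

#' Write a density sweep as CSV
#'
#' @param sweep result of [density_sweep()].
#' @param path output CSV path.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE)
  invisible(path)
}
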