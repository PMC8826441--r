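# Linear elasticity on hexahedral macro meshes (mm-N-MPa): stiffness
# assembly from a density field + surrogate or an explicit material field,
# direct sparse solution of KU = F, compliance c = U'KU, per-element strain
# energies (the GA fitness), and centroid von Mises stresses.

#' Construct a hexahedral macro mesh
#'
#' @param nodes numeric matrix (n x 3) of node coordinates (mm).
#' @param elements integer matrix (nel x 8) of node indices, standard hex
#'   ordering (counter-clockwise bottom face, then top).
#' @param fixed_dofs data frame with columns `node`, `dir` (1 = x, 2 = y,
#'   3 = z) of constrained displacement components.
#' @param loads data frame with columns `node`, `dir`, `value` (N).
#' @param check verify all element Jacobians are positive.
#' @return an object of class `macro_mesh`.
#' @export
macro_mesh <- function(nodes, elements, fixed_dofs, loads, check = TRUE) {
  nodes <- as.matrix(nodes)
  elements <- matrix(as.integer(as.matrix(elements)), nrow = NROW(elements))
  stopifnot(ncol(nodes) == 3L, ncol(elements) == 8L,
            all(elements >= 1L), all(elements <= nrow(nodes)),
            all(c("node", "dir") %in% names(fixed_dofs)),
            all(c("node", "dir", "value") %in% names(loads)))
  if (nrow(fixed_dofs) < 6L) {
    stop("underconstrained mesh: need at least 6 fixed dofs to remove rigid-body modes",
         call. = FALSE)
  }
  m <- structure(list(nodes = nodes, elements = elements,
                      fixed_dofs = fixed_dofs, loads = loads),
                 class = "macro_mesh")
  if (check) {
    for (e in seq_len(nrow(elements))) {
      co <- nodes[elements[e, ], , drop = FALSE]
      jac <- det(t(hex_dN(0, 0, 0)) %*% co)
      if (!is.finite(jac) || jac <= 0) {
        stop(sprintf("element %d has non-positive Jacobian", e), call. = FALSE)
      }
    }
  }
  m
}

#' @export
print.macro_mesh <- function(x, ...) {
  cat(sprintf("hex macro mesh: %d nodes, %d elements, %d fixed dofs, %d nodal loads\n",
              nrow(x$nodes), nrow(x$elements), nrow(x$fixed_dofs), nrow(x$loads)))
  invisible(x)
}

## per-element (E, nu) from the inputs of assemble()
resolve_material <- function(mesh, densities, surrogate, material) {
  nel <- nrow(mesh$elements)
  if (!is.null(material)) {
    if (inherits(material, "material_field")) {
      stopifnot(nrow(material) == nel)
      return(list(E = material$E, nu = material$nu))
    }
    stopifnot(length(material$E) %in% c(1L, nel))
    return(list(E = rep_len(material$E, nel), nu = rep_len(material$nu, nel)))
  }
  stopifnot(!is.null(densities), !is.null(surrogate))
  rho <- if (inherits(densities, "density_field")) densities$rho else densities
  stopifnot(length(rho) == nel)
  pr <- predict(surrogate, rho, clamp = FALSE)
  pr
}

## TRUE when all elements are congruent axis-aligned cubes of one size
## (regular-grid fixtures); enables the Lame fast path
uniform_cube_edge <- function(mesh) {
  co <- mesh$nodes[mesh$elements[1, ], , drop = FALSE]
  ref <- sweep(co, 2, co[1, ])
  h <- max(abs(ref))
  if (h <= 0) return(NULL)
  if (!isTRUE(all.equal(ref, ((HEX_XI + 1) / 2) * h, tolerance = 1e-9,
                        check.attributes = FALSE))) {
    return(NULL)
  }
  # spot-check a few more elements for congruence
  probe <- unique(round(seq(1, nrow(mesh$elements), length.out = 5)))
  for (e in probe) {
    coe <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    refe <- sweep(coe, 2, coe[1, ])
    if (!isTRUE(all.equal(refe, ref, tolerance = 1e-9,
                          check.attributes = FALSE))) {
      return(NULL)
    }
  }
  h
}

#' Assemble the global stiffness of a macro mesh
#'
#' Element stiffness uses the isotropic pair `(E(rho_e), nu(rho_e))` from the
#' surrogate, or an explicit per-element material. On regular cube grids the
#' assembly reuses one pair of Lame stiffness parts; general meshes
#' integrate each element.
#'
#' @param mesh a [macro_mesh()].
#' @param densities per-element relative densities (or a `density_field`),
#'   used with `surrogate`.
#' @param surrogate a `lattice_surrogate`.
#' @param material alternatively, a [map_volume()] `material_field` or a
#'   list with `E` and `nu` (scalar or per element).
#' @return an object of class `fg_stiffness`: sparse symmetric `K`, the
#'   free-dof index, per-element data needed for energies and stresses.
#' @export
assemble <- function(mesh, densities = NULL, surrogate = NULL, material = NULL) {
  stopifnot(inherits(mesh, "macro_mesh"))
  mat <- resolve_material(mesh, densities, surrogate, material)
  nel <- nrow(mesh$elements)
  ndof <- 3L * nrow(mesh$nodes)
  edof <- edof_from_nodes(mesh$elements)
  lam <- lame_lambda(mat$E, rep_len(mat$nu, nel))
  mu <- lame_mu(mat$E, rep_len(mat$nu, nel))
  h <- uniform_cube_edge(mesh)
  if (!is.null(h)) {
    parts <- hex_stiffness_parts(((HEX_XI + 1) / 2) * h)
    i0 <- rep(1:24, times = 24); j0 <- rep(1:24, each = 24)
    xx <- outer(lam, as.vector(parts$L)) + outer(mu, as.vector(parts$M))
    K <- Matrix::sparseMatrix(i = as.vector(edof[, i0]),
                              j = as.vector(edof[, j0]),
                              x = as.vector(xx), dims = c(ndof, ndof))
    kes <- list(uniform = TRUE, parts = parts, lam = lam, mu = mu)
  } else {
    kelist <- vector("list", nel)
    for (e in seq_len(nel)) {
      co <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
      kelist[[e]] <- hex_stiffness(co, mat$E[e], rep_len(mat$nu, nel)[e])
    }
    K <- assemble_sparse(edof, kelist, ndof = ndof)
    kes <- list(uniform = FALSE, kelist = kelist)
  }
  fixed <- unique(3L * (mesh$fixed_dofs$node - 1L) + mesh$fixed_dofs$dir)
  free <- setdiff(seq_len(ndof), fixed)
  structure(list(K = K, free = free, fixed = fixed, edof = edof,
                 E = mat$E, nu = rep_len(mat$nu, nel), kes = kes,
                 mesh = mesh),
            class = "fg_stiffness")
}

## element stiffness matrix for element e from an assembled operator
element_ke <- function(stiff, e) {
  if (stiff$kes$uniform) {
    stiff$kes$lam[e] * stiff$kes$parts$L + stiff$kes$mu[e] * stiff$kes$parts$M
  } else {
    stiff$kes$kelist[[e]]
  }
}

#' Solve the macro elasticity problem
#'
#' Eliminates the fixed dofs, solves `K U = F` with a sparse Cholesky
#' factorization, and fills the solution state: displacements, compliance
#' `c = U'KU` (N mm), per-element strain energies `dc_e = u_e' k_e u_e`
#' (which sum to `c`), and centroid von Mises stresses.
#'
#' @param mesh a [macro_mesh()].
#' @param stiff the matching [assemble()] result; assembled on the fly when
#'   `NULL` using `...` arguments.
#' @param ... passed to [assemble()] when `stiff` is `NULL`.
#' @param residual_tol acceptance threshold on `||KU - F|| / ||F||`.
#' @return an object of class `fe_solution`: `U` (mm), `compliance` (N mm),
#'   `element_energy` (N mm), `vm` (MPa), `residual`.
#' @export
fe_solve <- function(mesh, stiff = NULL, ..., residual_tol = 1e-8) {
  stopifnot(inherits(mesh, "macro_mesh"))
  if (is.null(stiff)) stiff <- assemble(mesh, ...)
  ndof <- 3L * nrow(mesh$nodes)
  F <- numeric(ndof)
  if (nrow(mesh$loads)) {
    idx <- 3L * (mesh$loads$node - 1L) + mesh$loads$dir
    F[idx] <- F[idx] + mesh$loads$value
  }
  U <- numeric(ndof)
  if (any(F[stiff$fixed] != 0)) {
    warning("loads applied on fixed dofs are ignored", call. = FALSE)
  }
  free <- stiff$free
  Kff <- stiff$K[free, free, drop = FALSE]
  if (sum(abs(F[free])) > 0) {
    Uf <- tryCatch(
      as.vector(Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(Kff)),
                              F[free])),
      error = function(e) {
        stop("stiffness factorization failed (singular or underconstrained mesh): ",
             conditionMessage(e), call. = FALSE)
      }
    )
    U[free] <- Uf
    res <- sqrt(sum((as.vector(Kff %*% Uf) - F[free])^2)) / sqrt(sum(F[free]^2))
    if (!is.finite(res) || res > residual_tol) {
      stop(sprintf("solver residual %.3g exceeds tolerance %.3g", res,
                   residual_tol), call. = FALSE)
    }
  } else {
    res <- 0
  }
  nel <- nrow(mesh$elements)
  energy <- numeric(nel)
  for (e in seq_len(nel)) {
    ue <- U[stiff$edof[e, ]]
    energy[e] <- sum(ue * (element_ke(stiff, e) %*% ue))
  }
  compliance <- sum(F * U)
  sol <- structure(list(U = U, compliance = compliance,
                        element_energy = energy, residual = res,
                        F = F),
                   class = "fe_solution")
  sol$vm <- von_mises(sol, mesh, stiff = stiff)
  sol
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("FE solution: compliance %.6g N mm, max |U| %.4g mm, peak von Mises %.4g MPa, residual %.2g\n",
              x$compliance, max(abs(x$U)), max(x$vm), x$residual))
  invisible(x)
}

#' Centroid von Mises stress per element
#'
#' Evaluates the stress tensor at each element centroid from the solved
#' displacement field and the element's isotropic material, and reduces it to
#' the von Mises equivalent.
#'
#' @param state an [fe_solve()] solution.
#' @param mesh the mesh it was solved on.
#' @param densities,surrogate,material material specification as in
#'   [assemble()]; ignored when `stiff` is given.
#' @param stiff optionally, the assembled operator (reuses its material).
#' @return numeric vector of von Mises stresses (MPa).
#' @export
von_mises <- function(state, mesh, densities = NULL, surrogate = NULL,
                      material = NULL, stiff = NULL) {
  stopifnot(inherits(state, "fe_solution"), inherits(mesh, "macro_mesh"))
  if (!is.null(stiff)) {
    E <- stiff$E; nu <- stiff$nu; edof <- stiff$edof
  } else {
    mat <- resolve_material(mesh, densities, surrogate, material)
    E <- mat$E; nu <- rep_len(mat$nu, nrow(mesh$elements))
    edof <- edof_from_nodes(mesh$elements)
  }
  nel <- nrow(mesh$elements)
  vm <- numeric(nel)
  for (e in seq_len(nel)) {
    co <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    bb <- hex_B(co, 0, 0, 0)
    sig <- iso_elasticity(E[e], nu[e]) %*% (bb$B %*% state$U[edof[e, ]])
    vm[e] <- sqrt(0.5 * ((sig[1] - sig[2])^2 + (sig[1] - sig[3])^2 +
                           (sig[2] - sig[3])^2) +
                    3 * (sig[4]^2 + sig[5]^2 + sig[6]^2))
  }
  vm
}

#' Von Mises stress profile along a surface node path
#'
#' Samples the solution along an ordered node path (e.g. the bone-implant
#' interface from the distal to the proximal end): at each path node the von
#' Mises stresses of the adjacent elements are averaged, and positions are
#' reported as arc length along the path.
#'
#' @param state an [fe_solve()] solution with `vm` filled.
#' @param mesh the mesh.
#' @param node_path ordered node indices.
#' @return data frame with columns `s` (arc position, mm) and `vm` (MPa).
#' @export
interface_profile <- function(state, mesh, node_path) {
  stopifnot(inherits(state, "fe_solution"), inherits(mesh, "macro_mesh"))
  node_path <- as.integer(node_path)
  if (any(node_path < 1L) || any(node_path > nrow(mesh$nodes))) {
    stop("invalid path: node index outside the mesh", call. = FALSE)
  }
  xyz <- mesh$nodes[node_path, , drop = FALSE]
  s <- if (nrow(xyz) > 1L) {
    c(0, cumsum(sqrt(rowSums((xyz[-1, , drop = FALSE] -
                                xyz[-nrow(xyz), , drop = FALSE])^2))))
  } else 0
  vm <- vapply(node_path, function(nd) {
    adj <- which(rowSums(mesh$elements == nd) > 0L)
    mean(state$vm[adj])
  }, numeric(1))
  data.frame(s = s, vm = vm)
}
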