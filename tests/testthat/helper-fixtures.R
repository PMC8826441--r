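# Shared fixtures and independent oracles for the test suite.

# published octet-truss polynomial surrogate (titanium, Es = 110 GPa)
published_surrogate <- function(Es = 110000, nus = 0.3) {
  surrogate_from_coefs(c(1.23, -0.2411, 0.03213),
                       c(0.7165, -0.7995, -0.05101, 1.134),
                       Es = Es, nus = nus, rho_domain = c(0.1, 0.8))
}

# small solved cantilever shared by several tests
small_cantilever <- function(nx = 8, ny = 4, nz = 2, h = 1) {
  make_cantilever(nx, ny, nz, h = h, total_load = c(0, -100, 0))
}

# --- independent oracles -----------------------------------------------------

# bisection inverse of the octet density relation (independent of the
# closed-form inverse in the package)
bisect_strut <- function(rho, l, tol = 1e-14) {
  lo <- 0; hi <- l
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (density_from_strut(mid, l) < rho) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# independent strain-displacement matrix at an element-local point by
# central finite differences of the trilinear shape functions
fd_B_matrix <- function(coords, xi, eta, zeta, h = 1e-6) {
  shape <- function(p) {
    x <- p[1]; y <- p[2]; z <- p[3]
    sgn <- cbind(c(-1, 1, 1, -1, -1, 1, 1, -1),
                 c(-1, -1, 1, 1, -1, -1, 1, 1),
                 c(-1, -1, -1, -1, 1, 1, 1, 1))
    0.125 * (1 + x * sgn[, 1]) * (1 + y * sgn[, 2]) * (1 + z * sgn[, 3])
  }
  # global position as a function of local coords
  pos <- function(p) as.vector(t(coords) %*% shape(p))
  p0 <- c(xi, eta, zeta)
  J <- matrix(0, 3, 3)  # J[a, b] = dx_b / dxi_a
  for (a in 1:3) {
    dp <- numeric(3); dp[a] <- h
    J[a, ] <- (pos(p0 + dp) - pos(p0 - dp)) / (2 * h)
  }
  dN_loc <- matrix(0, 8, 3)
  for (a in 1:3) {
    dp <- numeric(3); dp[a] <- h
    dN_loc[, a] <- (shape(p0 + dp) - shape(p0 - dp)) / (2 * h)
  }
  dN <- dN_loc %*% t(solve(J))
  B <- matrix(0, 6, 24)
  ix <- seq(1, 24, 3)
  B[1, ix] <- dN[, 1]; B[2, ix + 1] <- dN[, 2]; B[3, ix + 2] <- dN[, 3]
  B[4, ix] <- dN[, 2]; B[4, ix + 1] <- dN[, 1]
  B[5, ix] <- dN[, 3]; B[5, ix + 2] <- dN[, 1]
  B[6, ix + 1] <- dN[, 3]; B[6, ix + 2] <- dN[, 2]
  B
}

# isotropic elasticity matrix, Voigt (11,22,33,12,13,23), engineering shears
iso_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6); D[1:3, 1:3] <- lam
  diag(D) <- c(rep(lam + 2 * mu, 3), rep(mu, 3))
  D
}

# optimality-criteria reference optimizer (compliance minimization with the
# same surrogate stiffness law, bounds and volume constraint as the GA);
# used only as an independent near-optimal baseline in tests
oc_reference <- function(mesh, surr, vol_frac = 0.4, bounds = c(0.2, 0.7),
                         iters = 40, move = 0.1) {
  nel <- nrow(mesh$elements)
  rho <- rep(vol_frac, nel)
  dE <- function(r) 2 * surr$e_coeffs[["a2"]] * r + surr$e_coeffs[["a1"]]
  Ef <- function(r) surr$e_coeffs[["a2"]] * r^2 + surr$e_coeffs[["a1"]] * r +
    surr$e_coeffs[["a0"]]
  for (k in seq_len(iters)) {
    sol <- fe_solve(mesh, stiff = assemble(mesh, densities = rho,
                                           surrogate = surr))
    # dc/drho_e = -(E'(rho)/E(rho)) * energy_e  (energy at fixed U)
    sens <- sol$element_energy * dE(rho) / Ef(rho)
    l1 <- 1e-12; l2 <- 1e6
    while ((l2 - l1) / (l1 + l2) > 1e-6) {
      lmid <- 0.5 * (l1 + l2)
      rnew <- rho * sqrt(pmax(sens, 0) / lmid)
      rnew <- pmin(pmax(rnew, rho - move), rho + move)
      rnew <- pmin(pmax(rnew, bounds[1]), bounds[2])
      if (mean(rnew) > vol_frac) l1 <- lmid else l2 <- lmid
    }
    rho <- rnew
  }
  sol <- fe_solve(mesh, stiff = assemble(mesh, densities = rho,
                                         surrogate = surr))
  list(rho = rho, compliance = sol$compliance)
}

# orthotropic compliance re-assembled from engineering constants (oracle)
compliance_from_constants_oracle <- function(ec) {
  S <- matrix(0, 6, 6)
  diag(S) <- c(1 / ec$E1, 1 / ec$E2, 1 / ec$E3, 1 / ec$G12, 1 / ec$G13, 1 / ec$G23)
  S[1, 2] <- S[2, 1] <- -ec$nu12 / ec$E1
  S[1, 3] <- S[3, 1] <- -ec$nu13 / ec$E1
  S[2, 3] <- S[3, 2] <- -ec$nu23 / ec$E2
  S
}

# Euler characteristic and edge-manifoldness of a triangle soup
mesh_topology <- function(tris, tol = 1e-9) {
  verts <- rbind(tris[, 1:3], tris[, 4:6], tris[, 7:9])
  key <- apply(round(verts / tol), 1, paste, collapse = ",")
  vid <- match(key, unique(key))
  n <- nrow(tris)
  v1 <- vid[seq_len(n)]; v2 <- vid[seq_len(n) + n]; v3 <- vid[seq_len(n) + 2 * n]
  edges <- rbind(cbind(pmin(v1, v2), pmax(v1, v2)),
                 cbind(pmin(v2, v3), pmax(v2, v3)),
                 cbind(pmin(v1, v3), pmax(v1, v3)))
  ek <- paste(edges[, 1], edges[, 2])
  tab <- table(ek)
  list(V = length(unique(key)), E = length(tab), F = n,
       chi = length(unique(key)) - length(tab) + n,
       manifold = all(tab == 2L))
}

# renumber the nodes of a macro mesh with a permutation (solution invariance)
permute_mesh <- function(mesh, perm) {
  inv <- order(perm)
  macro_mesh(mesh$nodes[perm, , drop = FALSE],
             matrix(inv[mesh$elements], nrow = nrow(mesh$elements)),
             transform(mesh$fixed_dofs, node = inv[node]),
             transform(mesh$loads, node = inv[node]))
}

# cached expensive computations, shared across test files in one session
.cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}
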