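# Internal finite-element utilities: 8-node hexahedra, 2x2x2 Gauss
# quadrature, mm-N-MPa unit system throughout.

## local corner coordinates in [-1,1]^3, standard hex ordering
## (counter-clockwise bottom face, then top face)
HEX_XI <- cbind(c(-1, 1, 1, -1, -1, 1, 1, -1),
                c(-1, -1, 1, 1, -1, -1, 1, 1),
                c(-1, -1, -1, -1, 1, 1, 1, 1))

## Voigt strain order used everywhere: (11, 22, 33, 12, 13, 23),
## engineering shear strains in rows 4:6.

## isotropic 6x6 elasticity matrix (MPa)
iso_elasticity <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D) <- c(rep(lam + 2 * mu, 3), rep(mu, 3))
  D
}

## shape-function derivatives wrt local coords at (xi, eta, zeta): 8x3
hex_dN <- function(xi, eta, zeta) {
  0.125 * cbind(
    HEX_XI[, 1] * (1 + eta * HEX_XI[, 2]) * (1 + zeta * HEX_XI[, 3]),
    HEX_XI[, 2] * (1 + xi * HEX_XI[, 1]) * (1 + zeta * HEX_XI[, 3]),
    HEX_XI[, 3] * (1 + xi * HEX_XI[, 1]) * (1 + eta * HEX_XI[, 2])
  )
}

## strain-displacement matrix (6x24) and |J| at a local point for an element
## with corner coordinates `coords` (8x3)
hex_B <- function(coords, xi, eta, zeta) {
  dN <- hex_dN(xi, eta, zeta)
  J <- t(dN) %*% coords          # 3x3
  detJ <- det(J)
  dNx <- dN %*% t(solve(J))      # dN_i/dx_b = sum_a dN_i/dxi_a * dxi_a/dx_b
  B <- matrix(0, 6, 24)
  ix <- seq(1, 24, by = 3)
  B[1, ix]     <- dNx[, 1]
  B[2, ix + 1] <- dNx[, 2]
  B[3, ix + 2] <- dNx[, 3]
  B[4, ix]     <- dNx[, 2]; B[4, ix + 1] <- dNx[, 1]
  B[5, ix]     <- dNx[, 3]; B[5, ix + 2] <- dNx[, 1]
  B[6, ix + 1] <- dNx[, 3]; B[6, ix + 2] <- dNx[, 2]
  list(B = B, detJ = detJ)
}

GAUSS_1D <- c(-1, 1) / sqrt(3)

## element stiffness (24x24) for an 8-node hex with isotropic (E, nu)
hex_stiffness <- function(coords, E, nu) {
  D <- iso_elasticity(E, nu)
  ke <- matrix(0, 24, 24)
  for (a in GAUSS_1D) for (b in GAUSS_1D) for (c in GAUSS_1D) {
    bb <- hex_B(coords, a, b, c)
    if (bb$detJ <= 0) stop("non-positive Jacobian in hex element", call. = FALSE)
    ke <- ke + crossprod(bb$B, D %*% bb$B) * bb$detJ
  }
  ke
}

## Lame decomposition: ke(E, nu) = lam * keL + mu * keM for a FIXED geometry.
## Used to assemble heterogeneous meshes without re-integrating every element
## when all elements share one geometry (regular grids).
hex_stiffness_parts <- function(coords) {
  DL <- matrix(0, 6, 6); DL[1:3, 1:3] <- 1                    # lambda part
  DM <- diag(c(2, 2, 2, 1, 1, 1))                             # mu part
  keL <- matrix(0, 24, 24); keM <- matrix(0, 24, 24)
  for (a in GAUSS_1D) for (b in GAUSS_1D) for (c in GAUSS_1D) {
    bb <- hex_B(coords, a, b, c)
    if (bb$detJ <= 0) stop("non-positive Jacobian in hex element", call. = FALSE)
    keL <- keL + crossprod(bb$B, DL %*% bb$B) * bb$detJ
    keM <- keM + crossprod(bb$B, DM %*% bb$B) * bb$detJ
  }
  list(L = keL, M = keM)
}

lame_lambda <- function(E, nu) E * nu / ((1 + nu) * (1 - 2 * nu))
lame_mu <- function(E, nu) E / (2 * (1 + nu))

## 24 dof indices (x,y,z interleaved) for given node ids
edof_from_nodes <- function(nodes8) {
  # nodes8: nel x 8 integer matrix -> nel x 24
  nel <- nrow(nodes8)
  out <- matrix(0L, nel, 24L)
  for (a in 1:8) {
    out[, 3L * a - 2L] <- 3L * nodes8[, a] - 2L
    out[, 3L * a - 1L] <- 3L * nodes8[, a] - 1L
    out[, 3L * a]      <- 3L * nodes8[, a]
  }
  out
}

## assemble a sparse symmetric stiffness from per-element 24x24 blocks.
## kes: either a single 24x24 matrix (shared geometry, scaled by `scale`),
## or a list of per-element matrices. Returns dgCMatrix.
assemble_sparse <- function(edof, kes, scale = NULL, ndof) {
  nel <- nrow(edof)
  i0 <- rep(1:24, times = 24)
  j0 <- rep(1:24, each = 24)
  if (is.matrix(kes)) {
    kev <- as.vector(kes)
    xx <- if (is.null(scale)) {
      matrix(kev, nel, 576, byrow = TRUE)
    } else {
      outer(scale, kev)
    }
  } else {
    xx <- t(vapply(kes, as.vector, numeric(576)))
  }
  K <- Matrix::sparseMatrix(
    i = as.vector(edof[, i0]),
    j = as.vector(edof[, j0]),
    x = as.vector(xx),
    dims = c(ndof, ndof)
  )
  K
}

## Jacobi-preconditioned conjugate gradients with a block of right-hand
## sides advanced in lockstep (one sparse matvec per iteration for all
## columns). Returns list(X, iters, rel).
block_pcg <- function(K, B, tol = 1e-8, maxit = 10000L) {
  B <- as.matrix(B)
  m <- ncol(B)
  dK <- Matrix::diag(K)
  if (any(dK <= 0)) stop("non-positive diagonal in stiffness matrix", call. = FALSE)
  Minv <- 1 / dK
  X <- matrix(0, nrow(B), m)
  R <- B
  Z <- Minv * R
  P <- Z
  rz <- colSums(R * Z)
  nb <- sqrt(colSums(B * B))
  nb[nb == 0] <- 1
  active <- rep(TRUE, m)
  it <- 0L
  rel <- sqrt(colSums(R * R)) / nb
  while (any(active) && it < maxit) {
    AP <- as.matrix(K %*% P)
    pap <- colSums(P * AP)
    alpha <- ifelse(active & pap > 0, rz / pap, 0)
    X <- X + sweep(P, 2, alpha, `*`)
    R <- R - sweep(AP, 2, alpha, `*`)
    it <- it + 1L
    rel <- sqrt(colSums(R * R)) / nb
    active <- rel > tol
    if (!any(active)) break
    Z <- Minv * R
    rz2 <- colSums(R * Z)
    beta <- ifelse(rz > 0, rz2 / rz, 0)
    rz <- rz2
    P <- Z + sweep(P, 2, beta, `*`)
  }
  if (any(rel > tol)) {
    stop(sprintf("conjugate-gradient solver did not converge: relative residual %.3g after %d iterations",
                 max(rel), it), call. = FALSE)
  }
  list(X = X, iters = it, rel = max(rel))
}
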