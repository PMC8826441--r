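# Macro finite-element solver: assembly, solution, stresses, profiles.

test_that("assembly is linear in E, symmetric, and energy-exact on one cube", {
  g <- fglattice:::grid_mesh_nodes(1, 1, 1, 2)
  mesh <- macro_mesh(g$nodes, g$elements,
                     data.frame(node = rep(1:4, each = 3), dir = rep(1:3, 4)),
                     data.frame(node = 8, dir = 1, value = 1))
  K1 <- assemble(mesh, material = list(E = 1000, nu = 0.25))$K
  K2 <- assemble(mesh, material = list(E = 2000, nu = 0.25))$K
  expect_lt(max(abs(K2 - 2 * K1)), 1e-9 * max(abs(K1)))
  expect_lt(max(abs(K1 - Matrix::t(K1))), 1e-10 * max(abs(K1)))
  # constrained uniaxial stretch: u_x = eps * x, other components zero;
  # strain energy = 1/2 (lam + 2 mu) eps^2 V (constant strain is exact)
  eps <- 0.01; E <- 1000; nu <- 0.25; V <- 8
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  u <- numeric(24)
  u[seq(1, 24, 3)] <- eps * g$nodes[, 1]
  energy <- 0.5 * sum(u * as.vector(K1 %*% u))
  expect_equal(energy, 0.5 * (lam + 2 * mu) * eps^2 * V, tolerance = 1e-10)
})

test_that("zero load gives zero displacement and compliance", {
  mesh <- make_cantilever(4, 2, 2, total_load = c(0, 0, 0))
  sol <- fe_solve(mesh, material = list(E = 1000, nu = 0.3))
  expect_equal(sol$U, rep(0, length(sol$U)))
  expect_equal(sol$compliance, 0)
  expect_true(all(sol$element_energy == 0))
})

test_that("cantilever tip deflection matches beam theory within 10%", {
  mesh <- cached("beam40", make_cantilever(40, 4, 4, h = 1,
                                           total_load = c(0, -100, 0)))
  sol <- cached("beam40_sol", fe_solve(mesh, material = list(E = 1000, nu = 0.3)))
  tip <- which(abs(mesh$nodes[, 1] - 40) < 1e-9 & abs(mesh$nodes[, 2]) < 1e-9)
  uy <- mean(sol$U[3 * (tip - 1) + 2])
  P <- 100; L <- 40; E <- 1000; I <- 4 * 4^3 / 12
  expect_equal(uy, -P * L^3 / (3 * E * I), tolerance = 0.1)
})

test_that("element energies satisfy the compliance identity", {
  mesh <- cached("beam40", make_cantilever(40, 4, 4, h = 1,
                                           total_load = c(0, -100, 0)))
  sol <- cached("beam40_sol", fe_solve(mesh, material = list(E = 1000, nu = 0.3)))
  expect_equal(sum(sol$element_energy), sol$compliance, tolerance = 1e-8)
  expect_gte(min(sol$element_energy), 0)
  # and c = U'KU = F.U
  st <- assemble(mesh, material = list(E = 1000, nu = 0.3))
  expect_equal(as.numeric(t(sol$U) %*% (st$K %*% sol$U)), sol$compliance,
               tolerance = 1e-8)
})

test_that("von Mises matches an independent B-matrix recomputation", {
  set.seed(8)
  mesh <- make_cantilever(3, 2, 2, h = 1.3, total_load = c(5, -20, 3))
  surr <- published_surrogate()
  rho <- runif(nrow(mesh$elements), 0.2, 0.7)
  st <- assemble(mesh, densities = rho, surrogate = surr)
  sol <- fe_solve(mesh, stiff = st)
  mat <- predict(surr, rho)
  for (e in sample(nrow(mesh$elements), 4)) {
    co <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    B <- fd_B_matrix(co, 0, 0, 0)
    ue <- sol$U[fglattice:::edof_from_nodes(mesh$elements)[e, ]]
    sig <- iso_D(mat$E[e], mat$nu[e]) %*% (B %*% ue)
    vm_oracle <- sqrt(0.5 * ((sig[1] - sig[2])^2 + (sig[1] - sig[3])^2 +
                               (sig[2] - sig[3])^2) +
                        3 * sum(sig[4:6]^2))
    expect_equal(sol$vm[e], as.numeric(vm_oracle), tolerance = 1e-5)
  }
})

test_that("uniaxial and hydrostatic stress states reduce correctly", {
  # pure hydrostatic strain on one element: von Mises ~ 0
  g <- fglattice:::grid_mesh_nodes(1, 1, 1, 1)
  mesh <- macro_mesh(g$nodes, g$elements,
                     data.frame(node = rep(1:4, each = 3), dir = rep(1:3, 4)),
                     data.frame(node = 8, dir = 1, value = 0))
  st <- assemble(mesh, material = list(E = 1000, nu = 0.3))
  sol <- fe_solve(mesh, stiff = st)
  eps <- 0.01
  sol$U <- as.vector(t(g$nodes * eps))       # u = eps * x: hydrostatic
  vm <- von_mises(sol, mesh, stiff = st)
  expect_lt(vm[1], 1e-9)
  # uniaxial stress state sigma -> von Mises = sigma
  nu <- 0.3
  U <- cbind(eps * g$nodes[, 1], -nu * eps * g$nodes[, 2],
             -nu * eps * g$nodes[, 3])
  sol$U <- as.vector(t(U))
  vm2 <- von_mises(sol, mesh, stiff = st)
  expect_equal(vm2[1], 1000 * eps, tolerance = 1e-9)
})

test_that("solution is invariant under node renumbering", {
  mesh <- make_cantilever(4, 3, 2, total_load = c(0, -50, 0))
  sol <- fe_solve(mesh, material = list(E = 500, nu = 0.3))
  set.seed(13)
  perm <- sample(nrow(mesh$nodes))
  pm <- permute_mesh(mesh, perm)
  sol2 <- fe_solve(pm, material = list(E = 500, nu = 0.3))
  expect_equal(sol2$compliance, sol$compliance, tolerance = 1e-9)
  expect_equal(max(abs(sol2$U)), max(abs(sol$U)), tolerance = 1e-9)
})

test_that("compliance decreases when any element gets denser", {
  mesh <- make_cantilever(3, 2, 1, total_load = c(0, -10, 0))
  surr <- published_surrogate()
  rho0 <- rep(0.4, nrow(mesh$elements))
  c0 <- fe_solve(mesh, densities = rho0, surrogate = surr)$compliance
  for (e in seq_len(nrow(mesh$elements))) {
    rho <- rho0; rho[e] <- 0.55
    ce <- fe_solve(mesh, densities = rho, surrogate = surr)$compliance
    expect_lt(ce, c0)
  }
})

test_that("interface profiles sample ordered arc positions", {
  mesh <- cached("beam40", make_cantilever(40, 4, 4, h = 1,
                                           total_load = c(0, -100, 0)))
  sol <- cached("beam40_sol", fe_solve(mesh, material = list(E = 1000, nu = 0.3)))
  # path along the bottom beam edge
  path <- which(abs(mesh$nodes[, 2]) < 1e-9 & abs(mesh$nodes[, 3]) < 1e-9)
  path <- path[order(mesh$nodes[path, 1])]
  pr <- interface_profile(sol, mesh, path)
  expect_equal(nrow(pr), length(path))
  expect_true(all(diff(pr$s) > 0))
  expect_equal(pr$s[length(path)], 40)
  # single-node path gives a single sample at s = 0
  pr1 <- interface_profile(sol, mesh, path[1])
  expect_equal(nrow(pr1), 1)
  expect_equal(pr1$s, 0)
  expect_error(interface_profile(sol, mesh, c(1, 10^6)), "invalid path")
})

test_that("underconstrained meshes are rejected", {
  g <- fglattice:::grid_mesh_nodes(2, 1, 1, 1)
  expect_error(
    macro_mesh(g$nodes, g$elements,
               data.frame(node = 1, dir = 1),
               data.frame(node = 2, dir = 2, value = 1)),
    "underconstrained")
})
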