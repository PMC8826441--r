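# Genetic-algorithm operators and the density optimization loop.

test_that("binary encoding is linear with exact endpoints and bounded error", {
  cfg <- ga_config()
  g_lo <- encode_density(0.2, cfg)
  g_hi <- encode_density(0.7, cfg)
  expect_true(all(g_lo == 0L))
  expect_true(all(g_hi == 1L))
  expect_equal(decode_gene(g_lo, cfg), 0.2)
  expect_equal(decode_gene(g_hi, cfg), 0.7)
  step <- diff(cfg$rho_bounds) / (2^cfg$bits_per_gene - 1)
  set.seed(21)
  rho <- runif(1000, 0.2, 0.7)
  err <- abs(decode_gene(encode_density(rho, cfg), cfg) - rho)
  expect_lte(max(err), step / 2 + 1e-12)
  expect_warning(encode_density(0.9, cfg), "clamped")
})

test_that("fitness is the element strain energy and sums to the compliance", {
  mesh <- small_cantilever()
  surr <- published_surrogate()
  sol <- fe_solve(mesh, densities = rep(0.4, nrow(mesh$elements)),
                  surrogate = surr)
  fit <- ga_fitness(sol)
  expect_true(all(fit >= 0))
  expect_equal(sum(fit), sol$compliance, tolerance = 1e-8)
  expect_error(ga_fitness(list()), "solved")
  # ranking agrees with brute-force sensitivity: weakening a high-energy
  # element hurts compliance more than weakening a low-energy one
  hi <- which.max(fit); lo <- which.min(fit)
  perturb <- function(e) {
    rho <- rep(0.4, nrow(mesh$elements)); rho[e] <- 0.2
    fe_solve(mesh, densities = rho, surrogate = surr)$compliance
  }
  expect_gt(perturb(hi), perturb(lo))
})

test_that("roulette selection is fitness-proportional", {
  set.seed(4)
  # all mass on one element
  par <- select_parents(c(0, 0, 5, 0), n = 50)
  expect_true(all(par$father == 3L) && all(par$mother == 3L))
  # uniform fitness: frequencies uniform within 3 sigma of a multinomial
  n <- 1e5
  par <- select_parents(rep(1, 4), n = n)
  counts <- tabulate(par$father, 4)
  sigma <- sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(counts - n / 4) < 3 * sigma))
  # proportionality on skewed fitness
  par2 <- select_parents(c(1, 3), n = n)
  expect_equal(mean(par2$father == 2L), 0.75, tolerance = 0.02)
  # all-zero fitness falls back to uniform
  par3 <- select_parents(c(0, 0, 0), n = n)
  expect_true(all(abs(tabulate(par3$father, 3) - n / 3) < 3 * sqrt(n * 2 / 9)))
  expect_error(select_parents(c(-1, 1)), "non-negative")
})

test_that("uniform crossover takes mother bits at the crossover rate", {
  cfg <- ga_config(crossover_factor = 0.3)
  a <- matrix(0L, 1000, 8); b <- matrix(1L, 1000, 8)
  set.seed(9)
  child <- crossover(a, b, cfg)
  frac_b <- mean(child)
  sigma <- sqrt(0.3 * 0.7 / 8000)
  expect_lt(abs(frac_b - 0.3), 3 * sigma)
  # identical parents reproduce exactly; zero factor copies the father
  expect_identical(crossover(a, a, cfg), a)
  cfg0 <- ga_config(crossover_factor = 0)
  expect_identical(crossover(a, b, cfg0), a)
  expect_error(crossover(a, b[, 1:4], cfg), "mismatch")
})

test_that("mutation is directional: top ranks drift denser, bottom ranks sparser", {
  cfg <- ga_config(mutation_factor = 0.2)
  set.seed(14)
  n <- 1e4
  start <- encode_density(rep(0.45, n), cfg)
  up <- mutate(start, rep(1, n), cfg)
  dn <- mutate(start, rep(0, n), cfg)
  expect_true(all(decode_gene(up, cfg) >= decode_gene(start, cfg) - 1e-12))
  expect_true(all(decode_gene(dn, cfg) <= decode_gene(start, cfg) + 1e-12))
  expect_gt(mean(decode_gene(up, cfg)), 0.45)
  expect_lt(mean(decode_gene(dn, cfg)), 0.45)
  # per-bit mutation rate: each of the 7 zero bits of the 0.45-gene flips to
  # 1 with p = 0.2, so a fraction 1 - 0.8^7 of elements changes
  frac_hit <- mean(rowSums(up != start) > 0)
  expect_equal(frac_hit, 1 - 0.8^7, tolerance = 0.05)
  # changed-bit count per element is binomial(7, 0.2)
  expect_equal(mean(rowSums(up != start)), 7 * 0.2, tolerance = 0.05)
  # zero factor leaves genes unchanged
  cfg0 <- ga_config(mutation_factor = 0)
  expect_identical(mutate(start, rep(1, n), cfg0), start)
})

test_that("volume enforcement is a feasible fixed point that respects bounds", {
  cfg <- ga_config()
  # feasible fields pass through unchanged (up to quantization)
  set.seed(2)
  rho <- runif(200, 0.2, 0.55)
  rho <- rho * 0.38 / mean(rho)
  rho <- pmin(pmax(rho, 0.2), 0.7)
  out <- enforce_volume(rho, cfg)
  step <- fglattice:::ga_step(cfg)
  expect_lt(max(abs(out$rho - rho)), step)
  # saturated field scales to the constraint
  out2 <- enforce_volume(rep(0.7, 100), cfg)
  expect_lte(mean(out2$rho), 0.4 + 1e-9)
  expect_gte(mean(out2$rho), 0.4 - 2 * step)
  expect_true(all(out2$rho >= 0.2 - 1e-12 & out2$rho <= 0.7 + 1e-12))
  # decoded genes equal the returned densities (field invariant)
  expect_equal(decode_gene(out2$genes, cfg), out2$rho)
  expect_error(enforce_volume(rep(0.5, 10),
                              ga_config(volume_fraction = 0.45,
                                        rho_bounds = c(0.5, 0.7))),
               "infeasible|within")
})

test_that("optimization respects constraints, improves on uniform, and is elitist", {
  mesh <- cached("ga_mesh", small_cantilever(10, 5, 2))
  surr <- published_surrogate()
  cfg <- ga_config(seed = 42, max_iters = 30)
  des <- cached("ga_des", optimize_lattice_density(mesh, surr, cfg))
  expect_lte(mean(des$rho), 0.4 + 1e-9)
  expect_true(all(des$rho >= 0.2 - 1e-12 & des$rho <= 0.7 + 1e-12))
  expect_true(all(des$history$volume <= 0.4 + 1e-6))
  base <- fe_solve(mesh, densities = rep(0.4, nrow(mesh$elements)),
                   surrogate = surr)$compliance
  expect_lte(des$compliance, base)
  # best-so-far is the minimum of the recorded history
  expect_equal(des$compliance, min(des$history$compliance), tolerance = 1e-12)
  # high-fitness elements end denser on average
  expect_gt(cor(des$fitness0, des$rho), 0)
})

test_that("runs are bit-reproducible for a fixed seed", {
  mesh <- small_cantilever(6, 3, 2)
  surr <- published_surrogate()
  cfg <- ga_config(seed = 11, max_iters = 8)
  d1 <- optimize_lattice_density(mesh, surr, cfg)
  d2 <- optimize_lattice_density(mesh, surr, cfg)
  expect_identical(d1$history, d2$history)
  expect_identical(d1$rho, d2$rho)
  expect_identical(d1$genes, d2$genes)
})

test_that("zero load converges immediately with zero compliance", {
  mesh <- make_cantilever(4, 2, 2, total_load = c(0, 0, 0))
  des <- optimize_lattice_density(mesh, published_surrogate(),
                                  ga_config(seed = 1, max_iters = 10))
  expect_equal(des$compliance, 0)
  expect_equal(des$converged_at, 2L)
})

test_that("GA lands between the optimality-criteria optimum and the uniform design", {
  # the OC reference (same stiffness law, bounds and volume constraint) is a
  # near-optimal graded design; the rank-split GA cannot reach its
  # intermediate-density layouts but must improve on the uniform baseline
  mesh <- cached("mbb_mesh", make_cantilever(24, 8, 2, h = 1,
                                             total_load = c(0, -100, 0)))
  surr <- published_surrogate()
  oc <- cached("mbb_oc", oc_reference(mesh, surr, vol_frac = 0.4,
                                      bounds = c(0.2, 0.7), iters = 30))
  des <- cached("mbb_ga", optimize_lattice_density(
    mesh, surr, ga_config(seed = 3, max_iters = 60)))
  unif <- fe_solve(mesh, densities = rep(0.4, nrow(mesh$elements)),
                   surrogate = surr)$compliance
  expect_lte(mean(oc$rho), 0.4 + 1e-3)
  expect_gt(oc$compliance, 0)
  expect_gte(des$compliance, oc$compliance)   # OC bounds from below
  expect_lt(des$compliance, unif)             # GA strictly improves on uniform
  # and the gap to the optimum stays bounded (regression guard)
  expect_lte(des$compliance, 2 * oc$compliance)
})

test_that("configuration validation rejects out-of-domain bounds", {
  surr <- published_surrogate()             # domain [0.1, 0.8]
  mesh <- small_cantilever(4, 2, 2)
  cfg <- ga_config(rho_bounds = c(0.2, 0.7))
  cfg$rho_bounds <- c(0.05, 0.7)            # outside the surrogate domain
  expect_error(optimize_lattice_density(mesh, surr, cfg), "domain")
  expect_error(ga_config(volume_fraction = 0.1), "within")
})
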