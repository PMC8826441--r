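# Voxel homogenization: discretization, effective tensors, engineering
# constants. Expensive checks run at reduced resolution; the full-resolution
# sweep backs the acceptance tests.

test_that("voxelization matches the Monte-Carlo union oracle and clips as expected", {
  cell <- build_cell(unit_cell_spec("octet", l = 1, rho = 0.5))
  p <- voxelize(cell, 32)
  # frozen MC point-in-strut union fraction at rho = 0.5 (400k samples,
  # seed 42): 0.3598 +- 0.0015. The closed-form density 0.5 ignores junction
  # overlap and is a slender-strut approximation only.
  expect_equal(mean(p$indicator), 0.3598, tolerance = 0.02)
  expect_equal(mean(p$fraction), 0.3598, tolerance = 0.01)
  # at low density the closed form is accurate
  plo <- voxelize(build_cell(unit_cell_spec("octet", l = 1, rho = 0.1)), 48)
  expect_equal(mean(plo$fraction), 0.1, tolerance = 0.12)
  # a cell with struts thicker than the half cell is fully solid
  psolid <- voxelize(build_cell(unit_cell_spec("octet", l = 1, t = 0.8)), 12)
  expect_true(all(psolid$indicator))
  expect_true(all(psolid$fraction == 1))
  expect_error(voxelize(cell, 4), "at least 8")
  expect_warning(voxelize(build_cell(unit_cell_spec("octet", l = 1, rho = 0.1)), 16),
                 "fewer than 2 voxels")
})

test_that("voxel fraction is grid-converged (doubling n moves it < 2 points)", {
  cell <- build_cell(unit_cell_spec("octet", l = 1, rho = 0.4))
  f16 <- mean(voxelize(cell, 16)$fraction)
  f32 <- mean(voxelize(cell, 32)$fraction)
  expect_lt(abs(f32 - f16), 0.02)
})

test_that("fully solid RVE recovers the isotropic solid stiffness exactly", {
  p <- voxelize(build_cell(unit_cell_spec("octet", l = 1, t = 0.8)), 12,
                Es = 110000, nus = 0.3)
  C <- effective_tensor(p)
  D <- iso_D(110000, 0.3)
  expect_lt(max(abs(unclass(C) - D)) / max(abs(D)), 1e-6)
})

test_that("effective tensor is symmetric, PSD, bounded by Voigt, and cubic", {
  p <- cached("homog16", {
    voxelize(build_cell(unit_cell_spec("octet", l = 1, rho = 0.4)), 16)
  })
  C <- cached("C16", effective_tensor(p))
  M <- unclass(C)
  expect_lt(max(abs(M - t(M))), 1e-8 * max(abs(M)))
  expect_true(all(eigen(M, symmetric = TRUE, only.values = TRUE)$values > -1e-8 * max(abs(M))))
  # Voigt upper bound with the actual volume fraction
  expect_lte(M[1, 1], attr(C, "volume_fraction") * iso_D(110000, 0.3)[1, 1] + 1e-6)
  # cubic symmetry of the octet cell
  expect_lt(abs(M[1, 1] - M[2, 2]), 0.02 * M[1, 1])
  expect_lt(abs(M[1, 1] - M[3, 3]), 0.02 * M[1, 1])
  expect_lt(abs(M[4, 4] - M[5, 5]), 0.02 * M[1, 1])
  expect_lt(abs(M[4, 4] - M[6, 6]), 0.02 * M[1, 1])
  expect_lt(abs(M[1, 2] - M[1, 3]), 0.02 * M[1, 1])
})

test_that("disconnected solid phases are rejected with the axis named", {
  # two disjoint solid slabs normal to x: connected (wrapped) along y and z
  # but nowhere crossing x
  ind <- array(FALSE, dim = c(12, 12, 12))
  ind[3:4, , ] <- TRUE
  ind[8:9, , ] <- TRUE
  p <- structure(list(indicator = ind, fraction = NULL, Es = 1000, nus = 0.3,
                      n = 12L, l = 1), class = "homog_problem")
  expect_error(effective_tensor(p), "x")
  # single slab: continuous along y, z but not x -> error names x only
  ind2 <- array(FALSE, dim = c(12, 12, 12))
  ind2[3:5, , ] <- TRUE
  p2 <- structure(list(indicator = ind2, fraction = NULL, Es = 1000, nus = 0.3,
                       n = 12L, l = 1), class = "homog_problem")
  err <- tryCatch(effective_tensor(p2), error = conditionMessage)
  expect_match(err, "x")
  expect_no_match(err, "y,")
})

test_that("compliance tensor is the matrix inverse (dual-algorithm check)", {
  # solid titanium: 1/E on the compliance diagonal
  p <- voxelize(build_cell(unit_cell_spec("octet", l = 1, t = 0.8)), 12)
  C <- effective_tensor(p)
  S <- compliance_tensor(C)
  expect_equal(S[1, 1], 1 / 110000, tolerance = 1e-6)
  expect_lt(max(abs(as.matrix(unclass(C) %*% S) - diag(6))), 1e-8)
  # random SPD matrix: solve() vs qr.solve() agree
  set.seed(3)
  A <- crossprod(matrix(rnorm(36), 6))
  expect_equal(compliance_tensor(A), qr.solve(A), tolerance = 1e-10)
  expect_error(compliance_tensor(matrix(0, 6, 6)), "singular")
})

test_that("engineering constants read off the orthotropic compliance", {
  S <- compliance_tensor(iso_D(110000, 0.3))
  ec <- engineering_constants(S)
  expect_equal(ec$E1, 110000, tolerance = 1e-9)
  expect_equal(ec$nu12, 0.3, tolerance = 1e-9)
  expect_equal(ec$G12, 110000 / (2 * 1.3), tolerance = 1e-9)
  # round trip: constants re-assembled into compliance reproduce S
  expect_lt(max(abs(compliance_from_constants_oracle(ec) - S)), 1e-10)
  expect_error(engineering_constants(-S), "non-positive")
  # cubic lattice: E equal in the three directions
  C <- cached("C16", effective_tensor(cached("homog16", {
    voxelize(build_cell(unit_cell_spec("octet", l = 1, rho = 0.4)), 16)
  })))
  ecl <- engineering_constants(compliance_tensor(C))
  expect_equal(ecl$E1, ecl$E2, tolerance = 0.02)
  expect_equal(ecl$E1, ecl$E3, tolerance = 0.02)
})

test_that("density sweep is tabulated, monotone, and physically scaled", {
  sw <- cached("sweep12", suppressWarnings(
    density_sweep("octet", c(0.15, 0.3, 0.45, 0.6, 0.75), n = 12, l = 1)
  ))
  expect_equal(nrow(sw), 5)
  expect_true(all(diff(sw$E1) > 0))           # stiffness increases with density
  expect_true(all(diff(sw$volume_fraction) > 0))
  # low-density modulus within a factor 3 of the stretching-dominated rho/9
  r <- (sw$E1[1] / 110000) / (sw$rho[1] / 9)
  expect_gt(r, 1 / 3)
  expect_lt(r, 3)
  f <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, f)
  back <- read.csv(f)
  expect_equal(back$E1, sw$E1, tolerance = 1e-9)
})

test_that("refinement moves the Poisson ratio little and the moduli monotonically down", {
  # voxel stiffness of slender struts converges slowly from above (O(h),
  # stair-casing overstiffens); the Poisson ratio is already grid-converged
  cell <- build_cell(unit_cell_spec("octet", l = 1, rho = 0.4))
  e1 <- engineering_constants(compliance_tensor(
    effective_tensor(voxelize(cell, 24))))
  e2 <- engineering_constants(compliance_tensor(
    effective_tensor(voxelize(cell, 48))))
  expect_lt(abs(e2$nu12 - e1$nu12) / e1$nu12, 0.05)
  expect_lt(abs(e2$E1 - e1$E1) / e1$E1, 0.15)
  expect_lt(abs(e2$G12 - e1$G12) / e1$G12, 0.15)
  expect_lt(e2$E1, e1$E1)   # refinement softens toward the converged value
})
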