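# Unit-cell morphology relations and cell connectivity.

test_that("density_from_strut follows the octet closed form and its limits", {
  expect_equal(density_from_strut(0, 1.2), 0)
  expect_equal(density_from_strut(0.1, 1.5), 6 * sqrt(2) * pi * (0.1 / 1.5)^2,
               tolerance = 1e-12)
  # t/l that yields rho = 0.5, verified by round trip through the inverse
  tl <- sqrt(0.5 / (6 * sqrt(2) * pi))
  expect_equal(tl, 0.13695, tolerance = 1e-4)
  expect_equal(density_from_strut(tl * 2.7, 2.7), 0.5, tolerance = 1e-12)
  # clipping at full density and diameter convention
  expect_equal(density_from_strut(1, 1), 1)
  expect_equal(density_from_strut(0.2, 1, strut_size_is_diameter = TRUE),
               density_from_strut(0.1, 1))
  expect_error(density_from_strut(0.1, 0), "positive")
  expect_error(density_from_strut(-0.1, 1), "non-negative")
})

test_that("strut_for_density inverts the density relation (bisection oracle)", {
  expect_equal(strut_for_density(0.5, 1.0), bisect_strut(0.5, 1.0),
               tolerance = 1e-10)
  expect_equal(strut_for_density(0.5, 1.0), 0.13695, tolerance = 1e-4)
  # limit rho -> 0+ gives t -> 0
  expect_lt(strut_for_density(1e-12, 1.0), 1e-6)
  expect_error(strut_for_density(0, 1), "rho")
  expect_error(strut_for_density(1.2, 1), "rho")
  # round trips for random (t, l), both directions, 1e-12 relative
  set.seed(11)
  for (i in 1:100) {
    l <- runif(1, 0.5, 3)
    t <- runif(1, 0.001, l * 0.19)  # keep rho below 1
    rho <- density_from_strut(t, l)
    expect_equal(strut_for_density(rho, l), t, tolerance = 1e-12)
    expect_equal(density_from_strut(strut_for_density(rho, l), l), rho,
                 tolerance = 1e-12)
  }
})

test_that("density is increasing in t, decreasing in l, and porosity complements", {
  l <- 1.35
  tt <- seq(0.01, 0.18, length.out = 40)
  rr <- density_from_strut(tt, l)
  expect_true(all(diff(rr) > 0))
  ll <- seq(0.8, 2.5, length.out = 40)
  expect_true(all(diff(density_from_strut(0.1, ll)) < 0))
  for (rho in c(0.1, 0.37, 0.7)) {
    spec <- unit_cell_spec("octet", l = 1.3, rho = rho)
    expect_identical(1 - spec$rho, 1 - rho)  # porosity + density = 1 exactly
  }
})

test_that("unit_cell_spec determines the third parameter from any two", {
  s1 <- unit_cell_spec("octet", l = 1.35, rho = 0.4)
  s2 <- unit_cell_spec("octet", l = 1.35, t = s1$t)
  expect_equal(s2$rho, 0.4, tolerance = 1e-12)
  expect_error(unit_cell_spec("octet", l = 1.35), "supply one")
  expect_error(unit_cell_spec("octet", l = -1, rho = 0.4), "positive")
  expect_error(unit_cell_spec("octet", l = 1, t = 0.2, rho = 0.9),
               "inconsistent")
})

test_that("octet cell has the octahedral core of 6 nodes and 12 struts", {
  cell <- build_cell(unit_cell_spec("octet", l = 1.2, rho = 0.3))
  expect_equal(nrow(cell$nodes), 14)            # 8 corners + 6 face centres
  expect_equal(nrow(cell$struts), 36)
  expect_length(cell$core, 12)
  core_nodes <- unique(as.vector(cell$struts[cell$core, ]))
  expect_length(core_nodes, 6)
  # the core nodes are exactly the face centres
  fc <- cell$nodes[core_nodes, , drop = FALSE]
  expect_true(all(abs(rowSums(abs(fc / 1.2 - 0.5) < 1e-12)) == 2))
})

test_that("cells have no duplicate struts and valid node references", {
  for (ct in c("octet", "bcc", "fcc")) {
    cell <- build_cell(unit_cell_spec(ct, l = 1, rho = 0.3))
    expect_true(all(cell$struts >= 1 & cell$struts <= nrow(cell$nodes)))
    expect_true(all(cell$struts[, 1] != cell$struts[, 2]))
    key <- apply(cbind(pmin(cell$struts[, 1], cell$struts[, 2]),
                       pmax(cell$struts[, 1], cell$struts[, 2])), 1, paste,
                 collapse = "-")
    expect_false(any(duplicated(key)))
  }
  expect_error(unit_cell_spec("simple", l = 1, rho = 0.3))
})

test_that("cell geometry is invariant under 90-degree rotations", {
  cell <- build_cell(unit_cell_spec("octet", l = 2, rho = 0.35))
  ctr <- 1  # rotate about the cell centre (l/2 = 1)
  rot90 <- list(
    x = function(p) cbind(p[, 1], 2 * ctr - p[, 3], p[, 2]),
    y = function(p) cbind(p[, 3], p[, 2], 2 * ctr - p[, 1]),
    z = function(p) cbind(2 * ctr - p[, 2], p[, 1], p[, 3])
  )
  node_key <- function(P) sort(apply(round(P, 9), 1, paste, collapse = ","))
  strut_key <- function(P, S) {
    a <- apply(round(P[S[, 1], , drop = FALSE], 9), 1, paste, collapse = ",")
    b <- apply(round(P[S[, 2], , drop = FALSE], 9), 1, paste, collapse = ",")
    sort(paste(pmin(a, b), pmax(a, b)))
  }
  for (f in rot90) {
    expect_identical(node_key(f(cell$nodes)), node_key(cell$nodes))
    expect_identical(strut_key(f(cell$nodes), cell$struts),
                     strut_key(cell$nodes, cell$struts))
  }
})

test_that("admissible window reflects manufacturing and ingrowth limits", {
  win <- design_window()
  iv <- admissible_window(win, 1.35)
  expect_length(iv, 2)
  expect_gte(iv[1], 0.2)
  expect_lte(iv[2], 0.7)
  expect_lt(iv[1], iv[2])
  # the lower bound is active: the manufacturing constraint bites at 1.35 mm
  expect_gt(iv[1], 0.2)
  # widening pore_max never shrinks the interval
  iv2 <- admissible_window(design_window(pore_max = 1.6), 1.35)
  expect_lte(iv2[1], iv[1] + 1e-12)
  expect_gte(iv2[2], iv[2] - 1e-12)
  # an impossible strut requirement empties the interval
  expect_length(admissible_window(design_window(t_min = 2), 1.35), 0)
  expect_error(admissible_window(win, 3), "l_range")
})

test_that("wireframe export writes consistent node and strut tables", {
  cell <- build_cell(unit_cell_spec("octet", l = 1, rho = 0.3))
  nf <- tempfile(fileext = ".csv"); sf <- tempfile(fileext = ".csv")
  export_wireframe(cell, nf, sf)
  nodes <- read.csv(nf); struts <- read.csv(sf)
  expect_equal(nrow(nodes), 14)
  expect_equal(nrow(struts), 36)
  expect_true(all(struts$n1 %in% nodes$id & struts$n2 %in% nodes$id))
  expect_equal(unique(struts$radius), cell$t)
})
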