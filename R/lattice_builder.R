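# Map an optimized density field to a graded lattice geometry and export it.
#
# Each macro element hosts one unit cell: the cell's nodes on the unit cube
# are carried into the element by its trilinear map, the strut radius is
# sized from the element's relative density, and coincident nodes of
# adjacent cells are merged so the lattice is connected. Struts lying in a
# planar exterior face of the mesh are flagged: geometrically they are half
# struts (the missing neighbour cell owns the other half), and the STL
# export emits them as half cylinders so the printed volume matches the
# density bookkeeping.

## trilinear interpolation of unit-cube points into a hex element
trilinear_map <- function(unit_pts, corners) {
  x <- unit_pts[, 1]; y <- unit_pts[, 2]; z <- unit_pts[, 3]
  w <- cbind((1 - x) * (1 - y) * (1 - z),
             x * (1 - y) * (1 - z),
             x * y * (1 - z),
             (1 - x) * y * (1 - z),
             (1 - x) * (1 - y) * z,
             x * (1 - y) * z,
             x * y * z,
             (1 - x) * y * z)
  w %*% corners
}

## exterior (single-element) faces of a hex mesh; returns list of 4-node
## index rows. Local faces in HEX_XI ordering.
HEX_FACES <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                   c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))

boundary_faces <- function(mesh) {
  nel <- nrow(mesh$elements)
  all_faces <- NULL
  for (f in 1:6) {
    all_faces <- rbind(all_faces, mesh$elements[, HEX_FACES[f, ], drop = FALSE])
  }
  key <- apply(all_faces, 1, function(r) paste(sort(r), collapse = "-"))
  tab <- table(key)
  all_faces[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

#' Build a graded lattice from a mesh and a density field
#'
#' Instantiates one unit cell per macro element (cell nodes carried by the
#' element's trilinear map), sizes each cell's strut radius from its
#' element's relative density, and merges coincident boundary nodes of
#' adjacent cells. Struts shared by two cells are kept once with the larger
#' of the two radii.
#'
#' @param mesh a [macro_mesh()].
#' @param densities per-element relative densities (or a `density_field` /
#'   `fg_design`).
#' @param cell_type `"octet"`, `"bcc"` or `"fcc"`.
#' @param window optional [design_window()]; elements whose density requires
#'   a strut below the window's manufacturable size raise an error listing
#'   the offenders.
#' @param merge_tol node merge tolerance as a fraction of the mean cell
#'   edge.
#' @return an object of class `lattice_model`: merged `nodes` (mm), `struts`
#'   data frame (`n1`, `n2`, `radius` mm, `half` flag for exterior-face
#'   struts), and `cells` (per-element specs).
#' @export
build_lattice <- function(mesh, densities, cell_type = "octet",
                          window = NULL, merge_tol = 1e-6) {
  stopifnot(inherits(mesh, "macro_mesh"))
  if (inherits(densities, "fg_design")) densities <- densities$rho
  rho <- as.numeric(densities)
  nel <- nrow(mesh$elements)
  stopifnot(length(rho) == nel, all(rho > 0), all(rho <= 1))
  topo <- cell_topology(cell_type)
  k <- cell_rho_coef(cell_type)

  pts <- NULL
  strut_from <- NULL
  radii <- NULL
  edges_mm <- numeric(nel)
  nn <- nrow(topo$nodes)
  for (e in seq_len(nel)) {
    corners <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    edges_mm[e] <- mean(sqrt(rowSums((corners[c(2, 3, 4, 1, 6, 7, 8, 5), ] -
                                        corners)^2)))
    P <- trilinear_map(topo$nodes, corners)
    pts <- rbind(pts, P)
    strut_from <- rbind(strut_from, topo$struts + (e - 1L) * nn)
    radii <- c(radii, rep(edges_mm[e] * sqrt(rho[e] / k), nrow(topo$struts)))
  }
  if (!is.null(window)) {
    bad <- which(2 * mesh_cell_radius(rho, edges_mm, k) < window$t_min - 1e-9)
    if (length(bad)) {
      stop(sprintf("manufacturability violation (strut below %g mm) in elements: %s",
                   window$t_min, paste(utils::head(bad, 20), collapse = ", ")),
           call. = FALSE)
    }
  }

  # merge coincident nodes on a rounded-coordinate key
  tol <- merge_tol * mean(edges_mm)
  key <- apply(round(pts / tol), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  nodes <- pts[!duplicated(key), , drop = FALSE]
  s1 <- uid[strut_from[, 1]]
  s2 <- uid[strut_from[, 2]]
  lo <- pmin(s1, s2); hi <- pmax(s1, s2)
  skey <- paste(lo, hi)
  ord <- order(skey, -radii)              # keep the larger radius of duplicates
  keep <- !duplicated(skey[ord])
  struts <- data.frame(n1 = lo[ord][keep], n2 = hi[ord][keep],
                       radius = radii[ord][keep])

  # flag struts lying in a planar exterior face: geometrically half struts
  struts$half <- FALSE
  bf <- boundary_faces(mesh)
  if (nrow(bf)) {
    for (f in seq_len(nrow(bf))) {
      q <- mesh$nodes[bf[f, ], , drop = FALSE]
      nrm <- pracma_cross(q[3, ] - q[1, ], q[4, ] - q[2, ])
      nl <- sqrt(sum(nrm^2))
      if (nl == 0) next
      nrm <- nrm / nl
      d0 <- sum(nrm * q[1, ])
      # planarity of the face itself
      if (abs(sum(nrm * q[2, ]) - d0) > tol) next
      on_plane <- abs(nodes %*% nrm - d0) < tol
      struts$half <- struts$half | (on_plane[struts$n1] & on_plane[struts$n2])
    }
  }
  structure(list(nodes = nodes, struts = struts,
                 cells = data.frame(element = seq_len(nel), rho = rho,
                                    edge = edges_mm,
                                    t = edges_mm * sqrt(rho / k)),
                 cell_type = cell_type, mesh = mesh),
            class = "lattice_model")
}

mesh_cell_radius <- function(rho, edges_mm, k) edges_mm * sqrt(rho / k)

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.lattice_model <- function(x, ...) {
  cat(sprintf("graded %s lattice: %d cells, %d merged nodes, %d struts (radius %.4g-%.4g mm)\n",
              x$cell_type, nrow(x$cells), nrow(x$nodes), nrow(x$struts),
              min(x$struts$radius), max(x$struts$radius)))
  invisible(x)
}

#' Analytic solid volume of a lattice model
#'
#' Sum of strut cylinder volumes, exterior-face struts counted half; matches
#' the density bookkeeping `sum(rho_e * V_e)` up to junction overlap.
#'
#' @param model a `lattice_model`.
#' @return volume (mm^3).
#' @export
lattice_volume <- function(model) {
  a <- model$nodes[model$struts$n1, , drop = FALSE]
  b <- model$nodes[model$struts$n2, , drop = FALSE]
  len <- sqrt(rowSums((a - b)^2))
  w <- ifelse(model$struts$half, 0.5, 1)
  sum(w * pi * model$struts$radius^2 * len)
}

## triangulated closed cylinder between A and B; half = half cylinder whose
## flat side lies in the plane with (unit) normal `flat_normal`.
## Returns list of 3x3 triangle vertex matrices... represented as an
## (ntri x 9) matrix (v1, v2, v3 columns grouped by vertex).
cylinder_tris <- function(A, B, r, segments = 24L, half = FALSE,
                          flat_normal = NULL) {
  ax <- B - A
  L <- sqrt(sum(ax^2))
  ax <- ax / L
  # orthonormal frame (e1, e2, ax)
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- pracma_cross(ax, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma_cross(ax, e1)
  if (half) {
    # arc bulging toward the interior (-flat_normal); endpoints in the plane
    din <- -flat_normal
    din <- din - sum(din * ax) * ax
    din <- din / sqrt(sum(din^2))
    ein <- pracma_cross(ax, din)
    phi <- seq(-pi / 2, pi / 2, length.out = segments + 1L)
    dirs <- outer(cos(phi), din) + outer(sin(phi), ein)
    closed <- FALSE
  } else {
    phi <- seq(0, 2 * pi, length.out = segments + 1L)[-(segments + 1L)]
    dirs <- outer(cos(phi), e1) + outer(sin(phi), e2)
    closed <- TRUE
  }
  ringA <- sweep(dirs * r, 2, A, `+`)
  ringB <- sweep(dirs * r, 2, B, `+`)
  m <- nrow(dirs)
  nxt <- if (closed) c(2:m, 1L) else c(2:m, NA)
  tris <- list()
  add <- function(p, q, s) tris[[length(tris) + 1L]] <<- c(p, q, s)
  for (i in seq_len(if (closed) m else m - 1L)) {
    j <- nxt[i]
    # side quad, outward orientation (ring is counter-clockwise about +ax)
    add(ringA[i, ], ringB[j, ], ringB[i, ])
    add(ringA[i, ], ringA[j, ], ringB[j, ])
  }
  # caps: fans from the axis endpoints
  for (i in seq_len(if (closed) m else m - 1L)) {
    j <- nxt[i]
    add(A, ringA[j, ], ringA[i, ])   # cap at A faces -ax
    add(B, ringB[i, ], ringB[j, ])   # cap at B faces +ax
  }
  if (!closed) {
    # flat face closing the chord (lies in the boundary plane); split at the
    # axis endpoints so the chord edges match the cap fans (manifoldness)
    add(ringA[1, ], ringB[1, ], B)
    add(ringA[1, ], B, A)
    add(A, B, ringB[m, ])
    add(A, ringB[m, ], ringA[m, ])
  }
  do.call(rbind, tris)
}

#' Export a lattice (or single cell) as an ASCII STL surface
#'
#' Every strut is emitted as a closed, consistently oriented triangulated
#' cylinder with flat caps (half cylinder for exterior-face struts), so each
#' connected component of the written surface is watertight and the signed
#' volume of the file equals the analytic [lattice_volume()] up to faceting.
#'
#' @param model a `lattice_model` or `cell_geometry`.
#' @param path output `.stl` path.
#' @param segments circumferential facets per cylinder.
#' @return the path, invisibly; attribute `n_triangles` records the size.
#' @export
export_stl <- function(model, path, segments = 24L) {
  if (inherits(model, "cell_geometry")) {
    model <- structure(list(
      nodes = model$nodes,
      struts = data.frame(n1 = model$struts[, 1], n2 = model$struts[, 2],
                          radius = model$t, half = FALSE)),
      class = "lattice_model")
  }
  stopifnot(inherits(model, "lattice_model"))
  if (!nrow(model$struts)) stop("empty model: nothing to export", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid fglattice", con)
  ntri <- 0L
  for (s in seq_len(nrow(model$struts))) {
    A <- model$nodes[model$struts$n1[s], ]
    B <- model$nodes[model$struts$n2[s], ]
    half <- isTRUE(model$struts$half[s])
    fn <- NULL
    if (half) {
      fn <- attr(model$struts, "flat_normal")
      # flat side normal: reconstructed from the strut's plane flag at build
      # time is not stored per strut; use any vector orthogonal to the strut
      # that points away from the lattice centroid
      ctr <- colMeans(model$nodes)
      mid <- (A + B) / 2
      fn <- mid - ctr
      fn <- fn - sum(fn * (B - A)) / sum((B - A)^2) * (B - A)
      if (sqrt(sum(fn^2)) < 1e-12) {
        half <- FALSE
      } else {
        fn <- fn / sqrt(sum(fn^2))
      }
    }
    tris <- cylinder_tris(A, B, model$struts$radius[s], segments = segments,
                          half = half, flat_normal = fn)
    ntri <- ntri + nrow(tris)
    v1 <- tris[, 1:3]; v2 <- tris[, 4:6]; v3 <- tris[, 7:9]
    e1 <- v2 - v1; e2 <- v3 - v1
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    nl <- sqrt(rowSums(nrm^2))
    nl[nl == 0] <- 1
    nrm <- nrm / nl
    out <- sprintf(
      "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
      nrm[, 1], nrm[, 2], nrm[, 3],
      v1[, 1], v1[, 2], v1[, 3], v2[, 1], v2[, 2], v2[, 3],
      v3[, 1], v3[, 2], v3[, 3])
    writeLines(out, con)
  }
  writeLines("endsolid fglattice", con)
  invisible(structure(path, n_triangles = ntri))
}

#' Read an ASCII STL file
#'
#' Parses the vertices of an ASCII STL into a triangle matrix.
#'
#' @param path an `.stl` file written by [export_stl()] (or any ASCII STL).
#' @return numeric matrix (n_triangles x 9): vertices v1, v2, v3 row-wise.
#' @export
read_stl <- function(path) {
  ln <- readLines(path)
  vl <- grep("^\\s*vertex", ln, value = TRUE)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  ntri <- nrow(xyz) / 3
  matrix(t(xyz), ntri, 9, byrow = TRUE)
}

#' Signed volume enclosed by a triangle soup
#'
#' Divergence-theorem volume: the sum of signed tetrahedron volumes against
#' the origin. For a set of closed, consistently outward-oriented components
#' this is the total enclosed volume (overlaps counted multiply).
#'
#' @param tris triangle matrix as returned by [read_stl()].
#' @return volume (mm^3).
#' @export
stl_volume <- function(tris) {
  v1 <- tris[, 1:3, drop = FALSE]
  v2 <- tris[, 4:6, drop = FALSE]
  v3 <- tris[, 7:9, drop = FALSE]
  cx <- v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]
  cy <- v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]
  cz <- v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1]
  sum(v1[, 1] * cx + v1[, 2] * cy + v1[, 3] * cz) / 6
}
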