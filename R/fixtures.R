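# Deterministic synthetic fixtures: a three-tissue CT-like phantom, a
# cantilever optimization benchmark, and a hemispherical-shell "cage"
# benchmark with flange supports and the hip-joint resultant load. All
# generators are pure functions of their arguments and seed.

#' Hip-joint load model
#'
#' The design load is 250% of body weight; for the 80 kg reference subject
#' this is `2.5 * 80 * 9.81 = 1962 N`. The printed in-plane components of the
#' resultant are `(-408, 1919, 0) N`.
#'
#' @param body_mass_kg subject mass (kg).
#' @param factor multiple of body weight carried by the joint.
#' @param g gravitational acceleration (m/s^2).
#' @return resultant magnitude (N).
#' @export
hip_load_magnitude <- function(body_mass_kg = 80, factor = 2.5, g = 9.81) {
  factor * body_mass_kg * g
}

#' @rdname hip_load_magnitude
#' @return `hip_load_components()`: the default resultant force vector (N).
#' @export
hip_load_components <- function() {
  c(x = -408, y = 1919, z = 0)
}

#' Synthetic three-tissue CT phantom
#'
#' Concentric spherical regions emulating a bone cross-section: a marrow
#' core, a cancellous shell, and cortical bone filling the rest of the box,
#' with mean HU levels covering all three branches of the bone-material law.
#' Optional Gaussian HU noise; the generative region labels are attached as
#' ground truth.
#'
#' @param dims voxel grid dimensions (length 3).
#' @param spacing voxel size (mm), length 3.
#' @param radii_frac marrow and cancellous radii as fractions of the
#'   half-extent.
#' @param hu_levels named HU means for `marrow`, `cancellous`, `cortical`.
#' @param noise_sd HU noise standard deviation.
#' @param seed RNG seed; two calls with the same spec are identical.
#' @return a [voxel_volume()] with attributes `labels` (factor array of
#'   ground-truth regions) and `fractions` (generative volume fractions).
#' @export
make_phantom <- function(dims = c(48, 48, 48), spacing = c(1, 1, 1),
                         radii_frac = c(marrow = 0.45, cancellous = 0.8),
                         hu_levels = c(marrow = 50, cancellous = 600,
                                       cortical = 1800),
                         noise_sd = 30, seed = 1L) {
  stopifnot(length(dims) == 3L, all(dims >= 4), all(spacing > 0),
            radii_frac[1] < radii_frac[2], radii_frac[2] <= 1)
  cx <- (seq_len(dims[1]) - 0.5) * spacing[1]
  cy <- (seq_len(dims[2]) - 0.5) * spacing[2]
  cz <- (seq_len(dims[3]) - 0.5) * spacing[3]
  ctr <- c(max(cx) + spacing[1] / 2, max(cy) + spacing[2] / 2,
           max(cz) + spacing[3] / 2) / 2
  half <- min(ctr)
  R <- sqrt(outer(outer((cx - ctr[1])^2, (cy - ctr[2])^2, `+`),
                  (cz - ctr[3])^2, `+`))
  lab <- array("cortical", dim = dims)
  lab[R <= radii_frac[2] * half] <- "cancellous"
  lab[R <= radii_frac[1] * half] <- "marrow"
  hu <- array(hu_levels[lab], dim = dims)
  if (noise_sd > 0) {
    set.seed(seed)
    hu <- hu + array(stats::rnorm(prod(dims), sd = noise_sd), dim = dims)
  }
  vol <- voxel_volume(hu, spacing = spacing,
                      origin = spacing / 2)  # centre of voxel (1,1,1)
  attr(vol, "labels") <- array(factor(lab, levels = c("marrow", "cancellous",
                                                      "cortical")), dim = dims)
  attr(vol, "fractions") <- prop.table(table(lab))
  vol
}

## regular grid of nx x ny x nz cube elements with edge h; node index
## helper shared by the cantilever and the phantom-matched meshes
grid_mesh_nodes <- function(nx, ny, nz, h, origin = c(0, 0, 0)) {
  gx <- 0:nx * h + origin[1]
  gy <- 0:ny * h + origin[2]
  gz <- 0:nz * h + origin[3]
  nodes <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  nid <- function(i, j, k) 1L + i + j * (nx + 1L) + k * (nx + 1L) * (ny + 1L)
  el <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  elements <- cbind(
    nid(el$i,     el$j,     el$k),
    nid(el$i + 1, el$j,     el$k),
    nid(el$i + 1, el$j + 1, el$k),
    nid(el$i,     el$j + 1, el$k),
    nid(el$i,     el$j,     el$k + 1),
    nid(el$i + 1, el$j,     el$k + 1),
    nid(el$i + 1, el$j + 1, el$k + 1),
    nid(el$i,     el$j + 1, el$k + 1)
  )
  list(nodes = nodes, elements = elements, nid = nid)
}

#' Cantilever benchmark mesh
#'
#' A regular grid of cube elements with the `x = 0` face fully fixed and a
#' total load distributed over the far bottom edge (`x = L`, `y = 0`),
#' pointing in `-y` by default.
#'
#' @param nx,ny,nz element counts (x is the beam axis).
#' @param h element edge (mm).
#' @param total_load load resultant (N), length 3, shared equally by the
#'   edge nodes.
#' @param load_at `"edge"` (default) or `"center"` (single node at the
#'   centre of the far face, for symmetry checks).
#' @return a [macro_mesh()].
#' @export
make_cantilever <- function(nx = 20, ny = 10, nz = 4, h = 1,
                            total_load = c(0, -100, 0),
                            load_at = c("edge", "center")) {
  load_at <- match.arg(load_at)
  stopifnot(nx >= 1, ny >= 1, nz >= 1)
  g <- grid_mesh_nodes(nx, ny, nz, h)
  fixed_nodes <- which(abs(g$nodes[, 1]) < 1e-12)
  fixed <- data.frame(node = rep(fixed_nodes, each = 3L), dir = rep(1:3, length(fixed_nodes)))
  if (load_at == "edge") {
    ln <- which(abs(g$nodes[, 1] - nx * h) < 1e-12 & abs(g$nodes[, 2]) < 1e-12)
  } else {
    ln <- which(abs(g$nodes[, 1] - nx * h) < 1e-12 &
                  abs(g$nodes[, 2] - ny * h / 2) < 1e-9 &
                  abs(g$nodes[, 3] - nz * h / 2) < 1e-9)
    if (!length(ln)) stop("no centre node: use even ny, nz", call. = FALSE)
  }
  loads <- do.call(rbind, lapply(1:3, function(d) {
    if (total_load[d] == 0) return(NULL)
    data.frame(node = ln, dir = d, value = total_load[d] / length(ln))
  }))
  if (is.null(loads)) loads <- data.frame(node = integer(), dir = integer(),
                                          value = numeric())
  macro_mesh(g$nodes, g$elements, fixed, loads)
}

#' Hemispherical-shell cage benchmark
#'
#' A spherical shell (one hex element through the thickness) spanning polar
#' angles from a small socket opening down past the equator on two flange
#' sectors. The flange end rings are fully fixed (ischial/iliac analogs) and
#' the hip-joint resultant is distributed over the inner socket nodes
#' proportionally to tributary area.
#'
#' With `bone_layer = TRUE` a second radial layer of elements is bonded to
#' the cage's outer surface and flagged as bone (cancellous modulus from the
#' CT mapping at 600 HU): cage and bone then carry the joint load in
#' parallel, which is what makes stress shielding observable — a stiffer
#' cage attracts a larger load share. The cage element indices are identical
#' with and without the bone layer, so a density field optimized on the bare
#' cage can be evaluated on the assembly.
#'
#' @param refinement mesh refinement factor (>= 1).
#' @param radius inner shell radius (mm).
#' @param thickness shell thickness (mm).
#' @param resultant applied force resultant (N), defaults to the hip-joint
#'   components.
#' @param bone_layer bond a bone-analog element layer to the cage back.
#' @return a list with the [macro_mesh()] (`mesh`), the loaded node set
#'   (`socket_nodes`), the fixed node set (`flange_nodes`), an ordered
#'   interface node path from the distal flange end to the socket rim
#'   (`interface_path`), and (with `bone_layer`) the indices
#'   `bone_elements` and the bone material constants `bone_material`.
#' @export
make_cage_benchmark <- function(refinement = 1, radius = 25, thickness = 3,
                                resultant = hip_load_components(),
                                bone_layer = FALSE) {
  stopifnot(refinement >= 1)
  ntheta <- 6L * refinement       # polar divisions of the dome
  nphi <- 16L * refinement        # azimuthal divisions
  nflange <- 3L * refinement      # polar divisions of each flange
  th0 <- 0.15 * pi                # socket opening (pole left open)
  th1 <- 0.5 * pi                 # dome rim at the equator
  th2 <- 0.75 * pi                # flange ends
  dth <- (th1 - th0) / ntheta
  # flange sectors (azimuthal index windows)
  phis <- (0:(nphi - 1L)) * 2 * pi / nphi
  width <- max(2L, round(nphi / 8))
  f1 <- seq_len(width) + round(nphi / 4) - 1L
  f2 <- seq_len(width) + round(3 * nphi / 4) - 1L
  flange_cols <- sort(unique(c(f1, f2) %% nphi + 1L))

  # polar rows: dome rows for all phi; flange rows only for flange sectors
  th_dome <- seq(th0, th1, length.out = ntheta + 1L)
  th_flange <- seq(th1 + (th2 - th1) / nflange, th2, length.out = nflange)
  nodes <- NULL
  id <- new.env()
  key <- function(i, j, r) paste(i, j, r)
  get_node <- function(th_i, j, rlayer) {
    k <- key(th_i, j, rlayer)
    if (!is.null(id[[k]])) return(id[[k]])
    th <- if (th_i <= ntheta + 1L) th_dome[th_i] else th_flange[th_i - ntheta - 1L]
    r <- radius + (rlayer - 1L) * thickness
    ph <- phis[j]
    nodes <<- rbind(nodes, c(r * sin(th) * cos(ph),
                             r * cos(th),
                             r * sin(th) * sin(ph)))
    id[[k]] <- nrow(nodes)
    id[[k]]
  }
  elements <- NULL
  add_ring <- function(th_i, cols, layer = 1L) {
    for (j in cols) {
      jn <- j %% nphi + 1L
      n1 <- get_node(th_i,     j,  layer);      n2 <- get_node(th_i,     jn, layer)
      n3 <- get_node(th_i + 1L, jn, layer);     n4 <- get_node(th_i + 1L, j,  layer)
      n5 <- get_node(th_i,     j,  layer + 1L); n6 <- get_node(th_i,     jn, layer + 1L)
      n7 <- get_node(th_i + 1L, jn, layer + 1L); n8 <- get_node(th_i + 1L, j, layer + 1L)
      elements <<- rbind(elements, c(n1, n2, n3, n4, n5, n6, n7, n8))
    }
  }
  for (i in seq_len(ntheta)) add_ring(i, seq_len(nphi))
  for (i in seq_len(nflange)) add_ring(ntheta + i, flange_cols)
  n_cage <- nrow(elements)
  if (bone_layer) {
    for (i in seq_len(ntheta)) add_ring(i, seq_len(nphi), layer = 2L)
    for (i in seq_len(nflange)) add_ring(ntheta + i, flange_cols, layer = 2L)
  }
  bone_elements <- if (bone_layer) (n_cage + 1L):nrow(elements) else integer(0)

  mesh_nodes <- nodes
  # fixed: all radial layers of the flange end ring
  layers_fixed <- if (bone_layer) 1:3 else 1:2
  flange_end <- unlist(lapply(flange_cols, function(j) {
    jn <- j %% nphi + 1L
    unlist(lapply(layers_fixed, function(r) {
      c(id[[key(ntheta + nflange + 1L, j, r)]],
        id[[key(ntheta + nflange + 1L, jn, r)]])
    }))
  }))
  flange_end <- sort(unique(flange_end))
  fixed <- data.frame(node = rep(flange_end, each = 3L),
                      dir = rep(1:3, length(flange_end)))

  # socket: inner-layer nodes of the top two dome rings, loaded by tributary
  # area of the adjacent inner faces
  sock_rows <- 1:2
  socket <- unlist(lapply(sock_rows, function(i) {
    vapply(seq_len(nphi), function(j) id[[key(i, j, 1L)]], integer(1))
  }))
  socket <- sort(unique(socket))
  w <- numeric(length(socket))
  for (i in seq_len(ntheta)) {
    if (i > max(sock_rows)) break
    for (j in seq_len(nphi)) {
      jn <- j %% nphi + 1L
      quad <- c(id[[key(i, j, 1L)]], id[[key(i, jn, 1L)]],
                id[[key(i + 1L, jn, 1L)]], id[[key(i + 1L, j, 1L)]])
      q <- mesh_nodes[quad, , drop = FALSE]
      area <- 0.5 * sqrt(sum(pracma_cross(q[3, ] - q[1, ], q[4, ] - q[2, ])^2))
      hit <- match(quad, socket)
      ok <- !is.na(hit)
      w[hit[ok]] <- w[hit[ok]] + area / 4
    }
  }
  w <- w / sum(w)
  loads <- do.call(rbind, lapply(1:3, function(d) {
    if (resultant[d] == 0) return(NULL)
    data.frame(node = socket, dir = d, value = resultant[d] * w)
  }))
  mesh <- macro_mesh(mesh_nodes, elements, fixed, loads)

  # interface path: outer-layer nodes up one meridian of a flange sector,
  # from the distal flange end to the socket rim
  jpath <- flange_cols[1]
  path <- vapply((ntheta + nflange + 1L):1L, function(i) {
    v <- id[[key(i, jpath, 2L)]]
    if (is.null(v)) NA_integer_ else v
  }, integer(1))
  path <- path[!is.na(path)]
  list(mesh = mesh, socket_nodes = socket, flange_nodes = flange_end,
       interface_path = path, bone_elements = bone_elements,
       bone_material = list(E = hu_to_modulus(600), nu = 0.3))
}
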