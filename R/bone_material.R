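# CT Hounsfield-value to bone-material mapping.
#
# Bone tissue density is linear in the CT gray value (HU), with cortical bone
# assumed at 2.0 g/cm^3 for HU = 1500. Young's modulus follows a three-branch
# piecewise law: cortical bone (HU >= 1500) at 17000 MPa, bone marrow
# (HU <= 100) at 20 MPa, and cancellous bone in between with the power law
# 2713 * rho0^2.36 MPa. The outer branches win at the shared breakpoints.
# The law is discontinuous at HU = 1500 (2713 * 2^2.36 != 17000); it is
# implemented exactly as printed.

#' Bone tissue density from a CT Hounsfield value
#'
#' `rho0 = (HU / 1500) * 2.0` g/cm^3, floored at zero.
#'
#' @param hu Hounsfield values (vectorized).
#' @return tissue density (g/cm^3).
#' @export
hu_to_density <- function(hu) {
  stopifnot(all(is.finite(hu)))
  pmax(hu / 1500 * 2.0, 0)
}

#' Young's modulus of bone from a CT Hounsfield value
#'
#' Piecewise: 17000 MPa for `hu >= 1500` (cortical), 20 MPa for `hu <= 100`
#' (marrow), otherwise `2713 * rho0^2.36` MPa (cancellous) with `rho0` from
#' [hu_to_density()].
#'
#' @param hu Hounsfield values (vectorized).
#' @return Young's modulus (MPa).
#' @export
hu_to_modulus <- function(hu) {
  stopifnot(all(is.finite(hu)))
  E <- 2713 * hu_to_density(hu)^2.36
  E[hu <= 100] <- 20
  E[hu >= 1500] <- 17000
  E
}

#' Tissue class of a CT Hounsfield value
#'
#' @param hu Hounsfield values.
#' @return factor with levels `marrow`, `cancellous`, `cortical`.
#' @export
hu_tissue <- function(hu) {
  out <- ifelse(hu >= 1500, "cortical", ifelse(hu <= 100, "marrow", "cancellous"))
  factor(out, levels = c("marrow", "cancellous", "cortical"))
}

#' A scalar voxel volume (CT-like)
#'
#' @param values 3D numeric array of HU values.
#' @param spacing voxel edge lengths (mm), length 3, positive.
#' @param origin position of the centre of voxel (1,1,1) (mm).
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            all(is.finite(values)),
            length(spacing) == 3L, all(spacing > 0),
            length(origin) == 3L, all(is.finite(origin)))
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("voxel volume: %d x %d x %d, spacing (%g, %g, %g) mm, HU in [%g, %g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Assign heterogeneous bone material to macro-mesh elements
#'
#' Each element receives the mean HU of the voxels whose centres fall inside
#' the element's bounding box (falling back to the voxel nearest the element
#' centroid when the box captures none), then the piecewise modulus law and
#' tissue label are applied. Poisson's ratio is 0.3 throughout.
#'
#' @param vol a [voxel_volume()].
#' @param mesh a `macro_mesh` whose bounding box lies inside the volume.
#' @return an object of class `material_field`: data frame with columns
#'   `element`, `hu`, `E` (MPa), `nu`, `tissue`.
#' @export
map_volume <- function(vol, mesh) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(mesh, "macro_mesh"))
  d <- dim(vol$values)
  # voxel-centre coordinate vectors
  cx <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  cy <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  cz <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  ext_lo <- c(cx[1], cy[1], cz[1]) - vol$spacing / 2
  ext_hi <- c(cx[d[1]], cy[d[2]], cz[d[3]]) + vol$spacing / 2

  nel <- nrow(mesh$elements)
  hu <- numeric(nel)
  out_ids <- integer(0)
  for (e in seq_len(nel)) {
    xyz <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    lo <- apply(xyz, 2, min)
    hi <- apply(xyz, 2, max)
    if (any(lo < ext_lo - 1e-9) || any(hi > ext_hi + 1e-9)) {
      out_ids <- c(out_ids, e)
      next
    }
    ii <- which(cx >= lo[1] & cx <= hi[1])
    jj <- which(cy >= lo[2] & cy <= hi[2])
    kk <- which(cz >= lo[3] & cz <= hi[3])
    if (length(ii) && length(jj) && length(kk)) {
      hu[e] <- mean(vol$values[ii, jj, kk])
    } else {
      ctr <- colMeans(xyz)
      hu[e] <- vol$values[which.min(abs(cx - ctr[1])),
                          which.min(abs(cy - ctr[2])),
                          which.min(abs(cz - ctr[3]))]
    }
  }
  if (length(out_ids)) {
    stop(sprintf("elements outside the volume extent: %s",
                 paste(utils::head(out_ids, 20), collapse = ", ")),
         call. = FALSE)
  }
  structure(data.frame(element = seq_len(nel), hu = hu,
                       E = hu_to_modulus(hu), nu = 0.3,
                       tissue = hu_tissue(hu)),
            class = c("material_field", "data.frame"))
}

#' Write a material field as per-element CSV
#'
#' @param field a `material_field`.
#' @param path output CSV path.
#' @export
write_material_csv <- function(field, path) {
  utils::write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}

#' Write / read a voxel volume as raw binary plus JSON header
#'
#' The header (`<prefix>.json`) records dimensions, spacing, origin and the
#' value type; the values are stored as little-endian float32 in
#' `<prefix>.raw`, x fastest.
#'
#' @param vol a [voxel_volume()].
#' @param prefix path prefix (without extension).
#' @return the prefix, invisibly; `read_volume()` returns a `voxel_volume`.
#' @export
write_volume <- function(vol, prefix) {
  stopifnot(inherits(vol, "voxel_volume"))
  hdr <- list(dims = dim(vol$values), spacing = vol$spacing,
              origin = vol$origin, dtype = "float32", endian = "little")
  jsonlite::write_json(hdr, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(prefix, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(vol$values), con, size = 4, endian = "little")
  invisible(prefix)
}

#' @rdname write_volume
#' @export
read_volume <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- prod(hdr$dims)
  con <- file(paste0(prefix, ".raw"), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  voxel_volume(array(vals, dim = hdr$dims), spacing = hdr$spacing,
               origin = hdr$origin)
}
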