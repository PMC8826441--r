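# Polynomial density-property surrogates fitted to homogenization sweeps.
#
# The effective modulus ratio E/Es is fitted with a quadratic in the relative
# density rho, the effective Poisson ratio nu/nus with a cubic. Evaluating
# the surrogate gives the isotropic (E, nu) pair used for the macro-scale
# element stiffness.

#' Fit a density-property surrogate to homogenized lattice data
#'
#' Least-squares fits of a quadratic polynomial to the relative modulus
#' `E/Es` and a cubic to the relative Poisson ratio `nu/nus`, as functions of
#' relative density. Fit quality is reported as the coefficient of
#' determination `R^2 = 1 - SS_res/SS_tot` for each fit.
#'
#' @param sweep either a [density_sweep()] data frame (relative properties
#'   are derived from columns `E1` and `nu12` and the sweep's `Es`, `nus`
#'   attributes) or a data frame with columns `rho`, `E_rel`, `nu_rel`.
#' @param Es,nus solid constants (MPa, -); taken from the sweep attributes
#'   when present.
#' @return an object of class `lattice_surrogate`: coefficients `e_coeffs`
#'   `(a2, a1, a0)` of `E/Es`, `nu_coeffs` `(b3, b2, b1, b0)` of `nu/nus`,
#'   `r2_E`, `r2_nu`, the fitted density interval `rho_domain`, and the solid
#'   constants.
#' @export
#' @examples
#' pts <- data.frame(rho = seq(0.1, 0.8, 0.1))
#' pts$E_rel <- 1.23 * pts$rho^2 - 0.2411 * pts$rho + 0.03213
#' pts$nu_rel <- 0.7165 * pts$rho^3 - 0.7995 * pts$rho^2 - 0.05101 * pts$rho + 1.134
#' fit_surrogate(pts)
fit_surrogate <- function(sweep, Es = NULL, nus = NULL) {
  if (all(c("E_rel", "nu_rel") %in% names(sweep))) {
    rho <- sweep$rho
    e_rel <- sweep$E_rel
    nu_rel <- sweep$nu_rel
    if (is.null(Es)) Es <- attr(sweep, "Es") %||% 110000
    if (is.null(nus)) nus <- attr(sweep, "nus") %||% 0.3
  } else {
    if (is.null(Es)) Es <- attr(sweep, "Es")
    if (is.null(nus)) nus <- attr(sweep, "nus")
    if (is.null(Es) || is.null(nus)) {
      stop("`Es` and `nus` are required when the sweep carries no attributes",
           call. = FALSE)
    }
    rho <- sweep$rho
    e_rel <- sweep$E1 / Es
    nu_rel <- sweep$nu12 / nus
  }
  if (length(unique(rho)) < 4L) {
    stop("underdetermined fit: need at least 4 distinct densities", call. = FALSE)
  }
  fe <- stats::lm(e_rel ~ rho + I(rho^2))
  fn <- stats::lm(nu_rel ~ rho + I(rho^2) + I(rho^3))
  r2 <- function(fit, y) {
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((y - mean(y))^2)
    1 - ss_res / ss_tot
  }
  ce <- stats::coef(fe)   # (a0, a1, a2)
  cn <- stats::coef(fn)   # (b0, b1, b2, b3)
  structure(list(
    e_coeffs = c(a2 = unname(ce[3]), a1 = unname(ce[2]), a0 = unname(ce[1])),
    nu_coeffs = c(b3 = unname(cn[4]), b2 = unname(cn[3]),
                  b1 = unname(cn[2]), b0 = unname(cn[1])),
    r2_E = r2(fe, e_rel), r2_nu = r2(fn, nu_rel),
    rho_domain = range(rho), Es = Es, nus = nus
  ), class = "lattice_surrogate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Surrogate from known polynomial coefficients
#'
#' Builds a `lattice_surrogate` directly from coefficient vectors, e.g. the
#' published octet-truss fits `e_coeffs = c(1.23, -0.2411, 0.03213)` and
#' `nu_coeffs = c(0.7165, -0.7995, -0.05101, 1.134)`.
#'
#' @param e_coeffs `(a2, a1, a0)` of `E/Es = a2 rho^2 + a1 rho + a0`.
#' @param nu_coeffs `(b3, b2, b1, b0)` of
#'   `nu/nus = b3 rho^3 + b2 rho^2 + b1 rho + b0`.
#' @param Es,nus solid constants (MPa, -).
#' @param rho_domain density interval on which the polynomials are trusted.
#' @return a `lattice_surrogate`.
#' @export
surrogate_from_coefs <- function(e_coeffs, nu_coeffs, Es = 110000, nus = 0.3,
                                 rho_domain = c(0.1, 0.8)) {
  stopifnot(length(e_coeffs) == 3L, length(nu_coeffs) == 4L)
  structure(list(
    e_coeffs = stats::setNames(as.numeric(e_coeffs), c("a2", "a1", "a0")),
    nu_coeffs = stats::setNames(as.numeric(nu_coeffs), c("b3", "b2", "b1", "b0")),
    r2_E = NA_real_, r2_nu = NA_real_,
    rho_domain = rho_domain, Es = Es, nus = nus
  ), class = "lattice_surrogate")
}

#' Evaluate a surrogate at given densities
#'
#' Returns the effective Young's modulus (MPa) and Poisson ratio. Densities
#' outside the fitted domain clamp to it with a warning (the polynomials are
#' unsafe extrapolants), or raise an error with `clamp = FALSE`.
#'
#' @param object a `lattice_surrogate`.
#' @param rho relative densities.
#' @param clamp clamp out-of-domain densities to `rho_domain`.
#' @param ... unused.
#' @return a list with numeric vectors `E` (MPa) and `nu`.
#' @export
predict.lattice_surrogate <- function(object, rho, clamp = TRUE, ...) {
  out <- range(object$rho_domain)
  bad <- rho < out[1] - 1e-12 | rho > out[2] + 1e-12
  if (any(bad)) {
    if (!clamp) {
      stop(sprintf("density outside surrogate domain [%g, %g]", out[1], out[2]),
           call. = FALSE)
    }
    warning(sprintf("%d densities clamped to the surrogate domain [%g, %g]",
                    sum(bad), out[1], out[2]), call. = FALSE)
    rho <- pmin(pmax(rho, out[1]), out[2])
  }
  ec <- object$e_coeffs
  nc <- object$nu_coeffs
  e_rel <- ec[["a2"]] * rho^2 + ec[["a1"]] * rho + ec[["a0"]]
  nu_rel <- nc[["b3"]] * rho^3 + nc[["b2"]] * rho^2 + nc[["b1"]] * rho + nc[["b0"]]
  list(E = e_rel * object$Es, nu = nu_rel * object$nus)
}

#' @export
coef.lattice_surrogate <- function(object, ...) {
  list(e_coeffs = object$e_coeffs, nu_coeffs = object$nu_coeffs)
}

#' @export
print.lattice_surrogate <- function(x, ...) {
  e <- x$e_coeffs; n <- x$nu_coeffs
  cat("lattice density-property surrogate\n")
  cat(sprintf("  E/Es  = %.5g rho^2 + %.5g rho + %.5g   (R^2 = %s)\n",
              e[["a2"]], e[["a1"]], e[["a0"]],
              ifelse(is.na(x$r2_E), "-", sprintf("%.6f", x$r2_E))))
  cat(sprintf("  nu/nus = %.5g rho^3 + %.5g rho^2 + %.5g rho + %.5g   (R^2 = %s)\n",
              n[["b3"]], n[["b2"]], n[["b1"]], n[["b0"]],
              ifelse(is.na(x$r2_nu), "-", sprintf("%.6f", x$r2_nu))))
  cat(sprintf("  domain rho in [%g, %g]; Es = %g MPa, nus = %g\n",
              x$rho_domain[1], x$rho_domain[2], x$Es, x$nus))
  invisible(x)
}

#' Serialize / restore a surrogate as JSON
#'
#' @param m a `lattice_surrogate`.
#' @param path JSON file path.
#' @return `write_surrogate_json()` returns the path invisibly;
#'   `read_surrogate_json()` returns the restored `lattice_surrogate`.
#' @export
write_surrogate_json <- function(m, path) {
  stopifnot(inherits(m, "lattice_surrogate"))
  jsonlite::write_json(unclass(m), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surrogate_json
#' @export
read_surrogate_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  surr <- surrogate_from_coefs(x$e_coeffs, x$nu_coeffs, Es = x$Es, nus = x$nus,
                               rho_domain = x$rho_domain)
  surr$r2_E <- x$r2_E %||% NA_real_
  surr$r2_nu <- x$r2_nu %||% NA_real_
  surr
}
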