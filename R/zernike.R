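#' Zernike polynomial machinery
#'
#' Zernike polynomials are the standard orthogonal basis on the unit disk
#' used in ophthalmic optics to describe corneal surfaces and maps as a
#' function of radius and meridian. This package uses the OSA/ANSI
#' single-index ordering `j = (n (n + 2) + m) / 2` (radial order `n`,
#' azimuthal frequency `m`) with orthonormal (unit-RMS over the unit disk)
#' normalization, so the RMS contribution of any subset of terms is the
#' root-sum-square of its coefficients. Through order 6 there are 28 terms.
#'
#' @name zernike
NULL

# OSA/ANSI (n, m) pairs for single indices 0 .. n_terms-1
zernike_nm <- function(order_max) {
  nm <- do.call(rbind, lapply(0:order_max, function(n) {
    cbind(n = n, m = seq(-n, n, by = 2))
  }))
  nm[order((nm[, "n"] * (nm[, "n"] + 2) + nm[, "m"]) / 2), , drop = FALSE]
}

#' Number of Zernike terms through a radial order
#'
#' @param order_max Maximum radial order `n`.
#' @return `(order_max + 1) * (order_max + 2) / 2`.
#' @examples
#' zernike_n_terms(6)  # 28
#' @export
zernike_n_terms <- function(order_max) {
  (order_max + 1) * (order_max + 2) / 2
}

# radial polynomial R_n^|m|(rho)
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  out <- numeric(length(rho))
  for (k in 0:((n - m) / 2)) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k)) *
      rho^(n - 2 * k)
  }
  out
}

#' Evaluate the Zernike basis at points in the unit disk
#'
#' @param order_max Maximum radial order (>= 0).
#' @param points Two-column matrix or data frame of `(x, y)` coordinates with
#'   radius at most 1 (a small numerical tolerance is allowed).
#' @return Numeric matrix `[points x terms]`; columns are ordered by the
#'   OSA/ANSI single index and named `Z00`, `Z01`, ...
#' @export
zernike_basis <- function(order_max, points) {
  if (order_max < 0) stop_kc("`order_max` must be non-negative.")
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  x <- points[, 1]; y <- points[, 2]
  rho <- sqrt(x^2 + y^2)
  if (any(rho > 1 + 1e-9)) {
    stop_kc("all points must lie inside the unit disk (radius <= 1).")
  }
  rho <- pmin(rho, 1)
  theta <- atan2(y, x)
  nm <- zernike_nm(order_max)
  B <- matrix(0, nrow = length(rho), ncol = nrow(nm))
  for (j in seq_len(nrow(nm))) {
    n <- nm[j, "n"]; m <- nm[j, "m"]
    norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
    ang <- if (m > 0) cos(m * theta) else if (m < 0) sin(-m * theta) else 1
    B[, j] <- norm * zernike_radial(n, m, rho) * ang
  }
  colnames(B) <- sprintf("Z%02d", seq_len(nrow(nm)) - 1)
  B
}

#' Fit Zernike coefficients to a corneal map
#'
#' Least-squares projection of the valid pixels inside a centred circular
#' pupil onto the Zernike basis, with pixel coordinates normalized to the
#' unit disk by the pupil radius. The solution is computed by QR
#' decomposition; a rank-deficient design (fewer valid pixels than terms, or
#' degenerate geometry) is an error rather than a silent pseudo-solution.
#'
#' @param map A `corneal_map`.
#' @param order_max Maximum radial order (default 6, i.e. 28 terms).
#' @param pupil_diameter_mm Fitting pupil diameter in mm (default 8).
#' @return An object of class `zernike_fit`: coefficients (named by single
#'   index), `order_max`, `pupil_radius_mm`, `units` and `fit_rmse` (RMS
#'   residual over the fitted pixels, in map units).
#' @export
fit_zernike <- function(map, order_max = 6, pupil_diameter_mm = 8) {
  stopifnot(inherits(map, "corneal_map"))
  rad <- pupil_diameter_mm / 2
  ax <- map_axes(map)
  X <- matrix(rep(ax$x, each = length(ax$y)), nrow = length(ax$y))
  Y <- matrix(rep(ax$y, times = length(ax$x)), nrow = length(ax$y))
  sel <- map$mask & (X^2 + Y^2) <= rad^2 + 1e-12
  n_terms <- zernike_n_terms(order_max)
  if (sum(sel) < n_terms) {
    stop_kc(sprintf("only %d valid pixels inside the %.1f mm pupil; need at least %d.",
                    sum(sel), pupil_diameter_mm, n_terms))
  }
  pts <- cbind(X[sel] / rad, Y[sel] / rad)
  B <- zernike_basis(order_max, pts)
  qrB <- qr(B)
  if (qrB$rank < n_terms) {
    stop_kc("rank-deficient Zernike design matrix; refusing a pseudo-solution.")
  }
  z <- map$values[sel]
  coef <- qr.coef(qrB, z)
  resid <- z - as.vector(B %*% coef)
  structure(list(coeffs = coef, order_max = order_max,
                 pupil_radius_mm = rad, units = map$units,
                 fit_rmse = sqrt(mean(resid^2))),
            class = "zernike_fit")
}

#' @export
print.zernike_fit <- function(x, ...) {
  cat(sprintf("<zernike_fit> order %d (%d terms), pupil radius %.1f mm, RMSE %.3g %s\n",
              x$order_max, length(x$coeffs), x$pupil_radius_mm, x$fit_rmse, x$units))
  invisible(x)
}

#' Evaluate a fitted Zernike expansion at unit-disk points
#'
#' @param fit A `zernike_fit` (or a bare named coefficient vector with
#'   `order_max` supplied).
#' @param points Two-column `(x, y)` matrix in the unit disk.
#' @param order_max Required when `fit` is a bare vector.
#' @return Numeric vector of reconstructed values.
#' @export
zernike_eval <- function(fit, points, order_max = NULL) {
  if (inherits(fit, "zernike_fit")) {
    coef <- fit$coeffs
    order_max <- fit$order_max
  } else {
    coef <- fit
    if (is.null(order_max)) stop_kc("`order_max` required for a bare coefficient vector.")
  }
  as.vector(zernike_basis(order_max, points) %*% coef)
}

#' Tidy a Zernike fit
#'
#' @param x A `zernike_fit`.
#' @param ... Unused.
#' @return A tibble with one row per term: single index `j`, radial order
#'   `n`, azimuthal frequency `m`, and the coefficient `estimate`.
#' @export
tidy.zernike_fit <- function(x, ...) {
  nm <- zernike_nm(x$order_max)
  tibble::tibble(term = names(x$coeffs), j = seq_len(nrow(nm)) - 1L,
                 n = as.integer(nm[, "n"]), m = as.integer(nm[, "m"]),
                 estimate = unname(x$coeffs))
}

#' Standard aberration summaries of a Zernike expansion
#'
#' Reduces an order-6 expansion to the five summary statistics conventional
#' in corneal wavefront reporting. With unit-RMS normalization the RMS of a
#' term group is the root-sum-square of its coefficients:
#' low-order RMS (orders 1-2, piston excluded), high-order RMS (orders 3-6),
#' coma RMS (the two third-order coma terms), defocus (the `n=2, m=0`
#' coefficient) and primary spherical aberration (`n=4, m=0`).
#'
#' @param fit A `zernike_fit` of order at least 4.
#' @param prefix Optional string prepended to the summary names.
#' @return Named numeric vector `LORMS`, `HORMS`, `ComaRMS`, `Defocus`, `SA`.
#' @export
zernike_rms_summaries <- function(fit, prefix = "") {
  stopifnot(inherits(fit, "zernike_fit"))
  if (fit$order_max < 4) stop_kc("summaries need a fit of order >= 4.")
  nm <- zernike_nm(fit$order_max)
  co <- fit$coeffs
  n <- nm[, "n"]; m <- nm[, "m"]
  out <- c(
    LORMS = sqrt(sum(co[n %in% 1:2]^2)),
    HORMS = sqrt(sum(co[n >= 3]^2)),
    ComaRMS = sqrt(sum(co[n == 3 & abs(m) == 1]^2)),
    Defocus = unname(co[which(n == 2 & m == 0)]),
    SA = unname(co[which(n == 4 & m == 0)])
  )
  names(out) <- paste0(prefix, names(out))
  out
}
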