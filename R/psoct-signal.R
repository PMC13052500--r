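#' Paired orthogonal-channel A-scan amplitudes
#'
#' Holds the depth profiles of the two orthogonal polarization channels of a
#' polarization-sensitive OCT A-scan, `a1(z)` and `a2(z)`, as non-negative
#' amplitudes (magnitudes of the complex Fourier-domain signals).
#'
#' @param a1,a2 Numeric vectors of equal length, non-negative.
#' @param depth_spacing_um Axial sample pitch in micrometres.
#' @return An object of class `ascan_pair`.
#' @export
ascan_pair <- function(a1, a2, depth_spacing_um = 1) {
  if (!is.numeric(a1) || !is.numeric(a2) || length(a1) != length(a2)) {
    stop_kc("`a1` and `a2` must be numeric vectors of equal length.")
  }
  if (any(!is.finite(a1)) || any(!is.finite(a2)) || any(a1 < 0) || any(a2 < 0)) {
    stop_kc("channel amplitudes must be finite and non-negative.")
  }
  check_scalar_num(depth_spacing_um, "depth_spacing_um")
  structure(list(a1 = a1, a2 = a2, depth_spacing_um = depth_spacing_um),
            class = "ascan_pair")
}

#' Reflectivity profile from an orthogonal-channel pair
#'
#' The polarization-insensitive reflectivity is the summed channel power,
#' `R(z) = a1(z)^2 + a2(z)^2`. Only relative reflectivity is meaningful, so
#' any positive overall scale factor is admissible; this function returns the
#' unscaled sum of squares.
#'
#' @param pair An [ascan_pair()].
#' @return Numeric vector of reflectivities, same length as the input.
#' @examples
#' compute_reflectivity(ascan_pair(3, 4))  # 25
#' @export
compute_reflectivity <- function(pair) {
  stopifnot(inherits(pair, "ascan_pair"))
  pair$a1^2 + pair$a2^2
}

#' Phase retardation profile from an orthogonal-channel pair
#'
#' Cumulative phase retardation in degrees, `PR(z) = atan(a2(z) / a1(z))`,
#' mapped to `[0, 90]`. A sample with `a1 = 0` and `a2 > 0` is exactly 90
#' degrees (the arctangent limit). A sample where both channels vanish
#' carries no polarization information and is returned as `NA` (invalid),
#' never silently zeroed.
#'
#' @param pair An [ascan_pair()].
#' @return Numeric vector of phase retardation in degrees; `NA` marks
#'   invalid samples.
#' @examples
#' compute_phase_retardation(ascan_pair(1, 1))  # 45
#' @export
compute_phase_retardation <- function(pair) {
  stopifnot(inherits(pair, "ascan_pair"))
  pr <- atan2(pair$a2, pair$a1) * 180 / pi
  pr[pair$a1 == 0 & pair$a2 == 0] <- NA_real_
  pr
}

#' Synthesize a noiseless-or-noisy orthogonal-channel A-scan pair
#'
#' Generates channel amplitudes whose ratio encodes a known phase
#' retardation: `a1 = A cos(theta)`, `a2 = A sin(theta)` at every depth, so
#' `a2/a1 = tan(theta)` and retardation recovery is exact at zero noise.
#' Additive Gaussian noise (independent per channel and depth) is clamped at
#' zero because the channels are magnitudes.
#'
#' @param true_pr Phase retardation in degrees, in `[0, 90]`.
#' @param amplitude Channel envelope amplitude (arbitrary units, > 0).
#' @param n_depth Number of depth samples.
#' @param noise_sd Standard deviation of additive channel noise (same units
#'   as `amplitude`).
#' @param rng_seed Integer seed; the draw is deterministic given the seed.
#' @return An [ascan_pair()].
#' @export
synthesize_ascan_pair <- function(true_pr, amplitude = 1, n_depth = 16,
                                  noise_sd = 0, rng_seed = 1) {
  check_scalar_num(true_pr, "true_pr")
  if (true_pr < 0 || true_pr > 90) stop_kc("`true_pr` must lie in [0, 90].")
  if (amplitude <= 0) stop_kc("`amplitude` must be positive.")
  th <- true_pr * pi / 180
  a1 <- rep(amplitude * cos(th), n_depth)
  a2 <- rep(amplitude * sin(th), n_depth)
  if (noise_sd > 0) {
    set.seed(as.integer(rng_seed))
    a1 <- pmax(a1 + stats::rnorm(n_depth, 0, noise_sd), 0)
    a2 <- pmax(a2 + stats::rnorm(n_depth, 0, noise_sd), 0)
  }
  ascan_pair(a1, a2)
}

#' Volume of A-scan pairs on a raster grid
#'
#' Container for a raster-scanned PS-OCT volume: two 3-D amplitude arrays
#' indexed `[y, x, z]`.
#'
#' @param a1,a2 3-D numeric arrays `[y, x, z]`, non-negative.
#' @param spacing Lateral pixel pitch in mm (length 1 or 2, `(x, y)`).
#' @param depth_spacing_um Axial pitch in micrometres.
#' @return An object of class `ascan_volume`.
#' @export
ascan_volume <- function(a1, a2, spacing, depth_spacing_um = 1) {
  if (!is.array(a1) || length(dim(a1)) != 3 || !identical(dim(a1), dim(a2))) {
    stop_kc("`a1` and `a2` must be 3-D arrays of identical shape [y, x, z].")
  }
  if (any(a1 < 0) || any(a2 < 0)) stop_kc("amplitudes must be non-negative.")
  if (length(spacing) == 1L) spacing <- c(spacing, spacing)
  structure(list(a1 = a1, a2 = a2,
                 spacing = c(x = spacing[[1]], y = spacing[[2]]),
                 depth_spacing_um = depth_spacing_um),
            class = "ascan_volume")
}

#' Extract the posterior-surface phase-retardation en-face map
#'
#' Samples the phase retardation of each A-scan at its posterior-surface
#' depth index and assembles the values into a `corneal_map`. The posterior
#' stromal surface is polarization preserving, so retardation sampled there
#' integrates the birefringence accumulated through the stroma. A pixel whose
#' two channels both vanish at the surface sample is masked invalid.
#'
#' @param volume An [ascan_volume()].
#' @param surface_index Integer matrix `[y, x]` (or a scalar, recycled) of
#'   1-based depth sample indices of the posterior surface.
#' @return A `corneal_map` of quantity `"phase_retardation"`.
#' @export
extract_enface_pr <- function(volume, surface_index) {
  stopifnot(inherits(volume, "ascan_volume"))
  d <- dim(volume$a1)
  if (length(surface_index) == 1L) {
    surface_index <- matrix(surface_index, d[1], d[2])
  }
  if (!identical(dim(surface_index), d[1:2])) {
    stop_kc("`surface_index` must be a [y, x] matrix matching the volume.")
  }
  bad <- which(surface_index < 1 | surface_index > d[3], arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_kc(sprintf("surface index out of depth range for A-scan (y=%d, x=%d)",
                    bad[1, 1], bad[1, 2]))
  }
  idx <- cbind(as.vector(row(surface_index)), as.vector(col(surface_index)),
               as.vector(surface_index))
  a1 <- matrix(volume$a1[idx], d[1], d[2])
  a2 <- matrix(volume$a2[idx], d[1], d[2])
  pr <- atan2(a2, a1) * 180 / pi
  mask <- !(a1 == 0 & a2 == 0)
  pr[!mask] <- NA_real_
  corneal_map(pr, spacing = unname(volume$spacing), units = "degrees",
              quantity = "phase_retardation", mask = mask)
}

# nearest odd pixel count per axis covering >= window_mm
window_pixels <- function(window_mm, spacing_mm) {
  k <- ceiling(window_mm / spacing_mm - 1e-9)
  k + (k %% 2 == 0)
}

#' Floating-average smoothing of a corneal map
#'
#' Replaces each pixel by the mean of the valid pixels inside a centred
#' rectangular physical window (default 1 x 1 mm, the standard en-face
#' floating average). The window is converted to the nearest odd pixel count
#' per axis covering at least the requested size; at map borders the window
#' shrinks to the available pixels rather than padding. The validity mask is
#' unchanged.
#'
#' @param map A `corneal_map`.
#' @param window_mm Window size in mm, length 1 or 2 `(x, y)`; must be at
#'   least one pixel on each axis.
#' @return A smoothed `corneal_map`.
#' @export
smooth_map <- function(map, window_mm = c(1, 1)) {
  stopifnot(inherits(map, "corneal_map"))
  if (length(window_mm) == 1L) window_mm <- c(window_mm, window_mm)
  if (any(window_mm < map$spacing)) {
    stop_kc("smoothing window is smaller than one pixel.")
  }
  kx <- window_pixels(window_mm[[1]], map$spacing[["x"]])
  ky <- window_pixels(window_mm[[2]], map$spacing[["y"]])
  v <- map$values
  v[!map$mask] <- 0
  m <- matrix(as.numeric(map$mask), nrow(v), ncol(v))
  sums <- box_sum(v, ky, kx)
  cnts <- box_sum(m, ky, kx)
  out <- ifelse(cnts > 0, sums / cnts, NA_real_)
  out[!map$mask] <- NA_real_
  corneal_map(out, spacing = unname(map$spacing), units = map$units,
              quantity = map$quantity, mask = map$mask)
}

# clipped box-filter sums via summed-area table
box_sum <- function(x, ky, kx) {
  nr <- nrow(x); nc <- ncol(x)
  sat <- apply(apply(x, 2, cumsum), 1, cumsum) # transposed: [col, row]
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat)) # pad so sat[i+1, j+1] = sum x[1:i, 1:j]
  hy <- (ky - 1) %/% 2; hx <- (kx - 1) %/% 2
  r1 <- pmax(seq_len(nr) - hy, 1); r2 <- pmin(seq_len(nr) + hy, nr)
  c1 <- pmax(seq_len(nc) - hx, 1); c2 <- pmin(seq_len(nc) + hx, nc)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    out[, j] <- sat[r2 + 1, c2[j] + 1] - sat[r1, c2[j] + 1] -
      sat[r2 + 1, c1[j]] + sat[r1, c1[j]]
  }
  out
}

#' Centred crop of a corneal map to a smaller field
#'
#' Crops the map symmetrically about its centre to the requested physical
#' extent (e.g. a 10 x 8 mm retardation field down to the common 8 x 8 mm
#' analysis field), preserving pixel spacing.
#'
#' @param map A `corneal_map`.
#' @param extent_mm Target `(width, height)` in mm; must not exceed the map
#'   extent.
#' @return The cropped `corneal_map`.
#' @export
crop_field <- function(map, extent_mm) {
  stopifnot(inherits(map, "corneal_map"))
  if (length(extent_mm) == 1L) extent_mm <- c(extent_mm, extent_mm)
  cur <- map_extent(map)
  if (extent_mm[[1]] > cur[["width"]] + 1e-9 ||
      extent_mm[[2]] > cur[["height"]] + 1e-9) {
    stop_kc("requested extent exceeds the map extent.")
  }
  d <- dim(map$values)
  nx <- min(round(extent_mm[[1]] / map$spacing[["x"]]) + 1, d[2])
  ny <- min(round(extent_mm[[2]] / map$spacing[["y"]]) + 1, d[1])
  ox <- (d[2] - nx) %/% 2
  oy <- (d[1] - ny) %/% 2
  rows <- seq.int(oy + 1, oy + ny)
  cols <- seq.int(ox + 1, ox + nx)
  corneal_map(map$values[rows, cols, drop = FALSE],
              spacing = unname(map$spacing), units = map$units,
              quantity = map$quantity,
              mask = map$mask[rows, cols, drop = FALSE])
}
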