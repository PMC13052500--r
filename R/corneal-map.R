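#' Corneal en-face map
#'
#' A `corneal_map` is a 2-D scalar field sampled on a regular physical grid
#' centred on the corneal apex: phase retardation (degrees) or a sublayer
#' thickness (micrometres), together with a validity mask. Rows index the
#' vertical (y) axis, columns the horizontal (x) axis; x increases rightward
#' in the scan frame and y increases upward. Pixel centres span
#' `[-extent/2, +extent/2]` on each axis, so `extent = (n - 1) * spacing`.
#'
#' @param values Numeric matrix (rows = y, columns = x).
#' @param spacing Pixel pitch in mm, length-1 or length-2 `(x, y)`.
#' @param units `"degrees"` or `"um"`.
#' @param quantity One of `"phase_retardation"`, `"epithelium_thickness"`,
#'   `"bowman_thickness"`, `"reflectivity"`.
#' @param mask Logical matrix marking valid pixels; defaults to non-`NA`
#'   entries of `values`.
#' @return An object of class `corneal_map`.
#' @examples
#' m <- corneal_map(matrix(45, 9, 9), spacing = 0.25, units = "degrees",
#'                  quantity = "phase_retardation")
#' map_extent(m)
#' @export
corneal_map <- function(values, spacing, units = c("degrees", "um"),
                        quantity = c("phase_retardation", "epithelium_thickness",
                                     "bowman_thickness", "reflectivity"),
                        mask = NULL) {
  units <- match.arg(units)
  quantity <- match.arg(quantity)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_kc("`values` must be a numeric matrix.")
  }
  if (length(spacing) == 1L) spacing <- c(spacing, spacing)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_kc("`spacing` must be positive.")
  }
  if (is.null(mask)) mask <- !is.na(values)
  if (!is.logical(mask) || !identical(dim(mask), dim(values))) {
    stop_kc("`mask` must be a logical matrix with the same shape as `values`.")
  }
  m <- structure(
    list(values = values, mask = mask,
         spacing = c(x = spacing[[1]], y = spacing[[2]]),
         units = units, quantity = quantity),
    class = "corneal_map"
  )
  validate_corneal_map(m)
}

validate_corneal_map <- function(m) {
  v <- m$values[m$mask]
  if (any(!is.finite(v))) stop_kc("map values inside the mask must be finite.")
  if (m$quantity == "phase_retardation" && length(v) &&
      (min(v) < 0 || max(v) > 90)) {
    stop_kc("phase retardation values must lie in [0, 90] degrees.")
  }
  if (m$quantity %in% c("epithelium_thickness", "bowman_thickness") &&
      length(v) && min(v) <= 0) {
    stop_kc("thickness values inside the mask must be positive.")
  }
  m
}

#' @rdname corneal_map
#' @param map A `corneal_map`.
#' @export
map_extent <- function(map) {
  stopifnot(inherits(map, "corneal_map"))
  d <- dim(map$values)
  c(width = (d[2] - 1) * map$spacing[["x"]],
    height = (d[1] - 1) * map$spacing[["y"]])
}

# pixel-centre coordinates in mm, origin at grid centre
map_axes <- function(map) {
  d <- dim(map$values)
  list(x = (seq_len(d[2]) - (d[2] + 1) / 2) * map$spacing[["x"]],
       y = (seq_len(d[1]) - (d[1] + 1) / 2) * map$spacing[["y"]])
}

#' @export
print.corneal_map <- function(x, ...) {
  d <- dim(x$values)
  e <- map_extent(x)
  cat(sprintf("<corneal_map> %s [%s], %d x %d px, %.2f x %.2f mm, %d%% valid\n",
              x$quantity, x$units, d[1], d[2], e[["width"]], e[["height"]],
              round(100 * mean(x$mask))))
  invisible(x)
}

#' Convert a corneal map to a tidy tibble
#'
#' One row per pixel with physical coordinates, the sampled value and the
#' validity flag — the shape expected by ggplot2 and dplyr.
#'
#' @param map A `corneal_map`.
#' @return A tibble with columns `x_mm`, `y_mm`, `value`, `valid`.
#' @export
map_to_tibble <- function(map) {
  stopifnot(inherits(map, "corneal_map"))
  ax <- map_axes(map)
  tibble::tibble(
    x_mm = rep(ax$x, each = length(ax$y)),
    y_mm = rep(ax$y, times = length(ax$x)),
    value = as.vector(map$values),
    valid = as.vector(map$mask)
  )
}

#' @export
autoplot.corneal_map <- function(object, ...) {
  df <- dplyr::filter(map_to_tibble(object), .data$valid)
  lab <- sprintf("%s [%s]", gsub("_", " ", object$quantity), object$units)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' Write / read a corneal map as delimited text with a JSON header
#'
#' The on-disk format is plain text: the first line is a JSON object holding
#' the grid metadata (`spacing_mm`, `extent_mm`, `units`, `quantity`, and the
#' token used for masked pixels), followed by the value grid as
#' tab-separated rows (top row = largest y). Masked pixels are written as
#' `NA`.
#'
#' @param map A `corneal_map`.
#' @param path File path.
#' @return `write_corneal_map()` returns `path` invisibly; `read_corneal_map()`
#'   returns a `corneal_map`.
#' @export
write_corneal_map <- function(map, path) {
  stopifnot(inherits(map, "corneal_map"))
  hdr <- jsonlite::toJSON(list(
    spacing_mm = unname(map$spacing),
    extent_mm = unname(map_extent(map)),
    units = map$units, quantity = map$quantity, mask_token = "NA"
  ), auto_unbox = TRUE, digits = NA)
  v <- map$values
  v[!map$mask] <- NA
  # top row of the file = top of the map (largest y)
  lines <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1,
                 function(r) paste(format(r, trim = TRUE, digits = 17), collapse = "\t"))
  writeLines(c(as.character(hdr), lines), path)
  invisible(path)
}

#' @rdname write_corneal_map
#' @export
read_corneal_map <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[[1]])
  rows <- lapply(lines[-1], function(l) as.numeric(strsplit(l, "\t")[[1]]))
  v <- do.call(rbind, rows)
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  corneal_map(v, spacing = hdr$spacing_mm, units = hdr$units,
              quantity = hdr$quantity, mask = !is.na(v))
}
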