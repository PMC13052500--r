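# internal helpers: argument checks and deterministic seed derivation

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_kc <- function(..., class = "kcscreen_error") {
  rlang::abort(paste0(...), class = class)
}

check_scalar_num <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_kc("`", name, "` must be a single finite number.")
  }
  invisible(x)
}

#' Derive a child random seed from a base seed and a key
#'
#' Splittable seeding scheme used throughout the package: every stochastic
#' unit of work (one synthetic eye, one cross-validation fold) receives its
#' own seed computed from the user-supplied base seed and a stable key (an
#' integer index or a character identifier). The mix is a fixed-multiplier
#' congruential hash reduced modulo 2^31 - 2, so derived seeds are valid R
#' seeds, reproducible across sessions, and independent of the order in which
#' units are processed.
#'
#' @param base_seed Single integer base seed.
#' @param key Integer index or character identifier of the work unit.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(17, 3)
#' derive_seed(17, "eye_0003")
#' @export
derive_seed <- function(base_seed, key) {
  check_scalar_num(base_seed, "base_seed")
  if (is.character(key)) key <- string_hash(key)
  check_scalar_num(key, "key")
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- (as.numeric(base_seed) %% m)
  # two rounds of multiply-add-mod; multipliers from Park-Miller family
  h <- (h * 48271 + (as.numeric(key) %% m)) %% m
  h <- (h * 69621 + 12345) %% m
  as.integer(h %% (m - 1)) + 1L
}

# stable 31-bit hash of a character string (polynomial rolling hash)
string_hash <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  cp <- utf8ToInt(s)
  m <- 2147483647
  h <- 0
  for (c in cp) h <- (h * 131 + c) %% m
  h
}

#' The fixed diagnostic class order
#'
#' All tabulations (confusion rows/columns, probability columns, factor
#' levels, tie-breaking) use this order.
#'
#' @return `c("healthy", "skc", "kc")`.
#' @export
kc_groups <- function() c("healthy", "skc", "kc")

as_group_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), kc_groups())
  if (length(bad) > 0) {
    stop_kc("unknown group label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = kc_groups())
}
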