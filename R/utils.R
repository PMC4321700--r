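# Internal geometry and validation helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to (-180, 180] degrees
#'
#' Angular differences are reduced to the principal interval with the
#' tie broken toward +180: an exact reversal is reported as +180, never
#' -180, so repeated wrapping is deterministic.
#'
#' @param a Numeric vector of angles in degrees.
#' @return Numeric vector in (-180, 180].
#' @examples
#' wrap_deg(c(190, -190, 180, -180, 540))
#' @export
wrap_deg <- function(a) {
  a - 360 * ceiling((a - 180) / 360)
}

# Cumulative arc length along a polyline; first element 0.
cum_arc <- function(x, y) {
  c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
}

# Interpolate a polyline at given arc-length positions. Because x and y
# are piecewise-linear functions of arc length, stats::approx is exact.
interp_at_arc <- function(x, y, s_out, t = NULL) {
  s <- cum_arc(x, y)
  out <- list(
    x = stats::approx(s, x, xout = s_out, ties = "ordered")$y,
    y = stats::approx(s, y, xout = s_out, ties = "ordered")$y
  )
  if (!is.null(t)) {
    out$t <- stats::approx(s, t, xout = s_out, ties = "ordered")$y
  }
  out$s <- s_out
  out
}

# Greedy decimation: keep the first point, then every point at least
# `min_step` from the last retained one. Stabilises headings against
# sub-pixel jitter. Returns indices into the input.
retain_indices <- function(x, y, min_step) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  if (min_step <= 0) return(seq_len(n))
  keep <- integer(n)
  keep[1L] <- 1L
  m <- 1L
  last <- 1L
  for (i in 2:n) {
    if (sqrt((x[i] - x[last])^2 + (y[i] - y[last])^2) >= min_step) {
      m <- m + 1L
      keep[m] <- i
      last <- i
    }
  }
  keep[seq_len(m)]
}

abort_wormloop <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "wormloop_error"), ...)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_wormloop(
      sprintf("`%s` must be a single positive finite number.", name),
      "wormloop_parameter_error"
    )
  }
  invisible(x)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    abort_wormloop(
      sprintf("`%s` must be a probability in [0, 1].", name),
      "wormloop_parameter_error"
    )
  }
  invisible(x)
}

# Split a multi-animal table by animal_id, apply fn, and row-bind the
# results back into one tibble (animal order preserved).
by_animal <- function(df, fn, ...) {
  ids <- unique(df$animal_id)
  pieces <- lapply(ids, function(id) fn(df[df$animal_id == id, , drop = FALSE], ...))
  dplyr::bind_rows(pieces)
}

# Derive `n` reproducible sub-seeds (< 2^31) from a master seed without
# disturbing the caller's RNG state.
derive_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed),
                   sample.int(.Machine$integer.max - 1L, n))
}
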