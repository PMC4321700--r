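# Signed curving-rate analysis: the change in direction of locomotion
# per unit length of advancement (deg/mm), ventral-ward curves positive
# when the animal's ventral side is known.

curving_one <- function(tr, min_step_mm) {
  keep <- retain_indices(tr$x_mm, tr$y_mm, min_step_mm)
  if (length(keep) < 3L) {
    abort_wormloop(
      sprintf("Animal '%s': degenerate track (fewer than 3 samples %s).",
              tr$animal_id[1],
              if (min_step_mm > 0) sprintf("at least %.3g mm apart", min_step_mm)
              else "retained"),
      "wormloop_degenerate"
    )
  }
  x <- tr$x_mm[keep]
  y <- tr$y_mm[keep]
  t <- tr$t_s[keep]
  dx <- diff(x)
  dy <- diff(y)
  steps <- sqrt(dx^2 + dy^2)
  headings <- rad2deg(atan2(dy, dx))
  dturn <- wrap_deg(diff(headings))
  step_mid <- (steps[-length(steps)] + steps[-1]) / 2
  vil <- tr$ventral_is_left[1]
  if (is.na(vil)) {
    sign_convention <- "ccw_positive"
    flip <- 1
  } else {
    sign_convention <- "ventral_positive"
    # ventral on the left: a leftward (counter-clockwise) turn is
    # ventral-ward, so the mathematical sign already matches
    flip <- if (vil) 1 else -1
  }
  tibble::tibble(
    animal_id = tr$animal_id[1],
    t_mid_s = t[c(-1, -length(t))] - t[1],  # track start at 0
    step_mm = step_mid,
    curving_deg_per_mm = flip * dturn / step_mid,
    sign_convention = sign_convention
  )
}

#' Compute the signed curving-rate series
#'
#' The heading of each step is the direction of the displacement between
#' consecutive retained centroids (steps shorter than `min_step_mm` are
#' merged into their successor to stabilise headings against sub-pixel
#' jitter). The curving rate at an interior sample is the signed angular
#' difference between the incoming and outgoing headings, wrapped to
#' (-180, 180], divided by the mean of the two adjacent step lengths.
#' With a known ventral side the sign is mapped so that ventral-ward
#' curves are positive; with unknown ventral side the counter-clockwise-
#' positive mathematical convention is kept and recorded.
#'
#' @param trajs Trajectory tibble (one or more animals).
#' @param min_step_mm Minimum step length retained, mm.
#' @return A tibble with columns `animal_id`, `t_mid_s` (seconds from
#'   track start), `step_mm` (the mean adjacent step length, also the
#'   path-length weight), `curving_deg_per_mm` and `sign_convention`.
#' @examples
#' tr <- simulate_trajectory(walk_config(bias_deg_per_mm = 5,
#'                                       duration_s = 120))
#' cs <- compute_curving(tr)
#' mean(cs$curving_deg_per_mm)
#' @export
compute_curving <- function(trajs, min_step_mm = 0.05) {
  validate_trajectories(trajs)
  if (min_step_mm < 0) {
    abort_wormloop("`min_step_mm` must be nonnegative.", "wormloop_parameter_error")
  }
  if (!"ventral_is_left" %in% names(trajs)) trajs$ventral_is_left <- NA
  by_animal(trajs, curving_one, min_step_mm = min_step_mm)
}

#' Path-length-weighted mean curving over a fixed time window
#'
#' Averages the curving rate over the first `window_s` seconds of each
#' track (timestamps are measured from track start), weighting each
#' value by its step length so the mean is per unit of advancement.
#'
#' @param series Curving series from [compute_curving()].
#' @param window_s Averaging window, seconds (default 20 minutes).
#' @return A tibble with one row per animal: `mean_curving_deg_per_mm`,
#'   the path length analysed `weight_mm`, and `sign_convention`.
#' @export
mean_curving_fixed_time <- function(series, window_s = 1200) {
  check_positive(window_s, "window_s")
  by_animal(series, function(cs) {
    covered <- max(cs$t_mid_s)
    if (covered < window_s) {
      abort_wormloop(
        sprintf("Animal '%s': series covers only %.1f s (< window of %.1f s).",
                cs$animal_id[1], covered, window_s),
        "wormloop_short_track",
        covered_s = covered
      )
    }
    inside <- cs$t_mid_s <= window_s
    w <- cs$step_mm[inside]
    tibble::tibble(
      animal_id = cs$animal_id[1],
      mean_curving_deg_per_mm =
        sum(w * cs$curving_deg_per_mm[inside]) / sum(w),
      weight_mm = sum(w),
      sign_convention = cs$sign_convention[1]
    )
  })
}

#' Mean curving over a fixed initial path distance
#'
#' Averages the curving rate over the first `L0` millimetres of each
#' track ("the first 30 mm of each track"): the track is truncated by
#' arc length and the path-length-weighted mean of its curving series is
#' returned.
#'
#' @param trajs Trajectory tibble.
#' @param L0 Path distance analysed, mm.
#' @param min_step_mm Passed to [compute_curving()].
#' @return A tibble with one row per animal: `mean_curving_deg_per_mm`,
#'   `weight_mm`, `sign_convention`.
#' @export
mean_curving_fixed_distance <- function(trajs, L0 = 30, min_step_mm = 0.05) {
  truncated <- truncate_by_path_length(trajs, L0 = L0)
  series <- compute_curving(truncated, min_step_mm = min_step_mm)
  by_animal(series, function(cs) {
    tibble::tibble(
      animal_id = cs$animal_id[1],
      mean_curving_deg_per_mm = sum(cs$step_mm * cs$curving_deg_per_mm) /
        sum(cs$step_mm),
      weight_mm = sum(cs$step_mm),
      sign_convention = cs$sign_convention[1]
    )
  })
}

#' Pooled path-length-weighted curving-rate histogram
#'
#' Pools one or more curving series into a histogram whose per-bin mass
#' is path length (mm), not sample count, so fast and slow animals
#' contribute in proportion to distance travelled. Bins are half-open
#' `[lo, hi)` and aligned so that 0 deg/mm is a bin edge.
#'
#' @param series Curving series from [compute_curving()] (any number of
#'   animals, row-bound).
#' @param bin_width_deg_per_mm Bin width, deg/mm.
#' @return A tibble of class `curving_histogram` with columns `bin_lo`,
#'   `bin_hi`, `bin_mid` and `weight_mm`; the weights sum to the total
#'   analysed path length.
#' @export
curving_histogram <- function(series, bin_width_deg_per_mm = 1) {
  check_positive(bin_width_deg_per_mm, "bin_width_deg_per_mm")
  if (nrow(series) == 0L) {
    abort_wormloop("Empty curving series.", "wormloop_parameter_error")
  }
  w <- bin_width_deg_per_mm
  idx <- floor(series$curving_deg_per_mm / w)
  bins <- seq(min(idx), max(idx))
  weight <- vapply(bins, function(b) sum(series$step_mm[idx == b]), numeric(1))
  out <- tibble::tibble(
    bin_lo = bins * w,
    bin_hi = (bins + 1) * w,
    bin_mid = (bins + 0.5) * w,
    weight_mm = weight
  )
  class(out) <- c("curving_histogram", class(out))
  out
}
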