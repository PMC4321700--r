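# Fractal coarse-graining of trajectories: dividing points every delta
# of arc length, coarse-grained length L_delta, and the dimensionless
# directionality measure L_delta / L0.

#' Default logarithmic delta grid
#'
#' Ten points logarithmically spaced between `from` and `to` mm, spanning
#' step sizes from below a body length up to the full analysed distance.
#'
#' @param from,to Grid end points, mm.
#' @param n Number of grid points.
#' @return Numeric vector of delta values, mm.
#' @export
default_delta_grid <- function(from = 0.5, to = 30, n = 10) {
  check_positive(from, "from")
  check_positive(to, "to")
  g <- exp(seq(log(from), log(to), length.out = n))
  g[n] <- to  # guard against floating overshoot of the end point
  g
}

coarse_grain_points_one <- function(tr, delta_mm, L0) {
  tr <- truncate_one(tr, L0)
  s_grid <- seq(0, L0, by = delta_mm)
  if (s_grid[length(s_grid)] < L0 - 1e-9) s_grid <- c(s_grid, L0)
  p <- interp_at_arc(tr$x_mm, tr$y_mm, s_grid)
  tibble::tibble(
    animal_id = tr$animal_id[1],
    arc_mm = s_grid,
    x_mm = p$x,
    y_mm = p$y
  )
}

#' Dividing points of a coarse-grained trajectory
#'
#' Restricts each track to its first `L0` of path, places dividing
#' points at arc lengths 0, delta, 2*delta, ... (linearly interpolated
#' along the polyline, never snapped to samples), and appends the point
#' at arc length `L0` so the coarse-grained polyline always spans the
#' full analysed length.
#'
#' @param trajs Trajectory tibble.
#' @param delta_mm Sub-trajectory length delta, mm; must lie in (0, L0].
#' @param L0 Total analysed path length, mm.
#' @return A tibble of dividing points (`animal_id`, `arc_mm`, `x_mm`,
#'   `y_mm`).
#' @export
coarse_grain_points <- function(trajs, delta_mm, L0 = 30) {
  validate_trajectories(trajs)
  check_positive(L0, "L0")
  if (!is.numeric(delta_mm) || length(delta_mm) != 1L ||
      delta_mm <= 0 || delta_mm > L0) {
    abort_wormloop("`delta_mm` must lie in (0, L0].", "wormloop_parameter_error")
  }
  by_animal(trajs, coarse_grain_points_one, delta_mm = delta_mm, L0 = L0)
}

#' Coarse-grained length for one delta
#'
#' `L_delta` is the sum of Euclidean distances between consecutive
#' dividing points of the coarse-grained trajectory; the ratio
#' `L_delta / L0` is a dimensionless directionality measure — lower
#' values mean movement confined to narrower areas.
#'
#' @inheritParams coarse_grain_points
#' @return A tibble with one row per animal: `delta_mm`, `L_delta_mm`,
#'   `ratio` and `L0_mm`.
#' @export
coarse_grain <- function(trajs, delta_mm, L0 = 30) {
  pts <- coarse_grain_points(trajs, delta_mm, L0 = L0)
  by_animal(pts, function(p) {
    tibble::tibble(
      animal_id = p$animal_id[1],
      delta_mm = delta_mm,
      L_delta_mm = sum(sqrt(diff(p$x_mm)^2 + diff(p$y_mm)^2)),
      ratio = NA_real_,
      L0_mm = L0
    )
  }) |>
    dplyr::mutate(ratio = .data$L_delta_mm / .data$L0_mm)
}

#' L_delta / L0 ratio curve over a delta grid
#'
#' @param trajs Trajectory tibble.
#' @param delta_grid Strictly increasing delta values in (0, L0], mm.
#' @param L0 Total analysed path length, mm.
#' @return A tibble of class `ratio_curve`: one row per animal and
#'   delta with `L_delta_mm` and `ratio`.
#' @examples
#' tr <- simulate_trajectory(walk_config(bias_deg_per_mm = -12,
#'                                       duration_s = 400))
#' ratio_curve(tr, default_delta_grid())
#' @export
ratio_curve <- function(trajs, delta_grid = default_delta_grid(), L0 = 30) {
  if (length(delta_grid) == 0L || any(diff(delta_grid) <= 0)) {
    abort_wormloop("`delta_grid` must be strictly increasing.",
                   "wormloop_parameter_error")
  }
  out <- dplyr::bind_rows(lapply(delta_grid, function(d) {
    coarse_grain(trajs, d, L0 = L0)
  }))
  out <- dplyr::arrange(out, .data$animal_id, .data$delta_mm)
  class(out) <- c("ratio_curve", class(out))
  out
}

#' Cohort median-of-log summary of ratio curves
#'
#' Summarises a cohort's ratio curves per delta as the median of
#' log10(L_delta / L0) with first and third quartiles (linearly
#' interpolated, type 7), the standard presentation of coarse-graining
#' results on log-log axes. Single-animal cohorts report
#' q1 = q3 = median.
#'
#' @param results A `ratio_curve` tibble covering one or more animals;
#'   all animals must share the same delta grid and L0.
#' @return A tibble of class `cohort_log_summary` with columns
#'   `delta_mm`, `median_log10`, `q1_log10`, `q3_log10`, `n`.
#' @export
cohort_log_summary <- function(results) {
  grids <- split(results$delta_mm, results$animal_id)
  ref <- grids[[1]]
  for (g in grids) {
    if (length(g) != length(ref) || any(abs(g - ref) > 1e-9)) {
      abort_wormloop(
        sprintf("Animals have mismatched delta grids (offending deltas: %s).",
                paste(signif(union(setdiff(g, ref), setdiff(ref, g)), 6),
                      collapse = ", ")),
        "wormloop_grid_mismatch"
      )
    }
  }
  if (length(unique(results$L0_mm)) != 1L) {
    abort_wormloop("All animals must share the same L0.",
                   "wormloop_grid_mismatch")
  }
  out <- results |>
    dplyr::mutate(log10_ratio = log10(.data$ratio)) |>
    dplyr::group_by(.data$delta_mm) |>
    dplyr::summarise(
      median_log10 = stats::median(.data$log10_ratio),
      q1_log10 = stats::quantile(.data$log10_ratio, 0.25, names = FALSE, type = 7),
      q3_log10 = stats::quantile(.data$log10_ratio, 0.75, names = FALSE, type = 7),
      n = dplyr::n(),
      .groups = "drop"
    )
  class(out) <- c("cohort_log_summary", class(out))
  out
}
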