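# Quantification of GFP photobleach-and-recovery experiments and of
# synaptic/receptor puncta. All intensities are background-corrected by
# subtracting the mean of three background points before any ratio is
# formed, so a camera offset common to ROI and background cancels.

#' Read fluorescence records from delimited text
#'
#' Expected columns: `animal_id`, `condition` ("heat_shock" or
#' "control"), raw ROI means `roi_intact`, `roi_bleached`, `roi_after`,
#' and three background points per stage, `bg_intact_1..3`,
#' `bg_bleached_1..3`, `bg_after_1..3`.
#'
#' @param path Path to a comma- or tab-delimited file.
#' @return A fluorescence-record tibble.
#' @export
read_fluorescence <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  numeric_cols <- c("roi_intact", "roi_bleached", "roi_after",
                    paste0("bg_intact_", 1:3), paste0("bg_bleached_", 1:3),
                    paste0("bg_after_", 1:3))
  missing <- setdiff(c("animal_id", "condition", numeric_cols), names(raw))
  if (length(missing) > 0L) {
    abort_wormloop(
      sprintf("File '%s' is missing required column(s): %s.",
              path, paste(missing, collapse = ", ")),
      "wormloop_format_error"
    )
  }
  out <- tibble::tibble(
    animal_id = as.character(raw$animal_id),
    condition = as.character(raw$condition)
  )
  for (col in numeric_cols) {
    out[[col]] <- convert_numeric_col(raw[[col]], col, path)
  }
  out
}

#' Background-correct an ROI intensity
#'
#' Subtracts the average of three background-point intensities from the
#' ROI mean. Negative corrected values are allowed (and flagged by the
#' downstream validity checks), since noisy backgrounds can exceed dim
#' signals.
#'
#' @param roi_value ROI mean intensity (vectorised).
#' @param bg_points A length-3 numeric vector, or an n x 3 matrix /
#'   data frame of background points matching `roi_value`.
#' @return Corrected intensity `roi_value - mean(bg_points)` (row-wise
#'   for matrix input).
#' @examples
#' background_correct(50, c(10, 20, 30))  # 30
#' @export
background_correct <- function(roi_value, bg_points) {
  if (is.data.frame(bg_points)) bg_points <- as.matrix(bg_points)
  if (is.matrix(bg_points)) {
    if (ncol(bg_points) != 3L || nrow(bg_points) != length(roi_value)) {
      abort_wormloop("`bg_points` must have exactly 3 columns, one row per ROI value.",
                     "wormloop_format_error")
    }
    return(roi_value - rowMeans(bg_points))
  }
  if (length(bg_points) != 3L) {
    abort_wormloop("Exactly 3 background points are required.",
                   "wormloop_format_error")
  }
  roi_value - mean(bg_points)
}

correct_record_stages <- function(records) {
  records$intact_corr <- background_correct(
    records$roi_intact,
    cbind(records$bg_intact_1, records$bg_intact_2, records$bg_intact_3)
  )
  records$bleached_corr <- background_correct(
    records$roi_bleached,
    cbind(records$bg_bleached_1, records$bg_bleached_2, records$bg_bleached_3)
  )
  records$after_corr <- background_correct(
    records$roi_after,
    cbind(records$bg_after_1, records$bg_after_2, records$bg_after_3)
  )
  records$valid <- records$intact_corr > records$bleached_corr
  if (any(!records$valid)) {
    rlang::warn(sprintf(
      "%d record(s) flagged invalid: corrected intact <= corrected bleached (no photobleaching).",
      sum(!records$valid)
    ))
  }
  retention <- records$bleached_corr / records$intact_corr
  off <- records$valid & (retention < 0.5 - 1e-9 | retention > 0.7 + 1e-9)
  if (any(off)) {
    rlang::warn(sprintf(
      "%d record(s) outside the expected 50-70%% bleach retention range.",
      sum(off)
    ))
  }
  records$retention <- retention
  records
}

#' Per-animal rate of change of GFP intensity
#'
#' Applies, on background-corrected intensities,
#' `(after - bleached) / (intact - bleached)`:
#' 0 means no recovery of the bleached-away signal, 1 full recovery.
#' Values outside `[0, 1]` are allowed but flagged. Records in which the
#' corrected intact-minus-bleached difference does not exceed
#' `eps_fraction` of the corrected intact intensity carry no usable
#' bleaching signal and raise an error.
#'
#' @param records Fluorescence-record tibble (see [read_fluorescence()]
#'   or [simulate_fluorescence()]).
#' @param eps_fraction Minimum bleach depth as a fraction of corrected
#'   intact intensity.
#' @return The records with corrected intensities, `retention`, `valid`,
#'   `rate_of_change` and `rate_flagged` columns added.
#' @examples
#' rec <- simulate_fluorescence(fluor_sim_config(recovery_fraction = 0.6))
#' rate_of_change(rec)$rate_of_change
#' @export
rate_of_change <- function(records, eps_fraction = 0.01) {
  records <- correct_record_stages(records)
  denom <- records$intact_corr - records$bleached_corr
  eps <- eps_fraction * records$intact_corr
  bad <- denom <= eps
  if (any(bad)) {
    abort_wormloop(
      sprintf("Insufficient bleach for animal(s): %s (corrected intact - bleached <= %.3g of intact).",
              paste(records$animal_id[bad], collapse = ", "), eps_fraction),
      "wormloop_insufficient_bleach"
    )
  }
  records$rate_of_change <- (records$after_corr - records$bleached_corr) / denom
  records$rate_flagged <- records$rate_of_change < 0 | records$rate_of_change > 1
  if (any(records$rate_flagged)) {
    rlang::warn(sprintf("%d rate(s) of change outside [0, 1] (flagged).",
                        sum(records$rate_flagged)))
  }
  records
}

#' Control-normalised recovery ratio
#'
#' For each heat-shocked animal the recovery ratio is its rate of change
#' minus the mean rate of change of the control group, plus 1: a ratio
#' of 1 means the heat-shocked animal recovered exactly like the
#' controls, lower values mean knocked-down recovery.
#'
#' @param heat_shock_records,control_records Fluorescence-record tibbles
#'   for the two treatment groups.
#' @param eps_fraction Passed to [rate_of_change()].
#' @return An object of class `recovery_result`; [tidy()] gives the
#'   per-animal ratios, [glance()] the group mean, SD and sizes.
#' @export
recovery_ratio <- function(heat_shock_records, control_records,
                           eps_fraction = 0.01) {
  if (nrow(control_records) == 0L) {
    abort_wormloop("Control group is empty.", "wormloop_parameter_error")
  }
  if (nrow(heat_shock_records) == 0L) {
    abort_wormloop("Heat-shock group is empty.", "wormloop_parameter_error")
  }
  hs <- rate_of_change(heat_shock_records, eps_fraction = eps_fraction)
  ctl <- rate_of_change(control_records, eps_fraction = eps_fraction)
  ctl_mean <- mean(ctl$rate_of_change)
  per_animal <- tibble::tibble(
    animal_id = hs$animal_id,
    rate_of_change = hs$rate_of_change,
    recovery_ratio = hs$rate_of_change - ctl_mean + 1
  )
  structure(
    list(
      per_animal = per_animal,
      control_mean_rate = ctl_mean,
      mean_recovery_ratio = mean(per_animal$recovery_ratio),
      sd_recovery_ratio = stats::sd(per_animal$recovery_ratio),
      n_heat_shock = nrow(hs),
      n_control = nrow(ctl)
    ),
    class = "recovery_result"
  )
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf(
    "Recovery ratio: mean %.3f (sd %.3f, n = %d heat-shock vs %d control; control mean rate %.3f)\n",
    x$mean_recovery_ratio,
    ifelse(is.na(x$sd_recovery_ratio), 0, x$sd_recovery_ratio),
    x$n_heat_shock, x$n_control, x$control_mean_rate
  ))
  print(x$per_animal)
  invisible(x)
}

#' Summarise puncta intensities and areas
#'
#' Background-corrects per-punctum intensities (supplied by external
#' segmentation with an equal-size ROI across animals) and reports their
#' mean and areas. Corrected intensities are clipped at zero with a
#' warning when the background exceeds a punctum — dim puncta cannot
#' carry negative signal. An empty table is a valid "no puncta detected"
#' phenotype and yields a zero summary.
#'
#' @param puncta A data frame with columns `roi_id`, `punctum_id`,
#'   `raw_intensity`, `area`.
#' @param bg_points Length-3 vector of background-point intensities.
#' @param equal_roi Caller's assertion that ROI sizes are equivalent
#'   across animals; set to FALSE to record that the comparison is not
#'   size-controlled.
#' @return An object of class `puncta_summary`; [tidy()] gives the
#'   per-punctum table, [glance()] the mean corrected intensity, mean
#'   area and punctum count.
#' @export
summarize_puncta <- function(puncta, bg_points, equal_roi = TRUE) {
  required <- c("roi_id", "punctum_id", "raw_intensity", "area")
  missing <- setdiff(required, names(puncta))
  if (length(missing) > 0L && nrow(puncta) > 0L) {
    abort_wormloop(
      sprintf("Puncta table is missing column(s): %s.",
              paste(missing, collapse = ", ")),
      "wormloop_format_error"
    )
  }
  if (nrow(puncta) == 0L) {
    per <- tibble::tibble(roi_id = character(0), punctum_id = character(0),
                          corrected_intensity = numeric(0), area = numeric(0))
    return(structure(
      list(per_punctum = per, mean_intensity = 0, mean_area = NA_real_,
           n_puncta = 0L, equal_roi = equal_roi),
      class = "puncta_summary"
    ))
  }
  if (any(puncta$area <= 0)) {
    abort_wormloop("Punctum areas must be positive.", "wormloop_format_error")
  }
  corrected <- background_correct(puncta$raw_intensity,
                                  matrix(rep(bg_points, each = nrow(puncta)),
                                         ncol = 3))
  if (any(corrected < 0)) {
    rlang::warn(sprintf(
      "%d punctum(a) dimmer than background; corrected intensity clipped at 0.",
      sum(corrected < 0)
    ))
    corrected <- pmax(corrected, 0)
  }
  per <- tibble::tibble(
    roi_id = as.character(puncta$roi_id),
    punctum_id = as.character(puncta$punctum_id),
    corrected_intensity = corrected,
    area = puncta$area
  )
  structure(
    list(
      per_punctum = per,
      mean_intensity = mean(corrected),
      mean_area = mean(puncta$area),
      n_puncta = nrow(per),
      equal_roi = equal_roi
    ),
    class = "puncta_summary"
  )
}

#' @export
print.puncta_summary <- function(x, ...) {
  cat(sprintf("Puncta: n = %d, mean corrected intensity %.3f%s\n",
              x$n_puncta, x$mean_intensity,
              if (!x$equal_roi) " (ROI sizes NOT equal across animals)" else ""))
  invisible(x)
}
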