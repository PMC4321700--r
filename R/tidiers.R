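# Broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname assay_cl_proportion
#' @param x A `cl_assay_summary` object.
#' @param ... Unused.
#' @method tidy cl_assay_summary
#' @export
tidy.cl_assay_summary <- function(x, ...) {
  x$per_assay
}

#' @rdname assay_cl_proportion
#' @method glance cl_assay_summary
#' @export
glance.cl_assay_summary <- function(x, ...) {
  tibble::tibble(
    mean_pct_cl = x$mean_pct_cl,
    pooled_pct_cl = x$pooled_pct_cl,
    n_assays = x$n_assays,
    n_animals = x$n_animals,
    n_cl = x$n_cl
  )
}

#' @rdname recovery_ratio
#' @param x A `recovery_result` object.
#' @param ... Unused.
#' @method tidy recovery_result
#' @export
tidy.recovery_result <- function(x, ...) {
  x$per_animal
}

#' @rdname recovery_ratio
#' @method glance recovery_result
#' @export
glance.recovery_result <- function(x, ...) {
  tibble::tibble(
    mean_recovery_ratio = x$mean_recovery_ratio,
    sd_recovery_ratio = x$sd_recovery_ratio,
    control_mean_rate = x$control_mean_rate,
    n_heat_shock = x$n_heat_shock,
    n_control = x$n_control
  )
}

#' @rdname summarize_puncta
#' @param x A `puncta_summary` object.
#' @param ... Unused.
#' @method tidy puncta_summary
#' @export
tidy.puncta_summary <- function(x, ...) {
  x$per_punctum
}

#' @rdname summarize_puncta
#' @method glance puncta_summary
#' @export
glance.puncta_summary <- function(x, ...) {
  tibble::tibble(
    mean_intensity = x$mean_intensity,
    mean_area = x$mean_area,
    n_puncta = x$n_puncta,
    equal_roi = x$equal_roi
  )
}

#' @rdname extract_bends
#' @param x A `bend_summary` tibble.
#' @param ... Unused.
#' @method glance bend_summary
#' @export
glance.bend_summary <- function(x, ...) {
  ventral <- x$angle_deg[x$side == "ventral"]
  dorsal <- x$angle_deg[x$side == "dorsal"]
  tibble::tibble(
    mean_ventral_deg = if (length(ventral)) mean(ventral) else NA_real_,
    mean_dorsal_deg = if (length(dorsal)) mean(dorsal) else NA_real_,
    mean_dorsal_mag_deg = if (length(dorsal)) mean(abs(dorsal)) else NA_real_,
    n_ventral = length(ventral),
    n_dorsal = length(dorsal)
  )
}
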