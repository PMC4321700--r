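#' Assay configuration
#'
#' Bundles the plate and assay constants used across the analyses. The
#' defaults describe the standard exploratory assay: a 9 cm plate, ten
#' worms scored per assay, a 20 minute (1200 s) tracking window for the
#' fixed-time curving summary, and a 30 mm fixed distance which is also
#' the total analysed length L0 of the coarse-graining analysis.
#'
#' @param plate_diameter_mm Assay plate diameter in mm.
#' @param assay_duration_s Assay duration in seconds.
#' @param worms_per_assay Number of worms scored per assay.
#' @param fixed_time_window_s Window for fixed-time curving averages, seconds.
#' @param fixed_distance_mm Fixed path distance for per-track averages and
#'   the L0 of the coarse-graining analysis, mm.
#' @return A list of class `assay_config`.
#' @export
assay_config <- function(plate_diameter_mm = 90,
                         assay_duration_s = 1200,
                         worms_per_assay = 10,
                         fixed_time_window_s = 1200,
                         fixed_distance_mm = 30) {
  check_positive(plate_diameter_mm, "plate_diameter_mm")
  check_positive(assay_duration_s, "assay_duration_s")
  check_positive(worms_per_assay, "worms_per_assay")
  check_positive(fixed_time_window_s, "fixed_time_window_s")
  check_positive(fixed_distance_mm, "fixed_distance_mm")
  structure(
    list(
      plate_diameter_mm = plate_diameter_mm,
      assay_duration_s = assay_duration_s,
      worms_per_assay = as.integer(worms_per_assay),
      fixed_time_window_s = fixed_time_window_s,
      fixed_distance_mm = fixed_distance_mm
    ),
    class = "assay_config"
  )
}

parse_ventral <- function(v) {
  if (is.logical(v)) return(v)
  s <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% c("true", "t", "1", "yes", "left")] <- TRUE
  out[s %in% c("false", "f", "0", "no", "right")] <- FALSE
  as.logical(out)
}

convert_numeric_col <- function(values, col, path) {
  out <- suppressWarnings(as.numeric(values))
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    # +1 for the header row: report the physical line in the file
    abort_wormloop(
      sprintf(
        "Non-numeric value in column `%s` of '%s' at line(s) %s.",
        col, path, paste(bad + 1L, collapse = ", ")
      ),
      "wormloop_parse_error"
    )
  }
  out
}

#' Read centroid trajectories from delimited text
#'
#' Reads multi-worm tracker output: one row per captured frame with an
#' animal identifier, time in seconds, and centroid coordinates in mm.
#' Comma and tab delimiters are autodetected from the header row.
#' Expected columns are `animal_id`, `t_s`, `x_mm`, `y_mm` and an
#' optional `ventral_is_left` (true/false/unknown — whether the animal's
#' ventral side lies to the left of its heading). Rows are grouped by
#' animal and sorted by time; duplicated timestamps within an animal keep
#' the first observation and drop the rest with a warning. Deviations of
#' the median sampling interval from the nominal 1 s capture interval are
#' reported, not fatal.
#'
#' @param path Path to a delimited text file.
#' @param config An [assay_config()] (currently informational).
#' @param nominal_dt_s Nominal sampling interval in seconds.
#' @param dt_tol Relative tolerance on the median sampling interval before
#'   a note is emitted.
#' @return A tibble with columns `animal_id`, `t_s`, `x_mm`, `y_mm`,
#'   `ventral_is_left` (logical, `NA` = unknown) and `excluded` (logical).
#' @seealso [write_trajectories()], [flag_crossings()]
#' @export
read_trajectories <- function(path, config = assay_config(),
                              nominal_dt_s = 1.0, dt_tol = 0.25) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  required <- c("animal_id", "t_s", "x_mm", "y_mm")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    abort_wormloop(
      sprintf("File '%s' is missing required column(s): %s.",
              path, paste(missing, collapse = ", ")),
      "wormloop_format_error"
    )
  }
  out <- tibble::tibble(
    animal_id = as.character(raw$animal_id),
    t_s = convert_numeric_col(raw$t_s, "t_s", path),
    x_mm = convert_numeric_col(raw$x_mm, "x_mm", path),
    y_mm = convert_numeric_col(raw$y_mm, "y_mm", path),
    ventral_is_left = if ("ventral_is_left" %in% names(raw)) {
      parse_ventral(raw$ventral_is_left)
    } else {
      NA
    },
    excluded = FALSE
  )
  out <- by_animal(out, function(tr) {
    tr <- tr[order(tr$t_s), , drop = FALSE]
    dup <- duplicated(tr$t_s)
    if (any(dup)) {
      rlang::warn(sprintf(
        "Animal '%s': dropped %d duplicated timestamp(s), keeping the first.",
        tr$animal_id[1], sum(dup)
      ))
      tr <- tr[!dup, , drop = FALSE]
    }
    if (nrow(tr) >= 2L) {
      dt <- stats::median(diff(tr$t_s))
      if (abs(dt - nominal_dt_s) > dt_tol * nominal_dt_s) {
        rlang::inform(sprintf(
          "Animal '%s': median sampling interval %.3f s differs from the nominal %.3f s.",
          tr$animal_id[1], dt, nominal_dt_s
        ))
      }
    }
    tr
  })
  validate_trajectories(out)
  out
}

#' Write trajectories to delimited text
#'
#' Inverse of [read_trajectories()]: coordinates are written with full
#' round-trip precision and the ventral-side metadata is preserved
#' (`TRUE`/`FALSE`/`NA`).
#'
#' @param trajs Trajectory tibble as returned by [read_trajectories()] or
#'   [simulate_trajectory()].
#' @param path Output file path.
#' @param delim Field delimiter, `","` or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path, delim = ",") {
  validate_trajectories(trajs)
  cols <- intersect(c("animal_id", "t_s", "x_mm", "y_mm", "ventral_is_left"),
                    names(trajs))
  readr::write_delim(trajs[cols], path, delim = delim, na = "NA",
                     progress = FALSE)
  invisible(path)
}

# Structural checks on a trajectory table: required columns present,
# coordinates finite, time strictly increasing within each animal.
validate_trajectories <- function(trajs) {
  required <- c("animal_id", "t_s", "x_mm", "y_mm")
  missing <- setdiff(required, names(trajs))
  if (length(missing) > 0L) {
    abort_wormloop(
      sprintf("Trajectory table is missing column(s): %s.",
              paste(missing, collapse = ", ")),
      "wormloop_format_error"
    )
  }
  if (!all(is.finite(trajs$x_mm)) || !all(is.finite(trajs$y_mm)) ||
      !all(is.finite(trajs$t_s))) {
    abort_wormloop("Trajectory coordinates and times must be finite.",
                   "wormloop_format_error")
  }
  bad <- vapply(split(trajs$t_s, trajs$animal_id),
                function(t) any(diff(t) <= 0), logical(1))
  if (any(bad)) {
    abort_wormloop(
      sprintf("Time must be strictly increasing within each animal (violated for: %s).",
              paste(names(bad)[bad], collapse = ", ")),
      "wormloop_format_error"
    )
  }
  invisible(trajs)
}

#' Per-animal path summaries
#'
#' @param trajs Trajectory tibble.
#' @return A tibble with one row per animal: total path length `path_mm`,
#'   straight-line start-to-end distance `net_mm`, covered `duration_s`
#'   and the number of samples.
#' @export
path_lengths <- function(trajs) {
  validate_trajectories(trajs)
  by_animal(trajs, function(tr) {
    tibble::tibble(
      animal_id = tr$animal_id[1],
      path_mm = sum(sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2)),
      net_mm = sqrt((tr$x_mm[nrow(tr)] - tr$x_mm[1])^2 +
                      (tr$y_mm[nrow(tr)] - tr$y_mm[1])^2),
      duration_s = tr$t_s[nrow(tr)] - tr$t_s[1],
      n_samples = nrow(tr)
    )
  })
}

#' Flag animals that crossed each other
#'
#' Animals whose tracks cross contaminate centroid tracking, so both
#' members of any close encounter are excluded from analysis. Two tracks
#' are compared on their overlapping time range (positions linearly
#' interpolated to a common set of sample times); if the centroids come
#' within `min_separation_mm` of each other, both animals are marked
#' `excluded = TRUE`. The default threshold is roughly one adult body
#' width. A single trajectory passes through unchanged.
#'
#' @param trajs Trajectory tibble (possibly several animals).
#' @param min_separation_mm Centroid separation at or below which two
#'   animals count as crossing, mm.
#' @return The input tibble, original row order preserved, with
#'   `excluded` updated.
#' @export
flag_crossings <- function(trajs, min_separation_mm = 1.0) {
  validate_trajectories(trajs)
  check_positive(min_separation_mm, "min_separation_mm")
  if (!"excluded" %in% names(trajs)) trajs$excluded <- FALSE
  ids <- unique(trajs$animal_id)
  if (length(ids) < 2L) return(trajs)
  tracks <- lapply(ids, function(id) trajs[trajs$animal_id == id, , drop = FALSE])
  names(tracks) <- ids
  hit <- stats::setNames(rep(FALSE, length(ids)), ids)
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      a <- tracks[[i]]
      b <- tracks[[j]]
      lo <- max(min(a$t_s), min(b$t_s))
      hi <- min(max(a$t_s), max(b$t_s))
      if (lo > hi) next
      tt <- sort(unique(c(a$t_s[a$t_s >= lo & a$t_s <= hi],
                          b$t_s[b$t_s >= lo & b$t_s <= hi])))
      if (length(tt) == 0L) next
      ax <- stats::approx(a$t_s, a$x_mm, xout = tt, ties = "ordered")$y
      ay <- stats::approx(a$t_s, a$y_mm, xout = tt, ties = "ordered")$y
      bx <- stats::approx(b$t_s, b$x_mm, xout = tt, ties = "ordered")$y
      by <- stats::approx(b$t_s, b$y_mm, xout = tt, ties = "ordered")$y
      if (min(sqrt((ax - bx)^2 + (ay - by)^2)) <= min_separation_mm) {
        hit[i] <- TRUE
        hit[j] <- TRUE
      }
    }
  }
  trajs$excluded <- trajs$excluded | hit[trajs$animal_id]
  trajs
}

truncate_one <- function(tr, L0, tol = 1e-9) {
  s <- cum_arc(tr$x_mm, tr$y_mm)
  total <- s[length(s)]
  if (total < L0 - tol) {
    abort_wormloop(
      sprintf("Animal '%s': track too short (path length %.4f mm < L0 = %.4f mm).",
              tr$animal_id[1], total, L0),
      "wormloop_short_track",
      path_mm = total
    )
  }
  if (total <= L0 + tol) return(tr)
  keep <- s < L0 - tol
  cut <- interp_at_arc(tr$x_mm, tr$y_mm, L0, t = tr$t_s)
  out <- tr[keep, , drop = FALSE]
  end <- tr[1, , drop = FALSE]
  end$t_s <- cut$t
  end$x_mm <- cut$x
  end$y_mm <- cut$y
  dplyr::bind_rows(out, end)
}

#' Truncate each track to a fixed path length
#'
#' Restricts each animal's track to its first `L0` millimetres of
#' advancement, the preprocessing step behind fixed-distance summaries
#' ("the first 30 mm of each track"). The final point is obtained by
#' linear interpolation along the last segment, so the returned path
#' length equals `L0` up to interpolation tolerance. Truncation is
#' idempotent at the same `L0`.
#'
#' @param trajs Trajectory tibble.
#' @param L0 Target path length, mm (default 30).
#' @return Trajectory tibble truncated per animal.
#' @export
truncate_by_path_length <- function(trajs, L0 = 30) {
  validate_trajectories(trajs)
  check_positive(L0, "L0")
  by_animal(trajs, truncate_one, L0 = L0)
}
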