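# Head-bend kinematics: the head angle is the angle between the line
# from the worm centroid to the pharynx terminal bulb and the line from
# the terminal bulb to the nose tip, sampled every 500 ms; ventral bends
# are positive, dorsal bends negative.

#' Read head-landmark pose series from delimited text
#'
#' Expected columns: `animal_id`, `t_s`, and the landmark coordinates in
#' mm — centroid (`cx`, `cy`), pharynx terminal bulb (`bx`, `by`), nose
#' tip (`nx`, `ny`) — plus an optional `ventral_is_left`.
#'
#' @param path Path to a comma- or tab-delimited file.
#' @return A pose tibble.
#' @export
read_head_poses <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  required <- c("animal_id", "t_s", "cx", "cy", "bx", "by", "nx", "ny")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    abort_wormloop(
      sprintf("File '%s' is missing required column(s): %s.",
              path, paste(missing, collapse = ", ")),
      "wormloop_format_error"
    )
  }
  out <- tibble::tibble(animal_id = as.character(raw$animal_id))
  for (col in required[-1]) {
    out[[col]] <- convert_numeric_col(raw[[col]], col, path)
  }
  out$ventral_is_left <- if ("ventral_is_left" %in% names(raw)) {
    parse_ventral(raw$ventral_is_left)
  } else {
    NA
  }
  out
}

#' Signed head angle from three landmarks
#'
#' The unsigned angle is measured between the vector from centroid to
#' terminal bulb and the vector from terminal bulb to nose tip; the sign
#' comes from the cross-product orientation, mapped so that bends toward
#' the ventral side are positive when `ventral_is_left` is known
#' (ventral on the left of the body axis makes a counter-clockwise nose
#' deflection ventral-ward). With unknown ventral side the
#' counter-clockwise-positive convention is kept. The angle is invariant
#' under rigid motions and uniform scaling of the landmarks; mirror
#' reflection negates it. Vectorised over frames.
#'
#' @param cx,cy Centroid coordinates, mm.
#' @param bx,by Pharynx terminal-bulb coordinates, mm.
#' @param nx,ny Nose-tip coordinates, mm.
#' @param ventral_is_left Logical (NA = unknown).
#' @param eps_landmark Minimum pairwise landmark separation, mm.
#' @return Signed angle(s) in (-180, 180] degrees.
#' @examples
#' head_angle(0, 0, 1, 0, 1, 1, ventral_is_left = TRUE)  # +90
#' @export
head_angle <- function(cx, cy, bx, by, nx, ny, ventral_is_left = NA,
                       eps_landmark = 1e-6) {
  v1x <- bx - cx; v1y <- by - cy
  v2x <- nx - bx; v2y <- ny - by
  d1 <- sqrt(v1x^2 + v1y^2)
  d2 <- sqrt(v2x^2 + v2y^2)
  dcn <- sqrt((nx - cx)^2 + (ny - cy)^2)
  if (any(d1 <= eps_landmark | d2 <= eps_landmark | dcn <= eps_landmark)) {
    abort_wormloop("Degenerate pose: landmarks are not pairwise distinct.",
                   "wormloop_degenerate")
  }
  ang <- rad2deg(atan2(v1x * v2y - v1y * v2x, v1x * v2x + v1y * v2y))
  ang <- wrap_deg(ang)  # enforce the +180 tie-break at exact reversals
  flip <- ifelse(is.na(ventral_is_left), 1, ifelse(ventral_is_left, 1, -1))
  ang * flip
}

#' Head-angle series from a pose table
#'
#' Computes the signed head angle frame by frame; frames with
#' degenerate (coincident) landmarks are dropped with a warning rather
#' than aborting the series.
#'
#' @param poses Pose tibble (see [read_head_poses()] or
#'   [simulate_head_wave()]).
#' @param eps_landmark Minimum pairwise landmark separation, mm.
#' @return A tibble with `animal_id`, `t_s`, `angle_deg` and
#'   `sign_convention` (`"ventral_positive"` or `"ccw_positive"`).
#' @export
head_angle_series <- function(poses, eps_landmark = 1e-6) {
  required <- c("animal_id", "t_s", "cx", "cy", "bx", "by", "nx", "ny")
  missing <- setdiff(required, names(poses))
  if (length(missing) > 0L) {
    abort_wormloop(
      sprintf("Pose table is missing column(s): %s.",
              paste(missing, collapse = ", ")),
      "wormloop_format_error"
    )
  }
  if (!"ventral_is_left" %in% names(poses)) poses$ventral_is_left <- NA
  by_animal(poses, function(p) {
    if (nrow(p) < 2L) {
      abort_wormloop(
        sprintf("Animal '%s': need at least 2 frames.", p$animal_id[1]),
        "wormloop_degenerate"
      )
    }
    d1 <- sqrt((p$bx - p$cx)^2 + (p$by - p$cy)^2)
    d2 <- sqrt((p$nx - p$bx)^2 + (p$ny - p$by)^2)
    d3 <- sqrt((p$nx - p$cx)^2 + (p$ny - p$cy)^2)
    ok <- d1 > eps_landmark & d2 > eps_landmark & d3 > eps_landmark
    if (any(!ok)) {
      rlang::warn(sprintf(
        "Animal '%s': dropped %d frame(s) with degenerate landmarks.",
        p$animal_id[1], sum(!ok)
      ))
      p <- p[ok, , drop = FALSE]
    }
    vil <- p$ventral_is_left[1]
    tibble::tibble(
      animal_id = p$animal_id[1],
      t_s = p$t_s,
      angle_deg = head_angle(p$cx, p$cy, p$bx, p$by, p$nx, p$ny,
                             ventral_is_left = vil,
                             eps_landmark = eps_landmark),
      sign_convention = if (is.na(vil)) "ccw_positive" else "ventral_positive"
    )
  })
}

# Topographic prominence of local maxima of `v` at indices `peaks`:
# walk outward from each peak until a strictly higher value (or the
# series end); the prominence is the peak height above the higher of
# the two valley minima found on the way.
peak_prominence <- function(v, peaks) {
  n <- length(v)
  vapply(peaks, function(p) {
    left_min <- v[p]
    i <- p - 1L
    while (i >= 1L && v[i] <= v[p]) {
      left_min <- min(left_min, v[i])
      i <- i - 1L
    }
    right_min <- v[p]
    i <- p + 1L
    while (i <= n && v[i] <= v[p]) {
      right_min <- min(right_min, v[i])
      i <- i + 1L
    }
    # whichever side found a higher value (or the edge) bounds the
    # prominence by its valley minimum
    v[p] - max(left_min, right_min)
  }, numeric(1))
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Extract ventral and dorsal head bends
#'
#' A bend is a prominent local extremum of the head-angle series:
#' positive maxima are ventral bends, negative minima are dorsal bends,
#' and only extrema with topographic prominence of at least
#' `prominence_deg` qualify (small wiggles riding on a bend are not
#' separate bends). A series with no qualifying extrema yields an empty
#' summary, not an error.
#'
#' @param series Head-angle tibble from [head_angle_series()].
#' @param prominence_deg Minimum prominence of a bend, degrees.
#' @return A tibble of class `bend_summary`: one row per bend with
#'   `animal_id`, `t_s`, `angle_deg` and `side` ("ventral"/"dorsal").
#'   Use [glance()] for per-class means and counts (the dorsal mean is
#'   reported both signed and as a magnitude).
#' @examples
#' poses <- simulate_head_wave(head_wave_config(ventral_amp_deg = 20,
#'                                              dorsal_amp_deg = 35))
#' bends <- extract_bends(head_angle_series(poses))
#' glance(bends)
#' @export
extract_bends <- function(series, prominence_deg = 10) {
  check_positive(prominence_deg, "prominence_deg")
  if (nrow(series) < 3L) {
    abort_wormloop("Need at least 3 samples to extract bends.",
                   "wormloop_degenerate")
  }
  out <- by_animal(series, function(s) {
    v <- s$angle_deg
    up <- local_maxima(v)
    dn <- local_maxima(-v)
    up <- up[v[up] > 0]
    dn <- dn[v[dn] < 0]
    up <- up[peak_prominence(v, up) >= prominence_deg]
    dn <- dn[peak_prominence(-v, dn) >= prominence_deg]
    idx <- c(up, dn)
    if (length(idx) == 0L) {
      return(tibble::tibble(animal_id = character(0), t_s = numeric(0),
                            angle_deg = numeric(0), side = character(0)))
    }
    ord <- order(idx)
    tibble::tibble(
      animal_id = s$animal_id[1],
      t_s = s$t_s[idx][ord],
      angle_deg = v[idx][ord],
      side = c(rep("ventral", length(up)), rep("dorsal", length(dn)))[ord]
    )
  })
  class(out) <- c("bend_summary", class(out))
  out
}
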