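# Detection of loopy track segments (closed circles under a diameter
# bound) and classification of circular locomotion (CL): an animal is CL
# when loopy segments cover at least 30% of its track.

#' Classifier configuration for circular locomotion
#'
#' The two thresholds with a documented basis are
#' `max_loop_diameter_mm = 10` (loopy trajectories are parts of tracks
#' forming closed circles with a diameter under 1 cm) and
#' `loopy_fraction_threshold = 0.30` (an animal is CL when loopy
#' segments cover at least 30% of its track; the inclusive form is
#' used). The remaining knobs operationalise "closed circle" for
#' automated scoring of centroid tracks and are reported with results:
#' a closure is a return to within `closure_eps_mm` of an earlier point
#' after at least `min_loop_path_mm` of path, and a closed sub-path only
#' counts as a loop if its net signed turning reaches
#' `min_net_turn_deg` (so incidental track crossings do not count).
#' "Continuously only in a loopy pattern" (the strong class) is
#' operationalised as a loopy fraction of at least
#' `strong_fraction_threshold`, slightly below 1 to tolerate closure
#' gaps between consecutive circuits.
#'
#' @param max_loop_diameter_mm Maximum enclosing-circle diameter of a
#'   loop, mm.
#' @param loopy_fraction_threshold Loopy path fraction at or above which
#'   an animal is classified CL.
#' @param strong_fraction_threshold Loopy fraction at or above which the
#'   class is "strong" rather than "mild".
#' @param closure_eps_mm Maximum spatial gap for a closure, mm.
#' @param min_loop_path_mm Minimum path length of a loop, mm.
#' @param min_net_turn_deg Minimum absolute net signed turning of a
#'   loop, degrees.
#' @param min_step_mm Step-retention threshold used when accumulating
#'   net turning (see [compute_curving()]).
#' @param diameter_method `"mec"` computes the exact minimal enclosing
#'   circle of the sub-path's samples; `"max_pairwise"` is a cheaper
#'   alternative using the largest pairwise distance (which can
#'   underestimate the enclosing diameter by up to 2/sqrt(3)).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(max_loop_diameter_mm = 10.0,
                              loopy_fraction_threshold = 0.30,
                              strong_fraction_threshold = 0.95,
                              closure_eps_mm = 0.5,
                              min_loop_path_mm = 3.0,
                              min_net_turn_deg = 330,
                              min_step_mm = 0.05,
                              diameter_method = c("mec", "max_pairwise")) {
  check_positive(max_loop_diameter_mm, "max_loop_diameter_mm")
  check_positive(closure_eps_mm, "closure_eps_mm")
  check_positive(min_loop_path_mm, "min_loop_path_mm")
  check_positive(min_net_turn_deg, "min_net_turn_deg")
  check_probability(loopy_fraction_threshold, "loopy_fraction_threshold")
  check_probability(strong_fraction_threshold, "strong_fraction_threshold")
  if (loopy_fraction_threshold >= strong_fraction_threshold) {
    abort_wormloop(
      "`loopy_fraction_threshold` must be below `strong_fraction_threshold`.",
      "wormloop_parameter_error"
    )
  }
  structure(
    list(
      max_loop_diameter_mm = max_loop_diameter_mm,
      loopy_fraction_threshold = loopy_fraction_threshold,
      strong_fraction_threshold = strong_fraction_threshold,
      closure_eps_mm = closure_eps_mm,
      min_loop_path_mm = min_loop_path_mm,
      min_net_turn_deg = min_net_turn_deg,
      min_step_mm = min_step_mm,
      diameter_method = match.arg(diameter_method)
    ),
    class = "classifier_config"
  )
}

circle_from_2 <- function(p, q) {
  c((p + q) / 2, sqrt(sum((p - q)^2)) / 2)
}

circle_from_3 <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) {
    # collinear: the diametric circle of the farthest pair encloses all three
    pairs <- list(circle_from_2(a, b), circle_from_2(a, c), circle_from_2(b, c))
    return(pairs[[which.max(vapply(pairs, function(z) z[3], numeric(1)))]])
  }
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, sqrt((a[1] - ux)^2 + (a[2] - uy)^2))
}

circle_contains <- function(circ, p, tol) {
  sqrt((p[1] - circ[1])^2 + (p[2] - circ[2])^2) <= circ[3] * (1 + tol) + tol
}

#' Minimal enclosing circle of a planar point set
#'
#' Exact smallest enclosing circle via the randomized incremental
#' (Welzl-style) algorithm, expected linear time. The point order is
#' shuffled with an internal fixed seed so results are deterministic and
#' the caller's RNG state is untouched.
#'
#' @param x,y Point coordinates.
#' @return Named numeric vector `c(cx, cy, r)`.
#' @export
min_enclosing_circle <- function(x, y) {
  n <- length(x)
  if (n == 0L) abort_wormloop("Empty point set.", "wormloop_parameter_error")
  if (n == 1L) return(c(cx = x[1], cy = y[1], r = 0))
  ord <- withr::with_seed(8191L, sample.int(n))
  P <- cbind(x, y)[ord, , drop = FALSE]
  tol <- 1e-9
  circ <- circle_from_2(P[1, ], P[2, ])
  for (i in seq_len(n)[-(1:2)]) {
    if (circle_contains(circ, P[i, ], tol)) next
    circ <- circle_from_2(P[1, ], P[i, ])
    for (j in 2:(i - 1L)) {
      if (circle_contains(circ, P[j, ], tol)) next
      circ <- circle_from_2(P[j, ], P[i, ])
      if (j > 1L) {
        for (k in seq_len(j - 1L)) {
          if (circle_contains(circ, P[k, ], tol)) next
          circ <- circle_from_3(P[k, ], P[j, ], P[i, ])
        }
      }
    }
  }
  c(cx = unname(circ[1]), cy = unname(circ[2]), r = unname(circ[3]))
}

subpath_diameter <- function(x, y, method) {
  if (method == "mec") {
    unname(2 * min_enclosing_circle(x, y)["r"])
  } else {
    max(stats::dist(cbind(x, y)))
  }
}

net_turn_deg <- function(x, y, min_step_mm) {
  keep <- retain_indices(x, y, min_step_mm)
  if (length(keep) < 3L) return(0)
  dx <- diff(x[keep])
  dy <- diff(y[keep])
  sum(wrap_deg(diff(rad2deg(atan2(dy, dx)))))
}

detect_loops_one <- function(tr, cfg) {
  n <- nrow(tr)
  if (n < 3L) {
    abort_wormloop(
      sprintf("Animal '%s': degenerate track.", tr$animal_id[1]),
      "wormloop_degenerate"
    )
  }
  x <- tr$x_mm
  y <- tr$y_mm
  s <- cum_arc(x, y)
  eps2 <- cfg$closure_eps_mm^2
  # first index whose arc length is at least min_loop_path beyond each i
  jmin <- findInterval(s + cfg$min_loop_path_mm, s, left.open = TRUE) + 1L
  intervals <- list()
  i <- 1L
  while (i < n) {
    j0 <- jmin[i]
    if (j0 > n) break
    d2 <- (x[j0:n] - x[i])^2 + (y[j0:n] - y[i])^2
    hit <- which(d2 <= eps2)
    if (length(hit) == 0L) {
      i <- i + 1L
      next
    }
    j <- j0 + hit[1L] - 1L
    sub <- i:j
    # bounding-box pre-check: the enclosing diameter is at least the
    # larger box extent, and extending j only grows the sub-path
    ext <- max(diff(range(x[sub])), diff(range(y[sub])))
    if (ext < cfg$max_loop_diameter_mm) {
      diam <- subpath_diameter(x[sub], y[sub], cfg$diameter_method)
      if (diam < cfg$max_loop_diameter_mm) {
        turn <- net_turn_deg(x[sub], y[sub], cfg$min_step_mm)
        if (abs(turn) >= cfg$min_net_turn_deg) {
          intervals[[length(intervals) + 1L]] <-
            c(start = s[i], end = s[j], diameter = diam, turn = turn)
          i <- j  # resume the scan at the closure point
          next
        }
      }
    }
    i <- i + 1L
  }
  if (length(intervals) == 0L) {
    return(tibble::tibble(
      animal_id = character(0), start_mm = numeric(0), end_mm = numeric(0),
      diameter_mm = numeric(0), net_turn_deg = numeric(0)
    ))
  }
  m <- do.call(rbind, intervals)
  m <- m[order(m[, "start"]), , drop = FALSE]
  # merge overlapping or touching intervals into maximal loopy stretches
  merged <- list(m[1, ])
  if (nrow(m) > 1L) {
    for (r in 2:nrow(m)) {
      last <- merged[[length(merged)]]
      if (m[r, "start"] <= last["end"] + 1e-9) {
        last["end"] <- max(last["end"], m[r, "end"])
        last["diameter"] <- max(last["diameter"], m[r, "diameter"])
        last["turn"] <- last["turn"] + m[r, "turn"]
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1L]] <- m[r, ]
      }
    }
  }
  mm <- do.call(rbind, merged)
  tibble::tibble(
    animal_id = tr$animal_id[1],
    start_mm = unname(mm[, "start"]),
    end_mm = unname(mm[, "end"]),
    diameter_mm = unname(mm[, "diameter"]),
    net_turn_deg = unname(mm[, "turn"])
  )
}

#' Detect loopy track segments
#'
#' Scans each track for closures — returns to within `closure_eps_mm` of
#' an earlier position after at least `min_loop_path_mm` of path
#' (earliest closure first) — and accepts a closed sub-path as a loop
#' when its minimal-enclosing-circle diameter is below
#' `max_loop_diameter_mm` and its net signed turning reaches
#' `min_net_turn_deg`. Overlapping or touching loops (consecutive
#' circuits of the same loop) are merged into maximal intervals.
#'
#' @param trajs Trajectory tibble.
#' @param cfg A [classifier_config()].
#' @return A tibble of loop intervals per animal: `start_mm`, `end_mm`
#'   (arc-length positions), `diameter_mm` and `net_turn_deg` (summed
#'   over merged circuits).
#' @export
detect_loops <- function(trajs, cfg = classifier_config()) {
  validate_trajectories(trajs)
  stopifnot(inherits(cfg, "classifier_config"))
  by_animal(trajs, detect_loops_one, cfg = cfg)
}

#' Classify circular locomotion per animal
#'
#' The loopy path fraction is the arc length covered by merged loop
#' intervals divided by the total track length. Animals are classed
#' `strong` (fraction at or above `strong_fraction_threshold`), `mild`
#' (between the CL threshold and strong), or `normal`; CL comprises
#' strong and mild.
#'
#' @param trajs Trajectory tibble.
#' @param cfg A [classifier_config()].
#' @return A tibble of class `loop_report`: one row per animal with
#'   `n_loops`, `loopy_path_mm`, `total_path_mm`, `loopy_fraction`,
#'   `cl_class` (factor strong/mild/normal) and `is_cl`. Excluded
#'   animals (crossing-contaminated) are dropped with a message.
#' @examples
#' tr <- simulate_trajectory(walk_config(bias_deg_per_mm = -12,
#'                                       duration_s = 600))
#' classify_cl(tr)
#' @export
classify_cl <- function(trajs, cfg = classifier_config()) {
  validate_trajectories(trajs)
  stopifnot(inherits(cfg, "classifier_config"))
  if ("excluded" %in% names(trajs) && any(trajs$excluded)) {
    dropped <- unique(trajs$animal_id[trajs$excluded])
    rlang::inform(sprintf("Dropping %d excluded animal(s): %s.",
                          length(dropped), paste(dropped, collapse = ", ")))
    trajs <- trajs[!trajs$excluded, , drop = FALSE]
  }
  out <- by_animal(trajs, function(tr) {
    loops <- detect_loops_one(tr, cfg)
    total <- sum(sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2))
    loopy <- if (nrow(loops) > 0) sum(loops$end_mm - loops$start_mm) else 0
    frac <- loopy / total
    cl_class <- if (frac >= cfg$strong_fraction_threshold) {
      "strong"
    } else if (frac >= cfg$loopy_fraction_threshold) {
      "mild"
    } else {
      "normal"
    }
    tibble::tibble(
      animal_id = tr$animal_id[1],
      n_loops = nrow(loops),
      loopy_path_mm = loopy,
      total_path_mm = total,
      loopy_fraction = frac,
      cl_class = factor(cl_class, levels = c("strong", "mild", "normal")),
      is_cl = cl_class %in% c("strong", "mild")
    )
  })
  class(out) <- c("loop_report", class(out))
  out
}

#' Per-assay proportion of animals exhibiting circular locomotion
#'
#' Animals are grouped, in the order given, into assays of
#' `worms_per_assay` (ten worms counted per assay by default) and the
#' percentage of CL animals is computed per assay, together with the
#' mean across assays and the pooled percentage over all animals.
#'
#' @param reports A `loop_report` tibble from [classify_cl()], or any
#'   data frame with an `is_cl` logical column.
#' @param worms_per_assay Animals per assay.
#' @param allow_partial Allow a final short assay group.
#' @return An object of class `cl_assay_summary`; use [tidy()] for the
#'   per-assay table and [glance()] for the one-row cohort summary.
#' @export
assay_cl_proportion <- function(reports, worms_per_assay = 10,
                                allow_partial = FALSE) {
  if (!is.data.frame(reports) || !"is_cl" %in% names(reports)) {
    abort_wormloop("`reports` must contain an `is_cl` column.",
                   "wormloop_format_error")
  }
  n <- nrow(reports)
  if (n == 0L) {
    abort_wormloop("Empty report table.", "wormloop_parameter_error")
  }
  check_positive(worms_per_assay, "worms_per_assay")
  worms_per_assay <- as.integer(worms_per_assay)
  if (n %% worms_per_assay != 0L && !allow_partial) {
    abort_wormloop(
      sprintf("%d animals do not divide into assays of %d (set allow_partial = TRUE).",
              n, worms_per_assay),
      "wormloop_parameter_error"
    )
  }
  assay <- (seq_len(n) - 1L) %/% worms_per_assay + 1L
  per_assay <- tibble::tibble(assay = assay, is_cl = reports$is_cl) |>
    dplyr::group_by(.data$assay) |>
    dplyr::summarise(
      n_worms = dplyr::n(),
      n_cl = sum(.data$is_cl),
      pct_cl = 100 * mean(.data$is_cl),
      .groups = "drop"
    )
  structure(
    list(
      per_assay = per_assay,
      mean_pct_cl = mean(per_assay$pct_cl),
      pooled_pct_cl = 100 * mean(reports$is_cl),
      n_assays = nrow(per_assay),
      n_animals = n,
      n_cl = sum(reports$is_cl)
    ),
    class = "cl_assay_summary"
  )
}

#' @export
print.cl_assay_summary <- function(x, ...) {
  cat(sprintf(
    "Circular locomotion: %d/%d animals CL (%.1f%% pooled; mean of %d assay(s): %.1f%%)\n",
    x$n_cl, x$n_animals, x$pooled_pct_cl, x$n_assays, x$mean_pct_cl
  ))
  print(x$per_assay)
  invisible(x)
}
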