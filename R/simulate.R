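# Synthetic data generators. These emulate the statistical structure the
# analyses assume — a correlated random walk with signed turning bias and
# loopy bouts, an asymmetric head oscillation with invertible landmark
# geometry, and photobleach/recovery intensity triples — so every
# downstream module can be exercised and validated without animal data.

#' Configuration for the correlated-random-walk simulator
#'
#' The walker advances at constant speed and turns each step by
#' (regime bias + Gaussian noise) x step advancement, i.e. the bias and
#' noise are expressed per unit path length (deg/mm), matching the
#' per-length definition of the curving rate. A two-state Markov chain
#' toggles between a "normal" regime (using `bias_deg_per_mm`) and a
#' "loopy" regime (using `loopy_bias_deg_per_mm`) with probability
#' `bout_switch_prob` per step, emulating animals that show both normal
#' and loopy locomotion in bouts. Positive bias means ventral-ward
#' curving (the simulated animal's ventral side is to the left of its
#' heading); a constant bias b with zero noise closes onto a circle of
#' diameter 360 / (pi * |b|) mm.
#'
#' @param speed_mm_per_s Crawling speed, mm/s.
#' @param step_s Sampling interval, seconds.
#' @param bias_deg_per_mm Mean signed curving rate in the normal regime,
#'   deg/mm (ventral positive).
#' @param noise_deg_per_mm_sd SD of the per-step curving noise, deg/mm.
#' @param bout_switch_prob Per-step probability of toggling regimes.
#' @param loopy_bias_deg_per_mm Signed curving rate inside loopy bouts.
#' @param duration_s Track duration, seconds.
#' @param seed Integer seed; identical configs give bitwise-identical
#'   trajectories.
#' @param start_regime `"normal"`, `"loopy"`, or `NULL` (the default) to
#'   choose automatically: a walker that can never switch
#'   (`bout_switch_prob = 0`) but has a loopy bias set is a permanent
#'   loopy-locomotion mutant and starts (and stays) in the loopy regime;
#'   every other walker starts in the normal regime.
#' @return A list of class `walk_config`.
#' @export
walk_config <- function(speed_mm_per_s = 0.15,
                        step_s = 1.0,
                        bias_deg_per_mm = 0,
                        noise_deg_per_mm_sd = 0,
                        bout_switch_prob = 0,
                        loopy_bias_deg_per_mm = 0,
                        duration_s = 1200,
                        seed = 1L,
                        start_regime = NULL) {
  check_positive(speed_mm_per_s, "speed_mm_per_s")
  check_positive(step_s, "step_s")
  check_positive(duration_s, "duration_s")
  check_probability(bout_switch_prob, "bout_switch_prob")
  if (noise_deg_per_mm_sd < 0) {
    abort_wormloop("`noise_deg_per_mm_sd` must be nonnegative.",
                   "wormloop_parameter_error")
  }
  if (is.null(start_regime)) {
    start_regime <- if (bout_switch_prob == 0 && loopy_bias_deg_per_mm != 0) {
      "loopy"
    } else {
      "normal"
    }
  }
  start_regime <- match.arg(start_regime, c("normal", "loopy"))
  structure(
    list(
      start_regime = start_regime,
      speed_mm_per_s = speed_mm_per_s,
      step_s = step_s,
      bias_deg_per_mm = bias_deg_per_mm,
      noise_deg_per_mm_sd = noise_deg_per_mm_sd,
      bout_switch_prob = bout_switch_prob,
      loopy_bias_deg_per_mm = loopy_bias_deg_per_mm,
      duration_s = duration_s,
      seed = as.integer(seed)
    ),
    class = "walk_config"
  )
}

#' Simulate one centroid trajectory
#'
#' @param cfg A [walk_config()].
#' @param animal_id Label for the simulated animal.
#' @return A trajectory tibble (`animal_id`, `t_s`, `x_mm`, `y_mm`,
#'   `ventral_is_left = TRUE`, `excluded = FALSE`, plus a `regime`
#'   column recording the regime active on the step leading into each
#'   sample).
#' @examples
#' # A dorsal-biased walker closes onto a 10 mm circle:
#' tr <- simulate_trajectory(walk_config(bias_deg_per_mm = -11.459,
#'                                       duration_s = 300))
#' @export
simulate_trajectory <- function(cfg, animal_id = "sim_1") {
  stopifnot(inherits(cfg, "walk_config"))
  n_steps <- floor(cfg$duration_s / cfg$step_s)
  if (n_steps < 2L) {
    abort_wormloop("`duration_s` must cover at least two steps.",
                   "wormloop_parameter_error")
  }
  step_mm <- cfg$speed_mm_per_s * cfg$step_s
  withr::with_seed(cfg$seed, {
    toggles <- stats::runif(n_steps) < cfg$bout_switch_prob
    loopy <- xor((cumsum(toggles) %% 2L) == 1L, cfg$start_regime == "loopy")
    bias <- ifelse(loopy, cfg$loopy_bias_deg_per_mm, cfg$bias_deg_per_mm)
    turn_deg <- (bias + stats::rnorm(n_steps, 0, cfg$noise_deg_per_mm_sd)) * step_mm
  })
  heading <- deg2rad(cumsum(turn_deg))  # turn applied before each advance
  x <- c(0, cumsum(step_mm * cos(heading)))
  y <- c(0, cumsum(step_mm * sin(heading)))
  tibble::tibble(
    animal_id = animal_id,
    t_s = seq(0, by = cfg$step_s, length.out = n_steps + 1L),
    x_mm = x,
    y_mm = y,
    ventral_is_left = TRUE,
    excluded = FALSE,
    regime = c("normal", ifelse(loopy, "loopy", "normal"))
  )
}

#' Simulate a labelled two-group cohort
#'
#' Generates `n_per_group` trajectories per group ("wt" and "mut"),
#' with per-animal seeds derived deterministically from `seed` so the
#' whole cohort is a pure function of its arguments.
#'
#' @param cfg_wt,cfg_mut [walk_config()]s for the two groups (their own
#'   `seed` fields are overridden by the derived per-animal seeds).
#' @param n_per_group Animals per group (>= 1).
#' @param seed Master seed.
#' @return A trajectory tibble with an extra `group` column.
#' @export
simulate_cohort <- function(cfg_wt, cfg_mut, n_per_group, seed = 1L) {
  stopifnot(inherits(cfg_wt, "walk_config"), inherits(cfg_mut, "walk_config"))
  if (!is.numeric(n_per_group) || n_per_group < 1) {
    abort_wormloop("`n_per_group` must be at least 1.",
                   "wormloop_parameter_error")
  }
  n_per_group <- as.integer(n_per_group)
  seeds <- derive_seeds(seed, 2L * n_per_group)
  sim_group <- function(cfg, label, seed_offset) {
    dplyr::bind_rows(lapply(seq_len(n_per_group), function(i) {
      cfg$seed <- seeds[seed_offset + i]
      tr <- simulate_trajectory(cfg, animal_id = sprintf("%s_%02d", label, i))
      tr$group <- label
      tr
    }))
  }
  dplyr::bind_rows(
    sim_group(cfg_wt, "wt", 0L),
    sim_group(cfg_mut, "mut", n_per_group)
  )
}

#' Simulate several walkers, optionally conditioned on bout coverage
#'
#' Simulates `n` trajectories with per-animal seeds derived from
#' `seed`. With `min_loopy_coverage` set, runs whose realised
#' loopy-regime occupancy falls below the bound are discarded and
#' further seeds drawn until `n` qualifying animals are collected —
#' useful for building cohorts whose loopy bouts are guaranteed to
#' cover a stated fraction of the track, since the occupancy of the
#' symmetric two-state regime chain varies widely between animals.
#'
#' @param cfg A [walk_config()].
#' @param n Number of trajectories.
#' @param seed Master seed.
#' @param min_loopy_coverage Minimum fraction of steps in the loopy
#'   regime, or `NULL` for no conditioning.
#' @param id_prefix Prefix for animal ids.
#' @param max_tries Simulation budget before giving up.
#' @return A trajectory tibble of `n` animals.
#' @export
simulate_trajectories <- function(cfg, n, seed = 1L,
                                  min_loopy_coverage = NULL,
                                  id_prefix = "sim", max_tries = 50L * n) {
  stopifnot(inherits(cfg, "walk_config"))
  if (!is.numeric(n) || n < 1) {
    abort_wormloop("`n` must be at least 1.", "wormloop_parameter_error")
  }
  n <- as.integer(n)
  seeds <- derive_seeds(seed, max_tries)
  out <- vector("list", n)
  found <- 0L
  for (s in seeds) {
    cfg$seed <- s
    tr <- simulate_trajectory(cfg)
    if (!is.null(min_loopy_coverage) &&
        mean(tr$regime == "loopy") < min_loopy_coverage) {
      next
    }
    found <- found + 1L
    tr$animal_id <- sprintf("%s_%02d", id_prefix, found)
    out[[found]] <- tr
    if (found == n) break
  }
  if (found < n) {
    abort_wormloop(
      sprintf("Only %d of %d runs reached loopy coverage %.2f within %d tries.",
              found, n, min_loopy_coverage, max_tries),
      "wormloop_parameter_error"
    )
  }
  dplyr::bind_rows(out)
}

#' Configuration for the asymmetric head-wave generator
#'
#' The programmed head angle follows a sinusoid whose positive
#' half-cycles are scaled to `ventral_amp_deg` and negative half-cycles
#' to `dorsal_amp_deg`, emulating the ventral/dorsal asymmetry of
#' foraging head bends. The default 2 s period places the 0.5 s samples
#' exactly on the wave's extrema.
#'
#' @param ventral_amp_deg,dorsal_amp_deg Positive amplitudes, degrees.
#' @param period_s Oscillation period, seconds (> 1 s, i.e. more than
#'   twice the 0.5 s sampling interval).
#' @param noise_deg_sd SD of additive angular noise, degrees.
#' @param duration_s Duration, seconds.
#' @param seed Integer seed.
#' @return A list of class `head_wave_config`.
#' @export
head_wave_config <- function(ventral_amp_deg = 30,
                             dorsal_amp_deg = 30,
                             period_s = 2,
                             noise_deg_sd = 0,
                             duration_s = 60,
                             seed = 1L) {
  check_positive(ventral_amp_deg, "ventral_amp_deg")
  check_positive(dorsal_amp_deg, "dorsal_amp_deg")
  check_positive(period_s, "period_s")
  check_positive(duration_s, "duration_s")
  if (period_s <= 2 * 0.5) {
    abort_wormloop("`period_s` must exceed twice the 0.5 s sampling interval.",
                   "wormloop_parameter_error")
  }
  if (noise_deg_sd < 0) {
    abort_wormloop("`noise_deg_sd` must be nonnegative.",
                   "wormloop_parameter_error")
  }
  structure(
    list(
      ventral_amp_deg = ventral_amp_deg,
      dorsal_amp_deg = dorsal_amp_deg,
      period_s = period_s,
      noise_deg_sd = noise_deg_sd,
      duration_s = duration_s,
      seed = as.integer(seed)
    ),
    class = "head_wave_config"
  )
}

#' Simulate a head-landmark pose series
#'
#' Builds centroid / pharynx-terminal-bulb / nose-tip landmark frames at
#' 0.5 s intervals whose geometry exactly inverts under [head_angle()]:
#' the centroid sits at the origin, the terminal bulb 1 mm along the
#' body axis (+x), and the nose tip 0.5 mm from the bulb rotated by the
#' programmed angle (counter-clockwise for ventral-positive angles,
#' ventral side on the left).
#'
#' @param cfg A [head_wave_config()].
#' @param animal_id Label for the simulated animal.
#' @return A pose tibble with columns `animal_id`, `t_s`, `cx`, `cy`,
#'   `bx`, `by`, `nx`, `ny`, `ventral_is_left`, and the programmed
#'   `angle_true_deg`.
#' @export
simulate_head_wave <- function(cfg, animal_id = "sim_1") {
  stopifnot(inherits(cfg, "head_wave_config"))
  t <- seq(0, cfg$duration_s, by = 0.5)
  s <- sin(2 * pi * t / cfg$period_s)
  angle <- ifelse(s >= 0, cfg$ventral_amp_deg * s, cfg$dorsal_amp_deg * s)
  if (cfg$noise_deg_sd > 0) {
    angle <- angle + withr::with_seed(cfg$seed,
                                      stats::rnorm(length(t), 0, cfg$noise_deg_sd))
  }
  a <- deg2rad(angle)
  tibble::tibble(
    animal_id = animal_id,
    t_s = t,
    cx = 0, cy = 0,
    bx = 1, by = 0,
    nx = 1 + 0.5 * cos(a),
    ny = 0.5 * sin(a),
    ventral_is_left = TRUE,
    angle_true_deg = angle
  )
}

#' Configuration for the fluorescence-record generator
#'
#' Emulates photobleach-and-recovery experiments: per animal, an intact
#' ROI intensity is drawn around `intact_mean`, photobleaching retains a
#' uniform fraction of it drawn from `bleach_retention_range` (default
#' 50–70%, the retention observed after controlled photobleaching), and
#' the post-treatment intensity recovers a fraction `recovery_fraction`
#' of the bleached-away signal. A constant camera background is added to
#' every ROI and background-point reading so that background correction
#' is exercised.
#'
#' @param intact_mean Mean intact ROI intensity (background-free signal).
#' @param bleach_retention_range Length-2 interval inside (0, 1).
#' @param recovery_fraction Fraction of the bleached signal recovered.
#' @param noise_sd SD of intensity noise on intact/after readings.
#' @param n_animals Number of animals.
#' @param background Constant background level added to all readings.
#' @param seed Integer seed.
#' @return A list of class `fluor_sim_config`.
#' @export
fluor_sim_config <- function(intact_mean = 100,
                             bleach_retention_range = c(0.5, 0.7),
                             recovery_fraction = 0.6,
                             noise_sd = 0,
                             n_animals = 10,
                             background = 20,
                             seed = 1L) {
  check_positive(intact_mean, "intact_mean")
  check_positive(n_animals, "n_animals")
  check_probability(recovery_fraction, "recovery_fraction")
  if (length(bleach_retention_range) != 2L ||
      any(bleach_retention_range <= 0) || any(bleach_retention_range >= 1) ||
      bleach_retention_range[1] > bleach_retention_range[2]) {
    abort_wormloop("`bleach_retention_range` must be an ordered interval inside (0, 1).",
                   "wormloop_parameter_error")
  }
  if (noise_sd < 0 || background < 0) {
    abort_wormloop("`noise_sd` and `background` must be nonnegative.",
                   "wormloop_parameter_error")
  }
  structure(
    list(
      intact_mean = intact_mean,
      bleach_retention_range = bleach_retention_range,
      recovery_fraction = recovery_fraction,
      noise_sd = noise_sd,
      n_animals = as.integer(n_animals),
      background = background,
      seed = as.integer(seed)
    ),
    class = "fluor_sim_config"
  )
}

#' Simulate photobleach-and-recovery fluorescence records
#'
#' @param cfg A [fluor_sim_config()].
#' @param condition `"heat_shock"` or `"control"` label attached to all
#'   generated records.
#' @return A tibble of fluorescence records: raw ROI means
#'   (`roi_intact`, `roi_bleached`, `roi_after`) and three background
#'   points per stage (`bg_intact_1..3`, `bg_bleached_1..3`,
#'   `bg_after_1..3`), plus the true retention and recovery fractions
#'   used (for validation).
#' @export
simulate_fluorescence <- function(cfg, condition = c("heat_shock", "control")) {
  stopifnot(inherits(cfg, "fluor_sim_config"))
  condition <- match.arg(condition)
  n <- cfg$n_animals
  withr::with_seed(cfg$seed, {
    intact <- cfg$intact_mean + stats::rnorm(n, 0, cfg$noise_sd)
    retention <- stats::runif(n, cfg$bleach_retention_range[1],
                              cfg$bleach_retention_range[2])
    bleached <- intact * retention
    after <- bleached + cfg$recovery_fraction * (intact - bleached) +
      stats::rnorm(n, 0, cfg$noise_sd)
  })
  bg <- cfg$background
  tibble::tibble(
    animal_id = sprintf("%s_%02d", condition, seq_len(n)),
    condition = condition,
    roi_intact = intact + bg,
    roi_bleached = bleached + bg,
    roi_after = after + bg,
    bg_intact_1 = bg, bg_intact_2 = bg, bg_intact_3 = bg,
    bg_bleached_1 = bg, bg_bleached_2 = bg, bg_bleached_3 = bg,
    bg_after_1 = bg, bg_after_2 = bg, bg_after_3 = bg,
    retention_true = retention,
    recovery_fraction_true = cfg$recovery_fraction
  )
}
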