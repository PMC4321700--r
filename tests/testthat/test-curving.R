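test_that("collinear points give zero curving everywhere", {
  tr <- straight_track(30, step_mm = 0.5)
  cs <- compute_curving(tr)
  expect_equal(cs$curving_deg_per_mm, rep(0, nrow(cs)))
  expect_equal(sum(cs$step_mm), 30, tolerance = 0.5)  # within end-step slack
})

test_that("a circle yields the analytic constant rate, signed by direction", {
  ccw <- compute_curving(circle_track(5, 60, arc_step_mm = 0.5))
  expect_equal(mean(ccw$curving_deg_per_mm), 360 / (2 * pi * 5),
               tolerance = 0.01)
  expect_lt(stats::sd(ccw$curving_deg_per_mm), 1e-8)
  cw <- compute_curving(circle_track(5, 60, arc_step_mm = 0.5, ccw = FALSE))
  expect_equal(mean(cw$curving_deg_per_mm), -360 / (2 * pi * 5),
               tolerance = 0.01)
})

test_that("the vectorised pipeline matches a brute-force oracle", {
  tr <- simulate_trajectory(walk_config(bias_deg_per_mm = -4,
                                        noise_deg_per_mm_sd = 6,
                                        duration_s = 300, seed = 8))
  cs <- compute_curving(tr, min_step_mm = 0)
  oracle <- oracle_curving(tr$x_mm, tr$y_mm)
  # simulator sets ventral left, so ventral-positive equals ccw-positive
  expect_equal(cs$curving_deg_per_mm, oracle$curving, tolerance = 1e-10)
  expect_equal(cs$step_mm, oracle$weights, tolerance = 1e-12)
})

test_that("unknown ventral side is reported in the ccw convention, known right flips", {
  tr <- circle_track(5, 40, arc_step_mm = 0.5)  # ccw turn
  cs_unknown <- compute_curving(tr)
  expect_equal(unique(cs_unknown$sign_convention), "ccw_positive")
  expect_gt(mean(cs_unknown$curving_deg_per_mm), 0)

  tr$ventral_is_left <- FALSE  # ventral on the right: ccw turn is dorsal-ward
  cs_right <- compute_curving(tr)
  expect_equal(unique(cs_right$sign_convention), "ventral_positive")
  expect_equal(cs_right$curving_deg_per_mm, -cs_unknown$curving_deg_per_mm)
})

test_that("mirror reflection negates the series; rigid motions preserve it", {
  tr <- simulate_trajectory(walk_config(bias_deg_per_mm = 3,
                                        noise_deg_per_mm_sd = 5,
                                        duration_s = 240, seed = 21))
  base <- compute_curving(tr)
  mirrored <- compute_curving(mirror_traj(tr))
  expect_equal(mirrored$curving_deg_per_mm, base$curving_deg_per_mm,
               tolerance = 1e-9)  # ventral flag flips with the reflection
  tr_unknown <- tr
  tr_unknown$ventral_is_left <- NA
  mirrored_raw <- compute_curving(mirror_traj(tr_unknown))
  expect_equal(mirrored_raw$curving_deg_per_mm,
               -compute_curving(tr_unknown)$curving_deg_per_mm,
               tolerance = 1e-9)

  moved <- compute_curving(rotate_traj(tr, 37, dx = 5, dy = -11))
  expect_equal(moved$curving_deg_per_mm, base$curving_deg_per_mm,
               tolerance = 1e-8)
})

test_that("tiny jitter steps are merged before heading estimation", {
  x <- c(0, 1, 1.01, 2, 3)
  y <- c(0, 0, 0.02, 0, 0)
  tr <- make_traj(x, y)
  cs <- compute_curving(tr, min_step_mm = 0.05)
  expect_equal(cs$curving_deg_per_mm, rep(0, nrow(cs)))
  expect_error(compute_curving(make_traj(c(0, 0.01, 0.02), c(0, 0, 0))),
               class = "wormloop_degenerate")
})

test_that("fixed-time means are path-length weighted and window-checked", {
  tr <- straight_track(120, step_mm = 0.1)
  tr$t_s <- seq(0, by = 1, length.out = nrow(tr))
  cs <- compute_curving(tr)
  expect_equal(mean_curving_fixed_time(cs, 1000)$mean_curving_deg_per_mm, 0)

  # constant series: weighted mean is the constant
  circ <- circle_track(5, 60, arc_step_mm = 0.5)
  ccs <- compute_curving(circ)
  m <- mean_curving_fixed_time(ccs, max(ccs$t_mid_s))
  expect_equal(m$mean_curving_deg_per_mm, ccs$curving_deg_per_mm[1],
               tolerance = 1e-6)

  err <- expect_error(mean_curving_fixed_time(cs, 1e6),
                      class = "wormloop_short_track")
  expect_true(err$covered_s < 1e6)
})

test_that("balanced opposite curving averages to zero by weight", {
  series <- tibble::tibble(
    animal_id = "a",
    t_mid_s = 1:40,
    step_mm = c(rep(0.5, 20), rep(0.25, 20)),  # equal path in each half
    curving_deg_per_mm = c(rep(10, 20), rep(-10, 20)),
    sign_convention = "ccw_positive"
  )
  m <- mean_curving_fixed_time(series, 40)
  expect_equal(m$mean_curving_deg_per_mm, 10 * (10 - 5) / 15)
  series$step_mm <- c(rep(0.5, 20), rep(0.5, 20))
  expect_equal(mean_curving_fixed_time(series, 40)$mean_curving_deg_per_mm, 0)
})

test_that("fixed-distance means use only the first L0 of path", {
  expect_equal(
    mean_curving_fixed_distance(straight_track(50, 0.25), 30)$mean_curving_deg_per_mm,
    0
  )
  circ <- circle_track(5, 60, arc_step_mm = 0.25)
  full <- compute_curving(circ)
  fixed <- mean_curving_fixed_distance(circ, 30)
  expect_equal(fixed$mean_curving_deg_per_mm,
               sum(full$step_mm * full$curving_deg_per_mm) / sum(full$step_mm),
               tolerance = 1e-6)

  mixed <- straight_plus_loop_track(20, 6, step = 0.1)
  got <- mean_curving_fixed_distance(mixed, 30, min_step_mm = 0)
  cut <- truncate_by_path_length(mixed, 30)
  oracle <- oracle_curving(cut$x_mm, cut$y_mm)
  expect_equal(got$mean_curving_deg_per_mm,
               sum(oracle$weights * oracle$curving) / sum(oracle$weights),
               tolerance = 1e-9)
})

test_that("a closed noise-free loop accumulates 360 degrees of signed turning", {
  for (bias in c(-12, 9)) {
    circumference <- 360 / abs(bias)
    cfg <- walk_config(bias_deg_per_mm = bias,
                       duration_s = ceiling(circumference / 0.15) + 2)
    tr <- simulate_trajectory(cfg)
    cs <- compute_curving(tr, min_step_mm = 0)
    turn <- cumsum(cs$curving_deg_per_mm * cs$step_mm)
    total <- turn[length(turn)]
    step_turn <- abs(bias) * 0.15
    expect_equal(abs(total), 360, tolerance = (2 * step_turn + 1e-9) / 360)
    expect_equal(sign(total), sign(bias))
  }
})

test_that("histograms pool path-length weights into zero-anchored bins", {
  circ <- compute_curving(circle_track(5, 45, arc_step_mm = 0.5))
  h <- curving_histogram(circ, bin_width_deg_per_mm = 1)
  expect_s3_class(h, "curving_histogram")
  expect_equal(sum(h$weight_mm > 0), 1)
  expect_equal(h$bin_lo[h$weight_mm > 0], 11)  # 11.459 falls in [11, 12)
  expect_equal(sum(h$weight_mm), sum(circ$step_mm), tolerance = 1e-9)
  expect_true(all(abs(h$bin_lo / 1 - round(h$bin_lo / 1)) < 1e-12))

  cw <- compute_curving(circle_track(5, 45, arc_step_mm = 0.5, ccw = FALSE))
  h2 <- curving_histogram(dplyr::bind_rows(circ, cw), 1)
  up <- h2$weight_mm[h2$bin_lo == 11]
  dn <- h2$weight_mm[h2$bin_hi == -11]
  expect_equal(up, dn, tolerance = 1e-9)

  two <- dplyr::bind_rows(
    compute_curving(straight_track(10, 0.5, id = "s1")),
    compute_curving(straight_track(5, 0.5, id = "s2"))
  )
  h3 <- curving_histogram(two, 2)
  expect_equal(h3$weight_mm[h3$bin_lo == 0], sum(two$step_mm), tolerance = 1e-9)
  expect_error(curving_histogram(two, 0), class = "wormloop_parameter_error")
})
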