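test_that("the minimal enclosing circle is exact on known configurations", {
  expect_equal(min_enclosing_circle(c(0, 2), c(0, 0)),
               c(cx = 1, cy = 0, r = 1))
  # equilateral triangle, circumradius side/sqrt(3)
  side <- 2
  tri <- rbind(c(0, 0), c(side, 0), c(side / 2, side * sqrt(3) / 2))
  mec <- min_enclosing_circle(tri[, 1], tri[, 2])
  expect_equal(unname(mec["r"]), side / sqrt(3), tolerance = 1e-9)
  # obtuse triangle: circle spans the longest side only
  obt <- min_enclosing_circle(c(0, 10, 5), c(0, 0, 0.5))
  expect_equal(unname(obt["r"]), 5, tolerance = 1e-6)
  # collinear points
  col <- min_enclosing_circle(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_equal(unname(col["r"]), sqrt(18) / 2, tolerance = 1e-9)
  # points on a circle recover it
  th <- seq(0, 2 * pi, length.out = 60)
  mec2 <- min_enclosing_circle(3 + 4 * cos(th), -1 + 4 * sin(th))
  expect_equal(unname(mec2), c(3, -1, 4), tolerance = 1e-9)
})

test_that("a three-circuit 8 mm loop is one merged interval, classified strong", {
  bias <- -360 / (pi * 8)
  tr <- simulate_trajectory(walk_config(bias_deg_per_mm = bias,
                                        duration_s = ceiling(3 * pi * 8 / 0.15)))
  loops <- detect_loops(tr)
  expect_equal(nrow(loops), 1)
  expect_equal(loops$diameter_mm, 8, tolerance = 0.02)
  total <- path_lengths(tr)$path_mm
  expect_gt((loops$end_mm - loops$start_mm) / total, 0.95)

  rep <- classify_cl(tr)
  expect_equal(as.character(rep$cl_class), "strong")
  expect_true(rep$is_cl)
})

test_that("a 12 mm circle fails the under-1-cm test and a straight track has no loops", {
  tr12 <- simulate_trajectory(walk_config(bias_deg_per_mm = -360 / (pi * 12),
                                          duration_s = ceiling(3 * pi * 12 / 0.15)))
  expect_equal(nrow(detect_loops(tr12)), 0)
  rep12 <- classify_cl(tr12)
  expect_equal(as.character(rep12$cl_class), "normal")
  expect_false(rep12$is_cl)

  straight <- straight_track(30)
  expect_equal(nrow(detect_loops(straight)), 0)
  expect_false(classify_cl(straight)$is_cl)
})

test_that("a 20 mm run plus one 6 mm loop is mild CL at the constructed fraction", {
  tr <- straight_plus_loop_track(20, 6, step = 0.1)
  rep <- classify_cl(tr)
  expect_equal(rep$loopy_fraction, 6 * pi / (20 + 6 * pi), tolerance = 0.02)
  expect_equal(as.character(rep$cl_class), "mild")
  expect_true(rep$is_cl)
  loops <- detect_loops(tr)
  expect_equal(nrow(loops), 1)
  expect_equal(loops$diameter_mm, 6, tolerance = 0.05)
  expect_equal(abs(loops$net_turn_deg), 360, tolerance = 10)
})

test_that("incidental closures without net turning are not loops", {
  # out-and-back: returns to start but net turn ~ 180, far from 330
  x <- c(seq(0, 5, by = 0.1), seq(5, 0.02, by = -0.1))
  y <- c(rep(0, 51), rep(0.01, 50))
  tr <- make_traj(x, y)
  expect_equal(nrow(detect_loops(tr)), 0)
})

test_that("loop quantities are invariant under rigid motions", {
  tr <- simulate_trajectory(walk_config(noise_deg_per_mm_sd = 1.5,
                                        bout_switch_prob = 0.003,
                                        loopy_bias_deg_per_mm = -12,
                                        duration_s = 1800, seed = 7))
  a <- classify_cl(tr)
  b <- classify_cl(rotate_traj(tr, 113, dx = -4, dy = 9))
  expect_equal(b$loopy_fraction, a$loopy_fraction, tolerance = 1e-9)
  expect_identical(b$cl_class, a$cl_class)
  expect_equal(b$n_loops, a$n_loops)
})

test_that("widening the diameter bound never shrinks the loopy fraction", {
  trs <- list(
    simulate_trajectory(walk_config(bias_deg_per_mm = -360 / (pi * 11),
                                    duration_s = 800), animal_id = "d11"),
    simulate_trajectory(walk_config(noise_deg_per_mm_sd = 1.5,
                                    bout_switch_prob = 0.003,
                                    loopy_bias_deg_per_mm = -12,
                                    duration_s = 1800, seed = 3),
                        animal_id = "bouty")
  )
  for (tr in trs) {
    narrow <- classify_cl(tr, classifier_config(max_loop_diameter_mm = 10))
    wide <- classify_cl(tr, classifier_config(max_loop_diameter_mm = 14))
    expect_gte(wide$loopy_fraction, narrow$loopy_fraction - 1e-9)
  }
  # the 11 mm loop appears only under the wide bound
  expect_false(classify_cl(trs[[1]], classifier_config(max_loop_diameter_mm = 10))$is_cl)
  expect_true(classify_cl(trs[[1]], classifier_config(max_loop_diameter_mm = 14))$is_cl)
})

test_that("raising the CL fraction threshold never adds CL animals", {
  tr <- straight_plus_loop_track(20, 6, step = 0.1)  # fraction ~ 0.485
  lo <- classify_cl(tr, classifier_config(loopy_fraction_threshold = 0.30))
  hi <- classify_cl(tr, classifier_config(loopy_fraction_threshold = 0.60,
                                          strong_fraction_threshold = 0.95))
  expect_true(lo$is_cl)
  expect_false(hi$is_cl)
})

test_that("the cheaper max-pairwise diameter agrees on circular loops", {
  tr <- simulate_trajectory(walk_config(bias_deg_per_mm = -360 / (pi * 8),
                                        duration_s = 600))
  a <- detect_loops(tr, classifier_config(diameter_method = "mec"))
  b <- detect_loops(tr, classifier_config(diameter_method = "max_pairwise"))
  expect_equal(b$diameter_mm, a$diameter_mm, tolerance = 0.01)
})

test_that("excluded animals are dropped before classification", {
  a <- simulate_trajectory(walk_config(duration_s = 120), animal_id = "a")
  b <- simulate_trajectory(walk_config(duration_s = 120), animal_id = "b")
  b$excluded <- TRUE
  expect_message(rep <- classify_cl(dplyr::bind_rows(a, b)), "excluded")
  expect_equal(rep$animal_id, "a")
})

test_that("assay proportions follow ten-per-assay arithmetic", {
  rep <- tibble::tibble(is_cl = c(rep(TRUE, 3), rep(FALSE, 7)))
  one <- assay_cl_proportion(rep)
  expect_equal(glance(one)$pooled_pct_cl, 30)
  expect_equal(glance(one)$mean_pct_cl, 30)

  all_cl <- assay_cl_proportion(tibble::tibble(is_cl = rep(TRUE, 10)))
  expect_equal(glance(all_cl)$pooled_pct_cl, 100)

  two <- assay_cl_proportion(tibble::tibble(
    is_cl = c(rep(TRUE, 2), rep(FALSE, 8), rep(TRUE, 4), rep(FALSE, 6))
  ))
  expect_equal(tidy(two)$pct_cl, c(20, 40))
  expect_equal(glance(two)$mean_pct_cl, 30)
  expect_equal(glance(two)$n_assays, 2)

  expect_error(assay_cl_proportion(tibble::tibble(is_cl = logical(0))),
               class = "wormloop_parameter_error")
  expect_error(assay_cl_proportion(tibble::tibble(is_cl = rep(TRUE, 7))),
               class = "wormloop_parameter_error")
  part <- assay_cl_proportion(tibble::tibble(is_cl = rep(TRUE, 7)),
                              allow_partial = TRUE)
  expect_equal(glance(part)$n_animals, 7)
})
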