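test_that("background correction subtracts the three-point mean", {
  expect_equal(background_correct(100, c(10, 10, 10)), 90)
  expect_equal(background_correct(10, c(10, 10, 10)), 0)
  expect_equal(background_correct(50, c(10, 20, 30)), 30)
  expect_equal(background_correct(c(50, 60), rbind(c(10, 20, 30), c(0, 0, 0))),
               c(30, 60))
  expect_error(background_correct(50, c(10, 20)),
               class = "wormloop_format_error")
  expect_error(background_correct(c(1, 2), rbind(c(1, 2, 3))),
               class = "wormloop_format_error")
})

make_record <- function(id = "a", intact, bleached, after, bg = 0,
                        condition = "heat_shock") {
  tibble::tibble(
    animal_id = id, condition = condition,
    roi_intact = intact + bg, roi_bleached = bleached + bg,
    roi_after = after + bg,
    bg_intact_1 = bg, bg_intact_2 = bg, bg_intact_3 = bg,
    bg_bleached_1 = bg, bg_bleached_2 = bg, bg_bleached_3 = bg,
    bg_after_1 = bg, bg_after_2 = bg, bg_after_3 = bg
  )
}

test_that("the rate of change follows the recovery formula on corrected values", {
  expect_equal(rate_of_change(make_record(intact = 100, bleached = 60,
                                          after = 100))$rate_of_change, 1)
  expect_equal(rate_of_change(make_record(intact = 100, bleached = 60,
                                          after = 60))$rate_of_change, 0)
  expect_equal(rate_of_change(make_record(intact = 100, bleached = 50,
                                          after = 80))$rate_of_change, 0.6)
})

test_that("insufficient bleach and failed bleaching are caught", {
  suppressWarnings(expect_error(  # retention 99.8% also draws a range warning
    rate_of_change(make_record(intact = 100, bleached = 99.8, after = 100)),
    class = "wormloop_insufficient_bleach"
  ))
  w_invalid <- capture_warnings(
    try(rate_of_change(make_record(intact = 100, bleached = 110, after = 100)),
        silent = TRUE)
  )
  expect_match(w_invalid, "invalid", all = FALSE)
  w_off <- capture_warnings(
    out <- rate_of_change(make_record(intact = 100, bleached = 40, after = 110))
  )
  expect_match(w_off, "retention", all = FALSE)
  expect_match(w_off, "flagged", all = FALSE)
  expect_true(out$rate_flagged)
})

test_that("the rate is invariant under a constant offset on ROI and background", {
  withr::with_seed(42, {
    for (i in 1:100) {
      intact <- stats::runif(1, 50, 200)
      retention <- stats::runif(1, 0.5, 0.7)
      r <- stats::runif(1)
      offset <- stats::runif(1, 0, 500)
      bleached <- intact * retention
      after <- bleached + r * (intact - bleached)
      base <- make_record(intact = intact, bleached = bleached, after = after)
      shifted <- make_record(intact = intact, bleached = bleached,
                             after = after, bg = offset)
      expect_equal(rate_of_change(shifted)$rate_of_change,
                   rate_of_change(base)$rate_of_change, tolerance = 1e-9)
    }
  })
})

test_that("recovery ratios normalise against the control mean", {
  hs <- make_record(intact = 100, bleached = 50, after = 80)  # rate 0.6
  ctl <- make_record(id = "c", intact = 100, bleached = 60, after = 96,
                     condition = "control")  # rate 0.9
  rr <- recovery_ratio(hs, ctl)
  expect_equal(tidy(rr)$recovery_ratio, 0.7)
  expect_equal(glance(rr)$mean_recovery_ratio, 0.7)

  ident <- recovery_ratio(
    make_record(intact = 100, bleached = 60, after = 100),
    make_record(intact = 80, bleached = 48, after = 80)
  )
  expect_equal(tidy(ident)$recovery_ratio, 1.0)
  none <- recovery_ratio(
    make_record(intact = 100, bleached = 60, after = 60),
    make_record(intact = 80, bleached = 48, after = 80)
  )
  expect_equal(tidy(none)$recovery_ratio, 0.0)
  expect_error(recovery_ratio(hs, ctl[0, ]), class = "wormloop_parameter_error")
})

test_that("simulated groups reproduce the programmed recovery contrast", {
  hs <- simulate_fluorescence(fluor_sim_config(recovery_fraction = 0.6,
                                               n_animals = 12, seed = 9L))
  ctl <- simulate_fluorescence(fluor_sim_config(recovery_fraction = 0.9,
                                                n_animals = 12, seed = 10L),
                               condition = "control")
  rr <- recovery_ratio(hs, ctl)
  expect_equal(glance(rr)$mean_recovery_ratio, 0.7, tolerance = 1e-12)
  expect_equal(glance(rr)$sd_recovery_ratio, 0, tolerance = 1e-12)

  # with noise the group mean recovers the contrast within Monte-Carlo error
  hs_n <- simulate_fluorescence(fluor_sim_config(recovery_fraction = 0.6,
                                                 noise_sd = 3, n_animals = 20,
                                                 seed = 11L))
  ctl_n <- simulate_fluorescence(fluor_sim_config(recovery_fraction = 0.9,
                                                  noise_sd = 3, n_animals = 20,
                                                  seed = 12L),
                                 condition = "control")
  # measurement noise can push measured retention outside the 50-70% band
  rr_n <- suppressWarnings(recovery_ratio(hs_n, ctl_n))
  expect_equal(glance(rr_n)$mean_recovery_ratio, 0.7, tolerance = 0.1)
})

test_that("fluorescence records survive a text round-trip", {
  rec <- simulate_fluorescence(fluor_sim_config(n_animals = 4, noise_sd = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rec[, 1:14], path)
  back <- read_fluorescence(path)
  expect_equal(back$roi_intact, rec$roi_intact)
  expect_equal(rate_of_change(back)$rate_of_change,
               rate_of_change(rec)$rate_of_change)
})

test_that("puncta summaries background-correct, clip, and handle empties", {
  tab <- tibble::tibble(roi_id = "r1", punctum_id = c("p1", "p2"),
                        raw_intensity = c(30, 40), area = c(2, 3))
  ps <- summarize_puncta(tab, c(10, 10, 10))
  expect_equal(tidy(ps)$corrected_intensity, c(20, 30))
  expect_equal(glance(ps)$mean_intensity, 25)
  expect_equal(glance(ps)$n_puncta, 2)

  empty <- summarize_puncta(tab[0, ], c(10, 10, 10))
  expect_equal(glance(empty)$n_puncta, 0)
  expect_equal(glance(empty)$mean_intensity, 0)

  dim_tab <- tibble::tibble(roi_id = "r1", punctum_id = "p1",
                            raw_intensity = 5, area = 1)
  expect_warning(clipped <- summarize_puncta(dim_tab, c(10, 10, 10)),
                 "clipped")
  expect_equal(tidy(clipped)$corrected_intensity, 0)
})
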