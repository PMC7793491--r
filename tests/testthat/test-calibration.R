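test_that("temperature-averaged RMSD reproduces the reference table averages", {
  tab <- reference_rmsd_table()
  avg <- function(model, region) {
    round(mean_rmsd_over_temperatures(
      tab$rmsd[tab$model == model & tab$region == region]), 1)
  }
  expect_equal(avg("CCCT5", "whole"), 3.4)
  expect_equal(avg("CCCT7", "whole"), 5.0)
  expect_equal(avg("CCCT6", "whole"), 4.1)
  expect_equal(avg("CCCTA2", "whole"), 2.1)
  expect_equal(avg("CCCT3", "loop"), 4.2)
  expect_equal(mean_rmsd_over_temperatures(rep(0, 5)), 0)
  expect_error(mean_rmsd_over_temperatures(numeric(0)))
  expect_error(mean_rmsd_over_temperatures(c(1, -2)))
})

test_that("the TR-plot fit matches the reference line to two decimals", {
  cal <- fit_tr_plot(c(2.0, 3.4, 5.0), c(332, 321, 311),
                     labels = c("CCCT3", "CCCT5", "CCCT7"))
  expect_equal(round(cal$slope, 2), -6.98)
  expect_equal(round(cal$intercept, 2), 345.54)
  expect_gte(cal$r_squared, 0.99)
  expect_equal(unname(coef(cal)), c(cal$intercept, cal$slope))
})

test_that("OLS edge cases behave: interpolation, collinearity, degeneracy", {
  two <- fit_tr_plot(c(1, 3), c(330, 320))
  expect_equal(two$r_squared, 1)
  expect_equal(predict(two, c(1, 3)), c(330, 320))

  col3 <- fit_tr_plot(c(1, 2, 3), c(340, 335, 330))
  expect_equal(col3$r_squared, 1)
  expect_equal(col3$slope, -5)

  expect_error(fit_tr_plot(2, 330), "at least two")
  expect_error(fit_tr_plot(c(2, 2), c(330, 331)), "zero RMSD variance")
})

test_that("the fitted line satisfies the OLS identities", {
  cal <- published_calibration()
  pts <- cal$points
  # passes through the centroid
  expect_equal(predict(cal, mean(pts$rmsd)), mean(pts$tm), tolerance = 1e-12)
  # residuals sum to zero
  expect_lt(abs(sum(residuals(cal))), 1e-9)
  # agrees with the underlying lm fit
  expect_equal(predict(cal, c(0, 2.5, 6)),
               unname(predict(cal$model,
                              newdata = data.frame(rmsd = c(0, 2.5, 6)))))
})

test_that("refitting the embedded reference points reproduces the calibration", {
  cal <- published_calibration()
  refit <- fit_tr_plot(cal$points)
  expect_equal(round(refit$slope, 2), round(cal$slope, 2))
  expect_equal(round(refit$intercept, 2), round(cal$intercept, 2))
  expect_equal(cal$points$label, c("CCCT3", "CCCT5", "CCCT7"))
})

test_that("Tm predictions follow the line, round to kelvin, and flag extrapolation", {
  cal <- published_calibration()
  p <- predict_tm(2.1, cal)
  expect_equal(p$tm_rounded, 331)
  expect_equal(p$tm, cal$intercept + cal$slope * 2.1)
  expect_false(p$extrapolated)
  expect_equal(p$tm_rounded, round(p$tm))

  # RMSD 0 reads off the intercept, outside the calibration range
  p0 <- predict_tm(0, cal)
  expect_equal(p0$tm, cal$intercept)
  expect_true(p0$extrapolated)

  # strictly decreasing in flexibility (negative slope)
  tms <- vapply(seq(0.5, 6, by = 0.5),
                function(x) predict_tm(x, cal)$tm, numeric(1))
  expect_true(all(diff(tms) < 0))

  expect_error(predict_tm(-1, cal))
})

test_that("the pipeline maps static trajectories to the intercept", {
  seq <- cccta2_seq()
  st <- toy_imotif_structure(seq)
  trajs <- temperature_trajectory_set(st, seq, target_rmsd = rep(0, 5),
                                      n_frames = 20, seed = 3)
  res <- run_md_tspc4(trajs, seq)
  expect_equal(res$rmsd_mean, 0)
  expect_equal(res$prediction$tm, res$calibration$intercept)
  expect_equal(res$rmsd_table$temperature, c(280, 300, 320, 340, 360))
})

test_that("the pipeline recovers constructed per-temperature averages and Tm", {
  seq <- cccta2_seq()
  st <- toy_imotif_structure(seq)
  targets <- c(1.9, 1.9, 2.1, 2.5, 2.2)
  trajs <- temperature_trajectory_set(st, seq, target_rmsd = targets,
                                      n_frames = 200, seed = 17)
  res <- run_md_tspc4(trajs, seq)
  expect_equal(res$rmsd_table$whole, targets, tolerance = 0.02)
  expect_equal(round(res$rmsd_mean, 1), 2.1)
  analytic <- predict_tm(mean(targets))$tm
  expect_lt(abs(res$prediction$tm - analytic), 1)
  expect_equal(res$prediction$tm_rounded, 331)
})

test_that("doubling the fluctuation amplitude lowers the predicted Tm", {
  seq <- ccct3_seq()
  st <- toy_imotif_structure(seq)
  small <- temperature_trajectory_set(st, seq, sigma_schedule = 0.6,
                                      n_frames = 60, seed = 23)
  large <- temperature_trajectory_set(st, seq, sigma_schedule = 1.2,
                                      n_frames = 60, seed = 23)
  r_small <- run_md_tspc4(small, seq)
  r_large <- run_md_tspc4(large, seq)
  expect_gt(r_large$rmsd_mean, r_small$rmsd_mean)
  expect_lt(r_large$prediction$tm, r_small$prediction$tm)
})

test_that("pipeline contract violations are reported", {
  seq <- ccct3_seq()
  st <- toy_imotif_structure(seq)
  trajs <- temperature_trajectory_set(st, seq, sigma_schedule = 0.5,
                                      temps = c(280, 300), n_frames = 10,
                                      seed = 2)
  expect_error(run_md_tspc4(trajs[1], seq), ">= 2")
  unnamed <- unname(trajs)
  expect_error(run_md_tspc4(unnamed, seq), "named")

  other <- gaussian_trajectory(toy_imotif_structure(parse_imotif("CCTCCTCCTCC")),
                               0.5, n_frames = 10, seed = 2)
  mixed <- list("280" = trajs[[1]], "300" = other)
  expect_error(run_md_tspc4(mixed, seq), "inconsistent topologies")
})
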