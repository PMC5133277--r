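fake_trials <- function(rt) {
  data.frame(rt_s = rt, correct = TRUE)
}

test_that("RT filter removes upper-tail outliers against a hand oracle", {
  rt <- c(1, 1, 1, 1, 10)
  flt <- filter_rt_outliers(fake_trials(rt), k = 4)
  cutoff <- mean(rt) + 4 * sd(rt)
  expect_equal(flt$report$rt_cutoff_s, cutoff)
  expect_identical(flt$trials$rt_s, rt[rt <= cutoff])
  expect_equal(flt$report$n_input,
               flt$report$n_retained + flt$report$n_removed_rt)

  # identical RTs: sd 0, nothing removed
  same <- filter_rt_outliers(fake_trials(rep(2, 10)), k = 4)
  expect_equal(same$report$n_removed_rt, 0)

  # enormous k: zero removals
  loose <- filter_rt_outliers(fake_trials(c(rt, 100)), k = 1e6)
  expect_equal(loose$report$n_removed_rt, 0)

  expect_error(filter_rt_outliers(fake_trials(1), k = 4), "at least 2")
  expect_error(filter_rt_outliers(fake_trials(c(-1, 2)), k = 4), "positive")
})

test_that("correctness restriction keeps exactly the accurate trials", {
  d <- data.frame(rt_s = rep(1, 10), correct = rep(c(TRUE, FALSE),
                                                   c(7, 3)))
  expect_equal(nrow(select_correct(d)), 7)
  expect_warning(select_correct(data.frame(correct = c(FALSE, FALSE))),
                 "no correct")
  # saturated generator -> retention fraction 1
  params <- sim_params(
    beta_accuracy = c(50, 0, 0, 0, 0, 0, 0, 0),
    participant_sd = 0, scene_sd = 0)
  trials <- small_experiment(seed = 9, params = params)
  expect_equal(nrow(select_correct(trials)), nrow(trials))
})

test_that("canonicalization obeys the sign convention and is idempotent", {
  params <- sim_params()
  geom <- screen_geometry()
  for (side in c("left", "right")) {
    traj <- simulate_trajectory("plausible", "congruent", "scene_first",
                                params, geom, side, seed = 21)
    ct <- canonicalize(traj)
    # trajectory ends at the correct button: final canonical x negative
    expect_lt(ct$samples$x_std[nrow(ct$samples)], 0)
    # idempotent on canonical input
    expect_identical(canonicalize(ct), ct)
  }
})

test_that("canonicalization preserves shape up to the axis scale factors", {
  params <- sim_params()
  geom <- screen_geometry()
  traj <- simulate_trajectory("implausible", "congruent", "scene_first",
                              params, geom, "left", seed = 13)
  ct <- canonicalize(traj)
  # inverse-scaling the canonical coordinates recovers raw pixel distances
  x_px <- ct$samples$x_std * ct$px_per_x
  y_px <- ct$samples$y_std * ct$px_per_y
  raw_d <- sqrt(diff(traj$samples$x_px)^2 + diff(traj$samples$y_px)^2)
  can_d <- sqrt(diff(x_px)^2 + diff(y_px)^2)
  expect_equal(can_d, raw_d, tolerance = 1e-12)
})

test_that("points on the ideal line have zero perpendicular deviation", {
  geom <- screen_geometry()
  params <- sim_params(motor_noise_px = 0)
  traj <- simulate_trajectory("plausible", "congruent", "scene_first",
                              params, geom, "left", lambda = 0)
  ct <- canonicalize(traj)
  u <- c(-1, 1.5) / sqrt(1 + 1.5^2)
  dev <- ct$samples$x_std * u[2] - ct$samples$y_std * u[1]
  expect_lt(max(abs(dev)), 1e-9)
})

test_that("time normalization interpolates onto the bin grid exactly", {
  # straight vertical movement: all bins angle 0
  ct <- make_canonical(x_px = rep(0, 10), y_px = seq(0, 450, length.out = 10))
  tn <- time_normalize(ct, n_bins = 21)
  expect_true(all(abs(tn$angle_deg) < 1e-12))
  # endpoint fidelity
  expect_equal(tn$x_std[1], ct$samples$x_std[1])
  expect_equal(tn$y_std[21], ct$samples$y_std[10])

  # straight 45-degree movement toward the incorrect side: all bins +45
  ct45 <- make_canonical(x_px = seq(0, 300, length.out = 8),
                         y_px = seq(0, 300, length.out = 8))
  tn45 <- time_normalize(ct45, n_bins = 11)
  expect_equal(tn45$angle_deg, rep(45, 11), tolerance = 1e-9)

  expect_error(time_normalize(make_canonical(0, 0)), "2 samples")
})

test_that("time normalization agrees with a dense-resampling oracle", {
  set.seed(8)
  x <- cumsum(rnorm(40)); y <- cumsum(abs(rnorm(40)))
  ct <- make_canonical(x, y)
  tn <- time_normalize(ct, n_bins = 51)
  # oracle: resample at 10x density, then subsample every 10th point
  dense <- time_normalize(ct, n_bins = 501)
  sub <- dense[seq(1, 501, by = 10), ]
  expect_equal(tn$x_std, sub$x_std, tolerance = 1e-6)
  expect_equal(tn$y_std, sub$y_std, tolerance = 1e-6)
})

test_that("preprocessing conserves trial counts across its stages", {
  trials <- small_experiment(seed = 31, n_scenes = 12, n_participants = 8,
                             per_participant = 12)
  prep <- suppressMessages(preprocess_trials(trials))
  r <- prep$report
  expect_equal(r$n_input,
               r$n_retained + r$n_removed_rt + r$n_removed_error_trials)
  expect_equal(nrow(prep$trials), r$n_retained)
  expect_equal(nrow(prep$accuracy_trials), r$n_input - r$n_removed_rt)
  expect_true(all(prep$trials$correct))
})
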