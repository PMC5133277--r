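test_that("initial degree matches the trigonometric oracle", {
  # straight vertical exit
  up <- make_canonical(rep(0, 6), seq(0, 200, length.out = 6))
  expect_equal(initial_degree(up), 0)

  # first out-of-radius sample at equal offsets toward the incorrect side
  diag <- make_canonical(c(0, 60), c(0, 60))
  expect_equal(initial_degree(diag), 45)

  # exit toward the correct side: -atan2(|x|, y) in degrees
  set.seed(2)
  for (r in 1:20) {
    x_exit <- runif(1, -200, -30); y_exit <- runif(1, 40, 300)
    # intermediate point stays inside the 50-px region (radius ~14 px)
    ct <- make_canonical(c(0, 10 * sign(x_exit), x_exit),
                         c(0, 10, y_exit))
    expect_equal(initial_degree(ct),
                 -atan2(abs(x_exit), y_exit) * 180 / pi,
                 tolerance = 1e-9)
  }
  ct2 <- make_canonical(c(0, -120), c(0, 90))
  expect_equal(initial_degree(ct2), -atan2(120, 90) * 180 / pi,
               tolerance = 1e-9)

  # never exits the radius: missing, not an error
  tiny <- make_canonical(c(0, 5, -5), c(0, 10, 5))
  expect_true(is.na(initial_degree(tiny)))
  expect_true(is.na(latency(tiny)))
})

test_that("latency is the time of the first sample outside the start region", {
  dt <- 1000 / 60
  ct <- make_canonical(c(0, 0, 0, 0, 40), c(0, 10, 20, 30, 60))
  # sample 5 is the first with distance > 50 px; t = 4 * dt
  expect_equal(latency(ct), 4 * dt / 1000)
  # first sample already outside: its own timestamp (t = 0)
  far <- canonical_trajectory(t_ms = c(100, 120), x_std = c(1, 1.1),
                              y_std = c(1, 1.1), px_per_x = 100,
                              px_per_y = 100)
  expect_equal(latency(far), 0.1)
})

test_that("latency agrees with a forward-stepping oracle at known speed", {
  params <- sim_params(motor_noise_px = 0, base_speed_px_per_step = 12)
  geom <- screen_geometry()
  dwell <- 0.3
  traj <- simulate_trajectory("plausible", "congruent", "scene_first",
                              params, geom, "left", dwell_s = dwell,
                              lambda = 0)
  ct <- canonicalize(traj)
  # oracle: dwell samples sit at the start; movement covers 12 px per step,
  # so the first sample beyond 50 px is dwell steps + ceil(50/12) + 1 - 1
  n_hold <- round(dwell * 60)
  first_out <- n_hold + ceiling(50 / 12)  # 1-based sample index
  expect_equal(latency(ct), (first_out - 1) * (1000 / 60) / 1000,
               tolerance = 1e-9)
})

test_that("x-flips respects the jitter-collapsing rule", {
  # monotone x: zero flips
  expect_equal(xflips(make_canonical(c(0, 5, 12, 30), c(0, 1, 2, 3)), 0), 0)
  # sign pattern +,-,+,- at jitter 0
  expect_equal(xflips(make_canonical(c(0, 10, 5, 15, 10), 0:4), 0), 3)
  # a 1-px reversal is collapsed at jitter 3
  expect_equal(xflips(make_canonical(c(0, 10, 9, 15), 0:3), 3), 0)
  # the same path counts at jitter 0
  expect_equal(xflips(make_canonical(c(0, 10, 9, 15), 0:3), 0), 2)
})

test_that("x-flips at jitter 0 equals brute-force sign-change counting", {
  set.seed(14)
  for (r in 1:50) {
    x <- cumsum(sample(c(-6, -2, 0, 2, 6), 12, replace = TRUE))
    ct <- make_canonical(x, seq_along(x))
    expect_equal(xflips(ct, 0), brute_flips(x))
  }
})

test_that("AUC handles the canonical geometry examples", {
  # trajectory identical to the ideal line
  line <- canonical_trajectory(t_ms = 0:10, x_std = seq(0, -1, length.out = 11),
                               y_std = seq(0, 1.5, length.out = 11))
  expect_lt(abs(auc(line)), 1e-12)

  # ideal line plus a triangular detour of base b, height h toward the
  # incorrect side: area + b*h/2
  u <- c(-1, 1.5) / sqrt(1 + 1.5^2)
  perp <- c(u[2], -u[1])  # unit vector toward the incorrect side
  b <- 0.4; h <- 0.25
  a_pos <- c(0, 0.3, 0.3 + b / 2, 0.3 + b, sqrt(1 + 1.5^2))
  d_pos <- c(0, 0, h, 0, 0)
  x <- a_pos * u[1] + d_pos * perp[1]
  y <- a_pos * u[2] + d_pos * perp[2]
  tri <- canonical_trajectory(t_ms = seq_along(x), x_std = x, y_std = y)
  expect_equal(auc(tri), b * h / 2, tolerance = 1e-9)
})

test_that("AUC equals the shoelace polygon oracle on random polylines", {
  set.seed(3)
  worst <- 0
  for (r in 1:200) {
    n <- 50
    x <- cumsum(rnorm(n, -0.02, 0.05))
    y <- cumsum(abs(rnorm(n, 0.03, 0.03)))
    ct <- canonical_trajectory(t_ms = seq_len(n), x_std = x, y_std = y)
    worst <- max(worst, abs(auc(ct) - shoelace_auc(x, y)))
  }
  expect_lt(worst, 1e-6)
})

test_that("mirroring across the ideal line flips AUC and initial degree only", {
  params <- sim_params()
  traj <- simulate_trajectory("implausible", "congruent", "scene_first",
                              params, screen_geometry(), "left", seed = 77)
  ct <- canonicalize(traj)
  # exact reflection across the start->correct-button line negates the
  # signed area exactly
  u <- c(-1, 1.5) / sqrt(1 + 1.5^2)
  a <- ct$samples$x_std * u[1] + ct$samples$y_std * u[2]
  d <- ct$samples$x_std * u[2] - ct$samples$y_std * u[1]
  refl <- canonical_trajectory(
    ct$samples$t_ms,
    a * u[1] - d * u[2],
    a * u[2] + d * u[1],
    ct$px_per_x, ct$px_per_y)
  expect_equal(auc(refl), -auc(ct), tolerance = 1e-9)

  # vertical-axis mirroring (x -> -x) negates the initial angle and
  # preserves latency and x-flips exactly, whatever the axis scales
  mirror <- canonical_trajectory(ct$samples$t_ms, -ct$samples$x_std,
                                 ct$samples$y_std, ct$px_per_x, ct$px_per_y)
  expect_equal(initial_degree(mirror), -initial_degree(ct))
  expect_identical(latency(mirror), latency(ct))
  expect_identical(xflips(mirror), xflips(ct))
})

test_that("initial degree lies in [-90, 90] with the sign of the exit x", {
  set.seed(6)
  for (r in 1:30) {
    n <- 20
    x <- cumsum(rnorm(n, 0, 30))
    y <- cumsum(abs(rnorm(n, 25, 10)))  # upward motion
    ct <- make_canonical(x, y)
    deg <- initial_degree(ct)
    if (is.na(deg)) next
    expect_gte(deg, -90); expect_lte(deg, 90)
    i <- which(sqrt(x^2 + y^2) > 50)[1]
    expect_equal(sign(deg), sign(x[i]))
  }
})

test_that("measure_trials populates all six measures and propagates missing", {
  trials <- small_experiment(seed = 51)
  prep <- suppressMessages(preprocess_trials(trials))
  m <- measure_trials(prep$trials)
  expect_equal(nrow(m), nrow(prep$trials))
  expect_true(all(c("accuracy", "rt_s", "initial_degree", "latency_s",
                    "xflips", "auc") %in% names(m)))
  expect_true(all(m$latency_s <= m$rt_s, na.rm = TRUE))
  # re-run is bit-identical
  expect_identical(m, measure_trials(prep$trials))

  # a trial that never leaves the start region: missing degree and latency
  still <- prep$trials[1, ]
  still$canonical[[1]] <- make_canonical(c(0, 3, -2, 1), c(0, 2, 4, 3))
  m1 <- measure_trials(still)
  expect_true(is.na(m1$initial_degree) && is.na(m1$latency_s))
  expect_false(is.na(m1$auc) || is.na(m1$xflips))
})

test_that("cell summaries match a hand-computed oracle", {
  m <- data.frame(
    participant_id = 1, scene_id = 1:4,
    plausibility = c("plausible", "plausible", "implausible", "implausible"),
    congruency = "congruent", order = "scene_first",
    counterbalance = "yes_left",
    accuracy = TRUE, rt_s = c(1.0, 1.4, 2.0, 3.0),
    initial_degree = c(1, 3, 10, 30), latency_s = c(0.4, 0.6, 0.5, 0.7),
    xflips = c(0L, 2L, 1L, 5L), auc = c(0.1, 0.3, 0.6, 1.0))
  s <- summarize_cells(m)
  pc <- s[s$plausibility == "plausible" & s$congruency == "congruent" &
            s$order == "scene_first", ]
  expect_equal(pc$rt_s_mean, 1.2)
  expect_equal(pc$rt_s_sd, sd(c(1.0, 1.4)))
  expect_equal(pc$auc_mean, 0.2)
  ic <- s[s$plausibility == "implausible" & s$congruency == "congruent" &
            s$order == "scene_first", ]
  expect_equal(ic$xflips_mean, 3)
  # empty cells are reported with n = 0 and missing statistics
  empty <- s[s$order == "sentence_first", ]
  expect_true(all(empty$n == 0))
  expect_true(all(is.na(empty$rt_s_mean)))
  # single-trial cells report sd 0
  one <- summarize_cells(m[3, ])
  expect_equal(one$rt_s_sd[one$n == 1], 0)
})

test_that("strong conflict concentrates AUC in the implausible+congruent cell", {
  # low-conflict regime where both AUC and x-flips grow with the pull
  params <- sim_params(
    beta_conflict = c(intercept = 4, plausibility = -2, congruency = 0,
                      order = 0, plaus_cong = -10, plaus_order = 0,
                      cong_order = 0, plaus_cong_order = 0),
    motor_noise_px = 5,
    beta_accuracy = c(50, 0, 0, 0, 0, 0, 0, 0),
    participant_sd = 0, scene_sd = 0,
    conflict_participant_sd = 0, conflict_scene_sd = 0)
  agg <- NULL
  for (rep in 1:5) {
    trials <- small_experiment(seed = 300 + rep, n_scenes = 16,
                               n_participants = 8, per_participant = 16,
                               params = params)
    prep <- suppressMessages(preprocess_trials(trials))
    m <- measure_trials(prep$trials)
    cell <- aggregate(cbind(auc, xflips) ~ plausibility + congruency, m,
                      mean)
    agg <- if (is.null(agg)) cell else
      within(agg, {auc <- auc + cell$auc; xflips <- xflips + cell$xflips})
  }
  lab <- paste(agg$plausibility, agg$congruency)
  expect_equal(lab[which.max(agg$auc)], "implausible congruent")
  expect_equal(lab[which.max(agg$xflips)], "implausible congruent")
})
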