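contrast_code <- function(level, levels) {
  ifelse(level == levels[1], 0.5, -0.5)
}

answer_for <- function(congruency) {
  # verification ground truth: matching content -> "yes"
  ifelse(congruency == "congruent", "yes", "no")
}

side_of <- function(response, counterbalance) {
  yes_left <- counterbalance == "yes_left"
  ifelse((response == "yes") == yes_left, "left", "right")
}

button_at <- function(geometry, side) {
  if (side == "left") geometry$button_left else geometry$button_right
}

#' Simulate one cursor trajectory from the two-attractor model
#'
#' The cursor rests at the calibration point for a dwell period (choice
#' latency), then moves at 60 Hz toward the responded button. Each step adds
#' a competitor pull of strength `lambda` (decaying linearly to zero over
#' the first `conflict_w_frac` of the ideal path) and Gaussian motor noise.
#' `lambda` is `softplus()` of the conflict linear predictor on the trial's
#' +/-0.5 condition codes unless supplied directly.
#'
#' @param plausibility,congruency,order factor levels of the trial.
#' @param params a [sim_params()].
#' @param geometry a [screen_geometry()].
#' @param correct_side side (`"left"`/`"right"`) of the correct response
#'   button.
#' @param responds_correctly does the simulated participant click the
#'   correct button?
#' @param dwell_s pre-movement dwell in seconds.
#' @param lambda optional conflict strength (px/step) overriding the linear
#'   predictor; useful for calibration studies.
#' @param conflict_offset additive offset on the conflict linear predictor
#'   (random effects).
#' @param seed optional seed (set only if non-NULL, so callers managing
#'   their own RNG stream can leave it unset).
#' @return object of class `mt_trajectory`: a list with `samples`
#'   (data.frame `t_ms`, `x_px`, `y_px`; first sample at the calibration
#'   point, t = 0 at choice-display onset), `geometry`, `chosen_side`,
#'   `correct_side`.
#' @export
simulate_trajectory <- function(plausibility, congruency, order, params,
                                geometry, correct_side,
                                responds_correctly = TRUE,
                                dwell_s = params$latency_base_s,
                                lambda = NULL, conflict_offset = 0,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  correct_side <- match.arg(correct_side, c("left", "right"))
  if (is.null(lambda)) {
    basis <- design_basis(contrast_code(plausibility, PLAUSIBILITY_LEVELS),
                          contrast_code(congruency, CONGRUENCY_LEVELS),
                          contrast_code(order, ORDER_LEVELS))
    lambda <- softplus(sum(params$beta_conflict * basis) + conflict_offset)
  }
  if (!is.finite(lambda) || lambda < 0) {
    stop("conflict strength must be finite and non-negative", call. = FALSE)
  }
  chosen_side <- if (responds_correctly) correct_side else
    setdiff(c("left", "right"), correct_side)
  target <- button_at(geometry, chosen_side)
  other <- button_at(geometry, setdiff(c("left", "right"), chosen_side))

  hz <- geometry$sample_rate_hz
  max_steps <- as.integer(ceiling(params$max_duration_s * hz))
  res <- step_path_cpp(geometry$start, target, other, lambda,
                       params$base_speed_px_per_step, params$motor_noise_px,
                       params$conflict_w_frac, geometry$button_radius_px,
                       max_steps)
  if (!res$ok) {
    stop("simulation runaway: cursor did not reach the button within ",
         params$max_duration_s, " s", call. = FALSE)
  }
  n_hold <- max(1L, as.integer(round(dwell_s * hz)))
  xs <- c(rep(geometry$start[1], n_hold), res$path[, 1])
  ys <- c(rep(geometry$start[2], n_hold), res$path[, 2])
  n <- length(xs)
  traj <- list(
    samples = data.frame(t_ms = (seq_len(n) - 1) * 1000 / hz,
                         x_px = xs, y_px = ys),
    geometry = geometry,
    chosen_side = chosen_side,
    correct_side = correct_side
  )
  class(traj) <- "mt_trajectory"
  traj
}

#' Check the structural invariants of a raw trajectory
#'
#' Strictly increasing timestamps, first sample at the calibration point,
#' last sample within the button click radius of the chosen button.
#'
#' @param traj an `mt_trajectory`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_trajectory <- function(traj) {
  stopifnot(inherits(traj, "mt_trajectory"))
  s <- traj$samples
  g <- traj$geometry
  if (any(diff(s$t_ms) <= 0)) stop("timestamps not strictly increasing")
  if (s$x_px[1] != g$start[1] || s$y_px[1] != g$start[2]) {
    stop("first sample is not at the calibration point")
  }
  btn <- button_at(g, traj$chosen_side)
  last <- c(s$x_px[nrow(s)], s$y_px[nrow(s)])
  if (sqrt(sum((last - btn)^2)) > g$button_radius_px + 1e-9) {
    stop("last sample not within the click radius of the chosen button")
  }
  invisible(TRUE)
}

#' @export
print.mt_trajectory <- function(x, ...) {
  n <- nrow(x$samples)
  cat("cursor trajectory:", n, "samples,",
      sprintf("%.2f s,", x$samples$t_ms[n] / 1000),
      "chosen side:", x$chosen_side, "\n")
  invisible(x)
}

#' Simulate a full verification experiment
#'
#' For every scheduled trial, correctness is drawn from a Bernoulli whose
#' logit is the accuracy linear predictor plus participant and scene random
#' intercepts; the trajectory is simulated toward the responded button with
#' conflict strength from the conflict linear predictor (plus its own random
#' intercepts); the response time is the dwell (baseline + condition
#' effects + participant intercept + jitter) plus the movement duration.
#' Fully reproducible from `seed` via named substreams (participants,
#' scenes, accuracy, motor).
#'
#' @param schedules a [build_schedules()] result.
#' @param params a [sim_params()].
#' @param geometry a [screen_geometry()].
#' @param seed root integer seed.
#' @return data.frame of class `trial_table`, one row per trial, with a
#'   `trajectory` list-column of `mt_trajectory` objects.
#' @export
simulate_experiment <- function(schedules, params = sim_params(),
                                geometry = screen_geometry(), seed = 1L) {
  stopifnot(inherits(schedules, "schedules"))
  max_scene <- max(vapply(schedules, function(s) max(s$trials$scene_id), 1L))
  set.seed(substream_seed(seed, "scenes"))
  scene_acc <- rnorm(max_scene, 0, params$scene_sd)
  scene_conf <- rnorm(max_scene, 0, params$conflict_scene_sd)
  set.seed(substream_seed(seed, "participants"))
  n_p <- length(schedules)
  part_acc <- rnorm(n_p, 0, params$participant_sd)
  part_conf <- rnorm(n_p, 0, params$conflict_participant_sd)
  part_rt <- rnorm(n_p, 0, params$rt_participant_sd_s)

  flat <- do.call(rbind, lapply(schedules, function(s) {
    data.frame(participant_id = s$participant_id,
               trial_index = seq_len(nrow(s$trials)),
               scene_id = s$trials$scene_id,
               plausibility = s$trials$plausibility,
               congruency = s$trials$congruency,
               order = s$order, counterbalance = s$counterbalance,
               stringsAsFactors = FALSE)
  }))
  pl <- contrast_code(flat$plausibility, PLAUSIBILITY_LEVELS)
  cg <- contrast_code(flat$congruency, CONGRUENCY_LEVELS)
  od <- contrast_code(flat$order, ORDER_LEVELS)
  X <- cbind(1, pl, cg, od, pl * cg, pl * od, cg * od, pl * cg * od)

  acc_lp <- drop(X %*% params$beta_accuracy) +
    part_acc[flat$participant_id] + scene_acc[flat$scene_id]
  set.seed(substream_seed(seed, "accuracy"))
  responds_correctly <- runif(nrow(flat)) < plogis(acc_lp)

  answer <- answer_for(flat$congruency)
  response <- ifelse(responds_correctly, answer,
                     ifelse(answer == "yes", "no", "yes"))
  correct_side <- side_of(answer, flat$counterbalance)

  dwell_fix <- params$latency_base_s + drop(X %*% params$beta_rt_s) +
    part_rt[flat$participant_id]
  conf_lp <- drop(X %*% params$beta_conflict) +
    part_conf[flat$participant_id] + scene_conf[flat$scene_id]

  set.seed(substream_seed(seed, "motor"))
  n <- nrow(flat)
  trajectories <- vector("list", n)
  rt_s <- numeric(n)
  for (i in seq_len(n)) {
    dwell <- max(0.05, dwell_fix[i] + rnorm(1, 0, params$latency_jitter_s))
    traj <- simulate_trajectory(
      flat$plausibility[i], flat$congruency[i], flat$order[i],
      params, geometry, correct_side[i],
      responds_correctly = responds_correctly[i], dwell_s = dwell,
      lambda = softplus(conf_lp[i])
    )
    trajectories[[i]] <- traj
    rt_s[i] <- traj$samples$t_ms[nrow(traj$samples)] / 1000
  }
  out <- flat
  out$response <- response
  out$correct <- responds_correctly
  out$rt_s <- rt_s
  out$trajectory <- trajectories
  class(out) <- c("trial_table", "data.frame")
  out
}

#' @export
print.trial_table <- function(x, ...) {
  cat("trial table:", nrow(x), "trials,",
      length(unique(x$participant_id)), "participants; accuracy",
      sprintf("%.1f%%", 100 * mean(x$correct)), "\n")
  invisible(x)
}
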