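#' Derive a named RNG substream seed from a root seed
#'
#' Each stochastic stage (design, accuracy, motor, ...) consumes its own
#' substream so stages can be re-run independently with identical results.
#' Kept below 2^31 so it is a valid R integer seed.
#'
#' @param seed root integer seed.
#' @param stream substream name.
#' @return integer seed.
#' @export
substream_seed <- function(seed, stream) {
  offsets <- c(design = 1L, participants = 2L, scenes = 3L, accuracy = 4L,
               motor = 5L, replicate = 6L)
  off <- offsets[[match.arg(stream, names(offsets))]]
  as.integer((as.double(seed) * 48271 + off * 100003) %% 2147483647)
}

#' Screen and response-button geometry
#'
#' Defaults follow a 1024x768 display with the calibration circle at the
#' bottom-center of the screen, response buttons in the top corners inset
#' 15\% from the screen edges (equidistant from the vertical midline), a
#' 50-px start region and 60-Hz cursor sampling. Raw coordinates use the
#' screen convention: origin top-left, y increasing downward.
#'
#' @param width_px,height_px screen size in pixels.
#' @param start calibration-circle center `(x, y)` in pixels.
#' @param button_inset_frac fractional inset of the buttons from the screen
#'   corners.
#' @param start_radius_px radius of the start region (pixels).
#' @param button_radius_px click radius of a response button (pixels).
#' @param sample_rate_hz cursor sampling rate.
#' @return list of class `screen_geometry` with, additionally, `button_left`
#'   and `button_right` positions.
#' @export
screen_geometry <- function(width_px = 1024, height_px = 768,
                            start = c(width_px / 2, height_px - 18),
                            button_inset_frac = 0.15,
                            start_radius_px = 50, button_radius_px = 40,
                            sample_rate_hz = 60) {
  stopifnot(width_px > 0, height_px > 0, start_radius_px > 0,
            button_radius_px > 0, sample_rate_hz > 0,
            button_inset_frac > 0, button_inset_frac < 0.5)
  g <- list(
    width_px = width_px, height_px = height_px,
    start = as.numeric(start),
    button_left = c(width_px * button_inset_frac, height_px * button_inset_frac),
    button_right = c(width_px * (1 - button_inset_frac),
                     height_px * button_inset_frac),
    button_inset_frac = button_inset_frac,
    start_radius_px = start_radius_px,
    button_radius_px = button_radius_px,
    sample_rate_hz = sample_rate_hz
  )
  if (identical(g$button_left, g$button_right)) {
    stop("degenerate geometry: identical button positions", call. = FALSE)
  }
  class(g) <- "screen_geometry"
  g
}

#' Yes/no button positions under a counterbalance assignment
#'
#' @param geometry a [screen_geometry()].
#' @param counterbalance `"yes_left"` or `"yes_right"`.
#' @return list with `yes` and `no` positions.
#' @export
yes_no_positions <- function(geometry, counterbalance) {
  counterbalance <- match.arg(counterbalance, COUNTERBALANCE_LEVELS)
  if (counterbalance == "yes_left") {
    list(yes = geometry$button_left, no = geometry$button_right)
  } else {
    list(yes = geometry$button_right, no = geometry$button_left)
  }
}

#' Simulator parameters
#'
#' Coefficient vectors are on the eight-term contrast-coded design basis
#' `(intercept, plausibility, congruency, order, plaus:cong, plaus:order,
#' cong:order, plaus:cong:order)` with the +/-0.5 coding of
#' [code_contrasts()].
#'
#' Defaults emulate the qualitative effect structure of a sentence-scene
#' verification study: the accuracy logit row is anchored to published
#' model coefficients (intercept 2.87, plausibility 0.51, order -0.45,
#' plausibility:congruency 0.83), which under this coding makes the
#' implausible+congruent cell the least accurate; the conflict predictor
#' gives that same cell the strongest pull toward the competitor button;
#' the dwell (pre-movement) coefficients mirror the published latency
#' effects in seconds. Random-intercept sds for participants and scenes are
#' on the accuracy-logit scale and sized so the marginal accuracy is near
#' the observed ~87\%.
#'
#' @param beta_conflict coefficients mapping condition codes to the conflict
#'   linear predictor; conflict strength is `softplus(lp)` in px/step.
#' @param beta_accuracy coefficients of the correctness logit.
#' @param beta_rt_s coefficients (seconds) of the pre-movement dwell.
#' @param participant_sd,scene_sd sds of accuracy-logit random intercepts.
#' @param conflict_participant_sd,conflict_scene_sd sds of random intercepts
#'   on the conflict linear predictor.
#' @param rt_participant_sd_s sd (seconds) of the participant dwell
#'   intercept.
#' @param motor_noise_px per-step, per-axis Gaussian motor noise sd.
#' @param base_speed_px_per_step cursor speed toward the responded button.
#' @param latency_base_s,latency_jitter_s dwell baseline and per-trial
#'   jitter sd (seconds).
#' @param conflict_w_frac fraction of the ideal path length over which the
#'   competitor pull decays linearly from 1 to 0.
#' @param max_duration_s step cap; exceeding it raises a simulation-runaway
#'   error.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(
    beta_conflict = c(intercept = 18, plausibility = -2, congruency = 0.5,
                      order = 0, plaus_cong = -7, plaus_order = 0,
                      cong_order = 0, plaus_cong_order = 0),
    beta_accuracy = c(intercept = 2.87, plausibility = 0.51,
                      congruency = 0.005, order = -0.45, plaus_cong = 0.83,
                      plaus_order = 0.26, cong_order = -0.49,
                      plaus_cong_order = 0),
    beta_rt_s = c(intercept = 0, plausibility = -0.02, congruency = -0.007,
                  order = 0.01, plaus_cong = -0.001, plaus_order = 0.04,
                  cong_order = -0.03, plaus_cong_order = 0.001),
    participant_sd = 1.5, scene_sd = 1.2,
    conflict_participant_sd = 1, conflict_scene_sd = 0.5,
    rt_participant_sd_s = 0.05,
    motor_noise_px = 2.5, base_speed_px_per_step = 12,
    latency_base_s = 0.42, latency_jitter_s = 0.08,
    conflict_w_frac = 0.6, max_duration_s = 10) {
  stopifnot(
    length(beta_conflict) == 8, length(beta_accuracy) == 8,
    length(beta_rt_s) == 8,
    participant_sd >= 0, scene_sd >= 0, conflict_participant_sd >= 0,
    conflict_scene_sd >= 0, rt_participant_sd_s >= 0, motor_noise_px >= 0,
    base_speed_px_per_step > 0, latency_base_s >= 0, latency_jitter_s >= 0,
    conflict_w_frac > 0, conflict_w_frac <= 1, max_duration_s > 0
  )
  p <- list(
    beta_conflict = beta_conflict, beta_accuracy = beta_accuracy,
    beta_rt_s = beta_rt_s,
    participant_sd = participant_sd, scene_sd = scene_sd,
    conflict_participant_sd = conflict_participant_sd,
    conflict_scene_sd = conflict_scene_sd,
    rt_participant_sd_s = rt_participant_sd_s,
    motor_noise_px = motor_noise_px,
    base_speed_px_per_step = base_speed_px_per_step,
    latency_base_s = latency_base_s, latency_jitter_s = latency_jitter_s,
    conflict_w_frac = conflict_w_frac, max_duration_s = max_duration_s
  )
  class(p) <- "sim_params"
  p
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Expand +/-0.5 condition codes to the eight-term design basis
#'
#' @param plaus,cong,order numeric codes (+0.5 / -0.5).
#' @return named numeric vector of length 8.
#' @keywords internal
design_basis <- function(plaus, cong, order) {
  c(intercept = 1, plausibility = plaus, congruency = cong, order = order,
    plaus_cong = plaus * cong, plaus_order = plaus * order,
    cong_order = cong * order, plaus_cong_order = plaus * cong * order)
}
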