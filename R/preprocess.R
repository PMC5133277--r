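#' Remove response-time outliers
#'
#' Removes trials whose verification time exceeds the grand mean plus
#' `k` grand standard deviations (upper tail only, computed on the full
#' dataset).
#'
#' @param trials a `trial_table` (or any data.frame with an `rt_s` column).
#' @param k cutoff in standard deviations (default 4).
#' @return list with `trials` (retained rows) and `report`, a
#'   `filter_report` carrying the counts and the cutoff.
#' @export
filter_rt_outliers <- function(trials, k = 4) {
  stopifnot(is.numeric(k), k > 0)
  if (nrow(trials) < 2) {
    stop("need at least 2 trials to estimate the RT spread", call. = FALSE)
  }
  if (any(trials$rt_s <= 0)) stop("all rt_s must be positive", call. = FALSE)
  m <- mean(trials$rt_s)
  s <- sd(trials$rt_s)
  cutoff <- m + k * s
  keep <- trials$rt_s <= cutoff
  report <- list(
    n_input = nrow(trials),
    n_removed_rt = sum(!keep),
    n_removed_error_trials = NA_integer_,
    n_retained = sum(keep),
    rt_mean_s = m, rt_sd_s = s, rt_cutoff_s = cutoff, k_sd = k
  )
  class(report) <- "filter_report"
  list(trials = trials[keep, , drop = FALSE], report = report)
}

#' Restrict to accurate trials
#'
#' @param trials a `trial_table` with a logical `correct` column.
#' @return the correct trials; warns when the result is empty.
#' @export
select_correct <- function(trials) {
  stopifnot("correct" %in% names(trials))
  out <- trials[trials$correct, , drop = FALSE]
  if (nrow(out) == 0) warning("no correct trials retained")
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "trial filter: %d in, %d RT outliers removed (cutoff %.2f s = %.2f + %g sd), %d retained",
    x$n_input, x$n_removed_rt, x$rt_cutoff_s, x$rt_mean_s, x$k_sd, x$n_retained))
  if (!is.na(x$n_removed_error_trials)) {
    cat(sprintf("; %d error trials excluded from the dynamics analyses",
                x$n_removed_error_trials))
  }
  cat("\n")
  invisible(x)
}

#' Construct a canonical trajectory directly
#'
#' Canonical space: origin at the calibration point, y increasing toward
#' the response row with the button row at y = 1.5, x in [-1, 1] with the
#' INCORRECT button at +1 and the correct button at -1. `px_per_x` and
#' `px_per_y` record the raw-pixel equivalents of one standardized unit so
#' that pixel-defined quantities (the 50-px start region, x-flip jitter,
#' movement angles) can be evaluated in screen metric.
#'
#' @param t_ms,x_std,y_std sample vectors.
#' @param px_per_x,px_per_y pixels per standardized unit on each axis.
#' @param sample_rate_hz sampling rate.
#' @return object of class `canonical_trajectory`.
#' @export
canonical_trajectory <- function(t_ms, x_std, y_std, px_per_x = 358.4,
                                 px_per_y = 423.2, sample_rate_hz = 60) {
  stopifnot(length(t_ms) == length(x_std), length(x_std) == length(y_std),
            px_per_x > 0, px_per_y > 0)
  ct <- list(samples = data.frame(t_ms = t_ms, x_std = x_std, y_std = y_std),
             px_per_x = px_per_x, px_per_y = px_per_y,
             sample_rate_hz = sample_rate_hz)
  class(ct) <- "canonical_trajectory"
  ct
}

#' Put a raw trajectory into the canonical analysis frame
#'
#' Translates so the calibration point is the origin, flips y so upward
#' (toward the response row) is positive, reflects x when necessary so the
#' incorrect response lies at positive x, and rescales so the buttons sit
#' at x = +/-1 and the button row at y = 1.5. A point on the straight
#' start-to-correct-button line has signed perpendicular deviation 0, and
#' any trajectory ending on the correct button has a negative final x.
#' Idempotent on canonical input.
#'
#' @param traj an `mt_trajectory` (or an already-canonical trajectory,
#'   returned unchanged).
#' @param correct_side side of the correct button; defaults to the side
#'   recorded on the trajectory.
#' @return a [canonical_trajectory()].
#' @export
canonicalize <- function(traj, correct_side = traj$correct_side) {
  if (inherits(traj, "canonical_trajectory")) return(traj)
  stopifnot(inherits(traj, "mt_trajectory"))
  correct_side <- match.arg(correct_side, c("left", "right"))
  g <- traj$geometry
  sx <- abs(g$button_right[1] - g$start[1])
  sy <- g$start[2] - g$button_right[2]
  if (sx <= 0 || sy <= 0) {
    stop("degenerate geometry: buttons not offset from the start point",
         call. = FALSE)
  }
  x_dev <- traj$samples$x_px - g$start[1]
  y_up <- g$start[2] - traj$samples$y_px
  # positive x must point toward the INCORRECT button
  if (correct_side == "right") x_dev <- -x_dev
  canonical_trajectory(
    t_ms = traj$samples$t_ms,
    x_std = x_dev / sx,
    y_std = y_up / (sy / 1.5),
    px_per_x = sx, px_per_y = sy / 1.5,
    sample_rate_hz = g$sample_rate_hz
  )
}

#' @export
print.canonical_trajectory <- function(x, ...) {
  n <- nrow(x$samples)
  cat("canonical trajectory:", n, "samples, final position",
      sprintf("(%.2f, %.2f)", x$samples$x_std[n], x$samples$y_std[n]), "\n")
  invisible(x)
}

#' Time-normalize a canonical trajectory into angular bins
#'
#' Positions are linearly interpolated onto `n_bins` equally spaced time
#' points between trajectory onset and offset; each bin carries the signed
#' movement angle (degrees from vertical, in screen metric, positive toward
#' the incorrect response) of the displacement to the next bin, with the
#' final bin repeating the penultimate angle.
#'
#' @param traj a `canonical_trajectory`.
#' @param n_bins number of time bins (default 101).
#' @return data.frame with `bin`, `t_ms`, `x_std`, `y_std`, `angle_deg`.
#' @export
time_normalize <- function(traj, n_bins = 101L) {
  stopifnot(inherits(traj, "canonical_trajectory"), n_bins >= 2)
  s <- traj$samples
  if (nrow(s) < 2) stop("need at least 2 samples", call. = FALSE)
  if (s$t_ms[nrow(s)] <= s$t_ms[1]) {
    stop("zero-duration trajectory", call. = FALSE)
  }
  grid <- seq(s$t_ms[1], s$t_ms[nrow(s)], length.out = n_bins)
  x <- approx(s$t_ms, s$x_std, xout = grid)$y
  y <- approx(s$t_ms, s$y_std, xout = grid)$y
  dx_px <- diff(x) * traj$px_per_x
  dy_px <- diff(y) * traj$px_per_y
  ang <- atan2(dx_px, dy_px) * 180 / pi
  data.frame(bin = seq_len(n_bins), t_ms = grid, x_std = x, y_std = y,
             angle_deg = c(ang, ang[length(ang)]))
}

#' Run the full preprocessing stage
#'
#' RT-outlier removal on the full dataset, then restriction to accurate
#' trials, then canonicalization of every retained trajectory (stored in a
#' `canonical` list-column).
#'
#' @param trials a `trial_table` from [simulate_experiment()].
#' @param k_sd RT cutoff in standard deviations.
#' @return list with `trials` (correct trials, canonicalized — the set for
#'   the dynamics measures), `accuracy_trials` (the full RT-filtered set on
#'   which accuracy itself is analyzed) and `report`.
#' @export
preprocess_trials <- function(trials, k_sd = 4) {
  flt <- filter_rt_outliers(trials, k = k_sd)
  kept <- select_correct(flt$trials)
  flt$report$n_removed_error_trials <- flt$report$n_retained - nrow(kept)
  flt$report$n_retained <- nrow(kept)
  kept$canonical <- lapply(seq_len(nrow(kept)), function(i) {
    canonicalize(kept$trajectory[[i]])
  })
  list(trials = kept, accuracy_trials = flt$trials, report = flt$report)
}
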