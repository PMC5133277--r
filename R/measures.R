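px_coords <- function(traj) {
  cbind(x = traj$samples$x_std * traj$px_per_x,
        y = traj$samples$y_std * traj$px_per_y)
}

#' Initial movement angle
#'
#' Signed angle from vertical (degrees) of the cursor position at the first
#' sample outside a fixed radius around the start point; positive values
#' point toward the incorrect response. The radius is evaluated in screen
#' pixels (default 50 px). `NA` when the cursor never leaves the start
#' region.
#'
#' @param traj a `canonical_trajectory`.
#' @param start_radius_px start-region radius in pixels.
#' @return degrees, or `NA_real_`.
#' @export
initial_degree <- function(traj, start_radius_px = 50) {
  stopifnot(inherits(traj, "canonical_trajectory"))
  p <- px_coords(traj)
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  i <- which(r > start_radius_px)[1]
  if (is.na(i)) return(NA_real_)
  unname(atan2(p[i, 1], p[i, 2]) * 180 / pi)
}

#' Movement latency
#'
#' Time (seconds from choice-display onset) of the first sample outside the
#' start region. `NA` when the region is never exited.
#'
#' @inheritParams initial_degree
#' @return seconds, or `NA_real_`.
#' @export
latency <- function(traj, start_radius_px = 50) {
  stopifnot(inherits(traj, "canonical_trajectory"))
  p <- px_coords(traj)
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  i <- which(r > start_radius_px)[1]
  if (is.na(i)) return(NA_real_)
  traj$samples$t_ms[i] / 1000
}

#' Count directional changes on the x axis
#'
#' Walks along the horizontal displacement, collapsing sub-jitter
#' displacements into the running segment: a new segment is emitted only
#' once the cursor has moved at least `jitter_px` (screen pixels) from the
#' segment anchor. The returned count is the number of sign changes in the
#' surviving displacement sequence; `jitter_px = 0` reproduces the naive
#' sign-change count over all non-zero displacements.
#'
#' @param traj a `canonical_trajectory`.
#' @param jitter_px jitter threshold in pixels (default 3).
#' @return non-negative integer.
#' @export
xflips <- function(traj, jitter_px = 3) {
  stopifnot(inherits(traj, "canonical_trajectory"), jitter_px >= 0)
  x <- traj$samples$x_std * traj$px_per_x
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  anchor <- x[1]
  signs <- integer(0)
  for (xi in x[-1]) {
    d <- xi - anchor
    if (abs(d) >= jitter_px && d != 0) {
      signs <- c(signs, sign(d))
      anchor <- xi
    }
  }
  if (length(signs) < 2) return(0L)
  sum(diff(signs) != 0)
}

#' Signed area between the trajectory and the ideal response line
#'
#' Trapezoidal signed area between the sampled polyline and the straight
#' line from the start point to the correct response button (at (-1, 1.5)
#' in canonical space). Deviations toward the incorrect side accumulate
#' positively, excursions past the ideal line toward the far side
#' negatively; the net signed area is returned in standardized units.
#'
#' @param traj a `canonical_trajectory` with at least 2 samples.
#' @return signed area (standardized units^2).
#' @export
auc <- function(traj) {
  stopifnot(inherits(traj, "canonical_trajectory"))
  s <- traj$samples
  if (nrow(s) < 2) stop("need at least 2 samples", call. = FALSE)
  ideal <- c(-1, 1.5)
  len <- sqrt(sum(ideal^2))
  if (len == 0) stop("zero-length ideal line", call. = FALSE)
  u <- ideal / len
  # position along the ideal line and signed perpendicular deviation
  # (positive on the incorrect-button side)
  along <- s$x_std * u[1] + s$y_std * u[2]
  dev <- s$x_std * u[2] - s$y_std * u[1]
  sum(diff(along) * (head(dev, -1) + dev[-1]) / 2)
}

#' Compute all per-trial measures
#'
#' One row per trial with the six dependent measures: accuracy, response
#' time, initial degree, movement latency, x-flips and AUC. Trials whose
#' cursor never leaves the start region get `NA` initial degree and
#' latency.
#'
#' @param trials preprocessed trials (a data.frame with a `canonical`
#'   list-column, as from [preprocess_trials()]).
#' @param start_radius_px start-region radius in pixels.
#' @param jitter_px x-flip jitter threshold in pixels.
#' @return data.frame of class `measure_table`.
#' @export
measure_trials <- function(trials, start_radius_px = 50, jitter_px = 3) {
  stopifnot("canonical" %in% names(trials))
  n <- nrow(trials)
  out <- data.frame(
    participant_id = trials$participant_id,
    scene_id = trials$scene_id,
    plausibility = trials$plausibility,
    congruency = trials$congruency,
    order = trials$order,
    counterbalance = trials$counterbalance,
    accuracy = as.logical(trials$correct),
    rt_s = trials$rt_s,
    initial_degree = NA_real_, latency_s = NA_real_,
    xflips = NA_integer_, auc = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    ct <- trials$canonical[[i]]
    out$initial_degree[i] <- initial_degree(ct, start_radius_px)
    out$latency_s[i] <- latency(ct, start_radius_px)
    out$xflips[i] <- xflips(ct, jitter_px)
    out$auc[i] <- auc(ct)
  }
  class(out) <- c("measure_table", "data.frame")
  out
}

#' Summarize measures per design cell
#'
#' Mean and standard deviation of every measure in each order x congruency
#' x plausibility cell, in the style of an observed-data summary table.
#' With a single trial in a cell the SD is reported as 0 (population
#' convention); empty cells get `n = 0` and missing statistics.
#'
#' @param measures a `measure_table`.
#' @param accuracy_data optional data.frame (factor columns plus a logical
#'   `correct`) from which the accuracy row is computed instead — the
#'   convention is that accuracy is summarized over all retained trials
#'   while the dynamics measures are summarized over correct trials only.
#' @return data.frame of class `cell_summary`, one row per cell, with
#'   `<measure>_mean` / `<measure>_sd` columns.
#' @export
summarize_cells <- function(measures, accuracy_data = NULL) {
  stopifnot(nrow(measures) > 0)
  cells <- expand.grid(order = ORDER_LEVELS, congruency = CONGRUENCY_LEVELS,
                       plausibility = PLAUSIBILITY_LEVELS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  vars <- c("accuracy", "rt_s", "initial_degree", "latency_s", "xflips", "auc")
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- measures$order == cells$order[i] &
      measures$congruency == cells$congruency[i] &
      measures$plausibility == cells$plausibility[i]
    sub <- measures[sel, , drop = FALSE]
    stats <- lapply(vars, function(v) {
      x <- as.numeric(sub[[v]])
      x <- x[!is.na(x)]
      if (length(x) == 0) c(NA_real_, NA_real_)
      else c(mean(x), if (length(x) == 1) 0 else sd(x))
    })
    row <- c(list(order = cells$order[i], congruency = cells$congruency[i],
                  plausibility = cells$plausibility[i], n = nrow(sub)),
             setNames(unlist(stats),
                      paste0(rep(vars, each = 2), c("_mean", "_sd"))))
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(accuracy_data)) {
    for (i in seq_len(nrow(out))) {
      sel <- accuracy_data$order == out$order[i] &
        accuracy_data$congruency == out$congruency[i] &
        accuracy_data$plausibility == out$plausibility[i]
      y <- as.numeric(accuracy_data$correct[sel])
      if (length(y)) {
        out$accuracy_mean[i] <- mean(y)
        out$accuracy_sd[i] <- if (length(y) == 1) 0 else sd(y)
      }
    }
  }
  class(out) <- c("cell_summary", "data.frame")
  out
}
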