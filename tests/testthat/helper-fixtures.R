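# Small experiment used by several tests: 8 scenes, 8 participants x 8
# trials, default generator.
small_experiment <- function(seed = 42, n_scenes = 8, n_participants = 8,
                             per_participant = 8, params = sim_params()) {
  bank <- build_item_bank(n_scenes)
  lists <- build_latin_lists(bank)
  sched <- build_schedules(lists, n_participants, per_participant,
                           seed = seed)
  simulate_experiment(sched, params, seed = seed)
}

# Hand-built canonical trajectory with isotropic pixel scales, so geometry
# oracles can be written directly in pixels.
make_canonical <- function(x_px, y_px, px_per_unit = 100, dt_ms = 1000 / 60) {
  canonical_trajectory(
    t_ms = (seq_along(x_px) - 1) * dt_ms,
    x_std = x_px / px_per_unit,
    y_std = y_px / px_per_unit,
    px_per_x = px_per_unit, px_per_y = px_per_unit
  )
}

# Independent shoelace-polygon oracle for the signed area between a
# canonical polyline and the ideal start-to-correct-button line: close the
# polygon with the reversed ideal segment and take the signed shoelace
# area, oriented so that excursions toward the incorrect (positive-x) side
# count positive.
shoelace_auc <- function(x_std, y_std) {
  # project endpoints onto the ideal line so the polygon closes along it
  u <- c(-1, 1.5) / sqrt(1 + 1.5^2)
  proj <- function(x, y) {
    a <- x * u[1] + y * u[2]
    c(a * u[1], a * u[2])
  }
  p1 <- proj(x_std[1], y_std[1])
  pn <- proj(x_std[length(x_std)], y_std[length(y_std)])
  px <- c(p1[1], x_std, pn[1])
  py <- c(p1[2], y_std, pn[2])
  n <- length(px)
  s <- sum(px * py[c(2:n, 1)] - px[c(2:n, 1)] * py)
  # orientation: traversing the path toward (-1, 1.5) and closing back
  # along the ideal line turns excursions toward positive x into
  # counter-clockwise loops, so the raw shoelace sign is already the
  # incorrect-side-positive convention
  s / 2
}

# Brute-force x-flip count at jitter 0: sign changes over non-zero deltas.
brute_flips <- function(x) {
  d <- diff(x)
  s <- sign(d[d != 0])
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}
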