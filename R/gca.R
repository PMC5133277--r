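#' Build per-participant angular growth-curve profiles
#'
#' Time-normalizes every trial's canonical trajectory into `n_bins` angular
#' bins and averages the signed movement angle per participant x
#' plausibility x congruency x order cell per bin. Averaging within
#' participant-cell before modeling is the usual growth-curve-analysis
#' aggregation; it keeps the bin series from dominating the model with
#' within-trial autocorrelation.
#'
#' @param trials preprocessed trials with a `canonical` list-column.
#' @param n_bins number of time bins.
#' @return data.frame with `participant_id`, factor columns, `bin`,
#'   `angle_deg` and the contrast-code columns.
#' @export
gca_profiles <- function(trials, n_bins = 101L) {
  stopifnot("canonical" %in% names(trials), nrow(trials) > 0)
  pieces <- lapply(seq_len(nrow(trials)), function(i) {
    tn <- time_normalize(trials$canonical[[i]], n_bins = n_bins)
    data.frame(participant_id = trials$participant_id[i],
               plausibility = trials$plausibility[i],
               congruency = trials$congruency[i],
               order = trials$order[i],
               bin = tn$bin, angle_deg = tn$angle_deg,
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, pieces)
  agg <- stats::aggregate(
    angle_deg ~ participant_id + plausibility + congruency + order + bin,
    data = long, FUN = mean)
  code_contrasts(agg)
}

#' Growth-curve analysis of angular trajectories
#'
#' Mixed-effects regression of the time-normalized movement angle on
#' orthogonal polynomial time terms (default cubic) crossed with the
#' contrast-coded condition factors, with by-participant random intercept
#' and uncorrelated random slopes on the time terms.
#'
#' @param profiles a [gca_profiles()] result (or any data.frame with
#'   `angle_deg`, `bin`, code columns and `participant_id`).
#' @param poly_order polynomial order (default 3); must be below the number
#'   of bins.
#' @param df_policy passed to the coefficient table, as in
#'   [fit_lmm_maximal()].
#' @param condition_terms fixed condition structure crossed with time; the
#'   default crosses the full three-factor design.
#' @return an `mt_fit`; coefficient terms are labelled `ot1`..`otk` for the
#'   time basis and `ot1:Plausibility` etc. for the crossings.
#' @export
fit_gca <- function(profiles, poly_order = 3L,
                    df_policy = c("satterthwaite", "normal"),
                    condition_terms = "plaus_c * cong_c * order_c") {
  df_policy <- match.arg(df_policy)
  stopifnot(poly_order >= 1)
  bins <- sort(unique(profiles$bin))
  if (length(bins) < poly_order + 1) {
    stop("need more time bins than polynomial terms", call. = FALSE)
  }
  ot <- poly(profiles$bin, degree = poly_order)
  colnames(ot) <- paste0("ot", seq_len(poly_order))
  dat <- cbind(profiles, as.data.frame(ot))
  dat$participant_id <- factor(dat$participant_id)
  time_part <- paste(colnames(ot), collapse = " + ")
  fixed <- sprintf("angle_deg ~ (%s) * (%s)", time_part, condition_terms)
  rand <- paste(c("(1 | participant_id)",
                  sprintf("(0 + %s | participant_id)", colnames(ot))),
                collapse = " + ")
  formula <- paste(fixed, "+", rand)
  fit <- fit_engine(formula, dat, "gaussian", reml = TRUE)
  if (df_policy == "satterthwaite") fit <- lmerTest::as_lmerModLmerTest(fit)
  tab <- coef_table(fit, "gaussian", df_policy)
  tab$term <- vapply(strsplit(tab$term, ":", fixed = TRUE), function(parts) {
    paste(label_terms(parts), collapse = ":")
  }, "")
  new_mt_fit(tab, "angle_deg", "gaussian", df_policy, formula, fit,
             singular = lme4::isSingular(fit, tol = 1e-4),
             converged = length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0,
             reduction_path = character(0), n_obs = nrow(dat))
}
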