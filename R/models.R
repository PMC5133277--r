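TERM_LABELS <- c(
  "(Intercept)" = "Intercept",
  "plaus_c" = "Plausibility",
  "cong_c" = "Congruency",
  "order_c" = "Order",
  "plaus_c:cong_c" = "Plausibility:Congruency",
  "plaus_c:order_c" = "Plausibility:Order",
  "cong_c:order_c" = "Congruency:Order",
  "plaus_c:cong_c:order_c" = "Plausibility:Congruency:Order"
)

label_terms <- function(terms) {
  out <- TERM_LABELS[terms]
  out[is.na(out)] <- terms[is.na(out)]
  unname(out)
}

slope_code_of <- function(term) {
  # map an interaction slope label like pc_c back onto its product column
  term
}

# which candidate slope terms vary within the units of a grouping factor
varying_slopes <- function(data, group, candidates) {
  keep <- vapply(candidates, function(term) {
    any(tapply(data[[term]], data[[group]],
               function(v) length(unique(v)) > 1))
  }, TRUE)
  candidates[keep]
}

random_part <- function(slopes_by_group) {
  parts <- unlist(lapply(names(slopes_by_group), function(g) {
    c(sprintf("(1 | %s)", g),
      sprintf("(0 + %s | %s)", slopes_by_group[[g]], g))
  }))
  paste(parts, collapse = " + ")
}

# slope variances of a fitted merMod, named "group:term"
slope_sds <- function(fit) {
  vc <- lme4::VarCorr(fit)
  out <- numeric(0)
  for (g in names(vc)) {
    m <- vc[[g]]
    terms <- rownames(m)
    for (term in terms) {
      if (term != "(Intercept)") {
        grp <- sub("\\.[0-9]+$", "", g)  # lme4 suffixes repeated factors
        out[paste(grp, term, sep = ":")] <- sqrt(m[term, term])
      }
    }
  }
  out
}

# bobyqa with derivative checks off: same optima as the defaults on these
# models at a fraction of the cost
fit_engine <- function(formula, data, family, reml) {
  if (family == "gaussian") {
    suppressMessages(lme4::lmer(
      as.formula(formula), data = data, REML = reml,
      control = lme4::lmerControl(optimizer = "bobyqa",
                                  calc.derivs = FALSE)))
  } else {
    suppressMessages(lme4::glmer(
      as.formula(formula), data = data, family = family,
      control = lme4::glmerControl(optimizer = "bobyqa",
                                   calc.derivs = FALSE)))
  }
}

coef_table <- function(fit, family, df_policy) {
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)
  if (family == "gaussian" && "df" %in% colnames(sm)) {
    df <- sm[, "df"]
    stat <- sm[, "t value"]
    p <- if (df_policy == "normal") p_value(stat) else sm[, "Pr(>|t|)"]
    if (df_policy == "normal") df <- rep(Inf, length(stat))
  } else {
    stat <- sm[, grep("value", colnames(sm))[1]]
    df <- rep(Inf, length(stat))
    p <- p_value(stat)
  }
  data.frame(term = label_terms(terms), beta = unname(sm[, "Estimate"]),
             se = unname(sm[, "Std. Error"]), df = unname(df),
             stat = unname(stat), p = unname(p), stars = p_stars(unname(p)),
             stringsAsFactors = FALSE)
}

new_mt_fit <- function(coefficients, response, family, df_policy, formula,
                       model, singular, converged, reduction_path, n_obs) {
  structure(list(coefficients = coefficients, response = response,
                 family = family, df_policy = df_policy, formula = formula,
                 model = model, singular = singular, converged = converged,
                 reduction_path = reduction_path, n_obs = n_obs),
            class = "mt_fit")
}

#' Fit a contrast-coded maximal mixed-effects model
#'
#' Fixed effects are the three +/-0.5-coded factors with all two- and
#' three-way interactions. The random structure starts maximal: for every
#' grouping factor, a random intercept plus uncorrelated random slopes on
#' each requested predictor that varies within that factor's units (so,
#' e.g., no Order slope by participants, and intercept-only for
#' counterbalancing, a two-level grouping factor). Singular fits are pruned
#' automatically by dropping zero-variance slopes (smallest first) with the
#' reduction path logged.
#'
#' @param data trials or measures data.frame; contrast-code columns are
#'   added via [code_contrasts()] when absent. Rows with a missing response
#'   are dropped.
#' @param response name of the response column.
#' @param family `"gaussian"` (linear mixed model, REML) or `"poisson"`
#'   (log link, Laplace) for count measures.
#' @param groups named character vector of grouping-factor columns.
#' @param intercept_only_groups groups that only get a random intercept.
#' @param slope_terms candidate random-slope predictors (code columns).
#' @param df_policy `"satterthwaite"` (default; Satterthwaite degrees of
#'   freedom for linear models) or `"normal"` (normal reference for the
#'   t/z statistic).
#' @param reml fit linear models by REML (default) or ML.
#' @return object of class `mt_fit` with a `coefficients` table (term,
#'   beta, se, df, stat, p, stars), singularity/convergence flags and the
#'   pruning path.
#' @export
fit_lmm_maximal <- function(data, response,
                            family = c("gaussian", "poisson"),
                            groups = c("participant_id", "scene_id",
                                       "counterbalance"),
                            intercept_only_groups = "counterbalance",
                            slope_terms = c("plaus_c", "cong_c", "order_c",
                                            "pc_c"),
                            df_policy = c("satterthwaite", "normal"),
                            reml = TRUE) {
  family <- match.arg(family)
  df_policy <- match.arg(df_policy)
  if (!"plaus_c" %in% names(data)) data <- code_contrasts(data)
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  data[[response]] <- as.numeric(data[[response]])
  groups <- groups[groups %in% names(data)]
  fixed <- paste(response, "~ plaus_c * cong_c * order_c")

  if (length(groups) == 0) {
    fit <- lm(as.formula(fixed), data = data)
    sm <- summary(fit)$coefficients
    tab <- data.frame(term = label_terms(rownames(sm)),
                      beta = unname(sm[, 1]), se = unname(sm[, 2]),
                      df = fit$df.residual, stat = unname(sm[, 3]),
                      p = unname(sm[, 4]), stars = p_stars(unname(sm[, 4])),
                      stringsAsFactors = FALSE)
    return(new_mt_fit(tab, response, family, df_policy, fixed, fit,
                      singular = FALSE, converged = TRUE,
                      reduction_path = character(0), n_obs = nrow(data)))
  }

  for (g in groups) data[[g]] <- factor(data[[g]])
  groups <- groups[vapply(groups, function(g) nlevels(data[[g]]) >= 2, TRUE)]
  if (length(groups) == 0) stop("no grouping factor has >= 2 levels",
                                call. = FALSE)
  slopes_by_group <- lapply(setNames(groups, groups), function(g) {
    if (g %in% intercept_only_groups) character(0)
    else varying_slopes(data, g, slope_terms)
  })

  path <- character(0)
  # a linear mixed model needs fewer random-effect columns than
  # observations; on very small datasets shed slopes (scenes first, the
  # most level-rich factor) before attempting the fit
  re_cols <- function(sbg) sum(vapply(names(sbg), function(g) {
    nlevels(data[[g]]) * (1 + length(sbg[[g]]))
  }, 1))
  while (re_cols(slopes_by_group) >= nrow(data) &&
         sum(lengths(slopes_by_group)) > 0) {
    sizes <- vapply(names(slopes_by_group), function(g) {
      if (length(slopes_by_group[[g]]) == 0) 0L else nlevels(data[[g]])
    }, 1L)
    g <- names(slopes_by_group)[which.max(sizes)]
    term <- slopes_by_group[[g]][length(slopes_by_group[[g]])]
    slopes_by_group[[g]] <- setdiff(slopes_by_group[[g]], term)
    path <- c(path, sprintf(
      "dropped (0 + %s | %s): random structure larger than the data",
      term, g))
  }
  repeat {
    formula <- paste(fixed, "+", random_part(slopes_by_group))
    fit <- fit_engine(formula, data, family, reml)
    singular <- lme4::isSingular(fit, tol = 1e-4)
    n_slopes <- sum(lengths(slopes_by_group))
    if (!singular || n_slopes == 0) break
    sds <- slope_sds(fit)
    scale <- if (family == "gaussian") sd(data[[response]]) else 1
    # drop every slope estimated at (essentially) the boundary in one pass,
    # otherwise the smallest one, and refit until the fit is no longer
    # singular or no slopes remain; zero-variance random intercepts stay in
    # the model and are reported via the singularity flag
    drop <- names(sds)[sds < 1e-3 * scale]
    if (length(drop) == 0) drop <- names(sds)[which.min(sds)]
    for (d in drop) {
      parts <- strsplit(d, ":", fixed = TRUE)[[1]]
      g <- parts[1]; term <- parts[2]
      slopes_by_group[[g]] <- setdiff(slopes_by_group[[g]], term)
      path <- c(path, sprintf("dropped (0 + %s | %s), sd = %.3g", term, g,
                              sds[[d]]))
    }
  }
  conv_msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(conv_msgs) || length(conv_msgs) == 0
  if (family == "gaussian" && df_policy == "satterthwaite") {
    fit <- lmerTest::as_lmerModLmerTest(fit)
  }
  new_mt_fit(coef_table(fit, family, df_policy), response, family, df_policy,
             formula, fit, singular = singular, converged = converged,
             reduction_path = path, n_obs = nrow(data))
}

#' Fit the accuracy model (binomial logit GLMM)
#'
#' Same contrast-coded fixed structure as [fit_lmm_maximal()], binomial
#' family with logit link (Laplace approximation). By default the random
#' structure is reduced to intercepts per grouping factor — the usual
#' concession to GLMM estimation — and the reduction is recorded on the
#' returned object; `random_slopes = TRUE` requests the maximal structure
#' with the same singularity pruning as the linear models.
#'
#' @inheritParams fit_lmm_maximal
#' @param random_slopes start from the maximal slope structure.
#' @return an `mt_fit`.
#' @export
fit_accuracy_glmm <- function(data, response = "accuracy",
                              groups = c("participant_id", "scene_id",
                                         "counterbalance"),
                              slope_terms = c("plaus_c", "cong_c", "pc_c"),
                              random_slopes = FALSE) {
  if (!"plaus_c" %in% names(data)) data <- code_contrasts(data)
  y <- as.numeric(data[[response]])
  if (!all(y %in% c(0, 1))) stop("response must be binary", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("complete separation: response has no variation (all ",
         if (y[1] == 1) "correct" else "incorrect", ")", call. = FALSE)
  }
  data[[response]] <- y
  groups <- groups[groups %in% names(data)]
  for (g in groups) data[[g]] <- factor(data[[g]])
  groups <- groups[vapply(groups, function(g) nlevels(data[[g]]) >= 2, TRUE)]
  fixed <- paste(response, "~ plaus_c * cong_c * order_c")
  path <- character(0)
  slopes_by_group <- lapply(setNames(groups, groups), function(g) {
    if (random_slopes && g != "counterbalance")
      varying_slopes(data, g, slope_terms)
    else character(0)
  })
  if (!random_slopes) {
    path <- "random structure reduced to intercepts (binomial GLMM default)"
  }
  repeat {
    formula <- paste(fixed, "+", random_part(slopes_by_group))
    fit <- fit_engine(formula, data, "binomial", reml = FALSE)
    singular <- lme4::isSingular(fit, tol = 1e-4)
    if (!singular || sum(lengths(slopes_by_group)) == 0) break
    sds <- slope_sds(fit)
    drop <- names(sds)[which.min(sds)]
    parts <- strsplit(drop, ":", fixed = TRUE)[[1]]
    slopes_by_group[[parts[1]]] <- setdiff(slopes_by_group[[parts[1]]],
                                           parts[2])
    path <- c(path, sprintf("dropped (0 + %s | %s), sd = %.3g", parts[2],
                            parts[1], sds[[drop]]))
  }
  conv_msgs <- fit@optinfo$conv$lme4$messages
  if (any(grepl("failed to converge", unlist(conv_msgs %||% list())))) {
    # boundary trouble with near-saturated accuracy is surfaced, not hidden
    warning("accuracy GLMM reported convergence issues: ",
            paste(unlist(conv_msgs), collapse = "; "))
  }
  new_mt_fit(coef_table(fit, "binomial", "normal"), response, "binomial",
             "normal", formula, fit, singular = singular,
             converged = is.null(conv_msgs) || length(conv_msgs) == 0,
             reduction_path = path, n_obs = nrow(data))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mt_fit <- function(x, digits = 3, ...) {
  cat(sprintf("%s mixed model for '%s' (df policy: %s, n = %d)\n",
              x$family, x$response, x$df_policy, x$n_obs))
  tab <- x$coefficients
  tab$beta <- round(tab$beta, digits)
  tab$stat <- round(tab$stat, 2)
  tab$p <- signif(tab$p, 2)
  print(tab[, c("term", "beta", "stat", "p", "stars")], row.names = FALSE)
  if (x$singular) cat("note: fit is singular after pruning\n")
  if (length(x$reduction_path)) {
    cat("reduction path:\n")
    cat(paste0("  - ", x$reduction_path, collapse = "\n"), "\n")
  }
  invisible(x)
}
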