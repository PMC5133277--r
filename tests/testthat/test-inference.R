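test_that("contrast coding matches the reporting convention", {
  d <- data.frame(
    plausibility = c("plausible", "implausible"),
    congruency = c("congruent", "incongruent"),
    order = c("scene_first", "sentence_first"))
  cc <- code_contrasts(d)
  # Plausible/Congruent/Scene-First -> all +0.5; products +0.25 / +0.125
  expect_equal(unlist(cc[1, c("plaus_c", "cong_c", "order_c")]),
               c(plaus_c = 0.5, cong_c = 0.5, order_c = 0.5))
  expect_equal(unlist(cc[1, c("pc_c", "po_c", "co_c", "pco_c")]),
               c(pc_c = 0.25, po_c = 0.25, co_c = 0.25, pco_c = 0.125))
  # Implausible/Incongruent/Sentence-First -> all -0.5
  expect_equal(unlist(cc[2, c("plaus_c", "cong_c", "order_c")]),
               c(plaus_c = -0.5, cong_c = -0.5, order_c = -0.5))
  expect_equal(cc$pco_c[2], -0.125)
  expect_error(code_contrasts(data.frame(plausibility = "maybe",
                                         congruency = "congruent",
                                         order = "scene_first")),
               "unknown plausibility")
})

test_that("a balanced design has centered predictors", {
  d <- simulate_null_dataset(8, 16, seed = 2)
  for (v in c("plaus_c", "cong_c", "pc_c", "po_c", "co_c", "pco_c")) {
    expect_equal(mean(d[[v]]), 0, tolerance = 1e-12)
  }
})

test_that("two-tailed p-values and stars follow the normal reference", {
  expect_equal(p_value(0), 1)
  expect_equal(p_value(1.959964), 0.05, tolerance = 1e-6)
  expect_equal(p_value(2, df = 10), 2 * pt(-2, 10))
  expect_identical(p_stars(c(5e-4, 0.005, 0.03, 0.2)),
                   c("***", "**", "*", ""))
  # threshold edges are exclusive
  expect_identical(p_stars(c(0.001, 0.01, 0.05)), c("**", "*", ""))
  expect_identical(format_coef(0.51, 0.004), "0.51 **")
})

test_that("boundary mixed fits agree with ordinary least squares", {
  # iid noise: all random variances at the boundary; the pruned mixed model
  # must reproduce the OLS fixed effects
  d <- simulate_null_dataset(8, 16, seed = 7)
  fit <- fit_lmm_maximal(d, "y")
  ols <- fit_lmm_maximal(d, "y", groups = character(0))
  expect_equal(fit$coefficients$beta, ols$coefficients$beta,
               tolerance = 1e-6)
})

test_that("flipping a factor's labels flips its main-effect sign exactly", {
  d <- simulate_null_dataset(8, 16, seed = 13)
  d$y <- d$y + 0.4 * d$plaus_c + 0.2 * d$pc_c
  flip <- d
  flip$plausibility <- ifelse(d$plausibility == "plausible", "implausible",
                              "plausible")
  flip <- code_contrasts(flip[, setdiff(names(flip),
                                        c("plaus_c", "cong_c", "order_c",
                                          "pc_c", "po_c", "co_c", "pco_c"))])
  f1 <- fit_lmm_maximal(d, "y", slope_terms = character(0))
  f2 <- fit_lmm_maximal(flip, "y", slope_terms = character(0))
  b1 <- setNames(f1$coefficients$beta, f1$coefficients$term)
  b2 <- setNames(f2$coefficients$beta, f2$coefficients$term)
  expect_equal(b2[["Plausibility"]], -b1[["Plausibility"]],
               tolerance = 1e-8)
  expect_equal(b2[["Plausibility:Congruency"]],
               -b1[["Plausibility:Congruency"]], tolerance = 1e-8)
  expect_equal(b2[["Congruency"]], b1[["Congruency"]], tolerance = 1e-8)
  expect_equal(b2[["Intercept"]], b1[["Intercept"]], tolerance = 1e-8)
})

test_that("a pure intercept plus group noise is recovered", {
  set.seed(5)
  d <- simulate_null_dataset(12, 24, seed = 5, sigma = 0.3)
  mu <- 1.4
  re <- rnorm(12, 0, 0.2)
  d$y <- mu + re[d$participant_id] + d$y
  fit <- fit_lmm_maximal(d, "y")
  b <- fit$coefficients
  expect_equal(b$beta[b$term == "Intercept"], mu, tolerance = 0.15)
  # condition effects stay within sampling error of zero (between-
  # participant terms see only 12 participant intercepts)
  expect_true(all(abs(b$beta[b$term != "Intercept"]) < 0.3))
})

test_that("random-slope candidates respect within-unit variation", {
  d <- simulate_null_dataset(8, 16, seed = 3)
  fit <- fit_lmm_maximal(d, "y")
  # order is between participants and counterbalance is intercept-only, so
  # no formula term for either slope may appear
  expect_false(grepl("0 \\+ order_c \\| participant_id", fit$formula))
  expect_false(grepl("0 \\+ .* \\| counterbalance", fit$formula))
  # scenes see both orders, so the scene slope on order is a candidate
  expect_true(any(grepl("order_c \\| scene_id",
                        c(fit$formula, fit$reduction_path))))
})

test_that("accuracy GLMM guards its response contract", {
  d <- simulate_null_dataset(6, 8, seed = 1)
  d$accuracy <- TRUE
  expect_error(fit_accuracy_glmm(d), "separation")
  d$accuracy <- runif(nrow(d))
  expect_error(fit_accuracy_glmm(d), "binary")
})

test_that("accuracy GLMM recovers condition effects on the logit scale", {
  params <- sim_params(
    beta_accuracy = c(intercept = 1.2, plausibility = 1.5, congruency = 0,
                      order = 0, plaus_cong = 0, plaus_order = 0,
                      cong_order = 0, plaus_cong_order = 0),
    participant_sd = 0.3, scene_sd = 0.3)
  trials <- small_experiment(seed = 61, n_scenes = 24, n_participants = 24,
                             per_participant = 24, params = params)
  trials$accuracy <- trials$correct
  fit <- fit_accuracy_glmm(code_contrasts(trials))
  b <- fit$coefficients
  expect_equal(b$beta[b$term == "Plausibility"], 1.5, tolerance = 0.6)
  expect_gt(b$stat[b$term == "Plausibility"], 2)
  expect_equal(fit$family, "binomial")
  expect_match(fit$reduction_path[1], "reduced to intercepts")
})

test_that("count measures go through the poisson-log path", {
  d <- simulate_null_dataset(8, 16, seed = 17)
  lam <- exp(0.3 + 0.4 * d$plaus_c)
  set.seed(9)
  d$k <- rpois(nrow(d), lam)
  fit <- fit_lmm_maximal(d, "k", family = "poisson")
  expect_equal(fit$family, "poisson")
  b <- fit$coefficients
  expect_equal(b$beta[b$term == "Intercept"], 0.3, tolerance = 0.25)
  expect_equal(b$beta[b$term == "Plausibility"], 0.4, tolerance = 0.4)
})
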