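#' Add centered +/-0.5 contrast codes and their products
#'
#' Coding fixed by the reporting convention: Plausible = +0.5, Implausible
#' = -0.5; Congruent = +0.5, Incongruent = -0.5; Scene-First = +0.5,
#' Sentence-First = -0.5. Adds the three main-effect code columns plus the
#' three two-way and one three-way product columns.
#'
#' @param trials data.frame with `plausibility`, `congruency`, `order`
#'   columns holding valid factor levels.
#' @return the input with columns `plaus_c`, `cong_c`, `order_c`, `pc_c`,
#'   `po_c`, `co_c`, `pco_c` appended.
#' @export
code_contrasts <- function(trials) {
  check_levels <- function(x, levels, what) {
    bad <- setdiff(unique(as.character(x)), levels)
    if (length(bad)) {
      stop("unknown ", what, " level(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  check_levels(trials$plausibility, PLAUSIBILITY_LEVELS, "plausibility")
  check_levels(trials$congruency, CONGRUENCY_LEVELS, "congruency")
  check_levels(trials$order, ORDER_LEVELS, "order")
  trials$plaus_c <- contrast_code(trials$plausibility, PLAUSIBILITY_LEVELS)
  trials$cong_c <- contrast_code(trials$congruency, CONGRUENCY_LEVELS)
  trials$order_c <- contrast_code(trials$order, ORDER_LEVELS)
  trials$pc_c <- trials$plaus_c * trials$cong_c
  trials$po_c <- trials$plaus_c * trials$order_c
  trials$co_c <- trials$cong_c * trials$order_c
  trials$pco_c <- trials$plaus_c * trials$cong_c * trials$order_c
  trials
}

#' Two-tailed p-value for a model statistic
#'
#' @param stat t or z statistic.
#' @param df degrees of freedom; `Inf` (the default) gives the normal
#'   reference.
#' @return p-value in (0, 1].
#' @export
p_value <- function(stat, df = Inf) {
  stopifnot(all(is.finite(stat)))
  2 * pt(-abs(stat), df = df)
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty
#' otherwise.
#'
#' @param p p-value(s).
#' @return character vector.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}
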