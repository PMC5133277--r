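MEASURE_LABELS <- c(accuracy = "Accuracy (%)",
                    rt_s = "Response time (second)",
                    initial_degree = "Initial degree (degree)",
                    latency_s = "Latency (second)",
                    xflips = "X-flips (count)",
                    auc = "Area under curve (AUC)")

#' Format a coefficient with its significance stars
#'
#' @param beta coefficient.
#' @param p p-value.
#' @param digits decimals (default 2).
#' @return e.g. `"0.51 **"`.
#' @export
format_coef <- function(beta, p, digits = 2) {
  stars <- p_stars(p)
  paste0(formatC(beta, format = "f", digits = digits),
         ifelse(stars == "", "", paste0(" ", stars)))
}

#' Render the observed-data summary grid as markdown
#'
#' One row per measure, one column per order x congruency x plausibility
#' cell, each entry `mean ±sd` to two decimals.
#'
#' @param summary a [summarize_cells()] result.
#' @return character vector of markdown lines.
#' @export
table1_markdown <- function(summary) {
  cells <- summary[order(match(summary$order, ORDER_LEVELS),
                         match(summary$congruency, CONGRUENCY_LEVELS),
                         match(summary$plausibility, PLAUSIBILITY_LEVELS)), ]
  hdr <- paste0(cells$order, "/", cells$congruency, "/", cells$plausibility)
  lines <- c(paste0("| Measure | ", paste(hdr, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(hdr) + 1), collapse = "|"),
                    "|"))
  for (m in names(MEASURE_LABELS)) {
    vals <- sprintf("%.2f ±%.2f", cells[[paste0(m, "_mean")]],
                    cells[[paste0(m, "_sd")]])
    vals[is.na(cells[[paste0(m, "_mean")]])] <- "—"
    lines <- c(lines, paste0("| ", MEASURE_LABELS[[m]], " | ",
                             paste(vals, collapse = " | "), " |"))
  }
  lines
}

#' Render the model-coefficient grid as markdown
#'
#' One row per fixed term, per measure a `beta` (with stars) and `t`
#' column, in the style of a mixed-model coefficient table.
#'
#' @param fits named list of `mt_fit` objects (names = measure labels).
#' @return character vector of markdown lines; header only (with a warning)
#'   when `fits` is empty.
#' @export
table2_markdown <- function(fits) {
  if (length(fits) == 0) {
    warning("no fits supplied; rendering a header-only table")
    return(c("| Term |", "|---|"))
  }
  terms <- fits[[1]]$coefficients$term
  hdr <- unlist(lapply(names(fits), function(nm) c(paste0(nm, " β"),
                                                   paste0(nm, " t"))))
  lines <- c(paste0("| Term | ", paste(hdr, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(hdr) + 1), collapse = "|"),
                    "|"))
  for (term in terms) {
    row <- unlist(lapply(fits, function(f) {
      i <- match(term, f$coefficients$term)
      if (is.na(i)) return(c("—", "—"))
      c(format_coef(f$coefficients$beta[i], f$coefficients$p[i]),
        formatC(f$coefficients$stat[i], format = "f", digits = 2))
    }))
    lines <- c(lines, paste0("| ", term, " | ", paste(row, collapse = " | "),
                             " |"))
  }
  c(lines,
    "",
    "\\* p<0.05, \\*\\* p<0.01, \\*\\*\\* p<0.001")
}

#' Flatten a list of fits into a tidy coefficient data.frame
#'
#' @param fits named list of `mt_fit`.
#' @return data.frame with a `measure` column prepended.
#' @export
fits_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    cbind(measure = nm, fits[[nm]]$coefficients, stringsAsFactors = FALSE)
  }))
}
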