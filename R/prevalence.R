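#' Survey-weighted prevalence of a condition
#'
#' The population-weighted prevalence is the weighted mean of the 0/1
#' indicator, sum(w * x) / sum(w), over the selected subjects. With all
#' weights equal to 1 this reduces exactly to the sample proportion.
#'
#' @param cohort a [cohort_table()].
#' @param condition condition label.
#' @param stratum stratum label, or `NULL`/`"all"` for the whole cohort.
#' @return a proportion in [0, 1].
#' @export
weighted_prevalence <- function(cohort, condition, stratum = NULL) {
  if (!condition %in% condition_names(cohort)) {
    stop("unknown condition: ", condition)
  }
  rows <- stratum_rows(cohort, stratum)
  if (length(rows) == 0) stop("empty stratum: ", stratum)
  w <- cohort$weight[rows]
  sum(w * cohort[[condition]][rows]) / sum(w)
}

#' Weighted distribution of per-subject morbidity counts
#'
#' Summarises how many of the K conditions each subject carries: the
#' weighted proportion of subjects at each count 0..K, the multimorbidity
#' prevalence (weighted proportion with two or more conditions, the usual
#' definition of multimorbidity), the proportion free of all conditions,
#' the weighted median count (lowest count whose cumulative weighted
#' proportion reaches 0.5) and the maximum observed count.
#'
#' @param cohort a [cohort_table()].
#' @param stratum optional stratum label; default all subjects.
#' @return a `morbidity_distribution`: list with `distribution` (data frame
#'   of `count`, `proportion`), `multimorbid`, `prop_zero`, `median_count`,
#'   `max_count`.
#' @export
morbidity_distribution <- function(cohort, stratum = NULL) {
  rows <- stratum_rows(cohort, stratum)
  x <- indicator_matrix(cohort)[rows, , drop = FALSE]
  w <- cohort$weight[rows]
  K <- ncol(x)
  counts <- rowSums(x)
  prop <- vapply(0:K, function(k) sum(w[counts == k]) / sum(w), numeric(1))
  cum <- cumsum(prop)
  structure(list(
    distribution = data.frame(count = 0:K, proportion = prop),
    multimorbid = sum(prop[-(1:2)]),
    prop_zero = prop[1],
    median_count = (0:K)[which(cum >= 0.5)[1]],
    max_count = max(counts)
  ), class = "morbidity_distribution")
}

#' @export
print.morbidity_distribution <- function(x, ...) {
  cat("<morbidity_distribution>\n")
  cat(sprintf("  multimorbid (>= 2 conditions): %.2f%%\n",
              100 * x$multimorbid))
  cat(sprintf("  no condition: %.2f%%   median count: %d   max count: %d\n",
              100 * x$prop_zero, x$median_count, x$max_count))
  invisible(x)
}

#' Per-condition sex-association tests with FDR correction
#'
#' For each condition, tests association between condition status and the
#' (exactly two) strata with a 1-df chi-square test on the unweighted 2x2
#' contingency table, without continuity correction. Raw p-values are
#' adjusted across the K conditions by the Benjamini-Hochberg false
#' discovery rate; conditions with adjusted q < 0.05 are flagged
#' significant. Weighted prevalences (total and per stratum) are reported
#' alongside so the table mirrors the usual survey presentation: weighted
#' percentages, count-based tests.
#'
#' A condition with zero variance overall (all subjects 0, or all 1) has no
#' testable 2x2 table; its test fields are recorded as `NA` rather than
#' failing the run.
#'
#' @param cohort a [cohort_table()] with exactly two strata.
#' @param q_cutoff significance cut on the adjusted q-value (default 0.05).
#' @return a `prevalence_table` data frame: one row per condition with
#'   total and per-stratum weighted prevalence, per-stratum positive counts
#'   and sizes, `chisq`, `p_value`, `q_value`, `significant`.
#' @export
sex_association_tests <- function(cohort, q_cutoff = 0.05) {
  strata <- cohort_strata(cohort)
  if (length(strata) != 2) {
    stop("sex_association_tests needs exactly two strata, found ",
         length(strata))
  }
  cn <- condition_names(cohort)
  s1 <- strata[1]; s2 <- strata[2]
  r1 <- stratum_rows(cohort, s1); r2 <- stratum_rows(cohort, s2)
  res <- lapply(cn, function(cond) {
    x <- cohort[[cond]]
    n1 <- sum(x[r1]); n2 <- sum(x[r2])
    row <- data.frame(
      condition = cond,
      prev_total = weighted_prevalence(cohort, cond),
      stringsAsFactors = FALSE
    )
    row[[paste0("prev_", s1)]] <- weighted_prevalence(cohort, cond, s1)
    row[[paste0("prev_", s2)]] <- weighted_prevalence(cohort, cond, s2)
    row[[paste0("npos_", s1)]] <- n1
    row[[paste0("npos_", s2)]] <- n2
    if (sum(x) == 0 || sum(x) == length(x)) {
      row$chisq <- NA_real_
      row$p_value <- NA_real_
    } else {
      tab <- rbind(c(n1, length(r1) - n1), c(n2, length(r2) - n2))
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      row$chisq <- unname(ct$statistic)
      row$p_value <- ct$p.value
    }
    row
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$q_value) & out$q_value < q_cutoff
  attr(out, "strata") <- strata
  attr(out, "n_strata") <- c(length(r1), length(r2))
  class(out) <- c("prevalence_table", "data.frame")
  out
}
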