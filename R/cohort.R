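#' Construct a cohort table
#'
#' A cohort table is the package's central data structure: one row per
#' survey participant carrying a unique subject identifier, a stratum label
#' (sex in the motivating analysis), a strictly positive survey weight, and
#' one 0/1 indicator column per medical condition. All downstream stages
#' (prevalence, rule mining, networks) consume this object.
#'
#' @param subject_id character or integer vector of unique identifiers.
#' @param stratum character vector of stratum labels (e.g. `"male"`,
#'   `"female"`).
#' @param weight numeric vector of positive survey weights. Weighted
#'   estimates use these; test statistics use raw counts.
#' @param indicators matrix or data frame of 0/1 condition indicators, one
#'   column per condition. Column names become the condition names unless
#'   `condition_names` is given.
#' @param condition_names optional character vector overriding the
#'   indicator column names.
#'
#' @return A `cohort_table`: a data frame with columns `subject_id`,
#'   `stratum`, `weight` followed by the indicator columns, carrying a
#'   `condition_names` attribute.
#' @export
cohort_table <- function(subject_id, stratum, weight, indicators,
                         condition_names = NULL) {
  indicators <- as.matrix(indicators)
  storage.mode(indicators) <- "integer"
  if (!is.null(condition_names)) colnames(indicators) <- condition_names
  if (is.null(colnames(indicators))) {
    stop("indicator columns must be named (condition names)")
  }
  df <- data.frame(
    subject_id = as.character(subject_id),
    stratum = as.character(stratum),
    weight = as.numeric(weight),
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(indicators))
  new_cohort_table(df, colnames(indicators))
}

new_cohort_table <- function(df, condition_names) {
  rownames(df) <- NULL
  structure(df,
    condition_names = condition_names,
    class = c("cohort_table", "data.frame")
  )
}

#' Condition names of a cohort table
#' @param cohort a `cohort_table`.
#' @return character vector of the K condition labels, in column order.
#' @export
condition_names <- function(cohort) attr(cohort, "condition_names")

#' Stratum labels present in a cohort table
#' @param cohort a `cohort_table`.
#' @return character vector of unique stratum labels, in order of first
#'   appearance.
#' @export
cohort_strata <- function(cohort) unique(cohort$stratum)

#' Validate a cohort table
#'
#' Checks the structural invariants: unique subject ids, strictly positive
#' weights, exactly 0/1 indicators, and indicator columns matching the
#' recorded condition names in order.
#'
#' @param cohort object to validate.
#' @return the validated `cohort_table`, invisibly usable in pipelines.
#' @export
validate_cohort_table <- function(cohort) {
  if (!inherits(cohort, "cohort_table")) stop("not a cohort_table")
  cn <- condition_names(cohort)
  core <- c("subject_id", "stratum", "weight")
  if (!identical(names(cohort), c(core, cn))) {
    stop("cohort columns must be subject_id, stratum, weight, then the ",
         "indicator columns in condition_names order")
  }
  if (anyDuplicated(cohort$subject_id)) {
    stop("duplicate subject_id values: ",
         sum(duplicated(cohort$subject_id)), " duplicates")
  }
  if (any(!is.finite(cohort$weight)) || any(cohort$weight <= 0)) {
    bad <- which(!is.finite(cohort$weight) | cohort$weight <= 0)
    stop("non-positive or missing weights on ", length(bad),
         " row(s), first at row ", bad[1])
  }
  x <- indicator_matrix(cohort)
  if (anyNA(x) || !all(x == 0L | x == 1L)) {
    stop("indicators must be exactly 0 or 1 with no missing values")
  }
  invisible(cohort)
}

#' Indicator matrix of a cohort
#'
#' @param cohort a `cohort_table`.
#' @param stratum optional stratum label; `NULL` selects all subjects.
#' @return integer matrix, subjects x conditions.
#' @export
indicator_matrix <- function(cohort, stratum = NULL) {
  rows <- stratum_rows(cohort, stratum)
  x <- as.matrix(cohort[rows, condition_names(cohort), drop = FALSE])
  storage.mode(x) <- "integer"
  x
}

stratum_rows <- function(cohort, stratum = NULL) {
  if (is.null(stratum) || identical(stratum, "all")) {
    return(seq_len(nrow(cohort)))
  }
  if (!stratum %in% cohort$stratum) {
    stop("unknown stratum: ", stratum)
  }
  which(cohort$stratum == stratum)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x), " subjects, ",
      length(condition_names(x)), " conditions\n", sep = "")
  tab <- table(x$stratum)
  cat("strata: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  NextMethod()
  invisible(x)
}
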