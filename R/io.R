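#' Write a cohort table to CSV
#'
#' Header `subject_id,stratum,weight,<condition_1>,...,<condition_K>`,
#' indicators encoded 0/1, full double precision on the weights.
#'
#' @param cohort a [cohort_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort_table(cohort)
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Reads a subject-by-condition table and validates it into a
#' [cohort_table()]. Every column other than the id, stratum and weight
#' columns is taken as a condition indicator. Accepted indicator encodings
#' are 0/1 and true/false (case-insensitive). Diagnostics name the
#' offending rows: missing indicators, non-positive weights and duplicate
#' subject ids are all rejected with counts and first row numbers.
#'
#' @param path CSV file with a header row.
#' @param id_col,stratum_col,weight_col column names (defaults
#'   `subject_id`, `stratum`, `weight`).
#' @return a validated [cohort_table()].
#' @export
read_cohort <- function(path, id_col = "subject_id",
                        stratum_col = "stratum", weight_col = "weight") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(id_col, stratum_col, weight_col)) {
    if (!col %in% names(df)) stop("missing column '", col, "' in ", path)
  }
  cn <- setdiff(names(df), c(id_col, stratum_col, weight_col))
  if (length(cn) == 0) stop("no indicator columns found in ", path)

  dup <- duplicated(df[[id_col]])
  if (any(dup)) {
    stop("duplicate subject ids: ", sum(dup), " duplicate row(s), ",
         "first at row ", which(dup)[1])
  }
  w <- suppressWarnings(as.numeric(df[[weight_col]]))
  badw <- which(!is.finite(w) | w <= 0)
  if (length(badw) > 0) {
    stop("non-positive or unparseable weights on ", length(badw),
         " row(s): rows ", paste(utils::head(badw, 5), collapse = ", "))
  }
  ind <- matrix(NA_integer_, nrow(df), length(cn),
                dimnames = list(NULL, cn))
  for (j in seq_along(cn)) {
    ind[, j] <- parse_indicator(df[[cn[j]]], cn[j])
  }
  miss <- which(rowSums(is.na(ind)) > 0)
  if (length(miss) > 0) {
    stop("missing indicator values on ", length(miss), " row(s): rows ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  validate_cohort_table(cohort_table(
    subject_id = df[[id_col]], stratum = df[[stratum_col]],
    weight = w, indicators = ind
  ))
}

parse_indicator <- function(x, name) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (any(!is.na(x) & x != 0 & x != 1)) {
      stop("indicator column '", name, "' has values other than 0/1")
    }
    return(as.integer(x))
  }
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(v))
  out[v %in% c("1", "true")] <- 1L
  out[v %in% c("0", "false")] <- 0L
  unknown <- !is.na(x) & v != "" & is.na(out)
  if (any(unknown)) {
    stop("indicator column '", name, "' has ", sum(unknown),
         " unrecognised value(s), e.g. '", v[which(unknown)[1]],
         "' (accepted: 0/1, true/false)")
  }
  out
}
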