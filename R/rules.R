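#' Mining configuration for association-rule scoring
#'
#' Collects the thresholds and conventions used when scoring disease
#' association rules.
#'
#' The standardised lift rescales the lift (observed/expected ratio) onto
#' [0, 1] by its attainable bounds given the margins, the sample size and
#' any support/confidence floors. `upper_bound_variant` selects the upper
#' bound of the lift used in that rescaling:
#' \describe{
#'   \item{`"corrected"`}{1 / max(P(A), P(B)) — the lift's true attainable
#'     maximum, reached when the rarer condition is a subset of the other.
#'     This is the default and the variant consistent with the published
#'     worked value for the hypertension/high-cholesterol pair.}
#'   \item{`"as_printed"`}{1 / (P(A) P(B)) — the looser bound that appears
#'     in the printed form of the standardisation formula; retained for
#'     auditability only.}
#' }
#'
#' @param std_lift_threshold rules must exceed this standardised lift to be
#'   retained (default 0.2).
#' @param support_floor,confidence_floor minimum support `s` and confidence
#'   `c` imposed during mining. Both default to 0 — no lower limit, so that
#'   associations among rare conditions are not discarded — but they enter
#'   the lower bound of the lift, max(P(A)+P(B)-1, 1/n, s, c P(A)) / (P(A)
#'   P(B)), so nonzero floors are fully supported.
#' @param upper_bound_variant `"corrected"` (default) or `"as_printed"`.
#' @param weighting `"weighted"` (default; supports, confidences and
#'   margins from survey-weighted proportions) or `"unweighted"`. The
#'   sample size `n` in the 1/n term is always the unweighted respondent
#'   count.
#' @param triad_min_prevalence prevalence floor used when reporting the
#'   high-prevalence subset of triads (default 0.05).
#' @return a `mining_config` list.
#' @export
mining_config <- function(std_lift_threshold = 0.2,
                          support_floor = 0,
                          confidence_floor = 0,
                          upper_bound_variant = c("corrected", "as_printed"),
                          weighting = c("weighted", "unweighted"),
                          triad_min_prevalence = 0.05) {
  upper_bound_variant <- match.arg(upper_bound_variant)
  weighting <- match.arg(weighting)
  stopifnot(std_lift_threshold >= 0, std_lift_threshold <= 1,
            support_floor >= 0, support_floor <= 1,
            confidence_floor >= 0, confidence_floor <= 1,
            triad_min_prevalence >= 0, triad_min_prevalence <= 1)
  structure(list(std_lift_threshold = std_lift_threshold,
                 support_floor = support_floor,
                 confidence_floor = confidence_floor,
                 upper_bound_variant = upper_bound_variant,
                 weighting = weighting,
                 triad_min_prevalence = triad_min_prevalence),
            class = "mining_config")
}

#' Score an association rule A => B from its probabilities
#'
#' Given marginal probabilities P(A), P(B), the joint P(A, B) and the
#' stratum sample size n, computes the full set of rule metrics:
#' \itemize{
#'   \item support = P(A, B); confidence = P(B | A) = P(A, B) / P(A);
#'   \item lift = P(A, B) / (P(A) P(B)), the observed/expected ratio,
#'     equal to 1 under independence;
#'   \item lift_lower = max(P(A)+P(B)-1, 1/n, s, c P(A)) / (P(A) P(B)),
#'     the smallest lift an observed rule can attain given the margins,
#'     the sample size and the mining floors s, c;
#'   \item lift_upper = 1 / max(P(A), P(B)) under the corrected variant,
#'     or 1 / (P(A) P(B)) under the as-printed variant;
#'   \item std_lift = (lift - lift_lower) / (lift_upper - lift_lower),
#'     the lift standardised onto [0, 1] so rules with different margins
#'     can be ranked fairly.
#' }
#'
#' A rule is `defined` only when both margins are strictly inside (0, 1),
#' the joint probability is positive (an association rule must be observed
#' at least once — this is what the 1/n term in the lower bound encodes),
#' and the bound interval is wider than 1e-12. Undefined rules carry `NA`
#' metrics rather than raising errors, so full-matrix outputs keep their
#' shape.
#'
#' All arguments are vectorised over rules.
#'
#' @param p_a,p_b marginal probabilities of antecedent and consequent.
#' @param joint joint probability P(A, B); must lie within the Frechet
#'   bounds of the margins (tolerance 1e-9).
#' @param n unweighted subject count of the stratum.
#' @param config a [mining_config()].
#' @return data frame with columns `p_a`, `p_b`, `support`, `confidence`,
#'   `lift`, `lift_lower`, `lift_upper`, `std_lift`, `n`, `defined`.
#' @export
rule_metrics <- function(p_a, p_b, joint, n, config = mining_config()) {
  m <- max(length(p_a), length(p_b), length(joint), length(n))
  p_a <- rep_len(as.numeric(p_a), m)
  p_b <- rep_len(as.numeric(p_b), m)
  joint <- rep_len(as.numeric(joint), m)
  n <- rep_len(as.numeric(n), m)
  nondeg <- p_a > 0 & p_a < 1 & p_b > 0 & p_b < 1
  frechet_lo <- pmax(p_a + p_b - 1, 0)
  frechet_hi <- pmin(p_a, p_b)
  bad <- nondeg & (joint < frechet_lo - 1e-9 | joint > frechet_hi + 1e-9)
  if (any(bad)) {
    stop("joint probability outside the Frechet bounds for ", sum(bad),
         " rule(s), first at index ", which(bad)[1])
  }
  lift <- ifelse(nondeg, joint / (p_a * p_b), NA_real_)
  lower <- pmax(p_a + p_b - 1, 1 / n, config$support_floor,
                config$confidence_floor * p_a) / (p_a * p_b)
  upper <- switch(config$upper_bound_variant,
    corrected = 1 / pmax(p_a, p_b),
    as_printed = 1 / (p_a * p_b)
  )
  defined <- nondeg & joint > 0 & (upper - lower) >= 1e-12
  std <- ifelse(defined, (lift - lower) / (upper - lower), NA_real_)
  data.frame(
    p_a = p_a, p_b = p_b,
    support = ifelse(nondeg, joint, NA_real_),
    confidence = ifelse(nondeg, joint / p_a, NA_real_),
    lift = lift,
    lift_lower = ifelse(defined, lower, NA_real_),
    lift_upper = ifelse(defined, upper, NA_real_),
    std_lift = std,
    n = n,
    defined = defined
  )
}

# weighted (or unweighted) margins and pairwise joint proportions of the
# indicator matrix; returns list(p = K vector, joint = K x K matrix)
stratum_proportions <- function(cohort, stratum, config) {
  rows <- stratum_rows(cohort, stratum)
  x <- indicator_matrix(cohort)[rows, , drop = FALSE]
  w <- if (config$weighting == "weighted") cohort$weight[rows]
       else rep(1, length(rows))
  storage.mode(x) <- "double"
  p <- as.numeric(crossprod(x, w)) / sum(w)
  joint <- crossprod(x * w, x) / sum(w)
  names(p) <- colnames(x)
  list(p = p, joint = joint, n = length(rows), x = x, w = w)
}

#' Mine all pairwise association rules in a stratum
#'
#' Scores every ordered condition pair (A, B), A != B, with
#' [rule_metrics()] using weighted proportions (unless
#' `config$weighting = "unweighted"`), and retains the rules that are
#' defined and exceed the standardised-lift threshold. With threshold 0
#' and no degenerate or never-co-occurring conditions, all K(K-1) ordered
#' rules are returned.
#'
#' @param cohort a [cohort_table()].
#' @param stratum stratum label.
#' @param config a [mining_config()].
#' @return a `rule_set`: data frame of retained rules (`antecedent`,
#'   `consequent` plus the [rule_metrics()] columns), with attributes
#'   `config`, `stratum` and `n`.
#' @export
mine_pairwise <- function(cohort, stratum, config = mining_config()) {
  cn <- condition_names(cohort)
  K <- length(cn)
  if (K < 2) stop("pairwise mining needs at least two conditions")
  sp <- stratum_proportions(cohort, stratum, config)
  idx <- expand.grid(a = seq_len(K), b = seq_len(K))
  idx <- idx[idx$a != idx$b, ]
  metrics <- rule_metrics(sp$p[idx$a], sp$p[idx$b],
                          sp$joint[cbind(idx$a, idx$b)], sp$n, config)
  rules <- cbind(
    data.frame(antecedent = cn[idx$a], consequent = cn[idx$b],
               stringsAsFactors = FALSE),
    metrics
  )
  keep <- rules$defined & rules$std_lift > config$std_lift_threshold
  new_rule_set(rules[keep, , drop = FALSE], config, stratum, sp$n)
}

new_rule_set <- function(df, config, stratum, n) {
  rownames(df) <- NULL
  structure(df, config = config, stratum = stratum, n_stratum = n,
            class = c("rule_set", "data.frame"))
}

#' @export
print.rule_set <- function(x, ...) {
  cat("<rule_set> stratum ", attr(x, "stratum"), ": ", nrow(x),
      " retained rules (std lift > ",
      attr(x, "config")$std_lift_threshold, ")\n", sep = "")
  NextMethod()
  invisible(x)
}

#' Conditional-probability (confidence) matrix of all condition pairs
#'
#' Entry (row y, column x) is P(condition x | condition y): the probability
#' of having the column condition given the row condition is already
#' present. The diagonal is 1 for any condition with nonzero prevalence.
#' Rows for zero-prevalence conditions are undefined (`NA`). With K
#' conditions the matrix has K^2 entries (961 for the 31-condition study
#' layout).
#'
#' @param cohort a [cohort_table()].
#' @param stratum stratum label.
#' @param config a [mining_config()] (controls weighting).
#' @return K x K numeric matrix with condition labels as dimnames; rows are
#'   the conditioning disease.
#' @export
confidence_matrix <- function(cohort, stratum, config = mining_config()) {
  sp <- stratum_proportions(cohort, stratum, config)
  conf <- sp$joint / sp$p        # row y: P(x, y) / P(y)
  conf[sp$p == 0, ] <- NA_real_
  diag(conf)[sp$p > 0] <- 1
  dimnames(conf) <- list(names(sp$p), names(sp$p))
  conf
}

#' Mine condition triads and score them by standardised lift
#'
#' Enumerates every unordered set of three conditions observed together in
#' at least one subject. Each triad gets its weighted prevalence (the
#' proportion of subjects carrying all three) and `std_lift_max`, the
#' maximum standardised lift over the six bipartition rules of the triple
#' ({X} => {Y,Z} and {Y,Z} => {X} for each of the three choices of X),
#' where the margins are the probabilities of the corresponding set events.
#' A triad qualifies when `std_lift_max` exceeds the configured threshold;
#' `high_prevalence` additionally flags the reportable subset with
#' prevalence above `config$triad_min_prevalence`.
#'
#' @param cohort a [cohort_table()].
#' @param stratum stratum label.
#' @param config a [mining_config()].
#' @return data frame with one row per observed triad: `condition_1..3`
#'   (sorted), `prevalence`, `std_lift_max`, `qualifying`,
#'   `high_prevalence`, ordered by decreasing prevalence.
#' @export
mine_triads <- function(cohort, stratum, config = mining_config()) {
  cn <- condition_names(cohort)
  K <- length(cn)
  if (K < 3) stop("triad mining needs at least three conditions")
  sp <- stratum_proportions(cohort, stratum, config)
  x <- sp$x
  w <- sp$w
  sw <- sum(w)
  triples <- utils::combn(K, 3)
  rows <- vector("list", ncol(triples))
  for (t in seq_len(ncol(triples))) {
    i <- triples[1, t]; j <- triples[2, t]; k <- triples[3, t]
    all3 <- x[, i] * x[, j] * x[, k]
    if (!any(all3 > 0)) next
    prev <- sum(w * all3) / sw
    # set-event margins for the three single-vs-pair bipartitions
    p_single <- sp$p[c(i, j, k)]
    p_pair <- c(sp$joint[j, k], sp$joint[i, k], sp$joint[i, j])
    bip <- rule_metrics(
      p_a = c(p_single, p_pair), p_b = c(p_pair, p_single),
      joint = prev, n = sp$n, config = config
    )
    rows[[t]] <- data.frame(
      condition_1 = cn[i], condition_2 = cn[j], condition_3 = cn[k],
      prevalence = prev,
      std_lift_max = if (any(bip$defined)) {
        max(bip$std_lift[bip$defined])
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(condition_1 = character(), condition_2 = character(),
                      condition_3 = character(), prevalence = numeric(),
                      std_lift_max = numeric(), stringsAsFactors = FALSE)
  }
  out$qualifying <- !is.na(out$std_lift_max) &
    out$std_lift_max > config$std_lift_threshold
  out$high_prevalence <- out$qualifying &
    out$prevalence > config$triad_min_prevalence
  out <- out[order(-out$prevalence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stratum") <- stratum
  attr(out, "config") <- config
  out
}

#' Sensitivity of the retained-rule count to the standardised-lift cut
#'
#' Recounts the rules retained at each candidate threshold. The count is
#' non-increasing in the threshold, and at threshold 0 equals the number of
#' defined ordered rules with positive standardised lift.
#'
#' @param cohort a [cohort_table()].
#' @param stratum stratum label.
#' @param thresholds numeric vector of thresholds in [0, 1].
#' @param config a [mining_config()]; its own threshold is ignored here.
#' @return data frame with columns `threshold`, `n_rules`.
#' @export
threshold_sensitivity <- function(cohort, stratum, thresholds,
                                  config = mining_config()) {
  stopifnot(all(thresholds >= 0), all(thresholds <= 1))
  config$std_lift_threshold <- 0
  all_rules <- mine_pairwise(cohort, stratum, config)
  std <- all_rules$std_lift
  data.frame(
    threshold = thresholds,
    n_rules = vapply(thresholds, function(t) sum(std > t), integer(1))
  )
}

#' Enumerate rule metrics over all small 2x2 contingency tables
#'
#' Exhaustively enumerates every 2x2 table of non-negative integer counts
#' (a = both, b = A only, c = B only, d = neither) with total n from 2 to
#' `n_max` and non-degenerate margins, and scores each as an association
#' rule. Used to verify that the standardised lift stays within [0, 1] and
#' the lift within its bounds over the whole attainable space of tables.
#'
#' @param n_max largest table total to enumerate (40 gives ~135,000
#'   tables).
#' @param config a [mining_config()].
#' @return data frame with the table counts `n, a, b, c, d` and all
#'   [rule_metrics()] columns.
#' @export
enumerate_contingency_rules <- function(n_max, config = mining_config()) {
  stopifnot(n_max >= 2)
  tabs <- do.call(rbind, lapply(2:n_max, function(n) {
    g <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    g <- g[g$a + g$b + g$c <= n, ]
    g$d <- n - g$a - g$b - g$c
    g$n <- n
    g
  }))
  p_a <- (tabs$a + tabs$b) / tabs$n
  p_b <- (tabs$a + tabs$c) / tabs$n
  keep <- p_a > 0 & p_a < 1 & p_b > 0 & p_b < 1
  tabs <- tabs[keep, ]
  metrics <- rule_metrics((tabs$a + tabs$b) / tabs$n,
                          (tabs$a + tabs$c) / tabs$n,
                          tabs$a / tabs$n, tabs$n, config)
  out <- cbind(tabs[, c("n", "a", "b", "c", "d")], metrics)
  rownames(out) <- NULL
  out
}
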