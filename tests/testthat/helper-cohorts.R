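# Fixture cohorts built in code.

# 6 subjects x 3 conditions, unit weights, indicators chosen so that every
# pair co-occurs at least once and margins differ.
toy_cohort6 <- function() {
  ind <- rbind(
    c(1, 1, 0),
    c(1, 0, 1),
    c(1, 1, 1),
    c(0, 1, 0),
    c(1, 0, 0),
    c(0, 1, 1)
  )
  colnames(ind) <- c("a", "b", "c")
  cohort_table(subject_id = paste0("s", 1:6), stratum = "all6",
               weight = rep(1, 6), indicators = ind)
}

# 12 subjects x 4 conditions with non-trivial weights; all four triples
# observed.
toy_cohort12 <- function() {
  ind <- rbind(
    c(1, 1, 1, 0),
    c(1, 1, 0, 1),
    c(1, 0, 1, 1),
    c(0, 1, 1, 1),
    c(1, 1, 1, 1),
    c(1, 0, 0, 0),
    c(0, 1, 0, 0),
    c(0, 0, 1, 0),
    c(0, 0, 0, 1),
    c(1, 1, 0, 0),
    c(0, 0, 1, 1),
    c(1, 0, 1, 0)
  )
  colnames(ind) <- c("a", "b", "c", "d")
  cohort_table(subject_id = paste0("s", 1:12), stratum = "all12",
               weight = c(2, 1, 1, 0.5, 1, 3, 1, 1, 2, 1, 0.5, 1),
               indicators = ind)
}

# independent-conditions spec: identity latent correlation, same margins in
# each stratum
independent_spec <- function(margins, n1 = 500, n2 = 500, seed = 1,
                             labels = c("male", "female")) {
  K <- length(margins)
  cn <- sprintf("c%02d", seq_len(K))
  strata <- list(list(n = n1, margins = margins),
                 list(n = n2, margins = margins))
  names(strata) <- labels
  cohort_spec(cn, strata, seed = seed)
}

# two strata of n each; conditions 1-2 carry planted dependence calibrated
# to the given lift at margins (0.45, 0.48); the remaining conditions are
# mutually independent with low margins typical of rarer conditions
planted_pair_spec <- function(seed, n = 5000, lift = 1.5) {
  margins <- c(0.45, 0.48, 0.03, 0.05, 0.07, 0.09, 0.10, 0.12)
  K <- length(margins)
  cn <- c("planted_a", "planted_b", sprintf("indep_%d", 1:(K - 2)))
  rho <- calibrate_dependence(margins[1], margins[2],
                              lift * margins[1] * margins[2])
  R <- diag(K)
  R[1, 2] <- R[2, 1] <- rho
  strata <- list(
    male = list(n = n, margins = margins, latent_correlation = R),
    female = list(n = n, margins = margins, latent_correlation = R)
  )
  names(margins) <- cn
  cohort_spec(cn, strata, seed = seed)
}
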