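test_that("rule metrics match hand evaluation of the standardisation", {
  # pA=0.5, pB=0.4, joint=0.3, n=10: lambda = max(-0.1, 0.1)/0.2 = 0.5,
  # upsilon = 1/0.5 = 2, std = (1.5 - 0.5)/(2 - 0.5)
  m <- rule_metrics(0.5, 0.4, 0.3, 10)
  expect_equal(m$support, 0.3)
  expect_equal(m$confidence, 0.6)
  expect_equal(m$lift, 1.5)
  expect_equal(m$lift_lower, 0.5)
  expect_equal(m$lift_upper, 2)
  expect_equal(m$std_lift, 1 / 1.5)
})

test_that("the corrected variant reproduces the published worked value, as-printed does not", {
  corrected <- rule_metrics(0.4261, 0.5231, 0.262, 3347,
                            mining_config(upper_bound_variant = "corrected"))
  expect_lt(abs(corrected$std_lift - 0.61), 0.01)
  printed <- rule_metrics(0.4261, 0.5231, 0.262, 3347,
                          mining_config(upper_bound_variant = "as_printed"))
  expect_gt(abs(printed$std_lift - 0.61), 0.01)
})

test_that("lift equals one exactly at independence", {
  for (p in list(c(0.5, 0.4), c(0.9, 0.05), c(0.123, 0.987))) {
    m <- rule_metrics(p[1], p[2], p[1] * p[2], 1000)
    expect_identical(m$lift, 1)
  }
})

test_that("degenerate margins yield undefined rules, infeasible joints error", {
  m <- rule_metrics(c(0, 0.5, 1), c(0.4, 0.4, 0.4), c(0, 0.2, 0.4), 100)
  expect_equal(m$defined, c(FALSE, TRUE, FALSE))
  expect_true(all(is.na(m$std_lift[!m$defined])))
  expect_error(rule_metrics(0.5, 0.4, 0.45, 100), "Frechet")
})

test_that("standardised lift stays in [0,1] over exhaustive small tables", {
  tab <- enumerate_contingency_rules(15)
  d <- tab[tab$defined, ]
  expect_gt(nrow(d), 1000)
  expect_true(all(d$std_lift >= -1e-9 & d$std_lift <= 1 + 1e-9))
  expect_true(all(d$lift >= d$lift_lower - 1e-9))
  expect_true(all(d$lift <= d$lift_upper + 1e-9))
  # support within Frechet bounds, confidence * pA = support
  expect_true(all(d$support <= pmin(d$p_a, d$p_b) + 1e-12))
  expect_true(all(d$support >= pmax(d$p_a + d$p_b - 1, 0) - 1e-12))
  expect_true(all(abs(d$confidence * d$p_a - d$support) < 1e-12))
})

test_that("pairwise mining equals brute-force counting on the toy cohort", {
  co <- toy_cohort6()
  cfg <- mining_config(std_lift_threshold = 0)
  rules <- mine_pairwise(co, "all6", cfg)
  expect_equal(nrow(rules), 6)  # 3 conditions, all pairs co-occur
  for (i in seq_len(nrow(rules))) {
    o <- oracle_rule(co, "all6", rules$antecedent[i], rules$consequent[i])
    expect_equal(rules$support[i], o$joint)
    expect_equal(rules$confidence[i], o$confidence)
    expect_equal(rules$lift[i], o$lift)
    expect_equal(rules$p_a[i], o$p_a)
  }
})

test_that("all ordered pairs are returned at threshold zero with common conditions", {
  spec <- independent_spec(rep(0.5, 31), n1 = 1200, n2 = 1000, seed = 17)
  co <- generate_cohort(spec)
  rules <- mine_pairwise(co, "male", mining_config(std_lift_threshold = 0))
  expect_equal(nrow(rules), 31 * 30)
})

test_that("support and lift are symmetric, confidence is directional", {
  co <- toy_cohort12()
  rules <- mine_pairwise(co, "all12", mining_config(std_lift_threshold = 0))
  key <- paste(rules$antecedent, rules$consequent)
  rev_key <- paste(rules$consequent, rules$antecedent)
  rev_idx <- match(rev_key, key)
  expect_equal(rules$support, rules$support[rev_idx])
  expect_equal(rules$lift, rules$lift[rev_idx])
  expect_equal(rules$std_lift, rules$std_lift[rev_idx])  # s = c = 0, corrected
  expect_false(isTRUE(all.equal(rules$confidence,
                                rules$confidence[rev_idx])))
})

test_that("standardised lift increases strictly with the joint probability", {
  joints <- seq(0.05, 0.29, by = 0.03)
  m <- rule_metrics(rep(0.5, length(joints)), rep(0.3, length(joints)),
                    joints, 200)
  expect_true(all(diff(m$std_lift) > 0))
})

test_that("weighted mining with unit weights equals unweighted mining", {
  co <- generate_cohort(independent_spec(c(0.2, 0.4, 0.6), n1 = 300,
                                         n2 = 250, seed = 8))
  co$weight <- rep(1, nrow(co))
  w <- mine_pairwise(co, "male", mining_config(0, weighting = "weighted"))
  u <- mine_pairwise(co, "male", mining_config(0, weighting = "unweighted"))
  for (col in c("antecedent", "consequent", "support", "confidence",
                "lift", "std_lift")) {
    expect_identical(w[[col]], u[[col]])
  }
})

test_that("confidence matrix matches conditional counting and keeps its shape", {
  co <- toy_cohort6()
  cm <- confidence_matrix(co, "all6")
  expect_equal(dim(cm), c(3, 3))
  for (y in rownames(cm)) {
    for (x in colnames(cm)) {
      if (x == y) {
        expect_equal(cm[y, x], 1)
      } else {
        expect_equal(cm[y, x], oracle_rule(co, "all6", y, x)$confidence)
      }
    }
  }
  # 31 conditions give a 961-entry matrix
  spec <- independent_spec(rep(0.3, 31), n1 = 60, n2 = 50, seed = 4)
  cm31 <- confidence_matrix(generate_cohort(spec), "male")
  expect_equal(length(cm31), 961)
})

test_that("comonotone pairs have confidence one in both directions", {
  R <- matrix(1, 2, 2)
  spec <- cohort_spec(c("a", "b"),
                      list(s = list(n = 500, margins = c(0.3, 0.3),
                                    latent_correlation = R)), seed = 2)
  cm <- confidence_matrix(generate_cohort(spec), "s")
  expect_equal(unname(cm["a", "b"]), 1)
  expect_equal(unname(cm["b", "a"]), 1)
})

test_that("triad mining equals exhaustive enumeration on the toy cohort", {
  co <- toy_cohort12()
  cfg <- mining_config(std_lift_threshold = 0)
  triads <- mine_triads(co, "all12", cfg)
  expect_equal(nrow(triads), 4)  # all four triples observed
  for (i in seq_len(nrow(triads))) {
    trio <- unlist(triads[i, c("condition_1", "condition_2", "condition_3")])
    o_all <- oracle_rule(co, "all12", trio, trio)
    expect_equal(triads$prevalence[i], o_all$joint)
    # brute-force the six bipartition standardised lifts
    stds <- c()
    for (x in trio) {
      pair <- setdiff(trio, x)
      for (dir in 1:2) {
        a_set <- if (dir == 1) x else pair
        b_set <- if (dir == 1) pair else x
        o <- oracle_rule(co, "all12", a_set, b_set)
        m <- rule_metrics(o$p_a, o$p_b, o$joint, 12, cfg)
        if (m$defined) stds <- c(stds, m$std_lift)
      }
    }
    expect_equal(triads$std_lift_max[i], max(stds))
  }
})

test_that("triad limits: single carrier and perfect dependence", {
  ind <- cbind(a = c(1, rep(0, 9)), b = c(1, rep(0, 9)),
               c = c(1, 1, rep(0, 8)), d = rep(c(1, 0), 5))
  co <- cohort_table(1:10, "s", rep(1, 10), ind)
  triads <- mine_triads(co, "s", mining_config(std_lift_threshold = 0))
  abc <- triads[triads$condition_1 == "a" & triads$condition_2 == "b" &
                  triads$condition_3 == "c", ]
  expect_equal(abc$prevalence, 1 / 10)

  R <- matrix(1, 3, 3)
  spec <- cohort_spec(c("x", "y", "z"),
                      list(s = list(n = 4000, margins = rep(0.2, 3),
                                    latent_correlation = R)),
                      weight_model = list(family = "constant"), seed = 5)
  co2 <- generate_cohort(spec)
  tr2 <- mine_triads(co2, "s")
  expect_equal(nrow(tr2), 1)
  expect_lt(abs(tr2$prevalence - 0.2), 0.02)
  expect_equal(tr2$std_lift_max, 1)  # lift attains its upper bound
})

test_that("threshold sensitivity is a nested, non-increasing count", {
  co <- toy_cohort12()
  ts <- threshold_sensitivity(co, "all12", c(0, 1))
  all_defined <- mine_pairwise(co, "all12", mining_config(0))
  expect_equal(ts$n_rules, c(nrow(all_defined), 0L))

  set.seed(31)
  for (i in 1:20) {
    spec <- independent_spec(runif(5, 0.1, 0.6), n1 = 150, n2 = 120,
                             seed = i)
    co_i <- generate_cohort(spec)
    ts_i <- threshold_sensitivity(co_i, "male", seq(0, 1, by = 0.1))
    expect_true(all(diff(ts_i$n_rules) <= 0))
  }
})

test_that("the planted pair outlives independent pairs as the cut grows", {
  spec <- planted_pair_spec(seed = 123, n = 4000, lift = 1.5)
  co <- generate_cohort(spec)
  rules <- mine_pairwise(co, "male", mining_config(std_lift_threshold = 0))
  top <- rules[which.max(rules$std_lift), ]
  expect_setequal(c(top$antecedent, top$consequent),
                  c("planted_a", "planted_b"))
})
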