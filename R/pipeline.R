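#' Configuration for the end-to-end analysis pipeline
#'
#' Exactly one of `input` (path to a cohort CSV) or `spec` (a
#' [cohort_spec()] to simulate from) must be given.
#'
#' @param input path to a cohort CSV readable by [read_cohort()], or
#'   `NULL`.
#' @param spec a [cohort_spec()], or `NULL`.
#' @param config a [mining_config()].
#' @param thresholds standardised-lift cuts for the sensitivity analysis.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed applied before any random stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, spec = NULL,
                            config = mining_config(),
                            thresholds = c(0, 0.1, 0.2, 0.3, 0.5),
                            out_dir = "results", seed = 1L) {
  if (is.null(input) == is.null(spec)) {
    stop("exactly one of 'input' and 'spec' must be set")
  }
  structure(list(input = input, spec = spec, config = config,
                 thresholds = thresholds, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)),
      class = c("comorbnet_stage_error", "comorbnet_error"),
      stage = stage, code = paste0("E_", toupper(stage))
    ))
  })
}

#' Run the full multimorbidity analysis pipeline
#'
#' Executes, in order: cohort load/simulation, weighted prevalence and
#' sex-association testing, morbidity-count distribution, and per stratum:
#' pairwise rule mining at the configured standardised-lift threshold,
#' the confidence matrix, triad mining, network construction with
#' fast-greedy community detection, and the threshold sensitivity table.
#' Every table is written under `out_dir` as CSV (networks additionally as
#' GraphML) together with `manifest.json` recording the seed,
#' configuration, package version and retained-rule counts per stratum.
#' A failing stage aborts with a `comorbnet_stage_error` carrying the
#' stage name and a machine-readable code.
#'
#' Outputs are deterministic: the same configuration and seed reproduce
#' identical files.
#'
#' @param pc a [pipeline_config()].
#' @return (invisibly) a list with the in-memory results: `cohort`,
#'   `prevalence`, `morbidity`, and per stratum `rules`, `confidence`,
#'   `triads`, `network`, `communities`, `sensitivity`, plus `manifest`.
#' @export
run_pipeline <- function(pc) {
  stopifnot(inherits(pc, "pipeline_config"))
  dir.create(pc$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(pc$seed)
  cohort <- with_stage("load", {
    if (!is.null(pc$input)) read_cohort(pc$input)
    else generate_cohort(pc$spec)
  })
  out <- list(cohort = cohort)

  out$prevalence <- with_stage("prevalence", {
    tab <- sex_association_tests(cohort)
    utils::write.csv(as.data.frame(tab),
                     file.path(pc$out_dir, "prevalence.csv"),
                     row.names = FALSE)
    tab
  })
  out$morbidity <- with_stage("morbidity_distribution", {
    md <- morbidity_distribution(cohort)
    utils::write.csv(md$distribution,
                     file.path(pc$out_dir, "morbidity_counts.csv"),
                     row.names = FALSE)
    md
  })

  retained <- list()
  for (s in cohort_strata(cohort)) {
    res <- list()
    res$rules <- with_stage("mine_pairwise", {
      r <- mine_pairwise(cohort, s, pc$config)
      write_rules(r, file.path(pc$out_dir, paste0("rules_", s, ".csv")))
      r
    })
    retained[[s]] <- nrow(res$rules)
    res$confidence <- with_stage("confidence_matrix", {
      cm <- confidence_matrix(cohort, s, pc$config)
      utils::write.csv(cm,
                       file.path(pc$out_dir, paste0("confidence_", s, ".csv")))
      cm
    })
    res$triads <- with_stage("mine_triads", {
      tr <- if (length(condition_names(cohort)) < 3) {
        data.frame(condition_1 = character(), condition_2 = character(),
                   condition_3 = character(), prevalence = numeric(),
                   std_lift_max = numeric(), qualifying = logical(),
                   high_prevalence = logical())
      } else mine_triads(cohort, s, pc$config)
      utils::write.csv(tr, file.path(pc$out_dir, paste0("triads_", s, ".csv")),
                       row.names = FALSE)
      tr
    })
    res$network <- with_stage("build_network", {
      g <- build_network(res$rules, cohort)
      write_network(g, res$rules,
                    file.path(pc$out_dir, paste0("network_", s)))
      g
    })
    res$communities <- with_stage("detect_communities", {
      if (igraph::vcount(res$network) == 0) NULL else {
        cp <- detect_communities(res$network)
        utils::write.csv(
          data.frame(condition = names(cp$membership),
                     community = as.integer(cp$membership)),
          file.path(pc$out_dir, paste0("communities_", s, ".csv")),
          row.names = FALSE)
        cp
      }
    })
    res$sensitivity <- with_stage("threshold_sensitivity", {
      ts <- threshold_sensitivity(cohort, s, pc$thresholds, pc$config)
      utils::write.csv(ts,
                       file.path(pc$out_dir, paste0("sensitivity_", s, ".csv")),
                       row.names = FALSE)
      ts
    })
    out[[s]] <- res
  }

  out$manifest <- with_stage("manifest", {
    manifest <- list(
      seed = pc$seed,
      input = if (is.null(pc$input)) "simulated" else pc$input,
      mining_config = unclass(pc$config),
      thresholds = pc$thresholds,
      n_subjects = nrow(cohort),
      strata = as.list(table(cohort$stratum)),
      retained_rules = retained,
      package_version = as.character(utils::packageVersion("comorbnet")),
      r_version = R.version.string
    )
    jsonlite::write_json(manifest,
                         file.path(pc$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest
  })
  invisible(out)
}

write_rules <- function(ruleset, path) {
  df <- as.data.frame(ruleset)
  df$stratum <- rep(attr(ruleset, "stratum"), nrow(df))
  df$variant <- rep(attr(ruleset, "config")$upper_bound_variant, nrow(df))
  cols <- c("stratum", "antecedent", "consequent", "n", "p_a", "p_b",
            "support", "confidence", "lift", "lift_lower", "lift_upper",
            "std_lift", "variant")
  utils::write.csv(df[, cols], path, row.names = FALSE)
  invisible(path)
}

write_network <- function(g, ruleset, stem) {
  edges <- igraph::as_data_frame(g, what = "edges")
  if (nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        weight = integer())
  }
  names(edges) <- c("condition_a", "condition_b", "cooccurrence_count")
  utils::write.csv(edges, paste0(stem, "_edges.csv"), row.names = FALSE)
  if (igraph::vcount(g) > 0) {
    igraph::write_graph(g, paste0(stem, ".graphml"), format = "graphml")
  }
  invisible(stem)
}
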