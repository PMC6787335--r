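#!/usr/bin/env Rscript
# Comorbidity networks from the retained rules (nodes sized by weighted
# prevalence, edges weighted by co-occurrence counts) and fast-greedy
# community detection per sex stratum.

library(comorbnet)

out_dir <- "results/analysis"
cohort <- read_cohort(file.path(out_dir, "cohort.csv"))
cfg <- mining_config(std_lift_threshold = 0.2)

for (s in cohort_strata(cohort)) {
  g <- build_network(mine_pairwise(cohort, s, cfg), cohort)
  edges <- igraph::as_data_frame(g, what = "edges")
  names(edges) <- c("condition_a", "condition_b", "cooccurrence_count")
  write.csv(edges, file.path(out_dir, paste0("network_", s, "_edges.csv")),
            row.names = FALSE)
  igraph::write_graph(g, file.path(out_dir, paste0("network_", s, ".graphml")),
                      format = "graphml")
  cp <- detect_communities(g)
  write.csv(data.frame(condition = names(cp$membership),
                       community = as.integer(cp$membership)),
            file.path(out_dir, paste0("communities_", s, ".csv")),
            row.names = FALSE)
  cat(s, ": network of ", igraph::vcount(g), " conditions / ",
      igraph::ecount(g), " edges; ", length(unique(cp$membership)),
      " communities, modularity Q = ", round(cp$modularity, 3), "\n",
      sep = "")
  for (k in sort(unique(cp$membership))) {
    cat("   community ", k, ": ",
        paste(names(cp$membership)[cp$membership == k], collapse = ", "),
        "\n", sep = "")
  }
}
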