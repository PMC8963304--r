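# Independent brute-force oracles and fixture builders shared across tests.
# The oracles never call the code paths they check.

# Exhaustive upper-tail hypergeometric probability by enumerating all C(N, n)
# draws from a universe whose first K elements are the category.
hyper_enum <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Exhaustive enumeration of simple directed paths from any node of `a` to any
# node of `b` with at most `max_len` edges.
dfs_paths <- function(edges, a, b, max_len) {
  adj <- split(edges$target, edges$source)
  out <- list()
  walk <- function(path) {
    node <- path[length(path)]
    if (length(path) >= 2 && node %in% b) {
      out[[length(out) + 1L]] <<- path
    }
    if (length(path) - 1L >= max_len) return(invisible())
    for (nxt in adj[[node]]) {
      if (!nxt %in% path) walk(c(path, nxt))
    }
  }
  for (s in unique(a)) walk(s)
  out[order(vapply(out, paste, character(1), collapse = " "))]
}

# Direct re-application of the neurological target filter rules.
neuro_filter_oracle <- function(target_genes, catalog, min_terms = 2) {
  keep <- character()
  for (g in target_genes) {
    sub <- catalog[catalog$gene == g, ]
    if (!nrow(sub)) next
    n_bm <- length(unique(sub$term[sub$category == "disease_biomarker"]))
    n_pw <- length(unique(sub$term[sub$category == "canonical_pathway"]))
    if (n_bm + n_pw < 1) next
    if (n_bm + n_pw < min_terms) next
    keep <- c(keep, g)
  }
  sort(keep)
}

# Minimal ct_matrix from explicit values (one plate unless stated).
make_ct <- function(values, plate = 1L, treatment = "t1",
                    detection_limit = 35) {
  values <- as.matrix(values)
  n_rep <- ncol(values) / 2
  samples <- data.frame(
    sample = paste0("s", seq_len(ncol(values))),
    plate = plate,
    treatment = treatment,
    replicate = rep(seq_len(n_rep), 2),
    role = rep(c("treated", "control"), each = n_rep),
    stringsAsFactors = FALSE)
  colnames(values) <- samples$sample
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("miR-%04d", seq_len(nrow(values)))
  }
  secretomir:::new_ct_matrix(values, samples, detection_limit)
}

# Planted-pathway enrichment scenario: network, 12 spiked miRNAs, ontology
# with the configured overlap.
make_planted_scenario <- function(seed, overlap, n_spiked = 12L) {
  cfg <- ontology_sim_config(planted_pathway_overlap = overlap, seed = seed)
  net <- gen_target_network(cfg)
  spiked <- sort(sample(net$mirnas, n_spiked))
  ont <- gen_pathway_ontology(cfg, spiked, net)
  list(network = net, spiked = spiked, ontology = ont)
}

# 39-row fold-change profile with four planted centroids
# (strong down / mild down / mild up / strong up).
make_4centroid_profile <- function(seed, sd = 0.3) {
  set.seed(seed)
  centroids <- c(-2.5, -1, 1, 2.5)
  truth <- rep(1:4, c(10, 10, 10, 9))
  prof <- t(vapply(truth, function(g) rnorm(4, centroids[g], sd),
                   numeric(4)))
  rownames(prof) <- sprintf("miR-%04d", seq_along(truth))
  colnames(prof) <- paste0("exp", 1:4)
  list(profile = prof, truth = setNames(truth, rownames(prof)))
}
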