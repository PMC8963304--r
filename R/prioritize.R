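# Target prioritization: from significant miRNAs through validated targets
# and neurological annotation filters to direction prediction and signed
# signaling-cascade reconstruction.

#' Experimentally validated targets of a miRNA set
#'
#' Union of the targets of the given miRNAs restricted to edges with
#' `validated` evidence; each gene is annotated with its supporting miRNAs.
#'
#' @param sig_mirnas significant miRNA ids.
#' @param network a `target_network` with evidence grades.
#' @return data frame `gene, n_mirnas, mirnas` (comma-joined supporting
#'   miRNA ids).
#' @export
select_validated_targets <- function(sig_mirnas, network) {
  stopifnot(inherits(network, "target_network"))
  e <- network$edges
  keep <- e$mirna %in% sig_mirnas & e$evidence == "validated"
  if (!any(keep)) {
    return(data.frame(gene = character(), n_mirnas = integer(),
                      mirnas = character(), stringsAsFactors = FALSE))
  }
  by_gene <- split(e$mirna[keep], e$gene[keep])
  genes <- sort(names(by_gene))
  data.frame(gene = genes,
             n_mirnas = vapply(by_gene[genes], length, integer(1)),
             mirnas = vapply(by_gene[genes], function(m) {
               paste(sort(unique(m)), collapse = ",")
             }, character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter targets to neurologically annotated, multi-association genes
#'
#' Three-step funnel mirroring a pathway-analysis curation: (1) keep genes
#' with at least one term in the neurological annotation catalog; (2) drop
#' genes with no disease-biomarker and no canonical-pathway association;
#' (3) drop genes associated with exactly one specific condition (fewer than
#' `min_terms` distinct terms across the biomarker and pathway categories).
#' Filters only remove genes, never add.
#'
#' @param targets data frame from [select_validated_targets()].
#' @param catalog data frame `gene, term, category` with categories among
#'   disease_biomarker, canonical_pathway, go_process, toxic_pathology.
#' @param min_terms multiple-association threshold (default 2).
#' @return data frame `gene, n_mirnas, mirnas, n_biomarker_terms,
#'   n_pathway_terms` with attribute `funnel` (counts surviving each step).
#' @export
filter_neuro_targets <- function(targets, catalog, min_terms = 2L) {
  stopifnot(is.data.frame(catalog),
            all(c("gene", "term", "category") %in% names(catalog)))
  bad <- setdiff(unique(catalog$category),
                 c("disease_biomarker", "canonical_pathway", "go_process",
                   "toxic_pathology"))
  if (length(bad)) {
    stop(sprintf("unknown catalog category: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  count_terms <- function(g, cat) {
    length(unique(catalog$term[catalog$gene == g & catalog$category == cat]))
  }
  step1 <- targets[targets$gene %in% catalog$gene, , drop = FALSE]
  if (nrow(step1)) {
    step1$n_biomarker_terms <- vapply(step1$gene, count_terms, integer(1),
                                      cat = "disease_biomarker")
    step1$n_pathway_terms <- vapply(step1$gene, count_terms, integer(1),
                                    cat = "canonical_pathway")
  } else {
    step1$n_biomarker_terms <- integer()
    step1$n_pathway_terms <- integer()
  }
  assoc <- step1$n_biomarker_terms + step1$n_pathway_terms
  step2 <- step1[assoc >= 1, , drop = FALSE]
  step3 <- step2[step2$n_biomarker_terms + step2$n_pathway_terms >=
                   min_terms, , drop = FALSE]
  rownames(step3) <- NULL
  attr(step3, "funnel") <- c(input = nrow(targets),
                             in_catalog = nrow(step1),
                             with_association = nrow(step2),
                             multi_association = nrow(step3))
  step3
}

#' Predict a target's expression direction from its miRNAs' fold changes
#'
#' miRNAs repress their targets, so each supporting miRNA votes opposite to
#' its own direction, weighted by |log2 FC|; the sign of the weighted sum
#' (which reduces to `-sum(log2_fc)`) decides. A zero sum is ambiguous.
#'
#' @param log2_fcs numeric log2 fold changes of the supporting miRNAs.
#' @return `"up"`, `"down"`, or `"ambiguous"`.
#' @export
predict_direction <- function(log2_fcs) {
  stopifnot(length(log2_fcs) >= 1, all(is.finite(log2_fcs)))
  s <- -sum(log2_fcs)
  if (s > 0) "up" else if (s < 0) "down" else "ambiguous"
}

#' Prioritize neurological mRNA targets of significant miRNAs
#'
#' Runs the full funnel: validated targets, the neurological annotation
#' filters, and direction prediction from the supporting miRNAs' log2 fold
#' changes (a miRNA significant in several exposures contributes its mean
#' log2 fold change across its significant exposures).
#'
#' @param sig_records differential table rows for significant miRNAs
#'   (columns `mirna`, `log2_fc`).
#' @param network a `target_network`.
#' @param catalog annotation catalog as in [filter_neuro_targets()].
#' @param min_terms multiple-association threshold (default 2).
#' @return data frame `gene, supporting_mirnas, n_biomarker_terms,
#'   n_pathway_terms, predicted_direction, rationale` with the `funnel`
#'   attribute of [filter_neuro_targets()].
#' @export
prioritize_targets <- function(sig_records, network, catalog,
                               min_terms = 2L) {
  stopifnot(all(c("mirna", "log2_fc") %in% names(sig_records)))
  mir_lfc <- tapply(sig_records$log2_fc, sig_records$mirna, mean)
  targets <- select_validated_targets(names(mir_lfc), network)
  kept <- filter_neuro_targets(targets, catalog, min_terms = min_terms)
  if (nrow(kept)) {
    dir <- character(nrow(kept)); rat <- character(nrow(kept))
    for (i in seq_len(nrow(kept))) {
      mirs <- strsplit(kept$mirnas[i], ",")[[1]]
      lfc <- as.numeric(mir_lfc[mirs])
      dir[i] <- predict_direction(lfc)
      rat[i] <- sprintf("%d repressing miRNA(s), weighted vote %.3f",
                        length(mirs), -sum(lfc))
    }
  } else {
    dir <- character(); rat <- character()
  }
  out <- data.frame(gene = kept$gene, supporting_mirnas = kept$mirnas,
                    n_biomarker_terms = kept$n_biomarker_terms,
                    n_pathway_terms = kept$n_pathway_terms,
                    predicted_direction = dir, rationale = rat,
                    stringsAsFactors = FALSE)
  attr(out, "funnel") <- attr(kept, "funnel")
  out
}

#' Trace simple directed signaling cascades between two seed sets
#'
#' Enumerates every simple directed path (no repeated node) from any node of
#' `seeds_a` to any node of `seeds_b` with at most `max_len` edges, in
#' deterministic lexicographic order of the node sequences.
#'
#' @param graph an `interaction_graph` data frame (`source, sign, target`).
#' @param seeds_a,seeds_b node id vectors; all must be present in the graph.
#' @param max_len maximum path length in edges (default 4).
#' @return list of character vectors (node sequences).
#' @export
trace_cascades <- function(graph, seeds_a, seeds_b, max_len = 4L) {
  stopifnot(is.data.frame(graph),
            all(c("source", "sign", "target") %in% names(graph)))
  max_len <- check_count(max_len, "max_len")
  nodes <- unique(c(graph$source, graph$target))
  missing <- setdiff(c(seeds_a, seeds_b), nodes)
  if (length(missing)) {
    stop(sprintf("seed node(s) absent from graph: %s",
                 paste(sort(missing), collapse = ", ")), call. = FALSE)
  }
  if (!nrow(graph)) return(list())
  g <- igraph::graph_from_data_frame(graph[c("source", "target")],
                                     directed = TRUE)
  paths <- list()
  for (a in sort(unique(seeds_a))) {
    sp <- igraph::all_simple_paths(g, from = a,
                                   to = unique(seeds_b),
                                   mode = "out", cutoff = max_len)
    paths <- c(paths, lapply(sp, function(v) igraph::as_ids(v)))
  }
  paths <- paths[vapply(paths, length, integer(1)) >= 2]
  paths <- paths[vapply(paths, function(v) v[length(v)] %in% seeds_b,
                        logical(1))]
  paths[order(vapply(paths, paste, character(1), collapse = " "))]
}

#' Merge traced cascades into one signed network with node annotations
#'
#' Union of the edges of all paths (signs preserved from the interaction
#' graph, each edge once), with every node flagged by the ontology
#' categories annotating it and, optionally, the notable miRNAs targeting
#' it.
#'
#' @param paths list of node-sequence paths from [trace_cascades()].
#' @param graph the `interaction_graph` the paths were traced in.
#' @param catalog optional annotation catalog (`gene, term, category`).
#' @param network optional `target_network` for miRNA support flags.
#' @param sig_mirnas optional miRNA ids considered notable.
#' @return list with `nodes` (data frame `node, categories, mirnas`) and
#'   `edges` (data frame `source, sign, target`).
#' @export
merge_cascades <- function(paths, graph, catalog = NULL, network = NULL,
                           sig_mirnas = NULL) {
  if (!length(paths)) {
    return(list(nodes = data.frame(node = character(),
                                   categories = character(),
                                   mirnas = character(),
                                   stringsAsFactors = FALSE),
                edges = data.frame(source = character(), sign = character(),
                                   target = character(),
                                   stringsAsFactors = FALSE)))
  }
  edge_pairs <- unique(do.call(rbind, lapply(paths, function(v) {
    data.frame(source = v[-length(v)], target = v[-1],
               stringsAsFactors = FALSE)
  })))
  key <- paste(graph$source, graph$target, sep = "\r")
  edge_pairs$sign <- graph$sign[match(
    paste(edge_pairs$source, edge_pairs$target, sep = "\r"), key)]
  edge_pairs <- edge_pairs[order(edge_pairs$source, edge_pairs$target),
                           c("source", "sign", "target")]
  rownames(edge_pairs) <- NULL
  nodes <- sort(unique(unlist(paths)))
  cats <- vapply(nodes, function(nd) {
    if (is.null(catalog)) return("")
    paste(sort(unique(catalog$category[catalog$gene == nd])), collapse = ",")
  }, character(1))
  mirs <- vapply(nodes, function(nd) {
    if (is.null(network) || is.null(sig_mirnas)) return("")
    e <- network$edges
    paste(sort(unique(e$mirna[e$gene == nd & e$mirna %in% sig_mirnas])),
          collapse = ",")
  }, character(1))
  list(nodes = data.frame(node = nodes, categories = unname(cats),
                          mirnas = unname(mirs), stringsAsFactors = FALSE),
       edges = edge_pairs)
}
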