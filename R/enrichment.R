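# Dual bias-corrected pathway enrichment: gene-level over-representation on a
# miRNA-restricted universe (method 1), miRNA-set over-representation after
# transforming pathways to the miRNAs that target them (method 2), their
# intersection with Fisher ranking, and cluster-wise pathway-union enrichment.

#' Upper-tail hypergeometric probability P[X >= k]
#'
#' Probability of observing at least `k` category members in a draw of `n`
#' from a universe of `N` containing `K` members; exact and numerically
#' stable (log-space tail via [stats::phyper]).
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param K category size in the universe.
#' @param n draw (query) size.
#' @param N universe size.
#' @return probability in (0, 1].
#' @export
hypergeom_upper <- function(k, K, n, N) {
  for (v in list(k = k, K = K, n = n, N = N)) {
    if (length(v) != 1 || !is.finite(v) || v < 0 || v != round(v)) {
      stop("counts must be single non-negative integers", call. = FALSE)
    }
  }
  if (K > N || n > N || k > min(K, n)) {
    stop(sprintf("inconsistent counts: k=%d, K=%d, n=%d, N=%d", k, K, n, N),
         call. = FALSE)
  }
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fisher's method for combining p-values
#'
#' `X = -2 sum(log p)` referred to a chi-square with `2k` degrees of
#' freedom; a single p-value is returned unchanged (chi-square-2 identity).
#'
#' @param p vector of p-values in (0, 1].
#' @return combined probability in (0, 1].
#' @export
fisher_combine <- function(p) {
  stopifnot(length(p) >= 1, all(is.finite(p)), all(p > 0), all(p <= 1))
  pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

# Shared precondition: significant miRNAs must be network miRNAs.
check_sig_in_network <- function(sig_mirnas, network) {
  stopifnot(inherits(network, "target_network"))
  missing <- setdiff(sig_mirnas, network$mirnas)
  if (length(missing)) {
    stop(sprintf("significant miRNAs absent from network: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Method 1: enrichment of miRNA targets in pathways on a restricted universe
#'
#' Corrects for the sparse representation of miRNA signaling in pathway
#' ontologies by testing the miRNAs' \emph{gene targets} rather than the
#' miRNAs themselves, over a universe restricted to genes with at least one
#' miRNA association in the supplied network (genes unknown to any miRNA are
#' excluded from the ontology). For each pathway: `K` = pathway genes in the
#' universe, `n` = union of the significant miRNAs' targets, `k` = their
#' overlap, p = [hypergeom_upper()]. Pathways disjoint from the universe are
#' skipped with `K = 0` recorded.
#'
#' @param sig_mirnas significant miRNA ids (subset of network miRNAs).
#' @param network a `target_network`.
#' @param ontology a `pathway_ontology` or named list of gene sets.
#' @return data frame `pathway, p, k, K, n, N, skipped`.
#' @export
enrich_targets_method1 <- function(sig_mirnas, network, ontology) {
  check_sig_in_network(sig_mirnas, network)
  sets <- as_pathway_sets(ontology)
  universe <- network$genes
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  query <- targets_of(network, sig_mirnas)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(pw) {
    Kset <- intersect(sets[[pw]], universe)
    K <- length(Kset)
    if (K == 0) {
      return(data.frame(pathway = pw, p = NA_real_, k = 0L, K = 0L,
                        n = n, N = N, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    k <- length(intersect(query, Kset))
    data.frame(pathway = pw, p = hypergeom_upper(k, K, n, N),
               k = k, K = K, n = n, N = N, skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Method 2: enrichment of miRNAs in pathways transformed to miRNA sets
#'
#' Each pathway is transformed into the set of miRNAs with at least one
#' target gene in the pathway; significant miRNAs are then tested for
#' over-representation in that set over the universe of all network miRNAs.
#' Unlike method 1 this is insensitive to unbalanced target counts, at the
#' price of boosting miRNAs with few targets.
#'
#' @inheritParams enrich_targets_method1
#' @return data frame `pathway, p, k, K, n, N, skipped`.
#' @export
enrich_mirna_sets_method2 <- function(sig_mirnas, network, ontology) {
  check_sig_in_network(sig_mirnas, network)
  if (!length(sig_mirnas)) {
    stop("significant miRNA set is empty", call. = FALSE)
  }
  sets <- as_pathway_sets(ontology)
  universe <- network$mirnas
  if (!length(universe)) stop("empty miRNA universe", call. = FALSE)
  N <- length(universe)
  n <- length(unique(sig_mirnas))
  rows <- lapply(names(sets), function(pw) {
    pw_genes <- sets[[pw]]
    mir_set <- universe[vapply(universe, function(m) {
      any(network$by_mirna[[m]] %in% pw_genes)
    }, logical(1))]
    K <- length(mir_set)
    if (K == 0) {
      return(data.frame(pathway = pw, p = NA_real_, k = 0L, K = 0L,
                        n = n, N = N, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    k <- length(intersect(unique(sig_mirnas), mir_set))
    data.frame(pathway = pw, p = hypergeom_upper(k, K, n, N),
               k = k, K = K, n = n, N = N, skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Combine the two enrichment methods: intersection and Fisher ranking
#'
#' BH adjustment is applied within each method across pathways; a pathway is
#' `significant_both` when both BH values fall below `bh_alpha`. Pathways
#' are ranked by the Fisher-combined (cumulative) p-value of the two
#' methods, ranks 1..m assigned only among the significant_both subset. The
#' reporting subset additionally requires raw p < `report_alpha` in both
#' methods and keeps the `top_n` best-ranked pathways.
#'
#' @param m1,m2 data frames from [enrich_targets_method1()] and
#'   [enrich_mirna_sets_method2()] over the same pathways.
#' @param bh_alpha within-method BH significance level (default .01).
#' @param report_alpha raw-p threshold for the reporting subset
#'   (default .001).
#' @param top_n size of the reporting subset (default 20).
#' @return data frame `pathway, p_method1, p_method2, bh1, bh2,
#'   fisher_combined_p, significant_both, rank, reported` plus the count
#'   fields of both methods.
#' @export
combine_dual <- function(m1, m2, bh_alpha = 0.01, report_alpha = 0.001,
                         top_n = 20L) {
  stopifnot(setequal(m1$pathway, m2$pathway),
            !anyDuplicated(m1$pathway), !anyDuplicated(m2$pathway))
  m2 <- m2[match(m1$pathway, m2$pathway), ]
  out <- data.frame(pathway = m1$pathway,
                    p_method1 = m1$p, p_method2 = m2$p,
                    bh1 = NA_real_, bh2 = NA_real_,
                    fisher_combined_p = NA_real_,
                    significant_both = FALSE,
                    rank = NA_integer_, reported = FALSE,
                    k1 = m1$k, K1 = m1$K, n1 = m1$n, N1 = m1$N,
                    k2 = m2$k, K2 = m2$K, n2 = m2$n, N2 = m2$N,
                    stringsAsFactors = FALSE)
  ok1 <- !is.na(out$p_method1); ok2 <- !is.na(out$p_method2)
  out$bh1[ok1] <- bh_adjust(out$p_method1[ok1])
  out$bh2[ok2] <- bh_adjust(out$p_method2[ok2])
  both <- ok1 & ok2
  out$fisher_combined_p[both] <- vapply(which(both), function(i) {
    fisher_combine(c(out$p_method1[i], out$p_method2[i]))
  }, numeric(1))
  out$significant_both <- both & out$bh1 < bh_alpha & out$bh2 < bh_alpha
  sig_idx <- which(out$significant_both)
  if (length(sig_idx)) {
    ord <- sig_idx[order(out$fisher_combined_p[sig_idx],
                         out$pathway[sig_idx])]
    out$rank[ord] <- seq_along(ord)
  }
  rep_idx <- which(both & out$p_method1 < report_alpha &
                     out$p_method2 < report_alpha)
  if (length(rep_idx)) {
    keep <- rep_idx[order(out$fisher_combined_p[rep_idx],
                          out$pathway[rep_idx])]
    out$reported[utils::head(keep, top_n)] <- TRUE
  }
  out[order(out$fisher_combined_p, out$pathway, na.last = TRUE), ,
      drop = FALSE]
}

#' Pathway-union enrichment of a miRNA cluster
#'
#' For every (miRNA, pathway) pair a hypergeometric test of that miRNA's
#' targets against the pathway over the method-1 gene universe; per pathway
#' the per-miRNA p-values of the cluster's miRNAs (those with non-empty
#' target sets) are combined by Fisher's method. A pathway is significant if
#' the combined p falls below `alpha` and the gene targets of at least one
#' cluster miRNA are present in it; pathways hit by no cluster miRNA are
#' excluded.
#'
#' @param cluster_mirnas miRNA ids of one cluster (non-empty, subset of
#'   network miRNAs).
#' @param network a `target_network`.
#' @param ontology a `pathway_ontology` or named list of gene sets.
#' @param alpha significance level on the combined p (default .05).
#' @return data frame `pathway, p_combined, n_contributing, significant`
#'   with attribute `significant_set` (pathway names, sorted).
#' @export
pathway_union_enrichment <- function(cluster_mirnas, network, ontology,
                                     alpha = 0.05) {
  if (!length(cluster_mirnas)) stop("empty miRNA cluster", call. = FALSE)
  check_sig_in_network(cluster_mirnas, network)
  sets <- as_pathway_sets(ontology)
  universe <- network$genes
  N <- length(universe)
  cluster_mirnas <- unique(cluster_mirnas)
  tsets <- lapply(cluster_mirnas, function(m) network$by_mirna[[m]])
  names(tsets) <- cluster_mirnas
  tsets <- tsets[vapply(tsets, length, integer(1)) > 0]
  rows <- lapply(names(sets), function(pw) {
    Kset <- intersect(sets[[pw]], universe)
    K <- length(Kset)
    if (K == 0 || !length(tsets)) return(NULL)
    ks <- vapply(tsets, function(tg) length(intersect(tg, Kset)), integer(1))
    if (all(ks == 0)) return(NULL)  # no cluster miRNA targets the pathway
    ps <- vapply(seq_along(tsets), function(i) {
      hypergeom_upper(ks[i], K, length(tsets[[i]]), N)
    }, numeric(1))
    data.frame(pathway = pw, p_combined = fisher_combine(ps),
               n_contributing = sum(ks > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway = character(), p_combined = numeric(),
                      n_contributing = integer(), stringsAsFactors = FALSE)
  }
  out$significant <- out$p_combined < alpha
  out <- out[order(out$p_combined, out$pathway), , drop = FALSE]
  attr(out, "significant_set") <- sort(out$pathway[out$significant])
  out
}

#' Pathways common to every cluster's significant set
#'
#' @param cluster_sets list (one element per cluster) of significant pathway
#'   name vectors.
#' @return sorted character vector: the intersection across all clusters.
#' @export
common_pathways <- function(cluster_sets) {
  stopifnot(is.list(cluster_sets), length(cluster_sets) >= 1)
  sort(Reduce(intersect, cluster_sets))
}
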