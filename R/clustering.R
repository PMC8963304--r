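# Fold-change profile clustering: UPGMA on Euclidean distances and a
# deterministic top-down dynamic tree cut.

#' Build a log2 fold-change profile matrix for clustering
#'
#' One row per significant miRNA, one column per exposure, cell = log2 fold
#' change. Exposures not tested for a miRNA are imputed as 0 (no change) and
#' recorded in the `imputed` attribute.
#'
#' @param records differential table (rows for the significant miRNAs) with
#'   columns `mirna`, `exposure`, `log2_fc`.
#' @param exposures fixed column order (default: sorted unique exposures).
#' @return numeric matrix (miRNA x exposure) with attribute `imputed`.
#' @export
fold_change_profile <- function(records, exposures = NULL) {
  stopifnot(all(c("mirna", "exposure", "log2_fc") %in% names(records)))
  if (is.null(exposures)) exposures <- sort(unique(records$exposure))
  mirnas <- sort(unique(records$mirna))
  m <- matrix(0, length(mirnas), length(exposures),
              dimnames = list(mirnas, exposures))
  imputed <- matrix(TRUE, length(mirnas), length(exposures),
                    dimnames = dimnames(m))
  keep <- records$exposure %in% exposures
  idx <- cbind(match(records$mirna[keep], mirnas),
               match(records$exposure[keep], exposures))
  m[idx] <- records$log2_fc[keep]
  imputed[idx] <- FALSE
  attr(m, "imputed") <- imputed
  m
}

#' Average-linkage (UPGMA) dendrogram on Euclidean distances
#'
#' Rows are sorted lexicographically by miRNA name before clustering so that
#' ties in the distance matrix are broken deterministically.
#'
#' @param profile numeric matrix with unique rownames (miRNA x exposure).
#' @return an `hclust` object.
#' @export
average_linkage_dendrogram <- function(profile) {
  stopifnot(is.matrix(profile), nrow(profile) >= 2,
            !is.null(rownames(profile)))
  if (anyDuplicated(rownames(profile))) {
    stop("duplicate miRNA rows in profile", call. = FALSE)
  }
  profile <- profile[order(rownames(profile)), , drop = FALSE]
  hclust(dist(profile, method = "euclidean"), method = "average")
}

#' Dynamic tree cut of a dendrogram into fold-change clusters
#'
#' Adaptive variant of the fixed-height cut: the sorted merge heights are
#' scanned for cluster-separating gaps -- positions where the next merge
#' height exceeds the previous by more than the gap factor (controlled by
#' `deep_split`). Each such gap is a candidate cut; the candidate whose cut
#' yields the most clusters of at least `min_cluster_size` leaves wins
#' (ties: the coarsest cut, then the largest gap). Leaves falling into
#' clusters below the minimum size are unassigned (label 0). With no
#' qualifying gap, or none yielding two admissible clusters, everything is
#' one cluster. Deterministic for a given dendrogram.
#'
#' @param hc an `hclust` from [average_linkage_dendrogram()].
#' @param min_cluster_size smallest admissible cluster (default 3).
#' @param deep_split integer 0-4; larger values split more aggressively
#'   (gap factors 2.6, 2.0, 1.6, 1.3, 1.15).
#' @return named integer vector: miRNA -> cluster label (1..K, contiguous),
#'   0 = unassigned.
#' @export
dynamic_tree_cut <- function(hc, min_cluster_size = 3L, deep_split = 1L) {
  stopifnot(inherits(hc, "hclust"))
  if (length(min_cluster_size) != 1L || min_cluster_size < 1) {
    stop("min_cluster_size must be >= 1", call. = FALSE)
  }
  if (!deep_split %in% 0:4) stop("deep_split must be in 0..4", call. = FALSE)
  factor_gap <- c(2.6, 2.0, 1.6, 1.3, 1.15)[deep_split + 1L]
  n <- length(hc$labels)
  h <- sort(hc$height)
  m <- length(h)
  ratio <- if (m >= 2) {
    ifelse(h[-m] == 0, ifelse(h[-1] > 0, Inf, 1), h[-1] / h[-m])
  } else numeric()
  cand <- which(ratio >= factor_gap)
  raw <- rep(1L, n)
  if (length(cand)) {
    cuts <- lapply(cand, function(i) {
      cut_h <- if (is.finite(h[i])) (h[i] + h[i + 1]) / 2 else h[i + 1] / 2
      lab <- stats::cutree(hc, h = cut_h)
      sizes <- tabulate(lab)
      list(lab = lab, k_good = sum(sizes >= min_cluster_size),
           k_total = length(sizes), ratio = ratio[i])
    })
    score <- vapply(cuts, function(cc) {
      c(cc$k_good, -cc$k_total, cc$ratio)
    }, numeric(3))
    best <- order(-score[1, ], -score[2, ], -score[3, ])[1]
    if (cuts[[best]]$k_good >= 2) raw <- cuts[[best]]$lab
  }
  # demote undersized clusters, relabel contiguously in leaf order
  sizes <- tabulate(raw)
  labels <- setNames(ifelse(sizes[raw] >= min_cluster_size, raw, 0L),
                     hc$labels)
  kept <- unique(labels[hc$order])
  kept <- kept[kept != 0L]
  relabel <- setNames(seq_along(kept), kept)
  labels[labels != 0L] <- relabel[as.character(labels[labels != 0L])]
  if (n < min_cluster_size) labels[] <- 0L
  storage.mode(labels) <- "integer"
  labels
}

#' Export a dendrogram as Newick text
#'
#' @param hc an `hclust`.
#' @return single Newick string.
#' @export
dendrogram_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}

#' Rand index between two partitions
#'
#' Fraction of item pairs on which two clusterings agree (joined in both or
#' separated in both); label permutations do not matter.
#'
#' @param a,b integer/character cluster label vectors of equal length.
#' @return Rand index in [0, 1].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  pairs <- utils::combn(length(a), 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(same_a == same_b)
}
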