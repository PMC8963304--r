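# Ct processing and paired differential expression: detection-limit capping,
# mean-centered plate normalization, paired t tests, Storey q / BH adjustment,
# the joint fold-change + p significance filter, and annotation mapping.

#' Cap Ct values at the detection limit and flag censored entries
#'
#' Every raw Ct at or above the detection limit is replaced by the limit
#' exactly and flagged censored; all other values are untouched.
#'
#' @param ctm a `ct_matrix` (see [gen_ct_matrix()] or [read_ct_matrix()]).
#' @return the `ct_matrix` with capped values and a logical `censored`
#'   matrix.
#' @export
cap_detection_limit <- function(ctm) {
  stopifnot(inherits(ctm, "ct_matrix"), !is.null(ctm$detection_limit))
  cens <- ctm$ct >= ctm$detection_limit
  ctm$ct[cens] <- ctm$detection_limit
  ctm$censored <- cens
  ctm
}

#' Mean-centered plate normalization of capped Ct values
#'
#' For each plate the mean raw Ct is computed over non-censored entries only
#' (values below the detection limit), and the normalized expression of
#' every entry -- censored entries included, at the capped value -- is
#' `plate_mean - raw Ct`. Higher normalized expression therefore means
#' higher expression (the sign of a Ct is flipped). The per-plate mean of
#' normalized values over non-censored entries is exactly zero.
#'
#' @param ctm a capped `ct_matrix`; if not yet capped,
#'   [cap_detection_limit()] is applied first.
#' @return object of class `normalized_expression`: `values` (centered
#'   cycles, miRNA x sample), `censored`, `plate_means`, `samples`,
#'   `detection_limit`.
#' @export
mean_center_normalize <- function(ctm) {
  stopifnot(inherits(ctm, "ct_matrix"))
  if (is.null(ctm$censored)) ctm <- cap_detection_limit(ctm)
  plates <- sort(unique(ctm$samples$plate))
  values <- ctm$ct
  plate_means <- setNames(numeric(length(plates)), plates)
  for (p in plates) {
    cols <- ctm$samples$sample[ctm$samples$plate == p]
    block <- ctm$ct[, cols, drop = FALSE]
    keep <- !ctm$censored[, cols, drop = FALSE]
    if (!any(keep)) {
      stop(sprintf("plate %s is fully censored", p), call. = FALSE)
    }
    pm <- mean(block[keep])
    plate_means[as.character(p)] <- pm
    values[, cols] <- pm - block
  }
  structure(list(values = values, censored = ctm$censored,
                 plate_means = plate_means, samples = ctm$samples,
                 detection_limit = ctm$detection_limit,
                 truth = ctm$truth),
            class = "normalized_expression")
}

# Treated and control sample blocks of one exposure, ordered so that column r
# of each block is replicate r (the pairing key: same replicate index, same
# plate).
exposure_blocks <- function(norm, treatment) {
  s <- norm$samples
  tr <- s[s$treatment == treatment & s$role == "treated", ]
  co <- s[s$treatment == treatment & s$role == "control", ]
  if (!nrow(tr) || !nrow(co)) {
    stop(sprintf("treatment %s has no paired samples", treatment),
         call. = FALSE)
  }
  tr <- tr[order(tr$replicate), ]
  co <- co[order(co$replicate), ]
  if (!identical(tr$replicate, co$replicate) ||
      !identical(tr$plate, co$plate)) {
    stop(sprintf("treatment %s: treated/control replicates are not paired",
                 treatment), call. = FALSE)
  }
  list(treated = norm$values[, tr$sample, drop = FALSE],
       control = norm$values[, co$sample, drop = FALSE],
       samples = c(tr$sample, co$sample))
}

#' Per-miRNA fold change for one exposure
#'
#' `FC = 2 ^ (mean treated normalized expression - mean control normalized
#' expression)`: one cycle of expression difference is a 2-fold change, and
#' down-regulation gives FC < 1.
#'
#' @param norm a `normalized_expression`.
#' @param treatment exposure (treatment name) to contrast against its paired
#'   controls.
#' @return named numeric vector of fold changes (one per miRNA).
#' @export
fold_change <- function(norm, treatment) {
  b <- exposure_blocks(norm, treatment)
  2^(rowMeans(b$treated) - rowMeans(b$control))
}

#' Paired t tests per miRNA for one exposure
#'
#' Classic paired t on the per-pair differences of normalized expression
#' (treated replicate i vs control replicate i on the same plate), with
#' `df = n_pairs - 1`. Degenerate rows (zero variance of differences) report
#' t = 0, p = 1 when the mean difference is also zero, and the smallest
#' representable positive p with a `degenerate` flag otherwise.
#'
#' @inheritParams fold_change
#' @return data frame `mirna, t_stat, df, p, degenerate`.
#' @export
paired_t <- function(norm, treatment) {
  b <- exposure_blocks(norm, treatment)
  n <- ncol(b$treated)
  if (n < 2) stop("paired t requires >= 2 pairs", call. = FALSE)
  d <- b$treated - b$control
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  tstat <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, Inf * sign(m)))
  p <- ifelse(is.finite(tstat), 2 * pt(-abs(tstat), n - 1),
              .Machine$double.xmin)
  p[tstat == 0 & s == 0] <- 1
  data.frame(mirna = rownames(d), t_stat = tstat, df = n - 1, p = p,
             degenerate = s == 0 & m != 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted p-values (monotone in rank, capped at 1).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(is.finite(p)), all(p > 0), all(p <= 1))
  p.adjust(p, method = "BH")
}

#' Storey q-values with fixed lambda
#'
#' The null proportion is estimated as
#' `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) m))` (no smoother; floored
#' at 1/m to keep q-values positive) and
#' `q_i = min over thresholds t >= p_i of pi0 * m * t / #\{p <= t\}`, i.e.
#' the BH step-up values scaled by pi0. With fewer than 10 p-values, or when
#' `pi0` is supplied as 1, q-values coincide with BH adjusted p-values.
#'
#' @param p vector of p-values in (0, 1].
#' @param lambda tuning point for the pi0 estimate (default 0.5).
#' @param pi0 optional fixed null proportion overriding the estimate.
#' @return q-values, monotone in p.
#' @export
storey_q <- function(p, lambda = 0.5, pi0 = NULL) {
  stopifnot(all(is.finite(p)), all(p > 0), all(p <= 1),
            lambda > 0, lambda < 1)
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- if (m < 10) 1 else min(1, sum(p > lambda) / ((1 - lambda) * m))
    pi0 <- max(pi0, 1 / m)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * p[o] / (m - seq_len(m) + 1L)))[ro]
  q
}

#' Differential expression table across exposures
#'
#' For each requested exposure: per-miRNA fold change, paired t test,
#' Storey q-values and BH adjusted p-values (computed within the exposure
#' across the panel), the per-miRNA fraction of censored entries among the
#' samples used, and the significance flag from [select_significant()].
#'
#' @param norm a `normalized_expression`.
#' @param treatments exposures to analyze (default: all treatments in the
#'   sample sheet).
#' @param fc_up,fc_down,p_threshold joint filter thresholds passed to
#'   [select_significant()] (defaults 1.5, 0.67, .01).
#' @return data frame with one row per miRNA x exposure: `mirna, exposure,
#'   fold_change, log2_fc, t_stat, df, p, q_storey, p_bh, significant,
#'   n_pairs, censored_fraction`.
#' @export
differential_expression <- function(norm, treatments = NULL,
                                    fc_up = 1.5, fc_down = 0.67,
                                    p_threshold = 0.01) {
  stopifnot(inherits(norm, "normalized_expression"))
  if (is.null(treatments)) treatments <- unique(norm$samples$treatment)
  res <- lapply(treatments, function(trt) {
    fc <- fold_change(norm, trt)
    tt <- paired_t(norm, trt)
    b <- exposure_blocks(norm, trt)
    cf <- rowMeans(norm$censored[, b$samples, drop = FALSE])
    data.frame(mirna = tt$mirna, exposure = trt,
               fold_change = as.numeric(fc[tt$mirna]),
               log2_fc = log2(as.numeric(fc[tt$mirna])),
               t_stat = tt$t_stat, df = tt$df, p = tt$p,
               q_storey = storey_q(tt$p),
               p_bh = bh_adjust(tt$p),
               n_pairs = tt$df + 1L,
               censored_fraction = as.numeric(cf[tt$mirna]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  select_significant(out, fc_up = fc_up, fc_down = fc_down,
                     p_threshold = p_threshold)
}

#' Flag significant records by the joint fold-change and p filter
#'
#' A record is significant when `fold_change >= fc_up` or
#' `fold_change <= fc_down`, AND its unadjusted `p < p_threshold`
#' (defaults: 1.5 / 0.67 and .01). The q and BH values are carried through
#' but deliberately not used for the flag.
#'
#' @param records differential table with columns `fold_change` and `p`.
#' @param fc_up,fc_down,p_threshold filter thresholds.
#' @return `records` with a logical `significant` column.
#' @export
select_significant <- function(records, fc_up = 1.5, fc_down = 0.67,
                               p_threshold = 0.01) {
  stopifnot(all(c("fold_change", "p") %in% names(records)),
            fc_up > fc_down, p_threshold > 0, p_threshold <= 1)
  records$significant <-
    (records$fold_change >= fc_up | records$fold_change <= fc_down) &
    records$p < p_threshold
  records
}

#' Map assay names to annotation and exclude unmappable miRNAs
#'
#' Each assay name is classified as `mapped`, `unmapped` (absent from the
#' annotation table), `discontinued`, or `non-human`; only mapped names are
#' retained for downstream pathway analyses, and every exclusion carries its
#' reason.
#'
#' @param assay_names character vector of panel assay names.
#' @param annotation data frame `assay_name, accession, gene_id, status`
#'   (status one of mapped / discontinued / non-human).
#' @return list with `map` (data frame `assay_name, accession, gene_id,
#'   status, reason`) and `retained` (mapped assay names, input order).
#' @export
map_annotations <- function(assay_names, annotation) {
  stopifnot(is.data.frame(annotation),
            all(c("assay_name", "accession", "gene_id", "status")
                %in% names(annotation)))
  if (anyDuplicated(annotation$assay_name)) {
    stop("duplicate assay names in annotation table", call. = FALSE)
  }
  bad <- setdiff(unique(annotation$status),
                 c("mapped", "discontinued", "non-human"))
  if (length(bad)) {
    stop(sprintf("unknown annotation status: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  i <- match(assay_names, annotation$assay_name)
  status <- ifelse(is.na(i), "unmapped", annotation$status[i])
  reason <- c(mapped = "",
              unmapped = "assay name absent from annotation table",
              discontinued = "maps to a discontinued gene id",
              `non-human` = "does not map to a human miRNA")[status]
  map <- data.frame(assay_name = assay_names,
                    accession = ifelse(is.na(i), "", annotation$accession[i]),
                    gene_id = ifelse(is.na(i), "", annotation$gene_id[i]),
                    status = status, reason = unname(reason),
                    stringsAsFactors = FALSE)
  list(map = map, retained = assay_names[status == "mapped"])
}
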