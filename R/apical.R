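# Apical endpoint analysis: per-plate normalization to % of vehicle control,
# Dunnett many-to-one comparisons, endpoint correlation, and selection of the
# low/high concentrations carried into the miRNA stage.

#' Normalize well-level apical data to percent of same-plate vehicle control
#'
#' Within each (chemical, plate, endpoint) group the mean of the vehicle
#' wells (concentration 0) is mapped to 100 and every well scaled
#' accordingly, after which plates are poolable. Normalizing
#' already-normalized data is the identity.
#'
#' @param records data frame `chemical, concentration_uM, plate, well,
#'   endpoint, value`.
#' @param min_vehicle_wells minimum vehicle wells required per plate/endpoint
#'   (default 2).
#' @return `records` with `value` rescaled to percent of control.
#' @export
normalize_percent_of_control <- function(records, min_vehicle_wells = 2L) {
  req <- c("chemical", "concentration_uM", "plate", "endpoint", "value")
  stopifnot(all(req %in% names(records)))
  key <- interaction(records$chemical, records$plate, records$endpoint,
                     drop = TRUE)
  out <- records
  for (k in levels(key)) {
    idx <- key == k
    veh <- idx & records$concentration_uM == 0
    if (sum(veh) < min_vehicle_wells) {
      r <- records[idx, ][1, ]
      stop(sprintf(
        "plate %s has %d vehicle well(s) for endpoint %s (chemical %s); >= %d required",
        r$plate, sum(veh), r$endpoint, r$chemical, min_vehicle_wells),
        call. = FALSE)
    }
    out$value[idx] <- records$value[idx] / mean(records$value[veh]) * 100
  }
  out
}

# Memoised null distribution of max_i |T_i| for the Dunnett many-to-one
# family: Z_0..Z_k iid N(0,1), W ~ chi^2_df, and
# T_i = (Z_i/sqrt(n_i) - Z_0/sqrt(n_0)) / sqrt(1/n_i + 1/n_0) / sqrt(W/df).
.dunnett_cache <- new.env(parent = emptyenv())

dunnett_null_maxt <- function(n, df, nsim, mc_seed) {
  key <- paste(paste(n, collapse = ","), df, nsim, mc_seed, sep = "|")
  if (!is.null(.dunnett_cache[[key]])) return(.dunnett_cache[[key]])
  k <- length(n) - 1L
  draws <- with_seed(stage_seed(mc_seed, key), {
    z <- matrix(rnorm(nsim * (k + 1L)), nsim, k + 1L)
    w <- sqrt(rchisq(nsim, df) / df)
    se <- sqrt(1 / n[-1] + 1 / n[1])
    t_mat <- (z[, -1, drop = FALSE] %*% diag(1 / sqrt(n[-1]), k) -
                z[, 1] / sqrt(n[1])) / rep(se, each = nsim) / w
    sort(apply(abs(t_mat), 1, max))
  })
  .dunnett_cache[[key]] <- draws
  draws
}

#' Dunnett many-to-one comparisons against a shared control
#'
#' Pooled-variance t statistics for each treated group versus the control,
#' with family-wise adjusted two-sided p-values from the joint null of the
#' maximum absolute statistic over the equicorrelated multivariate t (general
#' correlations at unequal n). The joint tail is computed by seeded
#' Monte-Carlo integration (`nsim` draws, memoised per design), so adjusted
#' p-values are exact up to Monte-Carlo error at arbitrary k and unequal n
#' and fully reproducible. With a single treated group the comparison reduces
#' exactly to the classic pooled two-sample t test.
#'
#' @param values numeric response vector.
#' @param groups factor (or coercible) with the control as its first level.
#' @param nsim Monte-Carlo draws for the max-|t| null (default 1e5).
#' @param mc_seed seed for the Monte-Carlo integration.
#' @return data frame `comparison, estimate, t, df, p_adj`.
#' @export
dunnett_test <- function(values, groups, nsim = 1e5, mc_seed = 20240814L) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  n <- tabulate(groups, nlevels(groups))
  if (any(n < 2)) stop("every group needs >= 2 wells", call. = FALSE)
  means <- tapply(values, groups, mean)
  vars <- tapply(values, groups, var)
  df <- sum(n) - nlevels(groups)
  s2 <- sum((n - 1) * vars) / df
  if (s2 <= 0) {
    stop("zero pooled variance: degenerate data", call. = FALSE)
  }
  k <- nlevels(groups) - 1L
  est <- means[-1] - means[1]
  tstat <- est / sqrt(s2 * (1 / n[-1] + 1 / n[1]))
  p_adj <- if (k == 1L) {
    2 * pt(-abs(tstat), df)
  } else {
    maxt <- dunnett_null_maxt(n, df, nsim, mc_seed)
    vapply(abs(tstat), function(a) {
      (1 + nsim - findInterval(a, maxt)) / (nsim + 1)
    }, numeric(1))
  }
  data.frame(comparison = levels(groups)[-1],
             estimate = as.numeric(est), t = as.numeric(tstat), df = df,
             p_adj = as.numeric(p_adj),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dunnett tests per chemical and endpoint for normalized apical data
#'
#' Pools plates (data must already be normalized to % of control) and
#' compares every tested concentration against the vehicle (concentration 0)
#' group within each chemical x endpoint stratum.
#'
#' @param normalized output of [normalize_percent_of_control()].
#' @inheritParams dunnett_test
#' @return data frame `chemical, endpoint, concentration_uM, estimate, t,
#'   df, p_adj`.
#' @export
apical_dunnett <- function(normalized, nsim = 1e5, mc_seed = 20240814L) {
  combos <- unique(normalized[c("chemical", "endpoint")])
  res <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- normalized[normalized$chemical == combos$chemical[i] &
                        normalized$endpoint == combos$endpoint[i], ]
    conc <- sort(unique(sub$concentration_uM))
    if (!0 %in% conc || length(conc) < 2) {
      stop(sprintf("chemical %s endpoint %s needs vehicle plus >= 1 concentration",
                   combos$chemical[i], combos$endpoint[i]), call. = FALSE)
    }
    g <- factor(sub$concentration_uM, levels = conc)
    d <- dunnett_test(sub$value, g, nsim = nsim, mc_seed = mc_seed)
    data.frame(chemical = combos$chemical[i], endpoint = combos$endpoint[i],
               concentration_uM = as.numeric(d$comparison),
               estimate = d$estimate, t = d$t, df = d$df, p_adj = d$p_adj,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Lowest concentration with a significant Dunnett response
#'
#' @param dunnett data frame from [apical_dunnett()].
#' @param alpha significance level (default .05).
#' @return data frame `chemical, endpoint, lowest_effect_concentration`
#'   (NA when no concentration is significant).
#' @export
lowest_effect_concentration <- function(dunnett, alpha = 0.05) {
  combos <- unique(dunnett[c("chemical", "endpoint")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- dunnett[dunnett$chemical == combos$chemical[i] &
                     dunnett$endpoint == combos$endpoint[i], ]
    sub <- sub[order(sub$concentration_uM), ]
    sig <- sub$concentration_uM[sub$p_adj < alpha]
    data.frame(chemical = combos$chemical[i], endpoint = combos$endpoint[i],
               lowest_effect_concentration =
                 if (length(sig)) min(sig) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pearson correlation of log2 fold changes across endpoint pairs
#'
#' For each (chemical, concentration > 0) condition the pooled normalized
#' mean of each endpoint is converted to a log2 fold change versus vehicle
#' (100%), and each pair of endpoints is tested for Pearson correlation
#' (t transform, n - 2 df). p-values below the smallest representable
#' positive double are reported as that smallest positive value.
#'
#' @param normalized output of [normalize_percent_of_control()].
#' @param endpoints endpoints to correlate (default: all present).
#' @return data frame `endpoint_a, endpoint_b, r, p, n`.
#' @export
correlate_endpoints <- function(normalized, endpoints = NULL) {
  if (is.null(endpoints)) endpoints <- sort(unique(normalized$endpoint))
  stopifnot(length(endpoints) >= 2)
  sub <- normalized[normalized$concentration_uM > 0 &
                      normalized$endpoint %in% endpoints, ]
  agg <- aggregate(value ~ chemical + concentration_uM + endpoint, sub, mean)
  agg$log2_fc <- log2(pmax(agg$value, .Machine$double.eps) / 100)
  wide <- reshape(agg[c("chemical", "concentration_uM", "endpoint", "log2_fc")],
                  idvar = c("chemical", "concentration_uM"),
                  timevar = "endpoint", direction = "wide")
  names(wide) <- sub("^log2_fc\\.", "", names(wide))
  pairs <- utils::combn(endpoints, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- wide[[pairs[1, j]]]; b <- wide[[pairs[2, j]]]
    ok <- stats::complete.cases(a, b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 3) stop("need >= 3 paired conditions", call. = FALSE)
    if (sd(a) == 0 || sd(b) == 0) {
      stop(sprintf("zero variance in endpoint pair %s / %s",
                   pairs[1, j], pairs[2, j]), call. = FALSE)
    }
    r <- cor(a, b)
    n <- length(a)
    tt <- r * sqrt((n - 2) / max(1 - r^2, 0))
    p <- if (!is.finite(tt)) 0 else 2 * pt(-abs(tt), n - 2)
    data.frame(endpoint_a = pairs[1, j], endpoint_b = pairs[2, j],
               r = r, p = max(p, .Machine$double.xmin), n = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Select the low and high miRNA test concentrations per chemical
#'
#' Applies the screening rule: the \emph{low} concentration is the smallest
#' tested concentration with no/minimal effect on cell viability (ATP
#' decrease <= `viability_drop`) together with a statistically significant
#' decrease of at least `neurite_drop` in a neurite outgrowth endpoint; the
#' \emph{high} concentration is the smallest concentration (at or above the
#' low) with significant decreases of at least the screen size in both ATP
#' and a neurite endpoint. When no concentration meets the high rule the
#' maximum tested concentration is selected (the microtubule-agent rule).
#' A chemical for which no concentration meets the low rule yields an
#' explicit "no qualifying low concentration" outcome, not a silent
#' fallback. "Significant decrease >= 20%" is operationalized as group mean
#' <= 80% of control AND Dunnett adjusted p < `alpha`.
#'
#' @param normalized output of [normalize_percent_of_control()] (pooled
#'   means across plates are used for the percent screens).
#' @param dunnett output of [apical_dunnett()].
#' @param atp_endpoint name of the viability endpoint (default "ATP").
#' @param neurite_endpoints names of neurite outgrowth endpoints.
#' @param viability_drop,neurite_drop screen sizes as fractions of control
#'   (default 0.20 each).
#' @param alpha Dunnett significance level (default .05).
#' @return data frame `chemical, low, high, low_rationale, high_rationale`
#'   with NA low/high when no concentration qualifies.
#' @export
select_concentrations <- function(normalized, dunnett,
                                  atp_endpoint = "ATP",
                                  neurite_endpoints = c("neurite_length",
                                                        "neurite_count"),
                                  viability_drop = 0.20,
                                  neurite_drop = 0.20,
                                  alpha = 0.05) {
  stopifnot(atp_endpoint %in% normalized$endpoint,
            any(neurite_endpoints %in% normalized$endpoint))
  neurite_endpoints <- intersect(neurite_endpoints,
                                 unique(normalized$endpoint))
  agg <- aggregate(value ~ chemical + concentration_uM + endpoint,
                   normalized[normalized$concentration_uM > 0, ], mean)
  chems <- sort(unique(normalized$chemical))
  out <- lapply(chems, function(ch) {
    conc <- sort(unique(agg$concentration_uM[agg$chemical == ch]))
    pooled_mean <- function(ep, cc) {
      v <- agg$value[agg$chemical == ch & agg$endpoint == ep &
                       agg$concentration_uM == cc]
      if (length(v)) v else NA_real_
    }
    padj <- function(ep, cc) {
      v <- dunnett$p_adj[dunnett$chemical == ch & dunnett$endpoint == ep &
                           dunnett$concentration_uM == cc]
      if (length(v)) v else NA_real_
    }
    neurite_hit <- function(cc, drop) {
      any(vapply(neurite_endpoints, function(ep) {
        isTRUE(pooled_mean(ep, cc) <= (1 - drop) * 100) &&
          isTRUE(padj(ep, cc) < alpha)
      }, logical(1)))
    }
    low_ok <- vapply(conc, function(cc) {
      isTRUE(pooled_mean(atp_endpoint, cc) >= (1 - viability_drop) * 100) &&
        neurite_hit(cc, neurite_drop)
    }, logical(1))
    high_ok <- vapply(conc, function(cc) {
      isTRUE(pooled_mean(atp_endpoint, cc) <= (1 - viability_drop) * 100) &&
        isTRUE(padj(atp_endpoint, cc) < alpha) &&
        neurite_hit(cc, neurite_drop)
    }, logical(1))
    if (!any(low_ok)) {
      return(data.frame(chemical = ch, low = NA_real_, high = NA_real_,
                        low_rationale = "no qualifying low concentration",
                        high_rationale = NA_character_,
                        stringsAsFactors = FALSE))
    }
    low <- min(conc[low_ok])
    high_cand <- conc[high_ok & conc >= low]
    if (length(high_cand)) {
      high <- min(high_cand)
      high_rat <- sprintf(
        "smallest concentration >= low with significant >=%.0f%% decreases in both ATP and neurite endpoints",
        100 * viability_drop)
    } else {
      high <- max(conc)
      high_rat <- "no concentration met the dual-decrease rule; maximum tested concentration selected"
    }
    data.frame(
      chemical = ch, low = low, high = high,
      low_rationale = sprintf(
        "smallest concentration with ATP decrease <=%.0f%% and significant neurite decrease >=%.0f%%",
        100 * viability_drop, 100 * neurite_drop),
      high_rationale = high_rat, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
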