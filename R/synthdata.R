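# Synthetic-data generators. Every generator is a pure function of its config
# (including the seed) and returns its planted ground truth alongside the data
# so downstream recovery tests can score against it.

#' Configuration for the synthetic Ct-matrix generator
#'
#' Describes a TaqMan-style miRNA array card experiment: a fixed panel of
#' miRNAs measured for paired treated/control biological replicates, with one
#' plate (card) per compound treatment carrying a plate-level location shift,
#' and optional spiked log2 expression effects.
#'
#' @param n_mirnas number of miRNA features on the panel (default 754, the
#'   size of the human A+B card set).
#' @param treatments data frame with columns `name` and `n_paired_replicates`
#'   (default one treatment with 3 paired biological replicates), or a named
#'   integer vector of replicate counts.
#' @param n_plates number of plates; treatments are assigned to plates
#'   round-robin so that all samples of one treatment share a plate.
#'   Defaults to one plate per treatment.
#' @param baseline_mean_ct mean baseline Ct across the panel (cycles).
#' @param baseline_sd_between_mirnas between-miRNA sd of baseline Ct (cycles).
#' @param replicate_sd within-replicate technical noise sd (cycles).
#' @param plate_shift_sd sd of the per-plate location shift (cycles).
#' @param detection_limit right-censoring limit (cycles, default 35).
#' @param spikes data frame with columns `mirna_index`, `treatment`,
#'   `log2_effect`, or NULL. A positive `log2_effect` means higher expression
#'   in treatment, applied on the Ct scale as \eqn{-log2\_effect} cycles
#'   (1 cycle = 2-fold).
#' @param seed integer seed fixing all draws.
#' @return an object of class `ct_sim_config`.
#' @export
ct_sim_config <- function(n_mirnas = 754,
                          treatments = data.frame(
                            name = "treatment",
                            n_paired_replicates = 3L,
                            stringsAsFactors = FALSE),
                          n_plates = NULL,
                          baseline_mean_ct = 28,
                          baseline_sd_between_mirnas = 2,
                          replicate_sd = 0.5,
                          plate_shift_sd = 0.5,
                          detection_limit = 35,
                          spikes = NULL,
                          seed = 1L) {
  n_mirnas <- check_count(n_mirnas, "n_mirnas")
  if (!is.data.frame(treatments)) {
    if (is.null(names(treatments))) {
      stop("`treatments` must be a data frame or a named vector", call. = FALSE)
    }
    treatments <- data.frame(name = names(treatments),
                             n_paired_replicates = as.integer(treatments),
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "n_paired_replicates") %in% names(treatments)))
  if (anyDuplicated(treatments$name)) {
    stop("treatment names must be unique", call. = FALSE)
  }
  for (r in treatments$n_paired_replicates) check_count(r, "n_paired_replicates")
  if (is.null(n_plates)) n_plates <- nrow(treatments)
  n_plates <- check_count(n_plates, "n_plates")
  stopifnot(baseline_sd_between_mirnas >= 0, replicate_sd >= 0,
            plate_shift_sd >= 0, detection_limit > 0)
  if (!is.null(spikes)) {
    stopifnot(is.data.frame(spikes),
              all(c("mirna_index", "treatment", "log2_effect") %in% names(spikes)))
    bad <- spikes$mirna_index[spikes$mirna_index < 1 |
                              spikes$mirna_index > n_mirnas |
                              spikes$mirna_index != round(spikes$mirna_index)]
    if (length(bad)) {
      stop(sprintf("spike mirna_index out of range [1, %d]: %s",
                   n_mirnas, paste(bad, collapse = ", ")), call. = FALSE)
    }
    missing_trt <- setdiff(spikes$treatment, treatments$name)
    if (length(missing_trt)) {
      stop(sprintf("spike treatment(s) not in design: %s",
                   paste(missing_trt, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(n_mirnas = n_mirnas, treatments = treatments,
                 n_plates = n_plates, baseline_mean_ct = baseline_mean_ct,
                 baseline_sd_between_mirnas = baseline_sd_between_mirnas,
                 replicate_sd = replicate_sd, plate_shift_sd = plate_shift_sd,
                 detection_limit = detection_limit, spikes = spikes,
                 seed = as.integer(seed)),
            class = "ct_sim_config")
}

new_ct_matrix <- function(ct, samples, detection_limit, censored = NULL,
                          truth = NULL) {
  stopifnot(is.matrix(ct), identical(colnames(ct), samples$sample))
  structure(list(ct = ct, samples = samples,
                 detection_limit = detection_limit,
                 censored = censored, truth = truth),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("<ct_matrix> %d miRNAs x %d samples, detection limit Ct %s, %s\n",
              nrow(x$ct), ncol(x$ct), format(x$detection_limit),
              if (is.null(x$censored)) "uncapped" else
                sprintf("%d censored entries", sum(x$censored))))
  invisible(x)
}

#' Generate a raw Ct matrix with a paired treated/control design
#'
#' Raw Ct for miRNA i in sample s is
#' `baseline_i + plate_shift_p + effect + noise`, where `effect` is
#' \eqn{-log2\_effect} cycles for spiked (miRNA, treatment) combinations in
#' treated samples (lower Ct = higher expression). Values at or above the
#' detection limit are emitted as-is; capping and censoring flags are the
#' consumer's job (see [cap_detection_limit()]). Each treated replicate is
#' paired with the control replicate of the same index on the same plate.
#'
#' @param cfg a [ct_sim_config()].
#' @return a `ct_matrix`: raw Ct values, sample sheet
#'   (`sample`, `plate`, `treatment`, `replicate`, `role`), the detection
#'   limit, and `truth` (spike table, baselines, plate shifts).
#' @export
gen_ct_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "ct_sim_config"))
  trt <- cfg$treatments
  plate_of <- setNames(((seq_len(nrow(trt)) - 1L) %% cfg$n_plates) + 1L,
                       trt$name)
  sheets <- lapply(seq_len(nrow(trt)), function(t) {
    R <- trt$n_paired_replicates[t]
    data.frame(
      sample = sprintf("%s_%s_r%d", trt$name[t],
                       rep(c("treated", "control"), each = R),
                       rep(seq_len(R), 2L)),
      plate = plate_of[[trt$name[t]]],
      treatment = trt$name[t],
      replicate = rep(seq_len(R), 2L),
      role = rep(c("treated", "control"), each = R),
      stringsAsFactors = FALSE)
  })
  samples <- do.call(rbind, sheets)
  mirnas <- mirna_ids(cfg$n_mirnas)
  with_seed(cfg$seed, {
    baseline <- cfg$baseline_mean_ct +
      rnorm(cfg$n_mirnas, 0, cfg$baseline_sd_between_mirnas)
    shift <- rnorm(cfg$n_plates, 0, cfg$plate_shift_sd)
    ct <- matrix(baseline, cfg$n_mirnas, nrow(samples)) +
      matrix(shift[samples$plate], cfg$n_mirnas, nrow(samples), byrow = TRUE) +
      matrix(rnorm(cfg$n_mirnas * nrow(samples), 0, cfg$replicate_sd),
             cfg$n_mirnas, nrow(samples))
    if (!is.null(cfg$spikes)) {
      for (j in seq_len(nrow(cfg$spikes))) {
        cols <- samples$treatment == cfg$spikes$treatment[j] &
          samples$role == "treated"
        ct[cfg$spikes$mirna_index[j], cols] <-
          ct[cfg$spikes$mirna_index[j], cols] - cfg$spikes$log2_effect[j]
      }
    }
    dimnames(ct) <- list(mirnas, samples$sample)
    new_ct_matrix(ct, samples, cfg$detection_limit,
                  truth = list(spikes = cfg$spikes,
                               spiked_mirnas =
                                 unique(mirnas[cfg$spikes$mirna_index]),
                               baseline = setNames(baseline, mirnas),
                               plate_shift = shift))
  })
}

#' Configuration for the synthetic apical-endpoint generator
#'
#' @param chemicals data frame with one row per (chemical, endpoint) giving
#'   Hill parameters: `chemical`, `endpoint`, `top` (% of control at zero
#'   dose), `bottom` (% at saturating dose), `ec50` (uM), `slope`.
#' @param concentrations tested concentrations in uM, strictly positive and
#'   sorted ascending (default 0.1, 1, 10, 30, 100 uM).
#' @param wells_per_group wells per chemical x concentration x plate
#'   (default 3 technical replicates), must be >= 2.
#' @param well_cv coefficient of variation of well-level noise.
#' @param n_plates number of plates (biological replicates; default 2).
#' @param plate_scale_sd sd of the log-normal per-plate raw-scale factor,
#'   emulating between-plate instrument gain differences.
#' @param seed integer seed.
#' @return an object of class `apical_sim_config`.
#' @export
apical_sim_config <- function(chemicals,
                              concentrations = c(0.1, 1, 10, 30, 100),
                              wells_per_group = 3L,
                              well_cv = 0.1,
                              n_plates = 2L,
                              plate_scale_sd = 0.1,
                              seed = 1L) {
  stopifnot(is.data.frame(chemicals),
            all(c("chemical", "endpoint", "top", "bottom", "ec50", "slope")
                %in% names(chemicals)))
  if (any(chemicals$ec50 <= 0)) stop("ec50 must be positive", call. = FALSE)
  if (any(concentrations <= 0) || is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be strictly positive and sorted ascending",
         call. = FALSE)
  }
  wells_per_group <- check_count(wells_per_group, "wells_per_group", min = 2L)
  n_plates <- check_count(n_plates, "n_plates")
  stopifnot(well_cv >= 0, plate_scale_sd >= 0)
  structure(list(chemicals = chemicals, concentrations = concentrations,
                 wells_per_group = wells_per_group, well_cv = well_cv,
                 n_plates = n_plates, plate_scale_sd = plate_scale_sd,
                 seed = as.integer(seed)),
            class = "apical_sim_config")
}

#' Hill dose-response mean (% of control)
#'
#' `bottom + (top - bottom) / (1 + (conc / ec50)^slope)`; equals `top` at zero
#' concentration and the midpoint `(top + bottom)/2` at `conc = ec50`.
#'
#' @param conc concentration (uM); 0 returns `top`.
#' @param top,bottom,ec50,slope Hill parameters.
#' @export
hill_response <- function(conc, top, bottom, ec50, slope) {
  ifelse(conc <= 0, top, bottom + (top - bottom) / (1 + (conc / ec50)^slope))
}

#' Generate well-level apical endpoint data around Hill-curve means
#'
#' Emits one row per well: vehicle wells (concentration 0, at 100% of control
#' in normalized terms) and treated wells at each tested concentration, for
#' every endpoint of every chemical on every plate. Raw values carry a
#' per-plate scale factor so that per-plate normalization is exercised
#' downstream; within a plate, well values are Normal with mean equal to the
#' Hill response and sd `well_cv * mean`.
#'
#' @param cfg an [apical_sim_config()].
#' @return data frame `chemical, concentration_uM, plate, well, endpoint,
#'   value` with attribute `truth` (the per-condition Hill means and plate
#'   scale factors).
#' @export
gen_apical <- function(cfg) {
  stopifnot(inherits(cfg, "apical_sim_config"))
  with_seed(cfg$seed, {
    plate_scale <- exp(rnorm(cfg$n_plates, 0, cfg$plate_scale_sd))
    grid <- expand.grid(row = seq_len(nrow(cfg$chemicals)),
                        concentration_uM = c(0, cfg$concentrations),
                        plate = seq_len(cfg$n_plates),
                        well = seq_len(cfg$wells_per_group))
    ch <- cfg$chemicals[grid$row, ]
    mu <- hill_response(grid$concentration_uM, ch$top, ch$bottom,
                        ch$ec50, ch$slope)
    mu[grid$concentration_uM == 0] <- 100  # vehicle wells at 100% of control
    raw <- (mu + rnorm(length(mu), 0, cfg$well_cv * abs(mu))) *
      plate_scale[grid$plate]
    out <- data.frame(chemical = ch$chemical,
                      concentration_uM = grid$concentration_uM,
                      plate = grid$plate,
                      well = sprintf("%s_c%g_p%d_w%d", ch$chemical,
                                     grid$concentration_uM, grid$plate,
                                     grid$well),
                      endpoint = ch$endpoint,
                      value = raw,
                      stringsAsFactors = FALSE)
    truth <- unique(data.frame(chemical = ch$chemical, endpoint = ch$endpoint,
                               concentration_uM = grid$concentration_uM,
                               hill_mean = mu, stringsAsFactors = FALSE))
    attr(out, "truth") <- list(means = truth, plate_scale = plate_scale)
    out
  })
}

#' Configuration for synthetic target-network and pathway-ontology generation
#'
#' @param n_genes size of the gene namespace.
#' @param n_mirnas number of miRNAs in the network.
#' @param degree_distribution numeric triple `(min_targets, max_targets,
#'   tail_exponent)`: per-miRNA out-degree drawn from a truncated power law
#'   `P(d) ~ d^-tail` on `[min, max]`.
#' @param n_pathways number of gene sets.
#' @param pathway_size_range integer pair `(min, max)` gene-set size.
#' @param planted_pathway_overlap fraction of the union of spiked-miRNA
#'   targets placed into the designated planted pathway.
#' @param validated_fraction fraction of edges tagged `validated` (the rest
#'   `predicted`).
#' @param seed integer seed.
#' @export
ontology_sim_config <- function(n_genes = 2000,
                                n_mirnas = 200,
                                degree_distribution = c(4, 30, 2.5),
                                n_pathways = 50,
                                pathway_size_range = c(25, 120),
                                planted_pathway_overlap = 0.8,
                                validated_fraction = 0.6,
                                seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_mirnas <- check_count(n_mirnas, "n_mirnas")
  stopifnot(length(degree_distribution) == 3)
  dmin <- check_count(degree_distribution[1], "min_targets")
  dmax <- check_count(degree_distribution[2], "max_targets")
  if (dmin > dmax) stop("min_targets > max_targets", call. = FALSE)
  if (dmin > n_genes) {
    stop("min_targets exceeds the number of genes", call. = FALSE)
  }
  n_pathways <- check_count(n_pathways, "n_pathways")
  stopifnot(length(pathway_size_range) == 2)
  smin <- check_count(pathway_size_range[1], "pathway_size min")
  smax <- check_count(pathway_size_range[2], "pathway_size max")
  if (smin > smax || smax > n_genes) {
    stop("pathway sizes must satisfy min <= max <= n_genes", call. = FALSE)
  }
  planted_pathway_overlap <- check_fraction(planted_pathway_overlap,
                                            "planted_pathway_overlap")
  validated_fraction <- check_fraction(validated_fraction,
                                       "validated_fraction")
  structure(list(n_genes = n_genes, n_mirnas = n_mirnas,
                 degree_distribution = c(dmin, dmax, degree_distribution[3]),
                 n_pathways = n_pathways,
                 pathway_size_range = c(smin, smax),
                 planted_pathway_overlap = planted_pathway_overlap,
                 validated_fraction = validated_fraction,
                 seed = as.integer(seed)),
            class = "ontology_sim_config")
}

#' Construct a miRNA-target network from an edge table
#'
#' @param edges data frame with columns `mirna`, `gene`, `evidence`
#'   (`validated` or `predicted`).
#' @return object of class `target_network` with the edge table and miRNA /
#'   gene indexes.
#' @export
target_network <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("mirna", "gene", "evidence") %in% names(edges)))
  if (anyDuplicated(edges[c("mirna", "gene")])) {
    stop("duplicate (mirna, gene) pairs in network", call. = FALSE)
  }
  bad <- setdiff(unique(edges$evidence), c("validated", "predicted"))
  if (length(bad)) {
    stop(sprintf("unknown evidence grade(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(edges = edges,
                 mirnas = sort(unique(edges$mirna)),
                 genes = sort(unique(edges$gene)),
                 by_mirna = split(edges$gene, edges$mirna)),
            class = "target_network")
}

#' @export
print.target_network <- function(x, ...) {
  cat(sprintf("<target_network> %d edges, %d miRNAs, %d genes (%d validated)\n",
              nrow(x$edges), length(x$mirnas), length(x$genes),
              sum(x$edges$evidence == "validated")))
  invisible(x)
}

# Union of targets of a miRNA set, optionally restricted to validated edges.
targets_of <- function(network, mirnas, validated_only = FALSE) {
  stopifnot(inherits(network, "target_network"))
  e <- network$edges
  keep <- e$mirna %in% mirnas
  if (validated_only) keep <- keep & e$evidence == "validated"
  sort(unique(e$gene[keep]))
}

#' Generate a bipartite miRNA-to-gene target network
#'
#' Out-degrees are drawn from a truncated power law (`P(d) ~ d^-tail` on
#' `[min_targets, max_targets]`); each miRNA's targets are sampled without
#' replacement from the gene namespace; each edge is tagged `validated` with
#' probability `validated_fraction`, else `predicted`.
#'
#' @param cfg an [ontology_sim_config()].
#' @return a `target_network`.
#' @export
gen_target_network <- function(cfg) {
  stopifnot(inherits(cfg, "ontology_sim_config"))
  d <- cfg$degree_distribution
  genes <- gene_ids(cfg$n_genes)
  mirnas <- mirna_ids(cfg$n_mirnas)
  with_seed(stage_seed(cfg$seed, "target_network"), {
    support <- seq.int(d[1], d[2])
    degs <- if (length(support) == 1L) rep(support, cfg$n_mirnas) else
      sample(support, cfg$n_mirnas, replace = TRUE,
             prob = support^(-d[3]))
    edges <- do.call(rbind, lapply(seq_len(cfg$n_mirnas), function(i) {
      data.frame(mirna = mirnas[i],
                 gene = sample(genes, degs[i]),
                 stringsAsFactors = FALSE)
    }))
    edges$evidence <- ifelse(runif(nrow(edges)) < cfg$validated_fraction,
                             "validated", "predicted")
    target_network(edges)
  })
}

#' Generate a pathway ontology with one planted pathway
#'
#' The designated planted pathway receives `planted_pathway_overlap` of the
#' union of the spiked miRNAs' targets; its remaining members, and all other
#' pathways, are drawn uniformly from the gene namespace. The planted
#' pathway's size is drawn from the configured range, enlarged if necessary
#' to hold the overlap genes; an overlap demanding more genes than the
#' maximum pathway size is an error.
#'
#' @param cfg an [ontology_sim_config()].
#' @param spiked_mirnas character vector of spiked miRNA ids (must be network
#'   miRNAs).
#' @param network a `target_network` from [gen_target_network()].
#' @return object of class `pathway_ontology`: `sets` (named list of gene
#'   sets) and `planted` (the planted pathway's name).
#' @export
gen_pathway_ontology <- function(cfg, spiked_mirnas, network) {
  stopifnot(inherits(cfg, "ontology_sim_config"),
            inherits(network, "target_network"))
  missing <- setdiff(spiked_mirnas, network$mirnas)
  if (length(missing)) {
    stop(sprintf("spiked miRNAs absent from network: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  genes <- gene_ids(cfg$n_genes)
  u <- targets_of(network, spiked_mirnas)
  n_overlap <- round(cfg$planted_pathway_overlap * length(u))
  smin <- cfg$pathway_size_range[1]; smax <- cfg$pathway_size_range[2]
  if (n_overlap > smax) {
    stop(sprintf(
      "planted overlap needs %d genes but maximum pathway size is %d",
      n_overlap, smax), call. = FALSE)
  }
  names_pw <- sprintf("PW%02d", seq_len(cfg$n_pathways))
  with_seed(stage_seed(cfg$seed, "pathway_ontology"), {
    sizes <- sample(seq.int(smin, smax), cfg$n_pathways, replace = TRUE)
    sets <- lapply(sizes, function(s) sort(sample(genes, s)))
    names(sets) <- names_pw
    planted_size <- max(sizes[1], n_overlap)
    core <- if (n_overlap > 0) sample(u, n_overlap) else character()
    filler <- sample(setdiff(genes, core), planted_size - n_overlap)
    sets[[1]] <- sort(c(core, filler))
    structure(list(sets = sets, planted = names_pw[1]),
              class = "pathway_ontology")
  })
}

# Accept either a pathway_ontology or a plain named list of gene sets.
as_pathway_sets <- function(ontology) {
  sets <- if (inherits(ontology, "pathway_ontology")) ontology$sets else ontology
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (anyDuplicated(names(sets))) {
    stop("duplicate pathway names", call. = FALSE)
  }
  sets
}

#' Generate a signed directed gene-interaction graph
#'
#' Samples `round(edge_density * n * (n-1))` distinct ordered gene pairs (no
#' self-loops) and assigns each a sign from `sign_fractions`.
#'
#' @param n_genes number of genes (nodes are the first `n_genes` ids of the
#'   shared gene namespace).
#' @param edge_density fraction of all ordered pairs realized, in (0, 1].
#' @param sign_fractions named numeric vector of probabilities for
#'   `activating`, `inhibiting`, `unknown` (summing to 1).
#' @param seed integer seed.
#' @param genes optional explicit node names overriding `n_genes`.
#' @return data frame `source, sign, target` of class `interaction_graph`.
#' @export
gen_interaction_graph <- function(n_genes, edge_density,
                                  sign_fractions = c(activating = 0.5,
                                                     inhibiting = 0.3,
                                                     unknown = 0.2),
                                  seed = 1L, genes = NULL) {
  if (is.null(genes)) {
    n_genes <- check_count(n_genes, "n_genes", min = 2L)
    genes <- gene_ids(n_genes)
  } else {
    n_genes <- length(genes)
  }
  if (edge_density <= 0 || edge_density > 1) {
    stop("edge_density must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(abs(sum(sign_fractions) - 1) < 1e-8,
            all(names(sign_fractions) %in%
                  c("activating", "inhibiting", "unknown")))
  n_pairs <- n_genes * (n_genes - 1)
  m <- round(edge_density * n_pairs)
  with_seed(stage_seed(seed, "interaction_graph"), {
    out <- if (m == 0) {
      data.frame(source = character(), sign = character(),
                 target = character(), stringsAsFactors = FALSE)
    } else {
      idx <- sample.int(n_pairs, m)
      i <- (idx - 1L) %/% (n_genes - 1L) + 1L
      off <- (idx - 1L) %% (n_genes - 1L) + 1L
      j <- off + (off >= i)  # skip the diagonal
      data.frame(source = genes[i],
                 sign = sample(names(sign_fractions), m, replace = TRUE,
                               prob = sign_fractions),
                 target = genes[j],
                 stringsAsFactors = FALSE)
    }
    class(out) <- c("interaction_graph", "data.frame")
    out
  })
}

#' Generate a synthetic gene annotation catalog for target prioritization
#'
#' Emulates a neurological-disease annotation resource: genes in
#' `priority_genes` receive 2-4 terms drawn across the biomarker and
#' canonical-pathway categories (so they survive the multi-association
#' filter), a `background_fraction` of the remaining genes receive a single
#' term, and everything else is unannotated.
#'
#' @param genes character vector of gene ids to annotate from.
#' @param priority_genes genes planted as multi-association survivors.
#' @param n_terms_per_category number of distinct terms per category.
#' @param background_fraction fraction of non-priority genes given one term.
#' @param seed integer seed.
#' @return data frame `gene, term, category`.
#' @export
gen_annotation_catalog <- function(genes, priority_genes = character(),
                                   n_terms_per_category = 12L,
                                   background_fraction = 0.15,
                                   seed = 1L) {
  stopifnot(all(priority_genes %in% genes))
  background_fraction <- check_fraction(background_fraction,
                                        "background_fraction")
  cats <- c(disease_biomarker = "BM", canonical_pathway = "CP",
            go_process = "GO", toxic_pathology = "TX")
  terms <- lapply(cats, function(pfx) {
    sprintf("%s%02d", pfx, seq_len(n_terms_per_category))
  })
  with_seed(stage_seed(seed, "annotation_catalog"), {
    rows <- list()
    for (g in priority_genes) {
      k <- sample(2:4, 1)
      pool <- c(paste0("disease_biomarker:", terms$disease_biomarker),
                paste0("canonical_pathway:", terms$canonical_pathway))
      pick <- sample(pool, k)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g,
        term = sub("^[^:]+:", "", pick),
        category = sub(":.*$", "", pick),
        stringsAsFactors = FALSE)
    }
    bg <- setdiff(genes, priority_genes)
    bg <- bg[runif(length(bg)) < background_fraction]
    for (g in bg) {
      cat_i <- sample(names(cats), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, term = sample(terms[[cat_i]], 1), category = cat_i,
        stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) unique(do.call(rbind, rows)) else
      data.frame(gene = character(), term = character(),
                 category = character(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic miRNA assay annotation table
#'
#' Emulates a vendor annotation file mapping assay names to accession and
#' gene ids. A chosen few assays are flagged `non-human` or `discontinued`
#' so the exclusion logic of [map_annotations()] is exercised.
#'
#' @param mirnas panel assay names.
#' @param n_nonhuman,n_discontinued number of assays flagged as such (taken
#'   deterministically from the end of the panel).
#' @return data frame `assay_name, accession, gene_id, status`.
#' @export
gen_mirna_annotation <- function(mirnas, n_nonhuman = 2L,
                                 n_discontinued = 0L) {
  n <- length(mirnas)
  stopifnot(n_nonhuman + n_discontinued <= n)
  status <- rep("mapped", n)
  if (n_nonhuman > 0) status[seq(n, by = -1L, length.out = n_nonhuman)] <- "non-human"
  if (n_discontinued > 0) {
    status[seq(n - n_nonhuman, by = -1L, length.out = n_discontinued)] <-
      "discontinued"
  }
  data.frame(assay_name = mirnas,
             accession = sprintf("MIMAT%07d", seq_len(n)),
             gene_id = ifelse(status == "mapped",
                              sprintf("%d", 406880L + seq_len(n)), ""),
             status = status, stringsAsFactors = FALSE)
}
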