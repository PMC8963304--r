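# End-to-end orchestration: configuration, the default synthetic scenario,
# staged execution with named-substream seeding, strict input loading, and a
# reproducibility manifest.

#' Pipeline configuration
#'
#' Collects all stage parameters and thresholds (defaulting to the
#' workflow's standard values: detection limit Ct 35; fold-change 1.5 /
#' 0.67 with unadjusted p < .01; within-method BH < .01; reporting p < .001
#' with top 20; pathway-union p < .05; Dunnett p < .05), the run seed, and
#' the output directory. Validation happens here, before any compute.
#'
#' @param output_dir directory for stage tables and the manifest.
#' @param seed integer run seed; all stage randomness is forked from it by
#'   named substreams.
#' @param inputs optional named list of file paths (`ct`, `samples`,
#'   `apical`, `network`, `gmt`, `catalog`, `graph`, optionally
#'   `annotation`); when supplied they replace the synthetic scenario.
#' @param n_mirnas panel size for the synthetic scenario (default 754).
#' @param replicate_sd,detection_limit Ct generator noise and censoring
#'   limit.
#' @param fc_up,fc_down,p_threshold joint significance filter.
#' @param bh_alpha,report_alpha,top_n dual-enrichment parameters.
#' @param union_alpha pathway-union significance level.
#' @param dunnett_alpha apical significance level.
#' @param min_cluster_size,deep_split dynamic tree cut parameters.
#' @param max_cascade_len maximum cascade length in edges.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            seed = 1L,
                            inputs = NULL,
                            n_mirnas = 754L,
                            replicate_sd = 0.5,
                            detection_limit = 35,
                            fc_up = 1.5, fc_down = 0.67, p_threshold = 0.01,
                            bh_alpha = 0.01, report_alpha = 0.001,
                            top_n = 20L,
                            union_alpha = 0.05,
                            dunnett_alpha = 0.05,
                            min_cluster_size = 3L, deep_split = 1L,
                            max_cascade_len = 4L) {
  stopifnot(is.character(output_dir), length(output_dir) == 1L)
  for (nm in c("p_threshold", "bh_alpha", "report_alpha", "union_alpha",
               "dunnett_alpha")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0 || v > 1) {
      stop(sprintf("`%s` must lie in (0, 1]", nm), call. = FALSE)
    }
  }
  if (fc_up <= 1 || fc_down >= 1 || fc_down <= 0) {
    stop("fold-change thresholds must satisfy fc_down < 1 < fc_up",
         call. = FALSE)
  }
  if (detection_limit <= 0) stop("detection_limit must be positive",
                                 call. = FALSE)
  if (!is.null(inputs)) {
    stopifnot(is.list(inputs), !is.null(names(inputs)))
    missing_files <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(missing_files)) {
      stop(sprintf("input file(s) not found: %s",
                   paste(missing_files, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 inputs = inputs,
                 n_mirnas = check_count(n_mirnas, "n_mirnas"),
                 replicate_sd = replicate_sd,
                 detection_limit = detection_limit,
                 fc_up = fc_up, fc_down = fc_down,
                 p_threshold = p_threshold,
                 bh_alpha = bh_alpha, report_alpha = report_alpha,
                 top_n = check_count(top_n, "top_n"),
                 union_alpha = union_alpha, dunnett_alpha = dunnett_alpha,
                 min_cluster_size = check_count(min_cluster_size,
                                                "min_cluster_size"),
                 deep_split = deep_split,
                 max_cascade_len = check_count(max_cascade_len,
                                               "max_cascade_len")),
            class = "pipeline_config")
}

# Hill parameter table of the default synthetic scenario: a negative
# control, a microtubule-agent-like chemical (neurite collapse with intact
# viability up to the top concentration), and a cytotoxicant with separated
# neurite and viability potencies.
default_apical_chemicals <- function() {
  ep <- c("ATP", "neurite_length", "neurite_count", "neurons_per_field")
  rbind(
    data.frame(chemical = "ACET", endpoint = ep, top = 100, bottom = 100,
               ec50 = 1, slope = 1, stringsAsFactors = FALSE),
    data.frame(chemical = "COL",
               endpoint = ep,
               top = 100,
               bottom = c(92, 30, 35, 85),
               ec50 = c(10, 0.03, 0.03, 50),
               slope = c(1, 1.5, 1.5, 1), stringsAsFactors = FALSE),
    data.frame(chemical = "DOX",
               endpoint = ep,
               top = 100,
               bottom = c(25, 35, 40, 50),
               ec50 = c(8, 0.4, 0.4, 30),
               slope = c(1.5, 1.5, 1.5, 1.5), stringsAsFactors = FALSE))
}

# Spike design of the default scenario: 12 planted miRNAs in four
# fold-change groups (strong down, mild down, mild up, strong up), spiked in
# every exposure so cluster recovery has a 4-group truth.
default_spikes <- function(exposures, n_mirnas) {
  effects <- rep(c(-3, -1.7, 1.7, 3), each = 3)
  idx <- seq_len(12L)
  stopifnot(n_mirnas >= 12L)
  do.call(rbind, lapply(exposures, function(e) {
    data.frame(mirna_index = idx, treatment = e, log2_effect = effects,
               stringsAsFactors = FALSE)
  }))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Read and type-check all standard pipeline inputs
#'
#' @param paths named list of file paths: `ct` + `samples` (Ct CSV and
#'   sample sheet), `apical` (well-level CSV), `network` (TSV), `gmt`
#'   (gene sets), `catalog` (annotation TSV), `graph` (SIF-like TSV),
#'   optionally `annotation` (miRNA assay annotation TSV).
#' @param detection_limit censoring limit for the Ct matrix.
#' @return named list of typed inputs.
#' @export
read_standard_inputs <- function(paths, detection_limit = 35) {
  need <- c("ct", "samples", "apical", "network", "gmt", "catalog", "graph")
  missing <- setdiff(need, names(paths))
  if (length(missing)) {
    stop(sprintf("missing input path(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  list(ct = read_ct_matrix(paths$ct, paths$samples, detection_limit),
       apical = read_apical_csv(paths$apical),
       network = read_target_network(paths$network),
       gmt = read_gmt(paths$gmt),
       catalog = read_annotation_catalog(paths$catalog),
       graph = read_interaction_graph(paths$graph),
       annotation = if (!is.null(paths$annotation)) {
         utils::read.delim(paths$annotation, stringsAsFactors = FALSE)
       })
}

#' Run the full biomarker discovery pipeline
#'
#' Executes apical analysis and concentration selection, Ct differential
#' expression, fold-change clustering, dual and pathway-union enrichment,
#' target prioritization, and cascade reconstruction, writing every stage
#' table (TSV), the dendrogram (Newick), and a JSON manifest to
#' `config$output_dir`. With the default synthetic scenario all inputs are
#' generated from the run seed; identical seed and inputs give
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  seed <- config$seed
  manifest <- list(package = "secretomir",
                   version = as.character(utils::packageVersion("secretomir")),
                   seed = seed,
                   parameters = config[setdiff(names(config),
                                               c("inputs", "output_dir"))],
                   stages = list())
  synthetic <- is.null(config$inputs)
  inputs <- if (!synthetic) {
    run_stage("read_inputs",
              read_standard_inputs(config$inputs, config$detection_limit))
  }

  ## apical endpoints and concentration selection -------------------------
  apical_raw <- run_stage("apical", {
    if (synthetic) {
      gen_apical(apical_sim_config(default_apical_chemicals(),
                                   seed = stage_seed(seed, "apical")))
    } else inputs$apical
  })
  normalized <- run_stage("apical_normalize",
                          normalize_percent_of_control(apical_raw))
  dunnett <- run_stage("apical_dunnett", apical_dunnett(normalized))
  pairs <- run_stage("select_concentrations",
                     select_concentrations(normalized, dunnett,
                                           alpha = config$dunnett_alpha))
  correlations <- run_stage("correlate_endpoints",
                            correlate_endpoints(normalized))
  write_tsv_file(dunnett, out("dunnett.tsv"))
  write_tsv_file(pairs, out("concentration_pairs.tsv"))
  write_tsv_file(correlations, out("endpoint_correlations.tsv"))
  manifest$stages$apical <- list(n_wells = nrow(apical_raw),
                                 n_chemicals =
                                   length(unique(apical_raw$chemical)))
  manifest$stages$concentration_pairs <- pairs

  ## Ct differential expression -------------------------------------------
  tested <- pairs[!is.na(pairs$low), , drop = FALSE]
  exposures <- as.vector(t(outer(tested$chemical, c("low", "high"),
                                 paste, sep = "_")))
  ctm <- run_stage("ct_matrix", {
    if (synthetic) {
      trts <- data.frame(name = exposures, n_paired_replicates = 3L,
                         stringsAsFactors = FALSE)
      gen_ct_matrix(ct_sim_config(
        n_mirnas = config$n_mirnas, treatments = trts,
        replicate_sd = config$replicate_sd,
        detection_limit = config$detection_limit,
        spikes = default_spikes(exposures, config$n_mirnas),
        seed = stage_seed(seed, "ct")))
    } else inputs$ct
  })
  norm <- run_stage("normalize", mean_center_normalize(cap_detection_limit(ctm)))
  records <- run_stage("diffexp",
                       differential_expression(norm,
                                               fc_up = config$fc_up,
                                               fc_down = config$fc_down,
                                               p_threshold =
                                                 config$p_threshold))
  annotation <- run_stage("annotation", {
    if (synthetic || is.null(inputs$annotation)) {
      gen_mirna_annotation(rownames(ctm$ct))
    } else inputs$annotation
  })
  sig <- records[records$significant, , drop = FALSE]
  ann <- run_stage("map_annotations",
                   map_annotations(unique(sig$mirna), annotation))
  sig_mapped <- sig[sig$mirna %in% ann$retained, , drop = FALSE]
  volcano <- data.frame(mirna = records$mirna, exposure = records$exposure,
                        log2_fc = records$log2_fc,
                        neg_log10_p = -log10(records$p),
                        stringsAsFactors = FALSE)
  write_tsv_file(records, out("differential.tsv"))
  write_tsv_file(volcano, out("volcano.tsv"))
  write_tsv_file(sig_mapped, out("significant.tsv"))
  write_tsv_file(ann$map, out("annotation_map.tsv"))
  manifest$stages$diffexp <- list(
    n_tests = nrow(records),
    n_significant = length(unique(sig$mirna)),
    n_significant_mapped = length(unique(sig_mapped$mirna)))

  ## clustering -----------------------------------------------------------
  clusters <- NULL
  if (length(unique(sig_mapped$mirna)) >= 2) {
    profile <- run_stage("profile", fold_change_profile(sig_mapped))
    hc <- run_stage("dendrogram", average_linkage_dendrogram(profile))
    clusters <- run_stage("tree_cut",
                          dynamic_tree_cut(hc,
                                           min_cluster_size =
                                             config$min_cluster_size,
                                           deep_split = config$deep_split))
    write_tsv_file(data.frame(mirna = names(clusters),
                              cluster = as.integer(clusters),
                              stringsAsFactors = FALSE),
                   out("clusters.tsv"))
    writeLines(dendrogram_newick(hc), out("dendrogram.nwk"))
    manifest$stages$clustering <- list(
      n_clusters = length(setdiff(unique(clusters), 0L)),
      n_unassigned = sum(clusters == 0L))
  }

  ## enrichment -----------------------------------------------------------
  network <- run_stage("network", {
    if (synthetic) {
      gen_target_network(ontology_sim_config(
        n_mirnas = config$n_mirnas, seed = stage_seed(seed, "network")))
    } else inputs$network
  })
  ontology <- run_stage("ontology", {
    if (synthetic) {
      spiked <- ctm$truth$spiked_mirnas
      gen_pathway_ontology(ontology_sim_config(
        n_mirnas = config$n_mirnas, seed = stage_seed(seed, "network")),
        spiked, network)
    } else inputs$gmt
  })
  sig_in_net <- intersect(unique(sig_mapped$mirna), network$mirnas)
  dual <- NULL
  if (length(sig_in_net)) {
    dual <- run_stage("dual_enrichment", {
      m1 <- enrich_targets_method1(sig_in_net, network, ontology)
      m2 <- enrich_mirna_sets_method2(sig_in_net, network, ontology)
      combine_dual(m1, m2, bh_alpha = config$bh_alpha,
                   report_alpha = config$report_alpha,
                   top_n = config$top_n)
    })
    write_tsv_file(dual, out("enrichment_dual.tsv"))
    manifest$stages$enrichment <- list(
      n_significant_both = sum(dual$significant_both),
      top_pathway = if (any(dual$significant_both)) {
        dual$pathway[which(dual$rank == 1L)]
      } else NA_character_,
      planted_pathway = if (synthetic &&
                            inherits(ontology, "pathway_ontology")) {
        ontology$planted
      } else NA_character_)
  }
  union_sets <- list()
  if (!is.null(clusters)) {
    for (k in setdiff(sort(unique(clusters)), 0L)) {
      mir_k <- intersect(names(clusters)[clusters == k], network$mirnas)
      if (!length(mir_k)) next
      pu <- run_stage("pathway_union",
                      pathway_union_enrichment(mir_k, network, ontology,
                                               alpha = config$union_alpha))
      union_sets[[as.character(k)]] <- attr(pu, "significant_set")
      write_tsv_file(pu, out(sprintf("pathway_union_cluster%d.tsv", k)))
    }
    if (length(union_sets)) {
      common <- common_pathways(union_sets)
      write_tsv_file(data.frame(pathway = common, stringsAsFactors = FALSE),
                     out("common_pathways.tsv"))
      manifest$stages$pathway_union <- list(
        n_clusters_tested = length(union_sets),
        n_common_pathways = length(common))
    }
  }

  ## prioritization and cascades ------------------------------------------
  catalog <- run_stage("catalog", {
    if (synthetic) {
      gen_annotation_catalog(
        network$genes,
        priority_genes = targets_of(network, ctm$truth$spiked_mirnas,
                                    validated_only = TRUE),
        seed = stage_seed(seed, "catalog"))
    } else inputs$catalog
  })
  prioritized <- run_stage("prioritize",
                           prioritize_targets(sig_mapped[
                             sig_mapped$mirna %in% network$mirnas, ],
                             network, catalog))
  write_tsv_file(prioritized, out("prioritized_targets.tsv"))
  manifest$stages$prioritization <- as.list(attr(prioritized, "funnel"))

  top_pathway_genes <- if (!is.null(dual) && any(dual$significant_both)) {
    as_pathway_sets(ontology)[[dual$pathway[which(dual$rank == 1L)]]]
  } else if (inherits(ontology, "pathway_ontology")) {
    ontology$sets[[ontology$planted]]
  } else character()
  graph <- run_stage("interaction_graph", {
    if (synthetic) {
      nodes <- sort(unique(c(top_pathway_genes, prioritized$gene)))
      gen_interaction_graph(length(nodes), edge_density = 0.02,
                            seed = stage_seed(seed, "graph"), genes = nodes)
    } else inputs$graph
  })
  cascades <- list()
  seeds_a <- intersect(prioritized$gene, unique(c(graph$source, graph$target)))
  seeds_b <- intersect(top_pathway_genes,
                       unique(c(graph$source, graph$target)))
  if (length(seeds_a) && length(seeds_b) && nrow(graph)) {
    cascades <- run_stage("trace_cascades",
                          trace_cascades(graph, seeds_a, seeds_b,
                                         max_len = config$max_cascade_len))
  }
  net <- run_stage("merge_cascades",
                   merge_cascades(cascades, graph, catalog = catalog,
                                  network = network,
                                  sig_mirnas = unique(sig_mapped$mirna)))
  write_tsv_file(net$edges, out("cascade_network_edges.tsv"))
  write_tsv_file(net$nodes, out("cascade_network_nodes.tsv"))
  manifest$stages$cascades <- list(n_paths = length(cascades),
                                   n_nodes = nrow(net$nodes),
                                   n_edges = nrow(net$edges))

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
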