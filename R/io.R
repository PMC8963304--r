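# Strict readers and writers for the pipeline's plain-text interchange
# formats: Ct CSV + sample sheet TSV, target-network TSV, GMT gene sets,
# annotation TSVs, and SIF-like interaction TSVs. Parsers fail loudly with
# line numbers rather than guessing.

#' Write a Ct matrix and its sample sheet
#'
#' The matrix is written as CSV (first column `mirna`, one column per sample
#' id) and the sample sheet as TSV (`sample, plate, treatment, replicate,
#' role`).
#'
#' @param ctm a `ct_matrix`.
#' @param ct_path,samples_path output file paths.
#' @export
write_ct_matrix <- function(ctm, ct_path, samples_path) {
  stopifnot(inherits(ctm, "ct_matrix"))
  df <- data.frame(mirna = rownames(ctm$ct), ctm$ct, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, ct_path, row.names = FALSE, quote = FALSE)
  write_tsv_file(ctm$samples, samples_path)
  invisible(ct_path)
}

#' Read a Ct matrix and its sample sheet
#'
#' @param ct_path CSV with first column `mirna` and one column per sample.
#' @param samples_path TSV sample sheet (`sample, plate, treatment,
#'   replicate, role`); roles must be `treated` or `control`.
#' @param detection_limit censoring limit in cycles (default 35).
#' @return a `ct_matrix`.
#' @export
read_ct_matrix <- function(ct_path, samples_path, detection_limit = 35) {
  df <- utils::read.csv(ct_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (names(df)[1] != "mirna") {
    stop(sprintf("%s: first column must be 'mirna'", ct_path), call. = FALSE)
  }
  if (anyDuplicated(df$mirna)) {
    stop(sprintf("%s: duplicate miRNA names", ct_path), call. = FALSE)
  }
  ct <- as.matrix(df[, -1, drop = FALSE])
  rownames(ct) <- df$mirna
  if (!is.numeric(ct) || any(!is.finite(ct)) || any(ct <= 0)) {
    stop(sprintf("%s: Ct values must be finite and positive", ct_path),
         call. = FALSE)
  }
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  need <- c("sample", "plate", "treatment", "replicate", "role")
  if (!all(need %in% names(samples))) {
    stop(sprintf("%s: sample sheet needs columns %s", samples_path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (!setequal(samples$sample, colnames(ct))) {
    stop("sample sheet and Ct matrix disagree on sample ids", call. = FALSE)
  }
  bad_role <- setdiff(unique(samples$role), c("treated", "control"))
  if (length(bad_role)) {
    stop(sprintf("unknown sample role(s): %s",
                 paste(bad_role, collapse = ", ")), call. = FALSE)
  }
  samples <- samples[match(colnames(ct), samples$sample), ]
  rownames(samples) <- NULL
  new_ct_matrix(ct, samples, detection_limit)
}

#' Write a target network as a 3-column TSV
#' @param network a `target_network`.
#' @param path output path.
#' @export
write_target_network <- function(network, path) {
  stopifnot(inherits(network, "target_network"))
  write_tsv_file(network$edges[c("mirna", "gene", "evidence")], path)
}

#' Read a target network from a 3-column TSV (`mirna, gene, evidence`)
#' @param path input path.
#' @return a `target_network`.
#' @export
read_target_network <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  target_network(df)
}

#' Read gene sets from a GMT file
#'
#' Standard two-leading-column convention: set name, description, then the
#' member genes, tab-separated. Lines with fewer than three columns and
#' duplicated set names are errors with line numbers.
#'
#' @param path GMT file path.
#' @return named list of gene-id vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list(); desc <- character()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) {
      stop(sprintf("%s line %d: GMT line needs >= 3 tab-separated columns",
                   path, i), call. = FALSE)
    }
    if (f[1] %in% names(sets)) {
      stop(sprintf("%s line %d: duplicate pathway name '%s'", path, i, f[1]),
           call. = FALSE)
    }
    sets[[f[1]]] <- f[-(1:2)]
    desc[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of gene-id vectors (or a `pathway_ontology`).
#' @param path output path.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  sets <- as_pathway_sets(sets)
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a signed interaction graph from a SIF-like TSV
#'
#' Columns `source, sign, target`, sign one of activating / inhibiting /
#' unknown.
#'
#' @param path input path.
#' @return an `interaction_graph` data frame.
#' @export
read_interaction_graph <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "sign", "target")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: needs columns %s", path, paste(need, collapse = ", ")),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$sign), c("activating", "inhibiting", "unknown"))
  if (length(bad)) {
    stop(sprintf("%s: unknown sign(s): %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(df$source == df$target)) {
    stop(sprintf("%s: self-loops are not allowed", path), call. = FALSE)
  }
  class(df) <- c("interaction_graph", "data.frame")
  df
}

#' Write a signed interaction graph as a SIF-like TSV
#' @param graph an `interaction_graph` data frame.
#' @param path output path.
#' @export
write_interaction_graph <- function(graph, path) {
  write_tsv_file(as.data.frame(graph)[c("source", "sign", "target")], path)
}

#' Read an annotation catalog TSV (`gene, term, category`)
#' @param path input path.
#' @export
read_annotation_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "term", "category")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: needs columns %s", path, paste(need, collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Read a well-level apical endpoint CSV
#'
#' Column contract: `chemical, concentration_uM, plate, well, endpoint,
#' value`.
#'
#' @param path input path.
#' @export
read_apical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chemical", "concentration_uM", "plate", "well", "endpoint",
            "value")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: needs columns %s", path, paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.finite(df$value))) {
    stop(sprintf("%s: non-finite endpoint values", path), call. = FALSE)
  }
  df
}
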