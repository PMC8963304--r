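# Internal helpers: seeded RNG scoping and deterministic substream derivation.

# Evaluate `code` under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a deterministic stage seed from a run seed and a stage name
#'
#' A single run seed is forked into named substreams so that adding one stage
#' never perturbs another stage's random draws. The derived seed is a 31-bit
#' non-negative integer (a polynomial hash of the stage name folded into the
#' run seed modulo 2^31 - 1).
#'
#' @param seed integer run seed.
#' @param stage character stage name.
#' @return integer seed in [0, 2^31 - 2].
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stage),
            length(stage) == 1L, nzchar(stage))
  m <- 2147483647  # 2^31 - 1 (Mersenne prime)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer((abs(as.numeric(seed)) + h) %% m)
}

# Integer-count validation with a named error.
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

# Canonical id builders shared by the generators so that Ct panels, target
# networks, and interaction graphs live in one namespace.
mirna_ids <- function(n) sprintf("miR-%04d", seq_len(n))
gene_ids <- function(n) sprintf("G%05d", seq_len(n))

# write.table with the package's TSV conventions
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
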