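# Shared settings for the analysis scripts. Every script can be re-run on
# its own: stage inputs are the plain-text outputs of the previous script
# under results/analysis/.

library(nutriconnect)

MASTER_SEED <- 2026L
OUT <- "results/analysis"

study_config <- function() {
  sim_config(seed = MASTER_SEED) # the study conditions (package defaults)
}

analysis_params <- list(
  alpha = 0.05,
  rp_n_perm = 100L,
  es_n_perm = 1000L,
  cap = 250L,
  min_tags = 5L,
  prox_n_random = 1000L,
  prox_bin_min = 100L,
  tanimoto_cutoff = 0.4,
  syn_n_perm = 1000L,
  cluster_k = 2L
)

save_tsv <- function(df, name) {
  dir.create(OUT, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(OUT, name)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  message("  wrote ", path)
  invisible(path)
}

load_signatures <- function() {
  dir <- file.path(OUT, "signatures")
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  sigs <- lapply(files, read_signature_tsv)
  names(sigs) <- vapply(sigs, function(s) s$entity, character(1))
  sigs
}
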