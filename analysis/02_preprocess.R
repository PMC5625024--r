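#!/usr/bin/env Rscript
# Stage 2 — preprocessing: probe-level matrices are filtered (multi-mapped
# probes and probes with > 20% missing values removed), collapsed to gene
# level by per-sample averaging, and model-organism replicates are mapped to
# human orthologs. Writes gene-level matrices under
# results/analysis/preprocessed/.

source("analysis/common.R")

sim_dir <- file.path(OUT, "sim")
probe_map <- utils::read.delim(file.path(sim_dir, "probe_map.tsv"))
orthologs <- utils::read.delim(file.path(sim_dir, "orthologs.tsv"))

files <- list.files(file.path(sim_dir, "expression"),
  pattern = "^[a-z]+[0-9]+_ds[0-9]+\\.tsv$", full.names = TRUE
)
out_dir <- file.path(OUT, "preprocessed")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

n_probe <- n_mouse <- 0
for (f in files) {
  labels <- utils::read.delim(paste0(f, ".labels.tsv"))
  level <- if (labels$species[1] == "human") "probe" else "gene"
  x <- read_expression_tsv(f, level = level)
  if (inherits(x, "probe_matrix")) n_probe <- n_probe + 1 else
    n_mouse <- n_mouse + 1
  clean <- preprocess_dataset(x,
    probe_map = probe_map,
    ortholog_table = orthologs
  )
  write_expression_tsv(clean, file.path(out_dir, basename(f)))
}
message(
  "Preprocessed ", length(files), " datasets (",
  n_probe, " probe-level human, ", n_mouse, " mouse gene-level)."
)
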