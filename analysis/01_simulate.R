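#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic study: interactome, disease modules,
# planted signatures (reversal, risk and synergy relations), replicate
# case/control expression datasets (probe-level + one mouse replicate per
# entity), and all annotation tables. Everything lands as plain text under
# results/analysis/sim/.

source("analysis/common.R")

cfg <- study_config()
print(cfg)
study <- simulate_study(cfg)
write_simulation(study, file.path(OUT, "sim"))

truth <- study$truth
message("Planted truth:")
print(table(truth$pair_labels$label, truth$pair_labels$entity_class))
message(
  nrow(truth$synergy_pairs), " planted synergy pair(s): ",
  paste(truth$synergy_pairs$food_a, truth$synergy_pairs$food_b,
    sep = "+", collapse = ", "
  )
)
save_tsv(truth$pair_labels, "truth_pair_labels.tsv")
message("Done: simulated ", length(study$raw_datasets), " entities x ",
  cfg$datasets_per_entity, " datasets over ", cfg$n_genes, " genes.")
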