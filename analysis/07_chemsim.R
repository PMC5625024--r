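#!/usr/bin/env Rscript
# Stage 7 — chemical similarity: Morgan (ECFP4) fingerprints of every food
# and drug compound, all pairwise Tanimoto coefficients, food-drug pairs
# sharing a compound pair at Tanimoto >= 0.4, and the comparison of shared
# anti-correlated disease counts between similar and dissimilar pairs.

source("analysis/common.R")

foods <- utils::read.delim(file.path(OUT, "sim", "food_compounds.tsv"))
drugs <- utils::read.delim(file.path(OUT, "sim", "drug_compounds.tsv"))

sim <- similar_food_drug_pairs(foods, drugs,
  cutoff = analysis_params$tanimoto_cutoff
)
save_tsv(sim$edges, "chem_edges.tsv")
save_tsv(sim$pairs, "chem_pairs.tsv")
message(
  nrow(sim$pairs), " food-drug pairs share a compound pair at Tanimoto >= ",
  analysis_params$tanimoto_cutoff, " (", nrow(sim$edges), " edges, ",
  sim$n_rejected, " records rejected)."
)

food_res <- utils::read.delim(file.path(OUT, "pairs_food.tsv"))
drug_res <- utils::read.delim(file.path(OUT, "pairs_drug.tsv"))
cmp <- compare_shared_diseases(sim$pairs, food_res, drug_res)
save_tsv(cmp$counts, "chem_shared_diseases.tsv")
message(sprintf(
  "Similar pairs share a median of %g anti-correlated diseases vs %g for
 others (Wilcoxon P = %.4f)",
  stats::median(cmp$counts$shared[cmp$counts$similar]),
  stats::median(cmp$counts$shared[!cmp$counts$similar]),
  cmp$wilcox_p
))
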