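#!/usr/bin/env Rscript
# Stage 5 — pathway space: hypergeometric over-representation of each
# entity's DE genes, the (disease class x entity class) proportion score
# matrix over anti-correlated pairs, its PCA, and the top disease-related
# pathways shared between diseases and their anti-correlated entities.

source("analysis/common.R")

sigs <- load_signatures()
pathways <- read_gmt(file.path(OUT, "sim", "pathways.gmt"))
attr(pathways, "universe") <- sort(unique(unlist(pathways)))
truth <- read_truth_json(file.path(OUT, "sim", "truth.json"))

enr <- lapply(sigs, function(s) {
  tab <- enrich_pathways(c(s$up_set, s$down_set), pathways,
    alpha = analysis_params$alpha
  )
  tab$pathway[tab$enriched]
})
save_tsv(
  data.frame(
    entity = names(enr),
    n_enriched = lengths(enr)
  ),
  "enriched_pathway_counts.tsv"
)

food_res <- utils::read.delim(file.path(OUT, "pairs_food.tsv"))
drug_res <- utils::read.delim(file.path(OUT, "pairs_drug.tsv"))
anti <- rbind(
  data.frame(
    entity = food_res$query, disease = food_res$reference,
    entity_class = "diet", class = food_res$class
  ),
  data.frame(
    entity = drug_res$query, disease = drug_res$reference,
    entity_class = "drug", class = drug_res$class
  )
)
anti <- anti[anti$class == "anti-correlated", ]
anti$disease_class <- truth$disease_classes[anti$disease]

sm <- build_score_matrix(enr, anti)
save_tsv(data.frame(group = rownames(sm), sm, check.names = FALSE),
  "pathway_score_matrix.tsv")
pca <- pca_scores(sm)
message(sprintf(
  "PC1 + PC2 explain %.1f%% of the score-matrix variance",
  100 * sum(pca$variance_fraction[1:2])
))
save_tsv(pca$top_contributions, "pca_top_contributions.tsv")
save_tsv(
  data.frame(group = rownames(pca$coordinates),
    pca$coordinates[, 1:2, drop = FALSE]),
  "pca_coordinates.tsv"
)

top <- top_disease_pathways(enr, anti[, c("entity", "disease")])
save_tsv(top, "top_disease_pathways.tsv")
message("Top disease-related pathways written for ",
  length(unique(top$disease)), " diseases.")
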