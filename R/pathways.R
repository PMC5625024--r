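# Pathway over-representation of DE gene sets (one-sided hypergeometric with
# BH correction), the disease-class proportion score matrix built from
# anti-correlated pairs only, and its PCA separating diet from drug
# mechanism space.

#' Hypergeometric pathway over-representation
#'
#' Per pathway, the upper-tail probability `P(X >= k)` with
#' `X ~ Hypergeom(N = |universe|, K = |pathway|, n = |de_genes|)` and `k` the
#' observed overlap, BH-corrected across the collection. DE genes outside the
#' universe are dropped with a warning; pathway members outside the universe
#' are ignored.
#'
#' @param de_genes character vector of DE genes.
#' @param collection named list of pathway gene sets.
#' @param universe gene universe (defaults to attribute `"universe"` of the
#'   collection).
#' @param alpha FDR threshold for the `enriched` flag (default 0.05).
#' @return data.frame with columns `pathway`, `k`, `K`, `n`, `N`, `p`, `fdr`,
#'   `enriched`, ordered by `p`.
#' @export
enrich_pathways <- function(de_genes, collection,
                            universe = attr(collection, "universe"),
                            alpha = 0.05) {
  if (is.null(universe)) stop("a gene universe is required", call. = FALSE)
  outside <- setdiff(de_genes, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " DE gene(s) outside the universe dropped",
      call. = FALSE
    )
    de_genes <- intersect(de_genes, universe)
  }
  n_univ <- length(universe)
  n_de <- length(de_genes)
  rows <- lapply(names(collection), function(nm) {
    pw <- intersect(collection[[nm]], universe)
    k <- length(intersect(pw, de_genes))
    p <- if (n_de == 0L) 1 else
      phyper(k - 1, length(pw), n_univ - length(pw), n_de, lower.tail = FALSE)
    data.frame(
      pathway = nm, k = k, K = length(pw), n = n_de, N = n_univ, p = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$enriched <- out$fdr < alpha
  out[order(out$p, out$pathway), ]
}

#' Proportion score matrix over (disease class, entity class) groups
#'
#' Only anti-correlated pairs enter. For each disease class and entity class
#' (diet/drug), and each pathway, the score is the proportion of the group's
#' entities whose enrichment set contains the pathway — the binary
#' enriched/not matrix aggregated to proportions so differently sized groups
#' stay comparable.
#'
#' @param enrichments named list: entity -> character vector of enriched
#'   pathways.
#' @param anti_pairs data.frame with columns `entity`, `entity_class`
#'   (`"diet"`/`"drug"`), `disease_class`; one row per anti-correlated pair.
#' @param pathways character vector of pathway names to use as columns
#'   (default: union of all enrichment sets).
#' @return numeric matrix; rows named `<disease class>|<entity class>`,
#'   entries in `[0, 1]`. Groups with zero entities are omitted.
#' @export
build_score_matrix <- function(enrichments, anti_pairs, pathways = NULL) {
  if (is.null(pathways)) {
    pathways <- sort(unique(unlist(enrichments)))
  }
  groups <- split(
    anti_pairs,
    paste(anti_pairs$disease_class, anti_pairs$entity_class, sep = "|")
  )
  rows <- lapply(groups, function(df) {
    ents <- unique(df$entity)
    ents <- ents[ents %in% names(enrichments)]
    if (length(ents) == 0L) {
      return(NULL)
    }
    hits <- vapply(
      pathways,
      function(pw) mean(vapply(ents, function(e) pw %in% enrichments[[e]],
        logical(1)
      )),
      numeric(1)
    )
    hits
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!all(keep)) {
    message(sum(!keep), " group(s) without entities omitted from score matrix")
  }
  do.call(rbind, rows[keep])
}

#' PCA of the pathway-space score matrix
#'
#' Columns are mean-centered (no unit-variance scaling: entries are already
#' commensurable proportions) and decomposed by SVD. A variable's
#' contribution is its squared loading summed over PC1-PC2; the top 30 are
#' reported.
#'
#' @param score_matrix matrix from [build_score_matrix()] (>= 3 rows, >= 2
#'   columns).
#' @param n_top number of top-contributing variables to report (default 30).
#' @return list with `coordinates` (rows on PCs), `variance_fraction`,
#'   `loadings`, `top_contributions` (data.frame: pathway, contribution).
#' @export
pca_scores <- function(score_matrix, n_top = 30L) {
  if (nrow(score_matrix) < 3L || ncol(score_matrix) < 2L) {
    stop("need >= 3 rows and >= 2 columns for PCA", call. = FALSE)
  }
  pc <- prcomp(score_matrix, center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  n_pc <- min(2L, ncol(pc$rotation))
  contrib <- rowSums(pc$rotation[, seq_len(n_pc), drop = FALSE]^2)
  top <- sort(contrib, decreasing = TRUE)
  top <- head(top, n_top)
  list(
    coordinates = pc$x,
    variance_fraction = var_frac,
    loadings = pc$rotation,
    top_contributions = data.frame(
      pathway = names(top), contribution = as.numeric(top),
      stringsAsFactors = FALSE
    )
  )
}

#' Disease-related pathways of an entity
#'
#' The pathways enriched in both the entity's and the disease's signatures
#' (set intersection).
#'
#' @param entity_enrichment,disease_enrichment character vectors of enriched
#'   pathway names (from the same collection).
#' @return character vector.
#' @export
disease_related_pathways <- function(entity_enrichment, disease_enrichment) {
  intersect(entity_enrichment, disease_enrichment)
}

#' Top shared pathways per disease, ranked by anti-correlated support
#'
#' For each disease, ranks the pathways shared between the disease's
#' enrichment set and those of its anti-correlated entities by the number of
#' entities sharing them; reports the top `n_top`.
#'
#' @param enrichments named list: entity -> enriched pathway names (must also
#'   cover the diseases).
#' @param anti_pairs data.frame with columns `entity`, `disease`.
#' @param n_top pathways reported per disease (default 3).
#' @return data.frame with columns `disease`, `pathway`, `n_entities`.
#' @export
top_disease_pathways <- function(enrichments, anti_pairs, n_top = 3L) {
  rows <- lapply(split(anti_pairs, anti_pairs$disease), function(df) {
    d <- df$disease[1]
    d_enr <- enrichments[[d]]
    if (is.null(d_enr)) {
      return(NULL)
    }
    counts <- table(unlist(lapply(df$entity, function(e) {
      disease_related_pathways(enrichments[[e]], d_enr)
    })))
    if (length(counts) == 0L) {
      return(NULL)
    }
    counts <- sort(counts, decreasing = TRUE)
    counts <- head(counts, n_top)
    data.frame(
      disease = d, pathway = names(counts),
      n_entities = as.integer(counts), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
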