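# Bidirectional Kolmogorov-Smirnov enrichment scoring of signature pairs
# (connectivity-mapping style): a query's up-regulated tags concentrating at
# the top of a reference ranked list and its down tags at the bottom give a
# positive (correlated) score; the reverse arrangement gives a negative
# (anti-correlated, signature-reversing) score.

# KS running-sum statistic from tag positions alone.
# pos: ascending 1-based positions of the tags in a list of length n.
ks_positions <- function(pos, n) {
  t <- length(pos)
  if (t == 0L) {
    return(NA_real_)
  }
  if (t == n) {
    return(0)
  } # tags = whole list: no positional information
  j <- seq_len(t)
  a <- max(j / t - pos / n)
  b <- max(pos / n - (j - 1) / t)
  if (a >= b) a else -b
}

#' KS tag-set score against a ranked gene list
#'
#' With `pos(1..t)` the ascending positions of the tags in the list of length
#' `n`: `a = max_j (j/t - pos(j)/n)`, `b = max_j (pos(j)/n - (j-1)/t)`, and
#' the score is `a` if `a >= b`, else `-b`. Scores lie in `[-1, 1]`; tags
#' concentrated at the top of the list score near `+1`, at the bottom near
#' `-1`. Tags absent from the list are dropped with a warning; a tag set
#' covering the entire list scores 0 (degenerate: no positional information).
#'
#' @param tags character vector of gene ids.
#' @param ranked_list character vector, rank 1 first.
#' @return score in `[-1, 1]`, or `NA` if no tag maps.
#' @export
ks_tag_score <- function(tags, ranked_list) {
  pos <- match(tags, ranked_list)
  if (anyNA(pos)) {
    warning(sum(is.na(pos)), " tag(s) absent from the ranked list; dropped",
      call. = FALSE
    )
    pos <- pos[!is.na(pos)]
  }
  if (length(pos) == 0L) {
    return(NA_real_)
  }
  ks_positions(sort(pos), length(ranked_list))
}

#' Build a capped query signature from a DE signature
#'
#' Tag sets are the significant DE genes per direction, ordered by absolute
#' combined log fold change and capped; queries with fewer than `min_tags`
#' tags in either direction are not scorable.
#'
#' @param sig a [signature_ranking()].
#' @param cap maximum tags per direction (default 250).
#' @param min_tags minimum tags per direction for scoring (default 5).
#' @return list with `up`, `down`, `source`, `scorable`.
#' @export
query_signature <- function(sig, cap = 250L, min_tags = 5L) {
  up <- head(sig$up_set, cap)
  down <- head(sig$down_set, cap)
  list(
    up = up, down = down, source = sig$entity,
    scorable = length(up) >= min_tags && length(down) >= min_tags
  )
}

#' Directional enrichment score of a query signature in a reference ranking
#'
#' `ks_up` and `ks_down` are the tag scores of the query's up and down sets in
#' the reference ranked list; if they share the same sign the signature is not
#' discordantly placed and the score is 0, otherwise
#' `es = (ks_up - ks_down) / 2`.
#'
#' @param query a [query_signature()].
#' @param reference_ranking a [signature_ranking()].
#' @return enrichment score in `[-1, 1]`, or `NA` if unscorable.
#' @export
directional_es <- function(query, reference_ranking) {
  ranked <- reference_ranking$table$gene
  ks_up <- ks_tag_score(query$up, ranked)
  ks_down <- ks_tag_score(query$down, ranked)
  combine_ks(ks_up, ks_down)
}

combine_ks <- function(ks_up, ks_down) {
  if (is.na(ks_up) || is.na(ks_down)) {
    return(NA_real_)
  }
  if (sign(ks_up) == sign(ks_down)) {
    return(0)
  }
  (ks_up - ks_down) / 2
}

#' Bidirectional enrichment score of two entities
#'
#' Mean of the two directional scores: entity A's tags in entity B's ranked
#' list and vice versa. Pairs where either entity lacks scorable up and down
#' tag sets are unscored (`NA`).
#'
#' @param entity_a,entity_b [signature_ranking()]s.
#' @param cap,min_tags tag-set capping (see [query_signature()]).
#' @return enrichment score in `[-1, 1]`, or `NA`.
#' @export
pair_es <- function(entity_a, entity_b, cap = 250L, min_tags = 5L) {
  qa <- query_signature(entity_a, cap, min_tags)
  qb <- query_signature(entity_b, cap, min_tags)
  if (!qa$scorable || !qb$scorable) {
    return(NA_real_)
  }
  mean(c(directional_es(qa, entity_b), directional_es(qb, entity_a)))
}

# one null draw of the bidirectional ES: random disjoint up/down position
# sets of the observed sizes in each direction's reference list
null_pair_es <- function(n_a, t_up_a, t_down_a, n_b, t_up_b, t_down_b) {
  dir1 <- {
    s <- sample.int(n_b, t_up_a + t_down_a)
    combine_ks(
      ks_positions(sort(s[seq_len(t_up_a)]), n_b),
      ks_positions(sort(s[-seq_len(t_up_a)]), n_b)
    )
  }
  dir2 <- {
    s <- sample.int(n_a, t_up_b + t_down_b)
    combine_ks(
      ks_positions(sort(s[seq_len(t_up_b)]), n_a),
      ks_positions(sort(s[-seq_len(t_up_b)]), n_a)
    )
  }
  mean(c(dir1, dir2))
}

#' Score all query-reference pairs with permutation significance
#'
#' Computes the bidirectional enrichment score for every (query, reference)
#' pair, a two-sided permutation p-value per pair (null signatures of the
#' observed tag-set sizes sampled without replacement from each reference
#' list; ties counted as exceeding; add-one correction), Benjamini-Hochberg
#' FDR across the whole batch, and the correlation class:
#' `anti-correlated` (es < 0, fdr < alpha), `correlated` (es > 0,
#' fdr < alpha), else `not-significant`.
#'
#' @param queries named list of [signature_ranking()]s (e.g. foods or drugs).
#' @param references named list of [signature_ranking()]s (e.g. diseases).
#' @param n_perm permutations per pair (default 1000; < 100 draws a warning).
#' @param alpha FDR threshold for class assignment (default 0.05).
#' @param cap,min_tags tag-set capping.
#' @param seed integer seed.
#' @return data.frame with columns `query`, `reference`, `es`, `p_value`,
#'   `fdr`, `class` (unscored pairs carry `NA` scores and class `unscored`).
#' @export
score_pairs <- function(queries, references, n_perm = 1000L, alpha = 0.05,
                        cap = 250L, min_tags = 5L, seed = 1L) {
  if (n_perm < 100L) {
    warning("n_perm < 100 gives unstable permutation p-values", call. = FALSE)
  }
  set.seed(derive_seed(seed, "es"))
  rows <- list()
  idx <- 0L
  for (qn in names(queries)) {
    qa <- query_signature(queries[[qn]], cap, min_tags)
    n_a <- nrow(queries[[qn]]$table)
    for (rn in names(references)) {
      qb <- query_signature(references[[rn]], cap, min_tags)
      n_b <- nrow(references[[rn]]$table)
      idx <- idx + 1L
      es <- pair_es(queries[[qn]], references[[rn]], cap, min_tags)
      p <- NA_real_
      if (!is.na(es)) {
        null_es <- vapply(seq_len(n_perm), function(b) {
          null_pair_es(
            n_a, length(qa$up), length(qa$down),
            n_b, length(qb$up), length(qb$down)
          )
        }, numeric(1))
        p <- (sum(abs(null_es) >= abs(es)) + 1) / (n_perm + 1)
      }
      rows[[idx]] <- data.frame(
        query = qn, reference = rn, es = es, p_value = p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  scored <- !is.na(out$p_value)
  out$fdr[scored] <- bh_adjust(out$p_value[scored])
  out$class <- "not-significant"
  out$class[scored & out$fdr < alpha & out$es < 0] <- "anti-correlated"
  out$class[scored & out$fdr < alpha & out$es > 0] <- "correlated"
  out$class[!scored] <- "unscored"
  out
}

#' Enrichment-score profile matrix
#'
#' Diseases as rows, query entities (foods or drugs) as columns. Unscored
#' pairs are `NA`.
#'
#' @param results output of [score_pairs()].
#' @return numeric matrix.
#' @export
es_profile_matrix <- function(results) {
  diseases <- sort(unique(results$reference))
  entities <- sort(unique(results$query))
  m <- matrix(NA_real_, length(diseases), length(entities),
    dimnames = list(diseases, entities)
  )
  m[cbind(results$reference, results$query)] <- results$es
  m
}

#' Hierarchical clustering of diseases by their ES profiles
#'
#' Pairwise distance is `1 - Pearson(row_i, row_j)` over the ES profiles;
#' agglomerative clustering with average linkage. Missing entries are imputed
#' as 0 (flagged); a constant (zero-variance) row gets the maximal distance 2
#' to every other row.
#'
#' @param profile matrix from [es_profile_matrix()] (>= 3 rows).
#' @param k optional flat cut into `k` clusters.
#' @return list with `hclust`, `newick` (serialized dendrogram), `clusters`
#'   (named integer vector or `NULL`), `imputed` (count of imputed cells),
#'   `constant_rows`.
#' @export
cluster_diseases <- function(profile, k = NULL) {
  if (nrow(profile) < 3L) stop("need at least 3 diseases", call. = FALSE)
  imputed <- sum(is.na(profile))
  if (imputed > 0L) {
    message(imputed, " missing ES entries imputed as 0 for clustering")
    profile[is.na(profile)] <- 0
  }
  sds <- apply(profile, 1, sd)
  const <- sds == 0
  cors <- suppressWarnings(cor(t(profile)))
  d <- 1 - cors
  d[const, ] <- 2
  d[, const] <- 2
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  clusters <- if (!is.null(k)) cutree(hc, k = k) else NULL
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(
    hclust = hc, newick = newick, clusters = clusters,
    imputed = imputed, constant_rows = rownames(profile)[const]
  )
}

#' Recovery of known indications and per-class Fisher tests
#'
#' Counts how many known (query, reference) indication pairs were classed
#' anti-correlated, and per reference class builds the 2x2 table
#' (known indication vs not) x (anti-correlated vs not) over all scored pairs
#' of that class, with a two-sided Fisher's exact p-value.
#'
#' @param results output of [score_pairs()].
#' @param known_indications data.frame with columns `query`, `reference`.
#' @param class_map optional named vector: reference -> class label.
#' @return list with `overall` (data.frame: known pairs scored / recovered)
#'   and `per_class` (data.frame: class, counts of the 2x2 table, fisher_p).
#' @export
recovery_stats <- function(results, known_indications, class_map = NULL) {
  key <- function(q, r) paste(q, r, sep = "\r")
  known <- known_indications
  bad <- !(known$reference %in% results$reference)
  if (any(bad)) {
    warning(
      sum(bad), " indication(s) with unknown reference skipped",
      call. = FALSE
    )
    known <- known[!bad, , drop = FALSE]
  }
  scored <- results[results$class != "unscored", , drop = FALSE]
  scored$known <- key(scored$query, scored$reference) %in%
    key(known$query, known$reference)
  scored$anti <- scored$class == "anti-correlated"
  overall <- data.frame(
    n_known = nrow(known),
    n_known_scored = sum(scored$known),
    n_recovered = sum(scored$known & scored$anti)
  )
  per_class <- NULL
  if (!is.null(class_map) && nrow(scored) > 0L) {
    scored$ref_class <- class_map[scored$reference]
    per_class <- do.call(rbind, lapply(
      split(scored, scored$ref_class),
      function(df) {
        tab <- table(
          factor(df$known, c(TRUE, FALSE)),
          factor(df$anti, c(TRUE, FALSE))
        )
        data.frame(
          class = df$ref_class[1],
          known_anti = tab[1, 1], known_other = tab[1, 2],
          unknown_anti = tab[2, 1], unknown_other = tab[2, 2],
          fisher_p = fisher.test(tab)$p.value,
          stringsAsFactors = FALSE
        )
      }
    ))
    rownames(per_class) <- NULL
  }
  list(overall = overall, per_class = per_class)
}
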