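# Transcriptional synergy prediction for food pairs: core genes are those
# significantly DE in at least one member; scored by directional overlap
# ("Rank 2"), fold-change correlation ("Rank 4") and rank aggregation over
# expression/pathway/function similarity ("Rank 9"); evaluated against a
# literature-reference-count gold standard.

#' Core gene set of a food pair
#'
#' Genes significantly DE (pfp <= 0.05) in at least one of the two foods,
#' with per-food direction calls (+1 up, -1 down, 0 not significant) and
#' combined log fold changes.
#'
#' @param sig_a,sig_b [signature_ranking()]s.
#' @return data.frame with columns `gene`, `call_a`, `call_b`, `logfc_a`,
#'   `logfc_b`.
#' @export
core_gene_set <- function(sig_a, sig_b) {
  de_a <- c(sig_a$up_set, sig_a$down_set)
  de_b <- c(sig_b$up_set, sig_b$down_set)
  core <- sort(union(de_a, de_b))
  dir_of <- function(sig, genes) {
    out <- integer(length(genes))
    out[genes %in% sig$up_set] <- 1L
    out[genes %in% sig$down_set] <- -1L
    out
  }
  fc_of <- function(sig, genes) {
    sig$table$logfc[match(genes, sig$table$gene)]
  }
  data.frame(
    gene = core,
    call_a = dir_of(sig_a, core), call_b = dir_of(sig_b, core),
    logfc_a = fc_of(sig_a, core), logfc_b = fc_of(sig_b, core),
    stringsAsFactors = FALSE
  )
}

#' Directional-overlap interaction score ("Rank 2")
#'
#' Among the core genes, `O+` counts genes significantly DE in both foods
#' with equal direction and `O-` those DE in both with opposite direction;
#' the score is `(O+ - O-) / |core|`, in `[-1, 1]`, equal to 1 iff every
#' core gene is DE in both foods with the same direction.
#'
#' @param core data.frame from [core_gene_set()].
#' @return numeric score, or `NA` for an empty core.
#' @export
rank2_score <- function(core) {
  if (nrow(core) == 0L) {
    return(NA_real_)
  }
  both <- core$call_a != 0L & core$call_b != 0L
  o_plus <- sum(both & core$call_a == core$call_b)
  o_minus <- sum(both & core$call_a != core$call_b)
  (o_plus - o_minus) / nrow(core)
}

#' Fold-change correlation score ("Rank 4")
#'
#' Pearson correlation of the two foods' combined log fold changes restricted
#' to the core genes; requires at least 3 core genes and non-degenerate
#' variance.
#'
#' @param core data.frame from [core_gene_set()].
#' @return correlation in `[-1, 1]`, or `NA` (degenerate/small core).
#' @export
rank4_score <- function(core) {
  core <- core[stats::complete.cases(core[, c("logfc_a", "logfc_b")]), ]
  if (nrow(core) < 3L) {
    return(NA_real_)
  }
  if (sd(core$logfc_a) == 0 || sd(core$logfc_b) == 0) {
    return(NA_real_)
  }
  cor(core$logfc_a, core$logfc_b)
}

#' Rank aggregation over similarity lists ("Rank 9")
#'
#' Ranks every pair within each similarity (descending, average ranks on
#' ties) and aggregates by the mean of the three ranks (Borda). Pairs missing
#' any similarity are excluded (logged via message).
#'
#' @param similarities data.frame with columns `food_a`, `food_b`,
#'   `expression`, `pathway`, `function_` — higher = more similar.
#' @return the input restricted to complete pairs, with per-list rank
#'   columns and `aggregated_rank`, sorted ascending (best first).
#' @export
rank9_aggregate <- function(similarities) {
  needed <- c("food_a", "food_b", "expression", "pathway", "function_")
  stopifnot(all(needed %in% names(similarities)))
  ok <- stats::complete.cases(
    similarities[, c("expression", "pathway", "function_")]
  )
  if (!all(ok)) {
    message(sum(!ok), " pair(s) with missing similarities excluded")
  }
  df <- similarities[ok, , drop = FALSE]
  df$rank_expression <- rank(-df$expression, ties.method = "average")
  df$rank_pathway <- rank(-df$pathway, ties.method = "average")
  df$rank_function <- rank(-df$function_, ties.method = "average")
  df$aggregated_rank <-
    (df$rank_expression + df$rank_pathway + df$rank_function) / 3
  df <- df[order(df$aggregated_rank, df$food_a, df$food_b), ]
  rownames(df) <- NULL
  df
}

# Jaccard index of two sets
jaccard <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0L) {
    return(0)
  }
  length(intersect(a, b)) / length(u)
}

#' Score every food pair with the three synergy methods
#'
#' @param signatures named list of [signature_ranking()]s (foods).
#' @param enrich_pathway,enrich_function named lists: food -> enriched
#'   pathway / function-term names (for the rank-aggregation inputs);
#'   optional — without them only Rank 2/4 are computed.
#' @return data.frame, one row per unordered pair: `food_a`, `food_b`,
#'   `core_size`, `rank2_score`, `rank4_score`, and (when the collections are
#'   given) `rank9_rank`.
#' @export
score_food_pairs <- function(signatures, enrich_pathway = NULL,
                             enrich_function = NULL) {
  foods <- names(signatures)
  if (length(foods) < 2L) stop("need at least two foods", call. = FALSE)
  combos <- utils::combn(foods, 2)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]
    b <- combos[2, i]
    core <- core_gene_set(signatures[[a]], signatures[[b]])
    data.frame(
      food_a = a, food_b = b, core_size = nrow(core),
      rank2_score = rank2_score(core), rank4_score = rank4_score(core),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(enrich_pathway) && !is.null(enrich_function)) {
    sims <- data.frame(
      food_a = out$food_a, food_b = out$food_b,
      expression = out$rank4_score,
      pathway = mapply(function(a, b) {
        jaccard(enrich_pathway[[a]], enrich_pathway[[b]])
      }, out$food_a, out$food_b),
      function_ = mapply(function(a, b) {
        jaccard(enrich_function[[a]], enrich_function[[b]])
      }, out$food_a, out$food_b),
      stringsAsFactors = FALSE
    )
    agg <- rank9_aggregate(sims)
    out$rank9_rank <- agg$aggregated_rank[
      match(paste(out$food_a, out$food_b), paste(agg$food_a, agg$food_b))
    ]
  }
  out
}

#' Call synergistic pairs by permutation of direction calls
#'
#' The null redistributes each food's up/down calls uniformly over that
#' food's own DE genes (the DE sets, hence the core, stay fixed; only which
#' shared genes agree is randomized). The upper-tail add-one p-value of the
#' Rank 2 score against `n_perm` such draws, together with a positive score,
#' defines a synergistic call.
#'
#' @param signatures named list of [signature_ranking()]s.
#' @param scores data.frame from [score_food_pairs()].
#' @param n_perm permutation draws (default 1000).
#' @param alpha call threshold on the permutation p (default 0.05).
#' @param seed integer seed.
#' @return `scores` with added columns `p_value` and `call` (logical).
#' @export
call_synergy <- function(signatures, scores, n_perm = 1000L, alpha = 0.05,
                         seed = 1L) {
  set.seed(derive_seed(seed, "synergy"))
  p <- rep(NA_real_, nrow(scores))
  for (i in seq_len(nrow(scores))) {
    sa <- signatures[[scores$food_a[i]]]
    sb <- signatures[[scores$food_b[i]]]
    core <- core_gene_set(sa, sb)
    if (nrow(core) == 0L || is.na(scores$rank2_score[i])) next
    de_a <- core$call_a != 0L
    de_b <- core$call_b != 0L
    n_core <- nrow(core)
    null_scores <- vapply(seq_len(n_perm), function(b) {
      ca <- core$call_a
      cb <- core$call_b
      ca[de_a] <- sample(ca[de_a])
      cb[de_b] <- sample(cb[de_b])
      both <- de_a & de_b
      (sum(both & ca == cb) - sum(both & ca != cb)) / n_core
    }, numeric(1))
    p[i] <- (sum(null_scores >= scores$rank2_score[i]) + 1) / (n_perm + 1)
  }
  scores$p_value <- p
  scores$call <- !is.na(scores$rank2_score) & scores$rank2_score > 0 &
    !is.na(p) & p < alpha
  scores
}

#' Build the gold standard from a reference-count table
#'
#' A food pair is gold iff (1) at least one disease is associated with both
#' foods and (2) the sum over all shared diseases of both foods' reference
#' counts exceeds 10 (strict).
#'
#' @param reference_table data.frame with columns `food`, `disease`,
#'   `reference_count`.
#' @param threshold strict lower bound on the summed counts (default 10).
#' @return data.frame of gold pairs: `food_a`, `food_b`, `shared_diseases`,
#'   `summed_count`.
#' @export
build_gold_standard <- function(reference_table, threshold = 10) {
  foods <- sort(unique(reference_table$food))
  if (length(foods) < 2L) {
    return(data.frame(
      food_a = character(0), food_b = character(0),
      shared_diseases = integer(0), summed_count = numeric(0)
    ))
  }
  combos <- utils::combn(foods, 2)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]
    b <- combos[2, i]
    ta <- reference_table[reference_table$food == a, ]
    tb <- reference_table[reference_table$food == b, ]
    shared <- intersect(ta$disease, tb$disease)
    if (length(shared) == 0L) {
      return(NULL)
    }
    total <- sum(ta$reference_count[ta$disease %in% shared]) +
      sum(tb$reference_count[tb$disease %in% shared])
    if (total <= threshold) {
      return(NULL)
    }
    data.frame(
      food_a = a, food_b = b, shared_diseases = length(shared),
      summed_count = total, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      food_a = character(0), food_b = character(0),
      shared_diseases = integer(0), summed_count = numeric(0)
    )
  }
  out
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Gold-standard recovery per scoring method
#'
#' Rank 2 recovery counts gold pairs among the called-synergistic pairs; the
#' score-only methods (Rank 4, Rank 9) are evaluated among their top-k pairs
#' with k matched to the number of Rank 2 calls, for comparability.
#'
#' @param calls data.frame from [call_synergy()] (with `rank4_score` and
#'   optionally `rank9_rank`).
#' @param gold_pairs data.frame from [build_gold_standard()].
#' @return data.frame: `method`, `n_selected`, `n_gold`, `n_recovered`.
#' @export
evaluate_recovery <- function(calls, gold_pairs) {
  gold <- pair_key(gold_pairs$food_a, gold_pairs$food_b)
  keys <- pair_key(calls$food_a, calls$food_b)
  k <- sum(calls$call)
  sel_rank2 <- keys[calls$call]
  top_k <- function(score, decreasing = TRUE) {
    ord <- order(score, decreasing = decreasing, na.last = TRUE)
    keys[head(ord, k)]
  }
  sel_rank4 <- if (k > 0) top_k(calls$rank4_score) else character(0)
  sel_rank9 <- if ("rank9_rank" %in% names(calls) && k > 0) {
    top_k(calls$rank9_rank, decreasing = FALSE)
  } else {
    character(0)
  }
  data.frame(
    method = c("rank2", "rank4", "rank9"),
    n_selected = c(length(sel_rank2), length(sel_rank4), length(sel_rank9)),
    n_gold = length(gold),
    n_recovered = c(
      sum(sel_rank2 %in% gold), sum(sel_rank4 %in% gold),
      sum(sel_rank9 %in% gold)
    ),
    stringsAsFactors = FALSE
  )
}

#' Downstream characterization of synergistic calls
#'
#' (a) Per food pair, the number of diseases anti-correlated with both
#' members, compared between synergistic and non-synergistic pairs by a
#' two-sided Wilcoxon rank-sum test. (b) Per synergistic pair, the Pearson
#' correlation of the two foods' ES profiles across all diseases with its
#' t-distribution p-value (skipped below 3 diseases).
#'
#' @param calls data.frame from [call_synergy()].
#' @param food_results [score_pairs()] output for foods vs diseases.
#' @return list with `shared` (per-pair shared anti-correlated disease
#'   counts + `call`), `wilcox_p`, `profile_correlations` (data.frame per
#'   synergistic pair: `cor`, `p`).
#' @export
synergy_downstream <- function(calls, food_results) {
  anti <- split(
    food_results$reference[food_results$class == "anti-correlated"],
    food_results$query[food_results$class == "anti-correlated"]
  )
  shared <- calls[, c("food_a", "food_b", "call")]
  shared$shared_anti <- vapply(seq_len(nrow(shared)), function(i) {
    length(intersect(
      anti[[shared$food_a[i]]] %||% character(0),
      anti[[shared$food_b[i]]] %||% character(0)
    ))
  }, integer(1))
  wilcox_p <- if (any(shared$call) && any(!shared$call)) {
    suppressWarnings(
      wilcox.test(shared_anti ~ call, data = shared, exact = FALSE)$p.value
    )
  } else {
    NA_real_
  }
  prof <- es_profile_matrix(food_results)
  syn <- calls[calls$call, , drop = FALSE]
  cors <- NULL
  if (nrow(syn) > 0L && nrow(prof) >= 3L) {
    cors <- do.call(rbind, lapply(seq_len(nrow(syn)), function(i) {
      va <- prof[, syn$food_a[i]]
      vb <- prof[, syn$food_b[i]]
      ok <- stats::complete.cases(va, vb)
      if (sum(ok) < 3L || sd(va[ok]) == 0 || sd(vb[ok]) == 0) {
        return(data.frame(
          food_a = syn$food_a[i], food_b = syn$food_b[i],
          cor = NA_real_, p = NA_real_, stringsAsFactors = FALSE
        ))
      }
      ct <- cor.test(va[ok], vb[ok])
      data.frame(
        food_a = syn$food_a[i], food_b = syn$food_b[i],
        cor = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE
      )
    }))
  }
  list(
    shared = shared, wilcox_p = wilcox_p,
    profile_correlations = cors
  )
}
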