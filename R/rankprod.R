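# Rank-product meta-analytic differential expression: a gene's statistic is
# the geometric mean of its fold-change ranks across independent datasets,
# which makes the combination nonparametric and robust to platform
# heterogeneity; significance is a permutation-estimated proportion of false
# prediction (pfp), the method's FDR analogue.

#' Per-gene log2 fold change of one case/control dataset
#'
#' Unpaired difference of arm means on the log2 scale.
#'
#' @param dataset an [expression_dataset()].
#' @return named numeric vector of fold changes.
#' @export
fold_changes <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  case <- dataset$sample_labels == "case"
  ctrl <- dataset$sample_labels == "control"
  if (!any(case) || !any(ctrl)) {
    stop("dataset '", dataset$provenance, "' lacks a case or control arm",
      call. = FALSE
    )
  }
  rowMeans(dataset$values[, case, drop = FALSE]) -
    rowMeans(dataset$values[, ctrl, drop = FALSE])
}

# union fold-change matrix (genes x datasets), NA where a gene is absent
fc_matrix <- function(datasets) {
  fcs <- lapply(datasets, fold_changes)
  genes <- sort(unique(unlist(lapply(fcs, names))))
  m <- matrix(NA_real_, length(genes), length(fcs),
    dimnames = list(genes, names(datasets) %||% seq_along(datasets))
  )
  for (i in seq_along(fcs)) m[names(fcs[[i]]), i] <- fcs[[i]]
  m
}

# per-dataset fold-change ranks; rank 1 = most extreme in `direction`.
# Average ranks on ties; NA kept for absent genes.
rank_columns <- function(fc, direction = c("up", "down")) {
  direction <- match.arg(direction)
  apply(fc, 2, function(col) {
    x <- if (direction == "up") -col else col
    rank(x, ties.method = "average", na.last = "keep")
  })
}

# geometric mean of available ranks
rp_from_ranks <- function(ranks) {
  exp(rowMeans(log(ranks), na.rm = TRUE))
}

#' Rank-product statistic across datasets
#'
#' For each dataset, genes are ranked by log2 fold change (descending for
#' `direction = "up"`, ascending for `"down"`; rank 1 = most extreme, average
#' ranks on ties). The statistic is the geometric mean of a gene's ranks over
#' the datasets that contain it; genes present in fewer than half the
#' datasets are excluded.
#'
#' @param datasets list of [expression_dataset()]s (>= 1), each with both
#'   arms.
#' @param direction `"up"` or `"down"`.
#' @return named numeric vector of RP statistics over the retained genes,
#'   with the per-dataset rank matrix as attribute `"ranks"`.
#' @export
rank_product <- function(datasets, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(datasets) < 1L) stop("need at least one dataset", call. = FALSE)
  fc <- fc_matrix(datasets)
  k <- ncol(fc)
  keep <- rowSums(!is.na(fc)) * 2L >= k
  ranks <- rank_columns(fc, direction)[keep, , drop = FALSE]
  rp <- rp_from_ranks(ranks)
  attr(rp, "ranks") <- ranks
  rp
}

#' Permutation significance (pfp) for rank-product statistics
#'
#' Builds the null RP distribution from `n_perm` independent uniform random
#' permutations of each dataset's observed rank vector (permuted within the
#' genes that dataset measured), pools all null values, and converts to
#' per-gene p-values with an add-one correction:
#' `p_g = (#\{null RP <= RP_g\} + 1) / (n_genes * n_perm + 1)`.
#' The proportion of false prediction is `pfp_g = p_g * n_genes /
#' rank(RP_g ascending)`.
#'
#' @param rp named RP vector (as from [rank_product()]).
#' @param ranks per-dataset rank matrix (attribute `"ranks"` of
#'   [rank_product()]; defaults to that attribute).
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `rp`, `p`, `pfp`.
#' @export
rp_significance <- function(rp, ranks = attr(rp, "ranks"), n_perm = 200L,
                            seed = 1L) {
  if (is.null(ranks)) stop("rank matrix required", call. = FALSE)
  n_g <- nrow(ranks)
  set.seed(derive_seed(seed, "rankprod"))
  null_pool <- numeric(n_g * n_perm)
  perm_ranks <- ranks
  for (b in seq_len(n_perm)) {
    for (j in seq_len(ncol(ranks))) {
      present <- !is.na(ranks[, j])
      perm_ranks[present, j] <- sample(ranks[present, j])
    }
    null_pool[((b - 1L) * n_g + 1L):(b * n_g)] <- rp_from_ranks(perm_ranks)
  }
  null_sorted <- sort(null_pool)
  counts <- findInterval(rp, null_sorted) # nulls <= observed (ties counted)
  p <- (counts + 1) / (length(null_pool) + 1)
  pfp <- p * n_g / rank(rp, ties.method = "average")
  data.frame(
    gene = names(rp), rp = as.numeric(rp), p = p, pfp = pfp,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Construct a signature ranking object
#'
#' @param table data.frame with columns `gene`, `logfc`, `rp_up`, `rp_down`,
#'   `pfp_up`, `pfp_down`, `call`.
#' @param entity entity tag.
#' @return object of class `signature_ranking` with `table`, `entity`,
#'   `up_set`, `down_set` (each ordered by |logfc| descending).
#' @export
signature_ranking <- function(table, entity) {
  needed <- c("gene", "logfc", "rp_up", "rp_down", "pfp_up", "pfp_down", "call")
  if (!all(needed %in% names(table))) {
    stop("signature table missing columns", call. = FALSE)
  }
  by_abs <- table[order(-abs(table$logfc), table$gene), ]
  structure(
    list(
      table = table, entity = entity,
      up_set = by_abs$gene[by_abs$call == "up"],
      down_set = by_abs$gene[by_abs$call == "down"]
    ),
    class = "signature_ranking"
  )
}

#' @export
print.signature_ranking <- function(x, ...) {
  cat(sprintf(
    "<signature_ranking> %s: %d genes, %d up / %d down at pfp <= 0.05\n",
    x$entity, nrow(x$table), length(x$up_set), length(x$down_set)
  ))
  invisible(x)
}

#' Combine an entity's datasets into a differential-expression signature
#'
#' Runs the rank product in both directions with permutation pfp, averages
#' fold changes across the datasets containing each gene, and calls
#' significant up-/down-regulated sets at `pfp <= alpha`. A gene significant
#' in both directions is assigned to the direction with the smaller pfp, so
#' the sets stay disjoint. The ranked gene list is ordered by combined log
#' fold change (descending; ties broken by gene id).
#'
#' @param datasets list of [expression_dataset()]s.
#' @param entity entity tag carried on the result.
#' @param alpha pfp threshold for significance calls (default 0.05).
#' @param n_perm permutations for the pfp null (default 200).
#' @param seed integer seed.
#' @return a [signature_ranking()].
#' @export
build_signature <- function(datasets, entity = "entity", alpha = 0.05,
                            n_perm = 200L, seed = 1L) {
  rp_up <- rank_product(datasets, "up")
  rp_down <- rank_product(datasets, "down")
  # same seed for both directions: the null pool depends only on the rank
  # multiset, so label-swapped data yields exactly swapped calls
  sig_up <- rp_significance(rp_up, n_perm = n_perm, seed = seed)
  sig_down <- rp_significance(rp_down, n_perm = n_perm, seed = seed)
  fc <- fc_matrix(datasets)[names(rp_up), , drop = FALSE]
  logfc <- rowMeans(fc, na.rm = TRUE)

  call <- rep("ns", length(logfc))
  up_ok <- sig_up$pfp <= alpha
  down_ok <- sig_down$pfp <= alpha
  call[up_ok & (!down_ok | sig_up$pfp <= sig_down$pfp)] <- "up"
  call[down_ok & (!up_ok | sig_down$pfp < sig_up$pfp)] <- "down"

  tab <- data.frame(
    gene = names(logfc), logfc = as.numeric(logfc),
    rp_up = sig_up$rp, rp_down = sig_down$rp,
    pfp_up = sig_up$pfp, pfp_down = sig_down$pfp,
    call = call, stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$logfc, tab$gene), ]
  rownames(tab) <- NULL
  out <- signature_ranking(tab, entity)
  if (length(out$up_set) == 0L && length(out$down_set) == 0L) {
    message("signature '", entity, "': no significant DE genes at pfp <= ",
      alpha)
  }
  out
}
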