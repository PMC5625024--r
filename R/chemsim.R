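# Structural similarity between dietary compounds and drugs: circular
# (Morgan/ECFP4, radius 2) fingerprints computed through the OpenBabel
# backend, compared by this package's own Tanimoto coefficient, with the 0.4
# cutoff defining "similar" food-drug pairs.

#' Morgan (ECFP4) fingerprints for a table of compounds
#'
#' Parses each SMILES and computes a binary circular fingerprint of radius 2
#' (OpenBabel's ECFP4, hashed to 4096 bits). Records whose SMILES fail to
#' parse or yield an empty fingerprint are rejected and counted.
#'
#' @param compounds data.frame with columns `entity`, `compound_id`,
#'   `smiles`.
#' @return list with `fingerprints` (logical matrix, compounds x bits,
#'   rownames = compound ids), `table` (the retained rows) and `n_rejected`.
#' @export
fingerprint_compounds <- function(compounds) {
  stopifnot(all(c("entity", "compound_id", "smiles") %in% names(compounds)))
  n_in <- nrow(compounds)
  smi <- setNames(compounds$smiles, compounds$compound_id)
  # smiles2sdf silently drops records OpenBabel cannot parse; realign by id
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smi)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0L) {
    stop("no SMILES could be parsed", call. = FALSE)
  }
  sdf <- sdf[ChemmineR::validSDF(sdf)]
  compounds <- compounds[compounds$compound_id %in% ChemmineR::cid(sdf), ,
    drop = FALSE
  ]
  fp <- ChemmineR::fingerprintOB(sdf, "ECFP4")
  m <- fp@fpma > 0
  rownames(m) <- compounds$compound_id
  empty <- rowSums(m) == 0L
  if (any(empty)) {
    warning(sum(empty), " compound(s) with empty fingerprints rejected",
      call. = FALSE
    )
  }
  list(
    fingerprints = m[!empty, , drop = FALSE],
    table = compounds[!empty, , drop = FALSE],
    n_rejected = n_in - sum(!empty)
  )
}

#' Tanimoto coefficient of two binary fingerprints
#'
#' `|a AND b| / |a OR b|`; two empty fingerprints score 0 (flagged by a
#' warning).
#'
#' @param a,b logical (or 0/1) vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  stopifnot(length(a) == length(b))
  union_n <- sum(a | b)
  if (union_n == 0L) {
    warning("both fingerprints empty; Tanimoto set to 0", call. = FALSE)
    return(0)
  }
  sum(a & b) / union_n
}

# all-pairs Tanimoto between two fingerprint matrices (rows = compounds)
tanimoto_matrix <- function(fa, fb) {
  inter <- fa %*% t(fb)
  na <- rowSums(fa)
  nb <- rowSums(fb)
  uni <- outer(na, nb, `+`) - inter
  out <- inter / uni
  out[uni == 0] <- 0
  out
}

#' Food-drug pairs sharing at least one structurally similar compound
#'
#' Computes all pairwise Tanimoto similarities between food compounds and
#' drug compounds and retains every (food, drug) pair for which at least one
#' compound pair reaches the cutoff, together with the supporting edges.
#'
#' @param food_compounds,drug_compounds data.frames with columns `entity`,
#'   `compound_id`, `smiles`.
#' @param cutoff retained-edge threshold (default 0.4).
#' @return list with `pairs` (data.frame `food`, `drug`, `n_edges`,
#'   `max_tanimoto`), `edges` (data.frame `food`, `drug`, `food_compound`,
#'   `drug_compound`, `tanimoto`), `n_rejected`.
#' @export
similar_food_drug_pairs <- function(food_compounds, drug_compounds,
                                    cutoff = 0.4) {
  ff <- fingerprint_compounds(food_compounds)
  dd <- fingerprint_compounds(drug_compounds)
  sim <- tanimoto_matrix(
    ff$fingerprints * 1,
    dd$fingerprints * 1
  )
  hits <- which(sim >= cutoff, arr.ind = TRUE)
  edges <- data.frame(
    food = ff$table$entity[hits[, 1]],
    drug = dd$table$entity[hits[, 2]],
    food_compound = ff$table$compound_id[hits[, 1]],
    drug_compound = dd$table$compound_id[hits[, 2]],
    tanimoto = sim[hits],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$food, edges$drug, -edges$tanimoto), ]
  rownames(edges) <- NULL
  pairs <- if (nrow(edges) > 0L) {
    agg_n <- stats::aggregate(tanimoto ~ food + drug, edges, length)
    agg_m <- stats::aggregate(tanimoto ~ food + drug, edges, max)
    out <- merge(agg_n, agg_m, by = c("food", "drug"))
    names(out) <- c("food", "drug", "n_edges", "max_tanimoto")
    out[order(out$food, out$drug), ]
  } else {
    data.frame(
      food = character(0), drug = character(0),
      n_edges = integer(0), max_tanimoto = numeric(0)
    )
  }
  rownames(pairs) <- NULL
  list(
    pairs = pairs, edges = edges,
    n_rejected = ff$n_rejected + dd$n_rejected
  )
}

#' Do structurally similar food-drug pairs share more anti-correlated
#' diseases?
#'
#' For every food-drug pair, counts the diseases classed anti-correlated
#' with both members (from the connectivity results of both entity classes),
#' then compares the counts of similar pairs against all remaining pairs
#' with a two-sided Wilcoxon rank-sum test.
#'
#' @param similar_pairs data.frame with columns `food`, `drug` (the pairs
#'   passing the cutoff).
#' @param food_results,drug_results [score_pairs()] outputs for foods and
#'   drugs against the same diseases.
#' @return list with `counts` (data.frame `food`, `drug`, `shared`,
#'   `similar`) and `wilcox_p` (`NA` if either group is empty).
#' @export
compare_shared_diseases <- function(similar_pairs, food_results,
                                    drug_results) {
  anti <- function(res) {
    split(
      res$reference[res$class == "anti-correlated"],
      res$query[res$class == "anti-correlated"]
    )
  }
  fa <- anti(food_results)
  da <- anti(drug_results)
  foods <- unique(food_results$query)
  drugs <- unique(drug_results$query)
  grid <- expand.grid(food = foods, drug = drugs, stringsAsFactors = FALSE)
  grid$shared <- vapply(seq_len(nrow(grid)), function(i) {
    length(intersect(
      fa[[grid$food[i]]] %||% character(0),
      da[[grid$drug[i]]] %||% character(0)
    ))
  }, integer(1))
  key <- function(f, d) paste(f, d, sep = "\r")
  grid$similar <- key(grid$food, grid$drug) %in%
    key(similar_pairs$food, similar_pairs$drug)
  p <- if (any(grid$similar) && any(!grid$similar)) {
    suppressWarnings(
      wilcox.test(shared ~ similar, data = grid, exact = FALSE)$p.value
    )
  } else {
    NA_real_
  }
  list(counts = grid, wilcox_p = p)
}
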