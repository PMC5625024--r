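# Synergy scoring (directional overlap, correlation, rank aggregation),
# calling, gold standard and recovery.

# rankings over a 20-gene universe with prescribed DE calls and logfc
syn_ranking <- function(up, down, entity, logfc = NULL) {
  genes <- paste0("g", 1:20)
  make_ranking(genes, up = up, down = down, entity = entity, logfc = logfc)
}

test_that("rank2 reproduces the worked example and its extremes", {
  genes <- paste0("g", 1:20)
  # core of 10: 4 concordant both-DE, 1 discordant both-DE, 5 single-food
  a <- syn_ranking(up = genes[1:5], down = genes[6:8], entity = "a")
  b <- syn_ranking(up = c(genes[1:4], genes[9]), down = c(genes[5], genes[10]),
    entity = "b")
  core <- core_gene_set(a, b)
  expect_equal(nrow(core), 10)
  expect_equal(rank2_score(core), (4 - 1) / 10)

  # identical calls in both foods: every core gene concordant -> 1
  id <- core_gene_set(a, a)
  expect_equal(rank2_score(id), 1)
  # fully discordant shared genes
  flip <- syn_ranking(up = genes[6:8], down = genes[1:5], entity = "flip")
  expect_equal(rank2_score(core_gene_set(a, flip)), -1)
})

test_that("rank4 equals the closed-form Pearson correlation", {
  genes <- paste0("g", 1:20)
  lf <- c(3, 2, 1, rep(0, 17))
  a <- syn_ranking(up = genes[1:3], down = genes[19:20], entity = "a",
    logfc = c(3, 2, 1, rep(0, 15), -1, -2))
  expect_equal(rank4_score(core_gene_set(a, a)), 1)
  neg <- syn_ranking(up = genes[19:20], down = genes[1:3], entity = "n",
    logfc = -c(3, 2, 1, rep(0, 15), -1, -2))
  expect_equal(rank4_score(core_gene_set(a, neg)), -1)

  # printed toy vectors: (1,2,3) vs (2,4,7) -> r = 0.9934
  core <- data.frame(
    gene = c("x", "y", "z"), call_a = 1L, call_b = 1L,
    logfc_a = c(1, 2, 3), logfc_b = c(2, 4, 7)
  )
  manual <- {
    xa <- c(1, 2, 3)
    xb <- c(2, 4, 7)
    sum((xa - mean(xa)) * (xb - mean(xb))) /
      sqrt(sum((xa - mean(xa))^2) * sum((xb - mean(xb))^2))
  }
  expect_equal(rank4_score(core), manual)
  expect_equal(rank4_score(core), 0.9934, tolerance = 1e-4)
  # degenerate: constant vector unscored
  core$logfc_b <- 1
  expect_true(is.na(rank4_score(core)))
})

test_that("rank9 aggregation preserves unanimity and matches hand-computed
           mean ranks", {
  sims <- data.frame(
    food_a = c("f1", "f1", "f1", "f2"),
    food_b = c("f2", "f3", "f4", "f3"),
    expression = c(0.9, 0.5, 0.1, 0.3),
    pathway = c(0.8, 0.4, 0.2, 0.3),
    function_ = c(0.7, 0.2, 0.1, 0.4),
    stringsAsFactors = FALSE
  )
  agg <- rank9_aggregate(sims)
  # the pair dominating all three lists is first with aggregated rank 1
  expect_identical(agg$food_a[1], "f1")
  expect_identical(agg$food_b[1], "f2")
  expect_equal(agg$aggregated_rank[1], 1)
  # hand-computed mean ranks for the toy table:
  # expression ranks 1,2,4,3; pathway 1,2,4,3; function 1,3,4,2
  expect_equal(
    agg$aggregated_rank[match(
      paste(sims$food_a, sims$food_b),
      paste(agg$food_a, agg$food_b)
    )],
    c(
      mean(c(1, 1, 1)), mean(c(2, 2, 3)), mean(c(4, 4, 4)),
      mean(c(3, 3, 2))
    )
  )
  # missing similarity excludes the pair
  sims$expression[2] <- NA
  expect_message(agg2 <- rank9_aggregate(sims), "excluded")
  expect_equal(nrow(agg2), 3)
})

test_that("all pair scores are symmetric under pair reversal", {
  st <- small_study()
  foods <- names(st$truth$food_signatures)[1:3]
  sigs <- lapply(foods, function(e) {
    suppressMessages(
      build_signature(st$datasets[[e]], entity = e, n_perm = 100, seed = 2)
    )
  })
  names(sigs) <- foods
  for (i in 1:2) {
    for (j in (i + 1):3) {
      ca <- core_gene_set(sigs[[i]], sigs[[j]])
      cb <- core_gene_set(sigs[[j]], sigs[[i]])
      expect_equal(rank2_score(ca), rank2_score(cb))
      expect_equal(rank4_score(ca), rank4_score(cb))
    }
  }
})

test_that("gold standard applies both criteria with a strict threshold", {
  ref <- data.frame(
    food = c("fA", "fB", "fC", "fD", "fE", "fF"),
    disease = c("d1", "d1", "d2", "d2", "d3", "d4"),
    reference_count = c(6, 5, 5, 5, 9, 20),
    stringsAsFactors = FALSE
  )
  gold <- build_gold_standard(ref)
  # fA-fB share d1 with 6 + 5 = 11 > 10 -> gold
  expect_true(any(gold$food_a == "fA" & gold$food_b == "fB"))
  # fC-fD share d2 with 5 + 5 = 10, not > 10 -> excluded
  expect_false(any(gold$food_a == "fC" & gold$food_b == "fD"))
  # fE-fF share nothing despite high counts -> excluded
  expect_false(any(
    (gold$food_a == "fE" & gold$food_b == "fF") |
      (gold$food_a == "fF" & gold$food_b == "fE")
  ))
  expect_equal(nrow(gold), 1)
})

test_that("synergy calls require a positive score and small permutation p;
           alpha = 1 calls every positive pair", {
  st <- small_study()
  foods <- names(st$truth$food_signatures)
  sigs <- lapply(foods, function(e) {
    suppressMessages(
      build_signature(st$datasets[[e]], entity = e, n_perm = 100, seed = 2)
    )
  })
  names(sigs) <- foods
  scores <- score_food_pairs(sigs)
  calls <- call_synergy(sigs, scores, n_perm = 200, seed = 6)
  expect_true(all(calls$rank2_score[calls$call] > 0))
  expect_true(all(calls$p_value[calls$call] < 0.05))
  # the planted synergy pair is called
  sp <- st$truth$synergy_pairs
  planted <- pair_key(sp$food_a, sp$food_b)
  called <- pair_key(calls$food_a[calls$call], calls$food_b[calls$call])
  expect_true(all(planted %in% called))
  # alpha = 1: every positive-score pair is called
  all_called <- call_synergy(sigs, scores, n_perm = 50, alpha = 1, seed = 6)
  expect_identical(
    all_called$call,
    !is.na(all_called$rank2_score) & all_called$rank2_score > 0 &
      !is.na(all_called$p_value)
  )
})

test_that("recovery is plain set intersection, with top-k for score-only
           methods", {
  calls <- data.frame(
    food_a = c("f1", "f1", "f2"), food_b = c("f2", "f3", "f3"),
    core_size = 10,
    rank2_score = c(0.8, 0.1, -0.2), rank4_score = c(0.9, 0.5, 0.1),
    rank9_rank = c(1, 2, 3),
    p_value = c(0.001, 0.4, 0.9), call = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  gold <- data.frame(
    food_a = "f1", food_b = "f2", shared_diseases = 1, summed_count = 12,
    stringsAsFactors = FALSE
  )
  rec <- evaluate_recovery(calls, gold)
  expect_equal(rec$n_recovered[rec$method == "rank2"], 1)
  expect_equal(rec$n_selected[rec$method == "rank4"], 1) # k = 1 call
  expect_equal(rec$n_recovered[rec$method == "rank4"], 1)
  expect_equal(rec$n_recovered[rec$method == "rank9"], 1)
  # disjoint gold: zero recovery
  gold2 <- data.frame(
    food_a = "f9", food_b = "f8", shared_diseases = 1, summed_count = 12,
    stringsAsFactors = FALSE
  )
  expect_true(all(evaluate_recovery(calls, gold2)$n_recovered == 0))
})

test_that("downstream statistics: identical ES profiles give correlation 1;
           shared anti-correlated diseases are counted per pair", {
  res <- data.frame(
    query = rep(c("f1", "f2", "f3"), each = 3),
    reference = rep(c("d1", "d2", "d3"), 3),
    es = c(-0.9, -0.5, 0.2, -0.9, -0.5, 0.2, 0.1, 0.4, -0.3),
    p_value = 0.001, fdr = 0.001,
    class = c(
      "anti-correlated", "anti-correlated", "correlated",
      "anti-correlated", "anti-correlated", "correlated",
      "not-significant", "correlated", "anti-correlated"
    ),
    stringsAsFactors = FALSE
  )
  calls <- data.frame(
    food_a = c("f1", "f1", "f2"), food_b = c("f2", "f3", "f3"),
    call = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE
  )
  out <- synergy_downstream(calls, res)
  expect_equal(out$shared$shared_anti, c(2, 0, 0))
  # f1 and f2 have identical ES vectors across the 3 diseases
  expect_equal(out$profile_correlations$cor[1], 1)
  expect_lt(out$profile_correlations$p[1], 0.05)
})
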