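# KS tag scoring, bidirectional enrichment scores, permutation significance,
# ES-profile clustering and indication recovery.

test_that("KS tag score reproduces hand-evaluated cases", {
  genes <- paste0("g", 1:10)
  # tags at positions {1, 2}: a = max(0.4, 0.8), b = max(0.1, -0.3)
  expect_equal(ks_tag_score(genes[1:2], genes), 0.8)
  # tags at positions {9, 10}: symmetric bottom placement
  expect_equal(ks_tag_score(genes[9:10], genes), -0.9)
  # full coverage: no positional information
  expect_equal(ks_tag_score(genes, genes), 0)
  # unknown tags dropped with a warning
  expect_warning(s <- ks_tag_score(c("g1", "nope"), genes), "absent")
  expect_equal(s, ks_tag_score("g1", genes))
  expect_true(is.na(suppressWarnings(ks_tag_score("nope", genes))))
})

test_that("KS score depends on positions only and stays within [-1, 1]", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    genes <- paste0("g", sample(1e4, n)) # arbitrary labels
    tags <- sample(genes, sample(seq_len(n - 1), 1))
    s <- ks_tag_score(tags, genes)
    expect_gte(s, -1)
    expect_lte(s, 1)
    # relabeling genes leaves the score unchanged if positions are the same
    relabeled <- paste0("x", seq_len(n))
    s2 <- ks_tag_score(relabeled[match(tags, genes)], relabeled)
    expect_equal(s, s2)
  }
})

test_that("directional ES composes tag scores with the same-sign-zero rule", {
  genes <- paste0("g", 1:10)
  ref <- make_ranking(genes)
  q <- list(up = genes[1:2], down = genes[9:10], scorable = TRUE)
  expect_equal(directional_es(q, ref), (0.8 - (-0.9)) / 2) # 0.85
  # swapped query is exactly negated
  q_swap <- list(up = genes[9:10], down = genes[1:2], scorable = TRUE)
  expect_equal(directional_es(q_swap, ref), -0.85)
  # concordantly placed sets (same sign) score zero
  q_same <- list(up = genes[1:2], down = genes[3:4], scorable = TRUE)
  expect_equal(directional_es(q_same, ref), 0)
})

test_that("pair ES is positive for self, negated for a sign-flipped twin", {
  genes <- paste0("g", 1:40)
  a <- make_ranking(genes, up = genes[1:8], down = genes[33:40])
  self <- pair_es(a, a, min_tags = 5)
  expect_gt(self, 0)
  flipped <- make_ranking(rev(genes),
    up = genes[33:40], down = genes[1:8],
    entity = "twin"
  )
  expect_equal(pair_es(a, flipped, min_tags = 5), -self)
  # too few tags: unscored
  tiny <- make_ranking(genes, up = genes[1:2], down = genes[39:40])
  expect_true(is.na(pair_es(a, tiny, min_tags = 5)))
})

test_that("permutation significance honours the add-one convention and
           degenerate zero scores", {
  set.seed(1)
  n <- 60
  genes <- paste0("g", 1:n)
  # a strongly reversed pair: up tags at the bottom, down tags at the top
  q <- make_ranking(genes, up = genes[1:6], down = genes[(n - 5):n], entity = "q")
  # the reference ranks genes in reverse: its own up genes (top of its list)
  # sit at the bottom of the query's list and vice versa -> reversal
  ref <- make_ranking(rev(genes),
    up = genes[(n - 5):n], down = genes[1:6],
    entity = "r"
  )
  res <- score_pairs(list(q = q), list(r = ref), n_perm = 200, seed = 4)
  expect_equal(nrow(res), 1)
  expect_lt(res$es, 0)
  expect_gte(res$p_value, 1 / 201)
  expect_equal(res$class, "anti-correlated")
  # identical seed, identical result
  res2 <- score_pairs(list(q = q), list(r = ref), n_perm = 200, seed = 4)
  expect_identical(res, res2)
})

test_that("BH-adjusted values are monotone in the raw p-values", {
  st <- small_study()
  sigs <- lapply(names(st$datasets)[1:6], function(e) {
    suppressMessages(
      build_signature(st$datasets[[e]], entity = e, n_perm = 100, seed = 8)
    )
  })
  names(sigs) <- names(st$datasets)[1:6]
  is_dis <- grepl("^disease", names(sigs))
  res <- suppressWarnings(score_pairs(sigs[!is_dis], sigs[is_dis],
    n_perm = 150, seed = 2
  ))
  ok <- !is.na(res$p_value)
  ord <- order(res$p_value[ok])
  expect_true(all(diff(res$fdr[ok][ord]) >= -1e-12))
  expect_true(all(res$es[ok] >= -1 & res$es[ok] <= 1))
  # class invariant: anti-correlated implies negative es and fdr < 0.05
  anti <- res$class == "anti-correlated"
  expect_true(all(res$es[anti] < 0) && all(res$fdr[anti] < 0.05))
})

test_that("disease clustering recovers planted profile groups and honours
           the distance conventions", {
  # two identical profiles merge at distance zero
  prof <- rbind(
    d1 = c(1, 2, 3, 4), d2 = c(1, 2, 3, 4), d3 = c(4, 3, 2, 1)
  )
  cl <- cluster_diseases(prof, k = 2)
  m <- cl$hclust$merge[1, ]
  expect_setequal(rownames(prof)[-m[1:2]], c("d1", "d2"))
  expect_equal(cl$hclust$height[1], 0)
  # perfectly anti-correlated profiles sit at the maximal distance 2
  d <- 1 - cor(t(prof))
  expect_equal(max(d), 2)

  # planted two-group structure, between-group correlation ~ 0
  set.seed(9)
  base1 <- rnorm(30)
  base2 <- rnorm(30)
  prof2 <- rbind(
    a1 = base1 + rnorm(30, sd = 0.1), a2 = base1 + rnorm(30, sd = 0.1),
    a3 = base1 + rnorm(30, sd = 0.1),
    b1 = base2 + rnorm(30, sd = 0.1), b2 = base2 + rnorm(30, sd = 0.1),
    b3 = base2 + rnorm(30, sd = 0.1)
  )
  cl2 <- cluster_diseases(prof2, k = 2)
  expect_length(unique(cl2$clusters[c("a1", "a2", "a3")]), 1)
  expect_length(unique(cl2$clusters[c("b1", "b2", "b3")]), 1)
  expect_false(cl2$clusters[["a1"]] == cl2$clusters[["b1"]])
  # independent all-pairs correlation oracle: within-group correlations
  # exceed all between-group ones
  cors <- cor(t(prof2))
  within <- c(cors[1:3, 1:3][lower.tri(diag(3))],
    cors[4:6, 4:6][lower.tri(diag(3))])
  between <- as.vector(cors[1:3, 4:6])
  expect_gt(min(within), max(between))
  # newick serialization parses back to the same tip set
  tree <- ape::read.tree(text = cl2$newick)
  expect_setequal(tree$tip.label, rownames(prof2))
  # constant rows are flagged and pushed to maximal distance
  prof3 <- rbind(prof, flat = c(2, 2, 2, 2))
  cl3 <- cluster_diseases(prof3)
  expect_identical(cl3$constant_rows, "flat")
})

test_that("recovery statistics count known anti-correlated pairs and match
           an exhaustive Fisher enumeration", {
  res <- data.frame(
    query = rep(c("q1", "q2", "q3"), each = 2),
    reference = rep(c("r1", "r2"), 3),
    es = c(-0.5, 0.4, -0.6, -0.2, 0.3, 0.1),
    p_value = 0.01, fdr = 0.01,
    class = c(
      "anti-correlated", "correlated", "anti-correlated",
      "anti-correlated", "correlated", "not-significant"
    ),
    stringsAsFactors = FALSE
  )
  known <- data.frame(
    query = c("q1", "q2"), reference = c("r1", "r2"),
    stringsAsFactors = FALSE
  )
  out <- recovery_stats(res, known, class_map = c(r1 = "cA", r2 = "cA"))
  expect_equal(out$overall$n_recovered, 2)
  expect_equal(out$overall$n_known_scored, 2)
  # empty indication list: vacuous result, no error
  empty <- recovery_stats(res, known[0, , drop = FALSE])
  expect_equal(empty$overall$n_recovered, 0)
  # unknown reference skipped with warning
  expect_warning(
    recovery_stats(res, data.frame(query = "q1", reference = "zz")),
    "skipped"
  )

  # Fisher oracle: table (3,0,0,3) -> two-sided p = 0.1 by hypergeometric
  # enumeration over C(6,3) = 20 tables
  enum_p <- local({
    probs <- vapply(0:3, function(k) {
      choose(3, k) * choose(3, 3 - k) / choose(6, 3)
    }, numeric(1))
    p_obs <- probs[4]
    sum(probs[probs <= p_obs + 1e-12])
  })
  expect_equal(enum_p, 0.1)
  expect_equal(
    fisher.test(matrix(c(3, 0, 0, 3), 2))$p.value, enum_p,
    tolerance = 1e-12
  )
})
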