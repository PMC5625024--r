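# Rank-product statistics, permutation pfp, and the signature builder.

# build a dataset with prescribed per-gene fold changes (1 case, 1 control,
# noiseless)
fc_dataset <- function(fc, provenance = "toy") {
  genes <- names(fc)
  v <- cbind(ctrl = rep(0, length(fc)), case = as.numeric(fc))
  rownames(v) <- genes
  expression_dataset(v, c("control", "case"), provenance = provenance)
}

test_that("rank product equals the geometric mean of fold-change ranks", {
  # gene g1 ranked 2, 3, 4 across three datasets -> RP = 24^(1/3)
  g <- paste0("g", 1:5)
  ds <- list(
    fc_dataset(setNames(c(4, 5, 3, 2, 1), g)), # g1 descending rank 2
    fc_dataset(setNames(c(3, 5, 4, 2, 1), g)), # rank 3
    fc_dataset(setNames(c(2, 5, 4, 3, 1), g)) # rank 4
  )
  rp <- rank_product(ds, "up")
  expect_equal(unname(rp["g1"]), 24^(1 / 3))
  # a gene ranked 1 everywhere has the global minimum RP = 1
  expect_equal(unname(rp["g2"]), 1)
  # single dataset: RP equals the raw rank, ordering matches fold change
  rp1 <- rank_product(ds[1], "up")
  expect_equal(unname(rp1[paste0("g", 1:5)]), c(2, 1, 3, 4, 5))
})

test_that("rank product matches the brute-force oracle on an 8x3 toy and
           complementary ranks hold", {
  set.seed(101)
  genes <- paste0("g", 1:8)
  ds <- lapply(1:3, function(i) fc_dataset(setNames(rnorm(8), genes)))
  for (dir in c("up", "down")) {
    rp <- rank_product(ds, dir)
    oracle <- rp_oracle(ds, dir)
    expect_equal(as.numeric(rp[names(oracle)]), as.numeric(oracle),
      tolerance = 1e-12
    )
  }
  r_up <- attr(rank_product(ds, "up"), "ranks")
  r_down <- attr(rank_product(ds, "down"), "ranks")
  expect_true(all(r_up + r_down == 8 + 1))
})

test_that("rank statistics are invariant to strictly increasing transforms", {
  set.seed(7)
  genes <- paste0("g", 1:10)
  ds <- lapply(1:3, function(i) fc_dataset(setNames(rnorm(10), genes)))
  warped <- ds
  warped[[2]]$values <- exp(warped[[2]]$values) # monotone on all samples
  expect_equal(
    as.numeric(rank_product(ds, "up")),
    as.numeric(rank_product(warped, "up"))
  )
})

test_that("genes present in fewer than half the datasets are excluded and
           partial genes use available ranks", {
  g5 <- paste0("g", 1:5)
  d1 <- fc_dataset(setNames(c(5, 4, 3, 2, 1), g5))
  d2 <- fc_dataset(setNames(c(5, 4, 3), g5[1:3]))
  d3 <- fc_dataset(setNames(c(5, 4), g5[1:2]))
  rp <- rank_product(list(d1, d2, d3), "up")
  expect_false("g4" %in% names(rp)) # present in 1 of 3 only
  expect_true(all(c("g1", "g2", "g3") %in% names(rp)))
  expect_equal(unname(rp["g3"]), (3 * 3)^(1 / 2)) # 2 of 3 datasets
})

test_that("pfp agrees with exhaustive permutation enumeration on 5 genes x 2
           datasets", {
  genes <- paste0("g", 1:5)
  d1 <- fc_dataset(setNames(c(2.0, 1.5, 0.5, -0.5, -2.0), genes))
  d2 <- fc_dataset(setNames(c(1.8, 0.3, 1.2, -0.8, -1.6), genes))
  rp <- rank_product(list(d1, d2), "up")

  # exhaustive null: all (5!)^2 assignments of rank vectors to genes
  perm5 <- function() {
    out <- matrix(0L, 120, 5)
    i <- 0
    rec <- function(prefix, rest) {
      if (length(rest) == 0) {
        i <<- i + 1
        out[i, ] <<- prefix
        return()
      }
      for (r in rest) rec(c(prefix, r), setdiff(rest, r))
    }
    rec(integer(0), 1:5)
    out
  }
  p5 <- perm5()
  null_pool <- numeric(120 * 120 * 5)
  idx <- 0
  for (i in 1:120) {
    for (j in 1:120) {
      vals <- sqrt(p5[i, ] * p5[j, ])
      null_pool[(idx + 1):(idx + 5)] <- vals
      idx <- idx + 5
    }
  }
  n_pool <- length(null_pool)
  # tie tolerance: the implementation's geometric mean goes through
  # exp(mean(log(.))), the oracle through sqrt(); boundary ties must count
  p_exact <- vapply(rp, function(x) {
    (sum(null_pool <= x + 1e-9) + 1) / (n_pool + 1)
  }, numeric(1))
  pfp_exact <- p_exact * 5 / rank(rp, ties.method = "average")

  mc <- rp_significance(rp, n_perm = 400, seed = 99)
  # Monte-Carlo standard error of the p estimate, 3-sigma band
  se <- sqrt(p_exact * (1 - p_exact) / (5 * 400))
  expect_true(all(abs(mc$p - p_exact) <= 3 * se + 1e-9))
  expect_true(all(abs(mc$pfp - pfp_exact) <=
    (3 * se + 1e-9) * 5 / rank(rp, ties.method = "average")))
  # add-one bound: nothing can be smaller than 1/(n_genes*n_perm + 1)
  expect_true(all(mc$p >= 1 / (5 * 400 + 1)))
  # pfp of the top-ranked gene >= its p (rank-1 denominator)
  top <- which.min(mc$rp)
  expect_gte(mc$pfp[top], mc$p[top])
})

test_that("strongly separated planted signatures are fully recovered and
           label reversal swaps the calls exactly", {
  # effect far above the baseline spread, zero case noise: planted genes own
  # the extreme ranks in every replicate
  cfg <- sim_config(
    seed = 21, n_genes = 100, network_nodes = 50, module_size = 5,
    baseline_sd = 0.1, noise_sd = 0, effect_size = 3, samples_per_arm = 3,
    datasets_per_entity = 3
  )
  sig <- setNames(
    c(rep(1L, 5), rep(-1L, 5)),
    sprintf("g%04d", 1:10)
  )
  ds <- lapply(1:3, function(j) generate_expression_dataset(sig, cfg, seed = j))
  built <- suppressMessages(build_signature(ds, n_perm = 200, seed = 3))
  expect_true(all(names(sig)[sig == 1] %in% built$up_set))
  expect_true(all(names(sig)[sig == -1] %in% built$down_set))
  expect_length(intersect(built$up_set, built$down_set), 0)

  flipped <- lapply(ds, function(d) {
    expression_dataset(
      d$values,
      ifelse(d$sample_labels == "case", "control", "case"),
      provenance = d$provenance
    )
  })
  built_f <- suppressMessages(build_signature(flipped, n_perm = 200, seed = 3))
  expect_setequal(built_f$up_set, built$down_set)
  expect_setequal(built_f$down_set, built$up_set)
})

test_that("null data yields calibrated (conservative) DE calls", {
  cfg <- sim_config(
    seed = 33, n_genes = 100, network_nodes = 50, module_size = 5,
    datasets_per_entity = 2, samples_per_arm = 4
  )
  empty <- setNames(integer(0), character(0))
  rates <- vapply(1:25, function(s) {
    ds <- lapply(1:2, function(j) {
      generate_expression_dataset(empty, cfg, seed = 1000 * s + j)
    })
    built <- suppressMessages(build_signature(ds, n_perm = 100, seed = s))
    (length(built$up_set) + length(built$down_set)) / cfg$n_genes
  }, numeric(1))
  expect_lte(mean(rates), 0.05 * 2) # two directions, each controlled at 0.05
})

test_that("datasets without both arms are rejected by name", {
  v <- matrix(1, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  bad <- expression_dataset(v, c("case", "case"), provenance = "bad_ds")
  expect_error(fold_changes(bad), "bad_ds")
  expect_error(rank_product(list(bad), "up"), "bad_ds")
})
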