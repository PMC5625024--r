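# The generator's contracts: determinism, planted-truth consistency, and the
# limit cases of the reversal model.

test_that("configuration validation rejects inconsistent settings", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(reversal_fraction = 1.3), "reversal_fraction")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(
    sim_config(module_size = 600, network_nodes = 500),
    "module_size"
  )
  expect_error(
    sim_config(network_nodes = 10, edges_per_new_node = 10),
    "network_nodes"
  )
  expect_error(
    sim_config(pathway_size_range = c(50, 10)),
    "pathway_size_range"
  )
})

test_that("interactome generation yields a simple connected graph,
           deterministically", {
  g <- generate_interactome(100, 2, seed = 7)
  expect_equal(igraph::vcount(g), 100)
  expect_true(igraph::is_connected(g))
  expect_true(igraph::is_simple(g))
  g2 <- generate_interactome(100, 2, seed = 7)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))
  g3 <- generate_interactome(100, 2, seed = 8)
  expect_false(identical(igraph::as_edgelist(g), igraph::as_edgelist(g3)))
  expect_error(generate_interactome(10, 9, seed = 1), "exceed")
})

test_that("disease modules are connected induced subgraphs of the right
           size", {
  g <- generate_interactome(120, 3, seed = 2)
  for (s in 1:5) {
    mod <- generate_disease_module(g, 12, seed = s)
    expect_length(mod, 12)
    expect_true(igraph::is_connected(igraph::induced_subgraph(g, mod)))
  }
  expect_identical(
    generate_disease_module(g, 12, seed = 3),
    generate_disease_module(g, 12, seed = 3)
  )
  # exhaustion: module of the full graph order is the entire node set
  small <- generate_interactome(10, 2, seed = 1)
  expect_setequal(
    generate_disease_module(small, 10, seed = 1),
    igraph::V(small)$name
  )
  expect_error(generate_disease_module(small, 11, seed = 1), "exceeds")
})

test_that("full reversal plants exactly opposite signatures and zero
           reversal plants none", {
  cfg1 <- sim_config(
    seed = 5, n_genes = 300, network_nodes = 150, module_size = 10,
    n_diseases = 3, n_foods = 4, n_drugs = 2, reversal_fraction = 1,
    plant_synergy = FALSE
  )
  st <- suppressMessages(simulate_study(cfg1))
  anti <- subset(st$truth$pair_labels, label == "anti-correlated" &
    entity %in% names(st$truth$food_signatures))
  expect_gt(nrow(anti), 0)
  for (i in seq_len(nrow(anti))) {
    fs <- st$truth$food_signatures[[anti$entity[i]]]
    ds <- st$truth$disease_signatures[[anti$disease[i]]]
    shared <- intersect(names(fs), names(ds))
    expect_setequal(shared, names(ds)) # full coverage
    expect_true(all(fs[shared] == -ds[shared]))
  }

  cfg0 <- sim_config(
    seed = 5, n_genes = 300, network_nodes = 150, module_size = 10,
    n_diseases = 3, n_foods = 4, n_drugs = 2, reversal_fraction = 0
  )
  st0 <- suppressMessages(simulate_study(cfg0))
  expect_false(any(st0$truth$pair_labels$label == "anti-correlated"))
})

test_that("realized reversal share matches the configured fraction within
           one gene, and labels are recomputable", {
  st <- small_study()
  rf <- st$config$reversal_fraction
  truth <- st$truth
  # exclude synergy foods: they cover max(0.6, rf) by design
  syn_foods <- unique(c(truth$synergy_pairs$food_a, truth$synergy_pairs$food_b))
  anti <- subset(
    truth$pair_labels,
    label == "anti-correlated" & !(entity %in% syn_foods) &
      entity %in% names(truth$food_signatures)
  )
  expect_gt(nrow(anti), 0)
  for (i in seq_len(nrow(anti))) {
    fs <- truth$food_signatures[[anti$entity[i]]]
    ds <- truth$disease_signatures[[anti$disease[i]]]
    shared <- intersect(names(fs), names(ds))
    n_opp <- sum(fs[shared] == -ds[shared])
    expect_lte(abs(n_opp - ceiling(rf * length(ds))), 1)
  }
  # planted-label consistency: recomputation reproduces pair_labels exactly
  recomputed <- signed_agreement_labels(
    c(truth$food_signatures, truth$drug_signatures),
    truth$disease_signatures
  )
  expect_identical(
    recomputed$label,
    truth$pair_labels$label[
      match(
        paste(recomputed$entity, recomputed$disease),
        paste(truth$pair_labels$entity, truth$pair_labels$disease)
      )
    ]
  )
})

test_that("planted synergy pairs pass the gold-standard criteria and nothing
           else does", {
  st <- small_study()
  gold <- build_gold_standard(st$truth$reference_table)
  expect_setequal(
    paste(gold$food_a, gold$food_b),
    paste(st$truth$synergy_pairs$food_a, st$truth$synergy_pairs$food_b)
  )
})

test_that("expression generation honours the noiseless limit, the null
           signature and determinism", {
  cfg <- sim_config(
    seed = 9, n_genes = 50, network_nodes = 20, module_size = 5,
    baseline_sd = 0, noise_sd = 0, samples_per_arm = 3
  )
  sig <- setNames(c(1L, -1L), c("g0001", "g0002"))
  ds <- generate_expression_dataset(sig, cfg, seed = 4)
  fc <- fold_changes(ds)
  expect_equal(unname(fc["g0001"]), cfg$effect_size)
  expect_equal(unname(fc["g0002"]), -cfg$effect_size)
  expect_true(all(fc[setdiff(names(fc), names(sig))] == 0))

  empty <- generate_expression_dataset(
    setNames(integer(0), character(0)), cfg,
    seed = 4
  )
  expect_true(all(fold_changes(empty) == 0))

  cfg2 <- sim_config(seed = 9, n_genes = 50, network_nodes = 20,
    module_size = 5)
  d1 <- generate_expression_dataset(sig, cfg2, seed = 11)
  d2 <- generate_expression_dataset(sig, cfg2, seed = 11)
  expect_identical(d1$values, d2$values)
  expect_error(
    generate_expression_dataset(setNames(1L, "nope"), cfg2, seed = 1),
    "universe"
  )
})

test_that("annotation limits hold: zero dropout covers every gene, zero
           ambiguity yields a functional probe map", {
  cfg <- sim_config(
    seed = 3, n_genes = 100, network_nodes = 50, module_size = 5,
    ortholog_dropout = 0, ambiguous_probe_share = 0
  )
  orth <- generate_ortholog_table(cfg, seed = 3)
  expect_setequal(orth$human_gene, gene_universe(cfg))
  pm <- generate_probe_map(cfg, seed = 3)
  expect_false(any(duplicated(pm$probe)))
  # with ambiguity: flagged probes map to two genes
  cfg2 <- sim_config(
    seed = 3, n_genes = 100, network_nodes = 50, module_size = 5,
    ambiguous_probe_share = 0.2
  )
  pm2 <- generate_probe_map(cfg2, seed = 3)
  expect_gt(sum(duplicated(pm2$probe)), 0)
  amb <- pm2$probe[duplicated(pm2$probe)]
  per_probe <- table(unique(pm2[pm2$probe %in% amb, ])$probe)
  expect_true(all(per_probe >= 2))
})

test_that("identical configuration and seed reproduce the whole study", {
  cfg <- function() {
    sim_config(
      seed = 17, n_genes = 200, network_nodes = 100, module_size = 8,
      n_diseases = 2, n_foods = 4, n_drugs = 2, datasets_per_entity = 2
    )
  }
  s1 <- suppressMessages(simulate_study(cfg()))
  s2 <- suppressMessages(simulate_study(cfg()))
  expect_identical(
    igraph::as_edgelist(s1$graph),
    igraph::as_edgelist(s2$graph)
  )
  expect_identical(s1$truth$food_signatures, s2$truth$food_signatures)
  expect_identical(
    s1$datasets$food01$food01_ds1$values,
    s2$datasets$food01$food01_ds1$values
  )
  expect_identical(s1$annotations$probe_map, s2$annotations$probe_map)
})

test_that("all emitted files round-trip through the readers", {
  st <- small_study()
  dir <- withr::local_tempdir()
  write_simulation(st, dir)
  # expression + labels
  nm <- names(st$raw_datasets$food01)[1]
  back <- read_expression_tsv(
    file.path(dir, "expression", paste0(nm, ".tsv")),
    level = "probe"
  )
  expect_equal(back$values, st$raw_datasets$food01[[1]]$values)
  expect_identical(back$sample_labels, st$raw_datasets$food01[[1]]$sample_labels)
  # GMT
  pws <- read_gmt(file.path(dir, "pathways.gmt"))
  expect_identical(
    lapply(pws, identity),
    lapply(st$annotations$pathways, identity)[names(pws)]
  )
  # edge list: same graph up to edge order
  g <- read_edge_list(file.path(dir, "interactome.tsv"))
  expect_equal(igraph::ecount(g), igraph::ecount(st$graph))
  expect_true(igraph::identical_graphs(
    igraph::permute(g, match(igraph::V(g)$name, igraph::V(st$graph)$name)),
    st$graph
  ) || setequal(
    apply(igraph::as_edgelist(g), 1, function(r) paste(sort(r), collapse = "|")),
    apply(
      igraph::as_edgelist(st$graph), 1,
      function(r) paste(sort(r), collapse = "|")
    )
  ))
  # truth JSON
  tr <- read_truth_json(file.path(dir, "truth.json"))
  expect_identical(tr$disease_signatures, st$truth$disease_signatures)
  expect_identical(tr$food_signatures, st$truth$food_signatures)
  expect_equal(tr$synergy_pairs, st$truth$synergy_pairs)
})
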