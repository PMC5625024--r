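#' Configuration for an end-to-end pipeline run
#'
#' Bundles the synthetic-study configuration with every stage parameter. The
#' defaults reproduce the method's reference settings: FDR thresholds of
#' 0.05 throughout, 1,000 permutations for the enrichment-score significance,
#' and the 0.4 Tanimoto cutoff for structural similarity.
#'
#' @param sim a [sim_config()].
#' @param alpha FDR / pfp threshold used by every stage (default 0.05).
#' @param rp_n_perm rank-product permutations (default 100; the per-gene null
#'   pool is `n_genes`-fold larger than the per-pair ES null, so fewer draws
#'   suffice).
#' @param es_n_perm enrichment-score permutations (default 1000).
#' @param cap,min_tags query tag-set capping (defaults 250 / 5).
#' @param prox_n_random,prox_bin_min proximity null draws and degree-bin
#'   minimum (defaults 1000 / 100).
#' @param tanimoto_cutoff structural-similarity cutoff (default 0.4).
#' @param syn_n_perm synergy-call permutations (default 1000).
#' @param cluster_k flat clusters cut from the disease dendrogram (default
#'   2).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            alpha = 0.05,
                            rp_n_perm = 100L,
                            es_n_perm = 1000L,
                            cap = 250L,
                            min_tags = 5L,
                            prox_n_random = 1000L,
                            prox_bin_min = 100L,
                            tanimoto_cutoff = 0.4,
                            syn_n_perm = 1000L,
                            cluster_k = 2L) {
  stopifnot(inherits(sim, "sim_config"))
  assert_fraction(alpha, "alpha")
  structure(
    list(
      sim = sim, alpha = alpha, rp_n_perm = as.integer(rp_n_perm),
      es_n_perm = as.integer(es_n_perm), cap = as.integer(cap),
      min_tags = as.integer(min_tags),
      prox_n_random = as.integer(prox_n_random),
      prox_bin_min = as.integer(prox_bin_min),
      tanimoto_cutoff = tanimoto_cutoff,
      syn_n_perm = as.integer(syn_n_perm),
      cluster_k = as.integer(cluster_k)
    ),
    class = "pipeline_config"
  )
}

stage_classes <- function(entities, prefix) {
  grepl(paste0("^", prefix), entities)
}

#' Run the full pipeline on a synthetic study
#'
#' Executes every stage in order — simulate, preprocess, differential
#' expression, connectivity scoring + disease clustering, pathway space,
#' network proximity, chemical similarity, synergy — optionally writing all
#' stage outputs (plain TSV/GMT/Newick/JSON) plus a manifest with seeds and
#' file checksums under `out_dir`. Rerunning with the same configuration and
#' seed reproduces every output byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list of stage results: `study`, `preprocessed`, `signatures`,
#'   `connectivity` (food/drug results, profiles, clustering, recovery),
#'   `pathway_space`, `proximity`, `chemsim`, `synergy`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$sim$seed
  t_all <- list()
  tick <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(value = val, secs = proc.time()[["elapsed"]] - t0)
  }

  # -- simulate ---------------------------------------------------------
  st <- tick(simulate_study(config$sim))
  study <- st$value
  t_all$simulate <- st$secs
  truth <- study$truth
  ann <- study$annotations

  # -- preprocess -------------------------------------------------------
  st <- tick({
    lapply(study$raw_datasets, function(reps) {
      lapply(reps, preprocess_dataset,
        probe_map = ann$probe_map,
        ortholog_table = ann$ortholog_table
      )
    })
  })
  preprocessed <- st$value
  t_all$preprocess <- st$secs

  # -- differential expression -----------------------------------------
  st <- tick({
    sigs <- vector("list", length(preprocessed))
    names(sigs) <- names(preprocessed)
    for (i in seq_along(preprocessed)) {
      sigs[[i]] <- build_signature(
        preprocessed[[i]],
        entity = names(preprocessed)[i],
        alpha = config$alpha, n_perm = config$rp_n_perm,
        seed = derive_seed(seed, "rankprod", index = i)
      )
    }
    sigs
  })
  signatures <- st$value
  t_all$de <- st$secs

  is_food <- stage_classes(names(signatures), "food")
  is_drug <- stage_classes(names(signatures), "drug")
  is_disease <- stage_classes(names(signatures), "disease")
  food_sigs <- signatures[is_food]
  drug_sigs <- signatures[is_drug]
  disease_sigs <- signatures[is_disease]

  # -- connectivity -----------------------------------------------------
  st <- tick({
    food_res <- score_pairs(
      food_sigs, disease_sigs,
      n_perm = config$es_n_perm, alpha = config$alpha,
      cap = config$cap, min_tags = config$min_tags,
      seed = derive_seed(seed, "es", index = 1L)
    )
    drug_res <- score_pairs(
      drug_sigs, disease_sigs,
      n_perm = config$es_n_perm, alpha = config$alpha,
      cap = config$cap, min_tags = config$min_tags,
      seed = derive_seed(seed, "es", index = 2L)
    )
    drug_profile <- es_profile_matrix(drug_res)
    clustering <- if (nrow(drug_profile) >= 3L) {
      cluster_diseases(drug_profile, k = config$cluster_k)
    } else {
      NULL
    }
    recovery <- recovery_stats(
      drug_res,
      data.frame(
        query = truth$known_indications$drug,
        reference = truth$known_indications$disease,
        stringsAsFactors = FALSE
      ),
      class_map = truth$disease_classes
    )
    list(
      food_results = food_res, drug_results = drug_res,
      food_profile = es_profile_matrix(food_res),
      drug_profile = drug_profile,
      clustering = clustering, recovery = recovery
    )
  })
  connectivity <- st$value
  t_all$connect <- st$secs

  # -- pathway space ----------------------------------------------------
  st <- tick({
    de_union <- lapply(signatures, function(s) c(s$up_set, s$down_set))
    enr <- lapply(de_union, function(genes) {
      tab <- enrich_pathways(genes, ann$pathways, alpha = config$alpha)
      tab$pathway[tab$enriched]
    })
    anti <- rbind(
      data.frame(
        entity = connectivity$food_results$query,
        disease = connectivity$food_results$reference,
        entity_class = "diet",
        class = connectivity$food_results$class,
        stringsAsFactors = FALSE
      ),
      data.frame(
        entity = connectivity$drug_results$query,
        disease = connectivity$drug_results$reference,
        entity_class = "drug",
        class = connectivity$drug_results$class,
        stringsAsFactors = FALSE
      )
    )
    anti <- anti[anti$class == "anti-correlated", , drop = FALSE]
    anti$disease_class <- truth$disease_classes[anti$disease]
    score_mat <- if (nrow(anti) > 0L) {
      build_score_matrix(enr[!is_disease], anti)
    } else {
      NULL
    }
    pca <- if (!is.null(score_mat) && nrow(score_mat) >= 3L &&
      ncol(score_mat) >= 2L) {
      pca_scores(score_mat)
    } else {
      NULL
    }
    top_shared <- if (nrow(anti) > 0L) {
      top_disease_pathways(enr, anti[, c("entity", "disease")])
    } else {
      NULL
    }
    list(
      enrichments = enr, anti_pairs = anti, score_matrix = score_mat,
      pca = pca, top_disease_pathways = top_shared
    )
  })
  pathway_space <- st$value
  t_all$pathways <- st$secs

  # -- proximity --------------------------------------------------------
  st <- tick({
    de_union <- lapply(signatures[!is_disease], function(s) {
      c(s$up_set, s$down_set)
    })
    anti <- pathway_space$anti_pairs
    prox <- if (nrow(anti) > 0L) {
      tab <- proximity_table(
        de_union, truth$disease_modules, study$graph,
        pairs = anti[, c("entity", "disease")],
        n_random = config$prox_n_random, bin_min = config$prox_bin_min,
        seed = derive_seed(seed, "proximity")
      )
      tab$entity_class <- anti$entity_class[
        match(
          paste(tab$entity, tab$disease),
          paste(anti$entity, anti$disease)
        )
      ]
      classify_proximal(tab)
    } else {
      NULL
    }
    prox
  })
  proximity <- st$value
  t_all$proximity <- st$secs

  # -- chemical similarity ---------------------------------------------
  st <- tick({
    sim <- similar_food_drug_pairs(
      ann$food_compounds[, c("entity", "compound_id", "smiles")],
      ann$drug_compounds[, c("entity", "compound_id", "smiles")],
      cutoff = config$tanimoto_cutoff
    )
    shared <- compare_shared_diseases(
      sim$pairs, connectivity$food_results, connectivity$drug_results
    )
    list(similar = sim, shared_diseases = shared)
  })
  chemsim <- st$value
  t_all$chemsim <- st$secs

  # -- synergy ----------------------------------------------------------
  st <- tick({
    enr <- pathway_space$enrichments
    fn_enr <- lapply(
      lapply(food_sigs, function(s) c(s$up_set, s$down_set)),
      function(genes) {
        tab <- enrich_pathways(genes, ann$functions, alpha = config$alpha)
        tab$pathway[tab$enriched]
      }
    )
    scores <- score_food_pairs(
      food_sigs,
      enrich_pathway = enr[names(food_sigs)],
      enrich_function = fn_enr
    )
    calls <- call_synergy(
      food_sigs, scores,
      n_perm = config$syn_n_perm,
      alpha = config$alpha, seed = derive_seed(seed, "synergy")
    )
    gold <- build_gold_standard(truth$reference_table)
    recovery <- evaluate_recovery(calls, gold)
    downstream <- synergy_downstream(calls, connectivity$food_results)
    list(
      calls = calls, gold = gold, recovery = recovery,
      downstream = downstream
    )
  })
  synergy <- st$value
  t_all$synergy <- st$secs

  result <- list(
    config = config, study = study, preprocessed = preprocessed,
    signatures = signatures, connectivity = connectivity,
    pathway_space = pathway_space, proximity = proximity,
    chemsim = chemsim, synergy = synergy
  )
  if (!is.null(out_dir)) {
    result$manifest <- write_pipeline_outputs(result, out_dir, t_all)
  }
  result
}

#' Write all pipeline stage outputs and a manifest
#'
#' @param result list returned by [run_pipeline()].
#' @param out_dir output directory.
#' @param timings named list of stage runtimes in seconds (optional).
#' @return the manifest (also written as `manifest.json`), invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir, timings = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_simulation(result$study, file.path(out_dir, "sim"))

  sig_dir <- file.path(out_dir, "signatures")
  dir.create(sig_dir, showWarnings = FALSE)
  for (nm in names(result$signatures)) {
    write_signature_tsv(
      result$signatures[[nm]],
      file.path(sig_dir, paste0(nm, ".tsv"))
    )
  }

  write_tsv(
    result$connectivity$food_results,
    file.path(out_dir, "pairs_food.tsv")
  )
  write_tsv(
    result$connectivity$drug_results,
    file.path(out_dir, "pairs_drug.tsv")
  )
  prof <- result$connectivity$drug_profile
  write_tsv(
    data.frame(disease = rownames(prof), prof, check.names = FALSE),
    file.path(out_dir, "es_profile_drug.tsv")
  )
  if (!is.null(result$connectivity$clustering)) {
    writeLines(
      result$connectivity$clustering$newick,
      file.path(out_dir, "disease_dendrogram.nwk")
    )
  }
  if (!is.null(result$pathway_space$score_matrix)) {
    sm <- result$pathway_space$score_matrix
    write_tsv(
      data.frame(group = rownames(sm), sm, check.names = FALSE),
      file.path(out_dir, "pathway_score_matrix.tsv")
    )
  }
  if (!is.null(result$proximity)) {
    write_tsv(
      result$proximity$results,
      file.path(out_dir, "proximity.tsv")
    )
  }
  write_tsv(
    result$chemsim$similar$edges,
    file.path(out_dir, "chem_edges.tsv")
  )
  write_tsv(result$synergy$calls, file.path(out_dir, "synergy.tsv"))
  write_tsv(result$synergy$recovery, file.path(out_dir, "synergy_recovery.tsv"))

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = result$config$sim$seed,
    parameters = result$config[setdiff(names(result$config), "sim")],
    sim = unclass(result$config$sim),
    stage_runtimes_s = timings,
    files = data.frame(
      path = sub(paste0("^", out_dir, "/?"), "", files),
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}
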