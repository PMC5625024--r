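#' Simulate a complete synthetic study
#'
#' Generates every input the pipeline consumes, with planted ground truth:
#' the interactome and disease modules, signed signatures for all entities
#' (including designated anti-correlated, correlated and synergistic
#' relations), replicate case/control expression datasets per entity, and the
#' annotation bundle (pathway and function gene sets, ortholog table, probe
#' map, compound tables, reference-count table).
#'
#' Two views of the expression data are returned: `datasets` holds the clean
#' gene-level matrices, while `raw_datasets` holds what a real study would
#' start from — probe-level matrices with missing values and ambiguous
#' probes, and (when `datasets_per_entity >= 2`) one replicate per entity
#' recast as a mouse dataset that must pass through ortholog mapping.
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_study`: list with `config`, `graph`,
#'   `truth`, `annotations`, `datasets`, `raw_datasets`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(
#'   seed = 7, n_genes = 200, network_nodes = 100,
#'   n_diseases = 2, n_foods = 4, n_drugs = 2
#' ))
#' names(study$truth$food_signatures)
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  universe <- gene_universe(config)
  graph <- generate_interactome(
    config$network_nodes, config$edges_per_new_node, config$seed,
    gene_ids = universe
  )
  diseases <- entity_names("disease", config$n_diseases)
  modules <- lapply(seq_along(diseases), function(i) {
    generate_disease_module(
      graph, config$module_size,
      seed = derive_seed(config$seed, "module", index = i)
    )
  })
  names(modules) <- diseases
  truth <- generate_signatures(config, modules)
  annotations <- generate_annotations(config, truth, config$seed)

  all_sigs <- c(
    truth$disease_signatures, truth$food_signatures, truth$drug_signatures
  )
  datasets <- vector("list", length(all_sigs))
  raw <- vector("list", length(all_sigs))
  names(datasets) <- names(raw) <- names(all_sigs)
  for (i in seq_along(all_sigs)) {
    entity <- names(all_sigs)[i]
    reps <- lapply(seq_len(config$datasets_per_entity), function(j) {
      generate_expression_dataset(
        all_sigs[[entity]], config,
        seed = derive_seed(config$seed, "expression", index = i * 1000L + j),
        provenance = sprintf("%s_ds%d", entity, j)
      )
    })
    names(reps) <- sprintf("%s_ds%d", entity, seq_along(reps))
    datasets[[entity]] <- reps
    raw[[entity]] <- lapply(seq_along(reps), function(j) {
      if (j == 2L) {
        as_model_organism(reps[[j]], annotations$ortholog_table)
      } else {
        expand_to_probes(
          reps[[j]], annotations$probe_map, config,
          seed = derive_seed(config$seed, "probes", index = i * 1000L + j)
        )
      }
    })
    names(raw[[entity]]) <- names(reps)
  }

  structure(
    list(
      config = config, graph = graph, truth = truth,
      annotations = annotations, datasets = datasets, raw_datasets = raw
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d entities x %d datasets, %d genes, network %d nodes\n",
    length(x$datasets), x$config$datasets_per_entity, x$config$n_genes,
    igraph::vcount(x$graph)
  ))
  print(x$truth)
  invisible(x)
}

#' Write a simulated study to a directory of plain-text files
#'
#' Emits every artifact in the pipeline's exchange formats: probe-/gene-level
#' expression TSVs with label sidecars under `expression/`, GMT collections,
#' the interactome edge list, ortholog/probe maps, compound and reference
#' tables, disease-gene sets (GMT) and the truth JSON.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(file.path(dir, "expression"),
    recursive = TRUE,
    showWarnings = FALSE
  )
  for (entity in names(study$raw_datasets)) {
    reps <- study$raw_datasets[[entity]]
    for (nm in names(reps)) {
      write_expression_tsv(
        reps[[nm]],
        file.path(dir, "expression", paste0(nm, ".tsv"))
      )
    }
  }
  write_gmt(study$annotations$pathways, file.path(dir, "pathways.gmt"))
  write_gmt(study$annotations$functions, file.path(dir, "functions.gmt"))
  write_gmt(study$truth$disease_modules, file.path(dir, "disease_genes.gmt"))
  write_edge_list(study$graph, file.path(dir, "interactome.tsv"))
  write_tsv(study$annotations$ortholog_table, file.path(dir, "orthologs.tsv"))
  write_tsv(study$annotations$probe_map, file.path(dir, "probe_map.tsv"))
  write_tsv(
    study$annotations$food_compounds[, c("entity", "compound_id", "smiles")],
    file.path(dir, "food_compounds.tsv")
  )
  write_tsv(
    study$annotations$drug_compounds[, c("entity", "compound_id", "smiles")],
    file.path(dir, "drug_compounds.tsv")
  )
  write_tsv(study$truth$reference_table, file.path(dir, "references.tsv"))
  write_truth_json(study$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
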