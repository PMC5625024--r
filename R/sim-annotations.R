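# Built-in fixture of valid canonical SMILES for ~30 common small molecules
# (dietary phytochemicals, vitamins, simple drugs). Hard-coded so no
# chemistry download is ever needed; used to populate synthetic food/drug
# compound tables.
.smiles_fixture <- c(
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  ethanol = "CCO",
  glucose = "OCC1OC(O)C(O)C(O)C1O",
  fructose = "OCC1(O)OCC(O)C(O)C1O",
  citric_acid = "OC(=O)CC(O)(C(=O)O)CC(=O)O",
  ascorbic_acid = "OCC(O)C1OC(=O)C(O)=C1O",
  quercetin = "Oc1cc(O)c2c(c1)oc(-c1ccc(O)c(O)c1)c(O)c2=O",
  resveratrol = "Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1",
  curcumin = "COc1cc(/C=C/C(=O)CC(=O)/C=C/c2ccc(O)c(OC)c2)ccc1O",
  capsaicin = "COc1cc(CNC(=O)CCCC/C=C/C(C)C)ccc1O",
  menthol = "CC(C)C1CCC(C)CC1O",
  vanillin = "COc1cc(C=O)ccc1O",
  limonene = "CC(=C)C1CCC(C)=CC1",
  ibuprofen = "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
  paracetamol = "CC(=O)Nc1ccc(O)cc1",
  naproxen = "COc1ccc2cc(C(C)C(=O)O)ccc2c1",
  metformin = "CN(C)C(=N)NC(=N)N",
  salicylic_acid = "OC(=O)c1ccccc1O",
  nicotine = "CN1CCCC1c1cccnc1",
  catechin = "Oc1cc(O)c2c(c1)OC(c1ccc(O)c(O)c1)C(O)C2",
  gallic_acid = "OC(=O)c1cc(O)c(O)c(O)c1",
  cinnamaldehyde = "O=C/C=C/c1ccccc1",
  eugenol = "C=CCc1ccc(O)c(OC)c1",
  allicin = "C=CCSS(=O)CC=C",
  sulforaphane = "CS(=O)CCCCN=C=S",
  lycopene_frag = "CC(C)=CCC/C(C)=C/C=C/C(C)=C/C=C/C(C)=C/C=O",
  melatonin = "COc1ccc2[nH]cc(CCNC(C)=O)c2c1",
  folate_frag = "Nc1nc2ncc(CNc3ccc(C(=O)O)cc3)nc2c(=O)[nH]1",
  lauric_acid = "CCCCCCCCCCCC(=O)O"
)

#' The built-in SMILES fixture library
#'
#' @return named character vector of canonical SMILES strings.
#' @export
smiles_fixture <- function() .smiles_fixture

#' Generate a synthetic pathway collection
#'
#' Random gene sets within the configured size range; the first
#' `n_diseases` pathways are each seeded with at least 60% of one disease
#' module, so module-driven enrichment is detectable downstream.
#'
#' @param config a [sim_config()].
#' @param truth a `planted_truth` (supplies disease modules).
#' @param seed integer seed.
#' @return named list of gene-id character vectors with attribute
#'   `universe`.
#' @export
generate_pathway_collection <- function(config, truth, seed) {
  set.seed(derive_seed(seed, "annotations", index = 1L))
  universe <- gene_universe(config)
  rng <- config$pathway_size_range
  if (rng[1] > config$n_genes) {
    stop("pathway_size_range infeasible for the gene universe", call. = FALSE)
  }
  modules <- truth$disease_modules
  n_seeded <- min(length(modules), config$n_pathways)
  paths <- vector("list", config$n_pathways)
  names(paths) <- sprintf("pw%03d", seq_len(config$n_pathways))
  for (i in seq_len(config$n_pathways)) {
    size <- sample(seq.int(rng[1], rng[2]), 1L)
    if (i <= n_seeded) {
      mod <- modules[[i]]
      core <- sample(mod, ceiling(0.8 * length(mod)))
      size <- max(size, length(core))
      filler <- sample(setdiff(universe, core), size - length(core))
      paths[[i]] <- sort(c(core, filler))
    } else {
      paths[[i]] <- sort(sample(universe, size))
    }
  }
  attr(paths, "universe") <- universe
  paths
}

#' Generate a synthetic ortholog table
#'
#' One model-organism identifier (`m_<gene>`) per human gene, with an
#' `ortholog_dropout` share of genes omitted — emulating incomplete homology
#' annotation between species.
#'
#' @inheritParams generate_pathway_collection
#' @return data.frame with columns `model_gene`, `human_gene`.
#' @export
generate_ortholog_table <- function(config, seed) {
  set.seed(derive_seed(seed, "annotations", index = 2L))
  universe <- gene_universe(config)
  n_drop <- floor(config$ortholog_dropout * length(universe))
  keep <- sort(sample(universe, length(universe) - n_drop))
  data.frame(
    model_gene = paste0("m_", keep), human_gene = keep,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic probe map
#'
#' Assigns one to three probes to every gene; an `ambiguous_probe_share`
#' share of probes is additionally mapped to a second random gene (expressed
#' as repeated probe rows), making them removable by the multi-mapping filter.
#'
#' @inheritParams generate_pathway_collection
#' @return data.frame with columns `probe`, `gene`.
#' @export
generate_probe_map <- function(config, seed) {
  set.seed(derive_seed(seed, "annotations", index = 3L))
  universe <- gene_universe(config)
  n_probes_per_gene <- sample(1:3, length(universe), replace = TRUE)
  genes <- rep(universe, n_probes_per_gene)
  probes <- sprintf("p%05d", seq_along(genes))
  map <- data.frame(probe = probes, gene = genes, stringsAsFactors = FALSE)
  n_amb <- floor(config$ambiguous_probe_share * nrow(map))
  if (n_amb > 0L) {
    amb_idx <- sample(nrow(map), n_amb)
    second <- data.frame(
      probe = map$probe[amb_idx],
      gene = sample(universe, n_amb, replace = TRUE),
      stringsAsFactors = FALSE
    )
    # a self-pairing would not be a true multi-mapping; nudge those
    clash <- second$gene == map$gene[amb_idx]
    if (any(clash)) {
      second$gene[clash] <- universe[
        (match(second$gene[clash], universe) %% length(universe)) + 1L
      ]
    }
    map <- rbind(map, second)
  }
  map[order(map$probe), , drop = FALSE]
}

#' Generate food and drug compound tables
#'
#' Each food and drug receives one to five compounds drawn from the built-in
#' SMILES fixture. Designated food/drug pairs (`food01`/`drug01`, ...) share a
#' structurally identical compound, guaranteeing a downstream Tanimoto of 1.
#'
#' @inheritParams generate_pathway_collection
#' @param n_identical_pairs number of designated identical-compound
#'   food/drug pairs.
#' @return list with data.frames `food_compounds`, `drug_compounds` (columns
#'   `entity`, `compound_id`, `smiles`) and `designated_similar`
#'   (`food`, `drug`, `smiles_name`).
#' @export
generate_compound_tables <- function(config, seed, n_identical_pairs = 2L) {
  set.seed(derive_seed(seed, "annotations", index = 4L))
  foods <- entity_names("food", config$n_foods)
  drugs <- entity_names("drug", config$n_drugs)
  lib <- smiles_fixture()
  n_pairs <- min(n_identical_pairs, length(foods), length(drugs))
  shared <- sample(names(lib), n_pairs)

  draw <- function(entities, prefix, forced) {
    rows <- list()
    cid <- 0L
    for (i in seq_along(entities)) {
      picks <- sample(names(lib), sample(1:5, 1L))
      if (!is.na(forced[i])) picks <- union(picks, forced[i])
      for (nm in picks) {
        cid <- cid + 1L
        rows[[cid]] <- data.frame(
          entity = entities[i],
          compound_id = sprintf("%s%03d", prefix, cid),
          smiles = unname(lib[nm]), smiles_name = nm,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  }
  forced_f <- c(shared, rep(NA_character_, length(foods) - n_pairs))
  forced_d <- c(shared, rep(NA_character_, length(drugs) - n_pairs))
  list(
    food_compounds = draw(foods, "fc", forced_f),
    drug_compounds = draw(drugs, "dc", forced_d),
    designated_similar = data.frame(
      food = foods[seq_len(n_pairs)], drug = drugs[seq_len(n_pairs)],
      smiles_name = shared, stringsAsFactors = FALSE
    )
  )
}

#' Generate the full annotation bundle
#'
#' @inheritParams generate_pathway_collection
#' @return list with `pathways`, `functions` (a second, independent gene-set
#'   collection used for function-overlap similarity), `ortholog_table`,
#'   `probe_map`, `food_compounds`, `drug_compounds`, `designated_similar`.
#' @export
generate_annotations <- function(config, truth, seed) {
  pathways <- generate_pathway_collection(config, truth, seed)
  # second collection ("functions") for the rank-aggregation synergy input:
  # same construction, independent draw
  set.seed(derive_seed(seed, "annotations", index = 5L))
  universe <- gene_universe(config)
  rng <- config$pathway_size_range
  funcs <- lapply(seq_len(config$n_pathways), function(i) {
    sort(sample(universe, sample(seq.int(rng[1], rng[2]), 1L)))
  })
  names(funcs) <- sprintf("fn%03d", seq_len(config$n_pathways))
  attr(funcs, "universe") <- universe
  compounds <- generate_compound_tables(config, seed)
  list(
    pathways = pathways,
    functions = funcs,
    ortholog_table = generate_ortholog_table(config, seed),
    probe_map = generate_probe_map(config, seed),
    food_compounds = compounds$food_compounds,
    drug_compounds = compounds$drug_compounds,
    designated_similar = compounds$designated_similar
  )
}
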