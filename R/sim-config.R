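#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data generator: how many entities of
#' each class to simulate, the per-dataset expression model (a two-group
#' Gaussian shift on the log2 scale), the planted signature-reversal strength,
#' and the sizes of the synthetic interactome, pathway collection and
#' annotation maps. Identical configuration plus identical seed yields
#' byte-identical outputs everywhere downstream.
#'
#' The defaults define the study conditions used throughout the package's own
#' validation: an effect-to-noise ratio of 3 (`effect_size / noise_sd`), a
#' reversal fraction of 0.8 for planted therapeutic (anti-correlated)
#' diet-disease pairs, three replicate datasets per entity, and five samples
#' per arm — a small but realistic emulation of curated case/control microarray
#' collections.
#'
#' @param seed master integer seed; all stage seeds derive from it.
#' @param n_genes size of the gene universe.
#' @param n_diseases,n_foods,n_drugs entity counts per class.
#' @param datasets_per_entity replicate expression datasets per entity.
#' @param samples_per_arm case and control sample count per dataset.
#' @param baseline_mean,baseline_sd per-gene baseline expression level and sample-to-sample standard deviation (log2 scale).
#' @param effect_size shift added to (subtracted from) case samples for
#'   up- (down-) regulated signature genes, log2 units.
#' @param noise_sd additional case-arm noise standard deviation, log2 units.
#' @param reversal_fraction fraction of a disease signature that a planted
#'   anti-correlated food reverses (direction flipped). `0` disables all
#'   reversal planting.
#' @param extra_de_fraction fraction of the gene universe added to each
#'   food/drug signature as unrelated differential genes.
#' @param network_nodes,edges_per_new_node synthetic interactome size and
#'   preferential-attachment density.
#' @param module_size disease module size (connected subgraph).
#' @param n_pathways,pathway_size_range pathway collection shape.
#' @param ortholog_dropout fraction of model-organism genes missing from the
#'   ortholog table.
#' @param ambiguous_probe_share share of probes mapped to two genes.
#' @param missing_rate per-probe probability of carrying missing values.
#' @param plant_synergy plant synergistic food pairs (pairs of foods jointly
#'   covering one disease's reversal with partial overlap)?
#' @return an object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 200, network_nodes = 100)
#' cfg$effect_size / cfg$noise_sd
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       n_diseases = 6L,
                       n_foods = 8L,
                       n_drugs = 6L,
                       datasets_per_entity = 3L,
                       samples_per_arm = 5L,
                       baseline_mean = 8,
                       baseline_sd = 0.5,
                       effect_size = 1.5,
                       noise_sd = 0.5,
                       reversal_fraction = 0.8,
                       extra_de_fraction = 0.02,
                       network_nodes = 500L,
                       edges_per_new_node = 3L,
                       module_size = 25L,
                       n_pathways = 60L,
                       pathway_size_range = c(10L, 50L),
                       ortholog_dropout = 0.1,
                       ambiguous_probe_share = 0.05,
                       missing_rate = 0.02,
                       plant_synergy = TRUE) {
  assert_count(seed, "seed", min = 0L)
  assert_count(n_genes, "n_genes")
  assert_count(n_diseases, "n_diseases")
  assert_count(n_foods, "n_foods")
  assert_count(n_drugs, "n_drugs")
  assert_count(datasets_per_entity, "datasets_per_entity")
  assert_count(samples_per_arm, "samples_per_arm")
  assert_number(baseline_mean, "baseline_mean")
  assert_number(baseline_sd, "baseline_sd", min = 0)
  assert_number(effect_size, "effect_size", min = 0)
  assert_number(noise_sd, "noise_sd", min = 0)
  assert_fraction(reversal_fraction, "reversal_fraction")
  assert_fraction(extra_de_fraction, "extra_de_fraction")
  assert_count(network_nodes, "network_nodes")
  assert_count(edges_per_new_node, "edges_per_new_node")
  assert_count(module_size, "module_size")
  assert_count(n_pathways, "n_pathways")
  assert_fraction(ortholog_dropout, "ortholog_dropout")
  assert_fraction(ambiguous_probe_share, "ambiguous_probe_share")
  assert_fraction(missing_rate, "missing_rate")

  if (network_nodes <= edges_per_new_node) {
    stop("'network_nodes' must exceed 'edges_per_new_node'", call. = FALSE)
  }
  if (module_size > network_nodes) {
    stop("'module_size' must not exceed 'network_nodes'", call. = FALSE)
  }
  if (network_nodes > n_genes) {
    stop("'network_nodes' must not exceed 'n_genes' (nodes are genes)",
      call. = FALSE
    )
  }
  if (length(pathway_size_range) != 2L ||
    any(pathway_size_range < 1) ||
    pathway_size_range[1] > pathway_size_range[2] ||
    pathway_size_range[2] > n_genes) {
    stop("'pathway_size_range' must be (min, max) with max <= n_genes",
      call. = FALSE
    )
  }
  # 2 * module_size genes make up a disease signature (module + off-module).
  if (2L * module_size > n_genes) {
    stop("gene universe too small for disease signatures (need 2*module_size)",
      call. = FALSE
    )
  }

  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_diseases = as.integer(n_diseases), n_foods = as.integer(n_foods),
    n_drugs = as.integer(n_drugs),
    datasets_per_entity = as.integer(datasets_per_entity),
    samples_per_arm = as.integer(samples_per_arm),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    effect_size = effect_size, noise_sd = noise_sd,
    reversal_fraction = reversal_fraction,
    extra_de_fraction = extra_de_fraction,
    network_nodes = as.integer(network_nodes),
    edges_per_new_node = as.integer(edges_per_new_node),
    module_size = as.integer(module_size),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    ortholog_dropout = ortholog_dropout,
    ambiguous_probe_share = ambiguous_probe_share,
    missing_rate = missing_rate,
    plant_synergy = isTRUE(plant_synergy)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf(
    "  genes: %d | diseases: %d | foods: %d | drugs: %d\n",
    x$n_genes, x$n_diseases, x$n_foods, x$n_drugs
  ))
  cat(sprintf(
    "  %d dataset(s)/entity, %d samples/arm; effect %.2f, noise sd %.2f\n",
    x$datasets_per_entity, x$samples_per_arm, x$effect_size, x$noise_sd
  ))
  cat(sprintf(
    "  reversal fraction %.2f; network %d nodes (m = %d), module size %d\n",
    x$reversal_fraction, x$network_nodes, x$edges_per_new_node, x$module_size
  ))
  cat(sprintf("  master seed %d\n", x$seed))
  invisible(x)
}

#' Gene, entity and feature identifiers of the synthetic universe
#'
#' @param config a [sim_config()].
#' @return character vector of gene identifiers (`g0001`, ...).
#' @export
gene_universe <- function(config) {
  sprintf("g%04d", seq_len(config$n_genes))
}

entity_names <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))
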