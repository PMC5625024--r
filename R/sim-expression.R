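#' Construct an expression dataset object
#'
#' A light container for one normalized gene-by-sample expression matrix with
#' case/control labels, mirroring a curated two-arm intervention dataset.
#'
#' @param values numeric matrix, genes as rows (rownames = gene ids), samples
#'   as columns (colnames = sample ids).
#' @param sample_labels character/factor vector, one of `"case"`/`"control"`
#'   per column.
#' @param species species tag (`"human"`, `"mouse"`, ...).
#' @param provenance free-text source tag.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, sample_labels, species = "human",
                               provenance = "synthetic") {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  sample_labels <- as.character(sample_labels)
  if (length(sample_labels) != ncol(values)) {
    stop("one sample label per column required", call. = FALSE)
  }
  if (!all(sample_labels %in% c("case", "control"))) {
    stop("sample labels must be 'case' or 'control'", call. = FALSE)
  }
  structure(
    list(
      values = values, sample_labels = sample_labels,
      species = species, provenance = provenance
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %d genes x %d samples (%d case / %d control), %s [%s]\n",
    nrow(x$values), ncol(x$values),
    sum(x$sample_labels == "case"), sum(x$sample_labels == "control"),
    x$species, x$provenance
  ))
  invisible(x)
}

#' Simulate one case/control expression dataset around a planted signature
#'
#' Two-group Gaussian shift model on the log2 scale: control values are i.i.d.
#' `Normal(baseline_mean, baseline_sd^2)` per gene; case values additionally
#' receive `+effect_size` for up-regulated signature genes, `-effect_size` for
#' down-regulated ones, plus `Normal(0, noise_sd^2)` case-arm noise. In the
#' noiseless limit (`baseline_sd = noise_sd = 0`) the case-control difference
#' is exactly `±effect_size` on signature genes and zero elsewhere.
#'
#' @param signature signed gene set (named vector of +1/-1); must be a subset
#'   of the gene universe.
#' @param config a [sim_config()].
#' @param seed integer seed; fixed seed implies an identical matrix.
#' @param provenance source tag recorded on the dataset.
#' @return an [expression_dataset()].
#' @export
generate_expression_dataset <- function(signature, config, seed,
                                        provenance = "synthetic") {
  stopifnot(inherits(config, "sim_config"))
  universe <- gene_universe(config)
  if (!all(names(signature) %in% universe)) {
    stop("signature genes outside the gene universe", call. = FALSE)
  }
  set.seed(derive_seed(seed, "expression"))
  n_g <- config$n_genes
  n_arm <- config$samples_per_arm
  n_s <- 2L * n_arm
  base <- matrix(
    rnorm(n_g * n_s, mean = config$baseline_mean, sd = config$baseline_sd),
    nrow = n_g
  )
  rownames(base) <- universe
  colnames(base) <- c(
    sprintf("ctrl_%02d", seq_len(n_arm)),
    sprintf("case_%02d", seq_len(n_arm))
  )
  labels <- rep(c("control", "case"), each = n_arm)
  case_cols <- which(labels == "case")
  if (length(signature) > 0L) {
    shift <- config$effect_size * as.numeric(signature)
    base[names(signature), case_cols] <-
      base[names(signature), case_cols, drop = FALSE] + shift
  }
  if (config$noise_sd > 0) {
    base[, case_cols] <- base[, case_cols, drop = FALSE] +
      matrix(rnorm(n_g * n_arm, sd = config$noise_sd), nrow = n_g)
  }
  expression_dataset(base, labels, species = "human", provenance = provenance)
}

#' Expand a gene-level dataset to probe level
#'
#' Re-expresses a gene-level matrix on its probe map so the probe-filtering
#' and collapsing stages can be exercised: each probe row copies its gene's
#' values; probes mapped to two genes (ambiguous) copy the first gene;
#' a `missing_rate` share of probes receives missing values, a third of those
#' heavily enough (> 20% of samples) to trigger removal.
#'
#' @param dataset an [expression_dataset()] (gene level).
#' @param probe_map data.frame with columns `probe`, `gene` (multi-mapping as
#'   repeated probe rows).
#' @param config a [sim_config()] (supplies `missing_rate`).
#' @param seed integer seed.
#' @return a `probe_matrix` object (see [probe_matrix()]).
#' @export
expand_to_probes <- function(dataset, probe_map, config, seed) {
  stopifnot(inherits(dataset, "expression_dataset"))
  set.seed(derive_seed(seed, "probes"))
  first_gene <- probe_map[!duplicated(probe_map$probe), ]
  keep <- first_gene$gene %in% rownames(dataset$values)
  first_gene <- first_gene[keep, ]
  vals <- dataset$values[first_gene$gene, , drop = FALSE]
  rownames(vals) <- first_gene$probe
  n_s <- ncol(vals)
  miss_probes <- which(runif(nrow(vals)) < config$missing_rate)
  for (p in miss_probes) {
    heavy <- runif(1) < 1 / 3
    n_miss <- if (heavy) ceiling(0.3 * n_s) else max(1L, floor(0.1 * n_s))
    vals[p, sample(n_s, n_miss)] <- NA_real_
  }
  probe_matrix(vals, dataset$sample_labels,
    species = dataset$species,
    provenance = dataset$provenance
  )
}

#' Recast a human gene-level dataset as a model-organism dataset
#'
#' Relabels rows with model-organism gene identifiers via the ortholog table
#' (inverse direction) and drops genes absent from it, emulating a mouse or
#' rat dataset whose analysis must pass through ortholog mapping.
#'
#' @param dataset an [expression_dataset()] with human gene ids.
#' @param ortholog_table data.frame with columns `model_gene`, `human_gene`.
#' @param species species tag to record (default `"mouse"`).
#' @return an [expression_dataset()] with model-organism row names.
#' @export
as_model_organism <- function(dataset, ortholog_table, species = "mouse") {
  idx <- match(rownames(dataset$values), ortholog_table$human_gene)
  keep <- !is.na(idx)
  vals <- dataset$values[keep, , drop = FALSE]
  rownames(vals) <- ortholog_table$model_gene[idx[keep]]
  expression_dataset(vals, dataset$sample_labels,
    species = species,
    provenance = dataset$provenance
  )
}
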