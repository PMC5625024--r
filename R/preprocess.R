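#' Construct a probe-level matrix object
#'
#' @param values numeric matrix, probes as rows (unique rownames), samples as
#'   columns; may contain `NA`.
#' @param sample_labels `"case"`/`"control"` per column.
#' @param species species tag.
#' @param provenance source tag.
#' @return object of class `probe_matrix`.
#' @export
probe_matrix <- function(values, sample_labels, species = "human",
                         provenance = "unknown") {
  stopifnot(is.matrix(values), nrow(values) == 0L || !is.null(rownames(values)))
  if (nrow(values) > 0L && anyDuplicated(rownames(values))) {
    stop("probe ids must be unique", call. = FALSE)
  }
  sample_labels <- as.character(sample_labels)
  if (length(sample_labels) != ncol(values)) {
    stop("one sample label per column required", call. = FALSE)
  }
  structure(
    list(
      values = values, sample_labels = sample_labels,
      species = species, provenance = provenance
    ),
    class = "probe_matrix"
  )
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf(
    "<probe_matrix> %d probes x %d samples, %.1f%% missing, %s [%s]\n",
    nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values)),
    x$species, x$provenance
  ))
  invisible(x)
}

# probes mapping to exactly one gene, per the annotation
unambiguous_probes <- function(probe_map) {
  counts <- table(unique(probe_map[, c("probe", "gene")])$probe)
  names(counts)[counts == 1L]
}

#' Filter unreliable probes
#'
#' Removes probes that map to multiple gene identifiers and probes with
#' missing values in more than 20% of samples ("over 20%": a probe at exactly
#' the 20% boundary is retained). Probes absent from the map cannot be
#' assigned a gene and are removed as well. Probe order is preserved.
#'
#' @param matrix a [probe_matrix()].
#' @param probe_map data.frame with columns `probe`, `gene`; multi-mapping is
#'   expressed as repeated probe rows.
#' @param max_missing maximum tolerated missing fraction (default 0.2).
#' @return a filtered [probe_matrix()].
#' @export
filter_probes <- function(matrix, probe_map, max_missing = 0.2) {
  stopifnot(inherits(matrix, "probe_matrix"))
  ok_map <- unambiguous_probes(probe_map)
  missing_frac <- rowMeans(is.na(matrix$values))
  keep <- rownames(matrix$values) %in% ok_map & missing_frac <= max_missing
  if (!any(keep)) {
    warning("no probes survive filtering", call. = FALSE)
  }
  probe_matrix(
    matrix$values[keep, , drop = FALSE], matrix$sample_labels,
    species = matrix$species, provenance = matrix$provenance
  )
}

#' Collapse a filtered probe matrix to gene level
#'
#' Multiple probes of one gene are averaged per sample (arithmetic mean,
#' ignoring missing entries); any entry still missing afterwards is imputed
#' with the gene's row mean, so downstream rank statistics see complete
#' columns. Genes whose rows are entirely missing are dropped with a warning.
#'
#' @param matrix a [probe_matrix()] (already filtered).
#' @param probe_map data.frame with columns `probe`, `gene`.
#' @return an [expression_dataset()] with one row per gene.
#' @export
collapse_to_genes <- function(matrix, probe_map) {
  stopifnot(inherits(matrix, "probe_matrix"))
  map <- unique(probe_map[, c("probe", "gene")])
  map <- map[map$probe %in% rownames(matrix$values), , drop = FALSE]
  gene_of <- setNames(map$gene, map$probe)
  genes <- gene_of[rownames(matrix$values)]
  if (anyNA(genes)) {
    stop("filtered matrix contains unmapped probes", call. = FALSE)
  }
  vals <- matrix$values
  # per-sample mean over each gene's probes, NA-aware
  sums <- rowsum(ifelse(is.na(vals), 0, vals), genes)
  ns <- rowsum((!is.na(vals)) * 1, genes)
  out <- sums / ns # 0/0 -> NaN where all probes missing in a sample
  out[ns == 0] <- NA_real_
  all_missing <- rowSums(!is.na(out)) == 0L
  if (any(all_missing)) {
    warning(
      sum(all_missing), " gene(s) dropped: all values missing",
      call. = FALSE
    )
    out <- out[!all_missing, , drop = FALSE]
  }
  nas <- which(is.na(out), arr.ind = TRUE)
  if (nrow(nas) > 0L) {
    rmeans <- rowMeans(out, na.rm = TRUE)
    out[nas] <- rmeans[nas[, 1]]
  }
  out <- out[order(rownames(out)), , drop = FALSE]
  expression_dataset(out, matrix$sample_labels,
    species = matrix$species, provenance = matrix$provenance
  )
}

#' Map a model-organism dataset onto human orthologs
#'
#' Relabels rows to human gene identifiers using the ortholog table and drops
#' genes without a human ortholog. When several model genes map to the same
#' human gene, their rows are averaged after relabeling (consistent with the
#' probe-collapsing rule). Human datasets pass through unchanged.
#'
#' @param dataset an [expression_dataset()].
#' @param ortholog_table data.frame with columns `model_gene`, `human_gene`;
#'   required unless the dataset is human.
#' @return an [expression_dataset()] on human identifiers.
#' @export
map_orthologs <- function(dataset, ortholog_table = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (identical(dataset$species, "human")) {
    return(dataset)
  }
  if (is.null(ortholog_table)) {
    stop("non-human dataset requires an ortholog table", call. = FALSE)
  }
  idx <- match(rownames(dataset$values), ortholog_table$model_gene)
  keep <- !is.na(idx)
  if (!any(keep)) {
    stop(
      "no genes of dataset '", dataset$provenance,
      "' found in the ortholog table",
      call. = FALSE
    )
  }
  vals <- dataset$values[keep, , drop = FALSE]
  human <- ortholog_table$human_gene[idx[keep]]
  collapsed <- rowsum(vals, human) / as.vector(table(human)[sort(unique(human))])
  collapsed <- collapsed[order(rownames(collapsed)), , drop = FALSE]
  expression_dataset(collapsed, dataset$sample_labels,
    species = "human", provenance = dataset$provenance
  )
}

#' Run the full preprocessing path on one raw dataset
#'
#' Probe-level matrices are filtered and collapsed; model-organism gene-level
#' datasets are ortholog-mapped; human gene-level datasets pass through.
#'
#' @param x a [probe_matrix()] or [expression_dataset()].
#' @param probe_map probe annotation (for probe-level input).
#' @param ortholog_table ortholog annotation (for non-human input).
#' @return an [expression_dataset()] on human gene identifiers.
#' @export
preprocess_dataset <- function(x, probe_map = NULL, ortholog_table = NULL) {
  if (inherits(x, "probe_matrix")) {
    if (is.null(probe_map)) stop("probe-level input needs a probe map")
    x <- collapse_to_genes(filter_probes(x, probe_map), probe_map)
  }
  map_orthologs(x, ortholog_table)
}
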