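# Plain-text readers/writers for every artifact the pipeline exchanges:
# TSV matrices with label sidecars, GMT gene sets, edge lists, two-column
# maps, compound/reference tables and the truth JSON. All stage outputs are
# text so each stage is independently runnable and diffable.

write_tsv <- function(df, path) {
  write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE
  )
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write / read an expression matrix with its label sidecar
#'
#' The matrix is written genes-as-rows with an `id` first column and a header
#' row of sample identifiers; arm labels go to a two-column sidecar TSV
#' (`sample`, `label`).
#'
#' @param x an [expression_dataset()] or `probe_matrix`.
#' @param path matrix TSV path.
#' @param labels_path sidecar TSV path; defaults to `<path>.labels.tsv`.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path,
                                 labels_path = paste0(path, ".labels.tsv")) {
  df <- data.frame(id = rownames(x$values), x$values, check.names = FALSE)
  write_tsv(df, path)
  write_tsv(
    data.frame(
      sample = colnames(x$values), label = x$sample_labels,
      species = x$species, provenance = x$provenance
    ),
    labels_path
  )
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param level `"gene"` returns an [expression_dataset()], `"probe"` a
#'   [probe_matrix()].
#' @export
read_expression_tsv <- function(path,
                                labels_path = paste0(path, ".labels.tsv"),
                                level = c("gene", "probe")) {
  level <- match.arg(level)
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  lab <- read_tsv(labels_path)
  stopifnot(identical(lab$sample, colnames(m)))
  species <- lab$species[1] %||% "human"
  prov <- lab$provenance[1] %||% "unknown"
  if (level == "gene") {
    expression_dataset(m, lab$label, species = species, provenance = prov)
  } else {
    probe_matrix(m, lab$label, species = species, provenance = prov)
  }
}

#' Write / read gene-set collections in GMT format
#'
#' One set per line: name, description, then tab-separated members.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' Write / read an undirected interactome as a two-column edge list
#'
#' @param graph an igraph graph with named nodes.
#' @param path file path.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  write_tsv(data.frame(a = el[, 1], b = el[, 2]), path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- read_tsv(path)
  igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
}

#' Write / read a differential-expression signature table
#'
#' Columns: `gene`, `logfc`, `rp_up`, `rp_down`, `pfp_up`, `pfp_down`,
#' `call` (`up`/`down`/`ns`), ordered by combined log fold change.
#'
#' @param sig a `signature_ranking` (see [build_signature()]).
#' @param path file path.
#' @export
write_signature_tsv <- function(sig, path) {
  write_tsv(sig$table, path)
}

#' @rdname write_signature_tsv
#' @param entity entity tag to attach on read.
#' @export
read_signature_tsv <- function(path, entity = NULL) {
  tab <- read_tsv(path)
  signature_ranking(tab, entity %||% sub("\\.tsv$", "", basename(path)))
}

#' Serialize / restore the planted truth as JSON
#'
#' Signed gene sets become `{gene: direction}` maps; tables become arrays of
#' records.
#'
#' @param truth a `planted_truth`.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  enc_sig <- function(s) as.list(setNames(as.integer(s), names(s)))
  payload <- list(
    disease_classes = as.list(truth$disease_classes),
    disease_signatures = lapply(truth$disease_signatures, enc_sig),
    food_signatures = lapply(truth$food_signatures, enc_sig),
    drug_signatures = lapply(truth$drug_signatures, enc_sig),
    pair_labels = truth$pair_labels,
    disease_modules = truth$disease_modules,
    synergy_pairs = truth$synergy_pairs,
    known_indications = truth$known_indications,
    reference_table = truth$reference_table
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec_sig <- function(s) setNames(as.integer(unlist(s)), names(s))
  truth <- list(
    disease_classes = unlist(payload$disease_classes),
    disease_signatures = lapply(payload$disease_signatures, dec_sig),
    food_signatures = lapply(payload$food_signatures, dec_sig),
    drug_signatures = lapply(payload$drug_signatures, dec_sig),
    pair_labels = as.data.frame(payload$pair_labels),
    disease_modules = lapply(payload$disease_modules, unlist),
    synergy_pairs = as.data.frame(payload$synergy_pairs),
    known_indications = as.data.frame(payload$known_indications),
    reference_table = as.data.frame(payload$reference_table)
  )
  class(truth) <- "planted_truth"
  truth
}
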