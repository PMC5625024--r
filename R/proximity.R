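# Interactome closest-distance proximity: the average over an entity's DE
# genes of the shortest-path distance to the nearest disease gene, z-scored
# against random node sets matched to the observed degree distributions.
# Analysis is restricted to the network's largest connected component.

#' Largest connected component of a graph
#'
#' @param graph an igraph graph.
#' @return the induced subgraph of the largest component.
#' @export
largest_component <- function(graph) {
  comp <- igraph::components(graph)
  keep <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(graph, keep)
}

#' Closest-distance proximity between two node sets
#'
#' `d_c = mean over t in from_set of min over s in to_set of d(t, s)` with
#' unweighted hop distances. Members not mapped into the graph's largest
#' connected component are dropped (and counted); either set empty after
#' mapping makes the pair unscorable.
#'
#' @param from_set,to_set character vectors of node names (entity DE genes,
#'   disease genes).
#' @param graph an igraph graph (restricted internally to its LCC), or a
#'   precomputed all-pairs distance matrix with dimnames.
#' @return list with `d_c`, `n_mapped_from`, `n_mapped_to` (`d_c` is `NA`
#'   when unscorable).
#' @export
closest_distance <- function(from_set, to_set, graph) {
  if (is.matrix(graph)) {
    dmat <- graph
    nodes <- rownames(dmat)
    from <- intersect(from_set, nodes)
    to <- intersect(to_set, nodes)
    if (length(from) == 0L || length(to) == 0L) {
      return(list(
        d_c = NA_real_, n_mapped_from = length(from),
        n_mapped_to = length(to)
      ))
    }
    sub <- dmat[from, to, drop = FALSE]
  } else {
    lcc <- largest_component(graph)
    nodes <- igraph::V(lcc)$name
    from <- intersect(from_set, nodes)
    to <- intersect(to_set, nodes)
    if (length(from) == 0L || length(to) == 0L) {
      return(list(
        d_c = NA_real_, n_mapped_from = length(from),
        n_mapped_to = length(to)
      ))
    }
    sub <- igraph::distances(lcc, v = from, to = to)
  }
  list(
    d_c = mean(apply(sub, 1, min)),
    n_mapped_from = length(from), n_mapped_to = length(to)
  )
}

#' Degree bins for degree-matched null sampling
#'
#' Nodes are grouped by degree; adjacent degree values are merged (ascending)
#' until every bin holds at least `bin_min` nodes, and a trailing small bin
#' is merged into its predecessor. With fewer than `bin_min` nodes in total,
#' a single bin is used with a warning.
#'
#' @param graph an igraph graph.
#' @param bin_min minimum nodes per bin (default 100).
#' @return list with `bin_of` (named integer: node -> bin index) and `bins`
#'   (list of node-name vectors).
#' @export
degree_bins <- function(graph, bin_min = 100L) {
  deg <- igraph::degree(graph)
  if (length(deg) < bin_min) {
    warning("graph smaller than bin_min; using a single degree bin",
      call. = FALSE
    )
    return(list(
      bin_of = setNames(rep(1L, length(deg)), names(deg)),
      bins = list(names(deg))
    ))
  }
  degs <- sort(unique(deg))
  bins <- list()
  current <- character(0)
  for (d in degs) {
    current <- c(current, names(deg)[deg == d])
    if (length(current) >= bin_min) {
      bins[[length(bins) + 1L]] <- current
      current <- character(0)
    }
  }
  if (length(current) > 0L) {
    if (length(bins) == 0L) {
      bins[[1L]] <- current
    } else {
      bins[[length(bins)]] <- c(bins[[length(bins)]], current)
    }
  }
  bin_of <- integer(0)
  for (i in seq_along(bins)) {
    bin_of[bins[[i]]] <- i
  }
  list(bin_of = bin_of, bins = bins)
}

# one degree-matched random replacement of a node set: sample, within each
# bin, as many nodes as the set has in that bin (without replacement)
sample_degree_matched <- function(node_set, bins) {
  counts <- table(bins$bin_of[node_set])
  unlist(lapply(names(counts), function(b) {
    pool <- bins$bins[[as.integer(b)]]
    k <- counts[[b]]
    if (k >= length(pool)) pool else sample(pool, k)
  }), use.names = FALSE)
}

#' Proximity z-score against degree-matched random node sets
#'
#' Draws `n_random` null instances in which both node sets are replaced by
#' degree-matched random sets (sampling without replacement within degree
#' bins of at least `bin_min` nodes), recomputes the closest distance for
#' each, and standardizes the observed value:
#' `z_c = (d_c - mean_null) / sd_null`. `z_c < 0` means the entity's genes
#' are closer to the disease genes than chance ("proximal").
#'
#' @param from_set,to_set node-name vectors (entity DE genes, disease genes).
#' @param graph an igraph graph; analysis restricted to its LCC.
#' @param n_random null draws (default 1000).
#' @param bin_min minimum nodes per degree bin (default 100).
#' @param seed integer seed; identical seed gives an identical z-score.
#' @param entity,disease tags carried into the result.
#' @return one-row data.frame: `entity`, `disease`, `d_c`, `null_mean`,
#'   `null_sd`, `z_c`, `n_mapped_entity`, `n_mapped_disease`, `degenerate`.
#' @export
proximity_z <- function(from_set, to_set, graph, n_random = 1000L,
                        bin_min = 100L, seed = 1L,
                        entity = "entity", disease = "disease") {
  lcc <- largest_component(graph)
  dmat <- igraph::distances(lcc)
  obs <- closest_distance(from_set, to_set, dmat)
  if (is.na(obs$d_c)) {
    return(data.frame(
      entity = entity, disease = disease, d_c = NA_real_,
      null_mean = NA_real_, null_sd = NA_real_, z_c = NA_real_,
      n_mapped_entity = obs$n_mapped_from,
      n_mapped_disease = obs$n_mapped_to, degenerate = TRUE,
      stringsAsFactors = FALSE
    ))
  }
  bins <- degree_bins(lcc, bin_min)
  from <- intersect(from_set, rownames(dmat))
  to <- intersect(to_set, rownames(dmat))
  set.seed(derive_seed(seed, "proximity"))
  null_d <- vapply(seq_len(n_random), function(b) {
    rf <- sample_degree_matched(from, bins)
    rt <- sample_degree_matched(to, bins)
    mean(apply(dmat[rf, rt, drop = FALSE], 1, min))
  }, numeric(1))
  mu <- mean(null_d)
  sdv <- sd(null_d)
  z <- if (sdv == 0) NA_real_ else (obs$d_c - mu) / sdv
  data.frame(
    entity = entity, disease = disease, d_c = obs$d_c,
    null_mean = mu, null_sd = sdv, z_c = z,
    n_mapped_entity = obs$n_mapped_from,
    n_mapped_disease = obs$n_mapped_to,
    degenerate = sdv == 0, stringsAsFactors = FALSE
  )
}

#' Proximity of every entity DE set to every disease module
#'
#' @param entity_sets named list: entity -> DE gene vector (union of
#'   significant up and down genes, uncapped).
#' @param disease_sets named list: disease -> disease-gene vector.
#' @param graph the interactome.
#' @param pairs optional data.frame (`entity`, `disease`) restricting which
#'   pairs are scored (e.g. the anti-correlated ones); default: all crosses.
#' @inheritParams proximity_z
#' @return data.frame, one row per scored pair.
#' @export
proximity_table <- function(entity_sets, disease_sets, graph,
                            pairs = NULL, n_random = 1000L, bin_min = 100L,
                            seed = 1L) {
  if (is.null(pairs)) {
    pairs <- expand.grid(
      entity = names(entity_sets), disease = names(disease_sets),
      stringsAsFactors = FALSE
    )
  }
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    proximity_z(
      entity_sets[[pairs$entity[i]]], disease_sets[[pairs$disease[i]]],
      graph,
      n_random = n_random, bin_min = bin_min,
      seed = derive_seed(seed, "proximity", index = i),
      entity = pairs$entity[i], disease = pairs$disease[i]
    )
  })
  do.call(rbind, out)
}

#' Classify pairs as proximal or distant and compare entity classes
#'
#' Proximal means `z_c < 0`; the boundary `z_c = 0` is distant. When an
#' `entity_class` column is present (diet/drug), the 2x2 cross-tab of class
#' by proximal/distant is tested with a two-sided Fisher's exact test.
#'
#' @param results data.frame from [proximity_table()], optionally with an
#'   `entity_class` column.
#' @return list with `results` (input plus `label`), `cross_tab`, `fisher_p`
#'   (both `NULL` without an `entity_class` column or with one class only).
#' @export
classify_proximal <- function(results) {
  results$label <- ifelse(
    is.na(results$z_c), NA_character_,
    ifelse(results$z_c < 0, "proximal", "distant")
  )
  cross <- NULL
  p <- NULL
  if ("entity_class" %in% names(results)) {
    ok <- !is.na(results$label)
    if (length(unique(results$entity_class[ok])) == 2L) {
      cross <- table(
        results$entity_class[ok],
        factor(results$label[ok], c("proximal", "distant"))
      )
      p <- fisher.test(cross)$p.value
    }
  }
  list(results = results, cross_tab = cross, fisher_p = p)
}
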