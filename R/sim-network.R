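#' Generate a synthetic interactome
#'
#' Builds a simple connected undirected graph by preferential attachment
#' (Barabasi-Albert growth), which gives the heavy-tailed degree distribution
#' characteristic of protein-protein interaction networks. Node labels are
#' drawn from the synthetic gene universe so network analyses and expression
#' analyses share identifiers.
#'
#' @param n_nodes number of nodes; must exceed `edges_per_new_node`.
#' @param edges_per_new_node edges attached by each incoming node.
#' @param seed integer seed; the same call with the same seed returns an
#'   identical edge set.
#' @param gene_ids optional character vector (length >= `n_nodes`) to label
#'   nodes; defaults to `g0001...`.
#' @return an [igraph::graph] object, simple and connected.
#' @export
generate_interactome <- function(n_nodes, edges_per_new_node, seed,
                                 gene_ids = NULL) {
  assert_count(n_nodes, "n_nodes")
  assert_count(edges_per_new_node, "edges_per_new_node")
  if (n_nodes <= edges_per_new_node + 1L) {
    # n_nodes = m + 1 would force the complete graph: no preferential
    # attachment, no heavy tail
    stop("'n_nodes' must exceed 'edges_per_new_node'", call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(n_nodes))
  if (length(gene_ids) < n_nodes) {
    stop("'gene_ids' shorter than 'n_nodes'", call. = FALSE)
  }
  set.seed(derive_seed(seed, "interactome"))
  g <- igraph::sample_pa(
    n_nodes,
    m = edges_per_new_node, directed = FALSE,
    algorithm = "psumtree" # forbids multi-edges; growth forbids self-loops
  )
  labels <- sample(gene_ids, n_nodes)
  igraph::V(g)$name <- labels
  stopifnot(igraph::is_simple(g), igraph::is_connected(g))
  g
}

#' Grow a connected disease module on a graph
#'
#' Starts from a random node and repeatedly absorbs a uniformly random member
#' of the current frontier (seeded random breadth-style expansion), so the
#' induced subgraph of the returned node set is connected by construction —
#' mirroring the observation that disease-associated proteins aggregate in
#' connected interactome neighbourhoods.
#'
#' @param graph an igraph graph with named nodes.
#' @param module_size number of nodes to select; at most the graph order.
#' @param seed integer seed.
#' @return character vector of node names, length `module_size`.
#' @export
generate_disease_module <- function(graph, module_size, seed) {
  assert_count(module_size, "module_size")
  n <- igraph::vcount(graph)
  if (module_size > n) {
    stop("'module_size' exceeds the number of nodes", call. = FALSE)
  }
  set.seed(derive_seed(seed, "module"))
  nodes <- igraph::V(graph)$name
  start <- sample(nodes, 1L)
  chosen <- start
  frontier <- setdiff(names(igraph::neighbors(graph, start)), chosen)
  while (length(chosen) < module_size) {
    if (length(frontier) == 0L) {
      # disconnected remainder cannot happen on a connected graph, but guard
      stop("frontier exhausted before reaching module_size", call. = FALSE)
    }
    nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    chosen <- c(chosen, nxt)
    nbrs <- names(igraph::neighbors(graph, nxt))
    frontier <- setdiff(union(frontier, nbrs), chosen)
  }
  sort(chosen)
}
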