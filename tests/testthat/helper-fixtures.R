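# Shared fixtures and independent oracles, built in code at test time.

# A signature_ranking with a prescribed gene order and DE sets, bypassing the
# rank-product machinery (for connectivity/synergy unit tests).
make_ranking <- function(genes, up = character(0), down = character(0),
                         entity = "toy", logfc = NULL) {
  n <- length(genes)
  if (is.null(logfc)) logfc <- seq(n, 1) # descending, matching the order
  tab <- data.frame(
    gene = genes, logfc = logfc,
    rp_up = 1, rp_down = 1, pfp_up = 1, pfp_down = 1,
    call = ifelse(genes %in% up, "up", ifelse(genes %in% down, "down", "ns")),
    stringsAsFactors = FALSE
  )
  signature_ranking(tab, entity)
}

# Random null ranking: random gene order, random disjoint up/down sets.
random_ranking <- function(n_genes, t_up, t_down, entity) {
  genes <- sample(sprintf("g%04d", seq_len(n_genes)))
  de <- sample(genes, t_up + t_down)
  make_ranking(genes,
    up = de[seq_len(t_up)], down = de[-seq_len(t_up)],
    entity = entity
  )
}

# A small cached synthetic study shared across test files.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(simulate_study(sim_config(
        seed = 42, n_genes = 300, network_nodes = 150, module_size = 15,
        n_diseases = 3, n_foods = 4, n_drugs = 2, datasets_per_entity = 3
      )))
    }
    cache
  }
})

# Independent BFS shortest-path oracle (no igraph distance calls).
bfs_distances <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]
    b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- matrix(Inf, length(nodes), length(nodes),
    dimnames = list(nodes, nodes)
  )
  for (s in nodes) {
    d[s, s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# Exact upper-tail hypergeometric by combinatorial enumeration.
hyper_upper_tail <- function(N, K, n, k) {
  ks <- seq(k, min(K, n))
  if (length(ks) == 0 || k > min(K, n)) {
    return(0)
  }
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Brute-force rank product oracle: recompute all fold changes and ranks
# independently of the package's vectorized path.
rp_oracle <- function(datasets, direction) {
  fcs <- lapply(datasets, function(ds) {
    case <- ds$values[, ds$sample_labels == "case", drop = FALSE]
    ctrl <- ds$values[, ds$sample_labels == "control", drop = FALSE]
    apply(case, 1, mean) - apply(ctrl, 1, mean)
  })
  genes <- sort(unique(unlist(lapply(fcs, names))))
  out <- numeric(0)
  for (g in genes) {
    rs <- c()
    for (fc in fcs) {
      if (!g %in% names(fc)) next
      ordered <- sort(fc, decreasing = (direction == "up"))
      # average rank over ties, computed by hand
      val <- fc[[g]]
      n_better <- sum(if (direction == "up") fc > val else fc < val)
      n_tied <- sum(fc == val)
      rs <- c(rs, n_better + (n_tied + 1) / 2)
    }
    if (length(rs) * 2 >= length(datasets)) {
      out[g] <- prod(rs)^(1 / length(rs))
    }
  }
  out
}
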