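# Toy graphs and independent oracles used across test files.
# Oracles deliberately avoid the package's BFS machinery: degree by incident-
# edge scan, closeness from igraph::distances, stress by enumerating every
# shortest path with igraph::all_shortest_paths.

star_graph <- function(n_leaves = 4) {
  ppi_graph(edges = cbind("HUB", paste0("LEAF", seq_len(n_leaves))))
}

path_graph <- function(nodes = c("A", "B", "C")) {
  ppi_graph(edges = cbind(nodes[-length(nodes)], nodes[-1]))
}

triangle_graph <- function() {
  ppi_graph(edges = rbind(c("A", "B"), c("B", "C"), c("A", "C")))
}

# G(n, p)-style random simple graph with symbol names; may be disconnected
# and may contain isolated nodes.
random_test_graph <- function(n, p = 0.2, seed = 1) {
  withr::with_seed(seed, {
    nodes <- sprintf("N%02d", seq_len(n))
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < p
    ppi_graph(edges = pairs[keep, , drop = FALSE], nodes = nodes)
  })
}

oracle_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = length(g$nodes), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$nodes)
  if (nrow(g$edges) > 0) {
    ig <- igraph::add_edges(ig, rbind(match(g$edges[, 1], g$nodes),
                                      match(g$edges[, 2], g$nodes)))
  }
  ig
}

oracle_degree <- function(g) {
  vapply(g$nodes, function(v) sum(g$edges == v), numeric(1))
}

oracle_closeness <- function(g) {
  d <- igraph::distances(oracle_igraph(g))
  vapply(g$nodes, function(v) {
    dv <- d[v, colnames(d) != v]
    far <- sum(dv[is.finite(dv)])
    if (far > 0) 1 / far else 0
  }, numeric(1))
}

# Exhaustive shortest-path enumeration: count, for every unordered pair
# {s, t}, the shortest s-t paths passing through each interior node.
oracle_stress <- function(g) {
  ig <- oracle_igraph(g)
  st <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  n <- length(g$nodes)
  if (n < 3) return(st)
  for (i in seq_len(n - 1)) {
    asp <- suppressWarnings(
      igraph::all_shortest_paths(ig, from = i, to = (i + 1):n)$vpaths)
    for (pth in asp) {
      pv <- as.integer(pth)
      if (length(pv) > 2) {
        interior <- g$nodes[pv[-c(1, length(pv))]]
        st[interior] <- st[interior] + 1
      }
    }
  }
  st
}

# Small interaction table helper.
make_itab <- function(pairs, sources = "test") {
  df <- data.frame(mirna = normalize_mirna_id(pairs[, 1]),
                   gene = normalize_gene_symbol(pairs[, 2]),
                   sources = sources, stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(df[, c("mirna", "gene")], tf, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  load_interactions(tf, sources[1])
}
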