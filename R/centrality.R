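# Node centralities on unweighted PPI graphs: degree, closeness (reciprocal
# total distance within the node's component, the CentiScaPe convention), and
# stress (total shortest-path counts through a node), via all-sources BFS with
# Brandes-style path counting.

#' Degree centrality
#'
#' Number of incident edges per node (the graph is simple, so this equals the
#' number of neighbours).
#'
#' @param g a `ppi_graph`.
#' @return named integer vector over all nodes.
#' @export
degree_centrality <- function(g) {
  deg <- integer(n_nodes(g))
  names(deg) <- g$nodes
  if (n_edges(g) > 0) {
    tab <- table(factor(as.vector(g$edges), levels = g$nodes))
    deg[] <- as.integer(tab)
  }
  deg
}

#' Closeness centrality (reciprocal farness, component-restricted)
#'
#' closeness(v) = 1 / sum of shortest-path distances from v to every other
#' node in v's connected component; an isolated node scores 0. Distances to
#' nodes in other components are excluded rather than treated as infinite, so
#' values across components of different sizes are on the raw (unnormalized)
#' scale used by CentiScaPe-era network tools: larger components tend to give
#' smaller closeness.
#'
#' @param g a `ppi_graph`.
#' @return named numeric vector over all nodes.
#' @export
closeness_centrality <- function(g) {
  n <- n_nodes(g)
  out <- numeric(n)
  names(out) <- g$nodes
  if (n == 0) return(out)
  adj <- adjacency_list(g)
  for (v in seq_len(n)) {
    d <- bfs_distances(adj, v, n)
    farness <- sum(d[is.finite(d)]) # d[v] = 0 contributes nothing
    out[v] <- if (farness > 0) 1 / farness else 0
  }
  out
}

#' Stress centrality
#'
#' stress(v) = total number of shortest paths, over all unordered node pairs
#' {s, t} with s != v != t, that pass through v as an interior node. Computed
#' with one BFS per source and Brandes-style accumulation of shortest-path
#' counts; pairs in different components contribute nothing. Leaves and
#' isolated nodes score 0.
#'
#' @param g a `ppi_graph`.
#' @return named numeric vector (integer-valued) over all nodes.
#' @export
stress_centrality <- function(g) {
  n <- n_nodes(g)
  st <- numeric(n)
  names(st) <- g$nodes
  if (n == 0 || n_edges(g) == 0) return(st)
  adj <- adjacency_list(g)
  for (s in seq_len(n)) {
    b <- bfs_sigma(adj, s, n)
    # p[v] = number of shortest-path DAG paths starting at v (to any target);
    # accumulate in reverse BFS order: p[v] = sum over DAG successors w of
    # (1 + p[w]). Contribution of source s to stress(v) is sigma[s->v] * p[v].
    p <- numeric(n)
    ord <- b$order[b$order != s]
    for (v in rev(ord)) {
      acc <- 0
      for (w in adj[[v]]) {
        if (b$dist[w] == b$dist[v] + 1) acc <- acc + 1 + p[w]
      }
      p[v] <- acc
      st[v] <- st[v] + b$sigma[v] * p[v]
    }
  }
  st / 2 # each unordered pair {s,t} was counted from both endpoints
}

# BFS from src returning distances, shortest-path counts (sigma), and the
# visit order (non-decreasing distance).
bfs_sigma <- function(adj, src, n) {
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  dist[src] <- 0
  sigma[src] <- 1
  queue <- integer(n)
  queue[1] <- src
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        tail <- tail + 1L
        queue[tail] <- w
      }
      if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
    }
  }
  list(dist = dist, sigma = sigma, order = queue[seq_len(tail)])
}

#' Per-node centrality profile
#'
#' Degree, closeness and stress for every node of one graph.
#'
#' @param g a `ppi_graph`.
#' @param graph_id label stored on the profile.
#' @return a `centrality_profile` data.frame with columns node, degree,
#'   closeness, stress.
#' @export
centrality_profile <- function(g, graph_id = "graph") {
  df <- data.frame(node = g$nodes,
                   degree = as.numeric(degree_centrality(g)),
                   closeness = as.numeric(closeness_centrality(g)),
                   stress = as.numeric(stress_centrality(g)),
                   stringsAsFactors = FALSE)
  structure(df, class = c("centrality_profile", "data.frame"),
            graph_id = graph_id)
}

#' Whole-network centrality summary
#'
#' Arithmetic means of degree, closeness and stress over all nodes (isolated
#' nodes included), plus node and edge counts.
#'
#' @param g a non-empty `ppi_graph`.
#' @return a list with mean_degree, mean_closeness, mean_stress, n_nodes,
#'   n_edges.
#' @export
network_summary <- function(g) {
  if (n_nodes(g) == 0) stop_arg("network_summary requires a non-empty graph")
  list(mean_degree = mean(degree_centrality(g)),
       mean_closeness = mean(closeness_centrality(g)),
       mean_stress = mean(stress_centrality(g)),
       n_nodes = n_nodes(g),
       n_edges = n_edges(g))
}
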