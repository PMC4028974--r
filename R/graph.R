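# PPI graph container and IO: simple undirected graphs of protein symbols,
# read/written as two-column edge lists, SIF, or GraphML.

#' Construct a PPI graph
#'
#' A simple undirected graph over gene/protein symbols: self-loops are
#' dropped (with a logged count) and parallel/reversed duplicate edges are
#' collapsed. Isolated nodes are permitted.
#'
#' @param edges two-column character matrix (or data.frame) of endpoints;
#'   may have zero rows.
#' @param nodes optional additional node symbols (isolated nodes).
#' @return an object of class `ppi_graph` with elements `nodes` (character)
#'   and `edges` (two-column character matrix, each row sorted).
#' @export
ppi_graph <- function(edges = NULL, nodes = character()) {
  nodes <- unique(normalize_gene_symbol(nodes))
  nodes <- nodes[nzchar(nodes)]
  if (is.null(edges) || NROW(edges) == 0) {
    em <- matrix(character(), ncol = 2, dimnames = list(NULL, c("a", "b")))
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    em[] <- normalize_gene_symbol(em)
    loops <- em[, 1] == em[, 2]
    if (any(loops)) log_msg("network", sum(loops), " self-loops dropped")
    em <- em[!loops, , drop = FALSE]
    # canonical orientation so (a,b) == (b,a)
    swap <- em[, 1] > em[, 2]
    em[swap, ] <- em[swap, 2:1]
    em <- em[!duplicated(paste(em[, 1], em[, 2], sep = "\t")), , drop = FALSE]
    em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
    colnames(em) <- c("a", "b")
  }
  all_nodes <- sort(unique(c(nodes, as.vector(em))))
  structure(list(nodes = all_nodes, edges = em), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("ppi_graph: %d nodes, %d edges\n", n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Number of nodes / edges of a PPI graph
#' @param g a `ppi_graph`.
#' @return integer count.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

# Adjacency list as integer indices into g$nodes.
adjacency_list <- function(g) {
  n <- n_nodes(g)
  adj <- vector("list", n)
  if (n_edges(g) > 0) {
    ia <- match(g$edges[, 1], g$nodes)
    ib <- match(g$edges[, 2], g$nodes)
    for (k in seq_along(ia)) {
      adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
      adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
    }
  }
  adj
}

as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = 0, directed = FALSE)
  ig <- igraph::add_vertices(ig, n_nodes(g), name = g$nodes)
  if (n_edges(g) > 0) {
    ig <- igraph::add_edges(ig, rbind(match(g$edges[, 1], g$nodes),
                                      match(g$edges[, 2], g$nodes)))
  }
  ig
}

from_igraph <- function(ig) {
  nm <- igraph::V(ig)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(ig)))
  el <- igraph::as_edgelist(ig, names = FALSE)
  ppi_graph(edges = cbind(nm[el[, 1]], nm[el[, 2]]), nodes = nm)
}

#' Read a PPI graph from an edge list or SIF file
#'
#' Edge-list dialect: two whitespace/tab-separated symbol columns per line.
#' SIF dialect: `nodeA <tab> relation <tab> nodeB [nodeC ...]` (fan-out: one
#' edge from nodeA to each listed target); a single-token line declares an
#' isolated node. Symbols are uppercased; self-loops dropped and duplicate
#' edges collapsed, with logged counts.
#'
#' @param path input file.
#' @param format "auto" (by ".sif" extension), "edgelist", or "sif".
#' @return a `ppi_graph`.
#' @export
load_graph <- function(path, format = c("auto", "edgelist", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "edgelist"
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(ppi_graph())
  edges <- list()
  iso <- character()
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
    if (format == "edgelist") {
      if (length(tok) != 2) {
        stop_format("unparseable edge-list line ", i, ": expected 2 fields, got ",
                    length(tok))
      }
      edges[[length(edges) + 1]] <- matrix(tok, ncol = 2)
    } else {
      if (length(tok) == 1) {
        iso <- c(iso, tok)
      } else if (length(tok) == 2) {
        stop_format("unparseable SIF line ", i,
                    ": relation without target node")
      } else {
        edges[[length(edges) + 1]] <- cbind(tok[1], tok[-(1:2)])
      }
    }
  }
  ppi_graph(edges = do.call(rbind, edges), nodes = iso)
}

#' Write a PPI graph
#'
#' For "sif" and "edgelist" the round trip `load_graph(write_graph(g))`
#' recovers the same node and edge sets; "graphml" is written via igraph for
#' interoperability with Cytoscape-style tools.
#'
#' @param g a `ppi_graph`.
#' @param path output file.
#' @param format one of "sif", "edgelist", "graphml".
#' @param relation SIF relation token (default "pp").
#' @return the path, invisibly.
#' @export
write_graph <- function(g, path, format = c("sif", "edgelist", "graphml"),
                        relation = "pp") {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_arg("unknown graph format"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(g), path, format = "graphml")
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (n_edges(g) > 0) {
    lines <- if (format == "sif") {
      paste(g$edges[, 1], relation, g$edges[, 2], sep = "\t")
    } else {
      paste(g$edges[, 1], g$edges[, 2], sep = "\t")
    }
    writeLines(lines, con)
  }
  iso <- setdiff(g$nodes, as.vector(g$edges))
  if (length(iso) > 0 && format == "sif") writeLines(iso, con)
  if (length(iso) > 0 && format == "edgelist") {
    log_msg("network", length(iso),
            " isolated nodes not representable in edge-list format")
  }
  invisible(path)
}

#' Build a seed-protein subnetwork
#'
#' "induced": the subgraph of `global` induced on the seed proteins (seeds
#' absent from the global graph are dropped with a logged count). "bridged":
#' the induced result plus every non-seed node lying on at least one shortest
#' path of length <= `max_bridge_len` between two seeds, with all edges among
#' the retained nodes — a stand-in for shortest-path network expansion.
#'
#' @param global the global `ppi_graph`.
#' @param seeds non-empty character vector of seed protein symbols.
#' @param mode "induced" (default) or "bridged".
#' @param max_bridge_len maximum seed-to-seed shortest-path length through
#'   which connector nodes are recruited (bridged mode; >= 1).
#' @return a `ppi_graph` on the retained nodes.
#' @export
build_seed_network <- function(global, seeds, mode = c("induced", "bridged"),
                               max_bridge_len = 2) {
  mode <- match.arg(mode)
  seeds <- unique(normalize_gene_symbol(seeds))
  seeds <- seeds[nzchar(seeds)]
  if (length(seeds) == 0) stop_arg("seed set must be non-empty")
  if (mode == "bridged" && max_bridge_len < 1) {
    stop_arg("max_bridge_len must be >= 1")
  }
  present <- intersect(seeds, global$nodes)
  if (length(present) < length(seeds)) {
    log_msg("network", length(seeds) - length(present),
            " seeds absent from global graph dropped")
  }
  keep <- present
  if (mode == "bridged" && length(present) >= 2) {
    adj <- adjacency_list(global)
    idx <- match(present, global$nodes)
    dmat <- vapply(idx, function(s) bfs_distances(adj, s, n_nodes(global)),
                   numeric(n_nodes(global)))
    # node w bridges seeds s,t if d(s,w) + d(w,t) == d(s,t) <= max_bridge_len
    bridge <- rep(FALSE, n_nodes(global))
    ns <- length(idx)
    for (i in seq_len(ns - 1)) {
      for (j in (i + 1):ns) {
        dst <- dmat[idx[j], i]
        if (is.finite(dst) && dst <= max_bridge_len) {
          on_path <- is.finite(dmat[, i]) & is.finite(dmat[, j]) &
            (dmat[, i] + dmat[, j] == dst)
          bridge <- bridge | on_path
        }
      }
    }
    keep <- union(present, global$nodes[bridge])
  }
  induced_subgraph_ppi(global, keep)
}

induced_subgraph_ppi <- function(g, nodes) {
  nodes <- intersect(g$nodes, nodes)
  if (n_edges(g) > 0) {
    sel <- g$edges[, 1] %in% nodes & g$edges[, 2] %in% nodes
    ppi_graph(edges = g$edges[sel, , drop = FALSE], nodes = nodes)
  } else {
    ppi_graph(nodes = nodes)
  }
}

# BFS distances from source index src; Inf for unreachable.
bfs_distances <- function(adj, src, n) {
  dist <- rep(Inf, n)
  dist[src] <- 0
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
    }
  }
  dist
}
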