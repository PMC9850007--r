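# Fixture builders used across test files; all data is generated in code.

# small otu_table from a counts matrix, default taxonomy/groups
fixture_table <- function(counts, groups = NULL, taxonomy = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("S%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("OTU_%03d", seq_len(ncol(counts)))
  if (is.null(groups))
    groups <- stats::setNames(rep("G1", nrow(counts)), rownames(counts))
  if (is.null(taxonomy))
    taxonomy <- stats::setNames(
      rep("k__Bacteria;p__Firmicutes", ncol(counts)), colnames(counts))
  otu_table(counts, taxonomy, groups)
}

# igraph from an edge matrix/data.frame of node-name pairs, with the
# attributes build_network() would attach
fixture_net <- function(edges, nodes = NULL, rho = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:2] <- c("from", "to")
  edges$rho <- rho %||% rep(0.9, nrow(edges))
  edges$p <- 1e-6
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  nodes <- nodes %||% sort(unique(c(edges$from, edges$to)))
  verts <- data.frame(name = nodes,
                      lineage = "k__Bacteria;p__Firmicutes",
                      abundance_class = "moderate",
                      overall_mean = 0.001)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random connected-or-not graph with >= 1 edge on n nodes
fixture_random_graph <- function(n, p = 0.4) {
  repeat {
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
    adj <- adj + t(adj)
    if (sum(adj) > 0) break
  }
  rownames(adj) <- colnames(adj) <- sprintf("N%02d", seq_len(n))
  adj
}

fixture_connected_graph <- function(n, p = 0.5) {
  repeat {
    adj <- fixture_random_graph(n, p)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::is_connected(g)) return(adj)
  }
}

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
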