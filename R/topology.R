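#' Node-level centralities of a co-occurrence network
#'
#' Degree is the number of incident edges. Betweenness is the raw
#' (unnormalized) count of shortest paths through a node, with each
#' unordered pair of endpoints counted once — the convention under which
#' keystone cut-offs such as "betweenness < 5000" are meaningful on
#' networks of a few hundred nodes; the pair-fraction normalized variant
#' is returned alongside. Closeness uses the component-corrected form
#' `((n_c - 1) / (n - 1)) * ((n_c - 1) / sum of distances within the
#' component)`, which stays in \[0, 1\] on the disconnected graphs that
#' thresholding typically produces. Eigenvector centrality is computed on
#' the full graph by deterministic power iteration (on A + I, uniform
#' start vector) and max-normalized; nodes outside the dominant component
#' get values near 0.
#'
#' @param net an igraph network with at least 1 node.
#' @return data.frame with columns `otu_id`, `degree`, `betweenness`,
#'   `betweenness_normalized`, `closeness`, `eigenvector`.
#' @export
node_topology <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0) abort("empty network")
  ids <- igraph::V(net)$name %||% as.character(seq_len(n))
  deg <- as.integer(igraph::degree(net))
  btw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  btw_norm <- if (n > 2) btw / ((n - 1) * (n - 2) / 2) else rep(0, n)

  d <- igraph::distances(net)
  clo <- vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    reach <- dv[is.finite(dv)]
    if (n == 1 || length(reach) == 0) return(0)
    n_c <- length(reach) + 1
    ((n_c - 1) / (n - 1)) * ((n_c - 1) / sum(reach))
  }, numeric(1))

  adj <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  eig <- .power_eigenvector(adj)

  data.frame(otu_id = ids, degree = deg, betweenness = unname(btw),
             betweenness_normalized = unname(btw_norm),
             closeness = clo, eigenvector = eig, row.names = NULL)
}

# power iteration on A + I: the shift removes the +/-lambda ambiguity of
# bipartite components so iteration always converges; eigenvectors of A
# are unchanged. Uniform start, max-normalized output.
.power_eigenvector <- function(adj, tol = 1e-13, max_iter = 100000) {
  n <- nrow(adj)
  if (n == 1) return(1)
  x <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    x_new <- as.numeric(adj %*% x) + x
    m <- max(x_new)
    if (m == 0) return(rep(0, n))  # edgeless graph
    x_new <- x_new / m
    if (max(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  x
}

#' Two-sided Mann-Whitney U test between two node-feature samples
#'
#' U is the count of (a, b) pairs with a > b, plus half the tied pairs
#' (i.e. the U statistic for the first sample). When both samples have at
#' most 8 values the p-value is computed by exhaustive enumeration of all
#' `choose(n_a + n_b, n_a)` group labelings of the pooled values (ties
#' handled exactly); otherwise the normal approximation with tie
#' correction and continuity correction is used via [stats::wilcox.test()].
#'
#' @param a,b non-empty numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"` (a tends larger)
#'   or `"less"`.
#' @param exact_max largest per-sample size for the exact path.
#' @return list with `U`, `p` and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(a, b, alternative = c("two.sided", "greater",
                                                 "less"),
                           exact_max = 8) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) abort("both samples must be non-empty")
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2

  if (n_a <= exact_max && n_b <= exact_max) {
    combos <- utils::combn(n_a + n_b, n_a)
    null_U <- apply(combos, 2, function(idx)
      sum(r[idx]) - n_a * (n_a + 1) / 2)
    p <- switch(alternative,
      two.sided = {
        mu <- n_a * n_b / 2
        mean(abs(null_U - mu) >= abs(U - mu) - 1e-12)
      },
      greater = mean(null_U >= U - 1e-12),
      less = mean(null_U <= U + 1e-12))
    return(list(U = U, p = p, method = "exact"))
  }

  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = FALSE, correct = TRUE))
  list(U = U, p = unname(wt$p.value), method = "normal")
}

#' Compare one node-level feature between two networks
#'
#' Convenience wrapper extracting a [node_topology()] column from each
#' network and running [mann_whitney_u()] on the two distributions.
#'
#' @param net_a,net_b igraph networks.
#' @param feature one of `"degree"`, `"betweenness"`, `"closeness"`,
#'   `"eigenvector"`.
#' @param ... passed to [mann_whitney_u()].
#' @return list with `U`, `p`, `method`.
#' @export
compare_feature <- function(net_a, net_b,
                            feature = c("degree", "betweenness",
                                        "closeness", "eigenvector"), ...) {
  feature <- match.arg(feature)
  mann_whitney_u(node_topology(net_a)[[feature]],
                 node_topology(net_b)[[feature]], ...)
}
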