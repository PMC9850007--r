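#' Pairwise Spearman correlations with significance
#'
#' Correlations are computed on per-sample relative abundances (rank-based,
#' so identical to raw counts when sequencing depths are equal) with
#' average-rank tie handling. Two-sided p-values use the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of
#' freedom; `|rho| = 1` gives p = 0. With `p_method = "exact"` (n <= 8
#' samples) p-values come instead from the full permutation null over all
#' `n!` orderings. Constant (all-tied) OTU vectors have undefined
#' correlations; their pairs are recorded as rho = 0, p = 1 with a
#' warning, so degenerate OTUs can never create edges.
#'
#' @param table an [otu_table()] with at least 4 samples.
#' @param otus OTU ids to correlate (default: all in the table).
#' @param p_method `"t"` (default) or `"exact"` (permutation, n <= 8).
#' @return an object of class `correlation_set`: list with `otus`, `rho`
#'   and `p` (symmetric matrices) and `n_samples`.
#' @export
spearman_matrix <- function(table, otus = NULL, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  n <- nrow(table$counts)
  if (n < 4) abort("need at least 4 samples, got %d", n)
  otus <- otus %||% colnames(table$counts)
  missing <- setdiff(otus, colnames(table$counts))
  if (length(missing)) abort("OTU not in table: %s", missing[1])

  totals <- rowSums(table$counts)
  if (any(totals == 0))
    abort("sample has zero total count: %s",
          rownames(table$counts)[which(totals == 0)[1]])
  x <- (table$counts / totals)[, otus, drop = FALSE]

  const <- apply(x, 2, function(v) length(unique(v)) == 1)
  if (any(const))
    warning(sprintf("constant OTU vector(s): %s; their correlations are set to 0",
                    paste(otus[const], collapse = ", ")), call. = FALSE)

  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[const, ] <- 0; rho[, const] <- 0
  diag(rho) <- 1

  if (p_method == "exact") {
    if (n > 8) abort("exact permutation p-values limited to n <= 8 samples")
    p <- .spearman_exact_p(x, rho)
  } else {
    r <- pmin(pmax(rho, -1), 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[abs(r) >= 1 - 1e-15] <- 0
  }
  p[const, ] <- 1; p[, const] <- 1
  diag(p) <- 0
  structure(list(otus = otus, rho = rho, p = p, n_samples = n),
            class = "correlation_set")
}

# all permutations of 1..n, one per row (n <= 8)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# exhaustive permutation p-values for every pair; null = permute one vector
.spearman_exact_p <- function(x, rho_obs) {
  n <- nrow(x); m <- ncol(x)
  perms <- .permutations(n)
  ranks <- apply(x, 2, rank)  # average ranks
  p <- matrix(0, m, m, dimnames = dimnames(rho_obs))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      null_rho <- apply(perms, 1, function(pr)
        suppressWarnings(stats::cor(ranks[, i], ranks[pr, j])))
      null_rho[is.na(null_rho)] <- 0
      pv <- mean(abs(null_rho) >= abs(rho_obs[i, j]) - 1e-12)
      p[i, j] <- p[j, i] <- pv
    }
  }
  p
}

#' Build the signed co-occurrence network
#'
#' Edges are exactly the OTU pairs with `|rho| >= rho_threshold` (inclusive)
#' and `p <= p_threshold` (inclusive); the optional Benjamini-Hochberg
#' switch adjusts p-values across all distinct pairs before thresholding
#' and is off by default. Nodes carry taxonomy, abundance class and group
#' means from the profile; OTUs left without any surviving edge are
#' excluded. Edge sign is positive iff rho > 0; the graph is undirected
#' and unweighted for all downstream topology, with rho and p kept as edge
#' attributes.
#'
#' @param corr a [spearman_matrix()] correlation set.
#' @param profile an [relative_abundance()] profile covering the
#'   correlated OTUs.
#' @param rho_threshold minimum absolute correlation, in (0, 1].
#' @param p_threshold maximum p-value, in (0, 1].
#' @param adjust_p if TRUE, Benjamini-Hochberg adjust p-values first.
#' @return an igraph network (possibly with 0 nodes if no pair passes).
#' @export
build_network <- function(corr, profile, rho_threshold = 0.6,
                          p_threshold = 0.05, adjust_p = FALSE) {
  stopifnot(inherits(corr, "correlation_set"))
  if (rho_threshold <= 0 || rho_threshold > 1 ||
      p_threshold <= 0 || p_threshold > 1)
    abort("thresholds must be in (0, 1]")
  m <- length(corr$otus)
  p <- corr$p
  if (adjust_p) {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  keep <- abs(corr$rho) >= rho_threshold & p <= p_threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(igraph::make_empty_graph(0, directed = FALSE))
  edges <- data.frame(from = corr$otus[idx[, 1]],
                      to = corr$otus[idx[, 2]],
                      rho = corr$rho[idx],
                      p = p[idx])
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  nodes_in <- sort(unique(c(edges$from, edges$to)))
  verts <- data.frame(name = nodes_in,
                      lineage = unname(format_taxonomy(
                        profile$taxonomy[nodes_in, , drop = FALSE])),
                      abundance_class = unname(profile$class[nodes_in]),
                      overall_mean = unname(profile$overall_mean[nodes_in]))
  for (g in colnames(profile$group_mean))
    verts[[paste0("mean_", g)]] <- unname(profile$group_mean[nodes_in, g])
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Summarize edge signs of a network
#'
#' @param net an igraph network from [build_network()].
#' @return list with `n_edges`, `n_pos`, `n_neg` and `pct_pos`
#'   (100 * n_pos / n_edges, rounded half-up to 2 decimals; `NA` for an
#'   empty network).
#' @export
edge_sign_summary <- function(net) {
  n_edges <- igraph::ecount(net)
  if (n_edges == 0)
    return(list(n_edges = 0L, n_pos = 0L, n_neg = 0L, pct_pos = NA_real_))
  n_pos <- sum(igraph::E(net)$sign == "positive")
  list(n_edges = n_edges, n_pos = n_pos, n_neg = n_edges - n_pos,
       pct_pos = round_half_up(100 * n_pos / n_edges, 2))
}
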