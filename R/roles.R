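#' Within-module (Zi) and among-module (Pi) connectivity
#'
#' `Zi = (kappa_i - mean_s kappa) / sd_s kappa`, where `kappa_i` is the
#' number of links from node i to nodes of its own module s, and the mean
#' and population sd are taken over all nodes assigned to s; modules with
#' sd = 0 give Zi = 0 for their members. `Pi = 1 - sum_m (kappa_im /
#' k_i)^2`, summing over all modules, with `k_i` the total degree — the
#' participation coefficient, 0 when all links stay in one module.
#'
#' @param net an igraph network.
#' @param part a [detect_modules()] partition (or named assignment vector)
#'   covering every node.
#' @return data.frame with columns `otu_id`, `module`, `degree`,
#'   `within_degree`, `zi`, `pi`.
#' @export
zi_pi <- function(net, part) {
  assignment <- if (inherits(part, "module_partition")) part$assignment
                else part
  ids <- igraph::V(net)$name
  missing <- setdiff(ids, names(assignment))
  if (length(missing)) abort("assignment misses node: %s", missing[1])
  mods <- assignment[ids]
  adj <- igraph::as_adj_list(net)
  k <- as.integer(igraph::degree(net))

  within <- integer(length(ids))
  pi_val <- numeric(length(ids))
  for (i in seq_along(ids)) {
    nbrs <- ids[as.integer(adj[[i]])]
    if (!length(nbrs)) { pi_val[i] <- 0; next }
    nbr_mods <- mods[nbrs]
    within[i] <- sum(nbr_mods == mods[i])
    kim <- table(nbr_mods)
    pi_val[i] <- 1 - sum((as.numeric(kim) / k[i])^2)
  }

  zi <- numeric(length(ids))
  for (m in unique(mods)) {
    idx <- which(mods == m)
    mu <- mean(within[idx])
    sd_pop <- sqrt(mean((within[idx] - mu)^2))
    zi[idx] <- if (sd_pop > 0) (within[idx] - mu) / sd_pop else 0
  }

  data.frame(otu_id = ids, module = unname(mods), degree = k,
             within_degree = within, zi = zi, pi = pi_val,
             row.names = NULL)
}

#' Classify node roles from Zi and Pi
#'
#' Network hubs: Zi > 2.5 and Pi > 0.62; module hubs: Zi > 2.5 and
#' Pi <= 0.62; connectors: Zi <= 2.5 and Pi > 0.62; peripheral nodes:
#' Zi <= 2.5 and Pi <= 0.62. Both hub inequalities are strict in Zi and
#' the connector inequality strict in Pi, so boundary nodes fall into the
#' lower category.
#'
#' @param zi,pi numeric vectors (recycled together).
#' @param zi_threshold,pi_threshold role cut-offs, defaults 2.5 and 0.62.
#' @return character vector of `"network_hub"`, `"module_hub"`,
#'   `"connector"`, `"peripheral"`.
#' @export
classify_role <- function(zi, pi, zi_threshold = 2.5, pi_threshold = 0.62) {
  hub <- zi > zi_threshold
  conn <- pi > pi_threshold
  ifelse(hub & conn, "network_hub",
         ifelse(hub, "module_hub",
                ifelse(conn, "connector", "peripheral")))
}

#' Flag keystone species
#'
#' Keystones are nodes with degree strictly greater than `degree_min` and
#' raw betweenness centrality strictly less than `betweenness_max` —
#' highly connected yet not lying on many shortest paths, hence
#' disproportionately influential relative to their abundance.
#'
#' @param topo a [node_topology()] data.frame.
#' @param degree_min degree cut-off (default 50, exclusive).
#' @param betweenness_max betweenness cut-off (default 5000, exclusive).
#' @return character vector of keystone OTU ids.
#' @export
keystone_flags <- function(topo, degree_min = 50, betweenness_max = 5000) {
  topo$otu_id[topo$degree > degree_min & topo$betweenness < betweenness_max]
}

#' Full per-node role table
#'
#' Joins topology, Zi/Pi, role category, keystone flag, abundance class
#' and taxonomy into the per-node record emitted by the pipeline.
#'
#' @param net an igraph network from [build_network()].
#' @param part a [detect_modules()] partition.
#' @param zi_threshold,pi_threshold passed to [classify_role()].
#' @param keystone_degree_min,keystone_betweenness_max passed to
#'   [keystone_flags()].
#' @return data.frame with one row per node.
#' @export
role_table <- function(net, part, zi_threshold = 2.5, pi_threshold = 0.62,
                       keystone_degree_min = 50,
                       keystone_betweenness_max = 5000) {
  topo <- node_topology(net)
  zp <- zi_pi(net, part)
  stopifnot(identical(topo$otu_id, zp$otu_id))
  keystones <- keystone_flags(topo, keystone_degree_min,
                              keystone_betweenness_max)
  data.frame(otu_id = topo$otu_id,
             module = zp$module,
             degree = topo$degree,
             betweenness = topo$betweenness,
             closeness = topo$closeness,
             eigenvector = topo$eigenvector,
             zi = zp$zi, pi = zp$pi,
             role = classify_role(zp$zi, zp$pi, zi_threshold, pi_threshold),
             keystone = topo$otu_id %in% keystones,
             abundance_class = igraph::V(net)$abundance_class,
             lineage = igraph::V(net)$lineage,
             row.names = NULL)
}

#' Role counts and percentages of all nodes
#'
#' @param records a [role_table()] data.frame (column `role`).
#' @return data.frame with columns `role`, `n`, `pct` for the four role
#'   categories (zero rows included); `pct` is the half-up 2-decimal
#'   percentage of all nodes.
#' @export
role_summary <- function(records) {
  lv <- c("peripheral", "connector", "module_hub", "network_hub")
  n <- vapply(lv, function(r) sum(records$role == r), integer(1))
  data.frame(role = lv, n = n,
             pct = if (sum(n) > 0) round_half_up(100 * n / sum(n), 2)
                   else rep(NA_real_, 4),
             row.names = NULL)
}

#' Cross-tabulate node roles against abundance classes
#'
#' @param records a [role_table()] data.frame (columns `role` and
#'   `abundance_class`).
#' @return data.frame with columns `role`, `abundance_class`, `n`, `pct`;
#'   within each role the percentages (half-up, 2 decimals) sum to 100
#'   (+/- 0.01). Empty input gives an empty table.
#' @export
role_abundance_crosstab <- function(records) {
  if (!nrow(records))
    return(data.frame(role = character(), abundance_class = character(),
                      n = integer(), pct = numeric()))
  tab <- table(role = records$role, abundance_class = records$abundance_class)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df)[3] <- "n"
  totals <- tapply(df$n, df$role, sum)
  df$pct <- round_half_up(100 * df$n / as.numeric(totals[df$role]), 2)
  df <- df[order(df$role, df$abundance_class), ]
  rownames(df) <- NULL
  df
}
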