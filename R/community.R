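#' Newman modularity of a partition
#'
#' `Q = sum_s [ l_s / L - (d_s / (2L))^2 ]` with `L` the total edge count,
#' `l_s` the edges inside module `s` and `d_s` the degree sum of module
#' `s`. Unweighted and sign-blind: negative-correlation edges count as
#' ordinary edges.
#'
#' @param net an igraph network with at least one edge.
#' @param assignment named vector (by OTU id) of module labels covering
#'   every node.
#' @return Q, a number in \[-0.5, 1\].
#' @export
modularity_q <- function(net, assignment) {
  if (igraph::ecount(net) == 0) abort("modularity undefined for 0 edges")
  ids <- igraph::V(net)$name
  missing <- setdiff(ids, names(assignment))
  if (length(missing)) abort("assignment misses node: %s", missing[1])
  membership <- as.integer(factor(assignment[ids]))
  igraph::modularity(net, membership)
}

#' Detect modules by greedy modularity maximization
#'
#' Agglomerative CNM (fast-greedy) clustering followed by one
#' deterministic pass of local node moves: nodes are visited in
#' lexicographic id order and moved to a neighboring module when that
#' strictly increases Q (best improvement; ties resolved toward the
#' smallest module id). Module ids are relabeled 1..K by decreasing size,
#' ties by smallest member OTU id. The procedure is deterministic for a
#' given graph; `seed` is accepted for interface stability but the
#' algorithm draws no random numbers.
#'
#' @param net a non-empty igraph network with at least one edge.
#' @param min_major_size modules with more than this many nodes are
#'   "major" (default 10).
#' @param seed unused by the deterministic algorithm; kept for interface
#'   stability.
#' @return an object of class `module_partition`: list with `assignment`
#'   (named integer vector), `modularity_q`, `sizes`, `major_modules` and
#'   `min_major_size`.
#' @export
detect_modules <- function(net, min_major_size = 10, seed = 1) {
  if (igraph::vcount(net) == 0) abort("empty network")
  if (igraph::ecount(net) == 0) abort("network has no edges")
  ids <- igraph::V(net)$name
  fg <- igraph::cluster_fast_greedy(net)
  mem <- stats::setNames(igraph::membership(fg), ids)

  mem <- .refine_partition(net, mem)

  q <- modularity_q(net, mem)
  if (q < 0) {  # never worse than the trivial all-in-one partition (Q = 0)
    mem[] <- 1L
    q <- modularity_q(net, mem)
  }

  mem <- .relabel_partition(mem)
  sizes <- table(mem)
  sizes <- stats::setNames(as.integer(sizes), names(sizes))
  major <- as.integer(names(sizes)[sizes > min_major_size])
  structure(list(assignment = mem, modularity_q = q, sizes = sizes,
                 major_modules = major,
                 min_major_size = as.integer(min_major_size)),
            class = "module_partition")
}

# one sweep of best-improvement local moves, lexicographic node order
.refine_partition <- function(net, mem) {
  ids <- igraph::V(net)$name
  adj <- igraph::as_adj_list(net)
  names(adj) <- ids
  q_cur <- igraph::modularity(net, as.integer(factor(mem[ids])))
  for (v in sort(ids)) {
    nbr_mods <- sort(unique(mem[igraph::V(net)$name[as.integer(adj[[v]])]]))
    nbr_mods <- setdiff(nbr_mods, mem[v])
    if (!length(nbr_mods)) next
    best_q <- q_cur; best_mod <- NA
    for (m in nbr_mods) {
      trial <- mem; trial[v] <- m
      q_try <- igraph::modularity(net, as.integer(factor(trial[ids])))
      if (q_try > best_q + 1e-12) { best_q <- q_try; best_mod <- m }
    }
    if (!is.na(best_mod)) { mem[v] <- best_mod; q_cur <- best_q }
  }
  mem
}

# contiguous 1..K ids, size-descending, ties by smallest member id
.relabel_partition <- function(mem) {
  sizes <- table(mem)
  min_member <- tapply(names(mem), mem, min)
  ord <- order(-as.integer(sizes), min_member[names(sizes)])
  map <- stats::setNames(seq_along(ord), names(sizes)[ord])
  stats::setNames(as.integer(map[as.character(mem)]), names(mem))
}

#' Taxonomic composition of modules
#'
#' Node counts and within-module fractions of each taxon at one rank;
#' unknown taxa are pooled under `"unclassified"`.
#'
#' @param net an igraph network whose nodes carry a `lineage` attribute.
#' @param part a [detect_modules()] partition.
#' @param rank one of [TAX_RANKS].
#' @return data.frame with columns `module`, `taxon`, `n`, `fraction`;
#'   fractions sum to 1 within each module.
#' @export
module_composition <- function(net, part, rank = "phylum") {
  if (!rank %in% TAX_RANKS) abort("unknown rank: %s", rank)
  ids <- igraph::V(net)$name
  tax <- parse_taxonomy(stats::setNames(igraph::V(net)$lineage, ids))
  taxa <- tax[, rank]
  taxa[taxa == "unknown"] <- "unclassified"
  mods <- part$assignment[ids]
  tab <- table(module = mods, taxon = taxa)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df)[3] <- "n"
  df <- df[df$n > 0, ]
  df$module <- as.integer(df$module)
  totals <- tapply(df$n, df$module, sum)
  df$fraction <- df$n / as.numeric(totals[as.character(df$module)])
  df <- df[order(df$module, -df$n, df$taxon), ]
  rownames(df) <- NULL
  df
}
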