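#' Edge-based dissimilarity between two co-occurrence networks
#'
#' Node identity is the OTU id and edge identity the unordered id pair;
#' sign and correlation strength are ignored. With `a` shared edges and
#' `b`, `c` edges unique to each network, the Whittaker index is
#' `beta_w = (a + b + c) / ((2a + b + c) / 2) - 1 = (b + c) / (2a + b + c)`,
#' bounded in \[0, 1\] (0 for identical edge sets, 1 for disjoint ones).
#' The Jaccard distance `(b + c) / (a + b + c)` is available as an
#' alternative.
#'
#' @param net1,net2 non-empty igraph networks.
#' @param metric `"whittaker"` (default) or `"jaccard"`.
#' @return list with `shared_edges`, `unique_to_first`,
#'   `unique_to_second` and `dissimilarity`.
#' @export
network_dissimilarity <- function(net1, net2,
                                  metric = c("whittaker", "jaccard")) {
  metric <- match.arg(metric)
  if (igraph::ecount(net1) == 0 || igraph::ecount(net2) == 0)
    abort("both networks must have at least one edge")
  key <- function(net) {
    el <- igraph::as_edgelist(net)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  }
  e1 <- unique(key(net1)); e2 <- unique(key(net2))
  a <- length(intersect(e1, e2))
  b <- length(setdiff(e1, e2))
  c_ <- length(setdiff(e2, e1))
  dis <- switch(metric,
                whittaker = (b + c_) / (2 * a + b + c_),
                jaccard = (b + c_) / (a + b + c_))
  list(shared_edges = a, unique_to_first = b, unique_to_second = c_,
       dissimilarity = dis)
}
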