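test_that("spearman correlations handle perfect monotone and mixed-rank vectors", {
  counts <- cbind(a = c(10, 20, 30, 40, 50),
                  b = c(12, 25, 33, 47, 60),
                  c = c(50, 40, 30, 20, 10),
                  d = c(20, 10, 40, 30, 50))
  # equalize depths so proportions keep the intended orderings
  counts <- cbind(counts, filler = 1000 - rowSums(counts))
  cs <- spearman_matrix(fixture_table(counts))
  expect_equal(cs$rho["a", "b"], 1)
  expect_equal(cs$p["a", "b"], 0)
  expect_equal(cs$rho["a", "c"], -1)
  # x = 1..5 vs y = (2,1,4,3,5): sum d^2 = 4 -> rho = 1 - 24/120 = 0.8
  expect_equal(cs$rho["a", "d"], oracle_spearman(1:5, c(2, 1, 4, 3, 5)))
  expect_equal(cs$rho["a", "d"], 0.8)

  exact <- spearman_matrix(fixture_table(counts), p_method = "exact")
  expect_equal(exact$p["a", "d"],
               oracle_spearman_perm_p(1:5, c(2, 1, 4, 3, 5)))
  # t-approximation agrees with the exhaustive permutation null within
  # its documented tolerance at n = 5
  expect_lt(abs(cs$p["a", "d"] - exact$p["a", "d"]), 0.05)
})

test_that("spearman matrix agrees with explicit rank + Pearson brute force", {
  set.seed(71)
  for (rep in 1:20) {
    counts <- matrix(rpois(10 * 6, 40), 10, 6)
    counts[1, 1] <- counts[1, 1] + rep  # break symmetry across reps
    tab <- fixture_table(counts)
    cs <- spearman_matrix(tab)
    prop <- counts / rowSums(counts)
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(cs$rho[i, j], oracle_spearman(prop[, i], prop[, j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("constant OTUs warn and can never form edges", {
  counts <- cbind(a = c(10, 20, 30, 40), b = c(5, 5, 5, 5),
                  c = c(40, 30, 20, 10))
  counts <- cbind(counts, filler = 200 - rowSums(counts))
  expect_warning(cs <- spearman_matrix(fixture_table(counts)), "constant")
  expect_equal(cs$rho["b", "a"], 0)
  expect_equal(cs$p["b", "a"], 1)
  expect_error(spearman_matrix(fixture_table(counts[1:3, ])), "4 samples")
})

test_that("network edges respect inclusive rho and p thresholds", {
  otus <- c("A", "B", "C")
  rho <- matrix(c(1, 0.6, 0.59, 0.6, 1, -0.7, 0.59, -0.7, 1), 3, 3,
                dimnames = list(otus, otus))
  p <- matrix(c(0, 0.05, 0.001, 0.05, 0, 0.2, 0.001, 0.2, 0), 3, 3,
              dimnames = list(otus, otus))
  corr <- structure(list(otus = otus, rho = rho, p = p, n_samples = 20),
                    class = "correlation_set")
  prof <- relative_abundance(fixture_table(
    matrix(10L, 4, 3, dimnames = list(NULL, otus))))
  net <- build_network(corr, prof)
  # A-B passes exactly at both bounds; A-C fails rho; B-C fails p
  expect_equal(igraph::ecount(net), 1)
  expect_setequal(igraph::V(net)$name, c("A", "B"))  # C isolated, dropped
  expect_equal(igraph::E(net)$sign, "positive")

  none <- build_network(corr, prof, rho_threshold = 0.99)
  expect_equal(igraph::vcount(none), 0)
  expect_error(build_network(corr, prof, rho_threshold = 0), "thresholds")
})

test_that("raising the rho threshold never adds edges", {
  set.seed(5)
  counts <- matrix(rpois(30 * 8, 60), 30, 8)
  tab <- fixture_table(counts)
  cs <- spearman_matrix(tab)
  prof <- relative_abundance(tab)
  edge_key <- function(net) {
    if (igraph::ecount(net) == 0) return(character(0))
    el <- igraph::as_edgelist(net)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  thresholds <- c(0.1, 0.3, 0.5, 0.7)
  nets <- lapply(thresholds, function(r)
    build_network(cs, prof, rho_threshold = r, p_threshold = 1))
  for (k in seq_len(length(nets) - 1))
    expect_true(all(edge_key(nets[[k + 1]]) %in% edge_key(nets[[k]])))
})

test_that("edge sign summaries reproduce probability-of-positive percentages", {
  ring <- function(n_edges, n_pos) {
    g <- igraph::make_ring(n_edges)
    igraph::E(g)$sign <- c(rep("positive", n_pos),
                           rep("negative", n_edges - n_pos))
    g
  }
  expect_equal(edge_sign_summary(ring(4844, 4818))$pct_pos, 99.46)
  expect_equal(edge_sign_summary(ring(3379, 3377))$pct_pos, 99.94)
  expect_equal(edge_sign_summary(ring(100, 100))$pct_pos, 100)
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_true(is.na(edge_sign_summary(empty)$pct_pos))
})

test_that("strong planted modules contain nearly all network edges", {
  cfg <- simulation_config(n_groups = 1, samples_per_group = 150,
                           n_otus = 100, n_modules = 2, module_size = 15,
                           intra_module_correlation = 0.95,
                           hub_fraction = 0, connector_fraction = 0,
                           sequencing_depth = 30000, seed = 12)
  sim <- simulate_otu_table(cfg)
  prof <- relative_abundance(sim$table)
  cs <- suppressWarnings(spearman_matrix(sim$table))
  net <- build_network(cs, prof)
  el <- igraph::as_edgelist(net)
  truth <- sim$truth$otu_module
  same_module <- truth[el[, 1]] == truth[el[, 2]] &
    truth[el[, 1]] != "background"
  expect_gte(mean(same_module), 0.95)
})
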