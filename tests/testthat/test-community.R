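two_triangles <- function() {
  fixture_net(data.frame(from = c("a", "b", "c", "x", "y", "z"),
                         to   = c("b", "c", "a", "y", "z", "x")))
}

test_that("modularity matches closed forms and the brute-force formula", {
  tri <- two_triangles()
  part <- stats::setNames(c(1, 1, 1, 2, 2, 2), igraph::V(tri)$name)
  expect_equal(modularity_q(tri, part), 0.5)
  expect_equal(modularity_q(tri, stats::setNames(rep(1, 6),
                                                 igraph::V(tri)$name)), 0)

  k4 <- fixture_net(t(utils::combn(c("a", "b", "c", "d"), 2)))
  split22 <- stats::setNames(c(1, 1, 2, 2), c("a", "b", "c", "d"))
  expect_equal(modularity_q(k4, split22), -1 / 6)

  empty_edges <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(empty_edges)$name <- c("a", "b")
  expect_error(modularity_q(empty_edges, c(a = 1, b = 1)), "0 edges")

  set.seed(41)
  for (rep in 1:15) {
    adj <- fixture_random_graph(sample(4:8, 1))
    g <- graph_from_adj(adj)
    mem <- stats::setNames(sample(1:3, nrow(adj), replace = TRUE),
                           rownames(adj))
    el <- igraph::as_edgelist(g)
    expect_equal(modularity_q(g, mem), oracle_modularity(el, mem),
                 tolerance = 1e-12)
  }
})

test_that("module detection recovers separable structure exactly", {
  tri <- two_triangles()
  part <- detect_modules(tri)
  expect_equal(part$modularity_q, 0.5)
  expect_equal(length(unique(part$assignment)), 2)
  expect_equal(length(unique(part$assignment[c("a", "b", "c")])), 1)
  expect_equal(length(unique(part$assignment[c("x", "y", "z")])), 1)

  single <- fixture_net(data.frame(from = "a", to = "b"))
  ps <- detect_modules(single)
  expect_equal(unname(ps$assignment), c(1L, 1L))
  expect_equal(ps$modularity_q, 0)
})

test_that("detected modularity is near the exhaustive optimum on small graphs", {
  set.seed(43)
  for (rep in 1:12) {
    n <- sample(4:7, 1)
    adj <- fixture_random_graph(n)
    g <- graph_from_adj(adj)
    part <- detect_modules(g)
    el <- igraph::as_edgelist(g)
    best <- max(vapply(oracle_partitions(n), function(p)
      oracle_modularity(el, stats::setNames(p, rownames(adj))), numeric(1)))
    expect_gte(part$modularity_q, best - 0.05)
    # internal consistency and trivial-partition lower bounds
    expect_equal(modularity_q(g, part$assignment), part$modularity_q)
    expect_gte(part$modularity_q, 0)
  }
})

test_that("module ids are size-ordered and major modules exceed the cut-off", {
  cfg <- simulation_config(n_groups = 1, samples_per_group = 150,
                           n_otus = 80, n_modules = 3, module_size = 15,
                           sequencing_depth = 30000, seed = 19)
  sim <- simulate_otu_table(cfg)
  prof <- relative_abundance(sim$table)
  net <- build_network(suppressWarnings(spearman_matrix(sim$table)), prof)
  part <- detect_modules(net, min_major_size = 10)
  sizes <- part$sizes
  expect_equal(as.integer(names(sizes)), seq_along(sizes))
  expect_true(all(diff(unname(sizes)) <= 0))
  expect_true(all(unname(sizes[as.character(part$major_modules)]) > 10))
})

test_that("module composition pools unknowns and sums to one", {
  net <- fixture_net(t(utils::combn(c("a", "b", "c", "d"), 2)))
  igraph::V(net)$lineage <- c("k__Bacteria;p__Proteobacteria",
                              "k__Bacteria;p__Proteobacteria",
                              "k__Bacteria;p__Proteobacteria",
                              "k__Bacteria;p__Firmicutes")
  part <- detect_modules(net)
  comp <- module_composition(net, part, "phylum")
  expect_equal(comp$fraction[comp$taxon == "Proteobacteria"], 0.75)
  expect_equal(comp$fraction[comp$taxon == "Firmicutes"], 0.25)

  igraph::V(net)$lineage <- "k__Bacteria"
  comp2 <- module_composition(net, part, "phylum")
  expect_equal(comp2$taxon, "unclassified")
  expect_equal(comp2$fraction, 1)
  expect_error(module_composition(net, part, "clade"), "rank")

  sums <- tapply(comp$fraction, comp$module, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
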