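test_that("same config and seed reproduce byte-identical tables", {
  cfg <- simulation_config(n_groups = 2, samples_per_group = c(15, 15),
                           n_otus = 60, n_modules = 2, module_size = 8,
                           sequencing_depth = 5000, seed = 3)
  a <- simulate_otu_table(cfg)
  b <- simulate_otu_table(cfg)
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$table$taxonomy, b$table$taxonomy)
  expect_identical(a$truth, b$truth)
})

test_that("row sums equal the sequencing depth exactly", {
  cfg <- simulation_config(n_groups = 1, samples_per_group = 25,
                           n_otus = 80, n_modules = 2, module_size = 10,
                           sequencing_depth = 7321, seed = 9)
  sim <- simulate_otu_table(cfg)
  expect_true(all(rowSums(sim$table$counts) == 7321L))
})

test_that("equal baselines without module structure give symmetric abundances", {
  cfg <- simulation_config(n_groups = 1, samples_per_group = 200,
                           n_otus = 2, n_modules = 0, module_size = 0,
                           intra_module_correlation = 0, noise_sd = 0,
                           abundance_lognormal_sigma = 1e-9,
                           sequencing_depth = 10000, seed = 4)
  sim <- simulate_otu_table(cfg)
  shares <- colMeans(sim$table$counts) / 10000
  expect_equal(unname(shares), c(0.5, 0.5), tolerance = 0.02)
})

test_that("within-module correlations exceed between-module correlations", {
  cfg <- simulation_config(n_groups = 1, samples_per_group = 200,
                           n_otus = 30, n_modules = 2, module_size = 10,
                           intra_module_correlation = 0.9,
                           hub_fraction = 0, connector_fraction = 0,
                           sequencing_depth = 100000, seed = 5)
  sim <- simulate_otu_table(cfg)
  truth <- sim$truth$otu_module
  prop <- sim$table$counts / rowSums(sim$table$counts)
  rho <- suppressWarnings(stats::cor(prop, method = "spearman"))
  m1 <- names(truth)[truth == "M1"]; m2 <- names(truth)[truth == "M2"]
  within <- c(rho[m1, m1][upper.tri(diag(10))],
              rho[m2, m2][upper.tri(diag(10))])
  between <- rho[m1, m2]
  expect_gt(mean(within), mean(between))
})

test_that("a wide abundance spectrum spans rare, moderate and abundant classes", {
  cfg <- simulation_config(n_groups = 1, samples_per_group = 30,
                           n_otus = 800, n_modules = 4, module_size = 15,
                           abundance_lognormal_sigma = 2.5,
                           sequencing_depth = 50000, seed = 6)
  sim <- simulate_otu_table(cfg)
  prof <- relative_abundance(sim$table)
  expect_setequal(unique(prof$class), c("rare", "moderate", "abundant"))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(sequencing_depth = 0), "depth")
  expect_error(simulation_config(abundance_lognormal_sigma = 0), "sigma")
  expect_error(simulation_config(hub_fraction = 1.2), "hub_fraction")
  expect_error(simulation_config(intra_module_correlation = -0.1),
               "intra_module_correlation")
  expect_error(simulation_config(n_groups = 2,
                                 samples_per_group = c(10, 10, 10)),
               "length")
  expect_error(simulation_config(n_otus = 50, n_modules = 10,
                                 module_size = 10), "exceeds")
})

test_that("planted hubs and connectors are disjoint and written faithfully", {
  cfg <- simulation_config(n_groups = 1, samples_per_group = 20,
                           n_otus = 100, n_modules = 3, module_size = 20,
                           sequencing_depth = 5000, seed = 8)
  sim <- simulate_otu_table(cfg)
  expect_length(intersect(sim$truth$planted_hubs,
                          sim$truth$planted_connectors), 0)
  expect_true(all(sim$truth$otu_module[sim$truth$planted_hubs] != "background"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(sim$truth, path)
  gt <- utils::read.delim(path)
  expect_equal(nrow(gt), 100)
  expect_setequal(gt$otu_id[gt$is_hub], sim$truth$planted_hubs)
  expect_setequal(gt$otu_id[gt$is_connector], sim$truth$planted_connectors)
})
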