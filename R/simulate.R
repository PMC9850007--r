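#' Configuration for the synthetic OTU-table generator
#'
#' Defaults emulate the study conditions of a three-population giant panda
#' gut-microbiome dataset: 207 captive (GPCAP), 139 Minshan (GPMS) and 148
#' Xiaoxiangling (GPXXL) fecal samples, thousands of OTUs with a
#' heavy-tailed log-normal abundance spectrum spanning the rare (<0.01%)
#' to abundant (>0.1%) classes, and planted blocks of co-varying OTUs that
#' induce modular correlation structure with designated hub and connector
#' nodes.
#'
#' @param n_groups number of sample groups.
#' @param samples_per_group integer vector, one entry per group.
#' @param n_otus total number of OTUs; OTUs beyond the planted modules are
#'   uncorrelated background.
#' @param n_modules number of planted correlation modules.
#' @param module_size OTUs per module; `n_modules * module_size` must not
#'   exceed `n_otus`.
#' @param intra_module_correlation target latent (log-scale) correlation
#'   between members of the same module, in \[0, 1\].
#' @param hub_fraction fraction of each module designated as hubs (largest
#'   factor loading in their module).
#' @param connector_fraction fraction of each module designated as
#'   connectors, which additionally load on the next module.
#' @param abundance_lognormal_mu,abundance_lognormal_sigma location and
#'   scale (log scale, sigma > 0) of the per-OTU baseline abundance
#'   distribution. `sigma >= 2` spans all three abundance classes.
#' @param sequencing_depth reads per sample (multinomial total).
#' @param noise_sd sd of independent log-scale noise added per cell.
#' @param seed integer; the single source of randomness for a simulation.
#' @param group_labels optional group names; defaults to
#'   GPCAP/GPMS/GPXXL for three groups, `G1..Gk` otherwise.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_groups = 3,
                              samples_per_group = c(207, 139, 148),
                              n_otus = 3000,
                              n_modules = 10,
                              module_size = 20,
                              intra_module_correlation = 0.9,
                              hub_fraction = 0.05,
                              connector_fraction = 0.1,
                              abundance_lognormal_mu = 0,
                              abundance_lognormal_sigma = 2.5,
                              sequencing_depth = 50000,
                              noise_sd = 0.5,
                              seed = 1,
                              group_labels = NULL) {
  cfg <- list(n_groups = as.integer(n_groups),
              samples_per_group = as.integer(samples_per_group),
              n_otus = as.integer(n_otus),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              intra_module_correlation = intra_module_correlation,
              hub_fraction = hub_fraction,
              connector_fraction = connector_fraction,
              abundance_lognormal_mu = abundance_lognormal_mu,
              abundance_lognormal_sigma = abundance_lognormal_sigma,
              sequencing_depth = as.integer(sequencing_depth),
              noise_sd = noise_sd,
              seed = as.integer(seed))
  if (length(cfg$samples_per_group) != cfg$n_groups)
    abort("samples_per_group must have length n_groups")
  if (any(cfg$samples_per_group < 1))
    abort("samples_per_group entries must be positive")
  if (cfg$sequencing_depth <= 0) abort("sequencing_depth must be positive")
  if (cfg$abundance_lognormal_sigma <= 0)
    abort("abundance_lognormal_sigma must be > 0")
  for (f in c("intra_module_correlation", "hub_fraction",
              "connector_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      abort("%s must be in [0, 1]", f)
  if (cfg$noise_sd < 0) abort("noise_sd must be >= 0")
  if (cfg$n_modules * cfg$module_size > cfg$n_otus)
    abort("n_modules * module_size exceeds n_otus")
  if (is.null(group_labels)) {
    group_labels <- if (cfg$n_groups == 3) c("GPCAP", "GPMS", "GPXXL")
                    else paste0("G", seq_len(cfg$n_groups))
  }
  if (length(group_labels) != cfg$n_groups)
    abort("group_labels must have length n_groups")
  cfg$group_labels <- as.character(group_labels)
  structure(cfg, class = "simulation_config")
}

# mechanism constants of the generator. Ordinary member loading
# multipliers span [member_lo, member_hi] with full idiosyncratic noise:
# the spread creates a within-module degree gradient once count noise and
# edge thresholding act. Hubs and connectors are high-fidelity trackers
# of their factors: moderate loadings (hub_s, conn_s — large loadings
# would swing them to community dominance and distort every proportion
# through the shared denominator) but idiosyncratic noise scaled down by
# keystone_noise, which is what pushes their correlations above every
# ordinary member's. Module factors share a common component with
# pairwise correlation factor_cor: microbial modules are not orthogonal
# (host-level factors couple them), and it is this overlap that lets a
# connector correlate strongly enough with two modules at once to
# survive edge thresholding. The globally dominant core (top_protect
# fraction, at least 10 OTUs) stays background.
.sim_pars <- list(member_lo = 0.3, member_hi = 0.7, hub_s = 0.8,
                  conn_s = 0.7, conn_bridge = 0.5, keystone_noise = 0.1,
                  factor_cor = 0.3, top_protect = 0.01)

# small fixed lineage vocabulary so composition summaries are exercised;
# genera nested under their phylum, panda-gut flavoured
.tax_vocab <- list(
  Proteobacteria = c("Pseudomonas", "Escherichia-Shigella", "Serratia",
                     "Herbaspirillum", "Acinetobacter", "Bacteriovorax"),
  Firmicutes     = c("Lactobacillus", "Clostridium", "Streptococcus",
                     "Bacillus", "Enterococcus"),
  Bacteroidetes  = c("Pedobacter", "Flavobacterium", "Mucilaginibacter"),
  Actinobacteria = c("Streptomyces", "Mycobacterium"),
  Verrucomicrobia = c("Opitutus")
)

.synth_taxonomy <- function(n_otus, ids) {
  phyla <- names(.tax_vocab)
  ph <- sample(phyla, n_otus, replace = TRUE,
               prob = c(0.4, 0.3, 0.15, 0.1, 0.05))
  gen <- vapply(ph, function(p) sample(.tax_vocab[[p]], 1), "")
  # some lineages left partially unresolved, as real 16S assignments are
  unresolved <- stats::runif(n_otus) < 0.15
  gen[unresolved] <- "unknown"
  tax <- cbind(kingdom = "Bacteria", phylum = ph,
               class = paste0(ph, "ia"), order = paste0(gen, "ales"),
               family = paste0(gen, "aceae"), genus = gen,
               species = "unknown")
  tax[unresolved, c("order", "family")] <- "unknown"
  rownames(tax) <- ids
  tax
}

#' Simulate a grouped OTU count table with planted modules
#'
#' Generative mechanism, all on the log-abundance scale: (1) per-OTU
#' baselines are drawn from a normal with
#' (`abundance_lognormal_mu`, `abundance_lognormal_sigma`), winsorized at
#' the 99th percentile, so expected relative abundances are log-normal
#' and heavy-tailed without a single taxon dominating the community;
#' planted modules occupy the upper-middle abundance band (the dominant
#' stable core stays background) via a permutation of the same draws.
#' (2) Each module has one latent factor per sample (factors share a
#' common host-level component, pairwise correlation 0.3), added to every
#' member's log abundance with loading
#' `noise_sd * sqrt(icc / (1 - icc))`, which makes the latent correlation
#' between two full-loading members equal `icc`
#' (`intra_module_correlation`); ordinary member loadings are spread by
#' U(0.3, 0.7) multipliers so a within-module degree gradient emerges.
#' Planted hubs carry the largest loading in their module (0.8) and
#' planted connectors (0.7) additionally load, more weakly (0.5), on a
#' second rotating target module; both are high-fidelity trackers of
#' their factors, with idiosyncratic noise scaled down tenfold — which is
#' what makes the hub the most strongly connected member and lets
#' connector correlations reach two modules at once. (3) Independent
#' Gaussian noise with sd `noise_sd` is added to every other cell.
#' (4) Each sample's abundances are converted to counts by multinomial
#' sampling at `sequencing_depth`, so row sums equal the depth exactly.
#' All randomness flows from `config$seed`; the same config yields
#' identical output.
#'
#' @param config a [simulation_config()].
#' @return list with elements `table` (an [otu_table()]) and `truth`, the
#'   planted ground truth: `otu_module` (named vector, module label
#'   `"M<i>"` or `"background"`), `planted_hubs`, `planted_connectors`
#'   (disjoint character vectors of OTU ids).
#' @export
simulate_otu_table <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  set.seed(config$seed)
  n_samples <- sum(config$samples_per_group)
  n_otus <- config$n_otus
  otu_ids <- sprintf("OTU_%05d", seq_len(n_otus))
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  groups <- stats::setNames(
    rep(config$group_labels, times = config$samples_per_group), sample_ids)

  baseline <- stats::rnorm(n_otus, config$abundance_lognormal_mu,
                           config$abundance_lognormal_sigma)
  # winsorize the upper tail (99th percentile): a single draw from the
  # far tail would hold most of the community mass, and no real gut
  # community is one taxon — unchecked, its fluctuations would dominate
  # every proportion through the shared denominator
  baseline <- pmin(baseline, config$abundance_lognormal_mu +
                     stats::qnorm(0.99) * config$abundance_lognormal_sigma)

  n_planted <- config$n_modules * config$module_size
  k_top <- max(10, round(.sim_pars$top_protect * n_otus))
  if (n_planted > 0 && n_planted + k_top <= n_otus) {
    # planted modules occupy the upper-middle abundance band: the
    # globally dominant core taxa stay background (compositionally
    # stable), while module members are abundant enough for their
    # correlations to survive count noise but not so dominant that
    # factor-driven swings distort every proportion through the shared
    # denominator. Implemented as a permutation of the same draws, so
    # the marginal abundance spectrum is unchanged.
    ord <- order(baseline, decreasing = TRUE)
    band <- ord[(k_top + 1):(k_top + n_planted)]
    planted_idx <- seq_len(n_planted)
    vals_band <- baseline[band]
    vals_rest <- baseline[-band]
    baseline[planted_idx] <- vals_band[sample.int(n_planted)]
    baseline[-planted_idx] <- vals_rest
  }

  icc <- min(config$intra_module_correlation, 1 - 1e-9)
  base_loading <- if (config$noise_sd > 0)
    config$noise_sd * sqrt(icc / (1 - icc)) else icc

  loading <- matrix(0, n_otus, max(config$n_modules, 1))
  noise_scale <- rep(1, n_otus)
  otu_module <- stats::setNames(rep("background", n_otus), otu_ids)
  hubs <- character(0); connectors <- character(0)
  if (config$n_modules > 0 && config$module_size > 0) {
    n_hub <- round(config$hub_fraction * config$module_size)
    n_conn <- round(config$connector_fraction * config$module_size)
    if (n_hub + n_conn > config$module_size)
      abort("hub_fraction + connector_fraction exceed the module size")
    for (m in seq_len(config$n_modules)) {
      members <- (m - 1) * config$module_size + seq_len(config$module_size)
      # multiplier spread gives a within-module degree gradient (weak
      # members only correlate strongly with strong ones); hubs and
      # connectors get moderate loadings but their idiosyncratic noise
      # is scaled down below, which is what lifts their correlations
      # above every ordinary member's
      s <- stats::runif(config$module_size, .sim_pars$member_lo,
                        .sim_pars$member_hi)
      hub_idx <- seq_len(n_hub)
      conn_idx <- n_hub + seq_len(n_conn)
      s[hub_idx] <- .sim_pars$hub_s
      s[conn_idx] <- .sim_pars$conn_s
      noise_scale[members[c(hub_idx, conn_idx)]] <- .sim_pars$keystone_noise
      # hubs and connectors take their module's median baselines (a
      # within-module permutation of the same draws): abundant enough
      # that count noise cannot erase their correlations, yet small
      # enough that their large factor-driven swings leave no footprint
      # in the compositional denominator
      k <- n_hub + n_conn
      if (k > 0 && k < config$module_size) {
        b <- baseline[members]
        ord <- order(b, decreasing = TRUE)
        mid <- floor((config$module_size - k) / 2) + seq_len(k)
        baseline[members[c(hub_idx, conn_idx)]] <- b[ord[mid]]
        baseline[members[-c(hub_idx, conn_idx)]] <- b[ord[-mid]]
      }
      loading[members, m] <- s * base_loading
      if (n_conn > 0 && config$n_modules > 1) {
        # each connector bridges its own and one other module; the
        # second loading is somewhat weaker so the connector's primary
        # membership stays identifiable. Targets rotate so connectors
        # of one module do not all couple to the same neighbor
        for (j in seq_len(n_conn)) {
          m2 <- (m - 1 + j) %% config$n_modules + 1
          if (m2 == m) m2 <- m %% config$n_modules + 1
          v <- members[conn_idx[j]]
          loading[v, m2] <- .sim_pars$conn_bridge * base_loading
        }
        connectors <- c(connectors, otu_ids[members[conn_idx]])
      }
      if (n_hub > 0) hubs <- c(hubs, otu_ids[members[hub_idx]])
      otu_module[members] <- paste0("M", m)
    }
  }

  z <- matrix(stats::rnorm(n_samples * ncol(loading)),
              n_samples, ncol(loading))
  common <- stats::rnorm(n_samples)
  rf <- .sim_pars$factor_cor
  factors <- sqrt(1 - rf) * z + sqrt(rf) * common
  eta <- matrix(baseline, n_samples, n_otus, byrow = TRUE) +
    factors %*% t(loading)
  if (config$noise_sd > 0) {
    eps <- matrix(stats::rnorm(n_samples * n_otus, 0, config$noise_sd),
                  n_samples, n_otus)
    eta <- eta + sweep(eps, 2, noise_scale, "*")
  }

  counts <- matrix(0L, n_samples, n_otus,
                   dimnames = list(sample_ids, otu_ids))
  for (i in seq_len(n_samples)) {
    w <- exp(eta[i, ] - max(eta[i, ]))
    counts[i, ] <- stats::rmultinom(1, config$sequencing_depth, w / sum(w))
  }

  taxonomy <- .synth_taxonomy(n_otus, otu_ids)
  list(table = otu_table(counts, taxonomy, groups),
       truth = list(otu_module = otu_module,
                    planted_hubs = hubs,
                    planted_connectors = connectors))
}

#' Write the planted ground truth as TSV
#'
#' Columns: otu_id, module, is_hub, is_connector.
#'
#' @param truth the `truth` element returned by [simulate_otu_table()].
#' @param path output file path.
#' @export
write_ground_truth <- function(truth, path) {
  df <- data.frame(otu_id = names(truth$otu_module),
                   module = unname(truth$otu_module),
                   is_hub = names(truth$otu_module) %in% truth$planted_hubs,
                   is_connector =
                     names(truth$otu_module) %in% truth$planted_connectors)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
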