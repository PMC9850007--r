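#' Analysis configuration for the full pipeline
#'
#' Defaults are the conventional values of the co-occurrence workflow this
#' package implements: top 1000 OTUs per group, |rho| >= 0.6 and p <=
#' 0.05 edge filters, major modules with more than 10 nodes, role
#' thresholds 2.5 (Zi) and 0.62 (Pi), keystone thresholds degree > 50 and
#' betweenness < 5000, and rare/abundant cut-offs 0.01% / 0.1%.
#'
#' @param top_n OTUs per network, ranked by mean relative abundance.
#' @param rho_threshold,p_threshold edge filters, in (0, 1].
#' @param adjust_p Benjamini-Hochberg adjust p-values before thresholding.
#' @param min_major_size major-module size cut-off (exclusive).
#' @param zi_threshold,pi_threshold role classification cut-offs.
#' @param keystone_degree_min,keystone_betweenness_max keystone cut-offs.
#' @param rare_threshold,abundant_threshold abundance-class cut-offs on
#'   mean relative abundance.
#' @param dissimilarity_metric `"whittaker"` or `"jaccard"`.
#' @param seed passed to [detect_modules()].
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(top_n = 1000, rho_threshold = 0.6,
                       p_threshold = 0.05, adjust_p = FALSE,
                       min_major_size = 10,
                       zi_threshold = 2.5, pi_threshold = 0.62,
                       keystone_degree_min = 50,
                       keystone_betweenness_max = 5000,
                       rare_threshold = 1e-4, abundant_threshold = 1e-3,
                       dissimilarity_metric = "whittaker", seed = 1) {
  if (top_n < 1) abort("top_n must be >= 1")
  if (rho_threshold <= 0 || rho_threshold > 1 ||
      p_threshold <= 0 || p_threshold > 1)
    abort("thresholds must be in (0, 1]")
  if (rare_threshold > abundant_threshold)
    abort("rare_threshold must not exceed abundant_threshold")
  structure(list(top_n = as.integer(top_n),
                 rho_threshold = rho_threshold, p_threshold = p_threshold,
                 adjust_p = isTRUE(adjust_p),
                 min_major_size = as.integer(min_major_size),
                 zi_threshold = zi_threshold, pi_threshold = pi_threshold,
                 keystone_degree_min = keystone_degree_min,
                 keystone_betweenness_max = keystone_betweenness_max,
                 rare_threshold = rare_threshold,
                 abundant_threshold = abundant_threshold,
                 dissimilarity_metric = match.arg(dissimilarity_metric,
                                                  c("whittaker", "jaccard")),
                 seed = as.integer(seed)),
            class = "run_config")
}

# build profile -> top-N -> correlations -> network for one sample set
.build_stage <- function(table, config, log) {
  profile <- relative_abundance(table, config$rare_threshold,
                                config$abundant_threshold)
  top <- select_top_otus(profile, config$top_n)
  log(sprintf("selected %d of %d OTUs; computing %d x %d Spearman matrix on %d samples",
              length(top), ncol(table$counts), length(top), length(top),
              nrow(table$counts)))
  corr <- suppressWarnings(spearman_matrix(table, top))
  net <- build_network(corr, profile, config$rho_threshold,
                       config$p_threshold, config$adjust_p)
  log(sprintf("thresholds |rho| >= %g, p <= %g: %d nodes, %d edges (dropped %d isolated OTUs)",
              config$rho_threshold, config$p_threshold,
              igraph::vcount(net), igraph::ecount(net),
              length(top) - igraph::vcount(net)))
  list(profile = profile, network = net)
}

# the 8 summary columns of the per-network report row
.summarize_network <- function(label, net, part) {
  es <- edge_sign_summary(net)
  if (igraph::vcount(net) == 0)
    return(data.frame(network = label, n_nodes = 0L, n_edges = 0L,
                      n_pos = 0L, n_neg = 0L, pct_pos = NA_real_,
                      pct_rare = NA_real_, pct_abundant = NA_real_,
                      modularity = NA_real_))
  cls <- igraph::V(net)$abundance_class
  data.frame(network = label,
             n_nodes = igraph::vcount(net), n_edges = es$n_edges,
             n_pos = es$n_pos, n_neg = es$n_neg, pct_pos = es$pct_pos,
             pct_rare = round_half_up(100 * mean(cls == "rare"), 2),
             pct_abundant = round_half_up(100 * mean(cls == "abundant"), 2),
             modularity = part$modularity_q)
}

#' Analyze one sample group
#'
#' Builds the group's co-occurrence network (top-N OTUs by within-group
#' mean relative abundance, Spearman + thresholds) and summarizes it with
#' the standard report columns: node and edge counts, positive/negative
#' edge counts and percentage, rare/abundant node percentages, and
#' modularity of the detected partition.
#'
#' @param table an [otu_table()] containing the group.
#' @param group group label.
#' @param config a [run_config()].
#' @return list with `summary` (one-row data.frame), `network`,
#'   `profile` and `partition` (NULL for an empty network).
#' @export
run_group_analysis <- function(table, group, config = run_config()) {
  sub <- subset_group(table, group)
  stage <- .build_stage(sub, config, log = function(...) invisible())
  net <- stage$network
  part <- if (igraph::ecount(net) > 0)
    detect_modules(net, config$min_major_size, config$seed) else NULL
  list(summary = .summarize_network(group, net, part),
       network = net, profile = stage$profile, partition = part)
}

#' Run the full co-occurrence analysis
#'
#' Builds one network per group plus the combined network over all samples
#' pooled (top-N OTUs by overall mean relative abundance), then detects
#' modules, computes Zi/Pi roles, keystone flags, the role-by-abundance
#' cross-tabulation and ternary coordinates on the combined network, and
#' all pairwise network dissimilarities. With `out_dir` set, emits
#' `summary.tsv`, `modules.tsv`, `module_composition.tsv`, `roles.tsv`,
#' `crosstab.tsv`, `ternary.tsv` (three groups only), `dissimilarity.tsv`,
#' `keystones.tsv`, `networks/<label>.graphml` and a `run.log`; outputs
#' are byte-identical across runs with the same table and config.
#'
#' @param table an [otu_table()] with at least 2 groups.
#' @param config a [run_config()].
#' @param out_dir optional output directory (created if needed).
#' @param groups groups to analyze (default: all in the table).
#' @return (invisibly) list with `summary`, `networks`, `partitions`,
#'   `roles`, `crosstab`, `ternary`, `composition`, `dissimilarity`,
#'   `keystones` and `log`.
#' @export
run_pipeline <- function(table, config = run_config(), out_dir = NULL,
                         groups = NULL) {
  groups <- groups %||% sort(unique(table$groups))
  if (length(groups) < 2) abort("need at least 2 groups")
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)

  networks <- list(); partitions <- list(); summaries <- list()
  for (g in groups) {
    log(sprintf("[%s] group analysis", g))
    res <- run_group_analysis(table, g, config)
    networks[[g]] <- res$network
    partitions[[g]] <- res$partition
    summaries[[g]] <- res$summary
  }

  log("[GP] combined analysis over all samples pooled")
  stage <- .build_stage(table, config, log)
  gp_net <- stage$network
  networks[["GP"]] <- gp_net
  gp_part <- if (igraph::ecount(gp_net) > 0)
    detect_modules(gp_net, config$min_major_size, config$seed) else NULL
  partitions[["GP"]] <- gp_part
  summaries[["GP"]] <- .summarize_network("GP", gp_net, gp_part)
  summary_df <- do.call(rbind, summaries[c("GP", groups)])
  rownames(summary_df) <- NULL

  roles <- NULL; crosstab <- NULL; ternary <- NULL; composition <- NULL
  role_shares <- NULL
  if (!is.null(gp_part)) {
    roles <- role_table(gp_net, gp_part, config$zi_threshold,
                        config$pi_threshold, config$keystone_degree_min,
                        config$keystone_betweenness_max)
    crosstab <- role_abundance_crosstab(roles)
    role_shares <- role_summary(roles)
    composition <- module_composition(gp_net, gp_part, "phylum")
    if (length(groups) == 3) {
      ternary <- ternary_coordinates(stage$profile,
                                     igraph::V(gp_net)$name)
      ternary$module <- unname(gp_part$assignment[ternary$otu_id])
    } else {
      log("ternary coordinates skipped: needs exactly 3 groups")
    }
  }

  keystones <- do.call(rbind, lapply(names(networks), function(lbl) {
    net <- networks[[lbl]]
    if (igraph::vcount(net) == 0) return(NULL)
    ids <- keystone_flags(node_topology(net), config$keystone_degree_min,
                          config$keystone_betweenness_max)
    if (!length(ids)) return(NULL)
    data.frame(network = lbl, otu_id = ids)
  }))

  labels <- names(networks)
  nonempty <- labels[vapply(networks, igraph::ecount, 0) > 0]
  pairs <- if (length(nonempty) >= 2) utils::combn(nonempty, 2) else NULL
  dissimilarity <- if (!is.null(pairs)) {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      cmp <- network_dissimilarity(networks[[pairs[1, i]]],
                                   networks[[pairs[2, i]]],
                                   config$dissimilarity_metric)
      data.frame(network_a = pairs[1, i], network_b = pairs[2, i],
                 shared = cmp$shared_edges, unique_a = cmp$unique_to_first,
                 unique_b = cmp$unique_to_second,
                 dissimilarity = cmp$dissimilarity)
    }))
  } else NULL

  result <- list(summary = summary_df, networks = networks,
                 partitions = partitions, roles = roles,
                 role_summary = role_shares,
                 crosstab = crosstab, ternary = ternary,
                 composition = composition,
                 dissimilarity = dissimilarity, keystones = keystones,
                 log = log_lines)
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  invisible(result)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(file.path(out_dir, "networks"), recursive = TRUE,
             showWarnings = FALSE)
  .write_tsv(result$summary, file.path(out_dir, "summary.tsv"))
  for (lbl in names(result$networks)) {
    net <- result$networks[[lbl]]
    if (igraph::vcount(net) > 0)
      write_network(net, file.path(out_dir, "networks",
                                   paste0(lbl, ".graphml")), "graphml")
  }
  parts <- result$partitions
  mods <- do.call(rbind, lapply(names(parts), function(lbl) {
    p <- parts[[lbl]]
    if (is.null(p)) return(NULL)
    data.frame(network = lbl, otu_id = names(p$assignment),
               module = unname(p$assignment),
               major = unname(p$assignment) %in% p$major_modules)
  }))
  if (!is.null(mods)) .write_tsv(mods, file.path(out_dir, "modules.tsv"))
  if (!is.null(result$composition))
    .write_tsv(result$composition,
               file.path(out_dir, "module_composition.tsv"))
  if (!is.null(result$roles))
    .write_tsv(result$roles, file.path(out_dir, "roles.tsv"))
  if (!is.null(result$crosstab))
    .write_tsv(result$crosstab, file.path(out_dir, "crosstab.tsv"))
  if (!is.null(result$role_summary))
    .write_tsv(result$role_summary, file.path(out_dir, "role_summary.tsv"))
  if (!is.null(result$ternary))
    .write_tsv(result$ternary, file.path(out_dir, "ternary.tsv"))
  if (!is.null(result$dissimilarity))
    .write_tsv(result$dissimilarity,
               file.path(out_dir, "dissimilarity.tsv"))
  if (!is.null(result$keystones))
    .write_tsv(result$keystones, file.path(out_dir, "keystones.tsv"))
  writeLines(result$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
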