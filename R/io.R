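#' Read an OTU table and sample metadata from TSV
#'
#' The table has one row per OTU, one column per sample, and a final
#' `taxonomy` column holding a semicolon-separated lineage (QIIME-style
#' rank prefixes tolerated). The metadata file has columns `sample_id` and
#' `group`. Row and column order are preserved.
#'
#' @param table_path path to the OTU count TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(table_path, metadata_path) {
  raw <- utils::read.delim(table_path, check.names = FALSE,
                           colClasses = "character", sep = "\t")
  if (!"taxonomy" %in% colnames(raw))
    abort("table has no 'taxonomy' column")
  otu_ids <- raw[[1]]
  if (anyDuplicated(otu_ids))
    abort("duplicate OTU id: %s", otu_ids[duplicated(otu_ids)][1])
  sample_cols <- setdiff(colnames(raw)[-1], "taxonomy")
  if (anyDuplicated(sample_cols))
    abort("duplicate sample id: %s", sample_cols[duplicated(sample_cols)][1])

  counts <- matrix(0L, length(sample_cols), length(otu_ids),
                   dimnames = list(sample_cols, otu_ids))
  for (s in sample_cols) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    bad <- which(is.na(v))
    if (length(bad))
      abort("non-numeric count in column '%s', row '%s'", s, otu_ids[bad[1]])
    counts[s, ] <- as.integer(round(v))
  }

  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            colClasses = "character", sep = "\t")
  if (!all(c("sample_id", "group") %in% colnames(meta)))
    abort("metadata must have columns sample_id and group")
  groups <- stats::setNames(meta$group, meta$sample_id)
  missing <- setdiff(sample_cols, names(groups))
  if (length(missing))
    abort("sample missing from metadata: %s", missing[1])

  taxonomy <- parse_taxonomy(stats::setNames(raw$taxonomy, otu_ids))
  otu_table(counts, taxonomy, groups[sample_cols])
}

#' Write an OTU table (and its metadata) as TSV
#'
#' Inverse of [read_otu_table()]: OTUs in rows, samples in columns, final
#' `taxonomy` column with QIIME-style prefixed lineages.
#'
#' @param table an [otu_table()].
#' @param table_path output path for the count table.
#' @param metadata_path output path for the sample metadata.
#' @export
write_otu_table <- function(table, table_path, metadata_path) {
  df <- data.frame(`#OTU ID` = colnames(table$counts),
                   t(table$counts),
                   taxonomy = unname(format_taxonomy(table$taxonomy)),
                   check.names = FALSE)
  colnames(df)[2:(1 + nrow(table$counts))] <- rownames(table$counts)
  utils::write.table(df, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample_id = names(table$groups),
                     group = unname(table$groups))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table_path)
}

#' Write a co-occurrence network to disk
#'
#' GraphML preserves all node attributes (lineage, abundance class, group
#' means, module id when assigned) and edge attributes (rho, p, sign); the
#' edge-list format is a TSV with columns source, target, rho, p, sign.
#'
#' @param net an igraph network from [build_network()].
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (igraph::vcount(net) == 0) abort("refusing to write an empty network")
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net)
    df <- data.frame(source = el[, 1], target = el[, 2],
                     rho = sprintf("%.6g", igraph::E(net)$rho),
                     p = sprintf("%.6g", igraph::E(net)$p),
                     sign = igraph::E(net)$sign)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#'
#' @param path path to a GraphML file.
#' @return an igraph network.
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
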