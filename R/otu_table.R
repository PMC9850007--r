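#' Taxonomic ranks used throughout the package
#'
#' Lineages are stored at seven fixed ranks; shorter input lineages are
#' padded with `"unknown"`.
#' @export
TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family",
               "genus", "species")

#' Construct an OTU table
#'
#' The central data container: an integer count matrix (samples in rows,
#' OTUs in columns), a per-sample group label, and a per-OTU taxonomic
#' lineage at the seven ranks of [TAX_RANKS].
#'
#' @param counts non-negative integer matrix, samples x OTUs, with row and
#'   column names (sample ids and OTU ids).
#' @param taxonomy character matrix (OTUs x 7, rownames = OTU ids) or a
#'   named character vector of semicolon-separated lineage strings; parsed
#'   with [parse_taxonomy()]. Missing ranks become `"unknown"`.
#' @param groups named character vector mapping every sample id to a group
#'   label.
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `taxonomy` (OTUs x 7 character matrix) and `groups`.
#' @export
otu_table <- function(counts, taxonomy, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("counts must have sample rownames and OTU colnames")
  if (anyDuplicated(rownames(counts)))
    abort("duplicate sample id: %s",
          rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    abort("duplicate OTU id: %s",
          colnames(counts)[duplicated(colnames(counts))][1])
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0))
    abort("counts must be finite non-negative numbers")
  if (any(counts != round(counts)))
    abort("counts must be integers")
  storage.mode(counts) <- "integer"

  if (is.character(taxonomy) && is.null(dim(taxonomy)))
    taxonomy <- parse_taxonomy(taxonomy)
  taxonomy <- as.matrix(taxonomy)
  missing_tax <- setdiff(colnames(counts), rownames(taxonomy))
  if (length(missing_tax))
    abort("no taxonomy entry for OTU: %s", missing_tax[1])
  taxonomy <- taxonomy[colnames(counts), , drop = FALSE]
  colnames(taxonomy) <- TAX_RANKS

  groups <- stats::setNames(as.character(groups), names(groups))
  missing_grp <- setdiff(rownames(counts), names(groups))
  if (length(missing_grp))
    abort("sample missing from metadata: %s", missing_grp[1])
  groups <- groups[rownames(counts)]

  structure(list(counts = counts, taxonomy = taxonomy, groups = groups),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs, %d groups (%s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$groups)),
              paste(sort(unique(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Parse semicolon-separated taxonomy lineages
#'
#' QIIME-style rank prefixes (`k__`, `p__`, ...) are tolerated and
#' stripped; empty or missing ranks become `"unknown"`; lineages are padded
#' or truncated to the seven ranks of [TAX_RANKS].
#'
#' @param lineages character vector of lineage strings, optionally named by
#'   OTU id.
#' @return character matrix, length(lineages) x 7.
#' @export
#' @examples
#' parse_taxonomy("k__Bacteria;p__Firmicutes")[1, 1:3]
parse_taxonomy <- function(lineages) {
  out <- t(vapply(lineages, function(s) {
    parts <- trimws(strsplit(s %||% "", ";", fixed = TRUE)[[1]])
    parts <- sub("^[a-zA-Z]__", "", parts)
    parts[parts == "" | is.na(parts)] <- "unknown"
    length(parts) <- length(TAX_RANKS)           # pad with NA
    parts[is.na(parts)] <- "unknown"
    parts
  }, character(length(TAX_RANKS))))
  colnames(out) <- TAX_RANKS
  if (!is.null(names(lineages))) rownames(out) <- names(lineages)
  out
}

#' Format a taxonomy matrix back into lineage strings
#'
#' Inverse of [parse_taxonomy()]: ranks are re-prefixed QIIME-style and
#' `"unknown"` ranks are written as an empty field so round-trips are
#' lossless.
#'
#' @param taxonomy OTUs x 7 character matrix.
#' @return named character vector of lineage strings.
#' @export
format_taxonomy <- function(taxonomy) {
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  apply(taxonomy, 1, function(ranks) {
    ranks[ranks == "unknown"] <- ""
    paste0(prefixes, ranks, collapse = ";")
  })
}

#' Subset an OTU table to the samples of one group
#'
#' @param table an [otu_table()].
#' @param group group label present in `table$groups`.
#' @return an `otu_table` with only that group's samples.
#' @export
subset_group <- function(table, group) {
  keep <- names(table$groups)[table$groups == group]
  if (!length(keep)) abort("unknown group: %s", group)
  otu_table(table$counts[keep, , drop = FALSE], table$taxonomy,
            table$groups[keep])
}
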