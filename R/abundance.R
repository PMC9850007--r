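#' Relative abundances, group means and abundance classes
#'
#' Per-sample proportions are computed from counts (never read from file),
#' averaged arithmetically over all samples in scope and per group, and
#' each OTU is classified as rare (overall mean < `rare_threshold`),
#' abundant (> `abundant_threshold`) or moderate (inclusive boundaries
#' belong to the moderate class). With the default thresholds these are
#' the conventional <0.01% and >0.1% relative-abundance cut-offs.
#'
#' @param table an [otu_table()].
#' @param rare_threshold overall mean below which an OTU is rare.
#' @param abundant_threshold overall mean above which an OTU is abundant.
#' @return an object of class `abundance_profile`: list with
#'   `overall_mean` (named numeric), `group_mean` (OTUs x groups matrix),
#'   `class` (named character: rare/moderate/abundant), `taxonomy`
#'   (carried through from the table) and `n_samples`.
#' @export
relative_abundance <- function(table, rare_threshold = 1e-4,
                               abundant_threshold = 1e-3) {
  totals <- rowSums(table$counts)
  zero <- which(totals == 0)
  if (length(zero))
    abort("sample has zero total count: %s", rownames(table$counts)[zero[1]])
  prop <- table$counts / totals
  overall <- colMeans(prop)
  grps <- sort(unique(table$groups))
  group_mean <- vapply(grps, function(g)
    colMeans(prop[table$groups == g, , drop = FALSE]),
    numeric(ncol(prop)))
  group_mean <- matrix(group_mean, ncol = length(grps),
                       dimnames = list(colnames(prop), grps))
  cls <- ifelse(overall < rare_threshold, "rare",
                ifelse(overall > abundant_threshold, "abundant", "moderate"))
  structure(list(overall_mean = overall,
                 group_mean = group_mean,
                 class = stats::setNames(cls, names(overall)),
                 taxonomy = table$taxonomy,
                 n_samples = nrow(table$counts)),
            class = "abundance_profile")
}

#' Select the top-N OTUs by mean relative abundance
#'
#' Ranking uses the overall mean of per-sample proportions; ties are broken
#' by OTU id in ascending lexicographic order.
#'
#' @param profile an [relative_abundance()] profile.
#' @param n number of OTUs to keep (at least 1); if larger than the number
#'   of OTUs, all are returned.
#' @return character vector of OTU ids, most abundant first.
#' @export
select_top_otus <- function(profile, n = 1000) {
  if (n < 1) abort("n must be >= 1")
  ids <- names(profile$overall_mean)
  ord <- order(-profile$overall_mean, ids)
  ids[ord][seq_len(min(n, length(ids)))]
}

#' Ternary coordinates of OTUs across three groups
#'
#' Each OTU's three group-mean relative abundances are normalized to sum
#' to 1, locating it in the three-population simplex. OTUs with all-zero
#' group means are placed at the centroid (1/3, 1/3, 1/3).
#'
#' @param profile an [relative_abundance()] profile whose table contained
#'   exactly three groups.
#' @param otus optional subset of OTU ids.
#' @return data.frame with `otu_id` and one coordinate column per group;
#'   rows sum to 1.
#' @export
ternary_coordinates <- function(profile, otus = NULL) {
  gm <- profile$group_mean
  if (ncol(gm) != 3)
    abort("ternary coordinates need exactly 3 groups, got %d", ncol(gm))
  if (!is.null(otus)) gm <- gm[otus, , drop = FALSE]
  tot <- rowSums(gm)
  coords <- gm / ifelse(tot == 0, 1, tot)
  coords[tot == 0, ] <- 1 / 3
  data.frame(otu_id = rownames(gm), coords, row.names = NULL,
             check.names = FALSE)
}
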