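.CLUSTER_LEVELS <- c("pre_implantation", "post_implantation", "naive",
                     "formative", "general", "erk_activated",
                     "erk_suppressed", "none")

#' Validate an expression table
#'
#' Expression tables are plain data.frames with one row per gene and columns
#' `gene_id`, `log2fc` (log2 fold change, soft over stiff), `padj`
#' (adjusted p-value) and `cluster` (one of the fixed vocabulary:
#' pre_implantation, post_implantation, naive, formative, general,
#' erk_activated, erk_suppressed, none); an optional `condition` column
#' labels the media condition. Differential-expression estimation itself is
#' an upstream input, not computed here.
#'
#' @param table data.frame.
#' @return the table, invisibly, after validation.
#' @export
validateExpressionTable <- function(table) {
  need <- c("gene_id", "log2fc", "padj", "cluster")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop(sprintf("expression table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (any(table$padj < 0 | table$padj > 1, na.rm = TRUE))
    stop("padj must lie in [0, 1]")
  bad <- setdiff(unique(table$cluster), .CLUSTER_LEVELS)
  if (length(bad))
    stop(sprintf("unknown cluster label(s): %s", paste(bad, collapse = ", ")))
  if ("condition" %in% names(table)) {
    if (anyDuplicated(table[c("gene_id", "condition")]))
      stop("gene ids must be unique within a condition")
  } else if (anyDuplicated(table$gene_id)) {
    stop("gene ids must be unique")
  }
  invisible(table)
}

#' Cumulative log2 fold change of a gene cluster
#'
#' Running cumulative sum of log2 fold change over the genes of one cluster
#' with `|log2fc| > minAbs`. Genes are ordered by descending `|log2fc|`
#' (ties broken by gene id) purely for plotting; the endpoint — the total
#' cluster log2fc, the interpretable quantity — is invariant to the
#' ordering. Opposing systematic stiffness effects on two clusters show up
#' as cumulative series diverging to endpoints of opposite sign.
#'
#' @param table expression table (see [validateExpressionTable()]).
#' @param cluster cluster label to summarise.
#' @param minAbs inclusion threshold on `|log2fc|`, default 0.2.
#' @return list with `cluster`, `includedGenes`, `series` (named cumulative
#'   sums) and `endpoint`.
#' @export
cumulativeLog2fc <- function(table, cluster, minAbs = 0.2) {
  validateExpressionTable(table)
  if (!cluster %in% .CLUSTER_LEVELS)
    stop(sprintf("unknown cluster label: %s", cluster))
  sel <- table[table$cluster == cluster & abs(table$log2fc) > minAbs, , drop = FALSE]
  ord <- order(-abs(sel$log2fc), sel$gene_id)
  sel <- sel[ord, , drop = FALSE]
  series <- cumsum(sel$log2fc)
  names(series) <- sel$gene_id
  list(cluster = cluster,
       includedGenes = nrow(sel),
       series = series,
       endpoint = if (nrow(sel)) sum(sel$log2fc) else 0)
}

#' Fractions of up- and downregulated genes in a cluster
#'
#' Among the significantly regulated genes of a cluster (`padj <
#' padjThreshold`), the percentage with positive log2fc (up on soft) and
#' negative log2fc (down on soft). Genes with log2fc exactly zero are
#' excluded from the denominator, so the two percentages always sum to 100
#' when defined. With no significant genes the percentages are undefined
#' and flagged.
#'
#' @param table expression table.
#' @param cluster cluster label.
#' @param padjThreshold significance threshold, default 0.05.
#' @return list with `cluster`, `pctUp`, `pctDown`, `nSignificant` and
#'   `defined` flag.
#' @export
directionFractions <- function(table, cluster, padjThreshold = 0.05) {
  validateExpressionTable(table)
  if (!cluster %in% .CLUSTER_LEVELS)
    stop(sprintf("unknown cluster label: %s", cluster))
  sel <- table[table$cluster == cluster & table$padj < padjThreshold, , drop = FALSE]
  sel <- sel[sel$log2fc != 0, , drop = FALSE]
  n <- nrow(sel)
  if (n == 0L)
    return(list(cluster = cluster, pctUp = NA_real_, pctDown = NA_real_,
                nSignificant = 0L, defined = FALSE))
  up <- sum(sel$log2fc > 0)
  list(cluster = cluster,
       pctUp = 100 * up / n,
       pctDown = 100 * (n - up) / n,
       nSignificant = n,
       defined = TRUE)
}

#' Concordance of ERK-target regulation with substrate stiffness
#'
#' Direction fractions for the ERK-activated and ERK-suppressed gene
#' clusters (ERK-activated genes are expected mostly down on soft
#' substrates, where ERK activity is lower, and ERK-suppressed genes mostly
#' up), plus a comparison of the mean absolute log2 fold change of
#' ERK-target genes against non-target (`"none"` cluster) genes. When the
#' table carries no non-target genes the magnitude comparison is flagged
#' unavailable.
#'
#' @param table expression table containing both ERK clusters.
#' @param padjThreshold significance threshold for the direction fractions.
#' @return list with `activated` and `suppressed` (each as returned by
#'   [directionFractions()]), `meanAbsLog2fcErk`, `meanAbsLog2fcNonTarget`
#'   and `magnitudeComparisonAvailable`.
#' @export
erkConcordance <- function(table, padjThreshold = 0.05) {
  validateExpressionTable(table)
  for (cl in c("erk_activated", "erk_suppressed"))
    if (!any(table$cluster == cl))
      stop(sprintf("cluster '%s' is absent from the table", cl))
  act <- directionFractions(table, "erk_activated", padjThreshold)
  sup <- directionFractions(table, "erk_suppressed", padjThreshold)
  erk <- table$cluster %in% c("erk_activated", "erk_suppressed")
  non <- table$cluster == "none"
  list(activated = act,
       suppressed = sup,
       meanAbsLog2fcErk = mean(abs(table$log2fc[erk])),
       meanAbsLog2fcNonTarget = if (any(non)) mean(abs(table$log2fc[non])) else NA_real_,
       magnitudeComparisonAvailable = any(non))
}

#' Permutation test for systematic regulation of a gene set
#'
#' Tests whether a selection of genes is systematically differently
#' expressed on soft versus stiff substrates. The observed statistic is the
#' mean log2 fold change of the gene set; the null distribution is the same
#' statistic over random gene sets of identical size drawn without
#' replacement from the whole table. The two-sided p-value compares
#' magnitudes with the add-one correction,
#' \eqn{p = (1 + \#\{|null| \ge |obs|\}) / (n_{perm} + 1)}, so p is always
#' in (0, 1] and exactly 1 in the degenerate case where the gene set is the
#' entire table.
#'
#' @param table expression table.
#' @param geneSet character vector of gene ids, a subset of the table.
#' @param nPermutations number of random gene sets, >= 100. Default 999.
#' @param seed integer seed; the result is fully reproducible given the
#'   seed.
#' @return list with `observedStatistic`, `nullDistribution`, `pValue`,
#'   `nPermutations` and `seed`.
#' @export
permutationSystematic <- function(table, geneSet, nPermutations = 999L,
                                  seed = 1L) {
  validateExpressionTable(table)
  nPermutations <- as.integer(nPermutations)
  if (nPermutations < 100L) stop("nPermutations must be >= 100")
  miss <- setdiff(geneSet, table$gene_id)
  if (length(miss))
    stop(sprintf("gene set contains ids absent from the table (e.g. %s)", miss[1]))
  m <- length(geneSet)
  if (m > nrow(table)) stop("gene set is larger than the table")
  if (m == 0L) stop("gene set is empty")
  x <- table$log2fc
  observed <- mean(x[match(geneSet, table$gene_id)])
  null <- .withSeed(seed, {
    vapply(seq_len(nPermutations),
           function(i) mean(x[sample.int(length(x), m)]), numeric(1))
  })
  p <- (1 + sum(abs(null) >= abs(observed))) / (nPermutations + 1)
  list(observedStatistic = observed,
       nullDistribution = null,
       pValue = p,
       nPermutations = nPermutations,
       seed = seed)
}
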