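#' Build an n×2 contingency table of feature counts for one gene
#'
#' Features (isoforms or TSSs) are ranked by their summed count across the
#' two conditions (ties broken lexicographically by feature id).  When a
#' gene has more than `max_rows` features, the least-expressed ones are
#' pooled into a final `"other"` row so the table never exceeds `max_rows`
#' rows.
#'
#' @param counts_a,counts_b named integer count vectors over the same
#'   features, one per condition.
#' @param gene_id gene the features belong to.
#' @param max_rows maximum table rows (default 11).
#' @return object of class `usage_table`: list with `gene_id`, `counts`
#'   (rows × 2 matrix, columns A and B), `usage` (percent usage per
#'   condition) and `collapsed`.
#' @export
build_contingency <- function(counts_a, counts_b, gene_id = NA_character_,
                              max_rows = 11L) {
  stopifnot(length(counts_a) == length(counts_b))
  feats <- names(counts_a)
  if (is.null(feats)) feats <- paste0("f", seq_along(counts_a))
  stopifnot(identical(feats, names(counts_b) %||% feats))
  total <- counts_a + counts_b
  o <- order(-total, feats)
  counts <- cbind(A = as.numeric(counts_a[o]), B = as.numeric(counts_b[o]))
  rownames(counts) <- feats[o]
  collapsed <- FALSE
  if (nrow(counts) > max_rows) {
    keep <- seq_len(max_rows - 1L)
    pooled <- colSums(counts[-keep, , drop = FALSE])
    counts <- rbind(counts[keep, , drop = FALSE], other = pooled)
    collapsed <- TRUE
  }
  cs <- colSums(counts)
  usage <- sweep(counts, 2L, ifelse(cs > 0, cs, NA_real_), "/") * 100
  structure(list(gene_id = gene_id, counts = counts, usage = usage,
                 collapsed = collapsed), class = "usage_table")
}

#' Is a gene's contingency table testable?
#'
#' A gene is testable when both conditions contribute at least `min_reads`
#' supporting reads and the table has at least two feature rows.
#'
#' @param table a [build_contingency()] result.
#' @param min_reads minimum reads per condition (default 10).
#' @return logical.
#' @export
is_testable <- function(table, min_reads = 10L) {
  all(colSums(table$counts) >= min_reads) && nrow(table$counts) >= 2L
}

#' Pearson chi-squared test on an n×2 usage table
#'
#' The Pearson statistic `sum((O - E)^2 / E)` with expectations from the
#' row/column marginals, `df = rows - 1`, no continuity correction, and an
#' upper-tail p-value.  Rows with zero counts in both conditions are dropped
#' before the degrees of freedom are computed.
#'
#' @param table a testable [build_contingency()] result.
#' @return list with `chi2`, `df`, `p_raw`.
#' @export
chi_squared <- function(table) {
  m <- table$counts
  m <- m[rowSums(m) > 0, , drop = FALSE]
  cs <- colSums(m)
  if (any(cs == 0)) stop("zero column sum: table is untestable")
  if (nrow(m) < 2L) stop("fewer than two non-empty rows")
  E <- outer(rowSums(m), cs) / sum(m)
  chi2 <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1L) * 1L
  list(chi2 = chi2, df = df,
       p_raw = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Delta-pi: change in percent feature usage between conditions
#'
#' With `pi[i, c] = 100 * count[i, c] / colsum[c]`, delta-pi is the sum of
#' `|pi_A - pi_B|` over the two features with the highest summed count
#' across conditions.  It ranges from 0 (identical usage) to 200 (a
#' complete flip between two exclusive features).  The pooled `"other"` row
#' is eligible by default.
#'
#' @param table a [build_contingency()] result with both column sums > 0.
#' @param include_other may the pooled row count among the top two?
#' @return delta-pi in percent points.
#' @export
delta_pi <- function(table, include_other = TRUE) {
  m <- table$counts
  u <- table$usage
  if (any(is.na(u))) stop("delta_pi needs both column sums > 0")
  if (!include_other && table$collapsed) {
    keep <- rownames(m) != "other"
    m <- m[keep, , drop = FALSE]
    u <- u[keep, , drop = FALSE]
  }
  # rows are already ranked by summed count at construction
  top <- seq_len(min(2L, nrow(m)))
  sum(abs(u[top, "A"] - u[top, "B"]))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control over the supplied raw
#' p-values (testable genes only).
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Test genes for differential feature usage between two cell groups
#'
#' For each gene, reads are pooled over the cells of each group, a
#' contingency table over the gene's features is built (pooling beyond
#' `max_rows` rows), testability is checked (≥ `min_reads` per condition and
#' ≥ 2 features), and a Pearson chi-squared test plus delta-pi are computed.
#' Raw p-values of testable genes are BH-adjusted per comparison.  A gene is
#' a significant switch when `p_adj <= alpha` and `dpi >= dpi_min`.  The same
#' machinery serves isoform switching (features = transcripts) and
#' differential TSS usage (features = TSS peaks).
#'
#' @param mat feature × cell count matrix.
#' @param feature_genes named character vector mapping feature id to gene.
#' @param cell_groups named character vector mapping cell id to group.
#' @param pair character vector of the two group labels to compare (A, B).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param dpi_min minimum delta-pi (default 10).
#' @param min_reads minimum reads per gene per condition (default 10).
#' @param max_rows maximum contingency rows (default 11).
#' @param include_other pooled row eligible for delta-pi (default TRUE).
#' @return data.frame with one row per gene: gene_id, n_features, rows,
#'   colsum_a, colsum_b, chi2, df, p_raw, p_adj, dpi, testable, significant.
#' @export
run_usage_tests <- function(mat, feature_genes, cell_groups, pair,
                            alpha = 0.05, dpi_min = 10, min_reads = 10L,
                            max_rows = 11L, include_other = TRUE) {
  stopifnot(length(pair) == 2L)
  cells <- colnames(mat)
  stopifnot(!is.null(cells), all(cells %in% names(cell_groups)))
  grp <- cell_groups[cells]
  in_a <- grp == pair[1]
  in_b <- grp == pair[2]
  if (!any(in_a) || !any(in_b))
    stop("both groups must contain at least one cell")
  sum_a <- Matrix::rowSums(mat[, in_a, drop = FALSE])
  sum_b <- Matrix::rowSums(mat[, in_b, drop = FALSE])
  feats <- rownames(mat)
  stopifnot(all(feats %in% names(feature_genes)))
  genes <- unique(feature_genes[feats])

  res <- lapply(genes, function(g) {
    f <- feats[feature_genes[feats] == g]
    tab <- build_contingency(setNames(sum_a[f], f), setNames(sum_b[f], f),
                             gene_id = g, max_rows = max_rows)
    testable <- is_testable(tab, min_reads)
    row <- data.frame(gene_id = g, n_features = length(f),
                      rows = nrow(tab$counts),
                      colsum_a = sum(tab$counts[, "A"]),
                      colsum_b = sum(tab$counts[, "B"]),
                      chi2 = NA_real_, df = NA_integer_, p_raw = NA_real_,
                      p_adj = NA_real_, dpi = NA_real_,
                      testable = testable, significant = FALSE,
                      stringsAsFactors = FALSE)
    if (testable) {
      cs <- chi_squared(tab)
      row$chi2 <- cs$chi2; row$df <- cs$df; row$p_raw <- cs$p_raw
      row$dpi <- delta_pi(tab, include_other)
    }
    row
  })
  out <- do.call(rbind, res)
  t_idx <- which(out$testable)
  out$p_adj[t_idx] <- bh_adjust(out$p_raw[t_idx])
  out$significant <- out$testable & !is.na(out$p_adj) &
    out$p_adj <= alpha & out$dpi >= dpi_min
  rownames(out) <- NULL
  out
}
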