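#' Per-group mean of a TSS × cell matrix
#'
#' Arithmetic mean of each TSS over the cells of each group.
#'
#' @param mat TSS × cell matrix (dense or sparse).
#' @param groups named character vector mapping cell id to group.
#' @return TSS × group matrix of means.
#' @export
group_means <- function(mat, groups) {
  cells <- colnames(mat)
  stopifnot(!is.null(cells), all(cells %in% names(groups)))
  grp <- groups[cells]
  lev <- unique(grp)
  out <- sapply(lev, function(g) {
    idx <- which(grp == g)
    if (length(idx) == 0L) stop("empty group: ", g)
    Matrix::rowMeans(mat[, idx, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(mat), dimnames = list(rownames(mat), lev))
  out
}

#' Pseudocounted log2 fold change
#'
#' `log2((a + pseudocount) / (b + pseudocount))`: finite for zero means and
#' antisymmetric under swapping the groups; `lfc(0, 0) = 0`.
#'
#' @param mean_a,mean_b non-negative group means.
#' @param pseudocount added to both before the ratio (default 1).
#' @return log2 fold changes.
#' @export
lfc <- function(mean_a, mean_b, pseudocount = 1) {
  stopifnot(all(mean_a >= 0), all(mean_b >= 0))
  log2((mean_a + pseudocount) / (mean_b + pseudocount))
}

#' Classify group-specific TSSs from paired expression/accessibility fold
#' changes
#'
#' Thresholds are `k` standard deviations of each log2-fold-change vector,
#' computed independently over all TSSs of the comparison.  A TSS is
#' `GROUP_A_SPECIFIC` when both its expression and accessibility LFCs exceed
#' `+k*SD` of their respective vectors, `GROUP_B_SPECIFIC` when both fall
#' below `-k*SD`, else `NONE` — agreement in both modalities is required.
#'
#' @param lfc_expr,lfc_acc log2-fold-change vectors over the same TSSs
#'   (A vs B orientation).
#' @param k threshold in standard deviations (default 2).
#' @return character vector of `GROUP_A_SPECIFIC` / `GROUP_B_SPECIFIC` /
#'   `NONE`.
#' @export
classify_specific <- function(lfc_expr, lfc_acc, k = 2) {
  stopifnot(length(lfc_expr) == length(lfc_acc))
  if (length(lfc_expr) < 2L) stop("need at least 2 TSSs to estimate the SD")
  sd_e <- stats::sd(lfc_expr)
  sd_a <- stats::sd(lfc_acc)
  if (sd_e == 0 || sd_a == 0)
    stop("degenerate zero-variance LFC vector")
  thr_e <- k * sd_e
  thr_a <- k * sd_a
  ifelse(lfc_expr > thr_e & lfc_acc > thr_a, "GROUP_A_SPECIFIC",
         ifelse(lfc_expr < -thr_e & lfc_acc < -thr_a, "GROUP_B_SPECIFIC",
                "NONE"))
}

#' Binary expressed/accessible state per TSS
#'
#' A TSS is expressed when its read count reaches `expr_cut` (default 2)
#' and accessible when its normalized accessibility reaches `acc_cut`
#' (default 1000); both cutoffs are inclusive.  Also reports the 2×2
#' agreement table and the percent of TSSs whose two states agree.
#'
#' @param expr_reads per-TSS read counts.
#' @param acc_value per-TSS normalized accessibility.
#' @param expr_cut,acc_cut inclusive cutoffs.
#' @return list with `state` (data.frame expressed/accessible), `table`
#'   (2×2 contingency) and `pct_agree`.
#' @export
binary_state <- function(expr_reads, acc_value, expr_cut = 2,
                         acc_cut = 1000) {
  stopifnot(length(expr_reads) == length(acc_value))
  expressed <- expr_reads >= expr_cut
  accessible <- acc_value >= acc_cut
  tab <- table(expressed = factor(expressed, c(FALSE, TRUE)),
               accessible = factor(accessible, c(FALSE, TRUE)))
  list(state = data.frame(expressed = expressed, accessible = accessible),
       table = tab,
       pct_agree = 100 * mean(expressed == accessible))
}

#' Fraction of multi-TSS genes whose top TSS agrees across modalities
#'
#' Restricted to genes with more than one TSS: for each, the most expressed
#' and the most accessible TSS are compared; a gene is concordant when the
#' two argmax sets intersect (so exact ties count as concordant when
#' compatible).
#'
#' @param expr_means,acc_means named per-TSS mean vectors (same TSSs).
#' @param tss_genes named character vector mapping TSS to gene.
#' @return fraction in \[0, 1\], or `NA` when no gene has more than one TSS.
#' @export
top_tss_concordance <- function(expr_means, acc_means, tss_genes) {
  tss <- names(expr_means)
  stopifnot(!is.null(tss), identical(tss, names(acc_means)),
            all(tss %in% names(tss_genes)))
  by_gene <- split(tss, tss_genes[tss])
  by_gene <- by_gene[lengths(by_gene) > 1L]
  if (length(by_gene) == 0L) return(NA_real_)
  conc <- vapply(by_gene, function(ids) {
    e <- expr_means[ids]; a <- acc_means[ids]
    length(intersect(ids[e == max(e)], ids[a == max(a)])) > 0L
  }, logical(1))
  mean(conc)
}

#' Pearson and Spearman correlation of expression and accessibility
#'
#' @param expr,acc numeric vectors over the same TSSs, length ≥ 3.
#' @return list with `pearson` and `spearman` (NA for zero-variance input).
#' @export
expr_acc_correlation <- function(expr, acc) {
  stopifnot(length(expr) == length(acc), length(expr) >= 3L)
  if (stats::sd(expr) == 0 || stats::sd(acc) == 0)
    return(list(pearson = NA_real_, spearman = NA_real_))
  list(pearson = stats::cor(expr, acc, method = "pearson"),
       spearman = stats::cor(expr, acc, method = "spearman"))
}

#' Integrate TSS expression with TSS chromatin accessibility
#'
#' For each requested group pair: per-group means of both modalities,
#' pseudocounted log2 fold changes, and the two-standard-deviation
#' specificity call requiring agreement in both modalities.
#'
#' @param expr_mat TSS × cell normalized expression matrix.
#' @param acc_mat TSS × cell (or TSS × group) normalized accessibility
#'   matrix over the same TSSs.
#' @param expr_groups named map cell → group for `expr_mat`.
#' @param acc_groups named map cell → group for `acc_mat` (omit when
#'   `acc_mat` is already per group).
#' @param pairs list of 2-vectors of group labels to compare.
#' @param tss_genes optional named map TSS → gene (carried into the output).
#' @param pseudocount pseudocount for the fold changes (default 1).
#' @param k specificity threshold in SDs (default 2).
#' @return data.frame with one row per TSS per comparison: tss_name,
#'   gene_id, pair, group means, lfc_expr, lfc_acc, specificity.
#' @export
integrate_atac <- function(expr_mat, acc_mat, expr_groups, acc_groups = NULL,
                           pairs, tss_genes = NULL, pseudocount = 1, k = 2) {
  stopifnot(identical(rownames(expr_mat), rownames(acc_mat)))
  em <- group_means(expr_mat, expr_groups)
  am <- if (is.null(acc_groups)) as.matrix(acc_mat)
        else group_means(acc_mat, acc_groups)
  out <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2L, all(pr %in% colnames(em)),
              all(pr %in% colnames(am)))
    le <- lfc(em[, pr[1]], em[, pr[2]], pseudocount)
    la <- lfc(am[, pr[1]], am[, pr[2]], pseudocount)
    data.frame(tss_name = rownames(em),
               gene_id = if (is.null(tss_genes)) NA_character_
                         else unname(tss_genes[rownames(em)]),
               pair = paste(pr, collapse = "_vs_"),
               expr_mean_a = em[, pr[1]], expr_mean_b = em[, pr[2]],
               acc_mean_a = am[, pr[1]], acc_mean_b = am[, pr[2]],
               lfc_expr = le, lfc_acc = la,
               specificity = classify_specific(le, la, k),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}
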