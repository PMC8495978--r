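#' Expand read starts into symmetric windows
#'
#' Each read start becomes the 0-based half-open interval
#' `[five_prime_pos - pad, five_prime_pos + pad + 1)`, clipped at zero, so a
#' read whose start jitters around a TSS can still intersect the called
#' peak.
#'
#' @param annotations read annotations with `five_prime_pos`.
#' @param pad bp added on each side (default 25).
#' @return data.frame with read_id, cell_id, chrom, strand, gene_id, start,
#'   end.
#' @export
expand_read_starts <- function(annotations, pad = 25L) {
  data.frame(read_id = annotations$read_id,
             cell_id = annotations$cell_id,
             chrom = annotations$chrom,
             strand = annotations$strand,
             gene_id = annotations$gene_id,
             start = pmax(0L, annotations$five_prime_pos - as.integer(pad)),
             end = annotations$five_prime_pos + as.integer(pad) + 1L,
             stringsAsFactors = FALSE)
}

#' Quantify TSS usage per cell
#'
#' Intersects expanded read-start intervals with the wide intervals of the
#' filtered TSS peaks, requiring at least 1 bp of overlap.  By default a
#' read may only count towards a peak of its own gene (gene gating, which
#' prevents cross-gene bleed at overlapping loci; disable with
#' `gene_gate = FALSE`).  A read overlapping several eligible peaks is
#' assigned to the peak containing its unexpanded start, else the nearest
#' peak, with ties going to the upstream (lower-coordinate) peak.  Counts
#' are raw reads.
#'
#' @param annotations read annotations (one row per read).
#' @param peaks named TSS peaks from [call_ends()].
#' @param pad read-start expansion in bp (default 25).
#' @param gene_gate require the read's gene to match the peak's gene.
#' @param umi deduplicate reads sharing an identical (cell, peak, UMI)
#'   triple before counting (exact-match, no UMI error correction);
#'   requires a `umi` column in `annotations`.  Off by default: counts are
#'   raw reads.
#' @return list with `matrix` (sparse TSS × cell counts), `unassigned`
#'   (named per-cell counts of reads matching no peak), and `assignment`
#'   (per-read peak name or `NA`).  Per cell, `colSums(matrix) + unassigned`
#'   equals the number of input reads (with `umi = TRUE`, the number of
#'   deduplicated molecules).
#' @export
quantify_tss <- function(annotations, peaks, pad = 25L, gene_gate = TRUE,
                         umi = FALSE) {
  stopifnot(nrow(peaks) > 0L, !is.null(peaks$name))
  iv <- expand_read_starts(annotations, pad)
  rd <- GenomicRanges::GRanges(iv$chrom,
                               IRanges::IRanges(start = iv$start + 1L,
                                                end = iv$end),
                               strand = iv$strand)
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(start = peaks$wide_start + 1L,
                                                end = peaks$wide_end),
                               strand = peaks$strand)
  ov <- GenomicRanges::findOverlaps(rd, pk, minoverlap = 1L)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  if (gene_gate) {
    keep <- iv$gene_id[qh] == peaks$gene_id[sh]
    keep[is.na(keep)] <- FALSE
    qh <- qh[keep]; sh <- sh[keep]
  }
  assignment <- rep(NA_integer_, nrow(iv))
  if (length(qh)) {
    # resolve multi-peak overlaps: containment of the unexpanded start wins,
    # then distance to it, then the upstream peak
    start_pos <- annotations$five_prime_pos[qh]
    dist <- pmax(0L, peaks$wide_start[sh] - start_pos,
                 start_pos - (peaks$wide_end[sh] - 1L))
    o <- order(qh, dist, peaks$wide_start[sh])
    first <- !duplicated(qh[o])
    assignment[qh[o][first]] <- sh[o][first]
  }
  cells <- sort(unique(annotations$cell_id))
  cell_idx <- match(annotations$cell_id, cells)
  hit <- !is.na(assignment)
  keep <- rep(TRUE, length(assignment))
  if (umi) {
    if (is.null(annotations$umi))
      stop("umi = TRUE requires a 'umi' column in the annotations")
    keep <- !duplicated(data.frame(cell_idx, assignment, annotations$umi))
  }
  mat <- Matrix::sparseMatrix(i = assignment[hit & keep],
                              j = cell_idx[hit & keep], x = 1L,
                              dims = c(nrow(peaks), length(cells)),
                              dimnames = list(peaks$name, cells))
  unassigned <- tabulate(cell_idx[!hit & keep], nbins = length(cells))
  names(unassigned) <- cells
  list(matrix = mat, unassigned = unassigned,
       assignment = ifelse(hit, peaks$name[assignment], NA_character_))
}

#' Drop cells with too few reads
#'
#' Cells whose total read count falls below `min_reads` (default 500) are
#' removed; the filter is idempotent.
#'
#' @param mat feature × cell count matrix.
#' @param min_reads minimum column sum (inclusive).
#' @return the column subset.
#' @export
filter_cells_by_reads <- function(mat, min_reads = 500L) {
  mat[, Matrix::colSums(mat) >= min_reads, drop = FALSE]
}

#' Reproducibility filter for novel transcripts (single cell)
#'
#' Novel transcript models must be detected (count ≥ 1) in at least
#' `min_cells` sub-cells; transcripts annotated as KNOWN are exempt.
#'
#' @param mat transcript × cell count matrix.
#' @param novelty named character vector of novelty categories per
#'   transcript.
#' @param min_cells minimum detecting cells (default 4).
#' @return character vector of retained transcript ids.
#' @export
filter_novel_transcripts_sc <- function(mat, novelty, min_cells = 4L) {
  ids <- rownames(mat)
  stopifnot(!is.null(ids), all(ids %in% names(novelty)))
  n_cells <- Matrix::rowSums(mat >= 1L)
  keep <- novelty[ids] == "KNOWN" | n_cells >= min_cells
  ids[keep]
}

#' Reproducibility filter for novel transcripts (bulk)
#'
#' Novel transcript models must reach `min_count` copies in at least
#' `min_datasets` replicates; when a per-transcript internal-priming
#' fraction-A is supplied, it must additionally be at most `max_frac_a`.
#' KNOWN transcripts are exempt.
#'
#' @param mat transcript × replicate count matrix.
#' @param novelty named novelty vector per transcript.
#' @param min_count minimum copies per replicate (default 5).
#' @param min_datasets minimum qualifying replicates (default 2).
#' @param frac_a optional named fraction-A vector per transcript.
#' @param max_frac_a maximum tolerated fraction-A (default 0.5).
#' @return character vector of retained transcript ids.
#' @export
filter_novel_transcripts_bulk <- function(mat, novelty, min_count = 5L,
                                          min_datasets = 2L, frac_a = NULL,
                                          max_frac_a = 0.5) {
  ids <- rownames(mat)
  stopifnot(!is.null(ids), all(ids %in% names(novelty)))
  n_reps <- Matrix::rowSums(mat >= min_count)
  keep <- n_reps >= min_datasets
  if (!is.null(frac_a)) keep <- keep & frac_a[ids] <= max_frac_a
  keep <- novelty[ids] == "KNOWN" | keep
  ids[keep]
}

#' Per-cell feature complexity profile
#'
#' For each cell and each feature kind (isoforms, TSSs, TESs, ...), counts
#' the genes expressing at least two distinct features with count ≥ 1 in
#' that cell, plus the cell's total reads.
#'
#' @param mats named list of feature × cell count matrices (one per feature
#'   kind), all sharing cell ids.
#' @param feature_genes named list (parallel to `mats`) of named character
#'   vectors mapping feature id to gene id.
#' @return data.frame with cell_id, total_reads (from the first matrix), and
#'   one `multi_<kind>` column per feature kind.
#' @export
complexity_profile <- function(mats, feature_genes) {
  stopifnot(length(mats) > 0L, !is.null(names(mats)),
            identical(names(mats), names(feature_genes)))
  cells <- colnames(mats[[1]])
  out <- data.frame(cell_id = cells,
                    total_reads = Matrix::colSums(mats[[1]]),
                    stringsAsFactors = FALSE)
  for (kind in names(mats)) {
    m <- mats[[kind]]
    stopifnot(identical(colnames(m), cells))
    genes <- feature_genes[[kind]][rownames(m)]
    det <- m >= 1L
    # number of detected features per gene per cell
    per_gene <- Matrix::fac2sparse(factor(genes)) %*% det
    out[[paste0("multi_", kind)]] <-
      as.integer(Matrix::colSums(per_gene >= 2L))
  }
  rownames(out) <- NULL
  out
}

#' Detection overlap between feature sets
#'
#' Exact set-algebra combination counts over named feature sets (the numbers
#' behind an upset plot), plus — when categories are supplied — a per-category
#' support rate: the fraction of the first (query) set also present in the
#' second (reference) set.
#'
#' @param feature_sets named list of character vectors.
#' @param categories optional named character vector mapping feature id to a
#'   category (e.g. a novelty class).
#' @return list with `upset` (named combination counts,
#'   `+`-separated set names) and, when `categories` is given, `support_rate`
#'   (per-category `|set1 ∩ set2| / |set1|`).
#' @export
detection_overlap <- function(feature_sets, categories = NULL) {
  stopifnot(length(feature_sets) >= 2L, !is.null(names(feature_sets)))
  feats <- unique(unlist(feature_sets))
  member <- sapply(feature_sets, function(s) feats %in% s)
  combo <- apply(member, 1L, function(z)
    paste(names(feature_sets)[z], collapse = "+"))
  out <- list(upset = table(combo))
  if (!is.null(categories)) {
    q <- feature_sets[[1]]
    r <- feature_sets[[2]]
    cats <- categories[q]
    out$support_rate <- vapply(split(q, cats), function(ids)
      mean(ids %in% r), numeric(1))
  }
  out
}
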