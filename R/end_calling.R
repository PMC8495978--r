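#' Configuration for TSS/TES peak calling
#'
#' Bundles the parameters of the end caller.  Defaults follow the analysis
#' the package implements: a 50-bp scanning window; a minimum of 2 supporting
#' long reads (20 for short-read ends); per-gene fractional filters of >10%
#' of the strongest TSS for single-cell TSSs, >5% for bulk TSSs, and >80% of
#' the strongest TES for TESs (no fractional filter in short-read mode);
#' and novelty filters keeping read categories whose relevant end is likely
#' genuine (prefix-ISMs for TSSs, suffix-ISMs for TESs, plus KNOWN/NIC/NNC
#' for both).
#'
#' @param end_type `"tss"` or `"tes"`.
#' @param mode `"sc"` (single-cell long read), `"bulk"` (bulk long read) or
#'   `"short"` (short-read ends: min_reads 20, no novelty or gene-fraction
#'   filter).
#' @param window_size scanning window in bp.
#' @param min_reads minimum reads supporting a peak.
#' @param gene_fraction per-gene fractional threshold (strict `>`), or `NA`
#'   to skip.
#' @param novelty_filter novelty categories whose reads contribute ends, or
#'   `NULL` to skip filtering.
#' @return list of class `end_call_config`.
#' @export
end_call_config <- function(end_type = c("tss", "tes"),
                            mode = c("sc", "bulk", "short"),
                            window_size = 50L,
                            min_reads = NULL,
                            gene_fraction = NULL,
                            novelty_filter = NULL) {
  end_type <- match.arg(end_type)
  mode <- match.arg(mode)
  stopifnot(window_size > 0L)
  if (is.null(min_reads)) min_reads <- if (mode == "short") 20L else 2L
  if (is.null(gene_fraction)) {
    gene_fraction <- if (mode == "short") NA_real_
                     else if (end_type == "tes") 0.80
                     else if (mode == "bulk") 0.05 else 0.10
  }
  if (!is.na(gene_fraction))
    stopifnot(gene_fraction > 0, gene_fraction < 1)
  if (is.null(novelty_filter) && mode != "short") {
    novelty_filter <- c("KNOWN", "NIC", "NNC",
                        if (end_type == "tss") "ISM_PREFIX" else "ISM_SUFFIX")
  }
  structure(list(end_type = end_type, mode = mode,
                 window_size = as.integer(window_size),
                 min_reads = as.integer(min_reads),
                 gene_fraction = gene_fraction,
                 novelty_filter = novelty_filter),
            class = "end_call_config")
}

#' Filter read annotations by novelty category
#'
#' Only reads whose novelty category is in `novelty_filter` contribute ends:
#' prefix-ISM reads retain a credible 5' end, suffix-ISM reads a credible 3'
#' end; GENOMIC, ANTISENSE, INTERGENIC and the other ISM classes are
#' excluded.
#'
#' @param annotations a read-annotation data.frame (see
#'   [read_annotation_table()]).
#' @param config an [end_call_config()], or a character vector of categories.
#' @return the annotation subset.
#' @export
filter_reads_by_novelty <- function(annotations, config) {
  keep_set <- if (inherits(config, "end_call_config")) config$novelty_filter
              else config
  if (is.null(keep_set)) return(annotations)
  annotations[annotations$novelty %in% keep_set, , drop = FALSE]
}

#' Tally read end positions per chromosome and strand
#'
#' TSS mode tallies the biological 5' end (`five_prime_pos`), TES mode the 3'
#' end (`three_prime_pos`); counts are raw read counts.  Gene contributions
#' per position are retained for downstream peak-to-gene assignment.
#'
#' @param annotations filtered read annotations.
#' @param end_type `"tss"` or `"tes"`.
#' @return a `data.table` with columns chrom, strand, pos, gene_id, count
#'   (one row per distinct (chrom, strand, pos, gene) combination).
#' @export
collect_end_positions <- function(annotations, end_type = c("tss", "tes")) {
  end_type <- match.arg(end_type)
  pos <- if (end_type == "tss") annotations$five_prime_pos
         else annotations$three_prime_pos
  dt <- data.table::data.table(chrom = annotations$chrom,
                               strand = annotations$strand,
                               pos = as.integer(pos),
                               gene_id = annotations$gene_id)
  out <- dt[, list(count = .N), by = c("chrom", "strand", "pos", "gene_id")]
  data.table::setkeyv(out, c("chrom", "strand", "pos"))
  out[]
}

#' Call end peaks by window chaining
#'
#' Within each (chromosome, strand), distinct end positions are chained into
#' a cluster wherever the gap between consecutive positions is at most
#' `window_size`.  Per cluster: the summit is the highest-count position
#' (ties broken 5'-most in transcript orientation, i.e. lowest coordinate on
#' `+`, highest on `-`); the wide peak spans the cluster
#' (`[min, max+1)` half-open); the narrow peak is the summit ±
#' `window_size/2`, clipped to the wide peak; the read count is the cluster
#' sum.  Clusters supported by fewer than `min_reads` reads are dropped.
#' No per-position pre-filter is applied.
#'
#' @param position_counts output of [collect_end_positions()], or any
#'   data.frame with chrom, strand, pos, count (gene_id optional).
#' @param config an [end_call_config()].
#' @return data.frame of peaks: chrom, strand, wide_start, wide_end,
#'   narrow_start, narrow_end, summit, read_count (0-based half-open
#'   intervals, summit a single 0-based position).
#' @export
call_end_peaks <- function(position_counts, config = end_call_config()) {
  dt <- data.table::as.data.table(position_counts)
  # collapse per-gene rows to per-position totals
  pc <- dt[, list(count = sum(count)), by = c("chrom", "strand", "pos")]
  data.table::setorderv(pc, c("chrom", "strand", "pos"))
  w <- config$window_size
  half <- w %/% 2L
  pc[, cluster := cumsum(c(1L, (diff(pos) > w) * 1L)),
     by = c("chrom", "strand")]
  peaks <- pc[, {
    idx <- which(count == max(count))
    summit_pos <- if (strand[1] == "-") pos[max(idx)] else pos[min(idx)]
    list(wide_start = min(pos), wide_end = max(pos) + 1L,
         summit = summit_pos, read_count = sum(count))
  }, by = c("chrom", "strand", "cluster")]
  peaks[, narrow_start := pmax(wide_start, summit - half)]
  peaks[, narrow_end := pmin(wide_end, summit + half + 1L)]
  peaks <- peaks[read_count >= config$min_reads]
  peaks[, cluster := NULL]
  data.table::setcolorder(peaks, c("chrom", "strand", "wide_start",
                                   "wide_end", "narrow_start", "narrow_end",
                                   "summit", "read_count"))
  as.data.frame(peaks)
}

#' Assign each peak its gene by majority vote of supporting reads
#'
#' A peak's gene is the majority gene among the filtered reads whose counted
#' end falls in the wide peak; ties are broken in favour of the gene with the
#' larger total read count genome-wide; reads without a gene are excluded
#' from the vote, and peaks supported only by gene-less reads are dropped.
#'
#' @param peaks output of [call_end_peaks()].
#' @param position_counts the per-gene position tallies from
#'   [collect_end_positions()].
#' @return peaks with a `gene_id` column.
#' @export
assign_peak_gene <- function(peaks, position_counts) {
  pc <- data.table::as.data.table(position_counts)
  pc <- pc[!is.na(gene_id) & gene_id != ""]
  totals <- pc[, list(total = sum(count)), by = "gene_id"]
  gene_of <- function(chr, str, lo, hi) {
    votes <- pc[chrom == chr & strand == str & pos >= lo & pos < hi,
                list(n = sum(count)), by = "gene_id"]
    if (nrow(votes) == 0L) return(NA_character_)
    votes <- merge(votes, totals, by = "gene_id")
    data.table::setorderv(votes, c("n", "total", "gene_id"),
                          order = c(-1L, -1L, 1L))
    votes$gene_id[1L]
  }
  peaks$gene_id <- vapply(seq_len(nrow(peaks)), function(i)
    gene_of(peaks$chrom[i], peaks$strand[i],
            peaks$wide_start[i], peaks$wide_end[i]), character(1))
  peaks[!is.na(peaks$gene_id), , drop = FALSE]
}

#' Per-gene fractional peak filter
#'
#' Within each gene, let M be the read count of the strongest peak; peaks
#' with `read_count > gene_fraction * M` (strict inequality) are retained.
#' The strongest peak itself always survives.
#'
#' @param peaks gene-assigned peaks.
#' @param gene_fraction fractional threshold in (0, 1); `NA` disables the
#'   filter.
#' @return the retained peaks.
#' @export
filter_peaks_by_gene_fraction <- function(peaks, gene_fraction) {
  if (is.na(gene_fraction) || nrow(peaks) == 0L) return(peaks)
  dt <- data.table::as.data.table(peaks)
  dt[, gene_max := max(read_count), by = "gene_id"]
  out <- dt[read_count > gene_fraction * gene_max]
  out[, gene_max := NULL]
  as.data.frame(out)
}

#' Name peaks `<gene>_<k>` by genomic coordinate
#'
#' Within each gene, peaks are numbered 1..k by ascending genomic summit
#' coordinate, deterministically; renaming is idempotent.
#'
#' @param peaks gene-assigned peaks.
#' @return peaks with a `name` column.
#' @export
name_peaks <- function(peaks) {
  if (nrow(peaks) == 0L) { peaks$name <- character(0); return(peaks) }
  dt <- data.table::as.data.table(peaks)
  data.table::setorderv(dt, c("gene_id", "summit"))
  dt[, name := paste0(gene_id, "_", seq_len(.N)), by = "gene_id"]
  as.data.frame(dt)
}

#' Call, filter and name TSS or TES peaks from read annotations
#'
#' The full end-calling path: novelty filtering, per-position end tallies,
#' window chaining, the minimum-read filter, peak-to-gene assignment, the
#' per-gene fractional filter, and coordinate-ordered naming.
#'
#' @param annotations read-annotation data.frame.
#' @param config an [end_call_config()].
#' @return named, gene-assigned peaks (data.frame).
#' @export
call_ends <- function(annotations, config = end_call_config()) {
  ann <- filter_reads_by_novelty(annotations, config)
  pc <- collect_end_positions(ann, config$end_type)
  peaks <- call_end_peaks(pc, config)
  peaks <- assign_peak_gene(peaks, pc)
  peaks <- filter_peaks_by_gene_fraction(peaks, config$gene_fraction)
  peaks <- name_peaks(peaks)
  peaks$end_type <- config$end_type
  peaks
}

#' Short-read 5'-end filter: exact template-switching oligo
#'
#' A short read is a credible 5'-end read when it contains the complete
#' template-switching oligo with zero errors at full length (the semantics of
#' a non-anchored 5' adapter search at zero error rate with a minimum overlap
#' equal to the adapter length: internal occurrences count, partial or
#' mismatched ones do not).
#'
#' @param read_sequence character vector of read sequences.
#' @param tso the template-switching oligo (default
#'   `"AACGCAGAGTGAATGGG"`).
#' @return logical vector.
#' @export
short_read_tss_filter <- function(read_sequence,
                                  tso = "AACGCAGAGTGAATGGG") {
  grepl(tso, read_sequence, fixed = TRUE)
}

#' Short-read 3'-end filter: A-rich window
#'
#' A short read is a credible 3'-end read when some 20-bp window contains at
#' least 10 `A`s (a 20-A adapter matched at 50% error rate over its full
#' length).
#'
#' @param read_sequence character vector of read sequences.
#' @param window window length in bp (default 20).
#' @param min_a minimum `A`s in the window (default 10).
#' @return logical vector.
#' @export
short_read_tes_filter <- function(read_sequence, window = 20L, min_a = 10L) {
  vapply(read_sequence, function(s) {
    n <- nchar(s)
    if (n < window) return(FALSE)
    is_a <- as.integer(strsplit(s, "", fixed = TRUE)[[1]] == "A")
    cs <- cumsum(c(0L, is_a))
    any(cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)] >= min_a)
  }, logical(1), USE.NAMES = FALSE)
}

#' Intersect peaks with external validation sets
#'
#' A peak is supported by a validation source when its wide interval overlaps
#' any interval of that source by at least 1 bp (0-based half-open
#' coordinates on both sides; assemblies are assumed to match — a mismatch is
#' not detectable from coordinates alone).
#'
#' @param peaks called peaks (with wide_start/wide_end/chrom).
#' @param validation_sets named list of BED-like data.frames (chrom, start,
#'   end) or `GRanges`.
#' @return list with `support` (logical peak × source matrix),
#'   `fraction_supported` (share of peaks overlapping at least one source)
#'   and `upset` (named counts per source combination; names are
#'   `+`-separated source names, `"none"` for unsupported peaks).
#' @export
intersect_with_validation <- function(peaks, validation_sets) {
  stopifnot(length(validation_sets) > 0L, !is.null(names(validation_sets)))
  pk <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(start = peaks$wide_start + 1L, end = peaks$wide_end))
  support <- sapply(validation_sets, function(v) {
    if (!methods::is(v, "GRanges")) {
      v <- GenomicRanges::GRanges(
        v$chrom, IRanges::IRanges(start = v$start + 1L, end = v$end))
    }
    IRanges::overlapsAny(pk, v, ignore.strand = TRUE)
  })
  support <- matrix(support, nrow = nrow(peaks),
                    dimnames = list(peaks$name, names(validation_sets)))
  combo <- apply(support, 1L, function(z)
    if (any(z)) paste(colnames(support)[z], collapse = "+") else "none")
  list(support = support,
       fraction_supported = mean(rowSums(support) > 0),
       upset = table(combo))
}
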