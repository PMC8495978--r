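# Small deterministic fixtures and independent oracles shared across tests.

# A minimal layout with 8-bp barcodes: 2 round-1 barcodes (one dT + one hex
# well), 2 round-2, 2 round-3.
toy_layout <- function() {
  r1 <- c("AAAAAAAA", "CCCCCCCC")
  r2 <- c("GGGGGGGG", "TTTTTTTT")
  r3 <- c("ACACACAC", "GTGTGTGT")
  barcode_layout(
    list(r1, r2, r3),
    linkers = c("GTGGCCGATGTTTCGCATCGGC", "ATCCACGTGCTTGAGAGGCCAG"),
    umi_length = 10,
    priming_map = setNames(c("OLIGO_DT", "RANDOM_HEXAMER"), r1),
    well_pair_map = setNames(c("W01", "W01"), r1))
}

# forward-strand read construction: cDNA | UMI | bc3 | linker1 | bc2 |
# linker2 | bc1
build_read <- function(layout, bc1, bc2, bc3,
                       umi = strrep("A", layout$umi_length),
                       cdna = strrep("CGT", 20)) {
  paste0(cdna, umi, bc3, layout$linkers[1], bc2, layout$linkers[2], bc1)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# annotation row builder with defaults
ann_rows <- function(n, chrom = "chr1", strand = "+", five = 100L,
                     three = 5000L, gene = "geneA", cell = "cell_1",
                     novelty = "KNOWN", transcript = "tx1") {
  data.frame(read_id = sprintf("r%03d", seq_len(n)), cell_id = cell,
             chrom = chrom, strand = strand,
             five_prime_pos = as.integer(five),
             three_prime_pos = as.integer(three),
             gene_id = gene, transcript_id = transcript, novelty = novelty,
             priming = "OLIGO_DT", dataset = "d1",
             stringsAsFactors = FALSE)
}

# brute-force whitelist correction oracle (all-pairs Levenshtein via adist)
oracle_correct <- function(raw, whitelist, max_dist) {
  d <- as.vector(utils::adist(raw, whitelist))
  mn <- min(d)
  hits <- which(d == mn)
  if (mn > max_dist) list(barcode = NA_character_, status = "UNCORRECTABLE")
  else if (length(hits) > 1L) list(barcode = NA_character_,
                                   status = "AMBIGUOUS")
  else list(barcode = whitelist[hits], status = "OK")
}

# exhaustive gap-clustering oracle for the end caller, one (chrom, strand)
oracle_cluster <- function(pos, count, window, min_reads, strand = "+") {
  o <- order(pos)
  pos <- pos[o]; count <- count[o]
  brk <- c(1L, which(diff(pos) > window) + 1L)
  id <- rep(seq_along(brk), diff(c(brk, length(pos) + 1L)))
  out <- lapply(split(seq_along(pos), id), function(ix) {
    p <- pos[ix]; cnt <- count[ix]
    best <- which(cnt == max(cnt))
    summit <- if (strand == "-") max(p[best]) else min(p[best])
    data.frame(wide_start = min(p), wide_end = max(p) + 1L,
               summit = summit, read_count = sum(cnt))
  })
  res <- do.call(rbind, out)
  res[res$read_count >= min_reads, , drop = FALSE]
}

# brute-force step-up BH oracle
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force read-to-TSS assignment oracle mirroring the documented rules
oracle_quant <- function(ann, peaks, pad = 25L, gene_gate = TRUE) {
  assign <- rep(NA_character_, nrow(ann))
  for (i in seq_len(nrow(ann))) {
    lo <- max(0L, ann$five_prime_pos[i] - pad)
    hi <- ann$five_prime_pos[i] + pad + 1L
    cand <- which(peaks$chrom == ann$chrom[i] &
                    peaks$strand == ann$strand[i] &
                    peaks$wide_start < hi & peaks$wide_end > lo)
    if (gene_gate) cand <- cand[peaks$gene_id[cand] == ann$gene_id[i]]
    if (length(cand) == 0L) next
    s <- ann$five_prime_pos[i]
    d <- pmax(0L, peaks$wide_start[cand] - s,
              s - (peaks$wide_end[cand] - 1L))
    cand <- cand[order(d, peaks$wide_start[cand])]
    assign[i] <- peaks$name[cand[1L]]
  }
  assign
}

# exhaustive multi-feature gene recount per cell
oracle_complexity <- function(mat, genes) {
  vapply(seq_len(ncol(mat)), function(j) {
    det <- rownames(mat)[mat[, j] >= 1]
    sum(table(genes[det]) >= 2)
  }, numeric(1))
}
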