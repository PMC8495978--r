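#' Read and validate a read-annotation table
#'
#' The 11-column TSV schema mirrors a long-read annotation export: read_id,
#' cell_id, chrom, strand, five_prime_pos, three_prime_pos, gene_id,
#' transcript_id, novelty, priming, dataset.  Coordinates are 0-based; the
#' 5' coordinate is the biological start (so on the minus strand
#' `five_prime_pos >= three_prime_pos`).  Malformed rows (bad strand,
#' negative coordinate, unknown novelty, end order violating the strand) are
#' rejected with a warning listing their line numbers; a missing column is a
#' hard error.
#'
#' @param path TSV path (with header).
#' @return validated data.frame of annotations.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("read_id", "cell_id", "chrom", "strand", "five_prime_pos",
                "three_prime_pos", "gene_id", "transcript_id", "novelty",
                "priming", "dataset")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("annotation table missing required column(s): ",
         paste(missing, collapse = ", "))
  df <- df[required]
  novelties <- c("KNOWN", "ISM_PREFIX", "ISM_SUFFIX", "ISM_OTHER", "NIC",
                 "NNC", "ANTISENSE", "INTERGENIC", "GENOMIC")
  bad <- !(df$strand %in% c("+", "-")) |
    is.na(df$five_prime_pos) | df$five_prime_pos < 0 |
    is.na(df$three_prime_pos) | df$three_prime_pos < 0 |
    !(df$novelty %in% novelties) |
    (df$strand == "+" & df$five_prime_pos > df$three_prime_pos) |
    (df$strand == "-" & df$five_prime_pos < df$three_prime_pos)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    warning("rejected ", sum(bad), " malformed annotation row(s) at line(s) ",
            paste(utils::head(which(bad) + 1L, 20L), collapse = ", "),
            if (sum(bad) > 20L) ", ..." else "")
    df <- df[!bad, , drop = FALSE]
  }
  df$five_prime_pos <- as.integer(df$five_prime_pos)
  df$three_prime_pos <- as.integer(df$three_prime_pos)
  rownames(df) <- NULL
  df
}

#' @rdname read_annotation_table
#' @param annotations annotation data.frame.
#' @export
write_annotation_table <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BED interval file
#'
#' BED3+ with 0-based half-open coordinates.  Intervals with `start >= end`
#' or negative starts are a hard error.  Output is sorted stably by
#' (chrom, start, end, name).
#'
#' @param path BED path (tab-separated, no header).
#' @return data.frame with chrom, start, end and, when present, name,
#'   score, strand.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "narrow_start", "narrow_end", "summit")
  names(df) <- cols[seq_len(min(ncol(df), length(cols)))]
  if (any(df$start < 0)) stop("negative start coordinate in ", path)
  if (any(df$start >= df$end))
    stop("start >= end in ", path, " at row(s) ",
         paste(utils::head(which(df$start >= df$end), 10L), collapse = ", "))
  o <- do.call(order, df[intersect(c("chrom", "start", "end", "name"),
                                   names(df))])
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write called peaks as BED6+3
#'
#' Columns: chrom, wide_start, wide_end, name, read_count, strand,
#' narrow_start, narrow_end, summit — all 0-based half-open (the summit a
#' single base).
#'
#' @param peaks peaks from [call_ends()].
#' @param path output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$wide_start, peaks$wide_end,
                   peaks$name, peaks$read_count, peaks$strand,
                   peaks$narrow_start, peaks$narrow_end, peaks$summit)
  o <- order(df[[1]], df[[2]], df[[3]], df[[4]])
  utils::write.table(df[o, ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peaks written by [write_peaks_bed()]
#' @param path BED6+3 path.
#' @return peaks data.frame.
#' @export
read_peaks_bed <- function(path) {
  df <- read_bed(path)
  data.frame(chrom = df$chrom, strand = df$strand,
             wide_start = df$start, wide_end = df$end,
             narrow_start = df$narrow_start, narrow_end = df$narrow_end,
             summit = df$summit, read_count = df$score, name = df$name,
             gene_id = sub("_[0-9]+$", "", df$name),
             stringsAsFactors = FALSE)
}

#' Read / write sparse count matrices as MatrixMarket triplets
#'
#' The matrix goes to `<prefix>.mtx` with row ids in `<prefix>.rows.txt`
#' and column ids in `<prefix>.cols.txt`.
#'
#' @param prefix path prefix.
#' @return `read_count_matrix` returns a sparse `dgCMatrix`;
#'   `write_count_matrix` returns `prefix` invisibly.
#' @export
read_count_matrix <- function(prefix) {
  mtx <- paste0(prefix, ".mtx")
  if (!file.exists(mtx)) stop("matrix file not found: ", mtx)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  dimnames(m) <- list(readLines(paste0(prefix, ".rows.txt")),
                      readLines(paste0(prefix, ".cols.txt")))
  m
}

#' @rdname read_count_matrix
#' @param mat feature × cell matrix.
#' @export
write_count_matrix <- function(mat, prefix) {
  Matrix::writeMM(methods::as(mat, "CsparseMatrix"), paste0(prefix, ".mtx"))
  writeLines(rownames(mat), paste0(prefix, ".rows.txt"))
  writeLines(colnames(mat), paste0(prefix, ".cols.txt"))
  invisible(prefix)
}

#' Read / write FASTQ
#'
#' Four-line records, Phred+33 qualities passed through verbatim.
#'
#' @param path FASTQ path.
#' @return `read_fastq` returns a list with `seq` (named `DNAStringSet`,
#'   names truncated at the first space) and `qual` (named character).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  seq <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(seq)$qualities)
  ids <- sub("\\s.*$", "", names(seq))
  names(seq) <- ids
  names(qual) <- ids
  list(seq = seq, qual = qual)
}

#' @rdname read_fastq
#' @param seq named `DNAStringSet` (or named character vector).
#' @param qual named character vector of quality strings; defaults to
#'   constant 'I'.
#' @export
write_fastq <- function(seq, path, qual = NULL) {
  if (!methods::is(seq, "DNAStringSet"))
    seq <- Biostrings::DNAStringSet(seq)
  if (is.null(qual)) qual <- strrep("I", Biostrings::width(seq))
  Biostrings::writeXStringSet(seq, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Run the full pipeline on simulated data
#'
#' Executes every stage end to end on seed-controlled synthetic inputs:
#' read simulation → demultiplexing → end-annotation simulation for the
#' demuxed cells → TSS and TES calling → TSS quantification → differential
#' usage testing between two synthetic groups → accessibility simulation and
#' ATAC integration.  All outputs are written under `out_dir` as plain-text
#' files, and a manifest records stage parameters and content checksums so a
#' rerun can be verified byte-for-byte.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master RNG seed; each stage derives its own fixed offset.
#' @param n_reads reads for the demux stage.
#' @param n_cells simulated cells.
#' @param n_genes simulated genes.
#' @param reads_fastq optional existing FASTQ to demultiplex instead of
#'   simulating reads; missing file is a fail-fast error naming the stage.
#' @return named character vector of md5 checksums of every output file
#'   (also written to `manifest.json` with the stage parameters).
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_reads = 2000L, n_cells = 24L,
                         n_genes = 12L, reads_fastq = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- list(seed = seed, n_reads = n_reads, n_cells = n_cells,
                 n_genes = n_genes)

  # stage 1: demultiplex (simulated unless a FASTQ is supplied)
  layout <- sim_barcode_layout(seed = seed)
  write_layout(layout, file.path(out_dir, "layout.yaml"))
  if (!is.null(reads_fastq)) {
    if (!file.exists(reads_fastq))
      stop("demux: missing input FASTQ: ", reads_fastq)
    fq_path <- reads_fastq
  } else {
    sim <- simulate_barcoded_reads(layout, n_reads = n_reads,
                                   n_cells = n_cells, seed = seed + 1L)
    fq_path <- file.path(out_dir, "reads.fastq")
    write_fastq(sim$seq, fq_path, qual = sim$qual)
  }
  dm <- demux_reads(fq_path, layout,
                    trimmed_fastq = file.path(out_dir, "trimmed.fastq"))
  utils::write.table(dm$records, file.path(out_dir, "demux_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 2: end annotations for the demuxed cells + end calling
  models <- sim_gene_models(n_genes = n_genes, seed = seed + 2L)
  ends <- simulate_end_annotations(models, reads_per_gene = c(100L, 300L),
                                   n_cells = n_cells, seed = seed + 3L)
  ann_path <- file.path(out_dir, "read_annotations.tsv")
  write_annotation_table(ends$annotations, ann_path)
  ann <- read_annotation_table(ann_path)
  tss <- call_ends(ann, end_call_config("tss", "sc"))
  tes <- call_ends(ann, end_call_config("tes", "sc"))
  write_peaks_bed(tss, file.path(out_dir, "tss.bed"))
  write_peaks_bed(tes, file.path(out_dir, "tes.bed"))

  # stage 3: TSS quantification
  q <- quantify_tss(ann, tss)
  write_count_matrix(q$matrix, file.path(out_dir, "tss_counts"))

  # stage 4: differential usage on planted switches
  uc <- simulate_usage_counts(n_genes = 50L, n_switch = 5L,
                              pi_a = c(0.8, 0.2, rep(0, 3)),
                              reads_per_group = 100L, seed = seed + 4L)
  ut <- run_usage_tests(uc$matrix, uc$feature_genes, uc$cell_groups,
                        pair = c("A", "B"))
  utils::write.table(ut, file.path(out_dir, "usage_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # stage 5: ATAC integration on coupled accessibility
  groups <- setNames(rep(c("G1", "G2"), length.out = ncol(q$matrix)),
                     colnames(q$matrix))
  em <- group_means(q$matrix, groups)
  am <- apply(em, 2L, function(x)
    simulate_accessibility(x, target_r = 0.8, seed = seed + 5L))
  dimnames(am) <- dimnames(em)
  le <- lfc(em[, 1], em[, 2])
  la <- lfc(am[, 1], am[, 2])
  integ <- data.frame(tss_name = rownames(em), lfc_expr = le, lfc_acc = la,
                      row.names = NULL)
  utils::write.table(integ, file.path(out_dir, "integration.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  files <- c("layout.yaml", "demux_report.tsv", "read_annotations.tsv",
             "tss.bed", "tes.bed", "tss_counts.mtx", "tss_counts.rows.txt",
             "tss_counts.cols.txt", "usage_tests.tsv", "integration.tsv")
  sums <- tools::md5sum(file.path(out_dir, files))
  names(sums) <- files
  manifest <- list(params = params, checksums = as.list(sums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  sums
}
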