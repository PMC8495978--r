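#' Locate the inter-barcode linkers in a raw long read
#'
#' Searches for both linker sequences in the read and in its reverse
#' complement, each within a bounded window inferred from the layout geometry
#' (the barcode block sits at the 3' end of the forward-oriented read, so the
#' expected linker positions follow from the read length; a ±10 bp slack
#' absorbs indels).  Each linker must match with at most
#' `layout$max_linker_errors` edits (substitutions or indels).  The
#' orientation whose linker placements have the lower total edit distance
#' wins; ties go to forward.
#'
#' @param read_sequence a single read sequence (character or `DNAString`),
#'   uppercase ACGTN.
#' @param layout a [barcode_layout()].
#' @param slack positional slack around the expected linker location (bp).
#' @return On success, a list with `status = "OK"`, `orientation` (`"FORWARD"`
#'   or `"REVERSE_COMPLEMENT"`), `oriented_seq`, and 1-based inclusive
#'   coordinates `linker1` and `linker2` (each `c(start, end)`) on the
#'   oriented read.  On failure, `list(status = "NO_LINKERS")`.
#' @export
locate_linkers <- function(read_sequence, layout, slack = 10L) {
  seq_fwd <- as.character(read_sequence)
  if (nchar(seq_fwd) == 0L) stop("empty read sequence")
  fwd <- .place_linkers(seq_fwd, layout, slack)
  # a perfect forward placement cannot be beaten; skip the RC search
  if (!is.null(fwd) && fwd$score == 0L) {
    return(c(list(status = "OK", orientation = "FORWARD",
                  oriented_seq = seq_fwd), fwd[c("linker1", "linker2")]))
  }
  seq_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq_fwd)))
  rev <- .place_linkers(seq_rc, layout, slack)
  if (is.null(fwd) && is.null(rev)) return(list(status = "NO_LINKERS"))
  use_fwd <- !is.null(fwd) && (is.null(rev) || fwd$score <= rev$score)
  hit <- if (use_fwd) fwd else rev
  c(list(status = "OK",
         orientation = if (use_fwd) "FORWARD" else "REVERSE_COMPLEMENT",
         oriented_seq = if (use_fwd) seq_fwd else seq_rc),
    hit[c("linker1", "linker2")])
}

# Place both linkers on one oriented strand; NULL when either cannot be
# placed within the error budget or the placements overlap / are out of
# order.  Returns linker coordinates plus the summed edit distance.
.place_linkers <- function(seq, layout, slack) {
  n <- nchar(seq)
  bl <- vapply(layout$rounds, function(r) r$barcode_length, integer(1))
  L <- nchar(layout$linkers)
  # forward layout: ... umi | bc3 | linker1 | bc2 | linker2 | bc1 -3'
  exp_start <- c(n - bl[1] - L[2] - bl[2] - L[1] + 1L,  # linker1
                 n - bl[1] - L[2] + 1L)                 # linker2
  hits <- vector("list", 2L)
  total <- 0L
  for (i in 1:2) {
    win_lo <- max(1L, exp_start[i] - slack)
    win_hi <- min(n, exp_start[i] + L[i] - 1L + slack)
    if (win_hi - win_lo + 1L < L[i] - layout$max_linker_errors) return(NULL)
    al <- .linker_align_cpp(substring(seq, win_lo, win_hi),
                            layout$linkers[i],
                            exp_start[i] + L[i] - 1L - win_lo + 1L)
    if (al$dist > layout$max_linker_errors) return(NULL)
    hits[[i]] <- c(al$start + win_lo - 1L, al$end + win_lo - 1L)
    total <- total + al$dist
  }
  if (hits[[1]][2] >= hits[[2]][1]) return(NULL)  # overlap or out of order
  list(linker1 = hits[[1]], linker2 = hits[[2]], score = total)
}

#' Extract raw barcodes, UMI and the cDNA trim point from an oriented read
#'
#' The barcode windows are the fixed-length segments flanking the located
#' linkers: bc3 immediately 5' of linker1, bc2 immediately 3' of linker1,
#' bc1 immediately 3' of linker2, and the UMI immediately 5' of bc3.
#' `trim_end` is the number of leading cDNA bases, i.e. everything before the
#' UMI.
#'
#' @param oriented_read the forward-oriented read sequence (character).
#' @param hits result of [locate_linkers()] (with `status == "OK"`).
#' @param layout a [barcode_layout()].
#' @return list with `raw_bc` (character vector `c(bc1, bc2, bc3)`), `umi`,
#'   and `trim_end`; or `NULL` when the read is too short to contain all
#'   windows.
#' @export
extract_barcodes <- function(oriented_read, hits, layout) {
  s <- as.character(oriented_read)
  n <- nchar(s)
  bl <- vapply(layout$rounds, function(r) r$barcode_length, integer(1))
  l1 <- hits$linker1; l2 <- hits$linker2
  bc1_lo <- l2[2] + 1L;             bc1_hi <- l2[2] + bl[1]
  bc2_lo <- l1[2] + 1L;             bc2_hi <- l1[2] + bl[2]
  bc3_lo <- l1[1] - bl[3];          bc3_hi <- l1[1] - 1L
  umi_lo <- bc3_lo - layout$umi_length; umi_hi <- bc3_lo - 1L
  # bc1 sits at the read end: tolerate terminal truncation up to the edit
  # budget (the missing bases count as deletions during correction)
  if (bc1_hi > n) {
    if (n - bc1_lo + 1L < bl[1] - layout$max_edit_distance) return(NULL)
    bc1_hi <- n
  }
  if (umi_lo < 1L) return(NULL)
  list(raw_bc = c(substring(s, bc1_lo, bc1_hi),
                  substring(s, bc2_lo, bc2_hi),
                  substring(s, bc3_lo, bc3_hi)),
       umi = substring(s, umi_lo, umi_hi),
       trim_end = umi_lo - 1L,
       windows = rbind(c(bc1_lo, bc1_hi), c(bc2_lo, bc2_hi),
                       c(bc3_lo, bc3_hi)))
}

#' Correct an observed barcode against a whitelist
#'
#' Returns the unique whitelist entry at minimum Levenshtein distance from
#' `raw` when that minimum is at most `max_edit_distance` and uniquely
#' attained.  Ties at the minimum are rejected as `"AMBIGUOUS"` (determinism
#' over yield); minima above the threshold are `"UNCORRECTABLE"`.
#'
#' @param raw observed barcode (single string).
#' @param whitelist character vector of legal barcodes.
#' @param max_edit_distance maximum accepted distance.
#' @return list with `barcode` (whitelist entry or `NA`), `distance`, and
#'   `status` in `"OK"`, `"AMBIGUOUS"`, `"UNCORRECTABLE"`.
#' @export
correct_barcode <- function(raw, whitelist, max_edit_distance = 3L) {
  if (length(whitelist) == 0L) stop("empty whitelist")
  stopifnot(length(raw) == 1L, nchar(raw) > 0L)
  m <- .match_barcodes_cpp(as.character(raw), as.character(whitelist),
                           as.integer(max_edit_distance))
  status <- if (m$dist > max_edit_distance) "UNCORRECTABLE"
            else if (m$tie) "AMBIGUOUS" else "OK"
  list(barcode = if (is.na(m$idx)) NA_character_ else whitelist[m$idx],
       distance = m$dist, status = status)
}

# vectorised correction for one round; returns data.frame(barcode, distance,
# status)
.correct_round <- function(raws, whitelist, max_edit_distance) {
  m <- .match_barcodes_cpp(as.character(raws), as.character(whitelist),
                           as.integer(max_edit_distance))
  status <- ifelse(m$dist > max_edit_distance, "UNCORRECTABLE",
                   ifelse(m$tie, "AMBIGUOUS", "OK"))
  data.frame(barcode = ifelse(is.na(m$idx), NA_character_, whitelist[m$idx]),
             distance = m$dist, status = status, stringsAsFactors = FALSE)
}

#' Priming strategy encoded by a round-1 barcode
#'
#' @param corrected_round1_bc corrected round-1 barcode(s).
#' @param layout a [barcode_layout()].
#' @return character vector of `"OLIGO_DT"` / `"RANDOM_HEXAMER"`.
#' @export
assign_priming <- function(corrected_round1_bc, layout) {
  miss <- setdiff(stats::na.omit(corrected_round1_bc),
                  names(layout$priming_map))
  if (length(miss))
    stop("barcode(s) missing from priming_map: ", paste(miss, collapse = ", "))
  unname(layout$priming_map[corrected_round1_bc])
}

#' Filter demultiplexed reads to barcode combinations seen in companion
#' short-read data
#'
#' Reads whose corrected barcode triple is absent from `illumina_combos` are
#' reclassified `NOT_IN_ILLUMINA`; with `illumina_combos = NULL` the filter is
#' bypassed and all triples pass.
#'
#' @param records demux record data.frame (see [demux_reads()]).
#' @param illumina_combos character vector of corrected triples in
#'   `"bc1-bc2-bc3"` form, or `NULL` to disable filtering.
#' @return the records with updated `status`.
#' @export
assign_cell <- function(records, illumina_combos = NULL) {
  if (is.null(illumina_combos)) return(records)
  ok <- records$status == "OK"
  combo <- paste(records$bc1[ok], records$bc2[ok], records$bc3[ok], sep = "-")
  records$status[ok][!combo %in% illumina_combos] <- "NOT_IN_ILLUMINA"
  records$cell_id[records$status != "OK"] <- NA_character_
  records
}

#' Merge oligo-dT and random-hexamer wells into final cells
#'
#' Two round-1 barcodes (one per priming type) map to each physical well;
#' merging replaces the round-1 barcode in the cell id by the well id so both
#' priming reactions of a cell collapse onto one cell.  The per-read priming
#' label is retained for stratified analyses.
#'
#' @param records demux record data.frame with status `"OK"` rows.
#' @param layout a [barcode_layout()].
#' @return records with `cell_id` of the form `"<well>_<bc2>_<bc3>"`.
#' @export
merge_priming_pairs <- function(records, layout) {
  ok <- records$status == "OK"
  records$cell_id[ok] <- paste(unname(layout$well_pair_map[records$bc1[ok]]),
                               records$bc2[ok], records$bc3[ok], sep = "_")
  records
}

#' Demultiplex barcoded long reads
#'
#' Full demultiplexing of raw long reads: linker location (both
#' orientations), barcode window extraction, per-round whitelist correction
#' within `max_edit_distance`, optional filtering against barcode
#' combinations observed in companion short-read data, priming-strategy
#' assignment from the round-1 barcode, and merging of priming-pair wells
#' into cells.  Every read ends in exactly one status class:
#' `OK`, `NO_LINKERS`, `BC_UNCORRECTABLE`, `BC_AMBIGUOUS`, `NOT_IN_ILLUMINA`.
#'
#' @param reads a named character vector, a `DNAStringSet`, or the path to a
#'   FASTQ file.
#' @param layout a [barcode_layout()].
#' @param illumina_combos optional character vector of `"bc1-bc2-bc3"`
#'   triples (or a file with one per line) to filter against; `NULL` disables
#'   the filter.
#' @param max_edit_distance barcode correction threshold (defaults to the
#'   layout's).
#' @param trimmed_fastq optional path; when given, forward-oriented reads
#'   trimmed of their barcode block are written as FASTQ with the read-name
#'   suffix `cell:<id>;umi:<seq>;pr:<dT|hex>`.
#' @return A list with `records` (one row per read: read_id, status, raw and
#'   corrected barcodes, umi, priming, orientation, trim_end, cell_id) and
#'   `trimmed` (a `DNAStringSet` of trimmed cDNA for status-OK reads).
#' @export
demux_reads <- function(reads, layout, illumina_combos = NULL,
                        max_edit_distance = layout$max_edit_distance,
                        trimmed_fastq = NULL) {
  quals <- NULL
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fq <- read_fastq(reads)
    reads <- fq$seq
    quals <- fq$qual
  }
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (is.null(names(reads)))
    names(reads) <- sprintf("read_%06d", seq_along(reads))
  if (is.character(illumina_combos) && length(illumina_combos) == 1L &&
      file.exists(illumina_combos)) {
    illumina_combos <- readLines(illumina_combos)
  }

  n <- length(reads)
  status <- rep("OK", n)
  orientation <- rep(NA_character_, n)
  raw <- matrix(NA_character_, n, 3L)
  umi <- rep(NA_character_, n)
  trim_end <- rep(NA_integer_, n)
  oriented <- rep(NA_character_, n)
  win_lo <- win_hi <- matrix(NA_integer_, n, 3L)
  for (i in seq_len(n)) {
    hit <- locate_linkers(reads[[i]], layout)
    if (hit$status != "OK") { status[i] <- "NO_LINKERS"; next }
    orientation[i] <- hit$orientation
    ext <- extract_barcodes(hit$oriented_seq, hit, layout)
    if (is.null(ext)) { status[i] <- "NO_LINKERS"; next }
    raw[i, ] <- ext$raw_bc
    umi[i] <- ext$umi
    trim_end[i] <- ext$trim_end
    oriented[i] <- hit$oriented_seq
    win_lo[i, ] <- ext$windows[, 1L]
    win_hi[i, ] <- ext$windows[, 2L]
  }

  # correct each round over a small family of shifted windows: indels in or
  # near a linker can offset the fixed barcode window by a base or two.
  # Each shift is charged as an edit, so a candidate is accepted only when
  # dist + |shift| <= max_edit_distance; this keeps genuine offset matches
  # (few real errors at the correct shift) while rejecting chance matches
  # of corrupted windows against the wrong whitelist entry.  Shift 0 is
  # preferred on ties.
  shifts <- c(0L, -1L, 1L, -2L, 2L)
  corr <- matrix(NA_character_, n, 3L)
  located <- status == "OK"
  bc_status <- matrix("OK", n, 3L)
  for (r in 1:3) {
    if (!any(located)) break
    wl <- layout$rounds[[r]]$whitelist
    lo <- win_lo[located, r]; hi <- win_hi[located, r]
    seqs <- oriented[located]
    m <- length(seqs)
    adj_k <- matrix(NA_integer_, m, length(shifts))
    idx_k <- matrix(NA_integer_, m, length(shifts))
    tie_k <- matrix(FALSE, m, length(shifts))
    for (k in seq_along(shifts)) {
      cand <- substring(seqs, pmax(1L, lo + shifts[k]), hi + shifts[k])
      res <- .match_barcodes_cpp(cand, wl, as.integer(max_edit_distance))
      adj_k[, k] <- res$dist + abs(shifts[k])
      idx_k[, k] <- res$idx
      tie_k[, k] <- res$tie
    }
    pick <- max.col(-adj_k, ties.method = "first")
    sel <- cbind(seq_len(m), pick)
    corr[located, r] <- ifelse(is.na(idx_k[sel]), NA_character_,
                               wl[idx_k[sel]])
    bc_status[located, r] <- ifelse(adj_k[sel] > max_edit_distance,
                                    "UNCORRECTABLE",
                                    ifelse(tie_k[sel], "AMBIGUOUS", "OK"))
  }
  any_unc <- located & apply(bc_status == "UNCORRECTABLE", 1L, any)
  any_amb <- located & !any_unc & apply(bc_status == "AMBIGUOUS", 1L, any)
  status[any_unc] <- "BC_UNCORRECTABLE"
  status[any_amb] <- "BC_AMBIGUOUS"

  records <- data.frame(
    read_id = names(reads),
    status = status,
    raw_bc1 = raw[, 1], raw_bc2 = raw[, 2], raw_bc3 = raw[, 3],
    bc1 = corr[, 1], bc2 = corr[, 2], bc3 = corr[, 3],
    umi = umi,
    priming = NA_character_,
    orientation = orientation,
    trim_end = trim_end,
    cell_id = NA_character_,
    stringsAsFactors = FALSE
  )
  ok <- records$status == "OK"
  records$priming[ok] <- assign_priming(records$bc1[ok], layout)
  records <- merge_priming_pairs(records, layout)
  records <- assign_cell(records, illumina_combos)
  ok <- records$status == "OK"

  trimmed <- Biostrings::DNAStringSet(substring(oriented[ok], 1L,
                                                pmax(0L, trim_end[ok])))
  pr <- c(OLIGO_DT = "dT", RANDOM_HEXAMER = "hex")[records$priming[ok]]
  names(trimmed) <- paste0(records$read_id[ok], " cell:", records$cell_id[ok],
                           ";umi:", records$umi[ok], ";pr:", pr)
  if (!is.null(trimmed_fastq)) {
    tq <- .trimmed_quals(quals, records, ok)
    write_fastq(trimmed, trimmed_fastq, qual = tq)
  }
  list(records = records, trimmed = trimmed)
}

# pass input qualities through to the trimmed output, reversing them for
# reads demuxed on the reverse-complement strand
.trimmed_quals <- function(quals, records, ok) {
  if (is.null(quals)) return(NULL)
  q <- as.character(quals[records$read_id[ok]])
  rc <- records$orientation[ok] == "REVERSE_COMPLEMENT"
  q[rc] <- vapply(q[rc], function(x)
    paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1))
  substring(q, 1L, pmax(0L, records$trim_end[ok]))
}
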