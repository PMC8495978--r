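test_that("novelty filtering keeps end-faithful categories per end type", {
  ann <- ann_rows(4)
  ann$novelty <- c("KNOWN", "GENOMIC", "ISM_PREFIX", "ISM_SUFFIX")
  tss <- filter_reads_by_novelty(ann, end_call_config("tss", "sc"))
  expect_setequal(tss$novelty, c("KNOWN", "ISM_PREFIX"))
  tes <- filter_reads_by_novelty(ann, end_call_config("tes", "sc"))
  expect_setequal(tes$novelty, c("KNOWN", "ISM_SUFFIX"))
  expect_equal(nrow(filter_reads_by_novelty(ann[0, ],
                                            end_call_config())), 0L)
})

test_that("end positions are tallied per chromosome, strand and end type", {
  ann <- ann_rows(3, five = 100L)
  pc <- collect_end_positions(ann, "tss")
  expect_equal(pc$count, 3L)
  expect_equal(pc$pos, 100L)

  # identical coordinate on opposite strands stays separate
  ann2 <- rbind(ann_rows(2, five = 100L, strand = "+"),
                ann_rows(1, five = 100L, three = 50L, strand = "-"))
  pc2 <- collect_end_positions(ann2, "tss")
  expect_equal(nrow(pc2), 2L)

  # TES mode on a minus-strand read counts the 3' coordinate
  ann3 <- ann_rows(1, strand = "-", five = 500L, three = 200L)
  expect_equal(collect_end_positions(ann3, "tes")$pos, 200L)
})

test_that("window chaining matches the frozen worked examples", {
  cfg <- end_call_config("tss", "sc")
  pc <- data.frame(chrom = "chr1", strand = "+",
                   pos = c(100L, 103L, 400L), gene_id = "g",
                   count = c(5L, 3L, 4L))
  pk <- call_end_peaks(pc, cfg)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$summit, c(100L, 400L))
  expect_equal(pk$read_count, c(8L, 4L))
  expect_equal(pk$wide_start, c(100L, 400L))
  expect_equal(pk$wide_end, c(104L, 401L))

  # a single position with 1 read is below the 2-read support floor
  one <- data.frame(chrom = "chr1", strand = "+", pos = 10L,
                    gene_id = "g", count = 1L)
  expect_equal(nrow(call_end_peaks(one, cfg)), 0L)

  # gap of exactly window + 1 splits; gap of window chains
  split2 <- data.frame(chrom = "chr1", strand = "+", pos = c(100L, 151L),
                       gene_id = "g", count = c(2L, 2L))
  expect_equal(nrow(call_end_peaks(split2, cfg)), 2L)
  join2 <- data.frame(chrom = "chr1", strand = "+", pos = c(100L, 150L),
                      gene_id = "g", count = c(2L, 2L))
  expect_equal(nrow(call_end_peaks(join2, cfg)), 1L)
})

test_that("window chaining equals the exhaustive oracle on random instances", {
  cfg <- end_call_config("tss", "sc")
  set.seed(42)
  for (i in 1:200) {
    npos <- sample(1:40, 1)
    pos <- sort(sample.int(500, npos))
    count <- sample.int(6, npos, replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    pc <- data.frame(chrom = "chr1", strand = strand, pos = pos,
                     gene_id = "g", count = count)
    got <- call_end_peaks(pc, cfg)
    ora <- oracle_cluster(pos, count, cfg$window_size, cfg$min_reads,
                          strand)
    expect_equal(got$wide_start, ora$wide_start)
    expect_equal(got$wide_end, ora$wide_end)
    expect_equal(got$summit, ora$summit)
    expect_equal(got$read_count, ora$read_count)
  }
  # pre-filter count conservation on one instance
  pc <- data.frame(chrom = "chr1", strand = "+",
                   pos = sort(sample.int(2000, 60)), gene_id = "g",
                   count = sample.int(5, 60, replace = TRUE))
  cfg0 <- end_call_config("tss", "sc", min_reads = 1)
  expect_equal(sum(call_end_peaks(pc, cfg0)$read_count), sum(pc$count))
})

test_that("summit ties break 5'-most in transcript orientation and peaks mirror under strand flip", {
  cfg <- end_call_config("tss", "sc")
  tie_plus <- data.frame(chrom = "chr1", strand = "+", pos = c(100L, 120L),
                         gene_id = "g", count = c(4L, 4L))
  expect_equal(call_end_peaks(tie_plus, cfg)$summit, 100L)
  tie_minus <- tie_plus
  tie_minus$strand <- "-"
  expect_equal(call_end_peaks(tie_minus, cfg)$summit, 120L)

  # mirror all coordinates around a constant and flip strands: peaks mirror
  M <- 10000L
  pc <- data.frame(chrom = "chr1", strand = "+",
                   pos = c(100L, 130L, 145L, 400L, 460L), gene_id = "g",
                   count = c(3L, 7L, 2L, 5L, 5L))
  mir <- data.frame(chrom = "chr1", strand = "-", pos = M - pc$pos,
                    gene_id = "g", count = pc$count)
  a <- call_end_peaks(pc, cfg)
  b <- call_end_peaks(mir, cfg)
  expect_equal(sort(M - a$summit), sort(b$summit))
  expect_equal(sort(M - (a$wide_end - 1L)), sort(b$wide_start))
  expect_equal(sort(a$read_count), sort(b$read_count))
})

test_that("peak genes come from a majority vote with a genome-wide tie-break", {
  cfg <- end_call_config("tss", "sc")
  pc <- collect_end_positions(
    ann_rows(8, five = c(rep(100L, 7), 101L),
             gene = c(rep("A", 7), "B")), "tss")
  pk <- assign_peak_gene(call_end_peaks(pc, cfg), pc)
  expect_equal(pk$gene_id, "A")

  # 2 vs 2 in the peak, but gene A has more reads genome-wide
  ann <- rbind(ann_rows(2, five = 100L, gene = "A"),
               ann_rows(2, five = 101L, gene = "B"),
               ann_rows(3, five = 5000L, gene = "A"))
  pc2 <- collect_end_positions(ann, "tss")
  pk2 <- assign_peak_gene(call_end_peaks(pc2, cfg), pc2)
  expect_equal(pk2$gene_id[1], "A")

  # peaks supported only by gene-less reads are dropped
  ann3 <- ann_rows(3, five = 100L, gene = NA_character_)
  pc3 <- collect_end_positions(ann3, "tss")
  expect_equal(nrow(assign_peak_gene(call_end_peaks(pc3, cfg), pc3)), 0L)
})

test_that("the per-gene fractional filter uses a strict inequality", {
  mk <- function(counts) data.frame(
    chrom = "chr1", strand = "+", wide_start = seq_along(counts) * 1000L,
    wide_end = seq_along(counts) * 1000L + 10L,
    narrow_start = seq_along(counts) * 1000L,
    narrow_end = seq_along(counts) * 1000L + 10L,
    summit = seq_along(counts) * 1000L, read_count = counts,
    gene_id = "g", stringsAsFactors = FALSE)
  expect_equal(filter_peaks_by_gene_fraction(mk(c(100L, 12L, 9L)),
                                             0.10)$read_count,
               c(100L, 12L))
  # 10 > 10 is false: the boundary peak is dropped
  expect_equal(filter_peaks_by_gene_fraction(mk(c(100L, 10L)),
                                             0.10)$read_count, 100L)
  # TES threshold: 41 > 0.8 * 50 = 40 keeps both
  expect_equal(filter_peaks_by_gene_fraction(mk(c(50L, 41L)),
                                             0.80)$read_count,
               c(50L, 41L))
  # raising the fraction never enlarges the retained set
  set.seed(1)
  counts <- sample.int(100, 12)
  kept <- sapply(c(0.05, 0.1, 0.3, 0.5, 0.8, 0.95), function(f)
    nrow(filter_peaks_by_gene_fraction(mk(counts), f)))
  expect_true(all(diff(kept) <= 0))
})

test_that("peak names order by genomic coordinate and renaming is idempotent", {
  pk <- data.frame(chrom = "chr1", strand = "+",
                   wide_start = c(500L, 100L), wide_end = c(510L, 110L),
                   narrow_start = c(500L, 100L), narrow_end = c(510L, 110L),
                   summit = c(500L, 100L), read_count = c(5L, 9L),
                   gene_id = "G", stringsAsFactors = FALSE)
  named <- name_peaks(pk)
  expect_equal(named$name[named$summit == 100L], "G_1")
  expect_equal(named$name[named$summit == 500L], "G_2")
  expect_identical(name_peaks(named)$name, named$name)
  single <- name_peaks(pk[1, ])
  expect_equal(single$name, "G_1")
})

test_that("short-read end filters implement the exact TSO and A-window rules", {
  tso <- "AACGCAGAGTGAATGGG"
  expect_true(short_read_tss_filter(paste0(tso, "CCCGGG")))
  expect_true(short_read_tss_filter(paste0("TT", tso, "CCC")))  # internal
  mut <- paste0("AACGCAGAGTGAATGGC", "CCCGGG")  # one substitution
  expect_false(short_read_tss_filter(mut))
  expect_false(short_read_tss_filter("CCCCCCCCCCCCCCCCCCCCCC"))

  expect_true(short_read_tes_filter(paste0(strrep("A", 10),
                                           strrep("C", 10))))
  expect_false(short_read_tes_filter(strrep("C", 20)))
  # 9 As in every 20-bp window
  s <- paste0(strrep("A", 9), strrep("C", 11), strrep("A", 9),
              strrep("C", 11))
  win_max <- max(vapply(1:(nchar(s) - 19), function(i)
    sum(strsplit(substr(s, i, i + 19), "")[[1]] == "A"), numeric(1)))
  expect_equal(win_max, 9)
  expect_false(short_read_tes_filter(s))
})

test_that("validation intersection uses 1-bp overlap on half-open intervals", {
  pk <- data.frame(chrom = "chr1", strand = "+", wide_start = 100L,
                   wide_end = 150L, narrow_start = 100L, narrow_end = 150L,
                   summit = 120L, read_count = 10L, gene_id = "g",
                   name = "g_1", stringsAsFactors = FALSE)
  ov <- intersect_with_validation(pk, list(
    cage = data.frame(chrom = "chr1", start = 149L, end = 200L)))
  expect_true(ov$support[1, "cage"])
  ov2 <- intersect_with_validation(pk, list(
    cage = data.frame(chrom = "chr1", start = 150L, end = 200L)))
  expect_false(ov2$support[1, "cage"])
  expect_equal(ov2$fraction_supported, 0)
  ov3 <- intersect_with_validation(pk, list(
    a = data.frame(chrom = "chr1", start = 140L, end = 160L),
    b = data.frame(chrom = "chr1", start = 90L, end = 110L)))
  expect_equal(as.integer(ov3$upset["a+b"]), 1L)
})

test_that("planted TSS architecture is recovered by the full caller", {
  models <- sim_gene_models(n_genes = 8, max_tss = 3, tss_spacing = 300,
                            pi_shape = Inf, seed = 21)
  sim <- simulate_end_annotations(models, reads_per_gene = c(80L, 200L),
                                  jitter_sd = 5, noise_frac = 0.1,
                                  seed = 22)
  peaks <- call_ends(sim$annotations, end_call_config("tss", "sc"))
  truth <- sim$truth$tss
  d <- vapply(seq_len(nrow(truth)), function(i) {
    same <- peaks$chrom == truth$chrom[i] & peaks$strand == truth$strand[i]
    min(abs(peaks$summit[same] - truth$pos[i]))
  }, numeric(1))
  expect_true(all(d <= 10))
  near_any <- vapply(seq_len(nrow(peaks)), function(i) {
    same <- truth$chrom == peaks$chrom[i] & truth$strand == peaks$strand[i]
    min(abs(truth$pos[same] - peaks$summit[i])) <= 50
  }, logical(1))
  expect_true(all(near_any))
  # GENOMIC noise reads were excluded before calling
  kept <- filter_reads_by_novelty(sim$annotations,
                                  end_call_config("tss", "sc"))
  expect_true(all(kept$novelty == "KNOWN"))
})
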