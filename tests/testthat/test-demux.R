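test_that("linkers are located on exact constructions and their reverse complements", {
  lay <- toy_layout()
  rd <- build_read(lay, "AAAAAAAA", "GGGGGGGG", "ACACACAC")
  hit <- locate_linkers(rd, lay)
  expect_equal(hit$status, "OK")
  expect_equal(hit$orientation, "FORWARD")
  # constructed offsets: cDNA 60 + UMI 10 + bc3 8 -> linker1 at 79..100
  expect_equal(hit$linker1, c(79L, 100L))
  expect_equal(hit$linker2, c(109L, 130L))

  hit_rc <- locate_linkers(revcomp(rd), lay)
  expect_equal(hit_rc$status, "OK")
  expect_equal(hit_rc$orientation, "REVERSE_COMPLEMENT")
  expect_equal(hit_rc$linker1, hit$linker1)
  expect_equal(hit_rc$linker2, hit$linker2)

  # 3 substitutions in linker1 exceed the 2-edit budget
  l1_bad <- lay$linkers[1]
  substr(l1_bad, 3, 3) <- "A"; substr(l1_bad, 9, 9) <- "G"
  substr(l1_bad, 15, 15) <- "A"
  expect_equal(utils::adist(l1_bad, lay$linkers[1])[1, 1], 3)
  bad <- sub(lay$linkers[1], l1_bad, rd, fixed = TRUE)
  expect_equal(locate_linkers(bad, lay)$status, "NO_LINKERS")
})

test_that("barcode windows track the linker hits, including through an indel", {
  lay <- toy_layout()
  rd <- build_read(lay, "AAAAAAAA", "GGGGGGGG", "ACACACAC",
                   umi = "ACGTACGTAC")
  hit <- locate_linkers(rd, lay)
  ext <- extract_barcodes(hit$oriented_seq, hit, lay)
  expect_equal(ext$raw_bc, c("AAAAAAAA", "GGGGGGGG", "ACACACAC"))
  expect_equal(ext$umi, "ACGTACGTAC")
  expect_equal(ext$trim_end, 60L)

  # 1-bp insertion inside linker1 shifts everything downstream by one, but
  # the windows follow the alignment coordinates
  l1_ins <- paste0(substr(lay$linkers[1], 1, 10), "G",
                   substr(lay$linkers[1], 11, 22))
  rd_ins <- sub(lay$linkers[1], l1_ins, rd, fixed = TRUE)
  hit2 <- locate_linkers(rd_ins, lay)
  ext2 <- extract_barcodes(hit2$oriented_seq, hit2, lay)
  expect_equal(ext2$raw_bc, c("AAAAAAAA", "GGGGGGGG", "ACACACAC"))

  # a read too short to contain all windows fails
  stub <- substr(rd, 62, nchar(rd))  # cuts into the UMI
  hit3 <- locate_linkers(stub, lay)
  expect_null(extract_barcodes(hit3$oriented_seq, hit3, lay))
})

test_that("correct_barcode agrees with a brute-force Levenshtein oracle", {
  wl <- c("AAAAAAAA", "CCCCCCCC")
  expect_equal(correct_barcode("AAAAAAAT", wl, 3)$barcode, "AAAAAAAA")
  expect_equal(correct_barcode("AAAAAAAT", wl, 3)$distance, 1L)
  # distance 4 to both entries: uncorrectable, not ambiguous
  r <- correct_barcode("AAAACCCC", wl, 3)
  expect_equal(r$status, "UNCORRECTABLE")
  expect_true(is.na(r$barcode))
  expect_equal(correct_barcode("CCCCCCCC", wl, 3)$distance, 0L)
  expect_error(correct_barcode("AAAA", character(0)), "empty")

  # randomized agreement with the adist oracle on a 48-entry whitelist
  set.seed(11)
  wl48 <- make_whitelist(48, 10, 3)
  raws <- c(wl48[1:10],
            replicate(150, paste(sample(c("A", "C", "G", "T"), 10,
                                        replace = TRUE), collapse = "")))
  for (raw in raws) {
    got <- correct_barcode(raw, wl48, 3)
    ora <- oracle_correct(raw, wl48, 3)
    expect_identical(got$status, ora$status)
    expect_identical(got$barcode, ora$barcode)
  }
})

test_that("illumina combo filtering and priming assignment behave per status rules", {
  lay <- toy_layout()
  rec <- data.frame(status = "OK", bc1 = "AAAAAAAA", bc2 = "GGGGGGGG",
                    bc3 = "ACACACAC", cell_id = "W01_GGGGGGGG_ACACACAC",
                    stringsAsFactors = FALSE)
  keep <- assign_cell(rec, "AAAAAAAA-GGGGGGGG-ACACACAC")
  expect_equal(keep$status, "OK")
  drop <- assign_cell(rec, "CCCCCCCC-GGGGGGGG-ACACACAC")
  expect_equal(drop$status, "NOT_IN_ILLUMINA")
  expect_true(is.na(drop$cell_id))
  # disabled filter passes everything
  expect_equal(assign_cell(rec, NULL)$status, "OK")

  expect_equal(assign_priming("AAAAAAAA", lay), "OLIGO_DT")
  expect_equal(assign_priming("CCCCCCCC", lay), "RANDOM_HEXAMER")
  expect_error(assign_priming("GGGGGGGG", lay), "priming_map")
})

test_that("priming-pair wells merge into one cell and split back by priming", {
  lay <- toy_layout()
  reads <- c(
    setNames(replicate(10, build_read(lay, "AAAAAAAA", "GGGGGGGG",
                                      "ACACACAC")), sprintf("dt%02d", 1:10)),
    setNames(replicate(5, build_read(lay, "CCCCCCCC", "GGGGGGGG",
                                     "ACACACAC")), sprintf("hx%02d", 1:5)),
    setNames(replicate(3, build_read(lay, "AAAAAAAA", "TTTTTTTT",
                                     "ACACACAC")), sprintf("ot%02d", 1:3)))
  dm <- demux_reads(reads, lay)
  expect_true(all(dm$records$status == "OK"))
  tab <- table(dm$records$cell_id)
  # dT + hex of the same well merge: 15 reads in one cell, 3 in the other
  expect_equal(sort(as.integer(tab)), c(3L, 15L))
  merged <- dm$records[dm$records$cell_id == "W01_GGGGGGGG_ACACACAC", ]
  expect_equal(as.integer(table(merged$priming)[c("OLIGO_DT",
                                                  "RANDOM_HEXAMER")]),
               c(10L, 5L))
})

test_that("every read lands in exactly one status class and orientation is symmetric", {
  lay <- sim_barcode_layout(n_wells = 8, n_round = 12, seed = 5)
  sim <- simulate_barcoded_reads(lay, n_reads = 300, n_cells = 20,
                                 sub_rate = 0.03, indel_rate = 0.01,
                                 seed = 9)
  dm <- demux_reads(sim$seq, lay)
  expect_equal(nrow(dm$records), 300L)
  expect_true(all(dm$records$status %in%
                    c("OK", "NO_LINKERS", "BC_UNCORRECTABLE",
                      "BC_AMBIGUOUS", "NOT_IN_ILLUMINA")))
  expect_equal(sum(table(dm$records$status)), 300L)

  # demuxing a read and its reverse complement gives the same record apart
  # from orientation
  rd <- as.character(sim$seq[[which(dm$records$status == "OK")[1]]])
  a <- demux_reads(setNames(rd, "x"), lay)$records
  b <- demux_reads(setNames(revcomp(rd), "x"), lay)$records
  cols <- setdiff(names(a), "orientation")
  expect_identical(a[cols], b[cols])
  expect_false(identical(a$orientation, b$orientation))
})

test_that("noiseless and lightly mutated reads round-trip to their true cells", {
  lay <- sim_barcode_layout(n_wells = 8, n_round = 12, seed = 5)
  clean <- simulate_barcoded_reads(lay, n_reads = 400, n_cells = 20,
                                   sub_rate = 0, indel_rate = 0, seed = 2)
  dm <- demux_reads(clean$seq, lay)
  expect_true(all(dm$records$status == "OK"))
  expect_identical(dm$records$cell_id, clean$truth$cell_id)
  expect_identical(dm$records$umi, clean$truth$umi)
  expect_identical(dm$records$priming, clean$truth$priming)

  # up to max_edit_distance substitutions per barcode: still zero
  # misassignment with a distance-7 whitelist
  noisy <- simulate_barcoded_reads(lay, n_reads = 400, n_cells = 20,
                                   sub_rate = 0.02, indel_rate = 0,
                                   seed = 3)
  dm2 <- demux_reads(noisy$seq, lay)
  ok <- dm2$records$status == "OK"
  expect_gt(mean(ok), 0.95)
  expect_equal(sum(dm2$records$cell_id[ok] != noisy$truth$cell_id[ok]), 0L)
})
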