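#' Simulate barcoded long reads with ground truth
#'
#' Emits reads laid out as `cDNA | UMI | bc3 | linker1 | bc2 | linker2 | bc1`
#' on the forward strand, half of them reverse-complemented, with per-base
#' substitutions at `sub_rate` and insertions/deletions at `indel_rate`
#' (split evenly) applied uniformly across the read.  Every read carries a
#' complete truth record.  Deterministic under a fixed seed.
#'
#' @param layout a [barcode_layout()] (e.g. [sim_barcode_layout()]).
#' @param n_reads number of reads.
#' @param n_cells number of distinct cells drawn from the combinatorial
#'   barcode space.
#' @param sub_rate per-base substitution probability.
#' @param indel_rate per-base indel probability (half insertions, half
#'   deletions).
#' @param cdna_length range of cDNA stub lengths (uniform).
#' @param seed RNG seed.
#' @return list with `seq` (named `DNAStringSet`), `qual` (named character,
#'   constant Phred+33 'I'), and `truth` (read_id, cell_id, bc1, bc2, bc3,
#'   umi, priming, orientation).
#' @export
simulate_barcoded_reads <- function(layout, n_reads = 10000L, n_cells = 96L,
                                    sub_rate = 0.01, indel_rate = 0.002,
                                    cdna_length = c(60L, 160L), seed = 1L) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    wells <- unique(unname(layout$well_pair_map))
    r2 <- layout$rounds[[2]]$whitelist
    r3 <- layout$rounds[[3]]$whitelist
    # bc1 lookup: well + priming -> round-1 barcode
    r1 <- layout$rounds[[1]]$whitelist
    key <- paste(layout$well_pair_map[r1], layout$priming_map[r1])
    bc1_of <- setNames(r1, key)

    cell_tab <- unique(data.frame(
      well = sample(wells, n_cells * 10L, replace = TRUE),
      bc2 = sample(r2, n_cells * 10L, replace = TRUE),
      bc3 = sample(r3, n_cells * 10L, replace = TRUE)))
    stopifnot(nrow(cell_tab) >= n_cells)
    cell_tab <- cell_tab[seq_len(n_cells), ]
    ci <- sample.int(n_cells, n_reads, replace = TRUE)
    priming <- sample(c("OLIGO_DT", "RANDOM_HEXAMER"), n_reads,
                      replace = TRUE)
    bc1 <- unname(bc1_of[paste(cell_tab$well[ci], priming)])
    bc2 <- cell_tab$bc2[ci]
    bc3 <- cell_tab$bc3[ci]
    umi <- .random_seqs(n_reads, rep(layout$umi_length, n_reads))
    cdna <- .random_seqs(n_reads,
                         sample(cdna_length[1]:cdna_length[2], n_reads,
                                replace = TRUE))
    clean <- paste0(cdna, umi, bc3, layout$linkers[1], bc2,
                    layout$linkers[2], bc1)
    noisy <- .apply_read_noise(clean, sub_rate, indel_rate)
    orientation <- sample(c("FORWARD", "REVERSE_COMPLEMENT"), n_reads,
                          replace = TRUE)
    dna <- Biostrings::DNAStringSet(noisy)
    rc <- orientation == "REVERSE_COMPLEMENT"
    dna[rc] <- Biostrings::reverseComplement(dna[rc])
    names(dna) <- sprintf("read_%06d", seq_len(n_reads))
    qual <- setNames(strrep("I", Biostrings::width(dna)), names(dna))
    truth <- data.frame(
      read_id = names(dna),
      cell_id = paste(cell_tab$well[ci], bc2, bc3, sep = "_"),
      bc1 = bc1, bc2 = bc2, bc3 = bc3, umi = umi,
      priming = priming, orientation = orientation,
      stringsAsFactors = FALSE)
    list(seq = dna, qual = qual, truth = truth)
  })
}

.random_seqs <- function(n, lens) {
  flat <- sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE)
  vapply(split(flat, rep.int(seq_len(n), lens)), paste, character(1),
         collapse = "")
}

# substitutions always change the base (cyclic shift by 1-3); insertions add
# a random base after the position; deletions remove it
.apply_read_noise <- function(reads, sub_rate, indel_rate) {
  chars <- strsplit(reads, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  idx <- rep.int(seq_along(reads), lens)
  n <- length(flat)
  bases <- c("A", "C", "G", "T")
  sub <- stats::runif(n) < sub_rate
  if (any(sub)) {
    pos <- match(flat[sub], bases)
    shift <- sample.int(3L, sum(sub), replace = TRUE)
    flat[sub] <- bases[(pos - 1L + shift) %% 4L + 1L]
  }
  ins <- stats::runif(n) < indel_rate / 2
  if (any(ins)) {
    flat[ins] <- paste0(flat[ins],
                        sample(bases, sum(ins), replace = TRUE))
  }
  del <- stats::runif(n) < indel_rate / 2
  if (any(del)) {
    flat <- flat[!del]
    idx <- idx[!del]
  }
  out <- rep("", length(reads))
  got <- vapply(split(flat, idx), paste, character(1), collapse = "")
  out[as.integer(names(got))] <- got
  out
}

#' Simulate gene models with planted TSS/TES architecture
#'
#' Each gene receives 1 to `max_tss` TSSs spaced `tss_spacing` bp apart and
#' 1 to `max_tes` TESs, with usage probabilities drawn from a symmetric
#' Dirichlet (`pi_shape = Inf` gives equal usage).  Genes alternate strands;
#' on the minus strand TSS coordinates exceed TES coordinates.
#'
#' @param n_genes number of genes.
#' @param max_tss,max_tes maximum sites per gene (uniform in 1..max).
#' @param tss_spacing,tes_spacing distance between neighbouring planted
#'   sites of a gene (bp).
#' @param gene_span distance between a gene's TSS block and TES block (bp).
#' @param pi_shape Dirichlet concentration for usage vectors (`Inf` = equal).
#' @param seed RNG seed.
#' @return list of gene models: each has gene_id, chrom, strand, tss
#'   (coordinates), tss_pi, tes, tes_pi.
#' @export
sim_gene_models <- function(n_genes = 20L, max_tss = 4L, max_tes = 2L,
                            tss_spacing = 300L, tes_spacing = 300L,
                            gene_span = 50000L, pi_shape = 2, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_genes), function(g) {
      strand <- if (g %% 2L == 0L) "-" else "+"
      base <- 1e6 * g
      k_tss <- sample.int(max_tss, 1L)
      k_tes <- sample.int(max_tes, 1L)
      # on the minus strand the TSS block sits at the high coordinates
      tss_off <- if (strand == "+") 0 else gene_span
      tes_off <- if (strand == "+") gene_span else 0
      tss_block <- base + tss_off + (seq_len(k_tss) - 1L) * tss_spacing
      tes_block <- base + tes_off + (seq_len(k_tes) - 1L) * tes_spacing
      list(gene_id = sprintf("gene%03d", g),
           chrom = paste0("chr", (g - 1L) %% 5L + 1L),
           strand = strand,
           tss = as.integer(tss_block), tss_pi = .rdirichlet(k_tss, pi_shape),
           tes = as.integer(tes_block), tes_pi = .rdirichlet(k_tes, pi_shape))
    })
  })
}

.rdirichlet <- function(k, shape) {
  if (is.infinite(shape)) return(rep(1 / k, k))
  x <- stats::rgamma(k, shape)
  x / sum(x)
}

#' Simulate read annotations around planted TSS/TES architecture
#'
#' Per read: a TSS and a TES of its gene are drawn from the planted usage
#' vectors and the read's genomic 5'/3' ends are the chosen sites plus
#' rounded Gaussian jitter, respecting strand.  A configurable fraction of
#' reads is emitted with GENOMIC novelty (noise excluded by the end caller's
#' novelty filter); the rest are KNOWN.
#'
#' @param models gene models from [sim_gene_models()].
#' @param reads_per_gene single count, or range `c(lo, hi)` sampled per
#'   gene.
#' @param n_cells cells to spread reads over.
#' @param jitter_sd Gaussian jitter of read ends around the planted site
#'   (bp).
#' @param noise_frac fraction of GENOMIC-novelty noise reads.
#' @param dataset dataset label.
#' @param seed RNG seed.
#' @return list with `annotations` (the 11-column read-annotation table) and
#'   `truth` (`reads`: read_id, gene, true tss/tes ids; `tss`, `tes`:
#'   planted site tables with gene, site id, coordinate, usage).
#' @export
simulate_end_annotations <- function(models, reads_per_gene = c(50L, 500L),
                                     n_cells = 24L, jitter_sd = 5,
                                     noise_frac = 0, dataset = "sim",
                                     seed = 1L) {
  with_seed(seed, {
    per_gene <- if (length(reads_per_gene) == 1L)
      rep(reads_per_gene, length(models))
    else sample(reads_per_gene[1]:reads_per_gene[2], length(models),
                replace = TRUE)
    rows <- lapply(seq_along(models), function(gi) {
      m <- models[[gi]]
      n <- per_gene[gi]
      tss_i <- sample.int(length(m$tss), n, replace = TRUE, prob = m$tss_pi)
      tes_i <- sample.int(length(m$tes), n, replace = TRUE, prob = m$tes_pi)
      five <- m$tss[tss_i] + as.integer(round(stats::rnorm(n, 0, jitter_sd)))
      three <- m$tes[tes_i] + as.integer(round(stats::rnorm(n, 0, jitter_sd)))
      # keep ends consistent with strand orientation
      if (m$strand == "+") {
        bad <- five > three; three[bad] <- five[bad]
      } else {
        bad <- five < three; three[bad] <- five[bad]
      }
      noise <- stats::runif(n) < noise_frac
      data.frame(
        read_id = sprintf("%s_r%05d", m$gene_id, seq_len(n)),
        cell_id = sprintf("cell_%03d",
                          sample.int(n_cells, n, replace = TRUE)),
        chrom = m$chrom, strand = m$strand,
        five_prime_pos = pmax(0L, five),
        three_prime_pos = pmax(0L, three),
        gene_id = m$gene_id,
        transcript_id = sprintf("%s_t%d", m$gene_id, tss_i),
        novelty = ifelse(noise, "GENOMIC", "KNOWN"),
        priming = sample(c("OLIGO_DT", "RANDOM_HEXAMER"), n, replace = TRUE),
        dataset = dataset,
        true_tss = sprintf("%s_tss%d", m$gene_id, tss_i),
        true_tes = sprintf("%s_tes%d", m$gene_id, tes_i),
        stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, rows)
    site_tab <- function(field, pi_field, tag) {
      do.call(rbind, lapply(models, function(m) data.frame(
        gene_id = m$gene_id,
        site_id = sprintf("%s_%s%d", m$gene_id, tag,
                          seq_along(m[[field]])),
        chrom = m$chrom, strand = m$strand,
        pos = m[[field]], pi = m[[pi_field]],
        stringsAsFactors = FALSE)))
    }
    truth <- list(
      reads = ann[, c("read_id", "gene_id", "novelty", "true_tss",
                      "true_tes")],
      tss = site_tab("tss", "tss_pi", "tss"),
      tes = site_tab("tes", "tes_pi", "tes"))
    ann$true_tss <- NULL
    ann$true_tes <- NULL
    list(annotations = ann, truth = truth)
  })
}

#' Simulate per-cell feature counts with planted usage switches
#'
#' Genes share a usage vector between the two groups under the null; switch
#' genes use `pi_a` in group A and `pi_b` in group B.  Reads are drawn per
#' gene per group from a multinomial over (feature, cell) with cells
#' weighted equally.  The truth records each gene's switch status and its
#' population delta-pi.
#'
#' @param n_genes total genes.
#' @param n_features features (isoforms/TSSs) per gene.
#' @param reads_per_group reads per gene per group (scalar or length-2).
#' @param n_switch number of switch genes (the first `n_switch`).
#' @param pi_a usage vector for group A (default equal usage).
#' @param pi_b usage vector for group B switch genes (default `pi_a` with
#'   the top two entries swapped).
#' @param n_cells_per_group cells per group.
#' @param groups group labels.
#' @param seed RNG seed.
#' @return list with `matrix` (feature × cell sparse counts), `cell_groups`
#'   (named map), `feature_genes` (named map) and `truth` (gene_id, switch,
#'   dpi_true).
#' @export
simulate_usage_counts <- function(n_genes = 100L, n_features = 5L,
                                  reads_per_group = 50L, n_switch = 0L,
                                  pi_a = NULL, pi_b = NULL,
                                  n_cells_per_group = 10L,
                                  groups = c("A", "B"), seed = 1L) {
  with_seed(seed, {
    if (is.null(pi_a)) pi_a <- rep(1 / n_features, n_features)
    if (is.null(pi_b)) {
      pi_b <- pi_a
      o <- order(-pi_a)[1:2]
      pi_b[o] <- pi_a[rev(o)]
    }
    stopifnot(length(pi_a) == n_features, length(pi_b) == n_features,
              abs(sum(pi_a) - 1) < 1e-8, abs(sum(pi_b) - 1) < 1e-8)
    rpg <- rep(reads_per_group, length.out = 2L)
    cells <- c(sprintf("%s_c%03d", groups[1], seq_len(n_cells_per_group)),
               sprintf("%s_c%03d", groups[2], seq_len(n_cells_per_group)))
    cell_groups <- setNames(rep(groups, each = n_cells_per_group), cells)
    n_cell <- length(cells)
    blocks <- lapply(seq_len(n_genes), function(g) {
      switch_gene <- g <= n_switch
      pg <- list(pi_a, if (switch_gene) pi_b else pi_a)
      counts <- matrix(0L, n_features, n_cell)
      for (cond in 1:2) {
        in_g <- which(cell_groups[cells] == groups[cond])
        prob <- outer(pg[[cond]], rep(1 / length(in_g), length(in_g)))
        draw <- stats::rmultinom(1L, rpg[cond], as.vector(prob))
        counts[, in_g] <- matrix(draw, n_features, length(in_g))
      }
      counts
    })
    mat <- Matrix::Matrix(do.call(rbind, blocks), sparse = TRUE)
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    feat_ids <- as.vector(t(outer(gene_ids, seq_len(n_features),
                                  function(g, f) sprintf("%s_f%d", g, f))))
    dimnames(mat) <- list(feat_ids, cells)
    feature_genes <- setNames(rep(gene_ids, each = n_features), feat_ids)
    dpi_of <- function(p, q) {
      top <- order(-(p + q))[1:2]
      sum(abs(p[top] - q[top])) * 100
    }
    truth <- data.frame(
      gene_id = gene_ids,
      switch = seq_len(n_genes) <= n_switch,
      dpi_true = ifelse(seq_len(n_genes) <= n_switch, dpi_of(pi_a, pi_b), 0),
      stringsAsFactors = FALSE)
    list(matrix = mat, cell_groups = cell_groups,
         feature_genes = feature_genes, truth = truth)
  })
}

#' Simulate accessibility coupled to expression at a target correlation
#'
#' `acc = a * expr + noise`, with the coefficient and noise variance solved
#' so the population Pearson correlation equals `target_r`
#' (`a = sign(target_r)`, `sd_noise = sd(expr) * sqrt(1/r^2 - 1)`).
#' Negative values are truncated at zero when `truncate = TRUE`, which
#' biases the realised correlation at extreme settings; the sampling is
#' seed-fixed.
#'
#' @param expr numeric vector or matrix of expression values.
#' @param target_r target Pearson correlation, in \[-1, 1\].
#' @param seed RNG seed.
#' @param truncate clip negative accessibility at 0.
#' @return numeric object shaped like `expr`.
#' @export
simulate_accessibility <- function(expr, target_r, seed = 1L,
                                   truncate = TRUE) {
  stopifnot(abs(target_r) <= 1)
  with_seed(seed, {
    e <- as.numeric(expr)
    s <- stats::sd(e)
    if (target_r == 0) {
      acc <- stats::rnorm(length(e), mean = mean(e), sd = s)
    } else {
      a <- sign(target_r)
      sd_noise <- s * sqrt(1 / target_r^2 - 1)
      acc <- a * e + stats::rnorm(length(e), 0, sd_noise)
      if (a < 0) acc <- acc + 2 * mean(e)  # keep the location non-negative
    }
    if (truncate) acc <- pmax(0, acc)
    if (is.matrix(expr)) {
      acc <- matrix(acc, nrow(expr), dimnames = dimnames(expr))
    } else names(acc) <- names(expr)
    acc
  })
}
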