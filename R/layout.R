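#' @title Barcode layout for split-pool combinatorial demultiplexing
#'
#' @description A `barcode_layout` describes the geometry of the barcode block
#' appended to each cDNA molecule during three rounds of split-pool barcoding.
#' On the forward (cDNA-first) strand a read is laid out as
#'
#' ```
#' 5'- cDNA | UMI | bc3 | linker1 | bc2 | linker2 | bc1 -3'
#' ```
#'
#' where `bc1` is the round-1 barcode (ligated last, sequenced at the 3' end)
#' and the two fixed linker sequences separate the barcode rounds.  Round-1
#' wells carry both an oligo-dT and a random-hexamer primer, so two round-1
#' barcodes map to one physical well; `priming_map` records which primer each
#' round-1 barcode encodes and `well_pair_map` collapses the pair onto the
#' well.
#'
#' @param whitelists list of three character vectors (round 1, 2, 3), each the
#'   set of legal barcodes for that round.  All barcodes within a round must
#'   have the same length.
#' @param linkers character vector of two linker sequences; `linkers[1]`
#'   separates bc3 from bc2, `linkers[2]` separates bc2 from bc1.
#' @param umi_length length of the unique molecular identifier adjacent to the
#'   round-3 barcode (default 10).
#' @param priming_map named character vector mapping every round-1 barcode to
#'   `"OLIGO_DT"` or `"RANDOM_HEXAMER"`.
#' @param well_pair_map named character vector mapping every round-1 barcode
#'   to its well id; exactly two barcodes (one per priming type) must map to
#'   each well.
#' @param max_edit_distance maximum Levenshtein distance allowed when
#'   correcting an observed barcode to its whitelist (default 3).
#' @param max_linker_errors maximum edit errors tolerated when locating each
#'   linker (default 2).
#' @return An object of class `barcode_layout`.
#' @export
barcode_layout <- function(whitelists, linkers, umi_length = 10L,
                           priming_map, well_pair_map,
                           max_edit_distance = 3L, max_linker_errors = 2L) {
  stopifnot(length(whitelists) == 3L, length(linkers) == 2L,
            umi_length > 0L, max_edit_distance >= 0L, max_linker_errors >= 0L)
  whitelists <- lapply(whitelists, function(w) toupper(as.character(w)))
  for (i in seq_along(whitelists)) {
    w <- whitelists[[i]]
    if (length(w) == 0L) stop("round ", i, " whitelist is empty")
    if (length(unique(nchar(w))) != 1L)
      stop("round ", i, " barcodes differ in length")
    if (anyDuplicated(w)) stop("round ", i, " whitelist has duplicates")
  }
  r1 <- whitelists[[1L]]
  if (!all(r1 %in% names(priming_map)))
    stop("priming_map must cover every round-1 barcode")
  if (!all(priming_map %in% c("OLIGO_DT", "RANDOM_HEXAMER")))
    stop("priming_map values must be OLIGO_DT or RANDOM_HEXAMER")
  if (!all(r1 %in% names(well_pair_map)))
    stop("well_pair_map must cover every round-1 barcode")
  per_well <- table(well_pair_map[r1])
  if (!all(per_well == 2L))
    stop("well_pair_map must map exactly two round-1 barcodes to each well")
  layout <- structure(list(
    rounds = lapply(whitelists, function(w)
      list(whitelist = w, barcode_length = nchar(w[1L]))),
    linkers = toupper(as.character(linkers)),
    umi_length = as.integer(umi_length),
    priming_map = priming_map,
    well_pair_map = well_pair_map,
    max_edit_distance = as.integer(max_edit_distance),
    max_linker_errors = as.integer(max_linker_errors)
  ), class = "barcode_layout")
  layout
}

#' @export
print.barcode_layout <- function(x, ...) {
  bl <- vapply(x$rounds, function(r) r$barcode_length, integer(1))
  nw <- vapply(x$rounds, function(r) length(r$whitelist), integer(1))
  cat("barcode_layout: 3 rounds (", paste0(nw, "x", bl, "bp", collapse = ", "),
      "), UMI ", x$umi_length, " bp\n", sep = "")
  cat("  linkers: ", paste(nchar(x$linkers), collapse = " + "),
      " bp; max barcode edit distance ", x$max_edit_distance,
      "; max linker errors ", x$max_linker_errors, "\n", sep = "")
  cat("  wells: ", length(unique(x$well_pair_map)), "\n", sep = "")
  invisible(x)
}

# total length of the barcode block (UMI through bc1) on the forward strand
barcode_block_length <- function(layout) {
  bl <- vapply(layout$rounds, function(r) r$barcode_length, integer(1))
  layout$umi_length + sum(bl) + sum(nchar(layout$linkers))
}

#' Levenshtein edit distance
#'
#' Elementwise Levenshtein (substitution + indel) distance between two
#' character vectors, recycled to a common length.
#'
#' @param a,b character vectors.
#' @return integer vector of distances.
#' @export
edit_distance <- function(a, b) {
  .edit_distance_cpp(as.character(a), as.character(b))
}

#' Generate a whitelist with guaranteed pairwise separation
#'
#' Greedy rejection sampling of random barcodes: a candidate is accepted when
#' its Levenshtein distance to every already-accepted barcode is at least
#' `min_dist`.  With `min_dist >= 2*k + 1`, correction at edit distance `k`
#' is provably unambiguous.  Uses the current RNG state; seed beforehand for
#' reproducibility.
#'
#' @param n number of barcodes requested.
#' @param barcode_length barcode length in bp.
#' @param min_dist minimum pairwise Levenshtein distance.
#' @param max_tries candidate draws before giving up.
#' @return character vector of `n` barcodes.
#' @export
make_whitelist <- function(n, barcode_length = 14L, min_dist = 7L,
                           max_tries = 200000L) {
  acc <- character(0)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(max_tries)) {
    cand <- paste(sample(bases, barcode_length, replace = TRUE), collapse = "")
    ok <- length(acc) == 0L ||
      min(.match_barcodes_cpp(cand, acc, barcode_length)$dist) >= min_dist
    if (ok) acc <- c(acc, cand)
    if (length(acc) >= n) return(acc)
  }
  stop("could not find ", n, " barcodes of length ", barcode_length,
       " at min pairwise distance ", min_dist, " in ", max_tries, " tries")
}

# Fixed linker sequences separating the barcode rounds.  22 bp keeps the
# probability of exceeding a 2-edit budget negligible at long-read error
# rates while remaining specific.
.default_linkers <- c("GTGGCCGATGTTTCGCATCGGC",
                      "ATCCACGTGCTTGAGAGGCCAG")

#' Simulation barcode layout with provably unambiguous correction
#'
#' Builds a `barcode_layout` whose whitelists have minimum pairwise
#' Levenshtein distance `min_dist`.  With the defaults (`min_dist = 7`,
#' `max_edit_distance = 3`) every barcode within 3 edits of a whitelist entry
#' corrects to exactly one entry, so simulated round-trips have a provable
#' misassignment rate of zero.  Distance-7 codes require barcodes longer than
#' the 8 bp of commercial kits: 14 bp accommodates 48 words per round.  Use
#' `min_dist = 4` ("hard mode") to exercise the ambiguous-correction path.
#'
#' Round 1 carries `2 * n_wells` barcodes: each well has an oligo-dT and a
#' random-hexamer barcode.
#'
#' @param n_wells number of round-1 wells (default 24, i.e. 48 round-1
#'   barcodes).
#' @param n_round numbers of round-2 and round-3 barcodes (default 48).
#' @param barcode_length barcode length in bp (default 14).
#' @param min_dist minimum pairwise Levenshtein distance within each round.
#' @param umi_length UMI length (default 10).
#' @param seed RNG seed controlling whitelist construction.
#' @return A `barcode_layout`.
#' @export
sim_barcode_layout <- function(n_wells = 24L, n_round = 48L,
                               barcode_length = 14L, min_dist = 7L,
                               umi_length = 10L, seed = 1L) {
  with_seed(seed, {
    r1 <- make_whitelist(2L * n_wells, barcode_length, min_dist)
    r2 <- make_whitelist(n_round, barcode_length, min_dist)
    r3 <- make_whitelist(n_round, barcode_length, min_dist)
    wells <- sprintf("W%02d", seq_len(n_wells))
    priming <- setNames(rep(c("OLIGO_DT", "RANDOM_HEXAMER"), n_wells), r1)
    well_map <- setNames(rep(wells, each = 2L), r1)
    barcode_layout(list(r1, r2, r3), .default_linkers,
                   umi_length = umi_length,
                   priming_map = priming, well_pair_map = well_map)
  })
}

#' Read / write a barcode layout config file
#'
#' The layout is stored as YAML with fields `rounds` (list of `whitelist`
#' vectors), `linkers`, `umi_length`, `priming_map`, `well_pair_map`,
#' `max_edit_distance` and `max_linker_errors`, so any split-pool kit
#' revision is expressible without code changes.
#'
#' @param path file path.
#' @return `read_layout` returns a `barcode_layout`; `write_layout` returns
#'   `path` invisibly.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("layout config not found: ", path)
  y <- yaml::read_yaml(path)
  for (f in c("rounds", "linkers", "umi_length", "priming_map",
              "well_pair_map")) {
    if (is.null(y[[f]])) stop("layout config missing field: ", f)
  }
  barcode_layout(
    whitelists = lapply(y$rounds, function(r) unlist(r$whitelist)),
    linkers = unlist(y$linkers),
    umi_length = y$umi_length,
    priming_map = unlist(y$priming_map),
    well_pair_map = unlist(y$well_pair_map),
    max_edit_distance = y$max_edit_distance %||% 3L,
    max_linker_errors = y$max_linker_errors %||% 2L
  )
}

#' @rdname read_layout
#' @param layout a `barcode_layout`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "barcode_layout"))
  y <- list(
    umi_length = layout$umi_length,
    max_edit_distance = layout$max_edit_distance,
    max_linker_errors = layout$max_linker_errors,
    linkers = as.list(layout$linkers),
    rounds = lapply(layout$rounds, function(r)
      list(whitelist = as.list(r$whitelist))),
    priming_map = as.list(layout$priming_map),
    well_pair_map = as.list(layout$well_pair_map)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
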