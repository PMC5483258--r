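refine_pair <- function(scaffolds, ...) {
  anchors <- build_anchor_map(scaffolds)
  refine_segments(chain_anchors(anchors, ...), scaffolds)
}

test_that("identical scaffolds anchor along the main diagonal", {
  set.seed(101)
  x <- rand_dna(1000)
  an <- build_anchor_map(c(s1 = x, s2 = x), k = 15)
  diag_fwd <- an$scaffold_a == "s1" & an$scaffold_b == "s2" &
    an$orientation == "forward" & an$pos_a == an$pos_b
  expect_gte(sum(diag_fwd), 986)
})

test_that("a reverse complement anchors on the anti-diagonal", {
  set.seed(102)
  x <- rand_dna(1000)
  an <- build_anchor_map(c(s1 = x, s2 = revcomp(x)), k = 15)
  rev_anchors <- an[an$scaffold_a == "s1" & an$scaffold_b == "s2" &
                      an$orientation == "reverse", ]
  expect_gte(nrow(rev_anchors), 986)
  expect_true(all(rev_anchors$pos_b == 1000 - rev_anchors$pos_a - 15))
})

test_that("independent random scaffolds share no seeds", {
  set.seed(103)
  an <- build_anchor_map(c(s1 = rand_dna(1000), s2 = rand_dna(1000)), k = 15)
  expect_identical(sum(an$scaffold_a != an$scaffold_b), 0L)
})

fake_anchors <- function(pos_a, pos_b, seqlens) {
  out <- data.frame(scaffold_a = "s1", scaffold_b = "s2",
                    pos_a = pos_a, pos_b = pos_b, length = 15L,
                    orientation = "forward", stringsAsFactors = FALSE)
  attr(out, "seqlengths") <- seqlens
  out
}

test_that("anchors on one diagonal form a single chain", {
  p <- seq(0, 900, by = 100)
  ch <- chain_anchors(fake_anchors(p, p, c(s1 = 2000, s2 = 2000)))
  expect_length(ch, 1)
  expect_length(ch[[1]]$pa, 10)
})

test_that("a gap larger than max_gap splits the chain in two", {
  p <- c(seq(0, 400, by = 100), seq(1500, 1900, by = 100))
  ch <- chain_anchors(fake_anchors(p, p, c(s1 = 3000, s2 = 3000)),
                      max_gap = 500)
  expect_length(ch, 2)
})

test_that("a planted inversion yields a separate reverse chain", {
  cfg <- sim_config(seed = 21, ancestral_length = 60000, n_scaffolds = 2,
                    inversion_size_range = c(3000, 6000),
                    n_translocations = 0, n_genes = 15)
  tr <- generate_truth(cfg)
  ev <- tr$structural[tr$structural$type == "inversion", ]
  ch <- chain_anchors(build_anchor_map(c(tr$haplotype_a, tr$haplotype_b)))
  hit <- vapply(ch, function(c.)
    c.$orientation == "reverse" &&
      c.$scaffold_a == ev$a_scaffold &&
      min(c.$pa) < ev$a_end && max(c.$pa) > ev$a_start, logical(1))
  expect_gte(sum(hit), 1)
})

test_that("an identical 10 kb pair refines to one clean segment", {
  set.seed(104)
  x <- rand_dna(10000)
  segs <- refine_pair(c(s1 = x, s2 = x))
  expect_length(segs, 1)
  s <- segs[[1]]
  expect_identical(c(s$start_a, s$end_a), c(0L, 10000L))
  expect_identical(s$n_mismatch, 0L)
  expect_identical(s$n_ins_events + s$n_del_events, 0L)
})

test_that("exactly 57 planted substitutions are recovered", {
  set.seed(105)
  x <- rand_dna(5000)
  pos <- sample(5000, 57)
  ch <- strsplit(x, "")[[1]]
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA, b), 1),
                    character(1))
  segs <- refine_pair(c(s1 = x, s2 = paste(ch, collapse = "")))
  df <- as.data.frame(segs)
  expect_identical(sum(df$n_mismatch), 57L)
  expect_identical(sum(df$indel_events), 0L)
})

test_that("one planted 5 bp deletion is recovered as one event", {
  set.seed(106)
  x <- rand_dna(5000)
  y <- paste0(substr(x, 1, 2500), substr(x, 2506, 5000))
  segs <- refine_pair(c(s1 = x, s2 = y))
  expect_length(segs, 1)
  s <- segs[[1]]
  expect_identical(s$n_del_events, 1L)
  expect_identical(s$n_ins_events, 0L)
  expect_identical(s$len[s$op == 3L], 5L)
})

## op vector with mismatches at the given 0-based column offsets
op_with_mism <- function(n, mism) {
  v <- rep.int(0L, n); v[mism + 1L] <- 1L
  r <- rle(v); list(op = r$values, len = r$lengths)
}

test_that("non-overlapping segments pass tiling unchanged", {
  o1 <- op_with_mism(300, c(10, 200))
  o2 <- op_with_mism(300, 50)
  segs <- make_segments(list(
    c(list(scaffold_a = "A", start_a = 0, scaffold_b = "B", start_b = 0,
           orientation = "forward"), o1),
    c(list(scaffold_a = "A", start_a = 500, scaffold_b = "B", start_b = 500,
           orientation = "forward"), o2)), c(A = 1000, B = 1000))
  tiled <- reciprocal_best_tiling(segs, min_segment_length = 50)
  expect_equal(as.data.frame(tiled), as.data.frame(segs))
})

test_that("tiling trims the weaker of two A-overlapping segments", {
  o1 <- op_with_mism(100, c(10, 30, 50, 70, 90))            # density 0.9
  o2 <- op_with_mism(100, seq(1, 97, by = 4))               # density 0.5
  segs <- make_segments(list(
    c(list(scaffold_a = "A", start_a = 0, scaffold_b = "B", start_b = 0,
           orientation = "forward"), o1),
    c(list(scaffold_a = "A", start_a = 50, scaffold_b = "C", start_b = 0,
           orientation = "forward"), o2)), c(A = 1000, B = 1000, C = 1000))
  tiled <- as.data.frame(reciprocal_best_tiling(segs, min_segment_length = 10))
  expect_identical(nrow(tiled), 2L)
  s1 <- tiled[tiled$scaffold_b == "B", ]
  expect_identical(c(s1$start_a, s1$end_a), c(0L, 100L))
  s2 <- tiled[tiled$scaffold_b == "C", ]
  expect_identical(c(s2$start_a, s2$end_a), c(100L, 150L))
  expect_identical(c(s2$start_b, s2$end_b), c(50L, 100L))
})

test_that("a segment dominated on both sides is dropped", {
  o1 <- list(op = 0L, len = 300L)
  o2 <- op_with_mism(200, seq(1, 197, by = 4))
  segs <- make_segments(list(
    c(list(scaffold_a = "A", start_a = 0, scaffold_b = "B", start_b = 0,
           orientation = "forward"), o1),
    c(list(scaffold_a = "A", start_a = 50, scaffold_b = "B", start_b = 50,
           orientation = "forward"), o2)), c(A = 1000, B = 1000))
  tiled <- as.data.frame(reciprocal_best_tiling(segs, min_segment_length = 10))
  expect_identical(nrow(tiled), 1L)
  expect_identical(c(tiled$start_a, tiled$end_a), c(0L, 300L))
})

## swap the A and B roles of every segment
swap_segments <- function(segments) {
  seqlens <- attr(segments, "seqlengths")
  out <- lapply(segments, function(s) {
    op <- s$op; len <- s$len
    if (s$orientation == "reverse") { op <- rev(op); len <- rev(len) }
    op <- ifelse(op == 2L, 3L, ifelse(op == 3L, 2L, op))
    c(list(scaffold_a = s$scaffold_b, start_a = s$start_b, end_a = s$end_b,
           scaffold_b = s$scaffold_a, start_b = s$start_a, end_b = s$end_a,
           orientation = s$orientation, op = op, len = len, score = s$score),
      list(n_match = s$n_match, n_mismatch = s$n_mismatch,
           n_ins_events = s$n_del_events, n_del_events = s$n_ins_events))
  })
  structure(out, class = "paired_segments", seqlengths = seqlens)
}

## canonical base-level pairing of a tiling, as sortable strings
matched_pairs <- function(segments, swapped = FALSE) {
  out <- unlist(lapply(segments, function(s) {
    cc <- segment_columns(s)
    keep <- cc$op <= 1L
    if (swapped)
      paste(s$scaffold_b, cc$b_pos[keep], s$scaffold_a, cc$a_pos[keep])
    else
      paste(s$scaffold_a, cc$a_pos[keep], s$scaffold_b, cc$b_pos[keep])
  }))
  sort(out)
}

test_that("tiling is idempotent and symmetric on simulated segments", {
  cfg <- sim_config(seed = 22, ancestral_length = 30000, n_scaffolds = 2,
                    inversion_size_range = c(2000, 3000),
                    n_translocations = 0, n_genes = 8)
  tr <- generate_truth(cfg)
  scaffolds <- c(tr$haplotype_a, tr$haplotype_b)
  raw <- refine_pair(scaffolds)
  t1 <- reciprocal_best_tiling(raw)
  t2 <- reciprocal_best_tiling(t1)
  expect_equal(as.data.frame(t2), as.data.frame(t1))
  ts <- reciprocal_best_tiling(swap_segments(raw))
  expect_identical(matched_pairs(ts, swapped = TRUE), matched_pairs(t1))
})

test_that("the published totals give the published percentages", {
  s <- pairing_summary(genome_length = 170470384, paired_length = 152151424,
                       mismatches = 8685973, indel_events = 997343)
  expect_identical(round(100 * s$coverage_fraction, 1), 89.3)
  expect_identical(round(s$heterozygosity_pct, 1), 5.7)
  expect_identical(round(s$indel_pct, 2), 0.66)
})

test_that("an empty tiling summarizes to zero with a flag", {
  empty <- make_segments(list(), c(A = 1000, B = 1000))
  s <- summarize_pairing(empty, c(A = rand_dna(10), B = rand_dna(10)))
  expect_identical(s$coverage_fraction, 0)
  expect_identical(s$heterozygosity_pct, 0)
  expect_true(s$undefined)
})

test_that("adding a homolog-free scaffold can only lower coverage", {
  set.seed(107)
  x <- rand_dna(3000)
  y <- mutate_seq(x, 0.05, 0.002)
  s1 <- summarize_pairing(pair_scaffolds(c(s1 = x, s2 = y)),
                          c(s1 = x, s2 = y))
  z <- rand_dna(2000)
  s2 <- summarize_pairing(pair_scaffolds(c(s1 = x, s2 = y, s3 = z)),
                          c(s1 = x, s2 = y, s3 = z))
  expect_lte(s2$coverage_fraction, s1$coverage_fraction)
})

test_that("segment scores match unbanded global alignment on random pairs", {
  set.seed(108)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (i in 1:10) {
    a <- rand_dna(sample(500:2000, 1))
    b <- mutate_seq(a, 0.05, 0.01)
    segs <- refine_pair(c(sA = a, sB = b))
    want <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = 1, gapExtension = 1, scoreOnly = TRUE)
    expect_length(segs, 1)
    expect_identical(as.numeric(segs[[1]]$score), as.numeric(want))
  }
})
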