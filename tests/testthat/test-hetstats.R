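## one forward segment on scaffold pair (A, B) from an op/len spec
one_segment <- function(op, len, seqlens = c(A = 1000, B = 1000),
                        start_a = 0, start_b = 0) {
  make_segments(list(list(scaffold_a = "A", start_a = start_a,
                          scaffold_b = "B", start_b = start_b,
                          orientation = "forward", op = op, len = len)),
                seqlens)
}

test_that("variant totals follow the both-sides arithmetic", {
  segs <- one_segment(op = c(0L, 1L, 0L, 3L, 0L, 2L, 0L),
                      len = c(100L, 10L, 100L, 5L, 100L, 4L, 81L))
  vt <- variant_totals(segs)
  expect_identical(vt$snv_sites, 10L)
  expect_identical(vt$indel_event_sites, 2L)
  expect_identical(vt$snv_count, 20L)
  expect_identical(vt$indel_event_count, 4L)
  ## A consumes all but the insertion, B all but the deletion
  expect_identical(vt$paired_length, 791L)  # (400 - 4) + (400 - 5)
  expect_equal(vt$snv_pct, 100 * 20 / 791)
  expect_equal(vt$indel_pct, 100 * 4 / 791)
})

test_that("a zero-divergence simulation yields all-zero totals", {
  set.seed(201)
  x <- rand_dna(10000)
  vt <- variant_totals(pair_scaffolds(c(s1 = x, s2 = x)))
  expect_identical(vt$snv_sites, 0L)
  expect_identical(vt$indel_event_sites, 0L)
  expect_identical(vt$snv_pct, 0)
  expect_identical(vt$indel_pct, 0)
})

test_that("empty input reports zeros with the undefined flag", {
  vt <- variant_totals(make_segments(list(), c(A = 10, B = 10)))
  expect_true(vt$undefined)
  expect_identical(vt$snv_pct, 0)
})

test_that("isolated planted variants are recovered exactly from the ledger", {
  ## sparse rates: variants are far apart, so the planted edit script
  ## is the unique optimal alignment and must be recovered verbatim
  cfg <- sim_config(seed = 23, ancestral_length = 150000,
                    snv_rate_cds = 0.003, snv_rate_intron = 0.003,
                    snv_rate_intergenic = 0.003, indel_event_rate = 3e-4,
                    n_inversions = 0, n_translocations = 0)
  tr <- generate_truth(cfg)
  segs <- pair_scaffolds(c(tr$haplotype_a, tr$haplotype_b))
  vt <- variant_totals(segs)
  expect_gt(sum(tr$variants$type == "SNV"), 100)
  expect_gt(sum(tr$variants$type != "SNV"), 10)
  expect_identical(vt$snv_sites,
                   sum(tr$variants$type == "SNV"))
  expect_identical(vt$indel_event_sites,
                   sum(tr$variants$type != "SNV"))
})

test_that("measured totals stay within 3 SD of the ledger at study density", {
  ## at 5.7% divergence equally-optimal alignments may re-decompose
  ## variant clusters, so the comparison is statistical, not exact
  cfg <- sim_config(seed = 23, ancestral_length = 100000,
                    n_inversions = 0, n_translocations = 0)
  tr <- generate_truth(cfg)
  segs <- pair_scaffolds(c(tr$haplotype_a, tr$haplotype_b))
  vt <- variant_totals(segs)
  n_cols <- vt$paired_length / 2
  p <- sum(tr$variants$type == "SNV") / cfg$ancestral_length
  expect_lt(abs(vt$snv_sites / n_cols - p), 3 * sqrt(p * (1 - p) / n_cols))
})

test_that("class densities recover the planted class rates within 3 SD", {
  cfg <- sim_config(seed = 24, ancestral_length = 200000,
                    n_inversions = 0, n_translocations = 0)
  tr <- generate_truth(cfg)
  segs <- pair_scaffolds(c(tr$haplotype_a, tr$haplotype_b))
  genesA <- tr$genes[tr$genes$haplotype == "A", , drop = FALSE]
  cd <- class_densities(segs, genesA)
  rates <- c(intergenic = cfg$snv_rate_intergenic,
             intron = cfg$snv_rate_intron, CDS = cfg$snv_rate_cds)
  ## classes partition the aligned bases exactly
  cc <- lapply(segs, segment_columns)
  aligned_total <- length(unique(unlist(lapply(seq_along(segs), function(i)
    paste(segs[[i]]$scaffold_a, cc[[i]]$a_pos[cc[[i]]$op <= 1L])))))
  expect_identical(sum(cd$classes$aligned_bases), aligned_total)
  for (i in seq_len(nrow(cd$classes))) {
    p <- rates[[cd$classes$class[i]]]
    n <- cd$classes$aligned_bases[i]
    expect_gt(n, 10000)
    expect_lt(abs(cd$classes$density_pct[i] / 100 - p),
              3 * sqrt(p * (1 - p) / n))
  }
})

test_that("a gene-free annotation puts every aligned base in intergenic", {
  segs <- one_segment(op = c(0L, 1L, 0L), len = c(200L, 10L, 190L))
  empty_genes <- data.frame(gene_id = character(0), scaffold = character(0),
                            start = integer(0), end = integer(0))
  empty_genes$exons <- list()
  cd <- class_densities(segs, empty_genes)
  expect_identical(cd$classes$aligned_bases[cd$classes$class == "intergenic"],
                   400L)
  expect_identical(sum(cd$classes$aligned_bases), 400L)
  expect_identical(cd$classes$snvs[cd$classes$class == "intergenic"], 10L)
})

test_that("a 300 bp CDS with 12 SNVs has per-gene density 4.0", {
  mism <- seq(110, 220, by = 10)  # 12 positions inside the CDS
  opv <- rep.int(0L, 1000); opv[mism + 1L] <- 1L
  r <- rle(opv)
  segs <- one_segment(r$values, r$lengths)
  gene <- data.frame(gene_id = "g1", scaffold = "A", start = 100L, end = 400L,
                     stringsAsFactors = FALSE)
  gene$exons <- list(cbind(100L, 400L))
  cd <- class_densities(segs, gene)
  expect_identical(cd$genes$cds_aligned, 300L)
  expect_identical(cd$genes$cds_snvs, 12L)
  expect_equal(cd$genes$cds_density_pct, 4.0)
})

test_that("mismatches land in their 100 bp windows", {
  opv <- rep.int(0L, 400); opv[c(5, 150) + 1L] <- 1L
  r <- rle(opv)
  tk <- window_tracks(one_segment(r$values, r$lengths))
  mm <- tk$mismatch[tk$mismatch$scaffold == "A", ]
  expect_identical(mm$count[mm$window_start == 0], 1L)
  expect_identical(mm$count[mm$window_start == 100], 1L)
  expect_identical(sum(mm$count), 2L)
})

test_that("window counts conserve the mismatch totals per scaffold", {
  set.seed(202)
  x <- rand_dna(20000)
  y <- mutate_seq(x, 0.05, 0.003)
  segs <- pair_scaffolds(c(s1 = x, s2 = y))
  tk <- window_tracks(segs)
  df <- as.data.frame(segs)
  expect_identical(sum(tk$mismatch$count), sum(df$n_mismatch))
})

test_that("a 5 bp deletion at 250 is recorded at 249 with value -5", {
  segs <- one_segment(op = c(0L, 3L, 0L), len = c(250L, 5L, 145L))
  tk <- window_tracks(segs)
  expect_identical(nrow(tk$indels), 1L)
  expect_identical(tk$indels$pos, 249L)
  expect_identical(tk$indels$value, -5L)
})

test_that("no structural events are called on a colinear simulation", {
  cfg <- sim_config(seed = 25, ancestral_length = 60000,
                    n_inversions = 0, n_translocations = 0)
  tr <- generate_truth(cfg)
  segs <- pair_scaffolds(c(tr$haplotype_a, tr$haplotype_b))
  expect_identical(nrow(structural_events(segs)), 0L)
})

test_that("planted inversion and translocation are both recovered", {
  cfg <- sim_config(seed = 26, ancestral_length = 150000,
                    inversion_size_range = c(5000, 8000),
                    translocation_size_range = c(3000, 6000))
  tr <- generate_truth(cfg)
  segs <- pair_scaffolds(c(tr$haplotype_a, tr$haplotype_b))
  calls <- structural_events(segs)
  expect_identical(nrow(calls), 2L)
  inv <- tr$structural[tr$structural$type == "inversion", ]
  ci <- calls[calls$type == "inversion", ]
  expect_identical(nrow(ci), 1L)
  expect_identical(ci$scaffold_a, inv$a_scaffold)
  expect_true(ci$start_a < inv$a_end && ci$end_a > inv$a_start)
  tl <- tr$structural[tr$structural$type == "translocation", ]
  ct <- calls[calls$type == "translocation", ]
  expect_identical(nrow(ct), 1L)
  expect_identical(ct$scaffold_a, tl$a_scaffold)
  expect_identical(ct$partner, tl$dest_scaffold)
  expect_true(ct$start_a < tl$a_end && ct$end_a > tl$a_start)
})
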