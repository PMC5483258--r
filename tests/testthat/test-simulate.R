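test_that("zero-rate config is an exact identity with empty ledgers", {
  cfg <- sim_config(seed = 1, ancestral_length = 20000, n_scaffolds = 2,
                    snv_rate_cds = 0, snv_rate_intron = 0,
                    snv_rate_intergenic = 0, indel_event_rate = 0,
                    n_inversions = 0, n_translocations = 0, n_genes = 6)
  tr <- generate_truth(cfg)
  expect_identical(unname(tr$haplotype_b), unname(tr$haplotype_a))
  expect_identical(nrow(tr$variants), 0L)
  expect_identical(nrow(tr$structural), 0L)
})

test_that("uniform substitution rate is realized within 3 binomial SD", {
  cfg <- sim_config(seed = 2, ancestral_length = 100000, n_scaffolds = 2,
                    snv_rate_cds = 0.057, snv_rate_intron = 0.057,
                    snv_rate_intergenic = 0.057, indel_event_rate = 0,
                    n_inversions = 0, n_translocations = 0)
  tr <- generate_truth(cfg)
  frac <- nrow(tr$variants) / 100000
  expect_lt(abs(frac - 0.057), 3 * sqrt(0.057 * 0.943 / 100000))
})

test_that("generation is deterministic for a fixed config and seed", {
  cfg <- sim_config(seed = 3, ancestral_length = 30000, n_scaffolds = 2,
                    inversion_size_range = c(1000, 2000),
                    translocation_size_range = c(1000, 2000), n_genes = 8)
  expect_identical(generate_truth(cfg), generate_truth(cfg))
})

test_that("ledger replay reproduces haplotype B byte for byte", {
  cfg <- sim_config(seed = 7, ancestral_length = 80000, n_scaffolds = 2,
                    inversion_size_range = c(2000, 4000),
                    translocation_size_range = c(1000, 3000), n_genes = 20)
  tr <- generate_truth(cfg)
  expect_gt(nrow(tr$variants), 0)
  expect_identical(nrow(tr$structural), 2L)
  expect_identical(replay_truth(tr), tr$haplotype_b)
})

test_that("class-specific substitution rates are realized within 3 SD", {
  cfg <- sim_config(seed = 11, ancestral_length = 200000,
                    n_inversions = 0, n_translocations = 0)
  tr <- generate_truth(cfg)
  snv <- tr$variants[tr$variants$type == "SNV", ]
  class_bases <- vapply(0:2, function(k)
    sum(vapply(tr$class_map, function(m) sum(m == k), integer(1))), numeric(1))
  rates <- c(intergenic = cfg$snv_rate_intergenic,
             intron = cfg$snv_rate_intron, CDS = cfg$snv_rate_cds)
  for (i in 1:3) {
    cl <- c("intergenic", "intron", "CDS")[i]
    n <- class_bases[i]
    expect_gt(n, 10000)  # every class is large enough for the bound
    p <- rates[[cl]]
    realized <- sum(snv$class == cl) / n
    expect_lt(abs(realized - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("emit_assembly writes both haplotypes and round-trips the GFF3", {
  cfg <- sim_config(seed = 5, ancestral_length = 20000, n_scaffolds = 2,
                    n_inversions = 0, n_translocations = 0, n_genes = 6)
  tr <- generate_truth(cfg)
  fa <- tempfile(fileext = ".fasta"); gf <- tempfile(fileext = ".gff3")
  em <- emit_assembly(tr, fasta = fa, gff3 = gf)
  expect_identical(length(em$seqs), 4L)
  expect_identical(sum(startsWith(readLines(fa), ">")), 4L)
  ann <- read_annotation(gf)
  cds <- ann[S4Vectors::mcols(ann)$type == "CDS"]
  got <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(cds)),
    start = GenomicRanges::start(cds) - 1L,
    end = GenomicRanges::end(cds))
  want <- do.call(rbind, lapply(seq_len(nrow(tr$genes)), function(i)
    data.frame(scaffold = tr$genes$scaffold[i],
               start = tr$genes$exons[[i]][, 1],
               end = tr$genes$exons[[i]][, 2])))
  o1 <- order(got$scaffold, got$start); o2 <- order(want$scaffold, want$start)
  expect_equal(got[o1, ], want[o2, ], ignore_attr = TRUE)
  unlink(c(fa, gf))
})

test_that("fragmentation splits records and concatenation restores them", {
  cfg <- sim_config(seed = 6, ancestral_length = 10000, n_scaffolds = 2,
                    n_inversions = 0, n_translocations = 0, n_genes = 0)
  tr <- generate_truth(cfg)
  em <- emit_assembly(tr, fragmentation = list(A_01 = 2000L))
  expect_identical(length(em$seqs), 5L)  # one scaffold split in two
  expect_identical(paste0(em$seqs[["A_01.1"]], em$seqs[["A_01.2"]]),
                   tr$haplotype_a[["A_01"]])
})

test_that("scaffold identifier collisions are rejected", {
  cfg <- sim_config(seed = 6, ancestral_length = 10000, n_scaffolds = 2,
                    n_inversions = 0, n_translocations = 0, n_genes = 0)
  tr <- generate_truth(cfg)
  names(tr$haplotype_b)[1] <- names(tr$haplotype_a)[1]
  expect_error(emit_assembly(tr), "collision")
})

test_that("expression: deviant flags, folds and noiseless equality", {
  cfg <- sim_config(seed = 8, ancestral_length = 5200000, n_scaffolds = 2,
                    snv_rate_cds = 0, snv_rate_intron = 0,
                    snv_rate_intergenic = 0, indel_event_rate = 0,
                    n_inversions = 0, n_translocations = 0, n_genes = 1000,
                    deviant_pair_fraction = 0.05)
  tr <- generate_truth(cfg)
  ex <- simulate_expression(tr, noise = "none")
  tab <- ex$table
  a <- tab[tab$haplotype == "A", ]; b <- tab[tab$haplotype == "B", ]
  n <- nrow(a)
  expect_gte(n, 900)
  ## flagged-pair count within 3 binomial SD of the configured fraction
  flagged <- sum(a$deviant)
  expect_lt(abs(flagged - 0.05 * n), 3 * sqrt(n * 0.05 * 0.95))
  ## non-deviant pairs: equal counts without noise
  nd <- !a$deviant
  expect_identical(a$count[nd], b$count[nd])
  ## deviant pairs: expected-count ratio equals the planted fold
  dv <- a$deviant
  ratio <- pmax(a$expected[dv], b$expected[dv]) /
    pmin(a$expected[dv], b$expected[dv])
  expect_equal(ratio, a$deviant_fold[dv], tolerance = 1e-12)
})

small_truth <- function(seed, len = 10000, read_length = 100,
                        coverage = 1, error = 0) {
  cfg <- sim_config(seed = seed, ancestral_length = len, n_scaffolds = 1,
                    snv_rate_cds = 0, snv_rate_intron = 0,
                    snv_rate_intergenic = 0, indel_event_rate = 0,
                    n_inversions = 0, n_translocations = 0, n_genes = 0,
                    read_length = read_length,
                    coverage_per_haplotype = coverage,
                    read_error_rate = error)
  generate_truth(cfg)
}

test_that("read counts follow the coverage arithmetic", {
  tr <- small_truth(9)
  rd <- simulate_reads(tr)
  expect_identical(unname(rd$n_per_scaffold), c(100L, 100L))
  expect_identical(length(rd$reads), 200L)
})

test_that("error-free reads are exact substrings of a scaffold", {
  tr <- small_truth(9)
  rd <- simulate_reads(tr)
  src <- tr$haplotype_a[[1]]  # zero divergence: B is identical
  ok <- vapply(rd$reads, function(r)
    grepl(r, src, fixed = TRUE) || grepl(revcomp(r), src, fixed = TRUE),
    logical(1))
  expect_true(all(ok))
})

test_that("read error rate is realized within 3 binomial SD", {
  tr0 <- small_truth(10, coverage = 50, error = 0)
  tr1 <- small_truth(10, coverage = 50, error = 0.01)
  r0 <- simulate_reads(tr0)$reads
  r1 <- simulate_reads(tr1)$reads
  ## the first scaffold's reads share starts and orientations: the RNG
  ## consumes the error draws only after both are sampled
  n <- 5000L  # 5000 reads x 100 bp = 5e5 compared bases
  mm <- 0L
  for (i in seq_len(n))
    mm <- mm + sum(strsplit(r0[[i]], "")[[1]] != strsplit(r1[[i]], "")[[1]])
  bases <- 100 * n
  expect_lt(abs(mm / bases - 0.01), 3 * sqrt(0.01 * 0.99 / bases))
})

test_that("reads longer than a scaffold are skipped with a warning", {
  tr <- small_truth(12, len = 1000, read_length = 2000)
  w <- capture_warnings(rd <- simulate_reads(tr))
  expect_length(w, 2)  # one per haplotype scaffold
  expect_true(all(grepl("skipped", w)))
  expect_identical(length(rd$reads), 0L)
})

test_that("EST tags: family counts and error-free suffix structure", {
  cfg <- sim_config(seed = 13, ancestral_length = 10000, n_scaffolds = 2,
                    n_inversions = 0, n_translocations = 0, n_genes = 0,
                    est_families = 5, est_members_range = c(4, 4),
                    est_error_rate = 0, est_tag_length = 60)
  tr <- generate_truth(cfg)
  est <- simulate_est_tags(tr)
  expect_identical(length(est$tags), 20L)
  expect_identical(length(unique(est$truth$family_id)), 5L)
  for (f in unique(est$truth$family_id)) {
    mem <- est$tags[est$truth$tag_id[est$truth$family_id == f]]
    longest <- mem[[which.max(nchar(mem))]]
    expect_true(all(vapply(mem, function(m) endsWith(longest, m), logical(1))))
  }
})
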