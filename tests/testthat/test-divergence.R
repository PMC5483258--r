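rand_cds <- function(n_codons) rand_dna(3 * n_codons)

test_that("identical CDSs align gapless with full identity", {
  set.seed(501)
  a <- rand_cds(40)
  aln <- align_cds_pair(a, a)
  expect_false(grepl("-", aln$aligned_a, fixed = TRUE))
  expect_false(grepl("-", aln$aligned_b, fixed = TRUE))
  id <- identity_stats(aln)
  expect_equal(id$identity_overall_pct, 100)
  expect_equal(id$identity_pos3_pct, 100)
})

test_that("a deleted codon aligns as one codon-boundary gap", {
  set.seed(502)
  a <- rand_cds(8)
  b <- paste0(substr(a, 1, 12), substr(a, 16, 24))  # codon 5 removed
  aln <- align_cds_pair(a, b)
  expect_identical(nchar(aln$aligned_a), 24L)
  gaps <- gregexpr("-+", aln$aligned_b)[[1]]
  expect_identical(length(gaps), 1L)
  expect_identical(attr(gaps, "match.length"), 3L)
  expect_identical((gaps[1] - 1L) %% 3L, 0L)
  expect_equal(aln$score, oracle_codon_score(a, b))
})

test_that("an empty CDS aligns against pure codon gaps", {
  b <- "GGAATTCCC"
  aln <- align_cds_pair("", b)
  expect_identical(aln$aligned_a, "---------")
  expect_identical(aln$aligned_b, b)
  expect_identical(nrow(aln$codon_columns), 0L)
})

test_that("non-multiple-of-3 input is rejected", {
  expect_error(align_cds_pair("ACGTA", "ACG"), "multiple of 3")
})

test_that("alignment scores equal a brute-force codon DP on toys", {
  set.seed(503)
  for (i in 1:25) {
    a <- rand_cds(sample(0:10, 1))
    b <- if (nchar(a) >= 6 && runif(1) < 0.7) {
      drop <- 3 * (sample(nchar(a) / 3, 1) - 1)
      mutated <- paste0(substr(a, 1, drop), substr(a, drop + 4, nchar(a)))
      mutated
    } else rand_cds(sample(0:10, 1))
    aln <- align_cds_pair(a, b)
    expect_equal(aln$score, oracle_codon_score(a, b))
    expect_equal(codon_alignment_score(aln$aligned_a, aln$aligned_b),
                 aln$score)
  }
})

test_that("GGA vs GGG: overall 66.7, pos3 0, fourfold 0", {
  id <- identity_stats(align_cds_pair("GGA", "GGG"))
  expect_equal(id$identity_overall_pct, 200 / 3)
  expect_equal(id$identity_pos3_pct, 0)
  expect_equal(id$identity_fourfold_pct, 0)
  expect_identical(id$n_fourfold, 1L)
})

test_that("two-fold sites are excluded from the fourfold statistic", {
  ## columns {GGA/GGA, AAA/AAG}: AA* is 2-fold, so only GGA counts
  id <- identity_stats(align_cds_pair("GGAAAA", "GGAAAG"))
  expect_equal(id$identity_pos3_pct, 50)
  expect_equal(id$identity_fourfold_pct, 100)
  expect_identical(id$n_fourfold, 1L)
})

test_that("identical sequences give dN = dS = 0 and p = 1", {
  set.seed(504)
  a <- rand_cds(30)
  dn <- compute_dnds(align_cds_pair(a, a))
  expect_equal(dn$dN, 0)
  expect_equal(dn$dS, 0)
  expect_true(is.na(dn$dnds_ratio))
  expect_equal(dn$p_value, 1)
})

test_that("a purely synonymous change gives dN 0 and ratio 0", {
  ## two codons so the synonymous proportion stays inside the
  ## Jukes-Cantor domain (pS < 3/4)
  dn <- compute_dnds(align_cds_pair("GGAGGA", "GGCGGA"))
  expect_equal(dn$dN, 0)
  expect_gt(dn$dS, 0)
  expect_equal(dn$dnds_ratio, 0)
  expect_equal(dn$Sd, 1)
  expect_equal(dn$Nd, 0)
})

test_that("a saturated synonymous proportion yields dS NA", {
  ## single codon pair GGA/GGC: Sd = 1 on S = 1 site, pS = 1 >= 3/4,
  ## outside the Jukes-Cantor domain
  dn <- compute_dnds(align_cds_pair("GGA", "GGC"))
  expect_equal(dn$Sd, 1)
  expect_equal(dn$Nd, 0)
  expect_true(is.na(dn$dS))
  expect_true(dn$saturated)
})

test_that("NG86 site and path counts match the independent oracle", {
  set.seed(505)
  codons <- apply(expand.grid(DNA, DNA, DNA), 1, paste, collapse = "")
  for (cd in sample(codons, 20))
    expect_equal(diplopair:::ng86_syn_sites(cd), oracle_syn_sites(cd))
  for (i in 1:30) {
    ca <- sample(codons, 1); cb <- sample(codons, 1)
    expect_equal(diplopair:::ng86_path_counts(ca, cb),
                 oracle_path_counts(ca, cb))
  }
})

test_that("compute_dnds totals equal oracle sums on gapless toys", {
  set.seed(506)
  for (i in 1:10) {
    a <- rand_cds(5)
    b <- mutate_seq(a, sub = 0.2, indel = 0)  # keeps codon framing
    aln <- align_cds_pair(a, b)
    dn <- compute_dnds(aln)
    cc <- aln$codon_columns
    S_or <- (sum(vapply(cc$codon_a, oracle_syn_sites, numeric(1))) +
               sum(vapply(cc$codon_b, oracle_syn_sites, numeric(1)))) / 2
    cnt <- mapply(function(x, y) oracle_path_counts(x, y),
                  cc$codon_a, cc$codon_b)
    expect_equal(dn$S, S_or)
    expect_equal(dn$N, 3 * nrow(cc) - S_or)
    expect_equal(dn$Sd, sum(cnt["sd", ]))
    expect_equal(dn$Nd, sum(cnt["nd", ]))
  }
})

test_that("all statistics are symmetric in the two sequences", {
  set.seed(507)
  for (i in 1:5) {
    a <- rand_cds(40)
    b <- mutate_seq(a, sub = 0.06, indel = 0)
    id1 <- identity_stats(align_cds_pair(a, b))
    id2 <- identity_stats(align_cds_pair(b, a))
    expect_equal(id2$identity_overall_pct, id1$identity_overall_pct)
    expect_equal(id2$identity_pos3_pct, id1$identity_pos3_pct)
    expect_equal(id2$identity_fourfold_pct, id1$identity_fourfold_pct)
    d1 <- compute_dnds(align_cds_pair(a, b))
    d2 <- compute_dnds(align_cds_pair(b, a))
    expect_equal(d2$dN, d1$dN)
    expect_equal(d2$dS, d1$dS)
    expect_equal(d2$p_value, d1$p_value)
  }
})

test_that("identities are all 100 iff gapless columns are identical", {
  set.seed(508)
  a <- rand_cds(30)
  b <- mutate_seq(a, sub = 0.05, indel = 0)
  aln <- align_cds_pair(a, b)
  id <- identity_stats(aln)
  same <- all(aln$codon_columns$codon_a == aln$codon_columns$codon_b)
  all100 <- isTRUE(all.equal(id$identity_overall_pct, 100)) &&
    isTRUE(all.equal(id$identity_pos3_pct, 100)) &&
    (is.na(id$identity_fourfold_pct) ||
       isTRUE(all.equal(id$identity_fourfold_pct, 100)))
  expect_identical(same, all100)
})

test_that("a synonymous-dominated regime gives median dN/dS below 1", {
  set.seed(509)
  ## mutate third positions ten times more often than first/second
  mutate_pos3 <- function(a) {
    ch <- strsplit(a, "")[[1]]
    for (i in seq_along(ch)) {
      r <- if (i %% 3 == 0) 0.3 else 0.03
      if (runif(1) < r) ch[i] <- sample(setdiff(DNA, ch[i]), 1)
    }
    paste(ch, collapse = "")
  }
  ratios <- vapply(1:20, function(i) {
    a <- rand_cds(60)
    dn <- compute_dnds(align_cds_pair(a, mutate_pos3(a)))
    dn$dnds_ratio
  }, numeric(1))
  expect_lt(median(ratios, na.rm = TRUE), 1)
})

test_that("divergence_table reports one row per pair", {
  set.seed(510)
  cds <- c(g1 = rand_cds(30), g3 = rand_cds(25))
  cds <- c(cds, g2 = mutate_seq(cds[["g1"]], 0.04, 0),
           g4 = mutate_seq(cds[["g3"]], 0.04, 0))
  dt <- divergence_table(cds, data.frame(gene_a = c("g1", "g3"),
                                         gene_b = c("g2", "g4"),
                                         stringsAsFactors = FALSE))
  expect_identical(nrow(dt), 2L)
  expect_true(all(dt$identity_overall_pct > 80))
  expect_true(all(is.finite(dt$p_value)))
})
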