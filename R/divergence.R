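codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

## dinucleotide prefixes whose four codons encode one amino acid
fourfold_prefixes <- local({
  pref <- NULL
  function() {
    if (is.null(pref)) {
      gc <- codon_table()
      all_pref <- unique(substr(names(gc), 1, 2))
      pref <<- all_pref[vapply(all_pref, function(p) {
        aa <- gc[paste0(p, c("A", "C", "G", "T"))]
        length(unique(aa)) == 1
      }, logical(1))]
    }
    pref
  }
})

#' Codon-aware global alignment of two coding sequences
#'
#' Aligns two CDSs codon-by-codon (each codon is one alignment unit,
#' so gaps are always codon-sized and codon-boundary aligned), with a
#' codon-pair score of +1 per identical base and -1 per differing base
#' and affine codon-gap penalties.  Tie-breaking is deterministic:
#' diagonal first, then a gap in the first sequence.
#'
#' @param cds_a,cds_b coding sequences; lengths must be multiples of 3.
#' @return an object of class `codon_alignment` with gapped sequences
#'   `aligned_a`, `aligned_b`, the alignment `score`, and
#'   `codon_columns` (a data.frame of the gapless codon pairs).
#' @export
align_cds_pair <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) %% 3 || nchar(cds_b) %% 3)
    stop("CDS length must be a multiple of 3")
  r <- cpp_codon_align(cds_a, cds_b)
  n_col <- nchar(r$aligned_a) / 3
  ca <- substring(r$aligned_a, 3 * seq_len(n_col) - 2, 3 * seq_len(n_col))
  cb <- substring(r$aligned_b, 3 * seq_len(n_col) - 2, 3 * seq_len(n_col))
  gapless <- ca != "---" & cb != "---"
  structure(list(aligned_a = r$aligned_a, aligned_b = r$aligned_b,
                 score = r$score,
                 codon_columns = data.frame(codon_a = ca[gapless],
                                            codon_b = cb[gapless],
                                            stringsAsFactors = FALSE)),
            class = "codon_alignment")
}

#' Identity statistics of a codon alignment
#'
#' Overall identity over ungapped base columns, identity restricted to
#' third codon positions, and identity at 4-fold degenerate sites
#' (third positions of gapless codon columns where both codons share
#' an identical first two bases belonging to a 4-fold degenerate
#' family of the standard genetic code).
#'
#' @param alignment a [align_cds_pair()] result.
#' @return list with `identity_overall_pct`, `identity_pos3_pct`,
#'   `identity_fourfold_pct` (NA when a denominator is empty) and the
#'   underlying counts.
#' @export
identity_stats <- function(alignment) {
  cc <- alignment$codon_columns
  if (nrow(cc) == 0)
    return(list(identity_overall_pct = NA_real_,
                identity_pos3_pct = NA_real_,
                identity_fourfold_pct = NA_real_,
                n_columns = 0L, n_fourfold = 0L))
  a <- cc$codon_a; b <- cc$codon_b
  m1 <- substr(a, 1, 1) == substr(b, 1, 1)
  m2 <- substr(a, 2, 2) == substr(b, 2, 2)
  m3 <- substr(a, 3, 3) == substr(b, 3, 3)
  overall <- 100 * sum(m1 + m2 + m3) / (3 * nrow(cc))
  pos3 <- 100 * mean(m3)
  pa <- substr(a, 1, 2); pb <- substr(b, 1, 2)
  ff <- pa == pb & pa %in% fourfold_prefixes()
  fourfold <- if (any(ff)) 100 * mean(m3[ff]) else NA_real_
  list(identity_overall_pct = overall, identity_pos3_pct = pos3,
       identity_fourfold_pct = fourfold,
       n_columns = nrow(cc), n_fourfold = sum(ff))
}

## Synonymous site count of one codon (NG86): over the three positions,
## the fraction of the three possible changes that preserve the amino
## acid, summed.  Stop codons are treated like any other translation.
ng86_syn_sites <- function(codon) {
  gc <- codon_table()
  aa <- gc[[codon]]
  s <- 0
  for (p in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- alt
      if (gc[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

## Average synonymous/nonsynonymous substitution counts between two
## codons over all minimal mutation paths (orderings of the differing
## positions), NG86 style.
ng86_path_counts <- function(ca, cb) {
  gc <- codon_table()
  d <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  nd <- length(d)
  if (nd == 0) return(c(sd = 0, nd = 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  tot_s <- 0; tot_n <- 0
  paths <- perms(d)
  for (path in paths) {
    cur <- ca
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (gc[[cur]] == gc[[nxt]]) tot_s <- tot_s + 1 else tot_n <- tot_n + 1
      cur <- nxt
    }
  }
  c(sd = tot_s / length(paths), nd = tot_n / length(paths))
}

jukes_cantor <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Counting-method dN/dS of a codon alignment
#'
#' Nei-Gojobori (1986) counting over the gapless codon columns:
#' synonymous and nonsynonymous site counts are averaged over the two
#' sequences; substitutions between differing codons are classified
#' along minimal mutation paths, averaged over all equally parsimonious
#' orderings; proportions are Jukes-Cantor corrected.  Significance is
#' a two-sided Fisher exact test on the rounded 2x2 table of
#' (synonymous, nonsynonymous) x (substituted, unsubstituted) site
#' counts.
#'
#' @param alignment a [align_cds_pair()] result.
#' @return list with `dN`, `dS`, `dnds_ratio` (NA when dS is 0 or a
#'   correction is undefined), `p_value`, the raw counts (`S`, `N`,
#'   `Sd`, `Nd`, `pS`, `pN`) and a `saturated` flag set when a
#'   proportion reaches the Jukes-Cantor limit of 0.75.
#' @export
compute_dnds <- function(alignment) {
  cc <- alignment$codon_columns
  valid <- grepl("^[ACGT]{3}$", cc$codon_a) & grepl("^[ACGT]{3}$", cc$codon_b)
  cc <- cc[valid, , drop = FALSE]
  if (nrow(cc) == 0)
    return(list(dN = NA_real_, dS = NA_real_, dnds_ratio = NA_real_,
                p_value = NA_real_, S = 0, N = 0, Sd = 0, Nd = 0,
                pS = NA_real_, pN = NA_real_, saturated = FALSE))
  syn_a <- vapply(cc$codon_a, ng86_syn_sites, numeric(1))
  syn_b <- vapply(cc$codon_b, ng86_syn_sites, numeric(1))
  S <- (sum(syn_a) + sum(syn_b)) / 2
  N <- 3 * nrow(cc) - S
  counts <- mapply(function(a, b) ng86_path_counts(a, b),
                   cc$codon_a, cc$codon_b)
  Sd <- sum(counts["sd", ]); Nd <- sum(counts["nd", ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jukes_cantor(pS); dN <- jukes_cantor(pN)
  saturated <- (!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)
  ratio <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  tab <- matrix(round(c(Sd, S - Sd, Nd, N - Nd)), nrow = 2, byrow = TRUE)
  tab[tab < 0] <- 0
  p <- stats::fisher.test(tab)$p.value
  list(dN = dN, dS = dS, dnds_ratio = ratio, p_value = p,
       S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       saturated = saturated)
}

#' Divergence statistics for a set of CDS pairs
#'
#' @param cds named character vector of coding sequences.
#' @param pairs data.frame with columns `gene_a`, `gene_b` naming
#'   entries of `cds`.
#' @return data.frame with one row per pair: identities, dN, dS,
#'   dN/dS and Fisher p-value.
#' @export
divergence_table <- function(cds, pairs) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    aln <- align_cds_pair(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]])
    id <- identity_stats(aln)
    dn <- compute_dnds(aln)
    data.frame(gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
               identity_overall_pct = id$identity_overall_pct,
               identity_pos3_pct = id$identity_pos3_pct,
               identity_fourfold_pct = id$identity_fourfold_pct,
               dN = dn$dN, dS = dn$dS, dnds_ratio = dn$dnds_ratio,
               p_value = dn$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
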