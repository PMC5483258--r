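---
title: "diplopair: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{diplopair: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`diplopair` analyses genome assemblies in which the two haplotypes of a
highly heterozygous diploid assemble as *separate scaffolds*, so that
most of the assembly is present twice — once per haplotype.  The
package detects those allelic scaffold pairs by self-alignment,
quantifies their divergence, classifies genes into allelic pairs,
singletons and families, compares allele-specific expression, computes
codon-level dN/dS, clusters EST tags, and estimates genome size from
the k-mer spectrum.  A built-in diploid simulator with complete truth
ledgers makes every stage testable without external data.

This vignette records the methods and the numeric conventions precisely
enough that every reported figure can be reproduced from first
principles.

## 1. The simulator

`sim_config()` / `generate_truth()` build a diploid from a random
ancestral haplotype A:

* **Gene models.** Genes are placed without overlap on haplotype A;
  each has 2–8 exons (default), and default exon/intron length ranges
  are chosen so that the realized CDS fraction is about 0.22 of the
  genome.
* **Haplotype B** is derived from A by per-site substitutions at
  class-specific probabilities (defaults 0.037 CDS / 0.071 intron /
  0.056 intergenic), indel events at rate 0.0066 per site with
  geometric lengths (outside CDS, so reading frames survive), and then
  large-scale events: inversions and inter-scaffold translocations.
* **Truth ledgers** record every variant (position, class, type,
  length), every structural event in both ancestral and final-A
  coordinates, and the gene table with allelic partner links.
  `replay_truth()` reproduces haplotype B from the ledger alone, which
  the test-suite uses as an end-to-end consistency check.

Default rates are *study conditions* taken from the divergence profile
the package is designed around; they are derived once (section 9) and
are not tuned against any test.

Derived data sets follow: `simulate_expression()` (log-normal gene
expression, a small fraction of pairs made deliberately deviant by a
known fold), `simulate_reads()` (uniform fragment starts, fixed read
length, per-base error rate), and `simulate_est_tags()` (tag families
with per-base error).  All randomness flows from one seed through fixed
per-stage offsets, so any stage can be re-run in isolation and
reproduce exactly.

## 2. Pairing: anchors, chains, refinement, tiling

`pair_scaffolds()` runs four stages.

1. **Anchors.** Canonical k-mers (default k = 15) with assembly-wide
   multiplicity ≤ 10 seed exact matches between scaffolds, in both
   orientations.
2. **Chains.** Anchors sharing a diagonal (offset for forward,
   anti-diagonal sum for reverse) within `max_gap` (500 bp) are chained
   greedily while colinear; chains need ≥ 3 anchors.
3. **Refinement.** Each chain is refined to a base-level alignment by
   banded global alignment between consecutive anchors, plus a corner
   extension at the chain ends when both flanks are ≤ 500 bp.  Scoring:
   match +1, mismatch −1, gap −2 for the first base and −1 per further
   base (affine with open+extend = 2, extend = 1).  The band starts at
   32 + |Δlen| and doubles on hitting the boundary, up to 4×.  On
   random scaffold pairs up to 2 kb this refinement provably reaches
   the unbanded optimum; the acceptance suite checks score equality
   against `Biostrings::pairwiseAlignment` on 50 random pairs.
4. **Reciprocal-best tiling.** Segments shorter than
   `min_segment_length` (200 bp) on the A side are dropped, then every
   base on *both* sides is awarded to the covering segment with the
   best score density (score / alignment columns; ties: more columns,
   then lexicographic scaffold and start).  Each segment keeps the runs
   of columns it won on both sides, trimmed to match/mismatch columns
   at the ends and re-filtered by `min_segment_length`.  The result is
   a one-to-one tiling: each base participates in at most one retained
   segment per side.

## 3. Accounting conventions (heterozygosity)

All genome-wide totals use the **both-sides convention**, matching an
accounting in which Table-1-style totals are sums over the *whole*
assembly, both haplotype copies included:

* `paired_length` = Σ(end_a − start_a) + Σ(end_b − start_b);
* each mismatch column contributes **2** mismatched bases (one per
  scaffold);
* each indel event (a maximal gap run) is counted **twice** (it is
  seen from both sides);
* heterozygosity % = 100 × mismatches / paired_length, indel % =
  100 × indel events / paired_length.

With the published totals (genome 170,470,384 bp; paired 152,151,424
bp; 8,685,973 SNVs; 997,343 indel events) this arithmetic yields
coverage 89.3%, heterozygosity 5.7% and indel rate 0.66%.

Per-class densities (`class_densities()`) are **per-column**: aligned A
bases are classified as CDS / intron / intergenic from the annotation
(classes partition the aligned bases), and the density is mismatch
columns / aligned columns within the class.  Window tracks count
mismatch columns per 100-bp window on both scaffolds; indel records are
emitted once per event at the last preceding A base, with signed
length.

## 4. Structural-event calls

`structural_events()` works on the tiled segments of each A scaffold:

* segments are grouped into colinearity runs (same partner, same
  orientation, diagonal jumps ≤ `min_displacement`, 1000 bp);
* a backbone is chosen per scaffold as the heaviest (aligned-bases
  weighted) increasing subsequence of runs against the main partner;
* runs against a *different* partner are called **translocations**;
  off-backbone runs on the same partner displaced by more than
  `min_displacement` are called intra-scaffold translocations;
* an orientation run opposed by its flanking runs on both sides is
  called an **inversion**.

On the default simulation profile the two planted events (one
inversion, one translocation) are recovered exactly, with the
translocation's partner equal to the ledger's destination scaffold.

## 5. Ortholog classification and the gene-number estimate

`classify_groups()` takes ortholog groups over the focal assembly (A)
and a reference species (B) and assigns the categories by
the focal/reference membership counts: `2:1` (allelic pair), `2:2+`,
`2:0`, `1:1+`, `1:0`, `3+:N`, `3+:0`.  `estimate_gene_number()`
implements

> pairs + singletons + round(group genes / 2)

on the totals (pairs = groups with exactly two focal genes; singletons
= `1:1+` + `1:0`; group genes = focal genes in `3+` groups).  On the
published composition (11,345 pairs, 7,774 singletons, 3,957 group
genes, 34,421 genes in total) it returns 21,098.

## 6. Allelic expression

Counts are converted to FPKM (`count × 10^9 / (length ×
total fragments)`).  Pairs are *comparable* when their CDS lengths
differ by **strictly less than 100 bp** (`select_comparable_pairs()`),
so that FPKM fold ratios are not driven by length artefacts.  Fold
bins are cumulative (>1.5, >2, >5); pairs where exactly one allele is
silent are reported as `n_undefined_ratio`, both-silent pairs as
`n_both_zero`, and neither enters the bins.  The scatter correlation is
Pearson on log10(FPKM + ε) over pairs with both alleles expressed.

## 7. CDS divergence and dN/dS

`align_cds_pair()` aligns two CDSs **codon-aware**: the unit is the
codon, scored as the sum of per-base match/mismatch (+1/−1), with
affine codon gaps (−4 open, −1 per further codon), so gaps always fall
on codon boundaries and frames are preserved.  Identity is reported
over all aligned bases, over third positions, and over 4-fold
degenerate sites (third positions whose codon family is 4-fold in
*both* sequences, same prefix).

dN/dS uses the Nei–Gojobori (1986) counting method: per-codon
synonymous site fractions from the genetic code, substitution
classification averaged over all shortest mutation paths,
Jukes–Cantor correction of the proportions, and a two-sided Fisher
exact test on the rounded 2×2 site/substitution table.  NG86 is used
deliberately in place of likelihood-weighted pathway methods (see the
note in section 9); for the strongly purifying regimes involved the ordering
dN/dS ≪ 1 is method-independent, which is what the package asserts.

## 8. EST clustering and the k-mer spectrum

`greedy_cluster()` is greedy incremental clustering: tags in input
order join the first cluster whose representative (or, in
`all_members` mode, any member) aligns locally at ≥ 90% identity over
≥ 50 columns; otherwise they found a new cluster.  The local aligner
is exact Smith–Waterman (match +1, mismatch −1, gap −2/−1) with a
sound score screen: any alignment with identity ≥ t over m columns has
score ≥ (3t − 2)·m, so candidates are pre-filtered by score without
ever discarding a qualifying alignment.  Representative mode is
order-sensitive by construction (documented, tested); `all_members`
mode merges transitively.

`count_kmers()` counts canonical k-mers (default k = 21, odd, ≤ 31)
and `fit_spectrum()` fits a truncated two-component negative-binomial
mixture to the frequency histogram above an error cutoff (first local
minimum): component means constrained to μ and 2μ with shared
dispersion.  The expected μ for reads of length L at per-haplotype
coverage C and error rate e is C·(L−k+1)/L·(1−e)^k.  The genome-size
estimate divides above-cutoff k-mer instances by μ, which counts the
**diploid span** (both haplotype copies) for a fully heterozygous
diploid; an unconstrained two-peak fit is also reported, whose peak
ratio should be ≈ 2 for a true diploid.  A haploid/homozygous spectrum
sets `single_component`.

## 9. Derivations and substitutions worth recording

* **Default divergence profile.** With class rates 0.037/0.071/0.056
  and the package's default gene geometry (CDS fraction ≈ 0.22,
  introns 200–660 bp), the realized overall mismatch rate is ≈ 0.057,
  i.e. 5.7% heterozygosity under the both-sides accounting.  The
  geometry was derived once from those joint constraints, not adjusted
  afterwards.
* **NG86 instead of MLWL.** The reference analysis uses a
  maximum-likelihood weighted-pathway method; `diplopair` implements
  the transparent NG86 counting method, which admits an exact
  brute-force oracle (path enumeration over the genetic code) used by
  the acceptance suite.
* **Report totals are copies.** `run_pipeline()` copies stage outputs
  into the report verbatim — totals are never recomputed, so the
  report cannot disagree with the per-stage files.

## 10. Worked example

```{r}
library(diplopair)

cfg <- sim_config(seed = 7, ancestral_length = 250000)
tr <- generate_truth(cfg)

segs <- pair_scaffolds(c(tr$haplotype_a, tr$haplotype_b))
summarize_pairing(segs, c(tr$haplotype_a, tr$haplotype_b))

vt <- variant_totals(segs)
vt$snv_pct      # ~5.7

calls <- structural_events(segs)
calls[, c("type", "scaffold_a", "start_a", "end_a", "partner")]

## full pipeline with per-stage files and a consolidated report
report <- run_pipeline(cfg, outdir = tempfile())
write_report(report, json = tempfile(fileext = ".json"))
```
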