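stage_seed <- function(seed, stage) {
  offs <- c(truth = 0L, expression = 1013L, reads = 2027L, est = 3041L,
            pipeline = 4057L)
  s <- as.integer(seed) + offs[[stage]]
  s %% .Machine$integer.max
}

#' Convert truth gene models to a GFF3-style GRanges
#'
#' Produces gene/mRNA/exon/CDS features (1-based inclusive coordinates)
#' with ID/Parent links, suitable for [rtracklayer::export()].
#'
#' @param genes the `genes` table of a [generate_truth()] result.
#' @return a [GenomicRanges::GRanges] object.
#' @export
genes_to_granges <- function(genes) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    id <- g$gene_id
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = g$scaffold, start = g$start + 1L, end = g$end,
      strand = g$strand, type = c("gene", "mRNA"),
      ID = c(id, paste0(id, ".t1")),
      Parent = c(NA_character_, id), phase = NA_integer_,
      stringsAsFactors = FALSE)
    nE <- nrow(ex)
    lens <- ex[, 2] - ex[, 1]
    cds_phase <- (3L - cumsum(c(0L, lens[-nE])) %% 3L) %% 3L
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = g$scaffold, start = rep(ex[, 1] + 1L, 2),
      end = rep(ex[, 2], 2), strand = g$strand,
      type = rep(c("exon", "CDS"), each = nE),
      ID = c(paste0(id, ".exon", seq_len(nE)), paste0(id, ".cds", seq_len(nE))),
      Parent = rep(paste0(id, ".t1"), 2 * nE),
      phase = c(rep(NA_integer_, nE), cds_phase), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(GenomicRanges::GRanges())
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqnames,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$phase <- df$phase
  gr
}

#' Emit the simulated assembly as FASTA and GFF3
#'
#' Writes one FASTA containing both haplotypes' scaffolds (optionally
#' fragmented at supplied breakpoints) and a GFF3 of the gene models on
#' both haplotypes.
#'
#' @param truth a [generate_truth()] result.
#' @param fasta,gff3 output paths (either may be `NULL` to skip).
#' @param fragmentation optional named list of integer breakpoint
#'   vectors (0-based positions) per scaffold; fragments are named
#'   `<scaffold>.1`, `<scaffold>.2`, ...  Genes not fully contained in
#'   a single fragment are dropped with a warning.
#' @return invisibly, a list with the emitted `seqs` (named character
#'   vector) and `annotation` (GRanges).
#' @export
emit_assembly <- function(truth, fasta = NULL, gff3 = NULL,
                          fragmentation = NULL) {
  seqs <- c(truth$haplotype_a, truth$haplotype_b)
  genes <- truth$genes
  if (!is.null(fragmentation)) {
    out <- character(0)
    keep_rows <- list()
    for (nm in names(seqs)) {
      bp <- sort(unique(fragmentation[[nm]] %||% integer(0)))
      bp <- bp[bp > 0 & bp < nchar(seqs[[nm]])]
      bounds <- c(0L, bp, nchar(seqs[[nm]]))
      if (length(bp) == 0) {
        out[nm] <- seqs[[nm]]
        gi <- which(genes$scaffold == nm)
        if (length(gi)) keep_rows[[nm]] <- genes[gi, ]
        next
      }
      for (f in seq_len(length(bounds) - 1L)) {
        fn <- sprintf("%s.%d", nm, f)
        out[fn] <- substr(seqs[[nm]], bounds[f] + 1L, bounds[f + 1L])
        gi <- which(genes$scaffold == nm & genes$start >= bounds[f] &
                      genes$end <= bounds[f + 1L])
        if (length(gi)) {
          gg <- genes[gi, ]
          gg$scaffold <- fn
          gg$start <- gg$start - bounds[f]
          gg$end <- gg$end - bounds[f]
          gg$exons <- lapply(gg$exons, function(e) e - bounds[f])
          keep_rows[[fn]] <- gg
        }
      }
      n_lost <- sum(genes$scaffold == nm) -
        sum(vapply(keep_rows[paste0(nm, ".", seq_len(length(bounds) - 1L))],
                   function(x) if (is.null(x)) 0L else nrow(x), integer(1)),
            na.rm = TRUE)
      if (n_lost > 0)
        warning(n_lost, " gene(s) on ", nm, " span a breakpoint; dropped")
    }
    seqs <- out
    genes <- if (length(keep_rows)) do.call(rbind, keep_rows) else genes[0, ]
    rownames(genes) <- NULL
  }
  if (anyDuplicated(names(seqs)))
    stop("scaffold identifier collision in emitted assembly")
  ann <- genes_to_granges(genes)
  if (!is.null(fasta)) write_fasta(seqs, fasta)
  if (!is.null(gff3)) rtracklayer::export(ann, gff3, format = "gff3")
  invisible(list(seqs = seqs, annotation = ann, genes = genes))
}

#' Read a GFF3 annotation
#'
#' @param path GFF3 file.
#' @return a [GenomicRanges::GRanges] with a `type` metadata column.
#' @export
read_annotation <- function(path) {
  rtracklayer::import(path, format = "gff3")
}

exon_length <- function(ex) sum(ex[, 2] - ex[, 1])

#' Extract spliced CDS sequences for truth genes
#'
#' Concatenates exon sequences in genomic order and reverse-complements
#' minus-strand genes.
#'
#' @param truth a [generate_truth()] result.
#' @param gene_ids gene identifiers (default: all genes).
#' @return named character vector of CDS sequences.
#' @export
gene_cds_sequences <- function(truth, gene_ids = truth$genes$gene_id) {
  seqs <- c(truth$haplotype_a, truth$haplotype_b)
  idx <- match(gene_ids, truth$genes$gene_id)
  if (anyNA(idx)) stop("unknown gene id(s)")
  out <- vapply(idx, function(i) {
    g <- truth$genes[i, ]
    ex <- g$exons[[1]]
    s <- paste(vapply(seq_len(nrow(ex)), function(r)
      substr(seqs[[g$scaffold]], ex[r, 1] + 1L, ex[r, 2]), character(1)),
      collapse = "")
    if (g$strand == "-") revcomp(s) else s
  }, character(1))
  setNames(out, gene_ids)
}

#' Simulate allelic expression fragment counts
#'
#' Each allelic gene pair shares a log-normal expected fragment count;
#' a configured fraction of pairs is deviant, with one randomly chosen
#' allele's expectation multiplied by a fold drawn from the configured
#' range.  Observed counts are Poisson around the expectation (or the
#' rounded expectation when `noise = "none"`).
#'
#' @param truth a [generate_truth()] result.
#' @param config a [sim_config()]; defaults to the truth's own.
#' @param noise `"poisson"` or `"none"`.
#' @return list with `table` (per-gene records: gene_id, pair_id,
#'   cds_length, expected, count, deviant flag, deviant fold) and
#'   `total_fragments`.
#' @export
simulate_expression <- function(truth, config = truth$config,
                                noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  genes <- truth$genes
  gA <- genes[genes$haplotype == "A", , drop = FALSE]
  with_rng(stage_seed(config$seed, "expression"), {
    n_pair <- nrow(gA)
    base <- rlnorm(n_pair, config$expression_log_mean,
                   config$expression_log_sd)
    deviant <- runif(n_pair) < config$deviant_pair_fraction
    fold <- ifelse(deviant,
                   runif(n_pair, config$deviant_fold_range[1],
                         config$deviant_fold_range[2]), 1)
    up_b <- sample(c(TRUE, FALSE), n_pair, replace = TRUE)
    exp_a <- base * ifelse(deviant & !up_b, fold, 1)
    exp_b <- base * ifelse(deviant & up_b, fold, 1)
    tab <- data.frame(
      gene_id = c(gA$gene_id, gA$partner),
      pair_id = rep(sprintf("pair_%04d", seq_len(n_pair)), 2),
      haplotype = rep(c("A", "B"), each = n_pair),
      cds_length = c(vapply(gA$exons, exon_length, numeric(1)),
                     vapply(genes$exons[match(gA$partner, genes$gene_id)],
                            exon_length, numeric(1))),
      expected = c(exp_a, exp_b),
      deviant = rep(deviant, 2),
      deviant_fold = rep(fold, 2),
      stringsAsFactors = FALSE)
    tab$count <- if (noise == "poisson") rpois(nrow(tab), tab$expected)
                 else round(tab$expected)
    list(table = tab, total_fragments = sum(tab$count))
  })
}

#' Simulate uniform-coverage shotgun reads from both haplotypes
#'
#' Draws reads uniformly from every scaffold of both haplotypes at
#' `coverage_per_haplotype` each (so the diploid is sampled at twice
#' that depth relative to a haploid span), applies a per-base error
#' rate, and reverse-complements half the reads.
#'
#' @param truth a [generate_truth()] result.
#' @param config a [sim_config()]; defaults to the truth's own.
#' @return list with `reads` (named character vector) and
#'   `n_per_scaffold`.
#' @export
simulate_reads <- function(truth, config = truth$config) {
  seqs <- c(truth$haplotype_a, truth$haplotype_b)
  rl <- config$read_length
  with_rng(stage_seed(config$seed, "reads"), {
    all_reads <- list()
    n_per <- integer(0)
    for (nm in names(seqs)) {
      len <- nchar(seqs[[nm]])
      if (rl > len) {
        warning("read length exceeds scaffold ", nm, "; skipped")
        n_per[nm] <- 0L
        next
      }
      n <- as.integer(round(config$coverage_per_haplotype * len / rl))
      n_per[nm] <- n
      if (n == 0) next
      starts <- sample(len - rl + 1L, n, replace = TRUE)
      rd <- substring(seqs[[nm]], starts, starts + rl - 1L)
      flip <- runif(n) < 0.5
      if (any(flip))
        rd[flip] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(rd[flip])))
      if (config$read_error_rate > 0) {
        n_err <- rbinom(n, rl, config$read_error_rate)
        for (i in which(n_err > 0)) {
          pos <- sample(rl, n_err[i])
          ch <- strsplit(rd[i], "")[[1]]
          ch[pos] <- BASES[(match(ch[pos], BASES) - 1L +
                              sample(1:3, n_err[i], replace = TRUE)) %% 4L + 1L]
          rd[i] <- paste(ch, collapse = "")
        }
      }
      all_reads[[nm]] <- rd
    }
    reads <- unlist(all_reads, use.names = FALSE) %||% character(0)
    if (length(reads))
      names(reads) <- sprintf("read_%07d", seq_along(reads))
    list(reads = reads, n_per_scaffold = n_per)
  })
}

#' Simulate families of 3'-EST tags
#'
#' Each family has one source 3' region (the 3' end of a gene CDS when
#' gene models exist, otherwise a random sequence); members are copies
#' with a per-base error rate and a random 5' length jitter, emulating
#' single-pass EST sequencing of clones from the same transcript.
#'
#' @param truth a [generate_truth()] result.
#' @param config a [sim_config()]; defaults to the truth's own.
#' @return list with `tags` (named character vector) and `truth`
#'   (data.frame tag_id, family_id).
#' @export
simulate_est_tags <- function(truth, config = truth$config) {
  if (config$est_families < 1) stop("est_families must be >= 1")
  with_rng(stage_seed(config$seed, "est"), {
    n_fam <- config$est_families
    tl <- config$est_tag_length
    genesA <- truth$genes[truth$genes$haplotype == "A", , drop = FALSE]
    sources <- character(n_fam)
    if (nrow(genesA) >= n_fam) {
      pick <- sample(nrow(genesA), n_fam)
      cds <- gene_cds_sequences(truth, genesA$gene_id[pick])
      sources <- vapply(cds, function(s)
        substr(s, max(1L, nchar(s) - tl + 1L), nchar(s)), character(1))
    } else {
      sources <- vapply(seq_len(n_fam), function(i) random_dna(tl),
                        character(1))
    }
    tags <- character(0); fam <- character(0)
    for (f in seq_len(n_fam)) {
      mem_choices <- seq.int(config$est_members_range[1],
                             config$est_members_range[2])
      n_mem <- mem_choices[sample.int(length(mem_choices), 1)]
      for (m in seq_len(n_mem)) {
        s <- sources[f]
        jit_choices <- 0:max(0L, as.integer(round(0.1 * nchar(s))))
        jit <- jit_choices[sample.int(length(jit_choices), 1)]
        s <- substr(s, jit + 1L, nchar(s))
        if (config$est_error_rate > 0) {
          ch <- strsplit(s, "")[[1]]
          hit <- which(runif(length(ch)) < config$est_error_rate)
          if (length(hit))
            ch[hit] <- BASES[(match(ch[hit], BASES) - 1L +
                                sample(1:3, length(hit), replace = TRUE)) %%
                               4L + 1L]
          s <- paste(ch, collapse = "")
        }
        tags <- c(tags, s)
        fam <- c(fam, sprintf("family_%03d", f))
      }
    }
    names(tags) <- sprintf("tag_%05d", seq_along(tags))
    list(tags = tags,
         truth = data.frame(tag_id = names(tags), family_id = fam,
                            stringsAsFactors = FALSE))
  })
}
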