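#' Simulation configuration for a synthetic hyper-heterozygous diploid
#'
#' Builds a validated configuration for [generate_truth()].  The
#' defaults describe a diverged parthenogenetic-style diploid: two
#' haplotypes separated by class-specific substitution densities
#' (CDS 3.7\%, intron 7.1\%, intergenic 5.6\%, overall about 5.7\%),
#' short indel events at 0.66\% per bp, one inversion and one
#' translocation, allelic gene pairs that mostly share expression
#' levels apart from a small deviant fraction with a 2--10-fold
#' difference, uniform-coverage sequencing reads, and families of
#' 3'-EST tags.
#'
#' @param seed integer seed driving every random choice.
#' @param ancestral_length total length (bp) of the ancestral haplotype.
#' @param n_scaffolds number of scaffolds the haplotype is split into.
#' @param snv_rate_cds,snv_rate_intron,snv_rate_intergenic per-base
#'   substitution probabilities by annotation class.
#' @param indel_event_rate per-base probability of an indel event
#'   (events are placed outside coding sequence so both haplotypes keep
#'   codon-clean gene models).
#' @param indel_geom_prob geometric length parameter for indel events.
#' @param indel_max_length maximum indel length (bp).
#' @param n_inversions,n_translocations number of structural events
#'   planted on haplotype B.
#' @param inversion_size_range,translocation_size_range event size
#'   ranges (bp).
#' @param n_genes target number of gene models on haplotype A.
#' @param exons_per_gene_range integer range of exons per gene.
#' @param cds_fraction target fraction of the genome covered by CDS,
#'   used to size intergenic spacers.
#' @param expression_log_mean,expression_log_sd log-normal parameters
#'   of the shared expected fragment count of a gene pair.
#' @param deviant_pair_fraction fraction of pairs in which one allele's
#'   expression is multiplied by a deviant fold.
#' @param deviant_fold_range range the deviant fold is drawn from.
#' @param read_length,coverage_per_haplotype,read_error_rate read
#'   simulation parameters.
#' @param est_tag_length,est_error_rate,est_families,est_members_range
#'   3'-EST tag simulation parameters.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       ancestral_length = 500000L,
                       n_scaffolds = 2L,
                       snv_rate_cds = 0.037,
                       snv_rate_intron = 0.071,
                       snv_rate_intergenic = 0.056,
                       indel_event_rate = 0.0066,
                       indel_geom_prob = 0.4,
                       indel_max_length = 50L,
                       n_inversions = 1L,
                       n_translocations = 1L,
                       inversion_size_range = c(5000L, 20000L),
                       translocation_size_range = c(2000L, 10000L),
                       n_genes = 120L,
                       exons_per_gene_range = c(2L, 8L),
                       cds_fraction = 0.22,
                       expression_log_mean = 5,
                       expression_log_sd = 1,
                       deviant_pair_fraction = 121 / 7306,
                       deviant_fold_range = c(2, 10),
                       read_length = 100L,
                       coverage_per_haplotype = 30,
                       read_error_rate = 0.005,
                       est_tag_length = 300L,
                       est_error_rate = 0.02,
                       est_families = 50L,
                       est_members_range = c(2L, 8L)) {
  cfg <- as.list(environment())
  rates <- c(snv_rate_cds, snv_rate_intron, snv_rate_intergenic,
             indel_event_rate, read_error_rate, est_error_rate,
             deviant_pair_fraction, cds_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (ancestral_length < 1000) stop("ancestral_length too small")
  max_ev <- max(c(if (n_inversions > 0) inversion_size_range[2] else 0,
                  if (n_translocations > 0) translocation_size_range[2] else 0))
  if (max_ev > 0 && ancestral_length < 10 * max_ev)
    stop("ancestral_length must be at least 10x the largest structural event")
  if (n_translocations > 0 && n_scaffolds < 2)
    stop("translocations require at least 2 scaffolds")
  if (diff(exons_per_gene_range) < 0 || exons_per_gene_range[1] < 1)
    stop("bad exons_per_gene_range")
  structure(cfg, class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

## class codes used throughout: 0 intergenic, 1 intron, 2 CDS
CLASS_LEVELS <- c("intergenic", "intron", "CDS")

class_map_from_genes <- function(genes, seq_lengths) {
  maps <- lapply(seq_lengths, function(n) integer(n))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    m <- maps[[g$scaffold]]
    m[(g$start + 1):g$end] <- pmax(m[(g$start + 1):g$end], 1L)
    ex <- g$exons[[1]]
    for (r in seq_len(nrow(ex)))
      m[(ex[r, 1] + 1):ex[r, 2]] <- 2L
    maps[[g$scaffold]] <- m
  }
  maps
}

layout_genes_scaffold <- function(scaf_len, n_target, cfg) {
  exons <- list(); starts <- integer(0); ends <- integer(0)
  strands <- character(0)
  pos <- 0L
  while (length(starts) < n_target) {
    n_ex <- sample(seq(cfg$exons_per_gene_range[1],
                       cfg$exons_per_gene_range[2]), 1)
    ex_len <- 3L * sample(34:99, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) sample(200:660, n_ex - 1, replace = TRUE)
              else integer(0)
    gene_len <- sum(ex_len) + sum(in_len)
    s_target <- max(200, round(sum(ex_len) * (1 / cfg$cds_fraction - 1)) -
                      sum(in_len))
    spacer <- round(runif(1, 0.5, 1.5) * s_target)
    start <- pos + spacer
    end <- start + gene_len
    if (end > scaf_len - 200L) break
    offs <- cumsum(c(0L, head(ex_len + c(in_len, 0L), -1)))
    ex <- cbind(start + offs, start + offs + ex_len)
    exons[[length(exons) + 1L]] <- ex
    starts <- c(starts, start); ends <- c(ends, end)
    strands <- c(strands, sample(c("+", "-"), 1))
    pos <- end
  }
  list(start = starts, end = ends, strand = strands, exons = exons)
}

## map positions through the indel shift table of one scaffold.
## events: data.frame(pos, type, length) in A coordinates.
## Returns a function mapping A positions (0-based) to B1 positions.
make_indel_map <- function(events) {
  if (nrow(events) == 0) return(identity)
  ev <- events[order(events$pos), , drop = FALSE]
  # breakpoint k: positions >= k acquire the cumulated delta
  key <- ifelse(ev$type == "INS", ev$pos, ev$pos + ev$length)
  delta <- ifelse(ev$type == "INS", ev$length, -ev$length)
  cum <- cumsum(delta)
  function(p) p + c(0, cum)[findInterval(p, key) + 1L]
}

#' Generate a synthetic diploid genome with complete truth ledgers
#'
#' Builds haplotype A (the ancestral sequence with gene models), then
#' derives haplotype B by class-specific substitution sampling, indel
#' events, and structural events (inversions in place, translocations
#' excised and reinserted into a different scaffold), recording every
#' planted change in replayable ledgers.  Indel and structural-event
#' breakpoints are restricted to non-coding positions so gene models on
#' both haplotypes stay codon-clean.
#'
#' @param config a [sim_config()].
#' @return an object of class `diploid_truth` with elements
#'   `haplotype_a`, `haplotype_b` (named sequence vectors),
#'   `scaffold_correspondence`, `variants` (SNV/indel ledger in A
#'   coordinates), `structural` (event ledger in application-time B
#'   coordinates, plus the A-side interval), `genes` (gene models on
#'   both haplotypes with allelic pairing) and `class_map` (per-base
#'   annotation class of haplotype A).
#' @seealso [replay_truth()] verifies that the ledgers reproduce
#'   haplotype B exactly.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_rng(config$seed, generate_truth_impl(config))
}

generate_truth_impl <- function(cfg) {
  n_scaf <- cfg$n_scaffolds
  base_len <- cfg$ancestral_length %/% n_scaf
  lens <- rep(base_len, n_scaf)
  lens[1] <- lens[1] + cfg$ancestral_length - sum(lens)
  a_names <- sprintf("A_%02d", seq_len(n_scaf))
  b_names <- sprintf("B_%02d", seq_len(n_scaf))

  hapA_chars <- lapply(lens, function(n)
    sample(BASES, n, replace = TRUE))

  ## gene models on haplotype A
  n_per <- diff(round(cumsum(c(0, lens)) / sum(lens) * cfg$n_genes))
  glist <- lapply(seq_len(n_scaf), function(i)
    layout_genes_scaffold(lens[i], n_per[i], cfg))
  genes <- do.call(rbind, lapply(seq_len(n_scaf), function(i) {
    g <- glist[[i]]
    if (length(g$start) == 0) return(NULL)
    data.frame(scaffold = i, start = g$start, end = g$end,
               strand = g$strand, stringsAsFactors = FALSE)
  }))
  if (is.null(genes)) genes <- data.frame(scaffold = integer(0),
    start = integer(0), end = integer(0), strand = character(0))
  genes$exons <- do.call(c, lapply(glist, function(g) g$exons)) %||% list()
  genes$gene_id <- sprintf("gA_%04d", seq_len(nrow(genes)))

  class_map <- class_map_from_genes(genes, lens)

  ## --- substitutions, class-specific rates ---------------------------
  rate_by_class <- c(cfg$snv_rate_intergenic, cfg$snv_rate_intron,
                     cfg$snv_rate_cds)
  snv_ledger <- vector("list", n_scaf)
  b1_chars <- vector("list", n_scaf)
  for (i in seq_len(n_scaf)) {
    cls <- class_map[[i]]
    p <- rate_by_class[cls + 1L]
    hit <- which(runif(lens[i]) < p)
    ref <- hapA_chars[[i]][hit]
    alt_idx <- (match(ref, BASES) - 1L + sample(1:3, length(hit),
                                                replace = TRUE)) %% 4L + 1L
    alt <- BASES[alt_idx]
    b <- hapA_chars[[i]]
    b[hit] <- alt
    b1_chars[[i]] <- b
    snv_ledger[[i]] <- data.frame(
      scaffold = rep(a_names[i], length(hit)), pos = hit - 1L,
      type = rep("SNV", length(hit)), length = rep(1L, length(hit)),
      class = CLASS_LEVELS[cls[hit] + 1L], ref = ref, alt = alt,
      stringsAsFactors = FALSE)
  }

  ## --- indel events (non-CDS only) -----------------------------------
  indel_ledger <- vector("list", n_scaf)
  b1_seqs <- character(n_scaf)
  indel_events <- vector("list", n_scaf)
  for (i in seq_len(n_scaf)) {
    cls <- class_map[[i]]
    n <- lens[i]
    elig <- which(cls != 2L)
    elig <- elig[elig > 60 & elig <= n - 60]
    hit <- elig[runif(length(elig)) < cfg$indel_event_rate]
    if (length(hit)) {
      hit <- sort(hit)
      len <- pmin(rgeom(length(hit), cfg$indel_geom_prob) + 1L,
                  cfg$indel_max_length)
      type <- sample(c("INS", "DEL"), length(hit), replace = TRUE)
      keep <- logical(length(hit))
      prev_end <- -100L
      for (j in seq_along(hit)) {
        p <- hit[j]
        if (p - prev_end < 10L) next
        if (type[j] == "DEL") {
          span <- p:(p + len[j] - 1L)
          if (max(span) > n || any(cls[span] == 2L)) next
          prev_end <- p + len[j]
        } else prev_end <- p
        keep[j] <- TRUE
      }
      hit <- hit[keep]; len <- len[keep]; type <- type[keep]
    } else { len <- integer(0); type <- character(0) }
    ins_seq <- vapply(seq_along(hit), function(j)
      if (type[j] == "INS") random_dna(len[j]) else "", character(1))
    ev <- data.frame(pos = hit - 1L, type = type, length = len,
                     alt = ins_seq, stringsAsFactors = FALSE)
    indel_events[[i]] <- ev
    indel_ledger[[i]] <- if (nrow(ev)) data.frame(
      scaffold = a_names[i], pos = ev$pos, type = ev$type,
      length = ev$length, class = CLASS_LEVELS[cls[ev$pos + 1L] + 1L],
      ref = "", alt = ev$alt, stringsAsFactors = FALSE) else NULL

    ## assemble B1 sequence from pieces
    b <- b1_chars[[i]]
    if (nrow(ev)) {
      pieces <- character(2L * nrow(ev) + 1L)
      cur <- 1L  # 1-based cursor into b
      for (j in seq_len(nrow(ev))) {
        p1 <- ev$pos[j] + 1L   # 1-based event position
        pieces[2L * j - 1L] <- paste(b[cur:(p1 - 1L)], collapse = "")
        if (ev$type[j] == "INS") {
          pieces[2L * j] <- ev$alt[j]
          cur <- p1
        } else {
          pieces[2L * j] <- ""
          cur <- p1 + ev$length[j]
        }
      }
      pieces[2L * nrow(ev) + 1L] <-
        if (cur <= n) paste(b[cur:n], collapse = "") else ""
      b1_seqs[i] <- paste(pieces, collapse = "")
    } else b1_seqs[i] <- paste(b, collapse = "")
  }

  variants <- do.call(rbind, c(snv_ledger, indel_ledger))
  variants <- variants[order(variants$scaffold, variants$pos), ]
  rownames(variants) <- NULL

  maps <- lapply(indel_events, make_indel_map)

  ## gene models on haplotype B (through the indel coordinate map)
  genesB <- genes
  if (nrow(genes)) {
    genesB$gene_id <- sub("^gA", "gB", genes$gene_id)
    for (r in seq_len(nrow(genes))) {
      mp <- maps[[genes$scaffold[r]]]
      ex <- genes$exons[[r]]
      exB <- cbind(mp(ex[, 1]), mp(ex[, 2] - 1L) + 1L)
      genesB$exons[[r]] <- exB
      genesB$start[r] <- mp(genes$start[r])
      genesB$end[r] <- mp(genes$end[r] - 1L) + 1L
    }
  }

  ## --- structural events on haplotype B ------------------------------
  b_seqs <- b1_seqs
  used <- data.frame(scaffold = integer(0), start = integer(0),
                     end = integer(0))
  structural <- NULL
  ev_plan <- c(rep("inversion", cfg$n_inversions),
               rep("translocation", cfg$n_translocations))
  size_range <- function(type) if (type == "inversion")
    cfg$inversion_size_range else cfg$translocation_size_range

  pick_interval <- function(type) {
    for (try in 1:500) {
      i <- sample(n_scaf, 1, prob = lens)
      size <- sample(seq(size_range(type)[1], size_range(type)[2]), 1)
      if (size >= lens[i])
        stop("structural event larger than its scaffold (", size,
             " bp vs ", lens[i], " bp)")
      s <- sample(lens[i] - size - 100L, 1) + 50L
      e <- s + size
      cls <- class_map[[i]]
      if (cls[s + 1L] != 0L || cls[e + 1L] != 0L) next
      clash <- used$scaffold == i & used$start < e + 100L & used$end > s - 100L
      if (any(clash)) next
      return(list(scaffold = i, a_start = s, a_end = e))
    }
    stop("could not place a ", type, " in intergenic sequence; ",
         "reduce event sizes or counts")
  }
  pick_dest <- function(exclude_scaffold) {
    for (try in 1:500) {
      i <- sample(setdiff(seq_len(n_scaf), exclude_scaffold), 1)
      p <- sample(lens[i] - 200L, 1) + 100L
      if (class_map[[i]][p + 1L] != 0L) next
      clash <- used$scaffold == i & used$start < p + 100L & used$end > p - 100L
      if (any(clash)) next
      return(list(scaffold = i, a_pos = p))
    }
    stop("could not place a translocation destination")
  }

  ## frame adjustment from previously applied translocations:
  ## list of (scaffold, pos, delta) applied in order
  adjust <- list()
  cur_pos <- function(scaf, p) {
    for (ad in adjust) if (ad$scaffold == scaf && p >= ad$pos) p <- p + ad$delta
    p
  }

  for (type in ev_plan) {
    src <- pick_interval(type)
    used <- rbind(used, data.frame(scaffold = src$scaffold,
                                   start = src$a_start, end = src$a_end))
    mp <- maps[[src$scaffold]]
    s_b <- cur_pos(src$scaffold, mp(src$a_start))
    e_b <- cur_pos(src$scaffold, mp(src$a_end - 1L) + 1L)
    scaf_b <- b_names[src$scaffold]
    seq_x <- b_seqs[src$scaffold]
    if (type == "inversion") {
      inv <- revcomp(substr(seq_x, s_b + 1L, e_b))
      b_seqs[src$scaffold] <- paste0(substr(seq_x, 1L, s_b), inv,
                                     substr(seq_x, e_b + 1L, nchar(seq_x)))
      if (nrow(genesB)) {
        inside <- genesB$scaffold == src$scaffold &
          genesB$start >= s_b & genesB$end <= e_b
        for (r in which(inside)) {
          ex <- genesB$exons[[r]]
          exN <- cbind(s_b + (e_b - ex[, 2]), s_b + (e_b - ex[, 1]))
          genesB$exons[[r]] <- exN[rev(seq_len(nrow(exN))), , drop = FALSE]
          new_start <- s_b + (e_b - genesB$end[r])
          genesB$end[r] <- s_b + (e_b - genesB$start[r])
          genesB$start[r] <- new_start
          genesB$strand[r] <- if (genesB$strand[r] == "+") "-" else "+"
        }
      }
      structural <- rbind(structural, data.frame(
        type = "inversion", scaffold = scaf_b, src_start = s_b,
        src_end = e_b, dest_scaffold = NA_character_, dest_pos = NA_integer_,
        a_scaffold = a_names[src$scaffold], a_start = src$a_start,
        a_end = src$a_end, stringsAsFactors = FALSE))
    } else {
      dst <- pick_dest(src$scaffold)
      used <- rbind(used, data.frame(scaffold = dst$scaffold,
                                     start = dst$a_pos, end = dst$a_pos + 1L))
      d_b <- cur_pos(dst$scaffold, maps[[dst$scaffold]](dst$a_pos))
      L <- e_b - s_b
      moved <- substr(seq_x, s_b + 1L, e_b)
      b_seqs[src$scaffold] <- paste0(substr(seq_x, 1L, s_b),
                                     substr(seq_x, e_b + 1L, nchar(seq_x)))
      seq_y <- b_seqs[dst$scaffold]
      b_seqs[dst$scaffold] <- paste0(substr(seq_y, 1L, d_b), moved,
                                     substr(seq_y, d_b + 1L, nchar(seq_y)))
      if (nrow(genesB)) {
        shift_gene <- function(r, delta, new_scaf = NULL) {
          genesB$exons[[r]] <<- genesB$exons[[r]] + delta
          genesB$start[r] <<- genesB$start[r] + delta
          genesB$end[r] <<- genesB$end[r] + delta
          if (!is.null(new_scaf)) genesB$scaffold[r] <<- new_scaf
        }
        on_x <- genesB$scaffold == src$scaffold
        inside <- on_x & genesB$start >= s_b & genesB$end <= e_b
        after_x <- on_x & !inside & genesB$start >= e_b
        on_y_after <- genesB$scaffold == dst$scaffold & genesB$start >= d_b
        for (r in which(on_y_after)) shift_gene(r, L)
        for (r in which(after_x)) shift_gene(r, -L)
        for (r in which(inside)) shift_gene(r, d_b - s_b, dst$scaffold)
      }
      structural <- rbind(structural, data.frame(
        type = "translocation", scaffold = scaf_b, src_start = s_b,
        src_end = e_b, dest_scaffold = b_names[dst$scaffold],
        dest_pos = d_b, a_scaffold = a_names[src$scaffold],
        a_start = src$a_start, a_end = src$a_end, stringsAsFactors = FALSE))
      adjust <- c(adjust,
        list(list(scaffold = src$scaffold, pos = e_b, delta = -L)),
        list(list(scaffold = dst$scaffold, pos = d_b, delta = L)))
    }
  }

  hapA <- setNames(vapply(hapA_chars, paste, character(1), collapse = ""),
                   a_names)
  hapB <- setNames(b_seqs, b_names)

  ## combined gene table
  if (nrow(genes)) {
    gA <- data.frame(gene_id = genes$gene_id,
                     scaffold = a_names[genes$scaffold],
                     strand = genes$strand, haplotype = "A",
                     start = genes$start, end = genes$end,
                     partner = genesB$gene_id, stringsAsFactors = FALSE)
    gA$exons <- genes$exons
    gB <- data.frame(gene_id = genesB$gene_id,
                     scaffold = b_names[genesB$scaffold],
                     strand = genesB$strand, haplotype = "B",
                     start = genesB$start, end = genesB$end,
                     partner = genes$gene_id, stringsAsFactors = FALSE)
    gB$exons <- genesB$exons
    gene_tab <- rbind(gA, gB)
  } else {
    gene_tab <- data.frame(gene_id = character(0), scaffold = character(0),
                           strand = character(0), haplotype = character(0),
                           start = integer(0), end = integer(0),
                           partner = character(0))
    gene_tab$exons <- list()
  }

  structure(list(
    config = cfg,
    haplotype_a = hapA,
    haplotype_b = hapB,
    scaffold_correspondence = setNames(b_names, a_names),
    variants = variants,
    structural = structural %||% data.frame(
      type = character(0), scaffold = character(0), src_start = integer(0),
      src_end = integer(0), dest_scaffold = character(0),
      dest_pos = integer(0), a_scaffold = character(0),
      a_start = integer(0), a_end = integer(0)),
    genes = gene_tab,
    class_map = setNames(class_map, a_names)
  ), class = "diploid_truth")
}

#' @export
print.diploid_truth <- function(x, ...) {
  cat("diploid_truth:", length(x$haplotype_a), "scaffold pair(s),",
      sum(nchar(x$haplotype_a)), "bp (haplotype A)\n")
  cat("  variants:", sum(x$variants$type == "SNV"), "SNVs,",
      sum(x$variants$type != "SNV"), "indel events\n")
  cat("  structural:", nrow(x$structural), "event(s);  genes:",
      nrow(x$genes), "\n")
  invisible(x)
}

#' Replay the truth ledgers onto haplotype A
#'
#' Applies the SNV ledger, then the indel ledger, then the structural
#' ledger to haplotype A and returns the reconstructed haplotype B.
#' On a correct simulation this is byte-identical to
#' \code{truth$haplotype_b}.
#'
#' @param truth a [generate_truth()] result.
#' @return named character vector of reconstructed B scaffolds.
#' @export
replay_truth <- function(truth) {
  corr <- truth$scaffold_correspondence
  out <- setNames(character(length(corr)), unname(corr))
  for (a_name in names(corr)) {
    chars <- strsplit(truth$haplotype_a[[a_name]], "")[[1]]
    v <- truth$variants[truth$variants$scaffold == a_name, , drop = FALSE]
    snv <- v[v$type == "SNV", , drop = FALSE]
    chars[snv$pos + 1L] <- snv$alt
    ind <- v[v$type != "SNV", , drop = FALSE]
    if (nrow(ind)) {
      ind <- ind[order(-ind$pos), , drop = FALSE]  # apply right to left
      s <- chars
      for (j in seq_len(nrow(ind))) {
        p <- ind$pos[j]
        if (ind$type[j] == "INS") {
          s <- append(s, strsplit(ind$alt[j], "")[[1]], after = p)
        } else {
          s <- s[-((p + 1L):(p + ind$length[j]))]
        }
      }
      chars <- s
    }
    out[corr[[a_name]]] <- paste(chars, collapse = "")
  }
  st <- truth$structural
  for (j in seq_len(nrow(st))) {
    e <- st[j, ]
    x <- out[[e$scaffold]]
    if (e$type == "inversion") {
      out[[e$scaffold]] <- paste0(
        substr(x, 1, e$src_start), revcomp(substr(x, e$src_start + 1, e$src_end)),
        substr(x, e$src_end + 1, nchar(x)))
    } else {
      moved <- substr(x, e$src_start + 1, e$src_end)
      out[[e$scaffold]] <- paste0(substr(x, 1, e$src_start),
                                  substr(x, e$src_end + 1, nchar(x)))
      y <- out[[e$dest_scaffold]]
      out[[e$dest_scaffold]] <- paste0(substr(y, 1, e$dest_pos), moved,
                                       substr(y, e$dest_pos + 1, nchar(y)))
    }
  }
  out
}
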