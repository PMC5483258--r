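## Build per-base annotation class maps (0 intergenic, 1 intron, 2 CDS)
## for the scaffolds named in seqlens, from either a GFF3-style GRanges
## or a truth-style gene table with an `exons` list column.
annotation_class_maps <- function(annotation, seqlens) {
  maps <- lapply(seqlens, function(n) integer(n))
  if (methods::is(annotation, "GRanges")) {
    typ <- as.character(S4Vectors::mcols(annotation)$type)
    sn <- as.character(GenomicRanges::seqnames(annotation))
    known <- sn %in% names(seqlens)
    if (any(!known & typ %in% c("gene", "CDS", "exon")))
      warning("annotation features on scaffold(s) absent from the assembly ",
              "were skipped")
    st <- GenomicRanges::start(annotation)   # 1-based inclusive
    en <- GenomicRanges::end(annotation)
    for (i in which(known & typ == "gene"))
      maps[[sn[i]]][st[i]:en[i]] <- pmax(maps[[sn[i]]][st[i]:en[i]], 1L)
    for (i in which(known & typ == "CDS"))
      maps[[sn[i]]][st[i]:en[i]] <- 2L
  } else if (is.data.frame(annotation)) {
    for (i in seq_len(nrow(annotation))) {
      g <- annotation[i, ]
      if (!g$scaffold %in% names(seqlens)) next
      m <- maps[[g$scaffold]]
      m[(g$start + 1):g$end] <- pmax(m[(g$start + 1):g$end], 1L)
      ex <- g$exons[[1]]
      for (r in seq_len(nrow(ex))) m[(ex[r, 1] + 1):ex[r, 2]] <- 2L
      maps[[g$scaffold]] <- m
    }
  } else stop("annotation must be a GRanges or a gene table")
  maps
}

#' Variant totals over a segment tiling
#'
#' Counts mismatch (SNV) columns and indel events over a set of tiled
#' segments and expresses them as percentages of the paired length
#' (both-sides convention, as in [pairing_summary()]: each mismatch
#' column contributes one mismatched base on each scaffold, each indel
#' event is seen from both sides).
#'
#' @param segments a `paired_segments` object.
#' @return list with `snv_sites` and `indel_event_sites` (per-column
#'   counts, comparable to a planted-variant ledger), `snv_count` and
#'   `indel_event_count` (both-sides totals), `paired_length`,
#'   `snv_pct`, `indel_pct`, and an `undefined` flag for empty input.
#' @export
variant_totals <- function(segments) {
  df <- as.data.frame(segments)
  if (nrow(df) == 0)
    return(list(snv_sites = 0L, indel_event_sites = 0L, snv_count = 0L,
                indel_event_count = 0L, paired_length = 0L,
                snv_pct = 0, indel_pct = 0, undefined = TRUE))
  paired <- sum(df$end_a - df$start_a) + sum(df$end_b - df$start_b)
  sites <- sum(df$n_mismatch)
  ev <- sum(df$indel_events)
  list(snv_sites = sites, indel_event_sites = ev,
       snv_count = 2L * sites, indel_event_count = 2L * ev,
       paired_length = paired,
       snv_pct = 100 * 2 * sites / paired,
       indel_pct = 100 * 2 * ev / paired,
       undefined = FALSE)
}

#' SNV densities by annotation class
#'
#' Assigns every aligned A-side base (match or mismatch column) to
#' exactly one class with precedence CDS > intron > intergenic and
#' reports per-class SNV densities, plus per-gene CDS and intron
#' records for scatter output.
#'
#' @param segments a tiled `paired_segments` object (A side carries
#'   the annotation).
#' @param annotation a GRanges (from GFF3) or a truth-style gene table.
#' @return list with `classes` (class, aligned_bases, snvs,
#'   density_pct) and `genes` (per-gene aligned bases, SNVs and
#'   densities for CDS and intron).
#' @export
class_densities <- function(segments, annotation) {
  seqlens <- attr(segments, "seqlengths")
  a_names <- unique(vapply(segments, `[[`, character(1), "scaffold_a"))
  maps <- annotation_class_maps(annotation, seqlens[a_names])

  aligned <- lapply(seqlens[a_names], function(n) logical(n))
  snv <- lapply(seqlens[a_names], function(n) logical(n))
  for (s in segments) {
    cc <- segment_columns(s)
    al <- cc$a_pos[cc$op <= 1L]
    aligned[[s$scaffold_a]][al + 1L] <- TRUE
    mm <- cc$a_pos[cc$op == 1L]
    snv[[s$scaffold_a]][mm + 1L] <- TRUE
  }
  ab <- integer(3); sv <- integer(3)
  for (nm in a_names) {
    cls <- maps[[nm]]
    ab <- ab + tabulate(cls[aligned[[nm]]] + 1L, 3L)
    sv <- sv + tabulate(cls[snv[[nm]]] + 1L, 3L)
  }
  classes <- data.frame(class = CLASS_LEVELS, aligned_bases = ab,
                        snvs = sv,
                        density_pct = ifelse(ab > 0, 100 * sv / ab, NA_real_),
                        stringsAsFactors = FALSE)

  genes <- NULL
  gene_tab <- if (is.data.frame(annotation)) annotation else NULL
  if (!is.null(gene_tab) && nrow(gene_tab)) {
    gene_tab <- gene_tab[gene_tab$scaffold %in% a_names, , drop = FALSE]
    rows <- lapply(seq_len(nrow(gene_tab)), function(i) {
      g <- gene_tab[i, ]
      alv <- aligned[[g$scaffold]]; svv <- snv[[g$scaffold]]
      clsv <- maps[[g$scaffold]]
      span <- (g$start + 1):g$end
      cds_i <- span[clsv[span] == 2L]
      int_i <- span[clsv[span] == 1L]
      data.frame(gene_id = g$gene_id,
                 cds_aligned = sum(alv[cds_i]), cds_snvs = sum(svv[cds_i]),
                 intron_aligned = sum(alv[int_i]),
                 intron_snvs = sum(svv[int_i]), stringsAsFactors = FALSE)
    })
    genes <- do.call(rbind, rows)
    genes$cds_density_pct <- ifelse(genes$cds_aligned > 0,
                                    100 * genes$cds_snvs / genes$cds_aligned,
                                    NA_real_)
    genes$intron_density_pct <- ifelse(genes$intron_aligned > 0,
                                       100 * genes$intron_snvs /
                                         genes$intron_aligned, NA_real_)
  }
  list(classes = classes, genes = genes)
}

#' Mismatch and indel tracks in fixed windows
#'
#' Counts mismatch columns per fixed window anchored at coordinate 0 of
#' each A scaffold (the last partial window is kept), and reports each
#' indel event as one signed length (+insertion, -deletion) at the
#' A-side base one position before the gap.
#'
#' @param segments a tiled `paired_segments` object.
#' @param window window size (bp).
#' @return list with `mismatch` (scaffold, window_start, count; all
#'   windows of every scaffold that carries segments) and `indels`
#'   (scaffold, pos, value).
#' @export
window_tracks <- function(segments, window = 100L) {
  seqlens <- attr(segments, "seqlengths")
  a_names <- unique(vapply(segments, `[[`, character(1), "scaffold_a"))
  mm_pos <- setNames(vector("list", length(a_names)), a_names)
  ind <- list()
  for (s in segments) {
    cc <- segment_columns(s)
    mm_pos[[s$scaffold_a]] <- c(mm_pos[[s$scaffold_a]],
                                cc$a_pos[cc$op == 1L])
    ## indel events from the RLE runs
    run_end <- cumsum(s$len)
    run_start <- run_end - s$len + 1L
    last_a <- cummax(ifelse(is.na(cc$a_pos), -1L, cc$a_pos))
    for (ri in which(s$op %in% c(2L, 3L))) {
      if (s$op[ri] == 3L) {      # deletion: gap in B, consumes A
        pos <- cc$a_pos[run_start[ri]] - 1L
        val <- -s$len[ri]
      } else {                   # insertion: gap in A
        pos <- if (run_start[ri] == 1L) s$start_a - 1L
               else last_a[run_start[ri] - 1L]
        val <- s$len[ri]
      }
      ind[[length(ind) + 1L]] <- data.frame(
        scaffold = s$scaffold_a, pos = pos, value = val,
        stringsAsFactors = FALSE)
    }
  }
  mism <- do.call(rbind, lapply(a_names, function(nm) {
    nwin <- ceiling(seqlens[[nm]] / window)
    cnt <- tabulate(mm_pos[[nm]] %/% window + 1L, nwin)
    data.frame(scaffold = nm, window_start = (seq_len(nwin) - 1L) * window,
               count = cnt, stringsAsFactors = FALSE)
  }))
  indels <- if (length(ind)) do.call(rbind, ind) else
    data.frame(scaffold = character(0), pos = integer(0), value = integer(0))
  indels <- indels[order(indels$scaffold, indels$pos), , drop = FALSE]
  rownames(indels) <- NULL
  list(mismatch = mism, indels = indels)
}

#' Call inversions and translocations from a segment tiling
#'
#' The dominant partner of an A scaffold is the B scaffold covering the
#' most aligned bases.  A run of segments aligned to a different
#' partner is called a translocation; a run of dominant-partner
#' segments whose orientation opposes both flanking dominant-partner
#' runs is called an inversion (both flanks must agree, which avoids
#' edge artifacts).  Forward dominant-partner segments are grouped
#' into colinearity runs (split where the partner-coordinate offset
#' jumps by more than `min_displacement`); the maximum-aligned-bases
#' subset of runs that is monotone in partner coordinates forms the
#' syntenic backbone, and runs off the backbone are called
#' intra-scaffold translocations.
#'
#' @param segments a tiled `paired_segments` object.
#' @param min_displacement minimum partner-offset displacement (bp)
#'   for an intra-scaffold translocation call.
#' @return data.frame of calls (type, scaffold_a, start_a, end_a,
#'   partner, partner_start, partner_end, n_segments).
#' @export
structural_events <- function(segments, min_displacement = 1000L) {
  df <- as.data.frame(segments)
  empty <- data.frame(type = character(0), scaffold_a = character(0),
                      start_a = integer(0), end_a = integer(0),
                      partner = character(0), partner_start = integer(0),
                      partner_end = integer(0), n_segments = integer(0))
  if (nrow(df) == 0) return(empty)
  calls <- list()
  for (sa in unique(df$scaffold_a)) {
    d <- df[df$scaffold_a == sa, , drop = FALSE]
    d <- d[order(d$start_a), , drop = FALSE]
    cover <- tapply(d$end_a - d$start_a, d$scaffold_b, sum)
    dominant <- names(cover)[which.max(cover)]

    ## translocations: runs of foreign-partner segments
    foreign <- d$scaffold_b != dominant
    r <- rle(paste(foreign, d$scaffold_b))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (ri in which(grepl("^TRUE", r$values))) {
      sub <- d[starts[ri]:ends[ri], , drop = FALSE]
      calls[[length(calls) + 1L]] <- data.frame(
        type = "translocation", scaffold_a = sa,
        start_a = min(sub$start_a), end_a = max(sub$end_a),
        partner = sub$scaffold_b[1],
        partner_start = min(sub$start_b), partner_end = max(sub$end_b),
        n_segments = nrow(sub), stringsAsFactors = FALSE)
    }

    ## inversions: among dominant-partner segments, an orientation run
    ## opposed by both flanking runs
    dd <- d[!foreign, , drop = FALSE]
    if (nrow(dd) >= 3) {
      r <- rle(dd$orientation)
      if (length(r$lengths) >= 3) {
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        for (ri in 2:(length(r$lengths) - 1L)) {
          if (r$values[ri] == r$values[ri - 1L] ||
              r$values[ri] == r$values[ri + 1L]) next
          sub <- dd[starts[ri]:ends[ri], , drop = FALSE]
          calls[[length(calls) + 1L]] <- data.frame(
            type = "inversion", scaffold_a = sa,
            start_a = min(sub$start_a), end_a = max(sub$end_a),
            partner = dominant,
            partner_start = min(sub$start_b), partner_end = max(sub$end_b),
            n_segments = nrow(sub), stringsAsFactors = FALSE)
        }
      }
    }

    ## intra-scaffold translocations: forward dominant-partner runs
    ## off the maximum-weight partner-monotone backbone
    ff <- dd[dd$orientation == "forward", , drop = FALSE]
    if (nrow(ff) >= 2) {
      off <- ff$start_b - ff$start_a
      run_id <- cumsum(c(TRUE, abs(diff(off)) > min_displacement))
      n_runs <- max(run_id)
      if (n_runs >= 2) {
        run_b <- tapply(ff$start_b, run_id, min)
        run_w <- tapply(ff$end_a - ff$start_a, run_id, sum)
        ## weighted longest increasing subsequence over run partner order
        best <- as.numeric(run_w); prev <- rep(NA_integer_, n_runs)
        for (ri in seq_len(n_runs)) for (rj in seq_len(ri - 1L))
          if (run_b[[rj]] < run_b[[ri]] &&
              best[rj] + run_w[[ri]] > best[ri]) {
            best[ri] <- best[rj] + run_w[[ri]]; prev[ri] <- rj
          }
        bb <- which.max(best); backbone <- integer(0)
        while (!is.na(bb)) { backbone <- c(bb, backbone); bb <- prev[bb] }
        for (ri in setdiff(seq_len(n_runs), backbone)) {
          sub <- ff[run_id == ri, , drop = FALSE]
          calls[[length(calls) + 1L]] <- data.frame(
            type = "translocation", scaffold_a = sa,
            start_a = min(sub$start_a), end_a = max(sub$end_a),
            partner = dominant,
            partner_start = min(sub$start_b), partner_end = max(sub$end_b),
            n_segments = nrow(sub), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  out[order(out$scaffold_a, out$start_a), , drop = FALSE]
}

#' Write the mismatch window track as fixed-step wiggle
#' @param tracks result of [window_tracks()].
#' @param path output file.
#' @param window the window size used.
#' @return invisibly, the path.
#' @export
write_wiggle <- function(tracks, path, window = 100L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in unique(tracks$mismatch$scaffold)) {
    d <- tracks$mismatch[tracks$mismatch$scaffold == nm, ]
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       nm, window, window), con)
    writeLines(as.character(d$count), con)
  }
  invisible(path)
}

#' Write indel events as BED
#' @param tracks result of [window_tracks()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_indel_bed <- function(tracks, path) {
  d <- tracks$indels
  bed <- data.frame(chrom = d$scaffold, start = d$pos, end = d$pos + 1L,
                    name = ifelse(d$value > 0, "INS", "DEL"),
                    score = abs(d$value))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
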