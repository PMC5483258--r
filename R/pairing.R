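#' Build an exact k-mer anchor map over an assembly
#'
#' Finds every exact k-mer shared between two distinct scaffold
#' positions (both orientations, via canonical k-mers), excluding
#' positions whose window contains N and k-mers occurring more than
#' `max_seed_multiplicity` times in the whole assembly (repeat
#' suppression).
#'
#' @param scaffolds named character vector, DNAStringSet or FASTA path.
#' @param k seed length (default 15, minimum 11).
#' @param max_seed_multiplicity skip k-mers seen more often than this.
#' @return a data.frame of anchors (scaffold_a, scaffold_b, pos_a,
#'   pos_b, length, orientation) with 0-based positions and
#'   `scaffold_a <= scaffold_b` lexicographically; scaffold lengths are
#'   attached as the `seqlengths` attribute.
#' @export
build_anchor_map <- function(scaffolds, k = 15L, max_seed_multiplicity = 10L) {
  if (k < 11) stop("k must be at least 11")
  seqs <- as_seq_vector(scaffolds)
  seqs <- seqs[order(names(seqs))]  # lexicographic index order
  if (length(seqs) == 0 || all(nchar(seqs) == 0)) {
    out <- data.frame(scaffold_a = character(0), scaffold_b = character(0),
                      pos_a = integer(0), pos_b = integer(0),
                      length = integer(0), orientation = character(0))
    attr(out, "seqlengths") <- setNames(nchar(seqs), names(seqs))
    return(out)
  }
  df <- cpp_seed_anchors(unname(seqs), as.integer(k),
                         as.integer(max_seed_multiplicity))
  out <- data.frame(
    scaffold_a = names(seqs)[df$seq_a], scaffold_b = names(seqs)[df$seq_b],
    pos_a = df$pos_a, pos_b = df$pos_b,
    length = rep(as.integer(k), length(df$pos_a)),
    orientation = c("forward", "reverse")[df$orient + 1L],
    stringsAsFactors = FALSE)
  attr(out, "seqlengths") <- setNames(nchar(seqs), names(seqs))
  out
}

#' Chain colinear anchors
#'
#' Groups anchors by (scaffold pair, orientation) and links them into
#' maximal colinear chains: coordinates monotone on both sequences
#' (reverse-orientation anchors are first mapped into the
#' reverse-complement frame of scaffold B, so chaining is uniform) with
#' end-to-start gaps of at most `max_gap` on both sequences.
#'
#' @param anchors result of [build_anchor_map()].
#' @param max_gap maximum gap (bp) between consecutive anchors.
#' @param min_chain_anchors chains with fewer anchors are discarded.
#' @return an object of class `anchor_chains`: a list of chains, each
#'   holding the scaffold pair, orientation, anchor length `k`, and
#'   anchor start vectors `pa`, `pb` (pb in the reverse-complement
#'   frame for reverse chains).
#' @export
chain_anchors <- function(anchors, max_gap = 500L, min_chain_anchors = 3L) {
  seqlens <- attr(anchors, "seqlengths")
  if (is.null(seqlens)) stop("anchors lack the seqlengths attribute")
  k <- if (nrow(anchors)) anchors$length[1] else 15L
  chains <- list()
  if (nrow(anchors) == 0)
    return(structure(chains, class = "anchor_chains", seqlengths = seqlens,
                     k = k))
  pb_t <- ifelse(anchors$orientation == "reverse",
                 seqlens[anchors$scaffold_b] - anchors$pos_b - k,
                 anchors$pos_b)
  grp <- paste(anchors$scaffold_a, anchors$scaffold_b, anchors$orientation,
               sep = "\r")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    pa <- anchors$pos_a[idx]; pb <- pb_t[idx]
    o <- order(pa, pb)
    pa <- pa[o]; pb <- pb[o]
    cid <- cpp_chain_anchors(as.integer(pa), as.integer(pb),
                             as.integer(k), as.integer(max_gap))
    first <- idx[1]
    for (cu in unique(cid)) {
      sel <- cid == cu
      if (sum(sel) < min_chain_anchors) next
      chains[[length(chains) + 1L]] <- list(
        scaffold_a = anchors$scaffold_a[first],
        scaffold_b = anchors$scaffold_b[first],
        orientation = anchors$orientation[first],
        k = k, pa = pa[sel], pb = pb[sel])
    }
  }
  structure(chains, class = "anchor_chains", seqlengths = seqlens, k = k)
}

segment_stats <- function(op, len) {
  list(n_match = sum(len[op == 0L]),
       n_mismatch = sum(len[op == 1L]),
       n_ins_events = sum(op == 2L),
       n_del_events = sum(op == 3L))
}

segment_score <- function(op, len) {
  sum(len[op == 0L]) - sum(len[op == 1L]) +
    sum(-2L - (len[op %in% c(2L, 3L)] - 1L))
}

new_segments <- function(segs, seqlens) {
  structure(segs, class = "paired_segments", seqlengths = seqlens)
}

merge_rle <- function(op, len) {
  if (length(op) < 2) return(list(op = op, len = len))
  keep <- c(TRUE, op[-1] != op[-length(op)])
  grp <- cumsum(keep)
  list(op = op[keep],
       len = as.integer(unname(tapply(len, grp, sum))))
}

## Align one flank pair (either may be empty) as RLE edit ops.
flank_ops <- function(fa, fb, band) {
  if (nchar(fa) == 0 && nchar(fb) == 0)
    return(list(op = integer(0), len = integer(0)))
  if (nchar(fa) == 0) return(list(op = 2L, len = nchar(fb)))
  if (nchar(fb) == 0) return(list(op = 3L, len = nchar(fa)))
  r <- cpp_banded_global(fa, fb, as.integer(band))
  list(op = r$op, len = r$len)
}

#' Refine anchor chains into alignment segments
#'
#' Fills the regions between consecutive anchors of each chain by
#' banded global alignment (match +1, mismatch -1, gap open -2, gap
#' extend -1; band width `band` plus the local length difference,
#' doubled on overflow) and concatenates the edit operations over the
#' whole chain span.
#'
#' @param chains result of [chain_anchors()].
#' @param scaffolds the same scaffold set the anchors were built from.
#' @param band base band half-width (bp).
#' @return an object of class `paired_segments`: a list of segments
#'   with 0-based half-open coordinates (`start_b`/`end_b` always on
#'   the forward strand of scaffold B), run-length encoded edit
#'   operations (`op`: 0 match, 1 mismatch, 2 insertion in B,
#'   3 deletion from A, with `len`), match/mismatch/indel-event counts
#'   and an alignment score.
#' @export
refine_segments <- function(chains, scaffolds, band = 32L) {
  seqs <- as_seq_vector(scaffolds)
  seqlens <- attr(chains, "seqlengths")
  rc_cache <- new.env(parent = emptyenv())
  segs <- list()
  for (ch in chains) {
    a <- seqs[[ch$scaffold_a]]
    if (ch$orientation == "reverse") {
      key <- ch$scaffold_b
      if (is.null(rc_cache[[key]])) rc_cache[[key]] <- revcomp(seqs[[key]])
      b <- rc_cache[[key]]
    } else b <- seqs[[ch$scaffold_b]]
    r <- cpp_refine_chain(a, b, as.integer(ch$pa), as.integer(ch$pb),
                          as.integer(ch$k), as.integer(band))
    op <- r$op; len <- r$len
    sa <- r$start_a; sb <- r$start_b; ea <- r$end_a; eb <- r$end_b
    la <- nchar(a); lbw <- nchar(b)
    ## extend to the sequence corners when both remaining flanks are
    ## short (<= the chaining gap bound); longer flanks belong to other
    ## chains (e.g. across structural breakpoints) and are left alone
    if ((sa > 0 || sb > 0) && sa <= 500 && sb <= 500) {
      pre <- flank_ops(substr(a, 1, sa), substr(b, 1, sb), band)
      op <- c(pre$op, op); len <- c(pre$len, len)
      sa <- 0L; sb <- 0L
    }
    if ((ea < la || eb < lbw) && la - ea <= 500 && lbw - eb <= 500) {
      sfx <- flank_ops(substr(a, ea + 1, la), substr(b, eb + 1, lbw), band)
      op <- c(op, sfx$op); len <- c(len, sfx$len)
      ea <- la; eb <- lbw
    }
    m <- merge_rle(op, len)
    st <- segment_stats(m$op, m$len)
    lb <- seqlens[[ch$scaffold_b]]
    if (ch$orientation == "reverse") {
      start_b <- lb - eb; end_b <- lb - sb
    } else {
      start_b <- sb; end_b <- eb
    }
    segs[[length(segs) + 1L]] <- c(list(
      scaffold_a = ch$scaffold_a, start_a = sa, end_a = ea,
      scaffold_b = ch$scaffold_b, start_b = start_b, end_b = end_b,
      orientation = ch$orientation, op = m$op, len = m$len,
      score = segment_score(m$op, m$len)), st)
  }
  new_segments(segs, seqlens)
}

#' Per-column expansion of a segment's edit operations
#'
#' Expands the run-length encoded operations into per-column vectors:
#' the op code, the consumed A position (NA for insertion columns) and
#' the consumed B position on the forward strand (NA for deletion
#' columns).
#'
#' @param seg one element of a `paired_segments` list.
#' @return list with `op`, `a_pos`, `b_pos` (0-based).
#' @export
segment_columns <- function(seg) {
  opv <- rep.int(seg$op, seg$len)
  a_cons <- opv != 2L
  b_cons <- opv != 3L
  a_pos <- rep(NA_integer_, length(opv))
  a_pos[a_cons] <- seg$start_a + seq_len(sum(a_cons)) - 1L
  b_pos <- rep(NA_integer_, length(opv))
  if (seg$orientation == "forward") {
    b_pos[b_cons] <- seg$start_b + seq_len(sum(b_cons)) - 1L
  } else {
    b_pos[b_cons] <- seg$end_b - seq_len(sum(b_cons))
  }
  list(op = opv, a_pos = a_pos, b_pos = b_pos)
}

#' @method as.data.frame paired_segments
#' @export
as.data.frame.paired_segments <- function(x, ...) {
  if (length(x) == 0)
    return(data.frame(scaffold_a = character(0), start_a = integer(0),
                      end_a = integer(0), scaffold_b = character(0),
                      start_b = integer(0), end_b = integer(0),
                      orientation = character(0), n_match = integer(0),
                      n_mismatch = integer(0), indel_events = integer(0),
                      score = numeric(0)))
  do.call(rbind, lapply(x, function(s) data.frame(
    scaffold_a = s$scaffold_a, start_a = s$start_a, end_a = s$end_a,
    scaffold_b = s$scaffold_b, start_b = s$start_b, end_b = s$end_b,
    orientation = s$orientation, n_match = s$n_match,
    n_mismatch = s$n_mismatch,
    indel_events = s$n_ins_events + s$n_del_events,
    score = s$score, stringsAsFactors = FALSE)))
}

#' @export
print.paired_segments <- function(x, ...) {
  cat("paired_segments:", length(x), "segment(s)\n")
  if (length(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Reciprocal-best one-to-one tiling of alignment segments
#'
#' Resolves overlaps so that every scaffold base is covered by at most
#' one retained segment on its A-side projection and at most one on its
#' B-side projection, emulating split-alignment applied to both query
#' and reference.  Conflicts are resolved per base by best score
#' density (score per aligned column), ties broken by longer segment,
#' then lexicographic scaffold ids; surviving segments are trimmed to
#' maximal consistent runs and runs shorter than `min_segment_length`
#' (A span) are dropped.
#'
#' @param segments a `paired_segments` object.
#' @param min_segment_length minimum A-side span (bp) after trimming.
#' @return a `paired_segments` object.
#' @export
reciprocal_best_tiling <- function(segments, min_segment_length = 200L) {
  seqlens <- attr(segments, "seqlengths")
  if (length(segments) == 0) return(segments)
  ## refined segments already below the minimum span are noise; they
  ## are excluded before the per-base contest so they cannot carve
  ## holes in segments they could never survive alongside
  spans <- vapply(segments, function(s) s$end_a - s$start_a, numeric(1))
  segments <- new_segments(segments[spans >= min_segment_length], seqlens)
  if (length(segments) == 0) return(segments)
  df <- as.data.frame(segments)
  cols <- vapply(segments, function(s) sum(s$len), numeric(1))
  dens <- df$score / cols
  ord <- order(-dens, -cols, df$scaffold_a, df$scaffold_b, df$start_a)

  winA <- lapply(seqlens, function(n) integer(n))
  winB <- lapply(seqlens, function(n) integer(n))
  for (id in ord) {
    s <- segments[[id]]
    ia <- (s$start_a + 1L):s$end_a
    wa <- winA[[s$scaffold_a]]
    wa[ia[wa[ia] == 0L]] <- id
    winA[[s$scaffold_a]] <- wa
    ib <- (s$start_b + 1L):s$end_b
    wb <- winB[[s$scaffold_b]]
    wb[ib[wb[ib] == 0L]] <- id
    winB[[s$scaffold_b]] <- wb
  }

  out <- list()
  for (id in seq_along(segments)) {
    s <- segments[[id]]
    cc <- segment_columns(s)
    okA <- is.na(cc$a_pos) | winA[[s$scaffold_a]][cc$a_pos + 1L] == id
    okB <- is.na(cc$b_pos) | winB[[s$scaffold_b]][cc$b_pos + 1L] == id
    keep <- okA & okB
    if (!any(keep)) next
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values)) {
      i0 <- starts[ri]; i1 <- ends[ri]
      ## trim to match/mismatch columns at both ends
      sub <- i0:i1
      mm <- sub[cc$op[sub] <= 1L]
      if (!length(mm)) next
      i0 <- mm[1]; i1 <- mm[length(mm)]
      a0 <- cc$a_pos[i0]; a1 <- cc$a_pos[i1]
      if (a1 + 1L - a0 < min_segment_length) next
      opv <- cc$op[i0:i1]
      rl <- rle(opv)
      st <- segment_stats(rl$values, rl$lengths)
      if (s$orientation == "forward") {
        b0 <- cc$b_pos[i0]; b1 <- cc$b_pos[i1] + 1L
      } else {
        b0 <- cc$b_pos[i1]; b1 <- cc$b_pos[i0] + 1L
      }
      out[[length(out) + 1L]] <- c(list(
        scaffold_a = s$scaffold_a, start_a = a0, end_a = a1 + 1L,
        scaffold_b = s$scaffold_b, start_b = b0, end_b = b1,
        orientation = s$orientation, op = rl$values, len = rl$lengths,
        score = segment_score(rl$values, rl$lengths)), st)
    }
  }
  new_segments(out, seqlens)
}

#' Arithmetic constructor for a pairing summary
#'
#' Computes the derived coverage and density statistics from supplied
#' totals, the same arithmetic [summarize_pairing()] applies to
#' measured segments.  Lengths count scaffold bases on both sides of
#' each alignment; mismatch and indel totals follow the same
#' both-sides convention.
#'
#' @param genome_length total assembly length (bp).
#' @param paired_length bases covered by retained segments (bp).
#' @param mismatches mismatched bases within paired regions.
#' @param indel_events indel events within paired regions.
#' @param n_segments number of retained segments.
#' @return an object of class `pairing_summary`.
#' @export
pairing_summary <- function(genome_length, paired_length, mismatches,
                            indel_events, n_segments = NA_integer_) {
  if (genome_length <= 0) stop("genome length must be positive")
  undefined <- paired_length == 0
  structure(list(
    genome_length = genome_length,
    paired_length = paired_length,
    coverage_fraction = paired_length / genome_length,
    total_mismatches = mismatches,
    total_indel_events = indel_events,
    heterozygosity_pct = if (undefined) 0 else 100 * mismatches / paired_length,
    indel_pct = if (undefined) 0 else 100 * indel_events / paired_length,
    n_segments = n_segments,
    undefined = undefined), class = "pairing_summary")
}

#' Summarize a reciprocal-best tiling
#'
#' @param segments a tiled `paired_segments` object.
#' @param scaffolds the assembly the segments were computed on.
#' @return a `pairing_summary`; see [pairing_summary()] for the
#'   conventions.
#' @export
summarize_pairing <- function(segments, scaffolds) {
  seqs <- as_seq_vector(scaffolds)
  genome_length <- sum(nchar(seqs))
  df <- as.data.frame(segments)
  paired_length <- sum(df$end_a - df$start_a) + sum(df$end_b - df$start_b)
  pairing_summary(genome_length, paired_length,
                  mismatches = 2 * sum(df$n_mismatch),
                  indel_events = 2 * sum(df$indel_events),
                  n_segments = nrow(df))
}

#' @export
print.pairing_summary <- function(x, ...) {
  cat(sprintf("pairing summary: %d segment(s)\n", x$n_segments))
  cat(sprintf("  genome %s bp; paired %s bp (%.1f%%)\n",
              format(x$genome_length, big.mark = ","),
              format(x$paired_length, big.mark = ","),
              100 * x$coverage_fraction))
  cat(sprintf("  mismatches %s (%.1f%%); indel events %s (%.2f%%)\n",
              format(x$total_mismatches, big.mark = ","),
              x$heterozygosity_pct,
              format(x$total_indel_events, big.mark = ","), x$indel_pct))
  invisible(x)
}

#' Run the full pairing stage
#'
#' Convenience wrapper: anchors, chains, refinement and
#' reciprocal-best tiling with the default desk-scale parameters.
#'
#' @param scaffolds assembly (named character vector, DNAStringSet or
#'   FASTA path).
#' @param k seed length.
#' @param max_seed_multiplicity repeat-suppression threshold.
#' @param max_gap chaining gap bound (bp).
#' @param min_chain_anchors minimum anchors per chain.
#' @param band alignment band half-width (bp).
#' @param min_segment_length minimum retained segment span (bp).
#' @return a tiled `paired_segments` object.
#' @export
pair_scaffolds <- function(scaffolds, k = 15L, max_seed_multiplicity = 10L,
                           max_gap = 500L, min_chain_anchors = 3L,
                           band = 32L, min_segment_length = 200L) {
  anchors <- build_anchor_map(scaffolds, k, max_seed_multiplicity)
  chains <- chain_anchors(anchors, max_gap, min_chain_anchors)
  segs <- refine_segments(chains, scaffolds, band)
  reciprocal_best_tiling(segs, min_segment_length)
}

#' Write segments as TSV
#' @param segments a `paired_segments` object.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_segments <- function(segments, path) {
  write_tsv(as.data.frame(segments), path)
}
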