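## Shared helpers and independent oracles for the test suite.

DNA <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

## Independent point-mutation helper (per-base substitution, insertion
## and deletion), used to build test pairs without the package's own
## generator.
mutate_seq <- function(s, sub = 0.05, indel = 0) {
  v <- strsplit(s, "")[[1]]
  out <- character(0)
  for (ch in v) {
    r <- runif(1)
    if (r < indel / 2) next
    if (r < indel) { out <- c(out, ch, sample(DNA, 1)); next }
    if (r < indel + sub) out <- c(out, sample(setdiff(DNA, ch), 1))
    else out <- c(out, ch)
  }
  paste(out, collapse = "")
}

## Build a paired_segments object from explicit fields (op codes:
## 0 match, 1 mismatch, 2 insertion in B, 3 deletion from A).
make_segments <- function(specs, seqlens) {
  segs <- lapply(specs, function(sp) {
    op <- sp$op; len <- sp$len
    opv <- rep.int(op, len)
    gap_runs <- function(code) sum(op == code)
    span_a <- sum(len[op != 2L])
    span_b <- sum(len[op != 3L])
    score <- sum(len[op == 0L]) - sum(len[op == 1L]) +
      sum(-2L - (len[op %in% c(2L, 3L)] - 1L))
    c(list(scaffold_a = sp$scaffold_a, start_a = as.integer(sp$start_a),
           scaffold_b = sp$scaffold_b, start_b = as.integer(sp$start_b),
           orientation = sp$orientation),
      list(end_a = as.integer(sp$start_a + span_a),
           end_b = as.integer(sp$start_b + span_b),
           op = op, len = len, score = score,
           n_match = sum(len[op == 0L]), n_mismatch = sum(len[op == 1L]),
           n_ins_events = gap_runs(2L), n_del_events = gap_runs(3L)))
  })
  structure(segs, class = "paired_segments", seqlengths = seqlens)
}

## Brute-force per-base reciprocal-best assignment: for every A and B
## base independently, the covering segment with the best score
## density wins (ties: more columns, then lower index).  Returns, for
## each segment, the logical per-column keep mask.
tiling_oracle <- function(segments, min_segment_length = 200L) {
  seqlens <- attr(segments, "seqlengths")
  spans <- vapply(segments, function(s) s$end_a - s$start_a, numeric(1))
  segments <- segments[spans >= min_segment_length]
  dens <- vapply(segments, function(s) s$score / sum(s$len), numeric(1))
  cols <- vapply(segments, function(s) sum(s$len), numeric(1))
  rank_of <- order(-dens, -cols, seq_along(segments))
  prio <- integer(length(segments)); prio[rank_of] <- seq_along(segments)
  winA <- lapply(seqlens, function(n) rep(Inf, n))
  winB <- lapply(seqlens, function(n) rep(Inf, n))
  for (id in seq_along(segments)) {
    s <- segments[[id]]
    ia <- (s$start_a + 1):s$end_a
    winA[[s$scaffold_a]][ia] <- pmin(winA[[s$scaffold_a]][ia], prio[id])
    ib <- (s$start_b + 1):s$end_b
    winB[[s$scaffold_b]][ib] <- pmin(winB[[s$scaffold_b]][ib], prio[id])
  }
  lapply(seq_along(segments), function(id) {
    s <- segments[[id]]
    cc <- segment_columns(s)
    okA <- is.na(cc$a_pos) | winA[[s$scaffold_a]][cc$a_pos + 1] == prio[id]
    okB <- is.na(cc$b_pos) | winB[[s$scaffold_b]][cc$b_pos + 1] == prio[id]
    okA & okB
  })
}

## Independent NG86 oracle: synonymous site fraction per codon and
## path-averaged substitution classification, written as plain
## recursion over the genetic code (Biostrings' table).
oracle_syn_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  total <- 0
  for (p in 1:3) {
    nsyn <- 0
    for (alt in setdiff(DNA, substr(codon, p, p))) {
      m <- codon; substr(m, p, p) <- alt
      if (gc[[m]] == gc[[codon]]) nsyn <- nsyn + 1
    }
    total <- total + nsyn / 3
  }
  total
}

oracle_path_counts <- function(ca, cb) {
  gc <- Biostrings::GENETIC_CODE
  d <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(d) == 0) return(c(sd = 0, nd = 0))
  rec <- function(cur, remaining) {
    if (length(remaining) == 0) return(list(c(0, 0)))
    res <- list()
    for (i in seq_along(remaining)) {
      p <- remaining[i]
      nxt <- cur; substr(nxt, p, p) <- substr(cb, p, p)
      step <- if (gc[[cur]] == gc[[nxt]]) c(1, 0) else c(0, 1)
      for (tail in rec(nxt, remaining[-i]))
        res[[length(res) + 1]] <- step + tail
    }
    res
  }
  paths <- rec(ca, d)
  avg <- Reduce(`+`, paths) / length(paths)
  c(sd = avg[1], nd = avg[2])
}

## Independent codon-unit global alignment score (same scoring model
## as align_cds_pair), plain recursive DP over codon indices.
oracle_codon_score <- function(a, b) {
  split_codons <- function(s) {
    if (nchar(s) == 0) return(character(0))
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  ca <- split_codons(a)
  cb <- split_codons(b)
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -4 - (i - 1)
  for (j in seq_len(m)) Y[1, j + 1] <- -4 - (j - 1)
  pair_score <- function(x, y) {
    xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
    sum(ifelse(xs == ys, 1, -1))
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- pair_score(ca[i], cb[j])
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - 4, X[i, j + 1] - 1)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - 4, Y[i + 1, j] - 1)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## Score of a codon alignment's gapped strings under the same model.
codon_alignment_score <- function(aligned_a, aligned_b) {
  n <- nchar(aligned_a) / 3
  ca <- substring(aligned_a, 3 * seq_len(n) - 2, 3 * seq_len(n))
  cb <- substring(aligned_b, 3 * seq_len(n) - 2, 3 * seq_len(n))
  sc <- 0; last_gap <- ""
  for (i in seq_len(n)) {
    gap <- if (ca[i] == "---") "a" else if (cb[i] == "---") "b" else ""
    if (nzchar(gap)) {
      sc <- sc + if (identical(gap, last_gap)) -1 else -4
    } else {
      xs <- strsplit(ca[i], "")[[1]]; ys <- strsplit(cb[i], "")[[1]]
      sc <- sc + sum(ifelse(xs == ys, 1, -1))
    }
    last_gap <- gap
  }
  sc
}
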