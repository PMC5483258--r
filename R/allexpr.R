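#' Fragments per kilobase of transcript per million fragments
#'
#' @param count fragment count(s).
#' @param length transcript (CDS) length in bp.
#' @param total_fragments total mapped fragments in the library.
#' @return FPKM value(s).
#' @export
compute_fpkm <- function(count, length, total_fragments) {
  if (any(length <= 0)) stop("length must be positive")
  if (any(total_fragments <= 0)) stop("total_fragments must be positive")
  count / ((length / 1000) * (total_fragments / 1e6))
}

#' Build allelic expression records for gene pairs
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param expression data.frame with columns `gene_id`, `cds_length`,
#'   `count`.
#' @param total_fragments total mapped fragments; defaults to the sum
#'   of all counts in `expression`.
#' @return data.frame of records: CDS lengths, counts, FPKM values,
#'   ordered low/high FPKM, fold ratio (NA when the lower FPKM is 0)
#'   and nested fold bins (>1.5, >2, >5).
#' @export
allelic_expression_records <- function(pairs, expression,
                                       total_fragments = sum(expression$count)) {
  ia <- match(pairs$gene_a, expression$gene_id)
  ib <- match(pairs$gene_b, expression$gene_id)
  if (anyNA(ia) || anyNA(ib)) stop("pair gene(s) missing from expression table")
  rec <- data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    cds_len_a = expression$cds_length[ia],
    cds_len_b = expression$cds_length[ib],
    count_a = expression$count[ia], count_b = expression$count[ib],
    stringsAsFactors = FALSE)
  rec$fpkm_a <- compute_fpkm(rec$count_a, rec$cds_len_a, total_fragments)
  rec$fpkm_b <- compute_fpkm(rec$count_b, rec$cds_len_b, total_fragments)
  rec$fpkm_low <- pmin(rec$fpkm_a, rec$fpkm_b)
  rec$fpkm_high <- pmax(rec$fpkm_a, rec$fpkm_b)
  rec$fold_ratio <- ifelse(rec$fpkm_low > 0, rec$fpkm_high / rec$fpkm_low,
                           NA_real_)
  rec$gt1.5 <- !is.na(rec$fold_ratio) & rec$fold_ratio > 1.5
  rec$gt2 <- !is.na(rec$fold_ratio) & rec$fold_ratio > 2
  rec$gt5 <- !is.na(rec$fold_ratio) & rec$fold_ratio > 5
  rec
}

#' Filter gene pairs comparable by CDS length
#'
#' Keeps pairs whose CDS lengths differ by strictly less than
#' `max_length_difference` bp.
#'
#' @param pairs data.frame with columns `cds_len_a`, `cds_len_b` (for
#'   example from [allelic_expression_records()]).
#' @param max_length_difference bp threshold (default 100).
#' @return the filtered data.frame.
#' @export
select_comparable_pairs <- function(pairs, max_length_difference = 100L) {
  pairs[abs(pairs$cds_len_a - pairs$cds_len_b) < max_length_difference, ,
        drop = FALSE]
}

#' Compare allelic expression across pairs
#'
#' Counts pairs in the nested fold bins (>1.5, >2, >5), reports pairs
#' with one silent allele (lower FPKM of 0, undefined ratio)
#' separately, and computes Pearson's correlation of the higher versus
#' the lower FPKM over pairs where both alleles are expressed.
#'
#' @param records result of [allelic_expression_records()].
#' @return list with `n`, `bins` (named cumulative counts),
#'   `n_undefined_ratio`, `n_both_zero`, `correlation`, `p_value`
#'   (both NA when fewer than 3 expressed pairs) and `scatter`
#'   (low/high FPKM table of the expressed pairs).
#' @export
compare_pairs <- function(records) {
  defined <- records$fpkm_low > 0
  undef <- records$fpkm_low == 0 & records$fpkm_high > 0
  both_zero <- records$fpkm_low == 0 & records$fpkm_high == 0
  bins <- c("gt1.5" = sum(records$gt1.5), "gt2" = sum(records$gt2),
            "gt5" = sum(records$gt5))
  scatter <- data.frame(low = records$fpkm_low[defined],
                        high = records$fpkm_high[defined])
  if (sum(defined) >= 3 && stats::sd(scatter$low) > 0 &&
      stats::sd(scatter$high) > 0) {
    ct <- stats::cor.test(scatter$low, scatter$high, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  } else { r <- NA_real_; p <- NA_real_ }
  list(n = nrow(records), bins = bins,
       n_undefined_ratio = sum(undef), n_both_zero = sum(both_zero),
       correlation = r, p_value = p, scatter = scatter)
}
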