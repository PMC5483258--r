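trim_polya_tail <- function(x, min_run = 8L) {
  sub(sprintf("A{%d,}$", min_run), "", x)
}

#' Greedy incremental clustering of 3'-EST tags
#'
#' Processes tags in input order.  Each tag is locally aligned
#' (match +1, mismatch -1, affine gaps -2/-1) against existing clusters
#' in creation order and joins the first cluster with a qualifying
#' match: best local alignment identity (matches / aligned columns) at
#' least `identity_threshold` over at least `min_overlap` aligned
#' columns.  Otherwise it founds a new cluster.  In
#' `compare_mode = "all_members"` every prior member is a possible
#' match (single-linkage behaviour); `"representative"` compares only
#' against each cluster's founding member.  `join = "best"` joins the
#' cluster with the highest qualifying identity instead of the first.
#'
#' @param tags named character vector (or DNAStringSet / FASTA path)
#'   of tag sequences, in processing order.
#' @param identity_threshold minimum identity (default 0.90).
#' @param min_overlap minimum aligned columns (default 50).
#' @param compare_mode `"all_members"` or `"representative"`.
#' @param join `"first"` or `"best"`.
#' @param trim_polya trim terminal runs of 8 or more A's before
#'   comparison.
#' @return an object of class `tag_clusters`: a list of clusters, each
#'   with `cluster_id` (creation order), `representative` (first
#'   member) and `members`.
#' @export
greedy_cluster <- function(tags, identity_threshold = 0.90,
                           min_overlap = 50L,
                           compare_mode = c("all_members", "representative"),
                           join = c("first", "best"),
                           trim_polya = TRUE) {
  compare_mode <- match.arg(compare_mode)
  join <- match.arg(join)
  tags <- as_seq_vector(tags)
  if (length(tags) == 0) stop("no tags supplied")
  work <- if (trim_polya) vapply(tags, trim_polya_tail, character(1)) else
    unname(tags)
  nonempty <- nchar(work) > 0
  if (!all(nonempty))
    warning("empty tag(s) skipped: ",
            paste(utils::head(names(tags)[!nonempty], 5), collapse = ", "))
  ids <- cpp_greedy_cluster(work[nonempty], identity_threshold,
                            as.integer(min_overlap),
                            compare_mode == "all_members", join == "best")
  kept <- names(tags)[nonempty]
  out <- lapply(seq_len(max(ids, 0L)), function(ci) {
    mem <- kept[ids == ci]
    list(cluster_id = ci, representative = mem[1], members = mem)
  })
  structure(out, class = "tag_clusters")
}

#' @method as.data.frame tag_clusters
#' @export
as.data.frame.tag_clusters <- function(x, ...) {
  do.call(rbind, lapply(x, function(cl) data.frame(
    tag_id = cl$members, cluster_id = cl$cluster_id,
    stringsAsFactors = FALSE)))
}

#' @export
print.tag_clusters <- function(x, ...) {
  sizes <- vapply(x, function(cl) length(cl$members), integer(1))
  cat("tag_clusters:", length(x), "cluster(s) over", sum(sizes), "tag(s)\n")
  cat("  sizes:", paste(utils::head(sizes, 20), collapse = " "),
      if (length(sizes) > 20) "..." else "", "\n")
  invisible(x)
}

#' Agreement between a clustering and a truth partition
#'
#' Pair-counting agreement: the Rand index, its chance-adjusted form,
#' and per-family purity (largest fraction of a true family kept in a
#' single cluster).
#'
#' @param clusters a [greedy_cluster()] result.
#' @param truth data.frame with columns `tag_id`, `family_id` covering
#'   every clustered tag.
#' @return list with `n_clusters`, `rand`, `adjusted_rand`,
#'   `per_family_purity`.
#' @export
cluster_metrics <- function(clusters, truth) {
  memb <- as.data.frame(clusters)
  idx <- match(memb$tag_id, truth$tag_id)
  if (anyNA(idx))
    stop("tag(s) missing from truth: ",
         paste(head(memb$tag_id[is.na(idx)], 5), collapse = ", "))
  fam <- truth$family_id[idx]
  cl <- memb$cluster_id
  tab <- table(cl, fam)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  rand <- (total + 2 * sum_ij - sum_i - sum_j) / total
  exp_ij <- sum_i * sum_j / total
  max_ij <- (sum_i + sum_j) / 2
  adj <- if (max_ij == exp_ij) 1 else (sum_ij - exp_ij) / (max_ij - exp_ij)
  purity <- apply(tab, 2, function(col) max(col) / sum(col))
  list(n_clusters = length(clusters), rand = rand, adjusted_rand = adj,
       per_family_purity = purity)
}
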