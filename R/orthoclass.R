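#' Classify ortholog groups into allelic-pair categories
#'
#' Applies the doubleton/singleton/family scheme to two-species
#' ortholog groups: with `n_a` focal-species members and `n_b`
#' reference-species members, a group is `2:1` (an allelic pair with a
#' single reference ortholog), `2:2+`, `3+:N` (gene family with
#' reference orthologs), `1:1+`, `2:0`, `3+:0`, or `1:0`.  The two
#' focal members of any `n_a = 2` group are taken as the allelic pair.
#'
#' @param groups data.frame with columns `group_id`, `species` (`"A"`
#'   focal, `"B"` reference) and `gene_id`, or a path to such a TSV.
#' @param singles character vector of focal genes in no group
#'   (classified `1:0`).
#' @return data.frame with one row per group: `group_id`, `category`,
#'   `n_a`, `n_b`, and for doubleton groups the allelic pair
#'   (`pair_gene1`, `pair_gene2`).
#' @export
classify_groups <- function(groups, singles = character(0)) {
  if (is.character(groups) && length(groups) == 1) groups <- read_tsv(groups)
  stopifnot(all(c("group_id", "species", "gene_id") %in% names(groups)))
  if (!all(groups$species %in% c("A", "B")))
    stop("species must be 'A' (focal) or 'B' (reference)")
  focal <- groups[groups$species == "A", , drop = FALSE]
  dup <- unique(focal$gene_id[duplicated(focal$gene_id)])
  if (length(dup))
    stop("gene(s) present in more than one group: ",
         paste(head(dup, 5), collapse = ", "))
  both <- intersect(focal$gene_id, singles)
  if (length(both))
    stop("gene(s) listed both in a group and as singles: ",
         paste(head(both, 5), collapse = ", "))

  ids <- unique(groups$group_id)
  rows <- lapply(ids, function(g) {
    sub <- groups[groups$group_id == g, , drop = FALSE]
    ga <- sub$gene_id[sub$species == "A"]
    n_a <- length(ga); n_b <- sum(sub$species == "B")
    data.frame(group_id = as.character(g),
               category = ortholog_category(n_a, n_b),
               n_a = n_a, n_b = n_b,
               pair_gene1 = if (n_a == 2) sort(ga)[1] else NA_character_,
               pair_gene2 = if (n_a == 2) sort(ga)[2] else NA_character_,
               stringsAsFactors = FALSE)
  })
  single_rows <- lapply(singles, function(g)
    data.frame(group_id = g, category = "1:0", n_a = 1L, n_b = 0L,
               pair_gene1 = NA_character_, pair_gene2 = NA_character_,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, c(rows, single_rows))
  if (is.null(out))
    out <- data.frame(group_id = character(0), category = character(0),
                      n_a = integer(0), n_b = integer(0),
                      pair_gene1 = character(0), pair_gene2 = character(0))
  out
}

#' Category of an (n_a, n_b) ortholog group
#'
#' Pure function from member counts to category label.
#'
#' @param n_a,n_b focal and reference member counts (at least one
#'   positive).
#' @return one of `"2:1"`, `"2:2+"`, `"3+:N"`, `"1:1+"`, `"2:0"`,
#'   `"3+:0"`, `"1:0"`.
#' @export
ortholog_category <- function(n_a, n_b) {
  stopifnot(length(n_a) == 1, length(n_b) == 1, n_a >= 0, n_b >= 0,
            n_a + n_b > 0)
  if (n_a == 2 && n_b == 1) "2:1"
  else if (n_a == 2 && n_b >= 2) "2:2+"
  else if (n_a >= 3 && n_b >= 1) "3+:N"
  else if (n_a == 1 && n_b >= 1) "1:1+"
  else if (n_a == 2 && n_b == 0) "2:0"
  else if (n_a >= 3 && n_b == 0) "3+:0"
  else if (n_a == 1 && n_b == 0) "1:0"
  else if (n_a == 0) "0:N"   # reference-only group, no focal genes
  else stop("unreachable")
}

#' Summarize an ortholog classification
#'
#' @param classifications result of [classify_groups()].
#' @return an object of class `ortholog_summary`: per-category gene and
#'   pair/group counts, plus `pairs_total` (groups with two focal
#'   members), `singletons_total`, `group_genes_total` (focal genes in
#'   families of three or more) and `total_genes`.
#' @export
summarize_categories <- function(classifications) {
  cl <- classifications
  cats <- c("2:1", "2:2+", "3+:N", "1:1+", "2:0", "3+:0", "1:0")
  per <- lapply(cats, function(cat) {
    sub <- cl[cl$category == cat, , drop = FALSE]
    list(genes = sum(sub$n_a), groups = nrow(sub))
  })
  names(per) <- cats
  pairs_total <- sum(cl$n_a == 2)
  singletons_total <- per[["1:1+"]]$groups + per[["1:0"]]$groups
  group_genes_total <- sum(cl$n_a[cl$n_a >= 3])
  structure(list(
    per_category = per,
    pairs_total = pairs_total,
    singletons_total = singletons_total,
    group_genes_total = group_genes_total,
    total_genes = sum(cl$n_a)), class = "ortholog_summary")
}

#' @export
print.ortholog_summary <- function(x, ...) {
  cat("ortholog classification summary\n")
  for (cat_ in names(x$per_category))
    cat(sprintf("  %-6s %6d genes in %d group(s)\n", cat_,
                x$per_category[[cat_]]$genes, x$per_category[[cat_]]$groups))
  cat(sprintf("  allelic pairs %d, singletons %d, family genes %d, total %d\n",
              x$pairs_total, x$singletons_total, x$group_genes_total,
              x$total_genes))
  cat(sprintf("  conventional diploid gene number: %d\n",
              estimate_gene_number(x)))
  invisible(x)
}

#' Diploid gene-number estimate
#'
#' Under the assumption that all genes except singletons exist as
#' allelic pairs, the gene number of the conventional (collapsed)
#' diploid genome is `pairs + singletons + family_genes / 2`, the half
#' rounded up.
#'
#' @param summary an `ortholog_summary`, or the number of allelic
#'   pairs (then supply `singletons` and `group_genes` too).
#' @param singletons,group_genes counts, when `summary` is numeric.
#' @return integer gene-number estimate.
#' @export
estimate_gene_number <- function(summary, singletons = NULL,
                                 group_genes = NULL) {
  if (inherits(summary, "ortholog_summary")) {
    p <- summary$pairs_total; s <- summary$singletons_total
    g <- summary$group_genes_total
  } else {
    p <- summary; s <- singletons; g <- group_genes
  }
  as.integer(p + s + floor(g / 2 + 0.5))
}
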