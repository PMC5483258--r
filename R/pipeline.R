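PIPELINE_STAGES <- c("simulate", "pair", "stats", "classify", "expr",
                     "divergence", "estclust", "kmers")

stage_deps <- list(
  simulate = character(0), pair = "simulate", stats = "pair",
  classify = "simulate", expr = c("simulate", "classify"),
  divergence = c("simulate", "classify"), estclust = "simulate",
  kmers = "simulate")

## Reference-side ortholog table for a simulated truth: every allelic
## A/B gene pair forms one 2:1 group with one synthetic reference gene.
truth_ortholog_table <- function(truth) {
  gA <- truth$genes[truth$genes$haplotype == "A", , drop = FALSE]
  if (nrow(gA) == 0)
    return(data.frame(group_id = character(0), species = character(0),
                      gene_id = character(0)))
  gid <- sprintf("grp_%04d", seq_len(nrow(gA)))
  data.frame(
    group_id = rep(gid, 3),
    species = rep(c("A", "A", "B"), each = nrow(gA)),
    gene_id = c(gA$gene_id, gA$partner, sprintf("ref_%04d", seq_len(nrow(gA)))),
    stringsAsFactors = FALSE)
}

#' Run the analysis pipeline on a simulated diploid
#'
#' Orchestrates the stages (simulate, pair, stats, classify, expr,
#' divergence, estclust, kmers) with dependency checking, writing
#' per-stage files when `outdir` is given, and assembles a consolidated
#' report.  Report totals are copies of the stage outputs, never
#' recomputations.
#'
#' @param config a [sim_config()]; its seed drives every stage through
#'   named substreams.
#' @param stages character vector of stage names, or `"all"`.
#' @param outdir optional output directory for per-stage files.
#' @return an object of class `pipeline_report`.
#' @export
run_pipeline <- function(config, stages = "all", outdir = NULL) {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (st in stages) {
    miss <- setdiff(stage_deps[[st]], stages)
    if (length(miss))
      stop("stage '", st, "' requires stage(s): ",
           paste(miss, collapse = ", "))
  }
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  out_path <- function(f) if (is.null(outdir)) NULL else file.path(outdir, f)

  report <- list(schema_version = 1L, seed = config$seed, stages = stages)
  st <- list()  # stage results

  if ("simulate" %in% stages) {
    st$truth <- generate_truth(config)
    if (!is.null(outdir))
      emit_assembly(st$truth, fasta = out_path("assembly.fasta"),
                    gff3 = out_path("annotation.gff3"))
    report$simulate <- list(
      n_scaffolds = length(st$truth$haplotype_a),
      genome_length = sum(nchar(st$truth$haplotype_a)) +
        sum(nchar(st$truth$haplotype_b)),
      n_genes = nrow(st$truth$genes),
      n_snvs = sum(st$truth$variants$type == "SNV"),
      n_indel_events = sum(st$truth$variants$type != "SNV"),
      n_structural = nrow(st$truth$structural))
  }
  if ("pair" %in% stages) {
    scaffolds <- c(st$truth$haplotype_a, st$truth$haplotype_b)
    st$segments <- pair_scaffolds(scaffolds)
    st$pair_summary <- summarize_pairing(st$segments, scaffolds)
    if (!is.null(outdir)) {
      write_segments(st$segments, out_path("segments.tsv"))
      jsonlite::write_json(unclass(st$pair_summary),
                           out_path("pairing_summary.json"),
                           auto_unbox = TRUE, digits = 10)
    }
    report$pairing <- unclass(st$pair_summary)
  }
  if ("stats" %in% stages) {
    st$vt <- variant_totals(st$segments)
    genesA <- st$truth$genes[st$truth$genes$haplotype == "A", , drop = FALSE]
    st$cd <- class_densities(st$segments, genesA)
    st$tracks <- window_tracks(st$segments)
    st$calls <- structural_events(st$segments)
    if (!is.null(outdir)) {
      write_tsv(st$cd$classes, out_path("class_densities.tsv"))
      if (!is.null(st$cd$genes))
        write_tsv(st$cd$genes, out_path("gene_densities.tsv"))
      write_wiggle(st$tracks, out_path("mismatch_windows.wig"))
      write_indel_bed(st$tracks, out_path("indels.bed"))
      write_tsv(st$calls, out_path("structural_calls.tsv"))
    }
    report$variants <- st$vt
    report$class_densities <- st$cd$classes
    report$structural_calls <- nrow(st$calls)
  }
  if ("classify" %in% stages) {
    ortho <- truth_ortholog_table(st$truth)
    st$classification <- classify_groups(ortho)
    st$class_summary <- summarize_categories(st$classification)
    if (!is.null(outdir))
      write_tsv(st$classification, out_path("ortholog_classes.tsv"))
    report$classification <- list(
      pairs_total = st$class_summary$pairs_total,
      singletons_total = st$class_summary$singletons_total,
      group_genes_total = st$class_summary$group_genes_total,
      total_genes = st$class_summary$total_genes,
      gene_number_estimate = estimate_gene_number(st$class_summary))
  }
  if ("expr" %in% stages) {
    ex <- simulate_expression(st$truth, config)
    pairs <- st$classification[!is.na(st$classification$pair_gene1),
                               c("pair_gene1", "pair_gene2")]
    names(pairs) <- c("gene_a", "gene_b")
    rec <- allelic_expression_records(pairs, data.frame(
      gene_id = ex$table$gene_id, cds_length = ex$table$cds_length,
      count = ex$table$count, stringsAsFactors = FALSE),
      total_fragments = ex$total_fragments)
    rec <- select_comparable_pairs(rec)
    cmp <- compare_pairs(rec)
    if (!is.null(outdir)) {
      write_tsv(rec, out_path("allelic_expression.tsv"))
      write_tsv(cmp$scatter, out_path("expression_scatter.tsv"))
    }
    report$expression <- cmp[c("n", "bins", "n_undefined_ratio",
                               "n_both_zero", "correlation", "p_value")]
  }
  if ("divergence" %in% stages) {
    pairs <- st$classification[!is.na(st$classification$pair_gene1),
                               c("pair_gene1", "pair_gene2")]
    names(pairs) <- c("gene_a", "gene_b")
    real <- pairs$gene_a %in% st$truth$genes$gene_id &
      pairs$gene_b %in% st$truth$genes$gene_id
    pairs <- pairs[real, , drop = FALSE]
    cds <- gene_cds_sequences(st$truth,
                              unique(c(pairs$gene_a, pairs$gene_b)))
    dt <- divergence_table(cds, pairs)
    if (!is.null(outdir)) write_tsv(dt, out_path("divergence.tsv"))
    report$divergence <- list(
      n_pairs = nrow(dt),
      median_identity_overall_pct = median(dt$identity_overall_pct,
                                           na.rm = TRUE),
      median_identity_pos3_pct = median(dt$identity_pos3_pct, na.rm = TRUE),
      median_identity_fourfold_pct = median(dt$identity_fourfold_pct,
                                            na.rm = TRUE),
      median_dnds = median(dt$dnds_ratio, na.rm = TRUE),
      n_significant = sum(dt$p_value < 0.05, na.rm = TRUE))
  }
  if ("estclust" %in% stages) {
    est <- simulate_est_tags(st$truth, config)
    cl <- greedy_cluster(est$tags)
    met <- cluster_metrics(cl, est$truth)
    if (!is.null(outdir)) write_tsv(as.data.frame(cl), out_path("est_clusters.tsv"))
    report$est <- list(n_tags = length(est$tags),
                       n_clusters = met$n_clusters,
                       n_families = length(unique(est$truth$family_id)),
                       adjusted_rand = met$adjusted_rand)
  }
  if ("kmers" %in% stages) {
    rd <- simulate_reads(st$truth, config)
    spec <- count_kmers(rd$reads)
    fit <- fit_spectrum(spec)
    if (!is.null(outdir)) {
      write_tsv(spec$histogram, out_path("kmer_histogram.tsv"))
      jsonlite::write_json(unclass(fit)[c("mu_het", "mu_hom",
                                          "fraction_single_copy",
                                          "fraction_two_copy",
                                          "genome_size_estimate",
                                          "error_cutoff")],
                           out_path("spectrum_fit.json"),
                           auto_unbox = TRUE, digits = 10)
    }
    report$kmer <- list(mu_het = fit$mu_het, mu_hom = fit$mu_hom,
                        fraction_single_copy = fit$fraction_single_copy,
                        fraction_two_copy = fit$fraction_two_copy,
                        genome_size_estimate = fit$genome_size_estimate,
                        peak_ratio_unconstrained = fit$unconstrained$ratio,
                        single_component = fit$single_component)
  }
  structure(report, class = "pipeline_report")
}

#' Write a pipeline report as JSON and readable text
#'
#' @param report a [run_pipeline()] result.
#' @param json path for the JSON report.
#' @param text optional path for a human-readable summary laid out like
#'   an assembly-statistics table.
#' @return invisibly, the JSON path.
#' @export
write_report <- function(report, json, text = NULL) {
  jsonlite::write_json(unclass(report), json, auto_unbox = TRUE,
                       digits = 10, na = "null")
  if (!is.null(text)) {
    lines <- c("== pipeline report ==",
               paste0("seed: ", report$seed),
               paste0("stages: ", paste(report$stages, collapse = ", ")))
    if (!is.null(report$pairing)) {
      p <- report$pairing
      lines <- c(lines, "", "-- genome pairing --",
        sprintf("genome length       %15s", format(p$genome_length, big.mark = ",")),
        sprintf("paired regions      %15s (%.1f%%)",
                format(p$paired_length, big.mark = ","),
                100 * p$coverage_fraction),
        sprintf("SNVs                %15s (%.1f%%)",
                format(p$total_mismatches, big.mark = ","),
                p$heterozygosity_pct),
        sprintf("In/Dels             %15s (%.2f%%)",
                format(p$total_indel_events, big.mark = ","), p$indel_pct))
    }
    if (!is.null(report$classification)) {
      cl <- report$classification
      lines <- c(lines, "", "-- protein coding genes --",
        sprintf("allelic pairs       %8d", cl$pairs_total),
        sprintf("singletons          %8d", cl$singletons_total),
        sprintf("family genes        %8d", cl$group_genes_total),
        sprintf("total genes         %8d", cl$total_genes),
        sprintf("diploid gene number %8d", cl$gene_number_estimate))
    }
    if (!is.null(report$expression)) {
      e <- report$expression
      lines <- c(lines, "", "-- allelic expression --",
        sprintf("pairs compared      %8d", e$n),
        sprintf(">1.5 / >2 / >5 fold %8d / %d / %d",
                e$bins[["gt1.5"]], e$bins[["gt2"]], e$bins[["gt5"]]),
        sprintf("correlation         %8.3f", e$correlation))
    }
    writeLines(lines, text)
  }
  invisible(json)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (stages:", paste(x$stages, collapse = ", "), ")\n")
  invisible(x)
}
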