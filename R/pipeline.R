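# End-to-end orchestration: one configuration drives simulate/read -> QC ->
# profiles -> markers -> gradients -> spatial, with table exports and a
# structured summary.

#' Pipeline configuration
#'
#' Exactly one of `synthetic` (a [synthetic_spec()]) or `input_dir` (a
#' directory readable by [read_counts()] / [read_labels()]) must be given.
#'
#' @param synthetic A [synthetic_spec()] describing data to simulate.
#' @param input_dir Directory with counts, labels and AP order on disk.
#' @param qc [qc_thresholds()] applied before profiling.
#' @param normalization_total Profile normalization total (default 10000).
#' @param e_threshold Marker-list threshold on E (default 0.4).
#' @param min_expr Gradient expression filter (default 1.5).
#' @param transitions Transition list (default [germarium_transitions()]).
#' @param census,census_clusters,census_mapping Optional concordance inputs
#'   (defaults: the germarium census over clusters 0, 5, 1).
#' @param landmarks Optional [landmark_spec()] for AP ordering.
#' @param out_dir Optional directory; when given, every table is written as
#'   TSV.
#' @param seed Seed for the synthetic branch (overrides the seed inside
#'   `synthetic`).
#' @return An object of class `germ_config`.
#' @export
pipeline_config <- function(synthetic = NULL, input_dir = NULL,
                            qc = qc_thresholds(),
                            normalization_total = 10000,
                            e_threshold = 0.4, min_expr = 1.5,
                            transitions = germarium_transitions(),
                            census = germarium_census(),
                            census_clusters = c("0", "5", "1"),
                            census_mapping = c("0" = "r1_EC", "5" = "r2a_EC",
                                               "1" = "FSC"),
                            landmarks = NULL, out_dir = NULL, seed = NULL) {
  if (is.null(synthetic) == is.null(input_dir))
    stop("exactly one of 'synthetic' or 'input_dir' must be given", call. = FALSE)
  if (!is.null(synthetic) && !inherits(synthetic, "germ_synth_spec"))
    stop("'synthetic' must be a synthetic_spec()", call. = FALSE)
  if (!is.null(seed) && !is.null(synthetic)) {
    syn <- unclass(synthetic)
    syn$seed <- as.integer(seed)
    synthetic <- do.call(synthetic_spec, syn)
  }
  structure(list(synthetic = synthetic, input_dir = input_dir, qc = qc,
                 normalization_total = normalization_total,
                 e_threshold = e_threshold, min_expr = min_expr,
                 transitions = transitions, census = census,
                 census_clusters = census_clusters,
                 census_mapping = census_mapping,
                 landmarks = landmarks, out_dir = out_dir),
            class = "germ_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full germarium analysis pipeline
#'
#' Sequences data acquisition (simulation or reading), QC filtering,
#' cluster profiling and normalization, marker enrichment, the
#' transition-gradient classifier with both nulls, and (when its inputs are
#' present) census concordance and landmark-based AP ordering. Identical
#' configurations produce identical results.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `germ_pipeline` holding every intermediate
#'   (`counts_raw`, `counts_qc`, `labels`, `stats`, `profile`, `markers`,
#'   `transitions`, `categories`, `concordance`, `ordering`, `truth` for
#'   synthetic runs) plus a `summary` list and a `log` of per-stage counts.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "germ_config"))
    stop("'config' must come from pipeline_config()", call. = FALSE)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(config$synthetic)) {
    bundle <- run_stage("simulate", generate_germarium(config$synthetic))
    counts_raw <- bundle$counts; labels <- bundle$labels; truth <- bundle$truth
    note("simulate: %d genes x %d cells (seed %d)",
         nrow(counts_raw$counts), ncol(counts_raw$counts), config$synthetic$seed)
  } else {
    counts_raw <- run_stage("read", read_counts(config$input_dir))
    labels <- run_stage("read", read_labels(config$input_dir))
    truth <- NULL
    note("read: %d genes x %d cells from %s",
         nrow(counts_raw$counts), ncol(counts_raw$counts), config$input_dir)
  }

  counts_qc <- run_stage("qc", {
    m1 <- filter_genes(counts_raw, config$qc)
    note("qc genes: kept %d / %d (detected in > %d cells)",
         length(m1$gene_ids), length(counts_raw$gene_ids),
         config$qc$min_cells_per_gene)
    m2 <- filter_cells(m1, config$qc)
    note("qc cells: kept %d / %d (features %d-%d, mito < %g)",
         length(m2$barcodes), length(m1$barcodes), config$qc$min_features,
         config$qc$max_features, config$qc$max_mito_fraction)
    m2
  })
  labels_qc <- cluster_labeling(labels$assignment[counts_qc$barcodes],
                                labels$ap_order, labels$excluded)
  stats <- run_stage("stats", cell_stats(counts_qc, labels_qc))

  profile <- run_stage("profiles", {
    pr <- cluster_mean_profile(counts_qc, labels_qc)
    normalize_profile(pr, total = config$normalization_total)
  })
  note("profiles: %d genes x %d clusters, normalized to %g",
       nrow(profile$mean_raw), ncol(profile$mean_raw),
       config$normalization_total)

  markers <- run_stage("markers",
    marker_table(profile, counts_qc, labels_qc,
                 e_threshold = config$e_threshold))
  note("markers: %s genes above E > %g",
       paste(vapply(markers$markers, nrow, integer(1)), collapse = "/"),
       config$e_threshold)

  transitions <- run_stage("gradients",
    transition_table(profile, transitions = config$transitions,
                     min_expr = config$min_expr))
  categories <- run_stage("gradients", categorize(transitions))
  note("gradients: %d genes included, %d in each headline transition class",
       nrow(transitions), categories$n)

  concordance <- NULL
  if (!is.null(config$census) &&
      all(config$census_clusters %in% names(profile$cluster_sizes))) {
    concordance <- run_stage("spatial",
      proportion_concordance(profile$cluster_sizes, config$census_clusters,
                             config$census, config$census_mapping))
    note("spatial: TV distance to census %.3f", concordance$tv_distance)
  }
  ordering <- NULL
  if (!is.null(config$landmarks)) {
    ordering <- run_stage("spatial",
      order_clusters(profile, config$landmarks))
    note("spatial: AP order %s", paste(ordering$order, collapse = "-"))
  }

  res <- structure(list(
    config = config, counts_raw = counts_raw, counts_qc = counts_qc,
    labels = labels_qc, stats = stats, profile = profile, markers = markers,
    transitions = transitions, categories = categories,
    concordance = concordance, ordering = ordering, truth = truth,
    summary = list(
      n_genes_raw = length(counts_raw$gene_ids),
      n_cells_raw = length(counts_raw$barcodes),
      n_genes_qc = length(counts_qc$gene_ids),
      n_cells_qc = length(counts_qc$barcodes),
      per_cluster_depth = stats$per_cluster,
      marker_counts = vapply(markers$markers, nrow, integer(1)),
      category_counts = categories$counts,
      structural_expected = categories$structural$expected,
      empirical_expected = categories$empirical$expected,
      tv_distance = if (is.null(concordance)) NA_real_
                    else concordance$tv_distance
    ),
    log = log
  ), class = "germ_pipeline")
  if (!is.null(config$out_dir)) write_pipeline(res, config$out_dir)
  res
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pr <- res$profile
  mat_df <- function(m) data.frame(gene = rownames(m), m, check.names = FALSE)
  write_tsv(mat_df(pr$mean_raw), file.path(out_dir, "profile_mean_raw.tsv"))
  write_tsv(mat_df(pr$mean_norm), file.path(out_dir, "profile_mean_norm.tsv"))
  write_tsv(mat_df(pr$pct_detected), file.path(out_dir, "profile_pct_detected.tsv"))
  for (cl in names(res$markers$markers))
    write_tsv(res$markers$markers[[cl]],
              file.path(out_dir, sprintf("markers_cluster_%s.tsv", cl)))
  write_tsv(as.data.frame(res$transitions), file.path(out_dir, "transitions.tsv"))
  cc <- res$categories
  cat_df <- data.frame(
    category = paste(rep(rownames(cc$counts), 3),
                     rep(colnames(cc$counts), each = 3), sep = "-"),
    observed = as.vector(cc$counts),
    structural_expected = as.vector(cc$structural$expected),
    empirical_expected = as.vector(cc$empirical$expected))
  write_tsv(cat_df, file.path(out_dir, "categories.tsv"))
  write_tsv(res$stats$per_cluster, file.path(out_dir, "per_cluster_stats.tsv"))
  writeLines(res$log, file.path(out_dir, "pipeline_log.txt"))
  invisible(out_dir)
}

#' @export
print.germ_pipeline <- function(x, ...) {
  cat("Germarium pipeline result\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' @export
summary.germ_pipeline <- function(object, ...) {
  s <- object$summary
  cat(sprintf("Cells: %d -> %d after QC; genes: %d -> %d\n",
              s$n_cells_raw, s$n_cells_qc, s$n_genes_raw, s$n_genes_qc))
  cat("Per-cluster mean depth:\n")
  print(s$per_cluster_depth, row.names = FALSE)
  cat("Markers above threshold:",
      paste(names(s$marker_counts), s$marker_counts, sep = "=", collapse = ", "),
      "\n")
  cat("Category counts (first transition x second):\n")
  print(s$category_counts)
  if (!is.na(s$tv_distance))
    cat(sprintf("Census concordance TV distance: %.3f\n", s$tv_distance))
  invisible(s)
}
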