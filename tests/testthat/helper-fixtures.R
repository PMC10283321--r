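# Small fixtures built in code; full-size germaria are generated only where
# a test's claim concerns the study-scale conditions.

tiny_spec <- function(seed = 1L, ...) {
  args <- list(
    cluster_ids = c("A", "B", "C"),
    cells_per_cluster = c(60L, 40L, 50L),
    mean_depth_per_cluster = c(500, 800, 650),
    n_genes = 300L,
    fraction_marker_genes = 0.06,
    fraction_graded_genes = 0.06,
    mito_gene_count = 5L,
    seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_spec, args)
}

# A deterministic hand-made count matrix with known per-cell properties.
toy_counts <- function() {
  m <- rbind(
    "mt:a"   = c(1L, 0L, 5L, 0L),
    "gene-1" = c(2L, 3L, 0L, 0L),
    "gene-2" = c(0L, 1L, 1L, 0L),
    "gene-3" = c(4L, 0L, 2L, 0L)
  )
  colnames(m) <- paste0("c", 1:4)
  germ_counts(m)
}

# Build a normalized profile directly from a mean-expression matrix.
profile_from_matrix <- function(mean_raw, sizes = NULL, total = 10000) {
  sizes <- sizes %||% stats::setNames(rep(10L, ncol(mean_raw)), colnames(mean_raw))
  p <- structure(list(mean_raw = mean_raw, mean_norm = NULL,
                      pct_detected = 0 * mean_raw + 100,
                      cluster_sizes = sizes, ap_order = colnames(mean_raw)),
                 class = "germ_profile")
  normalize_profile(p, total = total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
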