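# Marker-gene enrichment: the pseudocounted log2 enrichment score E, ranked
# per-cluster marker tables with rank-sum p-values, and the table exports
# behind dot plots and row-scaled heat-maps.

#' Pseudocounted log2 enrichment score
#'
#' E = log2((1 + expr_in) / (1 + expr_out)), the statistic used to rank
#' genes by enrichment in one cluster relative to the average of all other
#' clusters. Strictly increasing in `expr_in`, strictly decreasing in
#' `expr_out`, and antisymmetric under swapping the two arguments.
#'
#' @param expr_in,expr_out Non-negative finite expression values
#'   (vectorized).
#' @return Numeric vector of enrichment scores (log2 units).
#' @export
enrichment_score <- function(expr_in, expr_out) {
  if (any(!is.finite(expr_in)) || any(!is.finite(expr_out)) ||
      any(expr_in < 0) || any(expr_out < 0))
    stop("expression values must be finite and non-negative", call. = FALSE)
  log2((1 + expr_in) / (1 + expr_out))
}

# Two-sided Wilcoxon rank-sum p-values for every gene, cluster vs all other
# cells, using the normal approximation with tie correction and continuity
# correction (the same approximation stats::wilcox.test applies for n > 50).
# Ranks and tie terms are computed once and shared across clusters.
ranksum_pvalues <- function(counts, cluster_of, clusters) {
  dense <- as.matrix(counts)
  n <- ncol(dense)
  ranks <- t(apply(dense, 1, rank))
  tie_term <- apply(dense, 1, function(v) {
    t <- tabulate(v + 1L)
    sum(t^3 - t)
  })
  out <- matrix(NA_real_, nrow(dense), length(clusters),
                dimnames = list(rownames(dense), clusters))
  for (j in seq_along(clusters)) {
    idx <- which(cluster_of == clusters[j])
    n1 <- length(idx)
    n2 <- n - n1
    u <- rowSums(ranks[, idx, drop = FALSE]) - n1 * (n1 + 1) / 2
    z <- u - n1 * n2 / 2
    sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1))))
    zc <- ifelse(sigma > 0, (z - sign(z) * 0.5) / sigma, 0)
    p <- 2 * pmin(stats::pnorm(zc), stats::pnorm(zc, lower.tail = FALSE))
    out[, j] <- ifelse(sigma > 0, pmin(1, p), 1)
  }
  out
}

#' Per-cluster marker enrichment table
#'
#' For each cluster X, computes the enrichment score E of every gene
#' (normalized mean in X vs the unweighted average of the normalized means
#' of all other clusters), detection percentages inside and outside X, a
#' two-sided Wilcoxon rank-sum p-value on the raw counts (cells of X vs all
#' other cells), and a Bonferroni-adjusted p-value. Genes with E strictly
#' above `e_threshold` form each cluster's ranked marker list (E descending,
#' ties broken by gene id).
#'
#' @param p A normalized `germ_profile` (see [normalize_profile()]).
#' @param m A [germ_counts] object sharing the profile's gene set (required
#'   for detection percentages and p-values; omit with `compute_p = FALSE`
#'   to work from the profile alone).
#' @param labels A [cluster_labeling()].
#' @param e_threshold Exclusive threshold on E for the marker lists
#'   (default 0.4).
#' @param expr_out_weighted If `TRUE`, weight the other clusters by cell
#'   count when averaging `expr_out` instead of the default unweighted mean
#'   over groups.
#' @param bonferroni Multiplicity universe: `"genes_by_clusters"` (default,
#'   genes tested x clusters) or `"genes"`.
#' @param compute_p Compute rank-sum p-values (requires `m` and `labels`).
#' @return An object of class `germ_markers`: `table` (one row per gene and
#'   cluster), `markers` (named list of per-cluster ranked data frames),
#'   `e_threshold` and `n_tests`.
#' @export
marker_table <- function(p, m = NULL, labels = NULL, e_threshold = 0.4,
                         expr_out_weighted = FALSE,
                         bonferroni = c("genes_by_clusters", "genes"),
                         compute_p = TRUE) {
  bonferroni <- match.arg(bonferroni)
  if (is.null(p$mean_norm))
    stop("profile must be normalized first (normalize_profile)", call. = FALSE)
  clusters <- p$ap_order
  if (length(clusters) < 2)
    stop("at least two clusters are required", call. = FALSE)
  genes <- rownames(p$mean_norm)
  if (compute_p || !is.null(m)) {
    if (is.null(m) || is.null(labels))
      stop("'m' and 'labels' are required unless compute_p = FALSE", call. = FALSE)
    if (!setequal(m$gene_ids, genes))
      stop("profile and count matrix gene sets differ", call. = FALSE)
  }

  ng <- length(genes)
  nc <- length(clusters)
  n_tests <- if (bonferroni == "genes_by_clusters") ng * nc else ng

  expr_in <- p$mean_norm
  expr_out <- matrix(0, ng, nc, dimnames = dimnames(expr_in))
  for (j in seq_len(nc)) {
    others <- setdiff(seq_len(nc), j)
    wts <- if (expr_out_weighted) p$cluster_sizes[others] else rep(1, length(others))
    expr_out[, j] <- as.vector(expr_in[, others, drop = FALSE] %*% (wts / sum(wts)))
  }
  e <- enrichment_score(expr_in, expr_out)

  pct_in <- p$pct_detected
  pct_out <- matrix(0, ng, nc, dimnames = dimnames(expr_in))
  pmat <- matrix(NA_real_, ng, nc, dimnames = dimnames(expr_in))
  if (!is.null(m)) {
    cl <- labels$assignment[m$barcodes]
    det <- m$counts[genes, , drop = FALSE] > 0
    for (j in seq_len(nc)) {
      out_cells <- which(cl != clusters[j] & cl %in% clusters)
      pct_out[, j] <- 100 * Matrix::rowSums(det[, out_cells, drop = FALSE]) /
        length(out_cells)
    }
    if (compute_p) {
      keep <- which(cl %in% clusters)
      pmat <- ranksum_pvalues(m$counts[genes, keep, drop = FALSE],
                              cl[keep], clusters)
    }
  }
  p_adj <- pmin(1, pmat * n_tests)

  tab <- data.frame(
    gene = rep(genes, nc),
    cluster = rep(clusters, each = ng),
    E = as.vector(e),
    expr_in = as.vector(expr_in),
    expr_out = as.vector(expr_out),
    pct_in = as.vector(pct_in),
    pct_out = as.vector(pct_out),
    p_raw = as.vector(pmat),
    p_adj = as.vector(p_adj),
    stringsAsFactors = FALSE
  )
  markers <- lapply(clusters, function(c) {
    s <- tab[tab$cluster == c & tab$E > e_threshold, , drop = FALSE]
    s[order(-s$E, s$gene), , drop = FALSE]
  })
  names(markers) <- clusters
  structure(list(table = tab, markers = markers, e_threshold = e_threshold,
                 n_tests = n_tests),
            class = "germ_markers")
}

#' @export
print.germ_markers <- function(x, ...) {
  counts <- vapply(x$markers, nrow, integer(1))
  cat(sprintf("Marker tables (E > %g): %s\n", x$e_threshold,
              paste(names(counts), counts, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Dot-plot table for a gene set
#'
#' Tidy per-(gene, cluster) table of normalized mean abundance and the
#' percentage of expressing cells — the two quantities shown as circle
#' color and size in cluster dot plots.
#'
#' @param p A normalized `germ_profile`.
#' @param genes Character vector of genes (empty gives an empty table).
#' @return Data frame with columns gene, cluster, mean_norm, pct_detected.
#' @export
dotplot_table <- function(p, genes) {
  if (is.null(p$mean_norm))
    stop("profile must be normalized first (normalize_profile)", call. = FALSE)
  unknown <- setdiff(genes, rownames(p$mean_norm))
  if (length(unknown) > 0)
    stop(sprintf("unknown gene(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  clusters <- p$ap_order
  data.frame(
    gene = rep(genes, each = length(clusters)),
    cluster = rep(clusters, length(genes)),
    mean_norm = as.vector(t(p$mean_norm[genes, , drop = FALSE])),
    pct_detected = as.vector(t(p$pct_detected[genes, , drop = FALSE])),
    stringsAsFactors = FALSE
  )
}

#' Row-scaled heat-map matrix
#'
#' Transforms each gene's expression across clusters to zero mean and unit
#' population standard deviation (rows scaled, as in the study's heat-maps).
#' Constant rows map to all zeros.
#'
#' @param p A normalized `germ_profile` with at least two clusters.
#' @param genes Genes to include (rows of the result).
#' @return Numeric matrix, genes x clusters, row-standardized.
#' @export
heatmap_matrix <- function(p, genes) {
  if (is.null(p$mean_norm))
    stop("profile must be normalized first (normalize_profile)", call. = FALSE)
  if (ncol(p$mean_norm) < 2)
    stop("at least two clusters are required", call. = FALSE)
  unknown <- setdiff(genes, rownames(p$mean_norm))
  if (length(unknown) > 0)
    stop(sprintf("unknown gene(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  x <- p$mean_norm[genes, , drop = FALSE]
  mu <- rowMeans(x)
  # population SD across clusters, not the sample SD
  sd_pop <- sqrt(rowMeans((x - mu)^2))
  z <- (x - mu) / ifelse(sd_pop > 0, sd_pop, 1)
  z[sd_pop == 0, ] <- 0
  z
}
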