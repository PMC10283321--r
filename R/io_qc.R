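# Count-matrix container, Matrix Market I/O and quality-control filters.

#' UMI count matrix container
#'
#' Holds a genes x cells matrix of non-negative integer UMI counts together
#' with unique gene identifiers, unique cell barcodes, and a mitochondrial
#' mask derived from gene-name prefixes (Drosophila convention "mt:").
#'
#' @param counts Genes x cells matrix (dense or sparse) of non-negative
#'   integers.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   the matrix rownames).
#' @param barcodes Character vector of unique cell barcodes (defaults to the
#'   matrix colnames).
#' @param mito_prefixes Gene-name prefixes identifying mitochondrial genes.
#' @return An object of class `germ_counts` with fields `counts` (sparse
#'   dgCMatrix), `gene_ids`, `barcodes`, `mito_mask`.
#' @export
germ_counts <- function(counts, gene_ids = rownames(counts),
                        barcodes = colnames(counts),
                        mito_prefixes = "mt:") {
  if (is.null(gene_ids) || is.null(barcodes))
    stop("gene_ids and barcodes are required", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  barcodes <- as.character(barcodes)
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(barcodes))
    stop("counts dimensions do not match gene_ids/barcodes", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique", call. = FALSE)
  if (anyDuplicated(barcodes)) stop("barcodes must be unique", call. = FALSE)
  cm <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  v <- cm@x
  if (any(v < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(v != floor(v))) stop("counts must be integers", call. = FALSE)
  dimnames(cm) <- list(gene_ids, barcodes)
  mito_mask <- Reduce(`|`, lapply(mito_prefixes, function(p) startsWith(gene_ids, p)),
                      accumulate = FALSE)
  structure(list(counts = cm, gene_ids = gene_ids, barcodes = barcodes,
                 mito_mask = mito_mask, mito_prefixes = mito_prefixes),
            class = "germ_counts")
}

#' @export
print.germ_counts <- function(x, ...) {
  cat(sprintf("UMI count matrix: %d genes x %d cells (%d mitochondrial genes)\n",
              length(x$gene_ids), length(x$barcodes), sum(x$mito_mask)))
  invisible(x)
}

#' @export
dim.germ_counts <- function(x) dim(x$counts)

find_member <- function(directory, stem) {
  for (f in c(stem, paste0(stem, ".gz"))) {
    p <- file.path(directory, f)
    if (file.exists(p)) return(p)
  }
  stop(sprintf("no '%s' (or '%s.gz') found in '%s'", stem, stem, directory),
       call. = FALSE)
}

#' Read a count matrix from a Matrix Market directory
#'
#' Expects `matrix.mtx`, `genes.tsv` (first column gene ids) and
#' `barcodes.tsv` (first column barcodes); each member may be gzipped.
#' Matrix Market coordinates are 1-based per the standard.
#'
#' @param directory Directory containing the three files.
#' @param mito_prefixes Gene-name prefixes identifying mitochondrial genes.
#' @return A [germ_counts] object.
#' @export
read_counts <- function(directory, mito_prefixes = "mt:") {
  mf <- find_member(directory, "matrix.mtx")
  gf <- find_member(directory, "genes.tsv")
  bf <- find_member(directory, "barcodes.tsv")
  m <- Matrix::readMM(mf)
  genes <- read_tsv(gf)
  bcs <- read_tsv(bf)
  if (nrow(m) != nrow(genes))
    stop(sprintf("dimension mismatch: '%s' has %d rows but '%s' lists %d genes",
                 basename(mf), nrow(m), basename(gf), nrow(genes)), call. = FALSE)
  if (ncol(m) != nrow(bcs))
    stop(sprintf("dimension mismatch: '%s' has %d columns but '%s' lists %d barcodes",
                 basename(mf), ncol(m), basename(bf), nrow(bcs)), call. = FALSE)
  germ_counts(m, gene_ids = genes[[1]], barcodes = bcs[[1]],
              mito_prefixes = mito_prefixes)
}

#' Read a cell-to-cluster labeling written by [write_synthetic()]
#'
#' @param directory Directory containing `labels.tsv` (barcode, cluster) and
#'   `ap_order.tsv` (clusters in anterior-to-posterior order).
#' @return A [cluster_labeling()] object.
#' @export
read_labels <- function(directory) {
  lab <- read_tsv(find_member(directory, "labels.tsv"))
  ap <- read_tsv(find_member(directory, "ap_order.tsv"))
  cluster_labeling(stats::setNames(lab$cluster, lab$barcode), ap_order = ap$cluster)
}

#' Quality-control thresholds
#'
#' Defaults follow the study's filtering: genes expressed in more than 3
#' cells are kept (exclusive bound); cells with 100-4500 detected features
#' (inclusive bounds) and fewer than 20% mitochondrial counts (exclusive)
#' are retained.
#'
#' @param min_cells_per_gene Gene filter bound (exclusive; keep genes
#'   detected in strictly more cells than this).
#' @param min_features,max_features Inclusive bounds on detected genes per
#'   cell.
#' @param max_mito_fraction Exclusive upper bound on the per-cell
#'   mitochondrial UMI fraction.
#' @return An object of class `germ_qc_thresholds`.
#' @export
qc_thresholds <- function(min_cells_per_gene = 3L, min_features = 100L,
                          max_features = 4500L, max_mito_fraction = 0.20) {
  if (min_features > max_features)
    stop_field("min_features", "must not exceed max_features")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop_field("max_mito_fraction", "must lie in [0, 1]")
  structure(list(min_cells_per_gene = as.integer(min_cells_per_gene),
                 min_features = as.integer(min_features),
                 max_features = as.integer(max_features),
                 max_mito_fraction = max_mito_fraction),
            class = "germ_qc_thresholds")
}

detected_cells_per_gene <- function(m) {
  Matrix::rowSums(m$counts > 0)
}

#' Filter genes by detection count
#'
#' Keeps genes detected (count > 0) in strictly more than
#' `min_cells_per_gene` cells. The cell set is unchanged.
#'
#' @param m A [germ_counts] object.
#' @param thresholds A [qc_thresholds()] object.
#' @return A filtered [germ_counts] object.
#' @export
filter_genes <- function(m, thresholds = qc_thresholds()) {
  keep <- detected_cells_per_gene(m) > thresholds$min_cells_per_gene
  if (!any(keep)) message("filter_genes: no genes survive the detection filter")
  germ_counts(m$counts[keep, , drop = FALSE],
              gene_ids = m$gene_ids[keep], barcodes = m$barcodes,
              mito_prefixes = m$mito_prefixes)
}

cell_qc_metrics <- function(m) {
  total <- Matrix::colSums(m$counts)
  features <- Matrix::colSums(m$counts > 0)
  mito <- if (any(m$mito_mask))
    Matrix::colSums(m$counts[m$mito_mask, , drop = FALSE]) else rep(0, ncol(m$counts))
  mito_fraction <- ifelse(total > 0, mito / total, 0)
  data.frame(barcode = m$barcodes, total = as.numeric(total),
             features = as.integer(features),
             mito_fraction = as.numeric(mito_fraction),
             stringsAsFactors = FALSE)
}

#' Filter cells by detected features and mitochondrial fraction
#'
#' Keeps cells whose detected-gene count lies within
#' `[min_features, max_features]` (inclusive) and whose mitochondrial UMI
#' fraction is strictly below `max_mito_fraction`. The gene set is unchanged.
#'
#' @inheritParams filter_genes
#' @return A filtered [germ_counts] object.
#' @export
filter_cells <- function(m, thresholds = qc_thresholds()) {
  qc <- cell_qc_metrics(m)
  keep <- qc$features >= thresholds$min_features &
    qc$features <= thresholds$max_features &
    qc$mito_fraction < thresholds$max_mito_fraction
  if (!any(keep)) message("filter_cells: no cells survive the QC filters")
  germ_counts(m$counts[, keep, drop = FALSE],
              gene_ids = m$gene_ids, barcodes = m$barcodes[keep],
              mito_prefixes = m$mito_prefixes)
}

#' Apply the standard QC sequence (genes, then cells)
#'
#' @inheritParams filter_genes
#' @return A filtered [germ_counts] object.
#' @export
apply_qc <- function(m, thresholds = qc_thresholds()) {
  filter_cells(filter_genes(m, thresholds), thresholds)
}

#' Per-cell and per-cluster summary statistics
#'
#' Reports each cell's total UMIs, detected features and mitochondrial
#' fraction (defined as 0 for an all-zero cell), plus per-cluster means of
#' each quantity — the per-group depth summary of the study's Fig 5A style.
#'
#' @param m A [germ_counts] object.
#' @param labels A [cluster_labeling()] covering every barcode of `m`.
#' @return A list with `per_cell` and `per_cluster` data frames.
#' @export
cell_stats <- function(m, labels) {
  cl <- labels$assignment[m$barcodes]
  missing <- m$barcodes[is.na(cl)]
  if (length(missing) > 0)
    stop(sprintf("unlabeled barcodes: %s",
                 paste(utils::head(missing, 10), collapse = ", ")), call. = FALSE)
  qc <- cell_qc_metrics(m)
  qc$cluster <- unname(cl)
  order_cl <- c(labels$ap_order, setdiff(unique(qc$cluster), labels$ap_order))
  order_cl <- order_cl[order_cl %in% qc$cluster]
  per_cluster <- do.call(rbind, lapply(order_cl, function(c) {
    s <- qc[qc$cluster == c, , drop = FALSE]
    data.frame(cluster = c, n_cells = nrow(s),
               mean_total = mean(s$total),
               mean_features = mean(s$features),
               mean_mito_fraction = mean(s$mito_fraction),
               stringsAsFactors = FALSE)
  }))
  list(per_cell = qc, per_cluster = per_cluster)
}
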