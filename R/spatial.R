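# Anatomical assignment: cluster-size concordance with a cell-type census
# and exhaustive marker-based ordering of clusters along the AP axis.

#' Reference germarium cell-type census
#'
#' Average counts per germarium of region 1 escort cells, region 2a escort
#' cells, and follicle stem cells — the anatomical census against which the
#' sizes of the three anterior expression clusters are compared.
#'
#' @return Named numeric vector of expected cell counts.
#' @export
germarium_census <- function() {
  c(r1_EC = 26, r2a_EC = 14, FSC = 16)
}

#' Proportion concordance between clusters and an anatomical census
#'
#' Compares the relative sizes of the considered clusters with the relative
#' abundances of the mapped anatomical cell types, reporting whole-percent
#' vectors for display (full precision retained) and the total-variation
#' distance between the two proportion vectors.
#'
#' @param cluster_sizes Named numeric vector of cells per cluster.
#' @param clusters Cluster ids to consider (e.g. the three anterior groups).
#' @param census Named numeric vector of expected cell counts per type
#'   (default [germarium_census()]).
#' @param mapping Named character vector, cluster id -> census cell type;
#'   must be a bijection between `clusters` and the census types used.
#' @return A list of class `germ_concordance`: `cluster_pct` / `census_pct`
#'   (whole percents), `cluster_prop` / `census_prop` (full precision), the
#'   mapping, and `tv_distance` in [0, 1].
#' @export
proportion_concordance <- function(cluster_sizes, clusters,
                                   census = germarium_census(),
                                   mapping = c("0" = "r1_EC", "5" = "r2a_EC",
                                               "1" = "FSC")) {
  clusters <- as.character(clusters)
  if (!all(clusters %in% names(cluster_sizes)))
    stop("clusters missing from cluster_sizes", call. = FALSE)
  if (!all(clusters %in% names(mapping)))
    stop("mapping must cover every considered cluster", call. = FALSE)
  types <- unname(mapping[clusters])
  if (anyDuplicated(types) || !all(types %in% names(census)))
    stop("mapping must be a bijection onto census cell types", call. = FALSE)
  if (any(census[types] <= 0)) stop("census counts must be positive", call. = FALSE)
  sizes <- as.numeric(cluster_sizes[clusters])
  p <- sizes / sum(sizes)
  q <- as.numeric(census[types]) / sum(census[types])
  structure(list(
    clusters = clusters, cell_types = types,
    cluster_sizes = stats::setNames(sizes, clusters),
    census_counts = stats::setNames(as.numeric(census[types]), types),
    cluster_prop = stats::setNames(p, clusters),
    census_prop = stats::setNames(q, types),
    cluster_pct = stats::setNames(round(100 * p), clusters),
    census_pct = stats::setNames(round(100 * q), types),
    tv_distance = 0.5 * sum(abs(p - q))
  ), class = "germ_concordance")
}

#' @export
print.germ_concordance <- function(x, ...) {
  cat("Cluster vs census proportions:\n")
  for (i in seq_along(x$clusters))
    cat(sprintf("  cluster %s (%d cells, %d%%)  <->  %s (%g cells, %d%%)\n",
                x$clusters[i], x$cluster_sizes[i], x$cluster_pct[i],
                x$cell_types[i], x$census_counts[i], x$census_pct[i]))
  cat(sprintf("  total-variation distance: %.3f\n", x$tv_distance))
  invisible(x)
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  unlist(lapply(seq_along(v), function(i) {
    lapply(all_permutations(v[-i]), function(rest) c(v[i], rest))
  }), recursive = FALSE)
}

#' Landmark-based spatial profile expectations
#'
#' @param ... Named expectations, one per landmark gene: `"increasing"`,
#'   `"decreasing"`, or an integer position k (peak-at-position-k).
#' @return A named list of class `germ_landmarks`.
#' @export
landmark_spec <- function(...) {
  lm <- list(...)
  if (length(lm) == 0 || is.null(names(lm)) || any(names(lm) == ""))
    stop("landmarks must be named by gene id", call. = FALSE)
  for (nm in names(lm)) {
    v <- lm[[nm]]
    ok <- (is.character(v) && v %in% c("increasing", "decreasing")) ||
      (is.numeric(v) && length(v) == 1 && v == floor(v) && v >= 1)
    if (!ok) stop_field(nm, "must be 'increasing', 'decreasing' or a peak position")
  }
  structure(lm, class = "germ_landmarks")
}

score_ordering <- function(mean_norm, landmarks, perm) {
  k <- length(perm)
  s <- 0
  for (nm in names(landmarks)) {
    x <- mean_norm[nm, perm]
    exp_profile <- landmarks[[nm]]
    if (identical(exp_profile, "increasing")) {
      s <- s + stats::cor(x, seq_len(k), method = "spearman")
    } else if (identical(exp_profile, "decreasing")) {
      s <- s + stats::cor(x, rev(seq_len(k)), method = "spearman")
    } else {
      s <- s + 1 - abs(which.max(x) - exp_profile) / (k - 1)
    }
  }
  s
}

#' Order clusters along the AP axis from landmark genes
#'
#' Evaluates every permutation of the clusters (exhaustive search, at most
#' 8 clusters) and scores each against the declared landmark expectations:
#' monotone landmarks by Spearman rank correlation between the expected
#' direction and the observed normalized means, peaked landmarks by the
#' proximity of the expression argmax to the expected position. The
#' best-scoring permutation is returned in a canonical orientation chosen
#' so that the first declared increasing landmark increases; ties are
#' reported, never silently broken.
#'
#' @param p A normalized `germ_profile`.
#' @param landmarks A [landmark_spec()] whose genes are all in the profile.
#' @param clusters Clusters to order (default: all profile clusters).
#' @return A list of class `germ_ordering`: `order` (best permutation),
#'   `score`, and `ties` (all permutations attaining the maximal score, in
#'   canonical list order).
#' @export
order_clusters <- function(p, landmarks, clusters = NULL) {
  if (is.null(p$mean_norm))
    stop("profile must be normalized first (normalize_profile)", call. = FALSE)
  clusters <- sort(as.character(clusters %||% p$ap_order))
  if (length(clusters) > 8)
    stop("more than 8 clusters: exhaustive ordering is out of scope", call. = FALSE)
  unknown <- setdiff(names(landmarks), rownames(p$mean_norm))
  if (length(unknown) > 0)
    stop(sprintf("landmark gene(s) not in profile: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  perms <- all_permutations(clusters)
  scores <- vapply(perms, function(pm) score_ordering(p$mean_norm, landmarks, pm),
                   numeric(1))
  best_score <- max(scores)
  ties <- perms[scores >= best_score - 1e-9]
  best <- ties[[1]]
  inc <- names(landmarks)[vapply(landmarks, identical, logical(1), "increasing")]
  if (length(inc) > 0) {
    rho <- stats::cor(p$mean_norm[inc[1], best], seq_along(best),
                      method = "spearman")
    if (!is.na(rho) && rho < 0) {
      best <- rev(best)
      ties <- lapply(ties, rev)
    }
  }
  structure(list(order = best, score = best_score, ties = ties,
                 n_permutations = length(perms)),
            class = "germ_ordering")
}

#' @export
print.germ_ordering <- function(x, ...) {
  cat("AP ordering:", paste(x$order, collapse = " -> "),
      sprintf("(score %.3f over %d permutations", x$score, x$n_permutations))
  if (length(x$ties) > 1) cat(sprintf("; %d tied orderings", length(x$ties)))
  cat(")\n")
  invisible(x)
}
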