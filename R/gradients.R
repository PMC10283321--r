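# Transition-gradient classifier: fractional changes between ordered cell
# states, an expression filter, separate quartiling of increases and
# decreases into UP/DOWN/NEUTRAL classes, pairwise category counts over two
# headline transitions, and structural / empirical independence nulls.

#' Fractional change relative to the larger value
#'
#' f(a, b) = (b - a) / max(a, b), so the change from `a` to `b` is expressed
#' as a fraction of the larger of the two values and lies in [-1, 1].
#' Positive values are anterior-to-posterior increases. The degenerate case
#' a = b = 0 is defined as 0.
#'
#' @param a,b Non-negative expression values (vectorized).
#' @return Numeric vector of fractional changes in [-1, 1].
#' @export
fractional_change <- function(a, b) {
  if (any(a < 0) || any(b < 0))
    stop("expression values must be non-negative", call. = FALSE)
  m <- pmax(a, b)
  ifelse(m > 0, (b - a) / m, 0)
}

#' Declare a transition between (possibly merged) cluster groups
#'
#' @param name Transition label, e.g. `"EC_FSC"`.
#' @param from,to Cluster ids on each side; multiple clusters are merged by
#'   weighted mean (default weights: cluster cell counts).
#' @param from_weights,to_weights Optional positive weights overriding the
#'   cell-count default.
#' @return An object of class `germ_transition_spec`.
#' @export
transition_spec <- function(name, from, to, from_weights = NULL, to_weights = NULL) {
  if (!is.null(from_weights) && (length(from_weights) != length(from) ||
                                 any(from_weights <= 0)))
    stop_field("from_weights", "must be positive and aligned with 'from'")
  if (!is.null(to_weights) && (length(to_weights) != length(to) ||
                               any(to_weights <= 0)))
    stop_field("to_weights", "must be positive and aligned with 'to'")
  structure(list(name = name, from = as.character(from), to = as.character(to),
                 from_weights = from_weights, to_weights = to_weights),
            class = "germ_transition_spec")
}

#' The study's four germarium transitions
#'
#' EC -> FSC (groups 0+5 merged to group 1), FSC -> FC (group 1 to groups
#' 4+2 merged), and the single-group transitions 5 -> 1 and 1 -> 4. Merged
#' sides are weighted by cluster cell counts.
#'
#' @return List of [transition_spec()] objects.
#' @export
germarium_transitions <- function() {
  list(transition_spec("EC_FSC", from = c("0", "5"), to = "1"),
       transition_spec("FSC_FC", from = "1", to = c("4", "2")),
       transition_spec("5_1", from = "5", to = "1"),
       transition_spec("1_4", from = "1", to = "4"))
}

#' Weighted combined expression over a cluster group
#'
#' Weighted mean of the normalized per-cluster means, used to merge the two
#' EC clusters and the two FC clusters before computing fractional changes.
#' Default weights are the cluster cell counts.
#'
#' @param p A normalized `germ_profile`.
#' @param groups Cluster ids to combine.
#' @param weights Optional positive weights (default: cluster sizes).
#' @return Named numeric vector, one value per gene.
#' @export
combined_expression <- function(p, groups, weights = NULL) {
  if (is.null(p$mean_norm))
    stop("profile must be normalized first (normalize_profile)", call. = FALSE)
  unknown <- setdiff(groups, colnames(p$mean_norm))
  if (length(unknown) > 0)
    stop(sprintf("unknown group(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (is.null(weights)) weights <- p$cluster_sizes[groups]
  if (length(weights) != length(groups) || any(weights <= 0))
    stop_field("weights", "must be positive and aligned with 'groups'")
  as.vector(p$mean_norm[, groups, drop = FALSE] %*% (weights / sum(weights)))
}

#' Expression filter for the gradient analysis
#'
#' Keeps genes whose normalized mean expression exceeds `min_expr`
#' (strictly) in at least one of the considered groups — the study's
#' "greater than 1.5 in at least one group" inclusion rule.
#'
#' @param p A normalized `germ_profile`.
#' @param groups Groups to consider (default: all profile clusters).
#' @param min_expr Exclusive threshold (default 1.5).
#' @return Character vector of retained gene ids.
#' @export
expression_filter <- function(p, groups = NULL, min_expr = 1.5) {
  if (is.null(p$mean_norm))
    stop("profile must be normalized first (normalize_profile)", call. = FALSE)
  groups <- groups %||% p$ap_order
  unknown <- setdiff(groups, colnames(p$mean_norm))
  if (length(unknown) > 0)
    stop(sprintf("unknown group(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  mx <- apply(p$mean_norm[, groups, drop = FALSE], 1, max)
  rownames(p$mean_norm)[mx > min_expr]
}

#' Quartile classification of fractional changes for one transition
#'
#' Increases (f > 0) and decreases (f < 0) are quartiled separately by |f|
#' in descending order (quartile 1 = largest changes), with ties broken by
#' gene id and quartile boundaries at ceiling(n/4) cumulative cuts. Genes in
#' the top two quartiles of increases are classed UP, the top two quartiles
#' of decreases DOWN, and everything else (lower quartiles and f = 0)
#' NEUTRAL.
#'
#' @param f Named numeric vector of fractional changes (names = gene ids).
#' @return Data frame with columns gene, f, sign, quartile (NA for f = 0),
#'   cls.
#' @export
quartile_classify <- function(f) {
  if (is.null(names(f))) stop("'f' must be named by gene ids", call. = FALSE)
  out <- data.frame(gene = names(f), f = as.numeric(f),
                    sign = ifelse(f > 0, "increase",
                                  ifelse(f < 0, "decrease", "zero")),
                    quartile = NA_integer_, cls = "NEUTRAL",
                    stringsAsFactors = FALSE)
  for (s in c("increase", "decrease")) {
    idx <- which(out$sign == s)
    n <- length(idx)
    if (n == 0) next
    ord <- idx[order(-abs(out$f[idx]), out$gene[idx])]
    cuts <- ceiling(n * (1:3) / 4)
    r <- seq_len(n)
    q <- 1L + (r > cuts[1]) + (r > cuts[2]) + (r > cuts[3])
    out$quartile[ord] <- q
    top <- ord[q <= 2L]
    out$cls[top] <- if (s == "increase") "UP" else "DOWN"
  }
  out
}

#' Transition table: fractional changes and classes for every transition
#'
#' Applies the expression filter, computes fractional changes for every
#' declared transition (merging cluster groups by weighted mean), quartiles
#' each transition's increases and decreases separately, and assigns the
#' pairwise category "first-second" from the two headline transitions.
#' Rows are sorted by gene id, so the result is independent of input order.
#'
#' @param p A normalized `germ_profile`.
#' @param transitions List of [transition_spec()] (default
#'   [germarium_transitions()]).
#' @param min_expr Expression-filter threshold (default 1.5).
#' @param filter_groups Groups the filter considers (default: all).
#' @param category_from Names of the two transitions defining the pairwise
#'   category (default: the first two).
#' @return An object of class `germ_transitions`: a data frame with per-gene
#'   columns `f_<name>`, `q_<name>`, `cls_<name>` and `category`, plus
#'   attributes recording the settings.
#' @export
transition_table <- function(p, transitions = germarium_transitions(),
                             min_expr = 1.5, filter_groups = NULL,
                             category_from = NULL) {
  genes <- sort(expression_filter(p, groups = filter_groups, min_expr = min_expr))
  nm <- vapply(transitions, function(t) t$name, character(1))
  if (anyDuplicated(nm)) stop("transition names must be unique", call. = FALSE)
  category_from <- category_from %||% nm[1:2]
  if (!all(category_from %in% nm))
    stop("category_from must name declared transitions", call. = FALSE)
  tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (t in transitions) {
    from <- combined_expression(p, t$from, t$from_weights)
    names(from) <- rownames(p$mean_norm)
    to <- combined_expression(p, t$to, t$to_weights)
    names(to) <- rownames(p$mean_norm)
    f <- fractional_change(from[genes], to[genes])
    names(f) <- genes
    q <- quartile_classify(f)
    tab[[paste0("f_", t$name)]] <- q$f
    tab[[paste0("q_", t$name)]] <- q$quartile
    tab[[paste0("cls_", t$name)]] <- q$cls
  }
  tab$category <- paste(tab[[paste0("cls_", category_from[1])]],
                        tab[[paste0("cls_", category_from[2])]], sep = "-")
  structure(tab, class = c("germ_transitions", "data.frame"),
            transitions = nm, category_from = category_from,
            min_expr = min_expr)
}

#' @export
print.germ_transitions <- function(x, ...) {
  cat(sprintf("Transition table: %d genes, transitions %s (category: %s)\n",
              nrow(x), paste(attr(x, "transitions"), collapse = ", "),
              paste(attr(x, "category_from"), collapse = " then ")))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

CLS_LEVELS <- c("UP", "DOWN", "NEUTRAL")

#' Pairwise category counts over two transitions
#'
#' Cross-tabulates the UP/DOWN/NEUTRAL classes of two transitions (the
#' first-named transition first), reports the marginals, the conditional
#' percentage of each category within its first-transition class (the
#' study's 50/379 = 13%-style figures), and attaches the structural and
#' empirical independence nulls.
#'
#' @param tt A `germ_transitions` table.
#' @param first,second Transition names (default: the table's
#'   `category_from` pair).
#' @return An object of class `germ_categories`: `counts` (3x3 matrix,
#'   first x second), `marginals`, `n`, `cond_freq_pct`, `structural`
#'   (see [structural_null()]) and `empirical` (see [empirical_null()]).
#' @export
categorize <- function(tt, first = NULL, second = NULL) {
  cf <- attr(tt, "category_from")
  first <- first %||% cf[1]
  second <- second %||% cf[2]
  c1 <- factor(tt[[paste0("cls_", first)]], levels = CLS_LEVELS)
  c2 <- factor(tt[[paste0("cls_", second)]], levels = CLS_LEVELS)
  counts <- table(first = c1, second = c2)
  counts <- matrix(as.integer(counts), 3, 3, dimnames = dimnames(counts))
  n <- sum(counts)
  marg1 <- rowSums(counts)
  marg2 <- colSums(counts)
  cond <- sweep(counts, 1, pmax(marg1, 1), `/`) * 100
  obj <- structure(list(counts = counts,
                        marginals = list(first = marg1, second = marg2),
                        n = n, cond_freq_pct = cond,
                        first = first, second = second),
                   class = "germ_categories")
  obj$structural <- structural_null(n)
  obj$empirical <- empirical_null(obj)
  obj
}

#' @export
print.germ_categories <- function(x, ...) {
  cat(sprintf("Category counts (%s then %s), n = %d genes\n",
              x$first, x$second, x$n))
  print(x$counts)
  cat("Conditional % within first-transition class:\n")
  print(round(x$cond_freq_pct))
  invisible(x)
}

#' Structural null for category co-occurrence
#'
#' Independence baseline in which each transition assigns UP and DOWN with
#' probability 0.25 each (the two top quartiles of increases and of
#' decreases, with increases and decreases balanced) and NEUTRAL with
#' probability 0.5. Under this null the conditional frequency of any
#' specific non-neutral class in the second transition is 25%, and of
#' NEUTRAL 50%, regardless of the first-transition class.
#'
#' @param n_included Number of included genes (>= 0).
#' @return A list with `probs` (3x3 joint probabilities summing to 1),
#'   `expected` (n x probs), and `conditional_pct` (each row the conditional
#'   percentages 25/25/50).
#' @export
structural_null <- function(n_included) {
  if (n_included < 0) stop_field("n_included", "must be non-negative")
  p <- c(UP = 0.25, DOWN = 0.25, NEUTRAL = 0.5)
  probs <- outer(p, p)
  dimnames(probs) <- list(first = CLS_LEVELS, second = CLS_LEVELS)
  cond <- matrix(rep(100 * p, each = 3), 3, 3, dimnames = dimnames(probs))
  list(probs = probs, expected = n_included * probs, conditional_pct = cond)
}

#' Empirical independence null from observed marginals
#'
#' Expected counts under independence of the two transitions given their
#' observed UP/DOWN/NEUTRAL marginals: expected[i, j] = m1[i] * m2[j] / n,
#' with a chi-square comparison of observed against expected.
#'
#' @param categories A `germ_categories` object (or a 3x3 count matrix).
#' @return A list with `expected`, `chisq`, `df` and `p_value` (cells with
#'   zero expectation are excluded from the statistic).
#' @export
empirical_null <- function(categories) {
  counts <- if (inherits(categories, "germ_categories")) categories$counts
            else categories
  n <- sum(counts)
  m1 <- rowSums(counts)
  m2 <- colSums(counts)
  expected <- outer(m1, m2) / max(n, 1)
  nz <- expected > 0
  chisq <- sum((counts[nz] - expected[nz])^2 / expected[nz])
  df <- (sum(m1 > 0) - 1) * (sum(m2 > 0) - 1)
  p_value <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  list(expected = expected, chisq = chisq, df = df, p_value = p_value)
}
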