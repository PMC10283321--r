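test_that("fractional change is relative to the larger value", {
  expect_equal(fractional_change(1, 3), 2 / 3)
  expect_equal(fractional_change(4, 4), 0)
  expect_equal(fractional_change(0, 5), 1)
  expect_equal(fractional_change(5, 0), -1)
  expect_equal(fractional_change(0, 0), 0)
  expect_error(fractional_change(-1, 2), "non-negative")
})

test_that("fractional change is antisymmetric, scale-invariant and bounded", {
  set.seed(8)
  a <- runif(200, 0, 50); b <- runif(200, 0, 50)
  f <- fractional_change(a, b)
  expect_equal(f, -fractional_change(b, a))
  expect_equal(f, fractional_change(3.7 * a, 3.7 * b))
  expect_true(all(f >= -1 & f <= 1))
})

test_that("combined expression is the weighted mean of cluster columns", {
  mr <- cbind(A = c(10, 5), B = c(20, 5), C = c(7, 5))
  rownames(mr) <- c("g1", "g2")
  p <- structure(list(mean_norm = mr, pct_detected = mr * 0,
                      cluster_sizes = c(A = 1L, B = 3L, C = 2L),
                      ap_order = colnames(mr)),
                 class = "germ_profile")
  expect_equal(combined_expression(p, c("A", "B"), weights = c(1, 3)),
               c((10 + 3 * 20) / 4, 5))
  # default weights are the cluster cell counts
  expect_equal(combined_expression(p, c("A", "B")), c(17.5, 5))
  # equal columns come back unchanged for any weights
  expect_equal(combined_expression(p, c("A", "C"), weights = c(9, 1))[2], 5)
  expect_error(combined_expression(p, "Z"), "unknown group")
  expect_error(combined_expression(p, c("A", "B"), weights = c(1, -1)),
               "weights")
})

test_that("merged-group weighting by cell count equals pooling cells at equal depth", {
  # two clusters of equal per-cell depth: pooling raw cells then averaging
  # equals the size-weighted mean of the per-cluster means
  m <- cbind(c(3L, 1L), c(1L, 3L), c(2L, 2L), c(4L, 0L), c(0L, 4L))
  rownames(m) <- c("g1", "g2"); colnames(m) <- paste0("c", 1:5)
  cl <- c(c1 = "A", c2 = "A", c3 = "A", c4 = "B", c5 = "B")
  lab <- cluster_labeling(cl, ap_order = c("A", "B"))
  cm <- germ_counts(m)
  pr <- normalize_profile(cluster_mean_profile(cm, lab))
  pooled <- rowSums(m) / 5
  pooled_norm <- pooled * 10000 / sum(pooled)
  expect_equal(combined_expression(pr, c("A", "B")), unname(pooled_norm))
})

test_that("expression filter is exclusive at the threshold", {
  mr <- cbind(A = c(1.5, 1.6, 0.5, 3), B = c(1.5, 0, 1.2, 5))
  mr <- rbind(mr, big = c(10000 - colSums(mr)))
  rownames(mr) <- c("g_at", "g_in", "g_out", "g_hi", "big")
  p <- structure(list(mean_norm = mr, pct_detected = mr * 0,
                      cluster_sizes = c(A = 1L, B = 1L), ap_order = c("A", "B")),
                 class = "germ_profile")
  kept <- expression_filter(p, min_expr = 1.5)
  expect_false("g_at" %in% kept)   # exactly 1.5 everywhere -> excluded
  expect_true("g_in" %in% kept)    # 1.6 in one group suffices
  expect_false("g_out" %in% kept)
  # brute-force scan agreement on random profiles
  set.seed(21)
  rnd <- matrix(runif(60, 0, 3), 20, 3,
                dimnames = list(paste0("g", 1:20), c("A", "B", "C")))
  p2 <- structure(list(mean_norm = rnd, pct_detected = rnd * 0,
                       cluster_sizes = c(A = 1L, B = 1L, C = 1L),
                       ap_order = colnames(rnd)),
                  class = "germ_profile")
  expect_identical(expression_filter(p2, min_expr = 1.5),
                   rownames(rnd)[apply(rnd, 1, function(x) any(x > 1.5))])
})

# Exhaustive pairwise-comparison oracle for the quartile rule: a gene's rank
# within its sign group is 1 + the number of genes strictly preceding it
# under (|f| descending, gene id ascending); quartile q is the smallest q
# with rank <= ceiling(q * n / 4).
oracle_quartiles <- function(f) {
  out <- data.frame(gene = names(f), quartile = NA_integer_, cls = "NEUTRAL",
                    stringsAsFactors = FALSE)
  for (s in c(1, -1)) {
    ids <- names(f)[sign(f) == s]
    n <- length(ids)
    for (g in ids) {
      before <- sum(vapply(ids, function(h) {
        abs(f[h]) > abs(f[g]) || (abs(f[h]) == abs(f[g]) && h < g)
      }, logical(1)))
      r <- before + 1
      q <- min(which(r <= ceiling((1:4) * n / 4)))
      out$quartile[out$gene == g] <- q
      if (q <= 2) out$cls[out$gene == g] <- if (s > 0) "UP" else "DOWN"
    }
  }
  out
}

test_that("quartile classification basics", {
  f <- setNames(c(0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1), paste0("g", 1:8))
  q <- quartile_classify(f)
  expect_equal(sum(q$cls == "UP"), 4)
  expect_equal(q$quartile, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  fz <- setNames(c(0.5, 0, -0.5), c("a", "b", "c"))
  qz <- quartile_classify(fz)
  expect_equal(qz$cls, c("UP", "NEUTRAL", "DOWN"))
  expect_true(is.na(qz$quartile[2]))
})

test_that("quartile classifier matches the pairwise oracle, ties included", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:60, 1)
    # coarse grid forces plenty of ties, including at quartile boundaries
    f <- sample(seq(-1, 1, by = 0.25), n, replace = TRUE)
    names(f) <- sprintf("g%03d", sample.int(999, n))
    got <- quartile_classify(f)
    ref <- oracle_quartiles(f)
    expect_identical(got$quartile, ref$quartile[match(got$gene, ref$gene)])
    expect_identical(got$cls, ref$cls[match(got$gene, ref$gene)])
    # quartile sizes within each sign group differ by at most 1
    for (s in c("increase", "decrease")) {
      qq <- got$quartile[got$sign == s]
      if (length(qq) >= 4) expect_lte(diff(range(table(factor(qq, 1:4)))), 1)
    }
  }
})

test_that("category counts cross-tabulate and partition the included genes", {
  tt <- data.frame(
    gene = paste0("g", 1:9),
    cls_t1 = c("UP", "UP", "UP", "DOWN", "DOWN", "NEUTRAL", "NEUTRAL", "UP", "DOWN"),
    cls_t2 = c("UP", "DOWN", "NEUTRAL", "UP", "DOWN", "NEUTRAL", "UP", "UP", "DOWN"),
    stringsAsFactors = FALSE)
  attr(tt, "category_from") <- c("t1", "t2")
  class(tt) <- c("germ_transitions", "data.frame")
  cc <- categorize(tt)
  expect_equal(cc$counts["UP", "UP"], 2L)
  expect_equal(cc$counts["UP", "DOWN"], 1L)
  expect_equal(cc$counts["DOWN", "DOWN"], 2L)
  expect_equal(sum(cc$counts), 9L)
  expect_equal(unname(cc$marginals$first), c(4L, 3L, 2L))
  expect_equal(cc$cond_freq_pct["UP", "UP"], 100 * 2 / 4)
})

test_that("structural null gives 25/25/50 conditionals and a coherent table", {
  sn <- structural_null(1600)
  expect_equal(unname(sn$conditional_pct[, "UP"]), rep(25, 3))
  expect_equal(unname(sn$conditional_pct[, "DOWN"]), rep(25, 3))
  expect_equal(unname(sn$conditional_pct[, "NEUTRAL"]), rep(50, 3))
  expect_equal(sum(sn$probs), 1)
  expect_equal(sn$expected["UP", "UP"], 100)  # 1600 x 0.0625
  expect_equal(sum(sn$expected), 1600)
  expect_error(structural_null(-1), "n_included")
})

test_that("empirical null matches hand-computed marginal products", {
  counts <- matrix(c(30L, 10L, 20L, 5L, 25L, 10L, 15L, 15L, 70L), 3, 3,
                   dimnames = list(first = c("UP", "DOWN", "NEUTRAL"),
                                   second = c("UP", "DOWN", "NEUTRAL")))
  en <- empirical_null(counts)
  n <- sum(counts)
  for (i in 1:3) for (j in 1:3)
    expect_equal(unname(en$expected[i, j]),
                 unname(rowSums(counts)[i] * colSums(counts)[j] / n))
  # degenerate marginal: all mass on the UP row
  deg <- matrix(0L, 3, 3, dimnames = dimnames(counts))
  deg["UP", ] <- c(10L, 5L, 5L)
  expect_true(all(empirical_null(deg)$expected[c("DOWN", "NEUTRAL"), ] == 0))
})

test_that("independent simulated labels give uniform chi-square p-values", {
  set.seed(9)
  ps <- replicate(40, {
    c1 <- sample(c("UP", "DOWN", "NEUTRAL"), 300, TRUE, prob = c(.25, .25, .5))
    c2 <- sample(c("UP", "DOWN", "NEUTRAL"), 300, TRUE, prob = c(.25, .25, .5))
    tt <- data.frame(gene = paste0("g", 1:300), cls_a = c1, cls_b = c2,
                     stringsAsFactors = FALSE)
    attr(tt, "category_from") <- c("a", "b")
    class(tt) <- c("germ_transitions", "data.frame")
    categorize(tt)$empirical$p_value
  })
  expect_gt(min(ps), 1e-4)       # no spurious dependence
  expect_gt(mean(ps > 0.5), 0.3) # roughly uniform
})

test_that("transition table is deterministic and input-order independent", {
  b <- generate_germarium(tiny_spec(seed = 16L))
  pr <- normalize_profile(cluster_mean_profile(b$counts, b$labels))
  tr <- list(transition_spec("AB", "A", "B"), transition_spec("BC", "B", "C"))
  t1 <- transition_table(pr, tr, min_expr = 1.5)
  # shuffle gene order in the profile
  set.seed(1)
  idx <- sample(nrow(pr$mean_norm))
  pr2 <- pr
  pr2$mean_raw <- pr$mean_raw[idx, ]
  pr2$mean_norm <- pr$mean_norm[idx, ]
  pr2$pct_detected <- pr$pct_detected[idx, ]
  t2 <- transition_table(pr2, tr, min_expr = 1.5)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  # class invariants: UP => f > 0 and top-two quartile; partition holds
  expect_true(all(t1$f_AB[t1$cls_AB == "UP"] > 0))
  expect_true(all(t1$q_AB[t1$cls_AB == "UP"] <= 2))
  expect_true(all(t1$f_AB[t1$cls_AB == "DOWN"] < 0))
  cc <- categorize(t1)
  expect_equal(cc$n, nrow(t1))
})
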