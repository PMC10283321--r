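test_that("enrichment score evaluates the pseudocounted log2 ratio", {
  expect_equal(enrichment_score(5, 5), 0)
  expect_equal(enrichment_score(1, 0), 1)
  expect_equal(enrichment_score(7, 3), 1)   # log2(8/4)
  expect_error(enrichment_score(-1, 2), "non-negative")
  expect_error(enrichment_score(Inf, 2), "finite")
})

test_that("enrichment score is antisymmetric and monotone", {
  set.seed(5)
  a <- runif(50, 0, 20); b <- runif(50, 0, 20)
  expect_equal(enrichment_score(a, b), -enrichment_score(b, a))
  e <- enrichment_score(sort(a), 1)
  expect_true(all(diff(e) > 0))
  e2 <- enrichment_score(1, sort(b))
  expect_true(all(diff(e2) < 0))
})

test_that("rank-sum p-values match stats::wilcox.test", {
  set.seed(31)
  g <- 15; n <- 40
  m <- matrix(rpois(g * n, 1.5), g, n,
              dimnames = list(paste0("g", 1:g), paste0("c", 1:n)))
  cl <- rep(c("A", "B"), each = n / 2)
  names(cl) <- colnames(m)
  lab <- cluster_labeling(cl, ap_order = c("A", "B"))
  cm <- germ_counts(m)
  pr <- normalize_profile(cluster_mean_profile(cm, lab))
  mk <- marker_table(pr, cm, lab)
  for (i in seq_len(g)) {
    ref <- suppressWarnings(
      wilcox.test(m[i, cl == "A"], m[i, cl == "B"],
                  exact = FALSE, correct = TRUE))$p.value
    got <- mk$table$p_raw[mk$table$gene == paste0("g", i) &
                            mk$table$cluster == "A"]
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("Bonferroni adjustment is exactly min(1, p * n_tests)", {
  b <- generate_germarium(tiny_spec(seed = 13L))
  pr <- normalize_profile(cluster_mean_profile(b$counts, b$labels))
  mk <- marker_table(pr, b$counts, b$labels)
  expect_equal(mk$n_tests, nrow(pr$mean_raw) * 3)
  expect_equal(mk$table$p_adj, pmin(1, mk$table$p_raw * mk$n_tests))
  expect_true(all(mk$table$p_adj >= mk$table$p_raw - 1e-12))
})

test_that("expr_out is the unweighted mean over the other clusters", {
  mr <- cbind(A = c(8000, 2000), B = c(6000, 4000), C = c(2000, 8000))
  rownames(mr) <- c("g1", "g2")
  p <- profile_from_matrix(mr)
  mk <- marker_table(p, compute_p = FALSE)
  row <- mk$table[mk$table$gene == "g1" & mk$table$cluster == "A", ]
  expect_equal(row$expr_out, mean(c(6000, 2000)))
  expect_equal(row$E, log2((1 + 8000) / (1 + 4000)))
  # cell-weighted alternative
  p$cluster_sizes <- c(A = 10L, B = 30L, C = 10L)
  mkw <- marker_table(p, compute_p = FALSE, expr_out_weighted = TRUE)
  roww <- mkw$table[mkw$table$gene == "g1" & mkw$table$cluster == "A", ]
  expect_equal(roww$expr_out, (30 * 6000 + 10 * 2000) / 40)
})

test_that("marker list threshold on E is exclusive and ranking tie-stable", {
  mr <- cbind(A = c(5000, 3000, 2000), B = c(3000, 3000, 4000))
  rownames(mr) <- c("g1", "g2", "g3")
  p <- profile_from_matrix(mr)
  mk0 <- marker_table(p, compute_p = FALSE, e_threshold = 0)
  e_g1 <- mk0$table$E[mk0$table$gene == "g1" & mk0$table$cluster == "A"]
  # a gene whose E equals the threshold exactly is excluded
  mk_at <- marker_table(p, compute_p = FALSE, e_threshold = e_g1)
  expect_false("g1" %in% mk_at$markers[["A"]]$gene)
  mk_below <- marker_table(p, compute_p = FALSE, e_threshold = e_g1 - 1e-9)
  expect_true("g1" %in% mk_below$markers[["A"]]$gene)
  # flat gene has E = 0 everywhere, excluded at 0.4
  mk <- marker_table(p, compute_p = FALSE)
  expect_equal(mk$table$E[mk$table$gene == "g2"], c(0, 0))
  expect_false("g2" %in% unlist(lapply(mk$markers, `[[`, "gene")))
})

test_that("expr_out reacts to the cluster set (ranking sensitivity documented)", {
  mr <- cbind(A = c(6000, 4000), B = c(4000, 6000))
  rownames(mr) <- c("g1", "g2")
  two <- marker_table(profile_from_matrix(mr), compute_p = FALSE)
  mr3 <- cbind(mr, C = c(5000, 5000))
  three <- marker_table(profile_from_matrix(mr3), compute_p = FALSE)
  e2 <- two$table$E[two$table$gene == "g1" & two$table$cluster == "A"]
  e3 <- three$table$E[three$table$gene == "g1" & three$table$cluster == "A"]
  expect_false(isTRUE(all.equal(e2, e3)))
})

test_that("dotplot table mirrors profile entries and validates genes", {
  b <- generate_germarium(tiny_spec(seed = 14L))
  pr <- normalize_profile(cluster_mean_profile(b$counts, b$labels))
  genes <- rownames(pr$mean_norm)[1:3]
  dt <- dotplot_table(pr, genes)
  expect_equal(nrow(dt), 9)
  for (i in seq_len(nrow(dt)))
    expect_equal(dt$mean_norm[i], pr$mean_norm[dt$gene[i], dt$cluster[i]])
  expect_equal(nrow(dotplot_table(pr, character())), 0)
  expect_error(dotplot_table(pr, "nope"), "nope")
})

test_that("planted graded genes are monotone in the dot-plot table", {
  b <- generate_germarium(tiny_spec(seed = 15L,
                                    cells_per_cluster = c(200L, 200L, 200L)))
  pr <- normalize_profile(cluster_mean_profile(b$counts, b$labels))
  up <- names(b$truth$gene_archetype)[b$truth$gene_archetype == "graded_up"]
  up <- intersect(up, rownames(pr$mean_norm))
  dt <- dotplot_table(pr, up)
  mono <- vapply(up, function(g) {
    v <- dt$mean_norm[dt$gene == g][match(pr$ap_order, dt$cluster[dt$gene == g])]
    all(diff(v) > 0)
  }, logical(1))
  expect_gt(mean(mono), 0.9)
})

test_that("heat-map rows are z-scored with the population SD", {
  mr <- cbind(A = c(1, 5, 2), B = c(2, 5, 2), C = c(3, 5, 2))
  rownames(mr) <- c("g1", "g2", "g3")
  p <- structure(list(mean_norm = mr, pct_detected = mr * 0,
                      cluster_sizes = c(A = 1L, B = 1L, C = 1L),
                      ap_order = colnames(mr)),
                 class = "germ_profile")
  z <- heatmap_matrix(p, c("g1", "g2"))
  expect_equal(unname(z["g1", ]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
  # any non-constant row: mean 0, population SD 1
  expect_lt(abs(mean(z["g1", ])), 1e-9)
  expect_lt(abs(sqrt(mean(z["g1", ]^2)) - 1), 1e-9)
})
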