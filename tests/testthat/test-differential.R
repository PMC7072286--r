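mat1 <- function(x) matrix(x, 1, dimnames = list("f", paste0("S", seq_along(x))))

test_that("AUC matches brute-force pair counting with the half-tie rule", {
  # pos {2,3,4} vs neg {1,2,3}: 7/9 by enumeration over all 9 pairs
  res <- rank_auc(mat1(c(2, 3, 4, 1, 2, 3)), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$auc, 7 / 9)
  expect_equal(res$direction, "up")
  expect_true(res$significant)

  # identical multisets: 0.5, not significant
  res2 <- rank_auc(mat1(c(5, 6, 7, 5, 6, 7)), rep(c(TRUE, FALSE), each = 3))
  expect_equal(res2$auc, 0.5)
  expect_false(res2$significant)

  # perfect separation: 1.0
  res3 <- rank_auc(mat1(c(10, 11, 1, 2)), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res3$auc, 1)

  expect_error(rank_auc(mat1(1:4), rep(TRUE, 4)), "nonempty")
})

test_that("AUC equals the pair-counting oracle on random tied instances", {
  set.seed(31)
  for (rep in 1:200) {
    n1 <- sample(1:20, 1)
    n2 <- sample(1:20, 1)
    pos <- sample(0:6, n1, replace = TRUE)  # small support forces ties
    neg <- sample(0:6, n2, replace = TRUE)
    labels <- c(rep(TRUE, n1), rep(FALSE, n2))
    got <- rank_auc(mat1(c(pos, neg)), labels)$auc
    expect_equal(got, auc_oracle(pos, neg), tolerance = 1e-12)
    # label-flip antisymmetry
    expect_equal(rank_auc(mat1(c(pos, neg)), !labels)$auc, 1 - got, tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(rank_auc(mat1(exp(c(pos, neg) / 2)), labels)$auc, got, tolerance = 1e-12)
  }
})

test_that("DEG detection finds a planted shift and controls the null", {
  set.seed(17)
  ng <- 200
  v <- matrix(stats::rexp(ng * 20, 0.05), ng,
              dimnames = list(paste0("G", 1:ng), paste0("S", 1:20)))
  labels <- rep(c(TRUE, FALSE), each = 10)
  v["G1", labels] <- v["G1", labels] + 500
  degs <- detect_degs(expr_from(v, normalized = TRUE), labels)
  expect_equal(degs$gene_id[which.min(degs$p_value)], "G1")
  expect_true(degs$significant[degs$gene_id == "G1"])
  expect_gt(degs$log_fold_change[degs$gene_id == "G1"], log(1.5))

  # identical groups: nothing significant
  w <- cbind(v[, 1:10], v[, 1:10])
  colnames(w) <- paste0("S", 1:20)
  degs0 <- detect_degs(expr_from(w, normalized = TRUE), labels)
  expect_false(any(degs0$significant))

  expect_error(detect_degs(expr_from(v, normalized = TRUE),
                           c(TRUE, rep(FALSE, 19))), "at least 2")
  expect_error(detect_degs(expr_from(v), labels), "normalized")
})

test_that("BH adjustment inside DEG detection matches the step-up oracle", {
  # hand case: p = (.01,.02,.03,.04), m = 4 -> all adjusted to .04
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(8)
  v <- matrix(stats::rexp(50 * 10), 50,
              dimnames = list(paste0("G", 1:50), paste0("S", 1:10)))
  degs <- detect_degs(expr_from(v, normalized = TRUE), rep(c(TRUE, FALSE), 5))
  expect_equal(degs$fdr, bh_oracle(degs$p_value))
})

test_that("false-discovery proportion stays controlled on exchangeable nulls", {
  set.seed(123)
  ng <- 1000
  v <- matrix(stats::rexp(ng * 24, 0.05), ng,
              dimnames = list(paste0("G", 1:ng), paste0("S", 1:24)))
  degs <- detect_degs(expr_from(v, normalized = TRUE), rep(c(TRUE, FALSE), each = 12))
  expect_lte(mean(degs$fdr <= 0.05), 0.05 + 0.02)
})

test_that("concordance keeps only shared same-direction significant features", {
  a <- data.frame(feature_id = c("P1", "P2", "P3", "P4"),
                  auc = c(0.9, 0.1, 0.8, 0.6),
                  direction = c("up", "down", "up", "up"),
                  median_pos = 0, median_neg = 0,
                  significant = c(TRUE, TRUE, TRUE, FALSE))
  # identical lists: every significant feature is shared
  same <- concordant_features(a, a)
  expect_equal(same$shared, c("P1", "P2", "P3"))
  expect_equal(unname(same$venn_counts), c(0L, 0L, 3L))

  # opposite direction in b: excluded from shared
  b <- a
  b$direction[1] <- "down"
  res <- concordant_features(a, b)
  expect_equal(res$shared, c("P2", "P3"))
  expect_true("P1" %in% res$a_only && "P1" %in% res$b_only)

  # disjoint significant sets: empty overlap
  c_set <- a
  c_set$significant <- c(FALSE, FALSE, FALSE, TRUE)
  expect_equal(concordant_features(a, c_set)$shared, character(0))
})

test_that("gene overlap requires matching fold-change sign", {
  d1 <- data.frame(gene_id = c("A", "B", "C"), log_fold_change = c(1, -1, 2),
                   p_value = 0.001, fdr = 0.001, significant = c(TRUE, TRUE, FALSE))
  d2 <- data.frame(gene_id = c("A", "B", "C"), log_fold_change = c(2, 1, 2),
                   p_value = 0.001, fdr = 0.001, significant = c(TRUE, TRUE, TRUE))
  expect_equal(overlap_genes(d1, d2), "A")  # B flips sign, C not significant in d1
  expect_equal(overlap_genes(d1, d1), c("A", "B"))
  d3 <- d2
  d3$significant <- FALSE
  expect_equal(overlap_genes(d1, d3), character(0))
})

test_that("nearest-centroid subtype assignment recovers planted labels", {
  set.seed(77)
  genes <- paste0("G", 1:60)
  sig_a <- subtype_signature("Proneural", genes[1:15])
  sig_b <- subtype_signature("Mesenchymal", genes[16:30])
  base <- stats::rexp(60, 0.05) + 1
  n <- 40
  truth <- rep(c("Proneural", "Mesenchymal"), each = n / 2)
  v <- sapply(seq_len(n), function(i) {
    own <- if (truth[i] == "Proneural") 1:15 else 16:30
    x <- log(base) + stats::rnorm(60, 0, 0.5)
    x[own] <- x[own] + 1
    exp(x)
  })
  dimnames(v) <- list(genes, paste0("S", 1:n))
  got <- assign_subtype(expr_from(v, normalized = TRUE), list(sig_a, sig_b))
  expect_gte(mean(got == truth), 0.95)

  # a sample exactly equal to a stored centroid gets that subtype
  cen <- stats::setNames(c(rep(5, 15), rep(1, 15)), genes[1:30])
  sig_ac <- subtype_signature("Proneural", genes[1:15], cen)
  cen_b <- stats::setNames(c(rep(1, 15), rep(5, 15)), genes[1:30])
  sig_bc <- subtype_signature("Mesenchymal_c", genes[16:30], cen_b)
  v2 <- matrix(c(cen, rep(1, 30)), ncol = 1, dimnames = list(genes, "S1"))
  got2 <- assign_subtype(expr_from(v2, normalized = TRUE), list(sig_ac, sig_bc))
  expect_equal(unname(got2), "Proneural")

  # equidistant-by-construction sample is unclassified
  flat <- matrix(7, 60, 1, dimnames = list(genes, "S1"))
  got3 <- assign_subtype(expr_from(flat, normalized = TRUE), list(sig_a, sig_b))
  expect_equal(unname(got3), "unclassified")

  # insufficient signature coverage errors
  sig_thin <- subtype_signature("Thin", c("Z1", "Z2"))
  expect_error(assign_subtype(expr_from(v, normalized = TRUE),
                              list(sig_a, sig_thin)), "fewer than 10")
})

test_that("clustering splits planted groups and PCA variance sums to 100", {
  set.seed(55)
  v <- cbind(matrix(stats::rnorm(50 * 5, 0), 50),
             matrix(stats::rnorm(50 * 5, 8), 50))
  dimnames(v) <- list(paste0("G", 1:50), paste0("S", 1:10))
  out <- cluster_and_project(v)
  top2 <- stats::cutree(out$hclust, k = 2)
  expect_equal(length(unique(top2[1:5])), 1L)
  expect_equal(length(unique(top2[6:10])), 1L)
  expect_true(top2[1] != top2[10])
  expect_equal(sum(out$var_pct), 100)
  expect_equal(dim(out$scores), c(10L, 2L))

  # duplicated sample: zero-distance leaf pair merges first
  v2 <- cbind(v, S11 = v[, 1])
  out2 <- cluster_and_project(v2)
  first_merge <- out2$hclust$merge[1, ]
  expect_setequal(abs(first_merge), c(1L, 11L))
  expect_equal(out2$hclust$height[1], 0)
})
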