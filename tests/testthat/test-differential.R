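test_that("cell QC applies the inclusive boundary rules", {
  ## 5 cells with feature counts 400, 500, 2000, 3500, 1000
  make_col <- function(n_feat, total = n_feat) {
    x <- integer(4000)
    x[seq_len(n_feat)] <- 1L
    x[1] <- x[1] + total - n_feat
    x
  }
  m <- cbind(make_col(400), make_col(500), make_col(2000),
             make_col(3500), make_col(1000))
  res <- qc_filter_cells(m)
  expect_equal(ncol(res$counts), 3L)
  expect_equal(unname(res$removed["total"]), 2L)
  ## exactly 500 features and exactly 40,000 UMIs is retained
  edge <- cbind(make_col(500, 40000), make_col(500, 40001),
                make_col(499), make_col(3000), make_col(3001))
  res2 <- qc_filter_cells(edge)
  expect_equal(ncol(res2$counts), 2L)
  ## all removed -> warning, empty matrix
  expect_warning(res3 <- qc_filter_cells(cbind(make_col(10))), "removed")
  expect_equal(ncol(res3$counts), 0L)
  ## metadata filtered in step
  meta <- data.frame(id = letters[1:5])
  res4 <- qc_filter_cells(m, cell_meta = meta)
  expect_equal(res4$cell_meta$id, c("b", "c", "e"))
})

test_that("lognormalize matches its closed form", {
  m <- matrix(c(0, 2, 5, 3), nrow = 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  norm <- lognormalize(m, scale = 100)
  expect_equal(norm["g1", "c1"], 0)
  expect_equal(norm["g2", "c1"], log(1 + 2 * 100 / 2))
  ## single-gene cell: count == total -> log(1 + scale)
  single <- matrix(c(7), nrow = 1)
  expect_equal(as.numeric(lognormalize(single, scale = 100)), log(101))
  expect_error(lognormalize(matrix(c(1, 0), ncol = 2)), "zero total")
  ## sparse and dense agree
  sp <- lognormalize(Matrix::Matrix(m, sparse = TRUE), scale = 100)
  expect_equal(as.matrix(sp), norm, tolerance = 1e-12,
               ignore_attr = TRUE)
  ## column-permutation equivariance
  norm_perm <- lognormalize(m[, c(2, 1)], scale = 100)
  expect_equal(norm_perm, norm[, c(2, 1)])
})

test_that("log2fc is 0 on identical groups, antisymmetric, and exact on a hand case", {
  ## construct normalized values whose expm1 means are 3 and 1
  norm <- matrix(log1p(c(3, 3, 1, 1)), nrow = 1)
  expect_equal(as.numeric(log2fc(norm, 1:2, 3:4)), 1.0)
  expect_equal(as.numeric(log2fc(norm, 1:2, 1:2)), 0)
  expect_equal(as.numeric(log2fc(norm, 1:2, 3:4)),
               -as.numeric(log2fc(norm, 3:4, 1:2)))
})

test_that("exact rank-sum p equals enumeration and known cases", {
  expect_equal(wilcoxon_test(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(wilcoxon_test(c(5, 6, 7), c(5, 6, 7)), 1)
  set.seed(11)
  for (i in 1:25) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(0:4, nx, replace = TRUE)  # ties likely
    y <- sample(0:4, ny, replace = TRUE)
    expect_equal(wilcoxon_test(x, y), perm_wilcox_p(x, y),
                 tolerance = 1e-12)
  }
  ## tie-free cases also match stats::wilcox.test's exact p
  for (i in 1:10) {
    x <- sample(1:100, 5); y <- sample(101:200, 6)
    expect_equal(wilcoxon_test(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact rank-sum p at sizes 8-12", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(8:12, 2, replace = TRUE)
    x <- rnorm(n[1]); y <- rnorm(n[2], mean = runif(1, 0, 1.5))
    approx_p <- wilcoxon_test(x, y, exact = FALSE)
    exact_p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_lt(abs(approx_p - exact_p), 0.01)
  }
})

test_that("wilcoxon_deg calls respect both thresholds and orderings", {
  set.seed(5)
  n <- 30
  norm <- rbind(
    shifted = c(log1p(rpois(n, 20)), log1p(rpois(n, 3))),
    small_shift = c(log1p(rpois(n, 11)), log1p(rpois(n, 10))),
    flat = log1p(rpois(2 * n, 8)))
  res <- wilcoxon_deg(norm, seq_len(n), n + seq_len(n))
  expect_equal(res$call[res$feature == "shifted"], "up")
  expect_equal(res$call[res$feature == "flat"], "ns")
  expect_true(all(res$p_adj >= res$p))
  ## a tiny p with |log2fc| below threshold stays ns
  lowfc <- res[res$feature == "small_shift", ]
  if (lowfc$p_adj < 0.01) expect_equal(lowfc$call, "ns")
  ## invariance to feature and cell order
  perm_cells <- c(sample(seq_len(n)), n + sample(seq_len(n)))
  res_perm <- wilcoxon_deg(norm[c(3, 1, 2), perm_cells],
                           seq_len(n), n + seq_len(n))
  expect_equal(res_perm$call[match(res$feature, res_perm$feature)],
               res$call)
  expect_error(wilcoxon_deg(norm, 1, 2:10), "at least 2")
})

test_that("p-value adjustment equals the brute-force definitions", {
  expect_equal(adjust_pvalues(0.001, "bonferroni"), 0.001)
  expect_equal(adjust_pvalues(rep(0.001, 10), "bonferroni"),
               rep(0.01, 10))
  expect_equal(adjust_pvalues(rep(0.2, 5), "bh"), rep(0.2, 5))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    expect_equal(adjust_pvalues(p, "bonferroni"), brute_bonferroni(p))
    expect_equal(adjust_pvalues(p, "bh"), brute_bh(p))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  ## BH output monotone in sorted-p order
  p <- runif(50)
  bh <- adjust_pvalues(p, "bh")
  expect_true(all(diff(bh[order(p)]) >= -1e-12))
})

test_that("common-dispersion estimator recovers truth and degenerates to 0", {
  groups <- rep(c("A", "B"), each = 4)
  ## constant matrix -> 0
  expect_equal(estimate_common_dispersion(
    matrix(5, nrow = 10, ncol = 8), groups), 0)
  set.seed(13)
  ## Poisson data -> phi near 0
  pois <- matrix(rpois(3000 * 8, 50), ncol = 8)
  expect_lt(estimate_common_dispersion(pois, groups), 0.02)
  ## NB data with phi = 0.2 -> estimate within [0.1, 0.3]
  nb <- matrix(rnbinom(2000 * 8, mu = 50, size = 1 / 0.2), ncol = 8)
  est <- estimate_common_dispersion(nb, groups)
  expect_gt(est, 0.1); expect_lt(est, 0.3)
  expect_error(estimate_common_dispersion(pois[, 1:3], c("A", "A", "B")),
               ">= 2 samples")
})

test_that("NB exact test: null identity, symmetry, binomial reduction", {
  cond <- rep(c("A", "B"), each = 3)
  ## identical counts in both groups -> p = 1
  m <- matrix(rep(c(10, 20, 30), 2), nrow = 1)
  res <- nb_exact_test(m, cond, "A", "B", dispersion = 0.1,
                       size_factors = rep(1, 6))
  expect_equal(res$p, 1)
  expect_equal(res$log2fc, 0)
  set.seed(3)
  cnt <- matrix(rnbinom(50 * 6, mu = 80, size = 10), ncol = 6)
  r1 <- nb_exact_test(cnt, cond, "A", "B", 0.1, size_factors = rep(1, 6))
  r2 <- nb_exact_test(cnt, cond, "B", "A", 0.1, size_factors = rep(1, 6))
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-12)
  ## dispersion 0 + equal library sizes == exact binomial test
  r0 <- nb_exact_test(cnt, cond, "A", "B", 0, size_factors = rep(1, 6))
  for (i in seq_len(nrow(cnt))) {
    ya <- sum(cnt[i, 1:3]); yb <- sum(cnt[i, 4:6])
    expect_lt(abs(r0$p[i] -
                    stats::binom.test(ya, ya + yb, 0.5)$p.value), 1e-9)
  }
  expect_error(nb_exact_test(cnt, cond, "A", "B", -1), ">= 0")
  expect_error(nb_exact_test(cnt, cond, "A", "Z", 0.1), "absent")
})

test_that("NB exact test type-I error is near nominal (quick check)", {
  set.seed(99)
  phi <- 0.1
  cnt <- matrix(rnbinom(2000 * 6, mu = 100, size = 1 / phi), ncol = 6)
  cond <- rep(c("A", "B"), each = 3)
  res <- nb_exact_test(cnt, cond, "A", "B", phi, size_factors = rep(1, 6))
  expect_gt(mean(res$p < 0.05), 0.03)
  expect_lt(mean(res$p < 0.05), 0.07)
})

test_that("correlation to an aggregated control behaves at its fixed points", {
  set.seed(17)
  ctrl <- matrix(rnorm(50 * 3, mean = 5), ncol = 3)
  ref <- rowMeans(ctrl)
  mat <- cbind(ctrl, ref, -(ref - mean(ref)) + mean(ref))
  expect_equal(correlation_to_reference(mat, 1:3, 4), 1.0)
  expect_equal(correlation_to_reference(mat, 1:3, 5), -1.0)
  big <- cbind(rnorm(10000), rnorm(10000))
  expect_lt(abs(correlation_to_reference(big, 1, 2)), 0.05)
  expect_error(correlation_to_reference(
    cbind(rep(1, 5), rnorm(5)), 1, 2), "zero-variance")
})
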