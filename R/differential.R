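#' @importFrom stats pnorm dbinom dnbinom median p.adjust cor setNames
NULL

#' Quality-control filter for single-nucleus count matrices
#'
#' Retains cells whose number of detected features lies in
#' `[min_features, max_features]` and whose total UMI count is at most
#' `max_umi`. Boundary values are retained: the discard rule is strictly
#' fewer than `min_features`, strictly more than `max_features`, or
#' strictly more than `max_umi`.
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse) of
#'   non-negative integer counts.
#' @param cell_meta Optional `data.frame` of per-cell annotations
#'   (one row per column of `counts`); filtered in step.
#' @param min_features,max_features Bounds on detected features per cell.
#' @param max_umi Maximum total UMI count per cell.
#' @return A list with `counts` (filtered matrix), `cell_meta` (filtered
#'   annotations or `NULL`) and `removed` (named counts of cells discarded
#'   by each rule and in total).
#' @export
qc_filter_cells <- function(counts, cell_meta = NULL, min_features = 500,
                            max_features = 3000, max_umi = 40000) {
  stopifnot(min_features > 0, max_features > min_features, max_umi > 0)
  n_feat <- Matrix::colSums(counts > 0)
  n_umi <- Matrix::colSums(counts)
  low <- n_feat < min_features
  high <- n_feat > max_features
  deep <- n_umi > max_umi
  keep <- !(low | high | deep)
  if (!any(keep)) warning("qc_filter_cells: all cells removed")
  list(
    counts = counts[, keep, drop = FALSE],
    cell_meta = if (is.null(cell_meta)) NULL else
      cell_meta[keep, , drop = FALSE],
    removed = c(low_features = sum(low), high_features = sum(high),
                high_umi = sum(deep), total = sum(!keep)))
}

#' Library-size log-normalization (counts per `scale`, log1p)
#'
#' Each cell's counts are scaled to a common total of `scale` and
#' transformed with the natural log1p:
#' `log(1 + count * scale / cell_total)`.
#'
#' @param counts genes x cells count matrix; no cell may have zero total.
#' @param scale Common library size after scaling (default 10000).
#' @return Matrix of the same shape and class family as the input.
#' @export
lognormalize <- function(counts, scale = 10000) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stop("lognormalize: cell(s) with zero total count")
  if (is(counts, "sparseMatrix")) {
    norm <- counts %*% Matrix::Diagonal(x = scale / totals)
    norm@x <- log1p(norm@x)
    dimnames(norm) <- dimnames(counts)
    norm
  } else {
    log1p(sweep(counts, 2, totals / scale, "/"))
  }
}

#' Per-gene log2 fold change between two cell groups
#'
#' Means are taken on the de-logged normalized scale (`expm1` of the
#' log-normalized values, i.e. counts-per-`scale`), a pseudocount is added
#' to both, and the ratio is logged:
#' `log2((mean_A + pc) / (mean_B + pc))`.
#'
#' @param norm Log-normalized matrix (see [lognormalize()]).
#' @param cells_a,cells_b Column indices or logical masks for the groups.
#' @param pseudocount Added to both group means (default 1).
#' @return Named numeric vector of per-gene log2 fold changes (A over B).
#' @export
log2fc <- function(norm, cells_a, cells_b, pseudocount = 1) {
  ma <- group_expm1_means(norm, cells_a)
  mb <- group_expm1_means(norm, cells_b)
  setNames(log2((ma + pseudocount) / (mb + pseudocount)), rownames(norm))
}

group_expm1_means <- function(norm, cells) {
  sub <- norm[, cells, drop = FALSE]
  if (ncol(sub) == 0L) stop("empty cell group")
  if (is(sub, "sparseMatrix")) {
    sub@x <- expm1(sub@x)
    Matrix::rowMeans(sub)
  } else {
    rowMeans(expm1(sub))
  }
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration of the permutation distribution of the rank sum when
#' both groups have at most `exact_limit` observations (ties handled via
#' midranks); otherwise the normal approximation with tie correction and
#' continuity correction. The two-sided exact p doubles the smaller tail
#' probability (capped at 1).
#'
#' @param x,y Numeric observations for the two groups (each of length >= 2,
#'   below for the DEG wrapper; length >= 1 accepted here).
#' @param exact_limit Largest group size for the exact path (default 8).
#' @param exact Force (`TRUE`)/suppress (`FALSE`) exact enumeration;
#'   `NULL` (default) applies the size rule.
#' @return The two-sided p-value.
#' @export
wilcoxon_test <- function(x, y, exact_limit = 8, exact = NULL) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 1, ny >= 1)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  use_exact <- if (is.null(exact)) nx <= exact_limit && ny <= exact_limit
               else exact
  if (use_exact) {
    combos <- utils::combn(nx + ny, nx)
    sums <- colSums(matrix(r[combos], nrow = nx))
    tol <- 1e-8
    lower <- mean(sums <= w + tol)
    upper <- mean(sums >= w - tol)
    min(1, 2 * min(lower, upper))
  } else {
    n <- nx + ny
    mu <- nx * (n + 1) / 2
    tie_tab <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                                (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  }
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' For every gene, a two-sided rank-sum test on normalized expression
#' between groups A and B, a log2 fold change on de-logged means, multiple
#' testing correction, and a call: `up` when `log2fc >= lfc_threshold` and
#' the (adjusted) p is below `alpha`, `down` mirrored, `ns` otherwise.
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param cells_a,cells_b Column indices/masks; each group needs >= 2 cells.
#' @param lfc_threshold Absolute log2 fold-change cut-off (default 0.5).
#' @param alpha Significance level on the adjusted p (default 0.01).
#' @param correction `"bonferroni"` (default) or `"bh"`.
#' @param alpha_on Apply `alpha` to `"p_adj"` (default) or raw `"p"`.
#' @param exact_limit Passed to [wilcoxon_test()].
#' @return `data.frame` with columns `feature`, `log2fc`, `p`, `p_adj`,
#'   `call`.
#' @export
wilcoxon_deg <- function(norm, cells_a, cells_b, lfc_threshold = 0.5,
                         alpha = 0.01, correction = c("bonferroni", "bh"),
                         alpha_on = c("p_adj", "p"), exact_limit = 8) {
  correction <- match.arg(correction)
  alpha_on <- match.arg(alpha_on)
  a <- as.matrix(norm[, cells_a, drop = FALSE])
  b <- as.matrix(norm[, cells_b, drop = FALSE])
  if (ncol(a) < 2 || ncol(b) < 2) stop("each group needs at least 2 cells")
  na <- ncol(a); nb <- ncol(b); n <- na + nb
  ## normal-approximation path vectorized over genes; exact path per gene
  if (na <= exact_limit && nb <= exact_limit) {
    p <- vapply(seq_len(nrow(a)), function(i)
      wilcoxon_test(a[i, ], b[i, ], exact_limit = exact_limit), numeric(1))
  } else {
    dat <- cbind(a, b)
    rk <- t(apply(dat, 1, rank))
    w <- rowSums(rk[, seq_len(na), drop = FALSE])
    mu <- na * (n + 1) / 2
    tie_term <- apply(rk, 1, function(r) {
      tt <- table(r); sum(tt^3 - tt)
    })
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- ifelse(sigma2 > 0,
                (w - mu - sign(w - mu) * 0.5) / sqrt(pmax(sigma2, 1e-300)),
                0)
    p <- pmin(1, 2 * pnorm(-abs(z)))
    p[sigma2 <= 0] <- 1
  }
  lfc <- log2fc(norm, cells_a, cells_b)
  p_adj <- adjust_pvalues(p, method = correction)
  feature <- if (is.null(rownames(norm))) as.character(seq_len(nrow(a)))
             else rownames(norm)
  build_diff_result(feature, lfc, p, p_adj, lfc_threshold, alpha, alpha_on)
}

build_diff_result <- function(feature, lfc, p, p_adj, lfc_threshold, alpha,
                              alpha_on = "p_adj") {
  crit <- if (alpha_on == "p_adj") p_adj else p
  call <- rep("ns", length(p))
  call[crit < alpha & lfc >= lfc_threshold] <- "up"
  call[crit < alpha & lfc <= -lfc_threshold] <- "down"
  data.frame(feature = as.character(feature), log2fc = as.numeric(lfc),
             p = p, p_adj = p_adj, call = call, row.names = NULL)
}

#' Multiple-testing correction
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up with
#' monotonicity enforcement, via [stats::p.adjust()].
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
adjust_pvalues <- function(pvals, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = if (method == "bh") "BH" else "bonferroni")
}

#' Median-of-ratios size factors for a count matrix
#'
#' DESeq-style: per sample, the median across features of the ratio of its
#' count to the feature's geometric mean, using features with all-positive
#' counts. Factors are rescaled to geometric mean 1.
#'
#' @param counts regions x samples count matrix.
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no feature with all-positive counts")
  logc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(logc)
  sf <- apply(logc, 2, function(col) exp(median(col - ref)))
  sf / exp(mean(log(sf)))
}

#' Method-of-moments common dispersion for region counts
#'
#' Counts are normalized by median-of-ratios size factors; within each
#' condition group, per-feature sample means and variances are formed and
#' the excess variance over the mean is pooled across features and groups
#' with a ratio estimator: `phi = max(0, sum(v - m) / sum(m^2))`, the
#' moment solution of `Var = mu + phi * mu^2`.
#'
#' @param counts regions x samples count matrix.
#' @param groups Factor/vector of condition labels, one per sample; every
#'   level used must have >= 2 samples.
#' @return A single non-negative dispersion estimate.
#' @export
estimate_common_dispersion <- function(counts, groups) {
  counts <- as.matrix(counts)
  groups <- as.factor(as.character(groups))
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  sf <- size_factors(counts)
  normed <- sweep(counts, 2, sf, "/")
  num <- 0; den <- 0
  for (g in levels(groups)) {
    sub <- normed[, groups == g, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    keep <- m > 0
    num <- num + sum(v[keep] - m[keep])
    den <- den + sum(m[keep]^2)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

## Two-sided exact-conditional NB p-value for one feature.
## ya, yb: integer group totals; na, nb: group sizes; phi: dispersion.
## Conditions on t = ya + yb; under H0 (equal means, equal library sizes)
## the conditional law of ya is dnbinom(a, na/phi) * dnbinom(t-a, nb/phi)
## renormalized (Binomial(t, na/(na+nb)) at phi = 0). Two-sided p sums the
## probabilities of all outcomes no more likely than the observed one.
nb_exact_pvalue <- function(ya, yb, na, nb, phi) {
  t <- ya + yb
  if (t == 0) return(1)
  a <- 0:t
  if (phi <= 0) {
    logp <- dbinom(a, t, na / (na + nb), log = TRUE)
  } else {
    ra <- na / phi; rb <- nb / phi
    logp <- lgamma(a + ra) - lgamma(a + 1) +
      lgamma(t - a + rb) - lgamma(t - a + 1)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  pobs <- logp[ya + 1]
  ## relative tie tolerance 1e-7, the convention of exact-binomial software
  min(1, sum(exp(logp[logp <= pobs + 1e-7])))
}

#' Exact-conditional negative-binomial differential test for region counts
#'
#' Library sizes are equalized by median-of-ratios size factors and the
#' rescaled counts rounded to integer pseudo-counts. Per feature, the test
#' conditions on the pseudo-count total across both groups and sums the
#' conditional probabilities of all outcomes as or less likely than the
#' observed group split, under the null of equal means with the supplied
#' common dispersion. At dispersion 0 this is the exact binomial test of
#' the group-A total against `Binomial(total, n_a / (n_a + n_b))`.
#'
#' @param counts regions x samples count matrix.
#' @param cond Vector of condition labels, one per sample.
#' @param cond_a,cond_b The two condition labels to contrast (A over B).
#' @param dispersion Common NB dispersion `phi >= 0` (`Var = mu + phi mu^2`);
#'   estimate with [estimate_common_dispersion()] if unknown.
#' @param lfc_threshold Absolute log2 fold-change cut-off (default 1).
#' @param alpha Significance level (default 0.01).
#' @param alpha_on Apply `alpha` to raw `"p"` (default, nominal-p policy) or
#'   to BH-adjusted `"fdr"`.
#' @param pseudocount Added to normalized group means for the fold change
#'   (default 1; means are on the per-size-factor scale).
#' @param size_factors Optional per-sample size factors (for the selected
#'   samples, in column order) overriding the median-of-ratios estimate;
#'   use `rep(1, n)` when library sizes are known equal.
#' @return `data.frame` with `feature`, `log2fc`, `p`, `p_adj` (BH), `call`.
#' @export
nb_exact_test <- function(counts, cond, cond_a, cond_b, dispersion,
                          lfc_threshold = 1, alpha = 0.01,
                          alpha_on = c("p", "fdr"), pseudocount = 1,
                          size_factors = NULL) {
  alpha_on <- match.arg(alpha_on)
  if (dispersion < 0) stop("dispersion must be >= 0")
  counts <- as.matrix(counts)
  cond <- as.character(cond)
  if (!cond_a %in% cond || !cond_b %in% cond) {
    stop("contrast condition absent from 'cond'")
  }
  sel <- cond %in% c(cond_a, cond_b)
  sub <- counts[, sel, drop = FALSE]
  grp <- cond[sel]
  sf <- if (is.null(size_factors)) adipomem::size_factors(sub) else {
    stopifnot(length(size_factors) == ncol(sub), all(size_factors > 0))
    size_factors
  }
  pseudo <- round(sweep(sub, 2, sf, "/"))
  ia <- grp == cond_a; ib <- grp == cond_b
  na <- sum(ia); nb <- sum(ib)
  ya <- rowSums(pseudo[, ia, drop = FALSE])
  yb <- rowSums(pseudo[, ib, drop = FALSE])
  p <- vapply(seq_along(ya), function(i)
    nb_exact_pvalue(ya[i], yb[i], na, nb, dispersion), numeric(1))
  lfc <- log2((ya / na + pseudocount) / (yb / nb + pseudocount))
  p_adj <- adjust_pvalues(p, method = "bh")
  feature <- if (is.null(rownames(counts))) as.character(seq_len(nrow(counts)))
             else rownames(counts)
  build_diff_result(feature, lfc, p, p_adj, lfc_threshold, alpha,
                    alpha_on = if (alpha_on == "fdr") "p_adj" else "p")
}

#' Pearson correlation of a sample against an aggregated control
#'
#' The reference profile is the element-wise mean of the control columns;
#' the statistic is the Pearson correlation between the query column and
#' that reference.
#'
#' @param mat Normalized features x samples matrix (>= 2 features).
#' @param control_samples Column indices/names of the control samples.
#' @param query_sample Single column index/name to compare.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
correlation_to_reference <- function(mat, control_samples, query_sample) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need >= 2 features")
  ctrl <- mat[, control_samples, drop = FALSE]
  if (ncol(ctrl) == 0) stop("control_samples is empty")
  ref <- rowMeans(ctrl)
  qry <- mat[, query_sample]
  if (stats::sd(ref) == 0 || stats::sd(qry) == 0) {
    stop("zero-variance profile; correlation undefined")
  }
  cor(qry, ref, method = "pearson")
}
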