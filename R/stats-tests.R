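#' Two-sided correlation test
#'
#' Pearson or Spearman correlation with the t-approximation
#' t = r sqrt(n-2) / sqrt(1-r^2) on n-2 degrees of freedom. With
#' `method = "auto"` a Shapiro-Wilk normality gate picks Pearson when both
#' variables look normal (p >= 0.05) and Spearman otherwise.
#'
#' @param x,y Numeric vectors.
#' @param method "pearson", "spearman", or "auto".
#' @return List (r, p, n, method).
#' @export
corr_test <- function(x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input")
  if (method == "auto") {
    px <- stats::shapiro.test(x)$p.value
    py <- stats::shapiro.test(y)$p.value
    method <- if (px >= 0.05 && py >= 0.05) "pearson" else "spearman"
  }
  r <- stats::cor(x, y, method = method)
  list(r = r, p = corr_pvalue(r, n), n = n, method = method)
}

#' Two-sided p-value of a correlation coefficient from (r, n)
#'
#' @param r Correlation coefficient.
#' @param n Sample size.
#' @return Two-sided p-value from the t distribution on n-2 df.
#' @export
corr_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3)), referred to the
#' standard normal. One-sided alternatives: "less" tests r1 < r2,
#' "greater" tests r1 > r2.
#'
#' @param r1,n1 First correlation and its sample size.
#' @param r2,n2 Second correlation and its sample size.
#' @param alternative "two.sided", "less", or "greater".
#' @return List (z, p, alternative).
#' @export
compare_correlations_fisher <- function(r1, n1, r2, n2,
                                        alternative = c("two.sided", "less",
                                                        "greater")) {
  alternative <- match.arg(alternative)
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both samples")
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              less = stats::pnorm(z),
              greater = stats::pnorm(z, lower.tail = FALSE))
  list(z = z, p = p, alternative = alternative)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; monotone in the raw ranks and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Edge-wise genotype contrast of Fisher-z connectivity matrices
#'
#' Per ROI pair: beta = mean z(group A) - mean z(group B), a pooled
#' two-sample t statistic (the GLM two-sample contrast on Fisher-z edges),
#' the uncorrected two-sided p, and the Benjamini-Hochberg FDR-adjusted p
#' across all edges. Per-group one-sample tests of mean z != 0 are also
#' reported (with their own across-edge FDR), since within-group
#' significance is part of the standard reporting.
#'
#' @param z_matrices List of `connectivity_matrix` objects (identical ROI
#'   sets), one per subject.
#' @param groups Factor/character of group labels, one per subject (2
#'   levels; the contrast is level1 - level2).
#' @return data.frame of edge rows sorted by `p_unc`.
#' @export
edge_group_compare <- function(z_matrices, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (length(z_matrices) != length(groups))
    stop("one connectivity matrix per subject required")
  if (any(table(groups) < 2)) stop("each group needs at least 2 subjects")
  labs <- rownames(z_matrices[[1]])
  k <- nrow(z_matrices[[1]])
  for (z in z_matrices)
    if (nrow(z) != k || !identical(rownames(z), labs))
      stop("all matrices must share the same ROI set")
  ut <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  Z <- sapply(z_matrices, function(z) unclass(z)[ut])  # edges x subjects
  Z <- matrix(Z, nrow = nrow(ut))
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  i1 <- groups == g1; i2 <- groups == g2
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(Z[, i1, drop = FALSE])
  m2 <- rowMeans(Z[, i2, drop = FALSE])
  v1 <- apply(Z[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(Z[, i2, drop = FALSE], 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  beta <- m1 - m2
  Tstat <- beta / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_unc <- 2 * stats::pt(-abs(Tstat), df = n1 + n2 - 2)
  one_sample <- function(M, V, n) {
    T1 <- M / sqrt(V / n)
    p1 <- 2 * stats::pt(-abs(T1), df = n - 1)
    list(T = T1, p = p1, p_fdr = bh_fdr(p1))
  }
  os1 <- one_sample(m1, v1, n1)
  os2 <- one_sample(m2, v2, n2)
  out <- data.frame(
    roi_i = labs[ut[, 1]], roi_j = labs[ut[, 2]],
    beta = beta, T = Tstat, p_unc = p_unc, p_fdr = bh_fdr(p_unc),
    stringsAsFactors = FALSE)
  out[[paste0("mean_z_", g1)]] <- m1
  out[[paste0("T_", g1)]] <- os1$T
  out[[paste0("p_fdr_", g1)]] <- os1$p_fdr
  out[[paste0("mean_z_", g2)]] <- m2
  out[[paste0("T_", g2)]] <- os2$T
  out[[paste0("p_fdr_", g2)]] <- os2$p_fdr
  out <- out[order(out$p_unc), ]
  rownames(out) <- NULL
  attr(out, "contrast") <- paste(g1, "-", g2)
  out
}
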