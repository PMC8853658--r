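# Group-level statistics on classification outputs.

#' Fisher's exact test on two responsive proportions
#'
#' Two-sided exact hypergeometric p-value (sum of table probabilities not
#' exceeding the observed table's probability) for k1/n1 versus k2/n2, plus
#' the sample odds ratio k1 (n2 - k2) / ((n1 - k1) k2) with an infinity
#' sentinel on a zero denominator.
#'
#' @param k1,n1 responsive count and total in group 1.
#' @param k2,n2 responsive count and total in group 2.
#' @return list with `odds_ratio`, `p_value`, and the input counts.
#' @export
fisher_proportions <- function(k1, n1, k2, n2) {
  counts <- c(k1 = k1, n1 = n1, k2 = k2, n2 = n2)
  if (any(counts < 0) || k1 > n1 || k2 > n2 ||
      any(counts != round(counts)))
    stopf("need integer counts with 0 <= k <= n in both groups")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2)
  p <- stats::fisher.test(tab)$p.value
  denom <- (n1 - k1) * k2
  or <- if (denom == 0) Inf else k1 * (n2 - k2) / denom
  list(odds_ratio = or, p_value = min(p, 1), k1 = k1, n1 = n1, k2 = k2,
       n2 = n2)
}

#' Two- or one-sided standard normal critical value
#'
#' The Z thresholds used by the classification rules are the two-sided
#' critical values at their stated levels: 2.58 at p < 0.01, 1.96 at
#' p < 0.05, 3.29 at p < 0.001 (to two decimals).
#'
#' @param alpha significance level in (0, 1).
#' @param tails `"two"` (default) or `"one"`.
#' @return the Z threshold.
#' @export
normal_critical_value <- function(alpha, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stopf("alpha must be in (0, 1)")
  stats::qnorm(1 - alpha / if (tails == "two") 2 else 1)
}

#' Principal component analysis of behavioral features
#'
#' Columns are standardized (the PCA is an eigendecomposition of the
#' correlation matrix, appropriate when features mix percentages and
#' seconds); components are ordered by eigenvalue and each loading vector's
#' sign is fixed so its largest-magnitude entry is positive.
#'
#' @param features data.frame or matrix, one row per subject, numeric
#'   behavioral features in columns (>= 3 subjects; constant columns are an
#'   error).
#' @return object of class `behavior_pca`: `loadings` (features x PCs),
#'   `explained_variance` (% per PC, sums to 100), `eigenvalues`, `scores`.
#' @export
pca_behavior <- function(features) {
  x <- as.matrix(features[vapply(as.data.frame(features), is.numeric, TRUE)])
  if (nrow(x) < 3) stopf("pca_behavior requires >= 3 subjects")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stopf("constant column(s): %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  xs <- scale(x)
  e <- eigen(stats::cor(x), symmetric = TRUE)
  load <- e$vectors
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  ev <- pmax(e$values, 0)
  structure(list(loadings = load,
                 explained_variance = 100 * ev / sum(ev),
                 eigenvalues = ev,
                 scores = xs %*% load),
            class = "behavior_pca")
}

#' @export
print.behavior_pca <- function(x, ...) {
  cat("<behavior_pca>\n  explained variance (%):",
      paste(sprintf("%.1f", x$explained_variance), collapse = ", "), "\n")
  cat("  PC1 loadings:\n")
  l <- x$loadings[, 1]
  for (nm in names(l)) cat(sprintf("    %-18s %6.2f\n", nm, l[nm]))
  invisible(x)
}
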