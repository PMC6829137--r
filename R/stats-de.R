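# Differential expression layer: median-of-ratios size factors, a
# negative-binomial Wald test with method-of-moments dispersion, and
# Benjamini-Hochberg adjustment.  This is a deliberately simple, fully
# specified stand-in for DESeq2-class machinery: the thresholds (FDR < 0.05,
# fold change >= 2), not any particular shrinkage estimator, define the
# method being reproduced.

#' Median-of-ratios size factors
#'
#' For each library, the median over features of count / (geometric mean of
#' the feature across libraries), restricted to features positive in all
#' libraries.
#'
#' @param counts Integer matrix, features x libraries (>= 2 libraries).
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 2L) stop("size factors need at least 2 libraries")
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) stop("no feature is positive in all libraries")
  lc <- log(counts[keep, , drop = FALSE])
  gm <- rowMeans(lc)
  sf <- apply(lc, 2L, function(v) exp(median(v - gm)))
  setNames(sf, colnames(counts))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: for order statistics `p_(i)`,
#' `padj_(i) = min_{j >= i} ( m * p_(j) / j )`, capped at 1.  `NA` p-values
#' are passed through and excluded from `m`.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * pv[o]))
  out[ok[o]] <- adj
  out
}

#' Negative-binomial Wald test between two groups of libraries
#'
#' Counts are normalized by size factors; per-feature dispersion is
#' estimated by the method of moments on normalized counts pooled across
#' both groups (`alpha = max(0, (s^2 - mu) / mu^2)`, i.e. a Poisson fallback
#' when the data are underdispersed or replicates are lacking).  The Wald
#' statistic tests `log2FC = log2((meanB + pc) / (meanA + pc))` against 0
#' using a delta-method standard error; p-values are two-sided normal and
#' BH-adjusted over the tested features.
#'
#' @param counts_a,counts_b Count matrices (features x replicates) for the
#'   two groups, same feature rows.
#' @param sf Size factors for `cbind(counts_a, counts_b)` (default:
#'   computed with [size_factors()]).
#' @param pseudocount Added to both normalized means for the fold change
#'   (default 0.5).
#' @return `data.table`: `feature`, `base_mean_a`, `base_mean_b`, `log2fc`,
#'   `p`, `padj`, `call` (`"up"` = higher in B, `"down"`, `"ns"`).
#'   All-zero features get `NA` p-values and `"ns"`.
#' @export
nb_differential_test <- function(counts_a, counts_b, sf = NULL,
                                 pseudocount = 0.5) {
  if (nrow(counts_a) != nrow(counts_b))
    stop("count matrices must share their feature rows")
  all_counts <- cbind(counts_a, counts_b)
  if (is.null(sf)) sf <- size_factors(all_counts)
  na <- ncol(counts_a); nb <- ncol(counts_b)
  norm <- sweep(all_counts, 2L, sf, "/")
  norm_a <- norm[, seq_len(na), drop = FALSE]
  norm_b <- norm[, na + seq_len(nb), drop = FALSE]
  mu_a <- rowMeans(norm_a); mu_b <- rowMeans(norm_b)
  # pooled method-of-moments dispersion on within-group deviations
  mu_all <- (mu_a * na + mu_b * nb) / (na + nb)
  dev2 <- rowSums((norm_a - mu_a)^2) + rowSums((norm_b - mu_b)^2)
  df <- na + nb - 2L
  s2 <- if (df > 0L) dev2 / df else rep(0, length(mu_all))
  alpha <- pmax(0, (s2 - mu_all) / mu_all^2)
  alpha[!is.finite(alpha)] <- 0
  log2fc <- log2((mu_b + pseudocount) / (mu_a + pseudocount))
  # Var(log2 mean_g) ~ (mu_g + alpha mu_g^2) / (n_g * mu_g^2 * ln(2)^2)
  v_a <- (mu_a + alpha * mu_a^2) / (na * pmax(mu_a, pseudocount)^2)
  v_b <- (mu_b + alpha * mu_b^2) / (nb * pmax(mu_b, pseudocount)^2)
  se <- sqrt(v_a + v_b) / log(2)
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))
  p[mu_a == 0 & mu_b == 0] <- NA_real_
  padj <- bh_adjust(p)
  feature <- rownames(all_counts)
  if (is.null(feature)) feature <- as.character(seq_len(nrow(all_counts)))
  res <- data.table(feature = feature, base_mean_a = mu_a, base_mean_b = mu_b,
                    log2fc = log2fc, p = p, padj = padj)
  res[, call := fifelse(is.na(padj), "ns",
                 fifelse(padj < 0.05 & log2fc >= 1, "up",
                  fifelse(padj < 0.05 & log2fc <= -1, "down", "ns")))]
  res[]
}

#' Call differentially expressed families and parent-exclusive sets
#'
#' DE iff `padj < fdr_max` and `|fold change| >= fc_min` (fold-change bound
#' inclusive, FDR bound strict).  When expressed-feature sets for the two
#' groups are supplied, DE features expressed in exactly one group form the
#' exclusive sets.
#'
#' @param results `data.table` from [nb_differential_test()].
#' @param fc_min Fold-change cutoff on the natural scale (default 2).
#' @param fdr_max FDR cutoff (default 0.05).
#' @param expressed_a,expressed_b Optional character vectors of features
#'   called expressed in group A / B.
#' @return List: `up_in_b`, `up_in_a` (character vectors of features),
#'   `exclusive_a`, `exclusive_b` (subsets expressed in exactly one group;
#'   `NULL` without expression calls), and `table` (the annotated results).
#' @export
call_de_families <- function(results, fc_min = 2, fdr_max = 0.05,
                             expressed_a = NULL, expressed_b = NULL) {
  r <- copy(results)
  lfc <- log2(fc_min)
  r[, de := !is.na(padj) & padj < fdr_max & abs(log2fc) >= lfc]
  up_in_b <- r[de == TRUE & log2fc > 0, feature]
  up_in_a <- r[de == TRUE & log2fc < 0, feature]
  excl_a <- excl_b <- NULL
  if (!is.null(expressed_a) && !is.null(expressed_b)) {
    de_all <- r[de == TRUE, feature]
    excl_a <- intersect(de_all, setdiff(expressed_a, expressed_b))
    excl_b <- intersect(de_all, setdiff(expressed_b, expressed_a))
  }
  list(up_in_b = up_in_b, up_in_a = up_in_a,
       exclusive_a = excl_a, exclusive_b = excl_b, table = r[])
}
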