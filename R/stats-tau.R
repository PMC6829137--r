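# Tissue-specificity index tau, computed on log2(1 + RPM) transformed
# expression profiles:  tau = sum_i (1 - x_i / max(x)) / (N - 1).
# 0 = perfectly constitutive, 1 = expressed in a single condition.

#' Tau tissue-specificity index
#'
#' @param x Non-negative per-condition expression values (already
#'   transformed; use `log2(1 + RPM)` for RPM input), length >= 2.
#' @return Tau in `[0, 1]`, or `NA` when `max(x) == 0`.
#' @examples
#' tau(c(0, 0, 5))   # 1: single-condition expression
#' tau(c(2, 2, 2))   # 0: constitutive
#' tau(c(4, 1, 1))   # 0.75
#' @export
tau <- function(x) {
  if (length(x) < 2L) stop("tau needs at least 2 conditions")
  if (anyNA(x) || any(x < 0)) stop("tau needs non-negative, non-missing input")
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1L)
}

#' Tau for every row of an expression matrix
#'
#' Transforms RPM to `log2(1 + RPM)`, optionally averages replicates per
#' condition, and applies [tau()] per feature.
#'
#' @param x An `expression_matrix` or RPM matrix (features x libraries).
#' @param features Optional subset of feature names (default: all; the
#'   conventional choice is the expressed set from [call_expressed()]).
#' @param group_by Optional metadata column to average replicates over
#'   before computing tau (requires an `expression_matrix`).
#' @return `data.table` with columns `feature`, `tau`, `n_conditions`.
#' @export
tau_matrix <- function(x, features = NULL, group_by = NULL) {
  rpm <- if (inherits(x, "expression_matrix")) x$rpm else x
  if (!is.null(features)) rpm <- rpm[rownames(rpm) %in% features, , drop = FALSE]
  tr <- log2(1 + rpm)
  if (!is.null(group_by)) {
    if (!inherits(x, "expression_matrix") || !group_by %in% names(x$metadata))
      stop("group_by needs an expression_matrix with metadata column '",
           group_by, "'")
    tr <- group_means(tr, x$metadata[[group_by]])
  }
  data.table(feature = rownames(tr),
             tau = apply(tr, 1L, function(v) if (max(v) == 0) NA_real_
                         else sum(1 - v / max(v)) / (length(v) - 1L)),
             n_conditions = ncol(tr))
}
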