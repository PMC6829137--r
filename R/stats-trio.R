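# Hybrid trio analysis: deviation of F1 expression from the mid-parent
# value, and non-additivity classification from the two F1-vs-parent
# differential tests.

#' Log2 deviation of hybrid expression from the mid-parent value
#'
#' `log2((f1 + pc) / ((p1 + p2)/2 + pc))`: 0 = exactly additive, positive =
#' above mid-parent, negative = below.
#'
#' @param f1,p1,p2 RPM values (vectors recycle).
#' @param pseudocount Added to hybrid and mid-parent values (default 0.5).
#' @return Numeric vector of log2 deviations.
#' @examples
#' midparent_deviation(15, 10, 20, pseudocount = 0)  # 0
#' midparent_deviation(30, 10, 20, pseudocount = 0)  # 1
#' @export
midparent_deviation <- function(f1, p1, p2, pseudocount = 0.5) {
  mp <- (p1 + p2) / 2
  if (any(mp + pseudocount <= 0)) stop("mid-parent + pseudocount must be positive")
  log2((f1 + pseudocount) / (mp + pseudocount))
}

#' Classify hybrid additivity from the two F1-vs-parent contrasts
#'
#' A feature is non-additive `above_both` when the F1 is significantly
#' higher than each parent (call `"up"` in both F1-vs-P1 and F1-vs-P2 at the
#' DE thresholds), `below_both` when significantly lower than each parent,
#' and `additive_range` otherwise.
#'
#' @param de_p1,de_p2 `data.table`s from [nb_differential_test()] with group
#'   A = the parent and group B = the F1 (so `"up"` means higher in the F1).
#' @return `data.table`: `feature`, `class`, plus the per-contrast calls.
#'   Features present in only one contrast are skipped with a warning.
#' @export
classify_additivity <- function(de_p1, de_p2) {
  common <- intersect(de_p1$feature, de_p2$feature)
  miss <- length(setdiff(union(de_p1$feature, de_p2$feature), common))
  if (miss > 0L)
    warning(miss, " feature(s) missing from one contrast were skipped")
  a <- de_p1[feature %chin% common, .(feature, call_p1 = call)]
  b <- de_p2[feature %chin% common, .(feature, call_p2 = call)]
  out <- merge(a, b, by = "feature")
  out[, class := fifelse(call_p1 == "up" & call_p2 == "up", "above_both",
                  fifelse(call_p1 == "down" & call_p2 == "down", "below_both",
                          "additive_range"))]
  out[]
}

#' Per-tissue tally of non-additive families
#'
#' @param trio_results Named list (by tissue) of [classify_additivity()]
#'   tables.
#' @return `data.table`: `tissue`, `above_both`, `below_both`,
#'   `non_additive` (their sum).
#' @export
nonadditive_counts <- function(trio_results) {
  rbindlist(lapply(names(trio_results), function(tt) {
    cl <- trio_results[[tt]]$class
    data.table(tissue = tt,
               above_both = sum(cl == "above_both"),
               below_both = sum(cl == "below_both"),
               non_additive = sum(cl != "additive_range"))
  }))
}
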