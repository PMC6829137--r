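# Expression layer: RPM normalization over the assigned-read universe,
# expressed-feature calling, per-library TE contribution summaries, and
# tissue-specificity set construction.
#
# The RPM denominator is the number of reads assigned unambiguously to genes
# or TE families (gene_unique + u_te.fam + m_te.fam); ambiguous te.g reads
# are tallied per library but excluded downstream.  The percent-TE summary
# is also offered with the ambiguous categories included, matching the
# per-category contribution plot.

#' RPM-normalize combined counts
#'
#' Denominator per library = sum of gene unique counts + sum of family
#' (u_te.fam + m_te.fam) counts; every feature's count is scaled to reads
#' per million of that total.  Element-level counts can be normalized with
#' the same library size via the returned `denominators`.
#'
#' @param family_sum `data.table` from [combine_family_counts()]
#'   (`$family_sum`): column `family` plus one count column per library.
#' @param gene_unique `data.table` with column `feature` plus one unique
#'   count column per library (same library columns), e.g. the gene rows of
#'   [combine_element_counts()] reduced to `<lib>.unique` columns renamed to
#'   `<lib>`.
#' @param metadata Optional `data.table` with columns `library_id`,
#'   `tissue`, `genotype`, `replicate`, `dataset` (any subset beyond
#'   `library_id`).
#' @return Object of class `expression_matrix`: list with `rpm` (numeric
#'   matrix, features x libraries; families then genes), `counts` (same
#'   shape, raw), `feature_type` (character vector "family"/"gene"),
#'   `denominators` (named numeric) and `metadata`.
#' @export
rpm_normalize <- function(family_sum, gene_unique, metadata = NULL) {
  libs <- setdiff(names(family_sum), "family")
  if (!identical(libs, setdiff(names(gene_unique), "feature")))
    stop("family and gene tables must share the same library columns")
  fam_m <- as.matrix(family_sum[, ..libs])
  rownames(fam_m) <- family_sum$family
  gene_m <- as.matrix(gene_unique[, ..libs])
  rownames(gene_m) <- gene_unique$feature
  counts <- rbind(fam_m, gene_m)
  denom <- colSums(counts)
  if (any(denom == 0))
    stop("zero assigned reads in librar",
         if (sum(denom == 0) > 1) "ies: " else "y: ",
         paste(libs[denom == 0], collapse = ", "))
  rpm <- sweep(counts, 2L, denom, "/") * 1e6
  md <- if (is.null(metadata)) data.table(library_id = libs)
        else merge(data.table(library_id = libs), metadata,
                   by = "library_id", all.x = TRUE, sort = FALSE)
  structure(list(rpm = rpm, counts = counts,
                 feature_type = c(rep("family", nrow(fam_m)),
                                  rep("gene", nrow(gene_m))),
                 denominators = denom, metadata = md),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$rpm), "features (",
      sum(x$feature_type == "family"), "families,",
      sum(x$feature_type == "gene"), "genes ) x", ncol(x$rpm), "libraries\n")
  invisible(x)
}

#' Call expressed features
#'
#' Three calling modes:
#' \describe{
#'   \item{`atlas`}{RPM strictly greater than `min_rpm` in at least
#'     `min_libraries` libraries (default > 1 RPM in >= 3 libraries).}
#'   \item{`replicate_mean`}{mean RPM across replicates of a condition
#'     >= `min_rpm` in at least one condition (`group_by` metadata column,
#'     default `tissue`).}
#'   \item{`single`}{RPM >= `min_rpm` in at least one library (the rule for
#'     panels without biological replicates).}
#' }
#'
#' @param x An `expression_matrix` (or plain RPM matrix).
#' @param mode `"atlas"`, `"replicate_mean"` or `"single"`.
#' @param min_rpm RPM threshold (default 1).
#' @param min_libraries Library count for atlas mode (default 3).
#' @param group_by Metadata column defining replicate groups.
#' @return Character vector of expressed feature names.
#' @export
call_expressed <- function(x, mode = c("atlas", "replicate_mean", "single"),
                           min_rpm = 1, min_libraries = 3,
                           group_by = "tissue") {
  mode <- match.arg(mode)
  rpm <- if (inherits(x, "expression_matrix")) x$rpm else x
  if (mode == "atlas") {
    keep <- rowSums(rpm > min_rpm) >= min_libraries
  } else if (mode == "single") {
    keep <- rowSums(rpm >= min_rpm) >= 1L
  } else {
    if (!inherits(x, "expression_matrix") || !group_by %in% names(x$metadata))
      stop("replicate_mean mode needs metadata column '", group_by, "'")
    grp <- x$metadata[[group_by]]
    gm <- group_means(rpm, grp)
    keep <- apply(gm, 1L, function(v) any(v >= min_rpm))
  }
  rownames(rpm)[keep]
}

# column-group means of a matrix (conditions in column order of appearance)
group_means <- function(m, groups) {
  ug <- unique(groups)
  out <- vapply(ug, function(g) rowMeans(m[, groups == g, drop = FALSE]),
                numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m),
                                       dimnames = list(rownames(m), ug))
  colnames(out) <- ug
  out
}

#' Percent of assigned reads attributed to TEs, per library
#'
#' From the per-library summary lines: the share of assigned reads that are
#' TE-derived, reported per category and in total.  With
#' `include_ambiguous = TRUE` (the per-category contribution convention)
#' both numerator and denominator include the ambiguous `te.g` categories;
#' with `FALSE` only unambiguous assignments (the RPM universe) are used.
#'
#' @param summaries `data.table` from [combine_summaries()].
#' @param include_ambiguous Include `u_te.g` / `m_te.g` (default `TRUE`).
#' @return `data.table` per library: percent per TE category and
#'   `te_percent` total.  `NA` when no reads are assigned.
#' @export
te_read_fraction <- function(summaries, include_ambiguous = TRUE) {
  s <- copy(summaries)
  cats <- if (include_ambiguous) c("u_te.fam", "m_te.fam", "u_te.g", "m_te.g")
          else c("u_te.fam", "m_te.fam")
  denom <- s$gene_unique + Reduce(`+`, lapply(cats, function(cn) s[[cn]]))
  out <- data.table(library_id = s$library_id, assigned = denom)
  for (cn in cats)
    out[, (paste0("pct_", cn)) := fifelse(denom > 0, 100 * s[[cn]] / denom,
                                          NA_real_)]
  out[, te_percent := Reduce(`+`, lapply(cats, function(cn)
    fifelse(denom > 0, 100 * s[[cn]] / denom, NA_real_)))]
  out[]
}

#' Contribution of the top-k TE families per library
#'
#' Families are ranked per library by family-sum counts (unique + multi,
#' ambiguous excluded); ties are broken lexicographically by family code.
#'
#' @param family_sum Family-sum `data.table` ([combine_family_counts()]).
#' @param k Number of top families (default 10).
#' @return `data.table` per library: `top_share` (percent of TE family reads
#'   captured by the top k), `top_family` (rank-1 family) and
#'   `top_family_share`.  `NA` when a library has no TE reads.
#' @export
top_family_contribution <- function(family_sum, k = 10) {
  stopifnot(k >= 1)
  libs <- setdiff(names(family_sum), "family")
  fams <- family_sum$family
  res <- lapply(libs, function(lb) {
    v <- family_sum[[lb]]
    tot <- sum(v)
    if (tot == 0)
      return(data.table(library_id = lb, top_share = NA_real_,
                        top_family = NA_character_, top_family_share = NA_real_))
    ord <- order(-v, fams)
    topk <- ord[seq_len(min(k, length(ord)))]
    data.table(library_id = lb,
               top_share = 100 * sum(v[topk]) / tot,
               top_family = fams[ord[1L]],
               top_family_share = 100 * v[ord[1L]] / tot)
  })
  rbindlist(res)
}

#' Row-relative expression on the log2(1 + RPM) scale
#'
#' Transforms RPM to `log2(1 + RPM)` and divides each row by its maximum,
#' so the most expressed library of each feature scales to exactly 1.
#' Rows whose maximum is 0 become all-`NA`.
#'
#' @param rpm RPM matrix (features x libraries) or `expression_matrix`.
#' @return Numeric matrix of the same shape.
#' @export
relative_expression <- function(rpm) {
  if (inherits(rpm, "expression_matrix")) rpm <- rpm$rpm
  tr <- log2(1 + rpm)
  mx <- apply(tr, 1L, max)
  out <- tr / mx
  out[mx == 0, ] <- NA_real_
  out
}

#' Constitutive and tissue-specific feature sets
#'
#' Replicate-mean RPM is computed per tissue; a feature is constitutive when
#' its mean is at least `min_rpm` in every tissue of the subset, and
#' tissue-specific when the threshold is met in exactly one tissue.
#'
#' @param x An `expression_matrix` with `tissue` metadata.
#' @param tissues Tissues forming the subset (default: all in metadata).
#' @param min_rpm Mean-RPM threshold (default 1).
#' @return List with `constitutive` (character vector) and `specific`
#'   (named list of character vectors, one per tissue).
#' @export
tissue_specific_sets <- function(x, tissues = NULL, min_rpm = 1) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!"tissue" %in% names(x$metadata)) stop("metadata lacks a 'tissue' column")
  if (is.null(tissues)) tissues <- unique(x$metadata$tissue)
  sel <- x$metadata$tissue %in% tissues
  if (!all(tissues %in% x$metadata$tissue))
    stop("tissue(s) with no libraries: ",
         paste(setdiff(tissues, x$metadata$tissue), collapse = ", "))
  gm <- group_means(x$rpm[, sel, drop = FALSE], x$metadata$tissue[sel])
  gm <- gm[, tissues, drop = FALSE]
  hit <- gm >= min_rpm
  n_hit <- rowSums(hit)
  constitutive <- rownames(gm)[n_hit == length(tissues)]
  specific <- lapply(setNames(tissues, tissues), function(tt)
    rownames(gm)[n_hit == 1L & hit[, tt]])
  list(constitutive = constitutive, specific = specific)
}
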