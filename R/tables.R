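# Cross-library combination of per-library counts into the four matrices:
# the four-column family matrix, the element/gene unique (+ te.g) matrix,
# the family sum matrix (u_te.fam + m_te.fam), and the proportion-unique
# matrix (u_te.fam / family_sum).

.lib_names <- function(libraries) {
  nm <- vapply(libraries, function(l) l$library_id, "")
  if (anyDuplicated(nm))
    stop("duplicate library names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  nm
}

#' Combine per-library family counts across libraries
#'
#' @param libraries List of `library_counts` objects ([count_library()]).
#' @param registry Optional family registry (`data.table` with a `family`
#'   column); when supplied, families never observed in any library are
#'   still emitted as zero rows.  When `NULL`, the union of observed
#'   families is used.
#' @return List of three `data.table`s keyed by `family`:
#'   `multi` (columns `<lib>.u_te.fam`, `<lib>.u_te.g`, `<lib>.m_te.fam`,
#'   `<lib>.m_te.g` per library), `family_sum` (one column per library,
#'   `u_te.fam + m_te.fam`), and `prop_unique` (u_te.fam / family_sum;
#'   `NA` where the sum is zero).
#' @export
combine_family_counts <- function(libraries, registry = NULL) {
  if (length(libraries) == 0L) stop("no libraries to combine")
  nm <- .lib_names(libraries)
  fams <- if (!is.null(registry)) sort(unique(registry$family))
          else sort(unique(unlist(lapply(libraries, function(l) l$family$family))))
  multi <- data.table(family = fams)
  fsum <- data.table(family = fams)
  prop <- data.table(family = fams)
  for (i in seq_along(libraries)) {
    f <- libraries[[i]]$family
    for (cn in c("u_te.fam", "u_te.g", "m_te.fam", "m_te.g")) {
      v <- setNames(f[[cn]], f$family)[fams]
      v[is.na(v)] <- 0L
      multi[, (paste0(nm[i], ".", cn)) := as.integer(v)]
    }
    s <- multi[[paste0(nm[i], ".u_te.fam")]] + multi[[paste0(nm[i], ".m_te.fam")]]
    fsum[, (nm[i]) := s]
    prop[, (nm[i]) := fifelse(s > 0L, multi[[paste0(nm[i], ".u_te.fam")]] / s,
                              NA_real_)]
  }
  list(multi = multi[], family_sum = fsum[], prop_unique = prop[])
}

#' Combine per-library element/gene counts across libraries
#'
#' @inheritParams combine_family_counts
#' @return A `data.table` keyed by `feature` and `type` with two columns per
#'   library: `<lib>.unique` and `<lib>.te.g`.
#' @export
combine_element_counts <- function(libraries) {
  if (length(libraries) == 0L) stop("no libraries to combine")
  nm <- .lib_names(libraries)
  feats <- unique(rbindlist(lapply(libraries, function(l)
    l$element[, .(feature, type)])))
  setorder(feats, type, feature)
  out <- copy(feats)
  for (i in seq_along(libraries)) {
    e <- libraries[[i]]$element
    u <- setNames(e$unique, e$feature)[feats$feature]
    g <- setNames(e$te.g, e$feature)[feats$feature]
    u[is.na(u)] <- 0L; g[is.na(g)] <- 0L
    out[, (paste0(nm[i], ".unique")) := as.integer(u)]
    out[, (paste0(nm[i], ".te.g")) := as.integer(g)]
  }
  out[]
}

#' Combine per-library summary lines
#'
#' @inheritParams combine_family_counts
#' @return One `data.table` row per library mirroring the per-library
#'   summary file.
#' @export
combine_summaries <- function(libraries) {
  .lib_names(libraries)
  rbindlist(lapply(libraries, function(l) l$summary))
}

#' Write the combined count tables
#'
#' @param tables Result of [combine_family_counts()].
#' @param elements Result of [combine_element_counts()].
#' @param summaries Result of [combine_summaries()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_combined_tables <- function(tables, elements, summaries, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(tables$multi, file.path(dir, "multi_combined_counts.txt"), sep = "\t")
  fwrite(elements, file.path(dir, "element_combined_counts.txt"), sep = "\t")
  fwrite(tables$family_sum, file.path(dir, "family_sum_combined_counts.txt"),
         sep = "\t")
  fwrite(tables$prop_unique, file.path(dir, "family_prop_unique.txt"),
         sep = "\t")
  fwrite(summaries, file.path(dir, "te_mapping_summary.txt"), sep = "\t")
  invisible(dir)
}
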