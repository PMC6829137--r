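# Segregation of family expression across a recombinant inbred line (RIL)
# panel: a single expressed element segregating 1:1 gives a bimodal
# expression distribution (expression in about half the lines), whereas
# several members contributing quantitatively give a unimodal one.  The dip
# test distinguishes the two; the presence fraction (share of RILs at or
# above an RPM threshold) summarizes segregation directly.

#' Dip-test segregation screen across RIL libraries
#'
#' Runs [dip_test()] on each requested family's expression values across the
#' RIL panel and reports the presence fraction (RPM >= `presence_rpm`).
#' The Monte-Carlo null table is computed once per distinct sample size and
#' shared across families.
#'
#' @param rpm RPM matrix, features x RIL libraries (>= 20 libraries).
#' @param families Features to test (default: all rows); absent features are
#'   skipped with a warning.
#' @param n_sim Monte-Carlo replicates for the dip null (default 2000).
#' @param seed Integer seed.
#' @param alpha Dip-test threshold (default 0.05).
#' @param call_convention Passed to [dip_test()] (default `"standard"`:
#'   `unimodal == TRUE` means the test failed to reject unimodality).
#' @param presence_rpm Presence threshold in RPM (default 1).
#' @return `data.table`: `feature`, `dip`, `p_value`, `unimodal`,
#'   `presence_fraction`, `n`.
#' @export
ril_segregation <- function(rpm, families = NULL, n_sim = 2000, seed = 1,
                            alpha = 0.05,
                            call_convention = c("standard", "p_lt_alpha"),
                            presence_rpm = 1) {
  call_convention <- match.arg(call_convention)
  if (ncol(rpm) < 20L) stop("RIL segregation needs at least 20 libraries")
  if (is.null(families)) families <- rownames(rpm)
  absent <- setdiff(families, rownames(rpm))
  if (length(absent))
    warning(length(absent), " famil",
            if (length(absent) > 1L) "ies" else "y",
            " absent from the matrix skipped")
  families <- intersect(families, rownames(rpm))
  null_tab <- dip_null(ncol(rpm), n_sim, seed)
  res <- lapply(families, function(f) {
    v <- rpm[f, ]
    dt <- dip_test(v, seed = seed, alpha = alpha,
                   call_convention = call_convention, null_table = null_tab)
    data.table(feature = f, dip = dt$statistic, p_value = dt$p_value,
               unimodal = dt$unimodal_call,
               presence_fraction = mean(v >= presence_rpm),
               n = length(v))
  })
  rbindlist(res)
}
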