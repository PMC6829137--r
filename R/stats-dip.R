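# Hartigan & Hartigan's dip statistic, implemented from the geometry of the
# empirical CDF: at each sorted observation x_(i) the ecdf occupies the
# vertical band [(i-1)/n, i/n].  A unimodal CDF is convex up to its mode and
# concave after it, so the best unimodal approximation threads between the
# greatest convex minorant (GCM) fitted through the lower band corners and
# the least concave majorant (LCM) through the upper corners.  The modal
# interval is located iteratively: while the maximal vertical gap between
# the two hull curves exceeds the largest one-sided hull deviation found so
# far, the interval shrinks to the hull touchpoints bracketing that gap and
# the deviations of the ecdf from its own hull outside the new interval are
# folded into the running maximum.  The dip is half the final maximum, with
# exact lower bound 1/(2n) (attained e.g. by constant samples).
#
# Touchpoint predecessors are built with cross-multiplied slope comparisons,
# so tied observations never divide by zero.

#' Hartigan's dip statistic
#'
#' Maximum distance between the empirical CDF and the closest unimodal CDF.
#' Scale- and shift-invariant; `dip_statistic(x) >= 1/(2n)` for every sample,
#' with equality for constant samples, and exactly 0.25 for any two distinct
#' points.
#'
#' @param x Numeric vector, `n >= 2`, finite.
#' @return The dip statistic (a single number in `[1/(2n), 0.25]`).
#' @references Hartigan, J. A. and Hartigan, P. M. (1985) The dip test of
#'   unimodality. *Annals of Statistics* 13, 70-84.
#' @export
dip_statistic <- function(x) {
  n <- length(x)
  if (n < 2L) stop("dip statistic needs at least 2 values")
  if (!all(is.finite(x))) stop("dip statistic needs finite values")
  x <- sort(x)
  if (x[1L] == x[n]) return(1 / (2 * n))

  # predecessor touchpoint of the convex minorant ending at each j
  mn <- integer(n); mn[1L] <- 1L
  for (j in 2:n) {
    mn[j] <- j - 1L
    repeat {
      a <- mn[j]; b <- mn[a]
      if (a == 1L || (x[j] - x[a]) * (a - b) < (x[a] - x[b]) * (j - a)) break
      mn[j] <- b
    }
  }
  # successor touchpoint of the concave majorant starting at each k
  mj <- integer(n); mj[n] <- n
  for (k in (n - 1L):1L) {
    mj[k] <- k + 1L
    repeat {
      a <- mj[k]; b <- mj[a]
      if (a == n || (x[k] - x[a]) * (a - b) < (x[a] - x[b]) * (k - a)) break
      mj[k] <- b
    }
  }
  # hull curve heights; GCM runs on lower band corners (i-1)/n, LCM on upper
  # corners i/n.  Vertical segments (tied x) take the corner height.
  gcm_line <- function(xq, a, b) {
    if (x[b] == x[a]) return((a - 1) / n)
    ((a - 1) + (b - a) * (xq - x[a]) / (x[b] - x[a])) / n
  }
  lcm_line <- function(xq, a, b) {
    if (x[b] == x[a]) return(b / n)
    (a + (b - a) * (xq - x[a]) / (x[b] - x[a])) / n
  }

  low <- 1L; high <- n
  D <- 1 / n
  repeat {
    if (low >= high) break
    g <- high; gcm <- g
    while (g > low) { g <- mn[g]; if (g < low) g <- low; gcm <- c(g, gcm) }
    l <- low; lcm <- l
    while (l < high) { l <- mj[l]; if (l > high) l <- high; lcm <- c(lcm, l) }
    K <- length(gcm); M <- length(lcm)

    # largest vertical gap between the LCM and GCM curves
    d <- -Inf; nlo <- low; nhi <- high
    for (ii in seq_len(M)) {
      li <- lcm[ii]
      si <- min(max(findInterval(li, gcm, rightmost.closed = TRUE), 1L), K - 1L)
      a <- gcm[si]; b <- gcm[si + 1L]
      gap <- li / n - gcm_line(x[li], a, b)
      if (gap > d) { d <- gap; nlo <- a; nhi <- li }
    }
    for (ii in seq_len(K)) {
      gi <- gcm[ii]
      si <- min(max(findInterval(gi, lcm, rightmost.closed = TRUE), 1L), M - 1L)
      a <- lcm[si]; b <- lcm[si + 1L]
      gap <- lcm_line(x[gi], a, b) - (gi - 1) / n
      if (gap > d) { d <- gap; nlo <- gi; nhi <- b }
    }
    if (d <= D) break

    # ecdf deviations from its own hulls outside the new modal interval
    for (ii in seq_len(K - 1L)) {
      a <- gcm[ii]; b <- gcm[ii + 1L]
      if (b > nlo) break
      if (b > a + 1L) {
        js <- (a + 1L):(b - 1L)
        dev <- max(js / n - vapply(js, function(j) gcm_line(x[j], a, b), 0))
        if (dev > D) D <- dev
      }
    }
    for (ii in seq_len(M - 1L)) {
      a <- lcm[ii]; b <- lcm[ii + 1L]
      if (a < nhi) next
      if (b > a + 1L) {
        js <- (a + 1L):(b - 1L)
        dev <- max(vapply(js, function(j) lcm_line(x[j], a, b), 0) - (js - 1L) / n)
        if (dev > D) D <- dev
      }
    }
    if (nlo == low && nhi == high) break
    low <- nlo; high <- nhi
  }
  D / 2
}

#' Monte-Carlo null distribution of the dip statistic
#'
#' Dip statistics of `n_sim` uniform(0,1) samples of size `n` — the
#' reference distribution for the simulated p-value.  Computing the table
#' once and reusing it across features with the same sample size is
#' equivalent to, and much cheaper than, re-simulating per test.
#'
#' @param n Sample size to match.
#' @param n_sim Number of Monte-Carlo draws (>= 100).
#' @param seed Integer seed (local RNG; the global RNG state is untouched).
#' @return Sorted numeric vector of `n_sim` dip statistics.
#' @export
dip_null <- function(n, n_sim = 2000, seed = 1) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  sims <- withr_seed(seed, {
    vapply(seq_len(n_sim), function(i) dip_statistic(runif(n)), 0)
  })
  sort(sims)
}

# evaluate expr with a local RNG seed, restoring the global state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Dip test of unimodality with Monte-Carlo p-values
#'
#' The p-value is the proportion of dip statistics from uniform(0,1) samples
#' of the same size that are at least as large as the observed dip.  Under
#' the standard null hypothesis (the distribution *is* unimodal), small
#' p-values reject unimodality.  `call_convention` controls how
#' `unimodal_call` is derived: `"standard"` calls a family unimodal when the
#' test does *not* reject (p >= alpha); `"p_lt_alpha"` reproduces an
#' operational rule found in parts of the TE expression literature, which
#' labels a family unimodal when p < alpha (inverting the conventional
#' null — see the methods vignette).
#'
#' @param x Numeric sample (n >= 2).
#' @param n_sim Monte-Carlo replicates (default 2000).
#' @param seed Integer seed for the null simulation.
#' @param alpha Call threshold (default 0.05).
#' @param call_convention `"standard"` or `"p_lt_alpha"`.
#' @param null_table Optional precomputed [dip_null()] table for this `n`
#'   (overrides `n_sim`/`seed`).
#' @return A `dip_result` list: `statistic`, `p_value`, `n`, `n_sim`,
#'   `seed`, `unimodal_call`, `call_convention`.
#' @export
dip_test <- function(x, n_sim = 2000, seed = 1, alpha = 0.05,
                     call_convention = c("standard", "p_lt_alpha"),
                     null_table = NULL) {
  call_convention <- match.arg(call_convention)
  stat <- dip_statistic(x)
  if (is.null(null_table)) null_table <- dip_null(length(x), n_sim, seed)
  p <- mean(null_table >= stat)
  call <- if (call_convention == "standard") p >= alpha else p < alpha
  structure(list(statistic = stat, p_value = p, n = length(x),
                 n_sim = length(null_table), seed = seed,
                 unimodal_call = call, call_convention = call_convention),
            class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("dip test: D = %.5f, n = %d, MC p = %.4f (%d sims) -> %s (%s convention)\n",
              x$statistic, x$n, x$p_value, x$n_sim,
              if (x$unimodal_call) "unimodal" else "not unimodal",
              x$call_convention))
  invisible(x)
}
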