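# Hartigan & Hartigan's dip test of unimodality, with a bootstrap null.

#' Dip statistic of unimodality
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical CDF and any unimodal CDF (a function convex up to a mode and
#' concave after it).  It is computed by the greatest-convex-minorant /
#' least-concave-majorant modal-interval algorithm, in compiled code.  For a
#' sample of `n` distinct values the dip lies in `[1/(2n), 1/4]`; larger
#' values indicate stronger departure from unimodality.  The statistic is
#' invariant under affine maps `a + b*x` (`b > 0`) but -- deliberately --
#' not under general monotone transforms, which is why expression values
#' are log-transformed before testing.
#'
#' Tied values degrade the empirical CDF, so exact ties are broken by a
#' deterministic jitter: after sorting, the i-th value is raised by
#' `(i-1) * 1e-9 * range(x)`.  This is seed-free and reproducible.
#'
#' @param x numeric sample, `length(x) >= 4`.
#' @return the dip statistic `D` (single number).
#' @examples
#' dip_statistic(c(rnorm(100), rnorm(100, 6)))  # clearly bimodal: large D
#' @export
dip_statistic <- function(x) {
  if (!is.numeric(x) || anyNA(x)) stopf("'x' must be numeric without NAs")
  n <- length(x)
  if (n < 4L) stopf("dip statistic undefined for n < 4 (n = %d)", n)
  x <- sort(x)
  if (x[n] > x[1L] && any(diff(x) == 0)) {
    x <- x + (seq_len(n) - 1) * 1e-9 * (x[n] - x[1L])
  }
  .dip_stat_cpp(x)
}

#' Bootstrap null distribution of the dip
#'
#' Dips of `n_boot` samples of size `n` drawn from the uniform(0,1)
#' distribution -- the calibration null used by reference dip-test
#' implementations.  The table depends on the sample size only, so it can be
#' computed once per panel and shared by all genes tested at that size.
#'
#' @param n sample size.
#' @param n_boot number of bootstrap samples (default 5000).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return sorted numeric vector of `n_boot` null dip values.
#' @export
dip_null_table <- function(n, n_boot = 5000L, seed = 1L) {
  assert_scalar_number(n, "n", 4)
  assert_scalar_number(n_boot, "n_boot", 1)
  with_seed(seed, sort(.dip_null_cpp(as.integer(n), as.integer(n_boot))))
}

#' Dip test with bootstrap p-value
#'
#' Computes the dip `D` of `x` and a p-value as the fraction of `n_boot`
#' uniform null samples of equal size whose dip is at least `D`.  A zero
#' count is reported as `1/(n_boot + 1)` so p-values are never exactly 0.
#'
#' @inheritParams dip_statistic
#' @inheritParams dip_null_table
#' @param null_dips optional pre-computed table from [dip_null_table()]
#'   (must have been built for `length(x)`); when supplied, `n_boot`/`seed`
#'   are ignored.
#' @return list with elements `dip` and `p_value`.
#' @export
dip_test <- function(x, n_boot = 5000L, seed = 1L, null_dips = NULL) {
  d <- dip_statistic(x)
  if (is.null(null_dips)) null_dips <- dip_null_table(length(x), n_boot, seed)
  p <- dip_pvalue(d, null_dips)
  list(dip = d, p_value = p)
}

# p = #(null >= D) / n_boot, guarded away from zero.
dip_pvalue <- function(d, sorted_null) {
  nb <- length(sorted_null)
  p <- (nb - findInterval(d - 1e-12, sorted_null)) / nb
  pmax(p, 1 / (nb + 1))
}
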