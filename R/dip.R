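#' Hartigans' dip statistic
#'
#' The dip of a sample: the minimum, over all unimodal distribution
#' functions, of the supremum distance to the empirical distribution
#' function. Computed exactly via the greatest-convex-minorant /
#' least-concave-majorant construction on the sorted sample (working on
#' the jump midpoints of the empirical CDF, with a shrinking modal
#' interval). The statistic lies in `[1/(2n), 0.25]`: a sample of equal
#' values attains the lower bound, two equal point masses approach the
#' upper.
#'
#' @param x Numeric sample with at least 4 finite values.
#' @return The dip statistic (scalar).
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x)))
    stop("x must be finite and free of missing values")
  if (length(x) < 4)
    stop("the dip statistic needs at least 4 observations")
  dip_stat_cpp(sort(x))
}

#' Monte-Carlo dip test of unimodality
#'
#' Tests the null hypothesis that the sample comes from a unimodal
#' distribution. The p-value is the Monte-Carlo proportion of dip
#' statistics from `n_boot` uniform(0,1) samples of the same size that
#' reach or exceed the observed dip (the uniform is the asymptotically
#' least favourable unimodal null), reported with the add-one convention
#' `(1 + #{null >= obs}) / (n_boot + 1)`. Samples larger than
#' `max_n` are randomly subsampled to `max_n` first.
#'
#' @param x Numeric sample (>= 4 finite values).
#' @param n_boot Null replicates (default 2000).
#' @param seed Optional seed for the null draws (and the subsampling
#'   guard).
#' @param max_n Subsampling guard (default 80000).
#' @param null_dips Optional precomputed vector of null dip statistics for
#'   this sample size (e.g. shared across many tests of equal n); when
#'   supplied, `n_boot` is ignored.
#' @return A `dip_test` object: list with `dip`, `p_value`, `n`,
#'   `n_boot`, `seed` and the null distribution used.
#' @export
dip_test <- function(x, n_boot = 2000, seed = NULL, max_n = 80000,
                     null_dips = NULL) {
  x <- as.numeric(x)
  with_seed(seed, {
    if (length(x) > max_n) x <- sample(x, max_n)
    obs <- dip_statistic(x)
    n <- length(x)
    if (is.null(null_dips))
      null_dips <- vapply(seq_len(n_boot),
                          function(i) dip_stat_cpp(sort(runif(n))),
                          numeric(1))
    p <- (1 + sum(null_dips >= obs)) / (length(null_dips) + 1)
    structure(list(dip = obs, p_value = p, n = n,
                   n_boot = length(null_dips), seed = seed,
                   null_dips = null_dips),
              class = "dip_test")
  })
}

#' Null dip distribution for a sample size
#'
#' Convenience for testing many samples of the same size: draws `n_boot`
#' uniform samples of size `n` and returns their dip statistics, to be
#' passed to [dip_test()] as `null_dips`.
#'
#' @param n Sample size.
#' @param n_boot Number of replicates.
#' @param seed Optional seed.
#' @return Numeric vector of null dip statistics.
#' @export
dip_null_distribution <- function(n, n_boot = 2000, seed = NULL) {
  with_seed(seed, vapply(seq_len(n_boot),
                         function(i) dip_stat_cpp(sort(runif(n))),
                         numeric(1)))
}

#' @export
print.dip_test <- function(x, ...) {
  cat("Hartigans' dip test of unimodality (Monte-Carlo)\n")
  cat(sprintf("  dip = %.6f, n = %d, p-value = %.4g (%d null replicates)\n",
              x$dip, x$n, x$p_value, x$n_boot))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.dip_test <- function(x, ...) {
  tibble(statistic = x$dip, p.value = x$p_value,
         method = "Hartigans' dip test (Monte-Carlo)")
}

#' @exportS3Method generics::glance
glance.dip_test <- function(x, ...) {
  tibble(statistic = x$dip, p.value = x$p_value, n = x$n, n_boot = x$n_boot)
}
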