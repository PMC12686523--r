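#' Hartigan & Hartigan dip statistic
#'
#' Maximum difference between the empirical CDF of `values` and the closest
#' unimodal CDF, computed with the greatest-convex-minorant /
#' least-concave-majorant construction. For a sample of size n the dip lies
#' in `[1/(2n), 0.25)`, reaching the lower bound for equally spaced values
#' and approaching 0.25 for two equal point masses.
#'
#' @param values numeric vector, at least 4 finite values with some spread.
#' @return the dip statistic (non-negative scalar).
#' @export
dip_statistic <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4)
    stop("dip statistic needs at least 4 finite values")
  dip_stat_cpp(sort(values))
}

#' Monte-Carlo dip test of unimodality
#'
#' The p-value is the fraction of `n_boot` sorted uniform(0,1) samples of
#' the same size whose dip is at least the observed dip (the uniform is the
#' asymptotically least favourable unimodal null). Seeded and reproducible.
#'
#' @param values numeric vector, at least 4 finite values.
#' @param n_boot Monte-Carlo replicates.
#' @param seed optional integer seed applied before drawing the null.
#' @return list with class `dip_test`: `statistic`, `p_value`, `n`,
#'   `n_boot`.
#' @export
dip_test <- function(values, n_boot = 2000, seed = NULL) {
  d <- dip_statistic(values)
  n <- sum(is.finite(values))
  if (!is.null(seed)) set.seed(seed)
  null <- dip_null_cpp(n, n_boot)
  structure(list(statistic = d, p_value = mean(null >= d), n = n,
                 n_boot = n_boot),
            class = "dip_test")
}

#' @export
print.dip_test <- function(x, ...) {
  cat(sprintf("Dip test of unimodality: D = %.4f, p = %.4f (n = %d, %d MC reps)\n",
              x$statistic, x$p_value, x$n, x$n_boot))
  invisible(x)
}
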