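#' Two-component univariate Gaussian mixture by EM
#'
#' Fits `w * N(mu1, sigma1^2) + (1 - w) * N(mu2, sigma2^2)` to the
#' normalised per-cell ecDNA signal. Initialised from 1-D k-means
#' centroids; converges when the relative log-likelihood change drops below
#' `tol`. Components are reordered so `mu1 <= mu2`, with `w` the weight of
#' the lower-mean component; `responsibilities` are the per-observation
#' posteriors of the higher-mean component.
#'
#' @param values numeric vector, at least 10 finite values.
#' @param sigma_floor lower bound on the component standard deviations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param seed optional seed for the k-means initialisation.
#' @return list with class `mixture_fit`: `w`, `mu1`, `mu2`, `sigma1`,
#'   `sigma2`, `loglik`, `loglik_trace`, `responsibilities`, `n_iter`,
#'   `converged`.
#' @export
fit_two_component_gmm <- function(values, sigma_floor = 1e-3, tol = 1e-8,
                                  max_iter = 1000, seed = NULL) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 10) stop("mixture fit needs at least 10 finite values")
  if (stats::sd(x) == 0) stop("no mixture structure: all values identical")
  if (!is.null(seed)) set.seed(seed)
  km <- suppressWarnings(stats::kmeans(x, centers = 2, nstart = 5))
  mu <- sort(km$centers[, 1])
  grp <- x > mean(mu)
  w <- c(mean(!grp), mean(grp))
  if (any(w == 0)) w <- c(0.5, 0.5)
  sg <- pmax(c(stats::sd(x[!grp]), stats::sd(x[grp])), sigma_floor)
  sg[is.na(sg)] <- stats::sd(x)

  loglik_trace <- numeric(0)
  ll_old <- -Inf
  n_iter <- 0L
  converged <- FALSE
  resp2 <- rep(0.5, n)
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    loglik_trace <- c(loglik_trace, ll)
    resp2 <- d2 / tot
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    ## M step
    n2 <- sum(resp2); n1 <- n - n2
    if (n1 < 1e-10 || n2 < 1e-10) break  # one component vanished
    mu <- c(sum((1 - resp2) * x) / n1, sum(resp2 * x) / n2)
    sg <- pmax(sqrt(c(sum((1 - resp2) * (x - mu[1])^2) / n1,
                      sum(resp2 * (x - mu[2])^2) / n2)), sigma_floor)
    w <- c(n1 / n, n2 / n)
  }
  if (mu[1] > mu[2]) {  # canonical ordering mu1 <= mu2
    mu <- rev(mu); sg <- rev(sg); w <- rev(w); resp2 <- 1 - resp2
  }
  structure(list(w = w[1], mu1 = mu[1], mu2 = mu[2],
                 sigma1 = sg[1], sigma2 = sg[2],
                 loglik = loglik_trace[length(loglik_trace)],
                 loglik_trace = loglik_trace,
                 responsibilities = resp2,
                 n_iter = n_iter, converged = converged),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "2-component GMM: w = %.3f, mu = (%.3f, %.3f), sigma = (%.3f, %.3f)\n",
    x$w, x$mu1, x$mu2, x$sigma1, x$sigma2))
  cat(sprintf("  loglik = %.3f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iter, x$converged))
  invisible(x)
}

#' Label cells from a mixture fit
#'
#' A cell is called ecDNA-positive iff its posterior responsibility for the
#' higher-mean component strictly exceeds `threshold` (the amplified state
#' always corresponds to the higher mean, never to a component index).
#'
#' @param fit a `mixture_fit`.
#' @param threshold posterior threshold (strict inequality).
#' @return logical vector, TRUE = ecDNA-positive.
#' @export
assign_by_gmm <- function(fit, threshold = 0.5) {
  stopifnot(inherits(fit, "mixture_fit"))
  fit$responsibilities > threshold
}
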