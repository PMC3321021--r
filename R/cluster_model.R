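# Model-based clustering at desk scale: a product-Bernoulli mixture fitted by
# EM (multiple random restarts) supplies L(K) for Evanno's delta-K selection
# of the number of clusters.

#' Fit a product-Bernoulli mixture to dominant marker data
#'
#' EM on a K-component mixture of independent Bernoulli loci. Cluster
#' band-presence frequencies are Laplace-smoothed in the M-step
#' (posterior-mean update under a symmetric Beta(1,1) prior:
#' (successes + 1) / (count + 2)), which keeps frequencies off the 0/1
#' boundary. Missing calls are marginalized out of the likelihood.
#' Responsibilities are initialized randomly per restart; the restart with
#' the best penalized objective is returned.
#'
#' @param x a [marker_matrix()] (replicate rows dropped)
#' @param k number of clusters (1 <= k <= number of samples)
#' @param n_restarts independent random restarts
#' @param seed RNG seed
#' @param tol absolute convergence tolerance on the EM objective
#' @param max_iter maximum EM iterations per restart
#' @return list of class `mixture_fit`: `k`, `freq` (k x loci), `weights`,
#'   `responsibilities` (samples x k), `log_lik` (observed-data
#'   log-likelihood), `objective` (penalized, monotone under EM),
#'   `objective_trace`, `converged`, `n_restarts`
#' @export
fit_bernoulli_mixture <- function(x, k, n_restarts = 10, seed = 1,
                                  tol = 1e-6, max_iter = 500) {
  x <- drop_replicates(x)
  m <- unclass(x)
  n <- nrow(m)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of samples (", n, ")")
  v <- !is.na(m)
  x0 <- m; x0[!v] <- 0L
  storage.mode(x0) <- "double"; storage.mode(v) <- "double"
  best <- NULL
  with_seed(seed, {
    for (rs in seq_len(n_restarts)) {
      fit <- em_bernoulli_once(x0, v, k, tol, max_iter)
      if (is.null(best) || fit$objective > best$objective) best <- fit
    }
  })
  best$n_restarts <- n_restarts
  rownames(best$responsibilities) <- rownames(m)
  colnames(best$freq) <- colnames(m)
  structure(best, class = "mixture_fit")
}

em_bernoulli_once <- function(x0, v, k, tol, max_iter) {
  n <- nrow(x0)
  # prototype initialization: k random samples seed the cluster frequencies,
  # responsibilities follow from one E-step (random responsibilities tend to
  # start EM near the uniform saddle and strand it in poor optima)
  idx <- sample.int(n, k)
  freq0 <- (x0[idx, , drop = FALSE] + 1) / (v[idx, , drop = FALSE] + 2)
  ll0 <- x0 %*% t(log(freq0)) + (v - x0) %*% t(log(1 - freq0))
  sc0 <- sweep(ll0, 2, log(rep(1 / k, k)), `+`)
  mx0 <- apply(sc0, 1, max)
  r <- exp(sc0 - (mx0 + log(rowSums(exp(sc0 - mx0)))))
  obj_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  freq <- weights <- log_lik <- obj <- NULL
  for (it in seq_len(max_iter)) {
    # M-step with Beta(1,1) posterior-mean smoothing
    nk <- colSums(r)
    freq <- (t(r) %*% x0 + 1) / (t(r) %*% v + 2)
    weights <- nk / n
    # E-step
    ll_ik <- x0 %*% t(log(freq)) + (v - x0) %*% t(log(1 - freq))
    lw <- ifelse(weights > 0, log(weights), -Inf)
    sc <- sweep(ll_ik, 2, lw, `+`)
    mx <- apply(sc, 1, max)
    lse <- mx + log(rowSums(exp(sc - mx)))
    r <- exp(sc - lse)
    log_lik <- sum(lse)
    obj <- log_lik + sum(log(freq) + log(1 - freq))
    trace <- c(trace, obj)
    if (is.finite(obj_old) && abs(obj - obj_old) < tol) { converged <- TRUE; break }
    obj_old <- obj
  }
  list(k = k, freq = freq, weights = weights, responsibilities = r,
       log_lik = log_lik, objective = obj, objective_trace = trace,
       converged = converged)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("bernoulli mixture: K = %d, logL = %.3f (%sconverged, %d restarts)\n",
              x$k, x$log_lik, if (x$converged) "" else "NOT ", x$n_restarts))
  invisible(x)
}

#' Closed-form K = 1 log-likelihood
#'
#' Independent-Bernoulli log-likelihood at the Beta(1,1)-smoothed per-locus
#' frequencies; reference point for the mixture fits.
#'
#' @param x a [marker_matrix()]
#' @return scalar log-likelihood
#' @export
loglik_k1 <- function(x) {
  m <- unclass(drop_replicates(x))
  v <- !is.na(m)
  s <- colSums(m == 1L, na.rm = TRUE)
  n <- colSums(v)
  p <- (s + 1) / (n + 2)
  sum(s * log(p) + (n - s) * log(1 - p))
}

#' Evanno delta-K table from clustering log-likelihoods
#'
#' For each K with at least two runs: mean L(K), run-to-run standard
#' deviation, first difference L'(K) = L(K) - L(K-1), second difference
#' |L''(K)| = |L(K+1) - 2 L(K) + L(K-1)| (means), and
#' delta-K = |L''(K)| / sd(L(K)). Delta-K is defined only for interior K
#' with sd > 0; endpoints are never candidates. The recommended K is the
#' argmax of delta-K over defined interior values.
#'
#' @param runs named list: names are consecutive integer K values, elements
#'   numeric vectors of L(K) over >= 2 runs each
#' @return list of class `delta_k_table`: `table` (data.frame) and
#'   `recommended_k`
#' @export
evanno_delta_k <- function(runs) {
  ks <- as.integer(names(runs))
  if (any(is.na(ks))) stop("run list must be named by integer K")
  o <- order(ks)
  ks <- ks[o]; runs <- runs[o]
  if (length(ks) < 3) stop("need at least 3 values of K")
  if (!all(diff(ks) == 1)) stop("K range must be contiguous")
  if (any(lengths(runs) < 2)) stop("need at least 2 runs per K")
  mean_l <- vapply(runs, mean, 0)
  sd_l <- vapply(runs, stats::sd, 0)
  nk <- length(ks)
  lprime <- c(NA, diff(mean_l))
  lsecond <- rep(NA_real_, nk)
  delta_k <- rep(NA_real_, nk)
  for (i in seq(2, nk - 1)) {
    lsecond[i] <- abs(mean_l[i + 1] - 2 * mean_l[i] + mean_l[i - 1])
    delta_k[i] <- if (sd_l[i] > 0) lsecond[i] / sd_l[i] else NA_real_
  }
  tab <- data.frame(K = ks, mean_l = mean_l, sd_l = sd_l,
                    l_prime = lprime, l_second = lsecond, delta_k = delta_k,
                    sd_zero = sd_l == 0, row.names = NULL)
  rec <- if (all(is.na(delta_k))) NA_integer_ else ks[which.max(delta_k)]
  structure(list(table = tab, recommended_k = rec), class = "delta_k_table")
}

#' @export
print.delta_k_table <- function(x, ...) {
  print(round_df(x$table, 4))
  cat("recommended K (argmax delta-K):", x$recommended_k, "\n")
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  df
}

#' Run the mixture over a K range and tabulate delta-K
#'
#' Convenience wrapper: performs `n_runs` independent runs over the whole K
#' range, collects L(K) and calls [evanno_delta_k()]. Each run fits every K
#' on the same bootstrap resample of the loci (best of `n_restarts` EM
#' restarts), so run-to-run scatter reflects sampling variability of the
#' data at every K alike. A deterministic fitter needs this: with the exact
#' same data each run converges to the same optimum at the easy K values,
#' the run-to-run standard deviation collapses and delta-K degenerates.
#' Stochastic-search clustering programs get the equivalent variability for
#' free from their Monte Carlo noise. Set `resample_loci = FALSE` to fit the
#' original matrix in every run.
#'
#' @param x a [marker_matrix()]
#' @param k_range integer vector of consecutive K values
#' @param n_runs independent runs per K
#' @param n_restarts EM restarts within each run
#' @param resample_loci bootstrap the loci per run (default TRUE)
#' @param seed RNG seed
#' @param ... passed to [fit_bernoulli_mixture()]
#' @return a `delta_k_table` with the per-run log-likelihoods attached as
#'   attribute `runs`
#' @export
delta_k_scan <- function(x, k_range = 1:6, n_runs = 10, n_restarts = 4,
                         resample_loci = TRUE, seed = 1, ...) {
  x <- drop_replicates(x)
  runs <- matrix(NA_real_, n_runs, length(k_range),
                 dimnames = list(NULL, as.character(k_range)))
  for (r in seq_len(n_runs)) {
    xr <- if (resample_loci) {
      cols <- with_seed(seed + 7000 + r, sample.int(ncol(x), replace = TRUE))
      m <- unclass(x)[, cols, drop = FALSE]
      colnames(m) <- paste0("b", seq_len(ncol(m)))
      marker_matrix(m)
    } else x
    for (i in seq_along(k_range)) {
      runs[r, i] <- fit_bernoulli_mixture(xr, k_range[i],
                                          n_restarts = n_restarts,
                                          seed = seed + 1000 * i + r,
                                          ...)$log_lik
    }
  }
  runs <- lapply(stats::setNames(seq_along(k_range), as.character(k_range)),
                 function(i) runs[, i])
  out <- evanno_delta_k(runs)
  attr(out, "runs") <- runs
  out
}
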