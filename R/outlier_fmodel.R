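# Bayesian F-model genome scan for dominant markers on population pairs,
# with a spike-and-slab selection indicator per locus, and the
# consistent-outlier aggregation across MOTU pairs.
#
# Model, per locus l and population j in the pair:
#   p_l           ~ Uniform(0, 1)              ancestral presence-allele freq
#   beta_j        ~ Normal(beta_mu, beta_sd)   population (drift) effect
#   delta_l       ~ Bernoulli(1 / (1 + prior_odds))
#   alpha_l|d=1   ~ Normal(0, alpha_sd)        locus (selection) effect
#   F_jl  = logistic(delta_l * alpha_l + beta_j)
#   q_jl  ~ Beta(p_l * th_jl, (1 - p_l) * th_jl), th = (1 - F) / F
#   y_jl  ~ Binomial(n_jl, 1 - (1 - q_jl)^2)   bands under HWE dominance
# Sampling is Metropolis-within-Gibbs, vectorized across loci; the indicator
# move proposes alpha from its prior so the prior density cancels.

#' Configuration for the F-model outlier scan
#'
#' Defaults map the usual "default settings" of dominant-marker genome scans:
#' prior odds 10 for neutrality, 5000 burn-in plus 50000 kept iterations
#' thinned by 10, outlier cut-off at posterior probability 0.95.
#'
#' @param prior_odds prior odds for neutrality, P(neutral)/P(selected)
#' @param n_iter kept MCMC iterations (after burn-in)
#' @param burn_in burn-in iterations
#' @param thin thinning interval for stored samples
#' @param cutoff posterior-probability cut-off for calling outliers
#' @param alpha_sd prior standard deviation of the locus effect
#' @param beta_mu,beta_sd prior mean / sd of the population effect
#' @param seed RNG seed
#' @return list of class `fmodel_config`
#' @export
fmodel_config <- function(prior_odds = 10, n_iter = 50000, burn_in = 5000,
                          thin = 10, cutoff = 0.95, alpha_sd = 2,
                          beta_mu = -1, beta_sd = 1.8, seed = 1) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  if (n_iter <= 0 || burn_in < 0) stop("iteration counts must be positive")
  if (prior_odds <= 0) stop("prior_odds must be positive")
  structure(list(prior_odds = prior_odds, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, cutoff = cutoff, alpha_sd = alpha_sd,
                 beta_mu = beta_mu, beta_sd = beta_sd, seed = seed),
            class = "fmodel_config")
}

#' Dominant-band likelihood layer
#'
#' Under Hardy-Weinberg dominance a diploid shows a band iff it carries at
#' least one presence allele: `band_prob(p) = 1 - (1 - p)^2`.
#' `band_loglik` is the binomial log-likelihood of band counts given the
#' presence-allele frequency; it is the likelihood layer shared by the
#' sampler and by test oracles.
#'
#' @param p presence-allele frequency in [0, 1]
#' @param n_present,n_total band counts per population per locus
#' @return `band_prob`: band probability; `band_loglik`: log-likelihood
#' @export
band_prob <- function(p) 1 - (1 - p)^2

#' @rdname band_prob
#' @export
band_loglik <- function(n_present, n_total, p) {
  if (any(n_present > n_total)) stop("n_present exceeds n_total")
  stats::dbinom(n_present, n_total, band_prob(p), log = TRUE)
}

# log Balding-Nichols density of q given ancestral p and divergence F
log_bn <- function(q, p, f) {
  th <- (1 - f) / f
  stats::dbeta(q, p * th, (1 - p) * th, log = TRUE)
}

#' Fit the F-model to one population pair
#'
#' @param x a [marker_matrix()]
#' @param pops character vector of the two population ids
#' @param hier a [hierarchy()] assigning samples to populations
#' @param config an [fmodel_config()]
#' @return list of class `pair_scan`: `pops`, `posterior_prob` (per locus),
#'   `alpha_mean` (posterior mean of delta * alpha), `beta_mean`,
#'   `outliers` (locus ids with probability > cutoff), `excluded`
#'   (monomorphic loci skipped), `acceptance`, `config`
#' @export
fit_fmodel_pair <- function(x, pops, hier, config = fmodel_config()) {
  stopifnot(length(pops) == 2, inherits(hier, "hierarchy"))
  x <- drop_replicates(x)
  m <- unclass(x)
  counts <- lapply(pops, function(pp) {
    ids <- names(hier$pop)[hier$pop == pp]
    ids <- intersect(ids, rownames(m))
    if (length(ids) < 2) stop("population '", pp, "' has fewer than 2 samples")
    sub <- m[ids, , drop = FALSE]
    list(y = colSums(sub == 1L, na.rm = TRUE), n = colSums(!is.na(sub)))
  })
  y <- rbind(counts[[1]]$y, counts[[2]]$y)
  n <- rbind(counts[[1]]$n, counts[[2]]$n)
  if (ncol(y) < 10) stop("need at least 10 loci")
  mono <- (colSums(y) == 0) | (colSums(y) == colSums(n))
  keep <- which(!mono)
  res <- fmodel_mcmc(y[, keep, drop = FALSE], n[, keep, drop = FALSE], config)
  L <- ncol(m)
  post <- alpha <- rep(NA_real_, L)
  post[keep] <- res$posterior_prob
  alpha[keep] <- res$alpha_mean
  names(post) <- names(alpha) <- colnames(m)
  structure(list(pops = pops,
                 posterior_prob = post,
                 alpha_mean = alpha,
                 beta_mean = stats::setNames(res$beta_mean, pops),
                 beta_ci90 = structure(res$beta_ci90,
                                       dimnames = list(c("q05", "q95"), pops)),
                 outliers = colnames(m)[keep][res$posterior_prob > config$cutoff],
                 excluded = colnames(m)[mono],
                 acceptance = res$acceptance,
                 config = config),
            class = "pair_scan")
}

#' @export
print.pair_scan <- function(x, ...) {
  cat(sprintf("pair_scan %s vs %s: %d loci scanned, %d excluded, %d outliers (> %.2f)\n",
              x$pops[1], x$pops[2], sum(!is.na(x$posterior_prob)),
              length(x$excluded), length(x$outliers), x$config$cutoff))
  invisible(x)
}

# Core sampler on count matrices y, n of dimension 2 x L.
fmodel_mcmc <- function(y, n, config) {
  L <- ncol(y)
  pi1 <- 1 / (1 + config$prior_odds)
  with_seed(config$seed, {
    # initialization from moment estimates
    q <- (y + 0.5) / (n + 1)
    q <- 1 - sqrt(1 - pmin(q, 0.98))            # invert band_prob
    q <- pmin(pmax(q, 0.02), 0.98)
    p <- pmin(pmax(colMeans(q), 0.02), 0.98)
    beta <- rep(config$beta_mu, 2)
    alpha <- rep(0, L)
    delta <- rep(FALSE, L)
    s_q <- 0.8; s_p <- 0.8; s_a <- 0.6; s_b <- 0.3
    lq <- stats::qlogis(q)
    lp <- stats::qlogis(p)
    fmat <- rbind(stats::plogis(ifelse(delta, alpha, 0) + beta[1]),
                  stats::plogis(ifelse(delta, alpha, 0) + beta[2]))
    ll_y <- band_loglik(y, n, q)
    ll_q <- log_bn(q, rep(p, each = 2), fmat)
    acc <- c(q = 0, p = 0, alpha = 0, delta = 0, beta = 0)
    try_n <- c(q = 0, p = 0, alpha = 0, delta = 0, beta = 0)
    total_iter <- config$burn_in + config$n_iter
    n_store <- floor(config$n_iter / config$thin)
    sum_delta <- numeric(L); sum_alpha <- numeric(L)
    sum_beta <- c(0, 0); n_kept <- 0
    beta_draws <- matrix(NA_real_, n_store, 2)
    for (it in seq_len(total_iter)) {
      ## q update (all 2L at once, logit random walk)
      lq_new <- lq + stats::rnorm(2 * L, 0, s_q)
      q_new <- stats::plogis(lq_new)
      ll_y_new <- band_loglik(y, n, q_new)
      ll_q_new <- log_bn(q_new, rep(p, each = 2), fmat)
      jac <- log(q_new) + log(1 - q_new) - log(q) - log(1 - q)
      ok <- log(stats::runif(2 * L)) < (ll_y_new + ll_q_new + jac - ll_y - ll_q)
      ok[!is.finite(ll_q_new)] <- FALSE
      q[ok] <- q_new[ok]; lq[ok] <- lq_new[ok]
      ll_y[ok] <- ll_y_new[ok]; ll_q[ok] <- ll_q_new[ok]
      acc["q"] <- acc["q"] + mean(ok); try_n["q"] <- try_n["q"] + 1
      ## p update (per locus)
      lp_new <- lp + stats::rnorm(L, 0, s_p)
      p_new <- stats::plogis(lp_new)
      num <- log_bn(q[1, ], p_new, fmat[1, ]) + log_bn(q[2, ], p_new, fmat[2, ]) +
        log(p_new) + log(1 - p_new)
      den <- ll_q[1, ] + ll_q[2, ] + log(p) + log(1 - p)
      okp <- log(stats::runif(L)) < (num - den)
      okp[!is.finite(num)] <- FALSE
      p[okp] <- p_new[okp]; lp[okp] <- lp_new[okp]
      if (any(okp)) {
        ll_q[, okp] <- log_bn(q[, okp, drop = FALSE],
                              rep(p[okp], each = 2),
                              fmat[, okp, drop = FALSE])
      }
      acc["p"] <- acc["p"] + mean(okp); try_n["p"] <- try_n["p"] + 1
      ## alpha random walk where delta = 1
      sel <- which(delta)
      if (length(sel)) {
        a_new <- alpha[sel] + stats::rnorm(length(sel), 0, s_a)
        f_new <- rbind(stats::plogis(a_new + beta[1]),
                       stats::plogis(a_new + beta[2]))
        num <- log_bn(q[1, sel], p[sel], f_new[1, ]) +
          log_bn(q[2, sel], p[sel], f_new[2, ]) +
          stats::dnorm(a_new, 0, config$alpha_sd, log = TRUE)
        den <- ll_q[1, sel] + ll_q[2, sel] +
          stats::dnorm(alpha[sel], 0, config$alpha_sd, log = TRUE)
        oka <- log(stats::runif(length(sel))) < (num - den)
        oka[!is.finite(num)] <- FALSE
        upd <- sel[oka]
        alpha[upd] <- a_new[oka]
        fmat[, upd] <- f_new[, oka, drop = FALSE]
        ll_q[, upd] <- log_bn(q[, upd, drop = FALSE],
                              rep(p[upd], each = 2),
                              fmat[, upd, drop = FALSE])
        acc["alpha"] <- acc["alpha"] + mean(oka)
        try_n["alpha"] <- try_n["alpha"] + 1
      }
      ## delta toggle: alpha drawn from prior on activation (prior cancels)
      a_prop <- ifelse(delta, 0, stats::rnorm(L, 0, config$alpha_sd))
      f_prop <- rbind(stats::plogis(a_prop + beta[1]),
                      stats::plogis(a_prop + beta[2]))
      ll_q_prop <- log_bn(q, rep(p, each = 2), f_prop)
      prior_shift <- ifelse(delta, log((1 - pi1) / pi1), log(pi1 / (1 - pi1)))
      lr <- colSums(ll_q_prop) - colSums(ll_q) + prior_shift
      okd <- log(stats::runif(L)) < lr
      okd[!apply(is.finite(ll_q_prop), 2, all)] <- FALSE
      if (any(okd)) {
        delta[okd] <- !delta[okd]
        alpha[okd] <- a_prop[okd]
        fmat[, okd] <- f_prop[, okd, drop = FALSE]
        ll_q[, okd] <- ll_q_prop[, okd, drop = FALSE]
      }
      acc["delta"] <- acc["delta"] + mean(okd)
      try_n["delta"] <- try_n["delta"] + 1
      ## beta updates
      for (j in 1:2) {
        b_new <- beta[j] + stats::rnorm(1, 0, s_b)
        f_new <- stats::plogis(ifelse(delta, alpha, 0) + b_new)
        ll_new <- log_bn(q[j, ], p, f_new)
        lr <- sum(ll_new) - sum(ll_q[j, ]) +
          stats::dnorm(b_new, config$beta_mu, config$beta_sd, log = TRUE) -
          stats::dnorm(beta[j], config$beta_mu, config$beta_sd, log = TRUE)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          beta[j] <- b_new
          fmat[j, ] <- f_new
          ll_q[j, ] <- ll_new
          acc["beta"] <- acc["beta"] + 1
        }
        try_n["beta"] <- try_n["beta"] + 1
      }
      ## proposal adaptation during burn-in
      if (it <= config$burn_in && it %% 100 == 0) {
        rate <- acc / pmax(try_n, 1)
        s_q <- s_q * exp(rate[["q"]] - 0.35)
        s_p <- s_p * exp(rate[["p"]] - 0.35)
        s_a <- s_a * exp(rate[["alpha"]] - 0.35)
        s_b <- s_b * exp(rate[["beta"]] - 0.35)
        acc[] <- 0; try_n[] <- 0
      }
      if (it == config$burn_in) { acc[] <- 0; try_n[] <- 0 }
      if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0) {
        sum_delta <- sum_delta + delta
        sum_alpha <- sum_alpha + ifelse(delta, alpha, 0)
        sum_beta <- sum_beta + beta
        n_kept <- n_kept + 1
        if (n_kept <= n_store) beta_draws[n_kept, ] <- beta
      }
    }
    rates <- acc / pmax(try_n, 1)
    if (any(rates[c("q", "p", "beta")] < 0.1 | rates[c("q", "p", "beta")] > 0.7)) {
      warning("MCMC acceptance rate outside [0.1, 0.7] after adaptation; ",
              "mixing may be poor")
    }
    list(posterior_prob = sum_delta / n_kept,
         alpha_mean = sum_alpha / n_kept,
         beta_mean = sum_beta / n_kept,
         beta_ci90 = apply(beta_draws[seq_len(min(n_kept, n_store)), ,
                                      drop = FALSE], 2,
                           stats::quantile, probs = c(0.05, 0.95)),
         acceptance = rates)
  })
}

#' Aggregate pair scans into consistent outliers per MOTU pair
#'
#' For each MOTU pair, every possible population-pair combination between
#' the two MOTUs must have been scanned. The consistent outlier set is the
#' intersection of the per-pair outlier sets; the report also carries the
#' mean number of outlier loci per pair. MOTUs represented by a single
#' population are flagged: their outliers may reflect population-specific
#' demographic history rather than selection.
#'
#' @param scans list of `pair_scan` objects
#' @param motu_of named character vector mapping population id to MOTU
#' @return list of class `outlier_report`, one element per MOTU pair with
#'   `motus`, `n_pairs`, `avg_n_outliers`, `consistent`,
#'   `single_population_caveat`
#' @export
consistent_outliers <- function(scans, motu_of) {
  if (!length(scans)) stop("no pair scans supplied")
  pair_motus <- t(vapply(scans, function(s) sort(motu_of[s$pops]), c("", "")))
  key <- paste(pair_motus[, 1], pair_motus[, 2], sep = " vs ")
  out <- list()
  for (k in unique(key)) {
    sel <- scans[key == k]
    motus <- sort(unique(as.vector(pair_motus[key == k, , drop = FALSE])))
    pops1 <- names(motu_of)[motu_of == motus[1]]
    pops2 <- names(motu_of)[motu_of == motus[length(motus)]]
    expect <- expand.grid(a = pops1, b = pops2, stringsAsFactors = FALSE)
    have <- vapply(sel, function(s) paste(sort(s$pops), collapse = "|"), "")
    need <- apply(expect, 1, function(r) paste(sort(unname(r)), collapse = "|"))
    missing <- setdiff(need, have)
    if (length(missing)) {
      stop("MOTU pair ", k, " is missing population pair(s): ",
           paste(gsub("\\|", " vs ", missing), collapse = ", "))
    }
    sets <- lapply(sel, `[[`, "outliers")
    out[[k]] <- list(motus = motus,
                     n_pairs = length(sel),
                     avg_n_outliers = mean(lengths(sets)),
                     consistent = sort(Reduce(intersect, sets)),
                     single_population_caveat =
                       length(pops1) == 1 || length(pops2) == 1)
  }
  structure(out, class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  for (k in names(x)) {
    e <- x[[k]]
    cat(sprintf("%s: %d pair(s), avg %.1f outliers, consistent: %s%s\n",
                k, e$n_pairs, e$avg_n_outliers,
                if (length(e$consistent)) paste(e$consistent, collapse = ", ")
                else "(none)",
                if (e$single_population_caveat)
                  " [single-population MOTU: population-specific history caveat]"
                else ""))
  }
  invisible(x)
}
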