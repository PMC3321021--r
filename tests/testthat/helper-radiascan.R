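# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own code paths: plain loops and closed forms only.

mm <- function(rows, ids = NULL, loci = NULL, ...) {
  m <- do.call(rbind, rows)
  rownames(m) <- ids %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- loci %||% paste0("L", seq_len(ncol(m)))
  marker_matrix(m, ...)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

rand_mm <- function(n, l, seed, p = 0.4, miss = 0) {
  set.seed(seed)
  m <- matrix(rbinom(n * l, 1, p), n, l)
  if (miss > 0) m[runif(n * l) < miss] <- NA
  mm(asplit(m, 1), ids = sprintf("s%02d", 1:n))
}

# brute-force Nei-Li over a pair of 0/1/NA vectors
oracle_nei_li <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  nx <- sum(x[ok] == 1); ny <- sum(y[ok] == 1)
  nxy <- sum(x[ok] == 1 & y[ok] == 1)
  if (nx + ny == 0) return(0)
  1 - 2 * nxy / (nx + ny)
}

# site-loop p-distance
oracle_p_dist <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  ok <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  mean(va[ok] != vb[ok])
}

# random additive (ultrametric-free) tree and its path-length matrix
random_additive_case <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 2)
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(tree = tr, d = d[ord, ord])
}

# hand AMOVA for a one-level design from explicit sums of squares
oracle_amova_1level <- function(m, pop) {
  n <- nrow(m)
  d2 <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) d2[i, j] <- sum(m[i, ] != m[j, ])
  ssd_t <- sum(d2) / (2 * n)
  pops <- unique(pop)
  ssd_wp <- 0
  for (pp in pops) {
    idx <- which(pop == pp)
    ssd_wp <- ssd_wp + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssd_ap <- ssd_t - ssd_wp
  np <- as.vector(table(pop)[pops])
  P <- length(pops)
  sig_c <- ssd_wp / (n - P)
  n0 <- (n - sum(np^2) / n) / (P - 1)
  sig_b <- (ssd_ap / (P - 1) - sig_c) / n0
  list(sig_b = sig_b, sig_c = sig_c, phi_st = sig_b / (sig_b + sig_c))
}

# Pearson r of upper triangles, plain loops
oracle_mantel_r <- function(a, b) {
  va <- a[upper.tri(a)]; vb <- b[upper.tri(b)]
  sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
}

# independent permutation generator (next_perm style via recursion on sets)
oracle_all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_all_perms(n - 1)) {
    for (pos in 0:(n - 1)) out[[length(out) + 1]] <- append(p, n, after = pos)
  }
  out
}

# grid-integration oracle for the single-locus F-model posterior; quadrature
# only, no MCMC
oracle_fmodel_grid <- function(y, n, prior_odds = 10, alpha_sd = 2,
                               beta_mu = -1, beta_sd = 1.8,
                               nq = 201, np = 81, nb = 41, na_ = 41) {
  qg <- (seq_len(nq) - 0.5) / nq
  pg <- (seq_len(np) - 0.5) / np
  bg <- seq(beta_mu - 4 * beta_sd, beta_mu + 4 * beta_sd, length.out = nb)
  ag <- seq(-4 * alpha_sd, 4 * alpha_sd, length.out = na_)
  wb <- dnorm(bg, beta_mu, beta_sd); wb <- wb / sum(wb)
  wa <- dnorm(ag, 0, alpha_sd); wa <- wa / sum(wa)
  Ij <- function(j, f) {
    th <- (1 - f) / f
    dens <- outer(qg, pg, function(q, p) dbeta(q, p * th, (1 - p) * th))
    colSums(dens * dbinom(y[j], n[j], 1 - (1 - qg)^2)) / nq
  }
  I0 <- lapply(1:2, function(j) sapply(bg, function(b) Ij(j, plogis(b))))
  L0 <- mean((I0[[1]] %*% wb) * (I0[[2]] %*% wb))
  L1 <- 0
  for (ai in seq_along(ag)) {
    Ia <- lapply(1:2, function(j) {
      sapply(bg, function(b) Ij(j, plogis(ag[ai] + b)))
    })
    L1 <- L1 + wa[ai] * mean((Ia[[1]] %*% wb) * (Ia[[2]] %*% wb))
  }
  pi1 <- 1 / (1 + prior_odds)
  pi1 * L1 / (pi1 * L1 + (1 - pi1) * L0)
}

# simulate a 2-population pair and return markers + hierarchy
sim_pair <- function(n_per, n_loci, fst, seed, alpha = 0) {
  sp <- sim_params(n_pops = 2, n_per_pop = n_per, n_loci = n_loci, fst = fst,
                   alpha = alpha, e01 = 0, e10 = 0, replicate_fraction = 0,
                   seed = seed)
  sim <- simulate_metapopulation(sp)
  list(markers = sim$markers, hier = hierarchy(sim$samples),
       truth = sim$truth, samples = sim$samples)
}
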