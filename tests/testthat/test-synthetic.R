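test_that("same seed gives bit-identical simulations", {
  sp <- sim_params(n_pops = 3, n_per_pop = 5, n_loci = 40, fst = 0.2, seed = 9)
  a <- simulate_metapopulation(sp)
  b <- simulate_metapopulation(sp)
  expect_identical(unclass(a$markers), unclass(b$markers))
  expect_identical(a$truth$p_pop, b$truth$p_pop)
})

test_that("sim_params validates rates and priors", {
  expect_error(sim_params(fst = 1.2), "fst")
  expect_error(sim_params(prior_a = 0), "degenerate ancestral prior")
  expect_error(sim_params(e01 = 1.5), "rates")
  expect_error(sim_params(prior_lo = 0.5, prior_hi = 0.4), "truncation")
})

test_that("moment estimator on realized truth recovers the generating F", {
  # oracle: per-locus between-population variance of p_ij over within-scale
  # p_anc(1 - p_anc); Balding-Nichols gives E[var] = F * p(1-p)
  est <- vapply(1:5, function(s) {
    sim <- sim_pair(50, 500, fst = 0.1, seed = 400 + s)
    p <- sim$truth$p_pop
    sum(apply(p, 1, var)) / sum(sim$truth$p_anc * (1 - sim$truth$p_anc))
  }, 0)
  expect_true(all(abs(est - 0.1) < 0.03))
})

test_that("F -> 0 limit collapses between-population variance", {
  sp <- sim_params(n_pops = 4, n_per_pop = 5, n_loci = 200, fst = 1e-5,
                   seed = 5)
  sim <- simulate_metapopulation(sp)
  expect_lt(max(apply(sim$truth$p_pop, 1, var)), 1e-3)
  expect_lt(max(abs(sim$truth$p_pop - sim$truth$p_anc)), 0.05)
})

test_that("a locus with alpha = +3 has elevated realized divergence", {
  # At the study's population count (dozens of populations) the selected
  # locus essentially never drifts the same way everywhere, so its realized
  # among-population variance ranks above the median locus. (With only 2
  # populations this fails ~40% of the time: the locus fixes identically in
  # both and carries no divergence — see the methods vignette.)
  hits <- 0
  for (s in 1:40) {
    al <- rep(0, 100); al[17] <- 3
    sp <- sim_params(n_pops = 47, n_per_pop = 3, n_loci = 100, fst = 0.1,
                     alpha = al, e01 = 0, e10 = 0, replicate_fraction = 0,
                     seed = 500 + s)
    sim <- simulate_metapopulation(sp)
    v <- apply(sim$truth$p_pop, 1, var) /
      (sim$truth$p_anc * (1 - sim$truth$p_anc))
    hits <- hits + (v[17] > median(v))
  }
  expect_gte(hits, 38)  # >= 95% of seeds
})

test_that("realized among-population variance is monotone in F", {
  grid <- c(0.02, 0.1, 0.3, 0.6)
  v <- vapply(grid, function(f) {
    sim <- sim_pair(5, 400, fst = f, seed = 77)
    mean(apply(sim$truth$p_pop, 1, var))
  }, 0)
  expect_true(all(diff(v) > 0))
})

test_that("spatial mode produces isolation by distance", {
  hits <- 0
  for (s in 1:20) {
    sp <- sim_params(n_pops = 8, n_per_pop = 5, n_loci = 150, spatial = TRUE,
                     step_km = 10, drift_per_km = 0.005, fst = 0.05,
                     seed = 600 + s)
    sim <- simulate_metapopulation(sp)
    p <- sim$truth$p_pop
    # truth-based pairwise differentiation vs km distance
    P <- ncol(p)
    fst_m <- matrix(0, P, P)
    for (i in 1:(P - 1)) for (j in (i + 1):P) {
      num <- mean((p[, i] - p[, j])^2) / 2
      den <- mean(((p[, i] + p[, j]) / 2) * (1 - (p[, i] + p[, j]) / 2))
      fst_m[i, j] <- fst_m[j, i] <- num / (num + den)
    }
    km <- abs(outer(sp$positions_km, sp$positions_km, `-`))
    hits <- hits + (oracle_mantel_r(fst_m, km) > 0)
  }
  expect_gte(hits, 19)  # >= 95/100 seeds scaled down
})

test_that("corrupt_and_replicate trivial and analytic cases hold", {
  x <- rand_mm(40, 50, seed = 3)
  clean <- corrupt_and_replicate(x, 0, 0, replicate_fraction = 0.5, seed = 1)
  rp <- replicate_pairs(clean)
  expect_identical(nrow(rp), 20L)
  expect_equal(unclass(clean)[rownames(x), ], unclass(x),
               ignore_attr = TRUE)
  for (k in seq_len(nrow(rp))) {
    expect_identical(unclass(clean)[rp$replicate[k], ],
                     unclass(clean)[rp$original[k], ])
  }
  flipped <- corrupt_and_replicate(x, e01 = 0, e10 = 1 - 1e-12,
                                   replicate_fraction = 0, seed = 1)
  expect_true(all(unclass(flipped) == 0L))
  expect_error(corrupt_and_replicate(x, 0.1, 0.1, replicate_fraction = 1.5),
               "replicate_fraction")

  # discordance rate of replicate pairs: a call disagrees when exactly one
  # copy flips; P = q(1-e01)e01*? -> closed form by truth state
  set.seed(11)
  big <- mm(asplit(matrix(rbinom(10000, 1, 0.3), 200, 50), 1))
  noisy <- corrupt_and_replicate(big, 0.04, 0.04, replicate_fraction = 1,
                                 seed = 2)
  rp <- replicate_pairs(noisy)
  a <- unclass(noisy)[rp$original, ]; b <- unclass(noisy)[rp$replicate, ]
  obs <- mean(a != b)
  p1 <- mean(unclass(big) == 1)
  # both copies re-corrupted independently from truth
  d1 <- 2 * 0.04 * 0.96          # truth 1: one of two flips (e10 = 0.04)
  d0 <- 2 * 0.04 * 0.96          # truth 0: one of two flips (e01 = 0.04)
  expected <- p1 * d1 + (1 - p1) * d0
  n_calls <- length(a)
  se <- sqrt(expected * (1 - expected) / n_calls)
  expect_lt(abs(obs - expected), 2.58 * se + 1e-9)
})

test_that("peak profiles round-trip and respect noise/jitter bounds", {
  x <- rand_mm(12, 40, seed = 21, p = 0.5)
  # ensure every sample has >= 2 presences for a defined relative threshold
  m <- unclass(x); m[, 1:2] <- 1L
  x <- marker_matrix(m)
  prof <- simulate_peak_profiles(x, noise_rate = 0, jitter_sd = 0, seed = 4)
  scored <- score_profiles(prof)
  expect_equal(unname(unclass(scored)), unname(unclass(x)),
               ignore_attr = TRUE)

  expect_error(simulate_peak_profiles(x, jitter_sd = -1), "jitter")

  # jitter sd 0.2 vs bin width 0.75: P(|jitter| > 0.75) < 0.02% (normal
  # tail), and adjacent loci here are ~12 b apart, so no peak can land in a
  # different locus's bin; a locus may split into adjacent sub-bins, but
  # >= 99% of true present calls must be recovered by a bin whose midpoint
  # lies within 1 b of the true locus size
  # loci placed strictly inside [60, 550]: jitter at the window edge would
  # (correctly) push peaks out of range
  prof_j <- simulate_peak_profiles(x, sizes = seq(62, 548, length.out = ncol(x)),
                                   noise_rate = 0, jitter_sd = 0.2, seed = 5)
  scored_j <- score_profiles(prof_j)
  sizes <- attr(prof_j, "locus_sizes")
  mids <- as.numeric(sub("bin_", "", colnames(scored_j)))
  sj <- unclass(scored_j)[rownames(x), , drop = FALSE]
  recovered <- 0; total <- 0
  for (l in seq_along(sizes)) {
    near <- which(abs(mids - sizes[l]) <= 1)
    pres <- which(unclass(x)[, l] == 1L)
    total <- total + length(pres)
    if (length(near)) {
      recovered <- recovered +
        sum(rowSums(sj[pres, near, drop = FALSE]) > 0)
    }
  }
  expect_gte(recovered / total, 0.99)
  # noise-only profiles: band frequency bounded by the noise-peak detection
  # rate (Poisson thinning: peaks above threshold per sample)
  empty <- marker_matrix(matrix(0L, 30, 5,
                                dimnames = list(sprintf("n%02d", 1:30),
                                                paste0("L", 1:5))))
  prof_n <- simulate_peak_profiles(empty, noise_rate = 20,
                                   noise_meanlog = log(30),
                                   noise_sdlog = 0.5, seed = 6)
  suppressWarnings(scored_n <- score_profiles(prof_n))
  # P(noise peak >= 50 units) under logN(log 30, 0.5); expected detected
  # noise peaks per sample = 20 * p_det; each lands in some bin
  p_det <- plnorm(50, log(30), 0.5, lower.tail = FALSE)
  expect_lte(mean(unclass(scored_n)), 20 * p_det / ncol(scored_n) + 0.05)
})

test_that("sequence simulator respects the divergence hierarchy", {
  expect_error(simulate_sequences(3, 4, 100, within_div = 0.2,
                                  between_div = 0.1), "within_div")
  ss <- simulate_sequences(4, 5, length = 600, within_div = 0,
                           between_div = 0.10, seed = 8)
  d <- p_distance(ss)
  labs <- attr(ss, "true_cluster")
  same <- outer(labs, labs, `==`)[upper.tri(d)]
  expect_true(all(as.matrix(d)[upper.tri(d)][same] == 0))
  expect_true(all(as.matrix(d)[upper.tri(d)][!same] > 0.05))

  # single cluster: pairwise distance bounded by twice the tip rate plus
  # binomial slack (each tip mutates independently at within_div)
  s1 <- simulate_sequences(1, 8, length = 800, within_div = 0.01,
                           between_div = 0.5, seed = 9)
  d1 <- as.matrix(p_distance(s1))
  bound <- 2 * 0.01 + 3 * sqrt(2 * 0.01 / 800)
  expect_true(all(d1[upper.tri(d1)] <= bound))
})

test_that("landmark simulator validates input and embeds the group offset", {
  expect_error(simulate_landmarks(n_landmarks = 2), "3 landmarks")
  expect_error(simulate_landmarks(noise_sd = -0.1), "noise sd")
  lm <- simulate_landmarks(2, per_group = 10, shape_offset = 0.3,
                           noise_sd = 0.001, seed = 3)
  ss <- gpa(lm$coords)
  f <- goodall_f(ss, lm$group, "G1", "G2", n_perm = 0)
  expect_gt(f$F, 100)  # large offset, tiny noise: huge group separation
})
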