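# Synthetic-data module: generates marker matrices, peak profiles, sequences,
# coordinates and landmarks with the statistical structure the downstream
# stages assume (Balding-Nichols population frequencies, HWE dominance,
# replicate re-scoring error, stepping-stone drift for isolation by distance).

# Run code under a locally-seeded RNG without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Parameters for the metapopulation simulator
#'
#' Defaults emulate the scale of a typical island-radiation AFLP study:
#' 47 populations of 13 diploid individuals, 1964 dominant loci, per-call
#' scoring error 4% in each direction (which yields a replicate discordance
#' rate near 7.6%), and an 11% replicate fraction. Ancestral presence-allele
#' frequencies follow a Beta(a, b) prior truncated to [0.05, 0.95];
#' per-population differentiation is Balding-Nichols with baseline
#' \eqn{F_j}; per-locus selection effects \eqn{\alpha_i} shift
#' locus-by-population differentiation on the logit scale,
#' \eqn{F_{ij} = \mathrm{logistic}(\alpha_i + \mathrm{logit}(F_j))}.
#'
#' @param n_pops number of populations
#' @param n_per_pop individuals per population (scalar or vector)
#' @param n_loci number of dominant loci
#' @param n_groups number of higher-level groups (MOTUs); populations are
#'   assigned to groups in contiguous blocks
#' @param fst per-population baseline differentiation \eqn{F_j} in (0,1)
#'   (scalar or length `n_pops`)
#' @param alpha per-locus selection effect on logit \eqn{F}; scalar 0 or a
#'   length-`n_loci` vector (nonzero entries mark selected loci)
#' @param prior_a,prior_b Beta prior shape parameters for ancestral
#'   frequencies
#' @param prior_lo,prior_hi truncation bounds of the ancestral prior
#' @param e01 false-presence scoring rate, `P(scored 1 | true 0)`
#' @param e10 false-absence scoring rate, `P(scored 0 | true 1)`
#' @param replicate_fraction fraction of samples genotyped twice
#' @param spatial if TRUE, population frequencies drift sequentially along a
#'   1-D stepping-stone chain so differentiation grows with distance
#' @param positions_km stepping-stone positions (default equally spaced
#'   `step_km` apart)
#' @param step_km spacing used when `positions_km` is NULL
#' @param drift_per_km drift accumulated per km of chain:
#'   \eqn{F_{step} = 1 - \exp(-d \cdot drift\_per\_km)} between neighbours
#' @param seed RNG seed
#' @return a list of class `sim_params`
#' @export
sim_params <- function(n_pops = 47, n_per_pop = 13, n_loci = 1964,
                       n_groups = 1, fst = 0.24, alpha = 0,
                       prior_a = 1, prior_b = 1,
                       prior_lo = 0.05, prior_hi = 0.95,
                       e01 = 0.04, e10 = 0.04, replicate_fraction = 0.11,
                       spatial = FALSE, positions_km = NULL, step_km = 5,
                       drift_per_km = 0.005, seed = 1) {
  if (prior_a <= 0 || prior_b <= 0) {
    stop("degenerate ancestral prior: shape parameters must be positive")
  }
  if (prior_lo <= 0 || prior_hi >= 1 || prior_lo >= prior_hi) {
    stop("ancestral prior truncation must satisfy 0 < lo < hi < 1")
  }
  if (any(fst <= 0) || any(fst >= 1)) stop("fst must lie in (0, 1)")
  rates <- c(e01, e10, replicate_fraction)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  if (n_loci < 1) stop("need at least one locus")
  n_per_pop <- rep_len(n_per_pop, n_pops)
  fst <- rep_len(fst, n_pops)
  alpha <- rep_len(alpha, n_loci)
  if (is.null(positions_km)) positions_km <- (seq_len(n_pops) - 1) * step_km
  if (length(positions_km) != n_pops) stop("positions_km length != n_pops")
  group_of <- rep(seq_len(n_groups), length.out = n_pops) |> sort()
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop, n_loci = n_loci,
                 n_groups = n_groups, group_of = group_of, fst = fst,
                 alpha = alpha, prior_a = prior_a, prior_b = prior_b,
                 prior_lo = prior_lo, prior_hi = prior_hi,
                 e01 = e01, e10 = e10,
                 replicate_fraction = replicate_fraction,
                 spatial = spatial, positions_km = positions_km,
                 drift_per_km = drift_per_km, seed = seed),
            class = "sim_params")
}

rbeta_trunc <- function(n, a, b, lo, hi) {
  u <- stats::runif(n, stats::pbeta(lo, a, b), stats::pbeta(hi, a, b))
  stats::qbeta(u, a, b)
}

# Balding-Nichols draw of a descendant frequency around `p` at divergence F.
rbn <- function(p, f) {
  theta <- (1 - f) / f
  q <- stats::rbeta(length(p), p * theta, (1 - p) * theta)
  # guard against numerical collapse to exactly 0/1 (downstream logits)
  pmin(pmax(q, 1e-12), 1 - 1e-12)
}

#' Simulate a structured metapopulation of dominant markers
#'
#' For each locus an ancestral presence-allele frequency \eqn{p_i} is drawn
#' from the truncated Beta prior. Population frequencies follow
#' Balding-Nichols: \eqn{p_{ij} \sim Beta(p_i\theta_{ij}, (1-p_i)\theta_{ij})}
#' with \eqn{\theta_{ij} = (1-F_{ij})/F_{ij}} and
#' \eqn{F_{ij} = \mathrm{logistic}(\alpha_i + \mathrm{logit}(F_j))}. Each
#' diploid individual shows a band with probability \eqn{1-(1-p_{ij})^2}
#' (dominance under Hardy-Weinberg). In spatial mode the independent
#' population effects are replaced by sequential drift along the
#' stepping-stone chain, so expected differentiation grows with pairwise
#' distance.
#'
#' @param params a [sim_params()] object
#' @return list with elements `markers` (clean [marker_matrix()]),
#'   `samples` (a [sample_table()] with coordinates), and `truth` (list:
#'   ancestral `p_anc`, realized `p_pop` (loci x pops), `selected` locus
#'   indices, `group_of`, error rates)
#' @export
simulate_metapopulation <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed(p$seed, {
    p_anc <- rbeta_trunc(p$n_loci, p$prior_a, p$prior_b, p$prior_lo, p$prior_hi)
    beta_j <- stats::qlogis(p$fst)
    p_pop <- matrix(NA_real_, p$n_loci, p$n_pops)
    if (!p$spatial) {
      for (j in seq_len(p$n_pops)) {
        f_ij <- stats::plogis(p$alpha + beta_j[j])
        p_pop[, j] <- rbn(p_anc, f_ij)
      }
    } else {
      f1 <- stats::plogis(p$alpha + beta_j[1])
      p_pop[, 1] <- rbn(p_anc, f1)
      for (j in 2:p$n_pops) {
        d <- abs(p$positions_km[j] - p$positions_km[j - 1])
        f_step <- 1 - exp(-d * p$drift_per_km)
        f_step <- pmin(pmax(stats::plogis(p$alpha + stats::qlogis(f_step)), 1e-6),
                       1 - 1e-6)
        p_pop[, j] <- rbn(p_pop[, j - 1], f_step)
      }
    }
    band_p <- 1 - (1 - p_pop)^2
    n_total <- sum(p$n_per_pop)
    pop_id <- rep(seq_len(p$n_pops), p$n_per_pop)
    calls <- matrix(0L, n_total, p$n_loci)
    for (j in seq_len(p$n_pops)) {
      rows <- which(pop_id == j)
      calls[rows, ] <- matrix(
        stats::rbinom(length(rows) * p$n_loci, 1L, rep(band_p[, j], each = length(rows))),
        nrow = length(rows))
    }
    pop_names <- sprintf("P%02d", seq_len(p$n_pops))
    ids <- sprintf("%s_i%02d", pop_names[pop_id],
                   unlist(lapply(p$n_per_pop, seq_len)))
    rownames(calls) <- ids
    colnames(calls) <- sprintf("L%04d", seq_len(p$n_loci))
    # coordinates: chain laid out along a meridian, 1 deg lat ~ 111.195 km
    lat <- p$positions_km / (6371 * pi / 180)
    samples <- sample_table(data.frame(
      sample_id = ids,
      population_id = pop_names[pop_id],
      group_id = sprintf("G%02d", p$group_of[pop_id]),
      island = "synthetic",
      latitude = lat[pop_id],
      longitude = 0,
      stringsAsFactors = FALSE))
    truth <- list(p_anc = p_anc, p_pop = p_pop,
                  selected = which(p$alpha != 0),
                  group_of = p$group_of, e01 = p$e01, e10 = p$e10,
                  band_p = band_p)
    list(markers = marker_matrix(calls), samples = samples, truth = truth)
  })
}

#' Apply scoring error and append replicate rows
#'
#' Independently flips calls (present to absent with probability `e10`,
#' absent to present with probability `e01`) and appends, for a random
#' `replicate_fraction` of the samples, a replicate row that is an
#' independent re-corruption of the same underlying true genotype row.
#' Missing calls are left missing.
#'
#' @param x clean [marker_matrix()] holding the true genotypes
#' @param e01 false-presence rate
#' @param e10 false-absence rate
#' @param replicate_fraction fraction of samples to re-genotype
#' @param seed RNG seed
#' @return a [marker_matrix()] with corrupted calls and replicate rows
#'   (ids `<sample>_rep1`)
#' @export
corrupt_and_replicate <- function(x, e01 = 0.04, e10 = 0.04,
                                  replicate_fraction = 0.11, seed = 1) {
  stopifnot(inherits(x, "marker_matrix"))
  if (e01 < 0 || e01 >= 1 || e10 < 0 || e10 >= 1) {
    stop("error rates must lie in [0, 1)")
  }
  if (replicate_fraction < 0 || replicate_fraction > 1) {
    stop("replicate_fraction must lie in [0, 1]")
  }
  truth <- unclass(x)
  with_seed(seed, {
    n_rep <- round(nrow(truth) * replicate_fraction)
    rep_idx <- sort(sample.int(nrow(truth), n_rep))
    corrupted <- corrupt_once(truth, e01, e10)
    reps <- corrupt_once(truth[rep_idx, , drop = FALSE], e01, e10)
    if (n_rep > 0) rownames(reps) <- paste0(rownames(truth)[rep_idx], "_rep1")
    out <- rbind(corrupted, reps)
    ro <- if (n_rep > 0) {
      stats::setNames(rownames(truth)[rep_idx], rownames(reps))
    } else character(0)
    marker_matrix(out, replicate_of = ro)
  })
}

corrupt_once <- function(m, e01, e10) {
  if (nrow(m) == 0) return(m)
  flip <- matrix(stats::runif(length(m)), nrow(m))
  out <- m
  out[m == 1L & flip < e10] <- 0L
  out[m == 0L & flip < e01] <- 1L
  out
}

#' Simulate electropherogram peak profiles from a marker matrix
#'
#' Each locus is mapped to a fragment size in [60, 550] bases (default:
#' evenly spaced). Every present call produces one peak at the locus size
#' plus Gaussian jitter, with log-normal height; each sample additionally
#' receives Poisson-many noise peaks at uniform sizes with low heights.
#'
#' @param x a [marker_matrix()] (missing calls produce no peak)
#' @param sizes fragment size per locus (length `ncol(x)`), default evenly
#'   spaced over [60, 550]
#' @param height_meanlog,height_sdlog log-normal parameters of present-peak
#'   heights (default around 5000 units)
#' @param noise_rate expected number of spurious peaks per sample
#' @param noise_meanlog,noise_sdlog log-normal parameters of noise-peak
#'   heights (default around 30 units, mostly below the 50-unit detection
#'   threshold)
#' @param jitter_sd fragment-sizing standard deviation in bases
#' @param seed RNG seed
#' @return data.frame with columns `sample`, `size_b`, `height`; the locus
#'   sizes are attached as attribute `locus_sizes`
#' @export
simulate_peak_profiles <- function(x, sizes = NULL,
                                   height_meanlog = log(5000),
                                   height_sdlog = 0.3,
                                   noise_rate = 0, noise_meanlog = log(30),
                                   noise_sdlog = 0.5,
                                   jitter_sd = 0.25, seed = 1) {
  stopifnot(inherits(x, "marker_matrix"))
  if (jitter_sd < 0) stop("jitter sd must be >= 0")
  if (noise_rate < 0) stop("noise rate must be >= 0")
  L <- ncol(x)
  if (is.null(sizes)) sizes <- seq(60, 550, length.out = L)
  if (length(sizes) != L) stop("sizes must have one entry per locus")
  if (any(sizes < 60 | sizes > 550)) stop("locus sizes must lie in [60, 550]")
  m <- unclass(x)
  with_seed(seed, {
    out <- vector("list", nrow(m))
    for (s in seq_len(nrow(m))) {
      present <- which(m[s, ] == 1L)
      pk_size <- sizes[present] + stats::rnorm(length(present), 0, jitter_sd)
      pk_h <- stats::rlnorm(length(present), height_meanlog, height_sdlog)
      n_noise <- stats::rpois(1, noise_rate)
      nz_size <- stats::runif(n_noise, 60, 550)
      nz_h <- stats::rlnorm(n_noise, noise_meanlog, noise_sdlog)
      out[[s]] <- data.frame(sample = rownames(m)[s],
                             size_b = c(pk_size, nz_size),
                             height = c(pk_h, nz_h),
                             stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    attr(res, "locus_sizes") <- stats::setNames(sizes, colnames(m))
    res
  })
}

#' Simulate clustered aligned sequences
#'
#' A random root sequence is mutated independently into `n_clusters`
#' ancestors (Jukes-Cantor style substitutions at rate `between_div / 2`, so
#' ancestor pairs diverge by about `between_div`); each tip then mutates from
#' its ancestor at rate `within_div`. No indels.
#'
#' @param n_clusters number of clusters
#' @param seqs_per_cluster sequences per cluster (scalar or vector)
#' @param length alignment length in bases
#' @param within_div per-tip substitution rate from the cluster ancestor
#' @param between_div target pairwise divergence among cluster ancestors
#' @param seed RNG seed
#' @return a [sequence_set()] with ids `C<k>_s<i>`; true cluster labels as
#'   attribute `true_cluster`
#' @export
simulate_sequences <- function(n_clusters, seqs_per_cluster, length = 606,
                               within_div = 0.005, between_div = 0.10,
                               seed = 1) {
  if (!(within_div >= 0 && within_div < between_div && between_div <= 0.75)) {
    stop("need 0 <= within_div < between_div <= 0.75")
  }
  seqs_per_cluster <- rep_len(seqs_per_cluster, n_clusters)
  bases <- c("A", "C", "G", "T")
  mutate <- function(seq, rate) {
    n_mut <- stats::rbinom(1, length(seq), rate)
    if (n_mut == 0) return(seq)
    pos <- sample.int(length(seq), n_mut)
    seq[pos] <- vapply(seq[pos],
                       function(b) sample(setdiff(bases, b), 1), "")
    seq
  }
  with_seed(seed, {
    root <- sample(bases, length, replace = TRUE)
    out <- character(0)
    labs <- character(0)
    for (k in seq_len(n_clusters)) {
      anc <- mutate(root, between_div / 2)
      for (i in seq_len(seqs_per_cluster[k])) {
        tip <- mutate(anc, within_div)
        out <- c(out, paste(tip, collapse = ""))
        labs <- c(labs, sprintf("C%d", k))
      }
    }
    names(out) <- sprintf("%s_s%d", labs,
                          unlist(lapply(seqs_per_cluster, seq_len)))
    res <- sequence_set(out, aligned = TRUE)
    attr(res, "true_cluster") <- stats::setNames(labs, names(out))
    res
  })
}

#' Simulate 2-D landmark configurations with group shape differences
#'
#' Group mean shapes are the unit-circle base configuration displaced by a
#' random direction of norm `shape_offset` in the Procrustes tangent space at
#' the base (orthogonal to translation, scale and rotation). Individuals add
#' isotropic landmark noise, then an arbitrary rotation/translation/scaling
#' is applied when `nuisance = TRUE`.
#'
#' @param n_groups number of groups
#' @param per_group specimens per group
#' @param n_landmarks number of landmarks (>= 3)
#' @param shape_offset tangent-space norm of the group mean displacement
#' @param noise_sd isotropic per-coordinate landmark noise
#' @param nuisance apply random similarity transformations
#' @param seed RNG seed
#' @return list with `coords` (array n_landmarks x 2 x n), `group` (factor),
#'   and `means` (true group mean shapes, list of matrices)
#' @export
simulate_landmarks <- function(n_groups = 2, per_group = 20, n_landmarks = 10,
                               shape_offset = 0.1, noise_sd = 0.02,
                               nuisance = TRUE, seed = 1) {
  if (n_landmarks < 3) stop("need at least 3 landmarks")
  if (noise_sd < 0) stop("noise sd must be >= 0")
  th <- seq(0, 2 * pi, length.out = n_landmarks + 1)[-(n_landmarks + 1)]
  base <- cbind(cos(th), sin(th))
  base <- scale(base, scale = FALSE)
  base <- base / sqrt(sum(base^2))          # unit centroid size preshape
  tangent_dir <- function() {
    v <- matrix(stats::rnorm(2 * n_landmarks), n_landmarks, 2)
    v <- scale(v, scale = FALSE)                       # remove translation
    v <- v - sum(v * base) * base                      # remove scale direction
    rot <- cbind(base[, 2], -base[, 1])                # rotation direction
    v <- v - sum(v * rot) * rot / sum(rot^2) * 1       # remove rotation
    v / sqrt(sum(v^2))
  }
  with_seed(seed, {
    means <- lapply(seq_len(n_groups), function(g) {
      if (g == 1) base else base + shape_offset * tangent_dir()
    })
    n <- n_groups * per_group
    coords <- array(NA_real_, c(n_landmarks, 2, n))
    group <- factor(rep(sprintf("G%d", seq_len(n_groups)), each = per_group))
    for (i in seq_len(n)) {
      g <- as.integer(group[i])
      cfg <- means[[g]] + matrix(stats::rnorm(2 * n_landmarks, 0, noise_sd),
                                 n_landmarks, 2)
      if (nuisance) {
        ang <- stats::runif(1, 0, 2 * pi)
        R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
        sc <- exp(stats::rnorm(1, 0, 0.2))
        tr <- stats::rnorm(2, 0, 2)
        cfg <- sweep(sc * cfg %*% R, 2, tr, `+`)
      }
      coords[, , i] <- cfg
    }
    dimnames(coords) <- list(NULL, c("x", "y"), sprintf("sp%03d", seq_len(n)))
    list(coords = coords, group = group, means = means)
  })
}
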