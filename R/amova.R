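# Hierarchical analysis of molecular variance for binary dominant phenotypes,
# in the pairwise squared-distance formulation, with the three standard
# permutation schemes, plus pairwise Phi_ST matrices.

#' Build a sampling hierarchy
#'
#' @param pop named character vector mapping sample id to population id, or a
#'   [sample_table()] (columns `sample_id`, `population_id`, optional
#'   `group_id`)
#' @param group optional named character vector mapping population id to
#'   group id
#' @return list of class `hierarchy` with elements `pop` and `group`
#' @export
hierarchy <- function(pop, group = NULL) {
  if (inherits(pop, "sample_table") || is.data.frame(pop)) {
    st <- pop
    pop <- stats::setNames(st$population_id, st$sample_id)
    if (is.null(group) && "group_id" %in% names(st) && !all(is.na(st$group_id))) {
      g <- unique(st[, c("population_id", "group_id")])
      if (anyDuplicated(g$population_id)) {
        stop("populations assigned to more than one group")
      }
      group <- stats::setNames(g$group_id, g$population_id)
    }
  }
  if (is.null(names(pop))) stop("pop must be a named vector (sample -> population)")
  if (!is.null(group)) {
    miss <- setdiff(unique(unname(pop)), names(group))
    if (length(miss)) stop("populations without group assignment: ",
                           paste(miss, collapse = ", "))
  }
  structure(list(pop = pop, group = group), class = "hierarchy")
}

# Pairwise squared distance = number of mismatching loci, rescaled for
# missing calls by total loci / comparable loci.
mismatch_d2 <- function(m) {
  v <- !is.na(m)
  m0 <- m; m0[!v] <- 0L
  storage.mode(m0) <- "double"; storage.mode(v) <- "double"
  comp <- v %*% t(v)
  if (any(comp[upper.tri(comp)] == 0)) stop("sample pair with no comparable loci")
  shared1 <- m0 %*% t(m0)
  ones_b <- m0 %*% t(v)                       # bands of x at loci valid in both
  mism <- ones_b + t(ones_b) - 2 * shared1
  d2 <- mism * ncol(m) / comp
  diag(d2) <- 0
  (d2 + t(d2)) / 2
}

ssd_within <- function(d2, f) {
  # f: integer group labels per individual; SSD within = sum over levels of
  # (sum of pairwise d2 inside the level) / (2 * level size)
  s <- 0
  for (lv in unique(f)) {
    idx <- which(f == lv)
    s <- s + sum(d2[idx, idx]) / (2 * length(idx))
  }
  s
}

amova_decompose <- function(d2, pop, grp = NULL) {
  N <- length(pop)
  ssd_t <- sum(d2) / (2 * N)
  ssd_wp <- ssd_within(d2, pop)
  n_p <- table(pop)
  P <- length(n_p)
  if (is.null(grp)) {
    df_ap <- P - 1; df_wp <- N - P
    ssd_ap <- ssd_t - ssd_wp
    ms_ap <- ssd_ap / df_ap
    sig_c <- ssd_wp / df_wp
    n0 <- (N - sum(n_p^2) / N) / (P - 1)
    sig_b <- (ms_ap - sig_c) / n0
    tot <- sig_b + sig_c
    list(ssd = c(among_pops = ssd_ap, within_pops = ssd_wp, total = ssd_t),
         df = c(among_pops = df_ap, within_pops = df_wp, total = N - 1),
         sigma = c(among_pops = sig_b, within_pops = sig_c),
         phi = c(phi_st = if (tot > 0) sig_b / tot else 0))
  } else {
    G <- length(unique(grp))
    ssd_wg <- ssd_within(d2, grp)
    ssd_ag <- ssd_t - ssd_wg
    ssd_ap <- ssd_wg - ssd_wp
    df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
    ms_ag <- ssd_ag / df_ag; ms_ap <- ssd_ap / df_ap
    sig_c <- ssd_wp / df_wp
    n_g <- table(grp)
    # per-group sum over populations of n_p^2 / n_g
    pop_grp <- tapply(grp, pop, `[`, 1)
    sum_g <- tapply(as.vector(n_p)^2 / as.vector(n_g[pop_grp]), pop_grp, sum)
    n1 <- (N - sum(sum_g)) / (P - G)
    n2 <- (sum(sum_g) - sum(n_p^2) / N) / (G - 1)
    n3 <- (N - sum(n_g^2) / N) / (G - 1)
    sig_b <- (ms_ap - sig_c) / n1
    sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
    tot <- sig_a + sig_b + sig_c
    list(ssd = c(among_groups = ssd_ag, among_pops_within_groups = ssd_ap,
                 within_pops = ssd_wp, total = ssd_t),
         df = c(among_groups = df_ag, among_pops_within_groups = df_ap,
                within_pops = df_wp, total = N - 1),
         sigma = c(among_groups = sig_a, among_pops_within_groups = sig_b,
                   within_pops = sig_c),
         phi = c(phi_ct = if (tot > 0) sig_a / tot else 0,
                 phi_sc = if (sig_b + sig_c > 0) sig_b / (sig_b + sig_c) else 0,
                 phi_st = if (tot > 0) (sig_a + sig_b) / tot else 0))
  }
}

#' Hierarchical AMOVA on dominant marker data
#'
#' Excoffier-Smouse-Quattro variance decomposition from pairwise squared
#' distances, where the distance between two band profiles is the number of
#' mismatching loci (rescaled for missing calls). One-level designs
#' (populations within the total) yield \eqn{\Phi_{ST}}; two-level designs
#' (populations within groups) additionally yield \eqn{\Phi_{CT}} and
#' \eqn{\Phi_{SC}}. Significance by permutation: individuals among
#' populations (\eqn{\Phi_{ST}}), individuals among populations within
#' groups (\eqn{\Phi_{SC}}), whole populations among groups
#' (\eqn{\Phi_{CT}}); p = (hits + 1) / (n_perm + 1).
#'
#' Populations with fewer than `min_pop_size` individuals are excluded
#' (warning); negative variance components are reported as-is and flagged.
#'
#' @param x a [marker_matrix()] (replicate rows are dropped)
#' @param hier a [hierarchy()]
#' @param n_perm number of permutations (0 = no test)
#' @param seed RNG seed for the permutations
#' @param min_pop_size minimum population sample size
#' @return object of class `amova_result`: variance components, percentages,
#'   Phi-statistics, permutation p-values
#' @export
amova <- function(x, hier, n_perm = 20022, seed = 1, min_pop_size = 5) {
  stopifnot(inherits(hier, "hierarchy"))
  x <- drop_replicates(x)
  ids <- intersect(rownames(x), names(hier$pop))
  if (!length(ids)) stop("no overlap between marker matrix and hierarchy")
  pop <- hier$pop[ids]
  sz <- table(pop)
  small <- names(sz)[sz < max(min_pop_size, 2)]
  if (length(small)) {
    warning("excluding population(s) below the size cut-off: ",
            paste(small, collapse = ", "))
    ids <- ids[!(pop %in% small)]
    pop <- pop[ids]
  }
  if (length(unique(pop)) < 2) stop("fewer than 2 populations after filtering")
  grp <- if (!is.null(hier$group)) unname(hier$group[pop]) else NULL
  if (!is.null(grp) && length(unique(grp)) < 2) grp <- NULL
  m <- unclass(x)[ids, , drop = FALSE]
  d2 <- mismatch_d2(m)
  pop <- unname(pop)
  obs <- amova_decompose(d2, pop, grp)
  p_vals <- NULL
  if (n_perm > 0) {
    p_vals <- with_seed(seed, amova_permute(d2, pop, grp, obs$phi, n_perm))
  }
  total_var <- sum(obs$sigma)
  structure(list(
    ssd = obs$ssd, df = obs$df, sigma = obs$sigma,
    percent = 100 * obs$sigma / total_var,
    phi = obs$phi, p = p_vals, n_perm = n_perm,
    negative_components = any(obs$sigma < 0),
    n_samples = length(ids), populations = sort(unique(pop))),
    class = "amova_result")
}

amova_permute <- function(d2, pop, grp, phi_obs, n_perm) {
  N <- length(pop)
  hits <- stats::setNames(numeric(length(phi_obs)), names(phi_obs))
  if (is.null(grp)) {
    for (b in seq_len(n_perm)) {
      perm <- amova_decompose(d2, pop[sample.int(N)], NULL)
      hits["phi_st"] <- hits["phi_st"] + (perm$phi["phi_st"] >= phi_obs["phi_st"])
    }
  } else {
    pops <- unique(pop)
    grp_of_pop <- tapply(grp, pop, `[`, 1)[pops]
    for (b in seq_len(n_perm)) {
      # Phi_ST: individuals among populations (and groups)
      prm <- sample.int(N)
      d_st <- amova_decompose(d2, pop[prm], grp[prm])
      hits["phi_st"] <- hits["phi_st"] + (d_st$phi["phi_st"] >= phi_obs["phi_st"])
      # Phi_SC: individuals among populations within their group
      pop_sc <- pop
      for (g in unique(grp)) {
        idx <- which(grp == g)
        pop_sc[idx] <- pop[idx][sample.int(length(idx))]
      }
      d_sc <- amova_decompose(d2, pop_sc, grp)
      hits["phi_sc"] <- hits["phi_sc"] + (d_sc$phi["phi_sc"] >= phi_obs["phi_sc"])
      # Phi_CT: whole populations among groups
      g_perm <- stats::setNames(sample(unname(grp_of_pop)), pops)
      d_ct <- amova_decompose(d2, pop, unname(g_perm[pop]))
      hits["phi_ct"] <- hits["phi_ct"] + (d_ct$phi["phi_ct"] >= phi_obs["phi_ct"])
    }
  }
  (hits + 1) / (n_perm + 1)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$n_samples, " samples, ",
      length(x$populations), " populations)\n", sep = "")
  comp <- data.frame(df = x$df[names(x$sigma)],
                     SSD = x$ssd[names(x$sigma)],
                     sigma2 = x$sigma,
                     percent = x$percent)
  print(round(comp, 4))
  phi <- x$phi
  for (i in seq_along(phi)) {
    cat(sprintf("  %s = %.4f%s\n", names(phi)[i], phi[i],
                if (!is.null(x$p)) sprintf(" (p = %.5g, %d perms)",
                                           x$p[names(phi)[i]], x$n_perm) else ""))
  }
  if (x$negative_components) cat("  note: negative variance component(s)\n")
  invisible(x)
}

#' Pairwise Phi_ST matrix between populations
#'
#' Two-population AMOVA for every population pair. Negative estimates are
#' clamped to 0 in the returned matrix (raw values kept in the `raw`
#' attribute) so the matrix can feed Mantel tests directly.
#'
#' @param x a [marker_matrix()]
#' @param hier a [hierarchy()]
#' @param n_perm permutations per pair (0 = none)
#' @param seed RNG seed
#' @param min_pop_size minimum population size
#' @return a [dist_matrix()] tagged `fst`, with attributes `raw` and
#'   (when `n_perm > 0`) `p_values`
#' @export
pairwise_fst <- function(x, hier, n_perm = 0, seed = 1, min_pop_size = 2) {
  stopifnot(inherits(hier, "hierarchy"))
  x <- drop_replicates(x)
  ids <- intersect(rownames(x), names(hier$pop))
  pop <- hier$pop[ids]
  sz <- table(pop)
  keep_pops <- names(sz)[sz >= max(min_pop_size, 2)]
  if (length(keep_pops) < 2) stop("fewer than 2 populations of sufficient size")
  pops <- sort(keep_pops)
  P <- length(pops)
  fst <- raw <- matrix(0, P, P, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      sel <- ids[pop %in% c(pops[i], pops[j])]
      res <- suppressWarnings(
        amova(marker_matrix(unclass(x)[sel, , drop = FALSE]),
              hierarchy(hier$pop[sel]), n_perm = n_perm,
              seed = seed + i * P + j, min_pop_size = min_pop_size))
      raw[i, j] <- raw[j, i] <- unname(res$phi["phi_st"])
      fst[i, j] <- fst[j, i] <- max(unname(res$phi["phi_st"]), 0)
      if (n_perm > 0) pv[i, j] <- pv[j, i] <- unname(res$p["phi_st"])
    }
  }
  out <- dist_matrix(fst, kind = "fst")
  attr(out, "raw") <- raw
  if (n_perm > 0) attr(out, "p_values") <- pv
  out
}
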