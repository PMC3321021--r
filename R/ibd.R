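# Isolation by distance: great-circle geographic distances and simple Mantel
# tests with exact enumeration for very small matrices.

EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance matrix between populations
#'
#' Aggregates a sample table to populations (the population coordinate is
#' the centroid of its samples' coordinates; studies typically have one site
#' per population so this is usually the site itself) and computes spherical
#' great-circle distances with earth radius 6371 km.
#'
#' @param samples a [sample_table()] with `latitude`/`longitude`
#' @return a [dist_matrix()] tagged `km`, populations as ids
#' @export
geodesic_km_matrix <- function(samples) {
  st <- as.data.frame(samples)
  if (!all(c("latitude", "longitude") %in% names(st))) {
    stop("sample table has no coordinates")
  }
  miss <- unique(st$population_id[is.na(st$latitude) | is.na(st$longitude)])
  if (length(miss)) stop("missing coordinates for population(s): ",
                         paste(miss, collapse = ", "))
  lat <- tapply(st$latitude, st$population_id, mean)
  lon <- tapply(st$longitude, st$population_id, mean)
  pops <- names(lat)
  phi <- lat * pi / 180; lam <- lon * pi / 180
  # haversine, numerically stable near zero
  dphi <- outer(phi, phi, `-`) / 2
  dlam <- outer(lam, lam, `-`) / 2
  a <- sin(dphi)^2 + outer(cos(phi), cos(phi)) * sin(dlam)^2
  d <- 2 * EARTH_RADIUS_KM * asin(pmin(sqrt(a), 1))
  dimnames(d) <- list(pops, pops)
  diag(d) <- 0
  dist_matrix((d + t(d)) / 2, kind = "km")
}

#' Simple Mantel test
#'
#' Pearson correlation of the off-diagonal upper triangles of two distance
#' matrices over the same ids. Significance by simultaneously permuting rows
#' and columns of the second matrix; for n <= 7 all n! permutations are
#' enumerated instead of sampled. The default test is one-tailed positive
#' (the isolation-by-distance direction);
#' p = (number of permutation r at least as extreme + 1) / (n_perm + 1)
#' (in enumeration mode the identity permutation is part of the count).
#'
#' @param a,b [dist_matrix()] objects with identical ids in identical order
#' @param n_perm number of sampled permutations (ignored in enumeration mode)
#' @param seed RNG seed
#' @param tail "positive" (default), "negative" or "two_sided"
#' @param exact_max enumerate all permutations when n <= `exact_max`
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `n`, `exact`
#' @export
mantel_test <- function(a, b, n_perm = 1e6, seed = 1,
                        tail = c("positive", "negative", "two_sided"),
                        exact_max = 7) {
  tail <- match.arg(tail)
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("matrix sizes differ")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    stop("matrix ids differ or are ordered differently")
  }
  n <- nrow(a)
  if (n < 4) stop("need at least 4 ids")
  ut <- upper.tri(a)
  va <- a[ut]
  if (stats::sd(va) == 0 || stats::sd(b[ut]) == 0) {
    stop("zero variance in a distance triangle; r undefined")
  }
  r_obs <- stats::cor(va, b[ut])
  score <- function(r) switch(tail, positive = r, negative = -r,
                              two_sided = abs(r))
  exact <- n <= exact_max
  if (exact) {
    perms <- all_permutations(n)
    rs <- vapply(seq_len(nrow(perms)), function(k) {
      p <- perms[k, ]
      stats::cor(va, b[p, p][ut])
    }, 0)
    p_val <- mean(score(rs) >= score(r_obs) - 1e-12)
    n_used <- nrow(perms)
  } else {
    hits <- with_seed(seed, {
      h <- 0L
      for (k in seq_len(n_perm)) {
        p <- sample.int(n)
        h <- h + (score(stats::cor(va, b[p, p][ut])) >= score(r_obs) - 1e-12)
      }
      h
    })
    p_val <- (hits + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p = p_val, n_perm = n_used, n = n, exact = exact,
                 tail = tail),
            class = "mantel_result")
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  blocks <- lapply(seq_len(n), function(pos) {
    left <- sub[, seq_len(pos - 1), drop = FALSE]
    right <- if (pos <= n - 1) sub[, pos:(n - 1), drop = FALSE] else
      sub[, 0, drop = FALSE]
    cbind(left, n, right)
  })
  unname(do.call(rbind, blocks))
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (n = %d): r = %.4f, p = %.5g (%s, %s%d permutations)\n",
              x$n, x$r, x$p, x$tail,
              if (x$exact) "exact, " else "", x$n_perm))
  invisible(x)
}
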