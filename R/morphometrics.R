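# Landmark-based geometric morphometrics: generalized Procrustes alignment,
# centroid size, shape PCA, CVA assignment with typicality probabilities,
# and Goodall's F.

centroid_size <- function(cfg) {
  ctr <- colMeans(cfg)
  sqrt(sum(sweep(cfg, 2, ctr)^2))
}

# optimal rotation of X onto Y (both centered), rotation only (no reflection)
opt_rotation <- function(x, y) {
  s <- svd(t(x) %*% y)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {
    u <- s$u; u[, ncol(u)] <- -u[, ncol(u)]
    r <- u %*% t(s$v)
  }
  r
}

#' Generalized Procrustes alignment
#'
#' Configurations are translated to centroid origin, scaled to unit centroid
#' size, and iteratively rotated onto the consensus (orthogonal Procrustes
#' via SVD, rotations only); the consensus is re-estimated until it changes
#' by less than `tol`. Original-unit centroid sizes are returned per
#' specimen.
#'
#' @param coords array of dimension k x 2 x n (landmarks, xy, specimens), or
#'   a list of k x 2 matrices
#' @param tol consensus convergence tolerance
#' @param max_iter iteration cap
#' @return list of class `shape_space`: `aligned` (k x 2 x n), `csize`,
#'   `consensus` (centered, unit centroid size)
#' @export
gpa <- function(coords, tol = 1e-10, max_iter = 200) {
  if (is.list(coords)) {
    coords <- array(unlist(coords), c(nrow(coords[[1]]), 2, length(coords)))
  }
  k <- dim(coords)[1]; n <- dim(coords)[3]
  if (n < 2) stop("need at least 2 specimens")
  if (k < 3) stop("need at least 3 landmarks")
  csize <- apply(coords, 3, centroid_size)
  if (any(csize < 1e-12)) {
    stop("degenerate configuration (zero centroid size) for specimen ",
         which(csize < 1e-12)[1])
  }
  aligned <- coords
  for (i in seq_len(n)) {
    cfg <- coords[, , i]
    cfg <- sweep(cfg, 2, colMeans(cfg))
    aligned[, , i] <- cfg / csize[i]
  }
  consensus <- aligned[, , 1]
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      aligned[, , i] <- aligned[, , i] %*% opt_rotation(aligned[, , i], consensus)
    }
    new_cons <- apply(aligned, c(1, 2), mean)
    new_cons <- sweep(new_cons, 2, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    if (sqrt(sum((new_cons - consensus)^2)) < tol) { consensus <- new_cons; break }
    consensus <- new_cons
  }
  nm <- dimnames(coords)[[3]] %||% sprintf("sp%03d", seq_len(n))
  dimnames(aligned)[[3]] <- nm
  structure(list(aligned = aligned, csize = stats::setNames(csize, nm),
                 consensus = consensus),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("shape_space: %d specimens, %d landmarks\n",
              dim(x$aligned)[3], dim(x$aligned)[1]))
  invisible(x)
}

# partial Procrustes distance between two configurations (centered,
# unit-scaled, optimally rotated)
procrustes_dist <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); a <- a / sqrt(sum(a^2))
  b <- sweep(b, 2, colMeans(b)); b <- b / sqrt(sum(b^2))
  b <- b %*% opt_rotation(b, a)
  sqrt(sum((a - b)^2))
}

flatten_shapes <- function(ss) {
  n <- dim(ss$aligned)[3]
  t(vapply(seq_len(n), function(i) as.vector(ss$aligned[, , i]),
           numeric(prod(dim(ss$aligned)[1:2]))))
}

#' PCA of Procrustes shape coordinates
#'
#' Covariance-matrix PCA on the flattened aligned coordinates. Variance
#' fractions sum to 1 over the non-null dimensions (at most 2k - 4 for 2-D
#' landmarks).
#'
#' @param ss a `shape_space` from [gpa()]
#' @return list of class `shape_pca`: `scores`, `loadings`, `var_frac`,
#'   `sdev`
#' @export
shape_pca <- function(ss) {
  x <- flatten_shapes(ss)
  if (nrow(x) < 2) stop("need at least 2 specimens")
  pc <- stats::prcomp(x, center = TRUE)
  tot <- sum(pc$sdev^2)
  if (tot < 1e-24) stop("no shape variation: all specimens identical")
  keep <- pc$sdev^2 > 1e-12 * tot
  structure(list(scores = pc$x[, keep, drop = FALSE],
                 loadings = pc$rotation[, keep, drop = FALSE],
                 var_frac = pc$sdev[keep]^2 / tot,
                 sdev = pc$sdev[keep]),
            class = "shape_pca")
}

#' CVA-based assignment test with typicality probabilities
#'
#' Canonical variates on tangent-space shape coordinates (dimensionality
#' reduced by PCA, pooled within-group covariance regularized if needed).
#' In leave-one-out mode each specimen is held out, the discriminant space
#' recomputed, and the specimen assigned to the group with the smallest
#' Mahalanobis distance. Typicality probabilities
#' (P(chi-square_d >= D^2)) classify each assignment: unambiguous and
#' statistically significant when the best group's typicality exceeds 0.05
#' while every other group's is at most 0.05.
#'
#' @param ss a `shape_space`
#' @param group factor of group labels (length = specimens)
#' @param mode "leave_one_out" or "resubstitution"
#' @param min_group_size groups smaller than this are excluded (warning)
#' @return list of class `cva_assignment`: `table` (per-specimen), `success`
#'   (per-group %), `overall_success`, `n_significant`
#' @export
cva_assign <- function(ss, group, mode = c("leave_one_out", "resubstitution"),
                       min_group_size = 3) {
  mode <- match.arg(mode)
  group <- factor(group)
  x <- flatten_shapes(ss)
  stopifnot(nrow(x) == length(group))
  sz <- table(group)
  small <- names(sz)[sz < min_group_size]
  if (length(small)) {
    warning("excluding group(s) smaller than ", min_group_size, ": ",
            paste(small, collapse = ", "))
    keep <- !(group %in% small)
    x <- x[keep, , drop = FALSE]
    group <- droplevels(group[keep])
  }
  if (nlevels(group) < 2) stop("need at least 2 groups")
  n <- nrow(x)
  ids <- dimnames(ss$aligned)[[3]][seq_len(n)]
  k2 <- ncol(x)
  max_dim <- min(k2 - 4, n - nlevels(group) - 2)
  if (max_dim < 1) stop("too few specimens for CVA")
  assess <- function(train_x, train_g, test_x) {
    pc <- stats::prcomp(train_x, center = TRUE)
    keep <- which(pc$sdev^2 > 1e-10 * sum(pc$sdev^2))[seq_len(
      min(max_dim, sum(pc$sdev^2 > 1e-10 * sum(pc$sdev^2))))]
    tr <- pc$x[, keep, drop = FALSE]
    te <- scale(test_x, center = pc$center, scale = FALSE) %*%
      pc$rotation[, keep, drop = FALSE]
    d <- length(keep)
    lv <- levels(train_g)
    mu <- do.call(rbind, lapply(lv, function(g) colMeans(tr[train_g == g, , drop = FALSE])))
    pooled <- matrix(0, d, d)
    for (g in lv) {
      sub <- tr[train_g == g, , drop = FALSE]
      pooled <- pooled + crossprod(scale(sub, scale = FALSE))
    }
    pooled <- pooled / (nrow(tr) - length(lv))
    pooled <- pooled + diag(1e-8 * mean(diag(pooled)), d)
    pinv <- solve(pooled)
    d2 <- vapply(seq_along(lv), function(gi) {
      diff <- sweep(te, 2, mu[gi, ])
      rowSums((diff %*% pinv) * diff)
    }, numeric(nrow(te)))
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
    list(d2 = d2, df = d, levels = lv)
  }
  rows <- vector("list", n)
  if (mode == "leave_one_out") {
    for (i in seq_len(n)) {
      a <- assess(x[-i, , drop = FALSE], droplevels(group[-i]),
                  x[i, , drop = FALSE])
      rows[[i]] <- score_assignment(a, ids[i], as.character(group[i]))
    }
  } else {
    a <- assess(x, group, x)
    for (i in seq_len(n)) {
      rows[[i]] <- score_assignment(list(d2 = a$d2[i, , drop = FALSE],
                                         df = a$df, levels = a$levels),
                                    ids[i], as.character(group[i]))
    }
  }
  tab <- do.call(rbind, rows)
  succ <- tapply(tab$correct, tab$true_group, mean) * 100
  structure(list(table = tab,
                 success = succ,
                 overall_success = 100 * mean(tab$correct),
                 n_significant = sum(tab$significant)),
            class = "cva_assignment")
}

score_assignment <- function(a, id, true_group) {
  d2 <- as.vector(a$d2)
  typ <- stats::pchisq(d2, df = a$df, lower.tail = FALSE)
  best <- which.min(d2)
  ambiguous <- sum(abs(d2 - d2[best]) < 1e-9) > 1
  data.frame(id = id,
             true_group = true_group,
             assigned = a$levels[best],
             correct = a$levels[best] == true_group,
             typicality_best = typ[best],
             significant = !ambiguous & typ[best] > 0.05 &
               all(typ[-best] <= 0.05),
             ambiguous = ambiguous,
             stringsAsFactors = FALSE)
}

#' @export
print.cva_assignment <- function(x, ...) {
  cat(sprintf("CVA assignment: %.1f%% overall success, %d of %d unambiguous and significant\n",
              x$overall_success, x$n_significant, nrow(x$table)))
  print(round(x$success, 1))
  invisible(x)
}

#' Goodall's F-test for a shape difference between two groups
#'
#' \eqn{F = [D^2 / (1/n_A + 1/n_B)] / [(SS_A + SS_B)/(n_A + n_B - 2)]} where
#' D is the Procrustes distance between the group consensus shapes and SS
#' the summed squared Procrustes distances of specimens to their own
#' consensus. For 2-D landmarks df1 = 2k - 4 and
#' df2 = (n_A + n_B - 2)(2k - 4). Significance both from the F distribution
#' and by permutation of group labels.
#'
#' @param ss a `shape_space`
#' @param group factor/vector of group labels
#' @param a,b the two group labels to compare
#' @param n_perm label permutations (0 = parametric only)
#' @param seed RNG seed
#' @return list of class `goodall_f`: `F`, `df1`, `df2`, `p_param`,
#'   `p_perm`, `d_proc`, `n`
#' @export
goodall_f <- function(ss, group, a, b, n_perm = 999, seed = 1) {
  group <- as.character(group)
  sel <- group %in% c(a, b)
  if (sum(group == a) < 2 || sum(group == b) < 2) {
    stop("both groups need at least 2 specimens")
  }
  shapes <- ss$aligned[, , sel, drop = FALSE]
  g <- group[sel]
  k <- dim(shapes)[1]
  stat <- function(g) {
    ia <- which(g == a); ib <- which(g == b)
    ma <- apply(shapes[, , ia, drop = FALSE], c(1, 2), mean)
    mb <- apply(shapes[, , ib, drop = FALSE], c(1, 2), mean)
    d <- procrustes_dist(ma, mb)
    ssw <- sum(vapply(ia, function(i) procrustes_dist(shapes[, , i], ma)^2, 0)) +
      sum(vapply(ib, function(i) procrustes_dist(shapes[, , i], mb)^2, 0))
    na <- length(ia); nb <- length(ib)
    num <- d^2 / (1 / na + 1 / nb)
    den <- ssw / (na + nb - 2)
    c(f = if (den > 0) num / den else if (num == 0) 0 else Inf, d = d)
  }
  obs <- stat(g)
  na <- sum(g == a); nb <- sum(g == b)
  df1 <- 2 * k - 4
  df2 <- (na + nb - 2) * (2 * k - 4)
  p_param <- stats::pf(obs["f"], df1, df2, lower.tail = FALSE)
  p_perm <- NA_real_
  if (n_perm > 0) {
    p_perm <- with_seed(seed, {
      hits <- 0L
      for (r in seq_len(n_perm)) {
        hits <- hits + (stat(sample(g))["f"] >= obs["f"] - 1e-12)
      }
      (hits + 1) / (n_perm + 1)
    })
  }
  structure(list(F = unname(obs["f"]), df1 = df1, df2 = df2,
                 p_param = unname(p_param), p_perm = unname(p_perm),
                 d_proc = unname(obs["d"]), n = c(na, nb)),
            class = "goodall_f")
}

#' @export
print.goodall_f <- function(x, ...) {
  cat(sprintf("Goodall's F = %.3f; df = %d, %d; parametric p = %.4g%s\n",
              x$F, x$df1, x$df2, x$p_param,
              if (!is.na(x$p_perm)) sprintf("; permutation p = %.4g", x$p_perm)
              else ""))
  invisible(x)
}

#' Read landmark configurations from a TPS file
#'
#' Minimal TPS reader: `LM=k` starts a specimen block of k "x y" coordinate
#' lines; `ID=` (or `IMAGE=`) names the specimen. Scale lines are ignored.
#'
#' @param path TPS file path
#' @return array k x 2 x n with specimen names
#' @export
read_tps <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no LM= records in ", path)
  specs <- list(); ids <- character(0)
  for (si in seq_along(starts)) {
    from <- starts[si]
    to <- if (si < length(starts)) starts[si + 1] - 1 else length(lines)
    k <- as.integer(sub("^LM=", "", lines[from], ignore.case = TRUE))
    coord_lines <- lines[(from + 1):(from + k)]
    xy <- do.call(rbind, lapply(strsplit(coord_lines, "[ \t]+"), function(v) {
      as.numeric(v[1:2])
    }))
    if (anyNA(xy)) stop("malformed coordinates in specimen block ", si)
    id_line <- grep("^(ID|IMAGE)=", lines[from:to], ignore.case = TRUE, value = TRUE)
    ids <- c(ids, if (length(id_line)) sub("^(ID|IMAGE)=", "", id_line[1],
                                           ignore.case = TRUE)
             else sprintf("sp%03d", si))
    specs[[si]] <- xy
  }
  ks <- vapply(specs, nrow, 1L)
  if (length(unique(ks)) != 1) stop("unequal landmark counts across specimens")
  out <- array(unlist(specs), c(ks[1], 2, length(specs)))
  dimnames(out) <- list(NULL, c("x", "y"), ids)
  out
}
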