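# Distances, neighbor-joining with locus bootstrap, and threshold MOTU
# clustering.

#' Nei-Li (Dice) distance between dominant marker profiles
#'
#' \eqn{D(x, y) = 1 - 2 n_{xy} / (n_x + n_y)} where \eqn{n_x, n_y} are the
#' band counts of the two samples and \eqn{n_{xy}} the number of shared
#' bands, computed over loci non-missing in both samples. Shared absences are
#' ignored (a fragment can be lost in many independent ways). Pairs with
#' \eqn{n_x + n_y = 0} get distance 0 with a warning. Replicate rows are
#' excluded by default.
#'
#' @param x a [marker_matrix()]
#' @param include_replicates keep replicate rows in the computation
#' @return a [dist_matrix()] tagged `nei_li`
#' @export
nei_li_distance <- function(x, include_replicates = FALSE) {
  if (!include_replicates) x <- drop_replicates(x)
  m <- unclass(x)
  if (nrow(m) < 2) stop("need at least 2 samples")
  v <- !is.na(m)               # validity mask
  m0 <- m; m0[!v] <- 0L
  storage.mode(m0) <- "double"; storage.mode(v) <- "double"
  overlap <- v %*% t(v)
  if (any(overlap[upper.tri(overlap)] == 0)) {
    idx <- which(overlap == 0 & upper.tri(overlap), arr.ind = TRUE)[1, ]
    stop(sprintf("samples '%s' and '%s' share no non-missing locus",
                 rownames(m)[idx[1]], rownames(m)[idx[2]]))
  }
  nxy <- m0 %*% t(m0)
  nx <- m0 %*% t(v)            # bands of row sample at loci valid in both
  tot <- nx + t(nx)
  d <- 1 - 2 * nxy / tot
  zero_tot <- tot == 0
  if (any(zero_tot[upper.tri(zero_tot)])) {
    warning("pair(s) with no bands in either sample: distance set to 0")
    d[zero_tot] <- 0
  }
  diag(d) <- 0
  d[d < 0] <- 0
  dist_matrix((d + t(d)) / 2, kind = "nei_li")
}

#' Uncorrected p-distance between aligned sequences
#'
#' Proportion of differing sites among positions where both sequences carry
#' an unambiguous A/C/G/T (pairwise deletion of gaps and ambiguities).
#'
#' @param x an aligned [sequence_set()]
#' @return a [dist_matrix()] tagged `p_distance`
#' @export
p_distance <- function(x) {
  stopifnot(inherits(x, "sequence_set"))
  if (!isTRUE(attr(x, "aligned"))) stop("p-distance requires aligned sequences")
  n <- length(x)
  if (n < 2) stop("need at least 2 sequences")
  chars <- do.call(rbind, strsplit(unclass(x), ""))
  code <- matrix(match(chars, c("A", "C", "G", "T")), nrow = n)
  d <- matrix(0, n, n, dimnames = list(names(x), names(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(code[i, ]) & !is.na(code[j, ])
      if (!any(ok)) {
        stop(sprintf("sequences '%s' and '%s' share no comparable site",
                     names(x)[i], names(x)[j]))
      }
      d[i, j] <- d[j, i] <- mean(code[i, ok] != code[j, ok])
    }
  }
  dist_matrix(d, kind = "p_distance")
}

#' Neighbor-joining tree with optional locus bootstrap
#'
#' Saitou-Nei neighbor joining on a distance matrix (Q-matrix criterion;
#' ties broken at the lowest index pair so trees are reproducible). Negative
#' branch lengths are clamped to zero with the deficit moved to the adjacent
#' branch, preserving path lengths. When `bootstrap` is supplied, loci are
#' resampled with replacement, the Nei-Li distance and tree recomputed, and
#' bipartition frequencies (percent) attached as internal node labels.
#'
#' @param d a [dist_matrix()] (or plain symmetric matrix) over >= 3 taxa
#' @param bootstrap optional list with elements `markers` (the
#'   [marker_matrix()] the distances came from), `n_reps` (default 1000) and
#'   `seed`
#' @return an unrooted [ape::phylo] tree; bootstrap supports (if any) in
#'   `$node.label`
#' @export
neighbor_joining <- function(d, bootstrap = NULL) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("non-finite distances")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  tree <- nj_build(d)
  if (!is.null(bootstrap)) {
    x <- bootstrap$markers
    stopifnot(inherits(x, "marker_matrix"))
    n_reps <- bootstrap$n_reps %||% 1000
    boots <- with_seed(bootstrap$seed %||% 1, {
      lapply(seq_len(n_reps), function(r) {
        cols <- sample.int(ncol(x), replace = TRUE)
        xb <- marker_matrix(
          unclass(x)[, cols, drop = FALSE] |>
            (\(m) { colnames(m) <- paste0("b", seq_len(ncol(m))); m })(),
          replicate_of = attr(x, "replicate_of"))
        nj_build(as.matrix(nei_li_distance(xb)))
      })
    })
    cnt <- ape::prop.clades(tree, boots, rooted = FALSE)
    tree$node.label <- ifelse(is.na(cnt), "", round(100 * cnt / n_reps))
  }
  tree
}

# Core NJ: returns an ape phylo built from a Newick string assembled during
# agglomeration.
nj_build <- function(d) {
  labels <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  sub <- gsub("([(),:;])", "_", labels)  # guard separators in labels
  active <- seq_len(nrow(d))
  newick <- sub
  repeat {
    r <- length(active)
    if (r == 3) break
    dm <- d[active, active]
    R <- rowSums(dm)
    q <- (r - 2) * dm - outer(R, R, `+`)
    diag(q) <- Inf
    # lowest (i, j) among minima, scanning rows then columns
    min_q <- min(q)
    cand <- which(q <= min_q + 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    la <- dm[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lb <- dm[i, j] - la
    cl <- clamp_pair(la, lb)
    ai <- active[i]; aj <- active[j]
    new_d <- (d[ai, ] + d[aj, ] - d[ai, aj]) / 2
    d <- rbind(cbind(d, new_d), c(new_d, 0))
    k <- nrow(d)
    newick <- c(newick, sprintf("(%s:%.15g,%s:%.15g)",
                                newick[ai], cl[1], newick[aj], cl[2]))
    active <- c(setdiff(active, c(ai, aj)), k)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  lx <- (d[a, b] + d[a, c3] - d[b, c3]) / 2
  ly <- (d[a, b] + d[b, c3] - d[a, c3]) / 2
  lz <- (d[a, c3] + d[b, c3] - d[a, b]) / 2
  lx <- max(lx, 0); ly <- max(ly, 0); lz <- max(lz, 0)
  str <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 newick[a], lx, newick[b], ly, newick[c3], lz)
  tr <- ape::read.tree(text = str)
  tr$tip.label <- labels[match(tr$tip.label, sub)]
  tr
}

clamp_pair <- function(la, lb) {
  if (la < 0) { lb <- lb + la; la <- 0 }
  if (lb < 0) { la <- max(la + lb, 0); lb <- 0 }
  c(la, lb)
}

#' Threshold clustering of sequences into MOTUs
#'
#' Single-linkage transitive closure: two ids belong to the same molecular
#' operational taxonomic unit whenever a chain of pairwise distances at or
#' below the threshold links them. Cluster labels are deterministic: each
#' cluster is named after its lexicographically smallest member.
#'
#' @param d a [dist_matrix()] of pairwise p-distances
#' @param threshold joining threshold (default 0.03, i.e. 3% divergence)
#' @return named character vector mapping id to cluster label, with
#'   attribute `threshold`; class `motu_partition`
#' @export
motu_cluster <- function(d, threshold = 0.03) {
  if (threshold < 0) stop("threshold must be >= 0")
  d <- as.matrix(d)
  n <- nrow(d)
  ids <- rownames(d)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  lab <- vapply(split(ids, root), min, "")
  out <- stats::setNames(lab[as.character(root)], ids)
  structure(out, threshold = threshold, class = "motu_partition")
}

#' @export
print.motu_partition <- function(x, ...) {
  cat(sprintf("motu_partition: %d ids in %d clusters (threshold %g)\n",
              length(x), length(unique(unclass(x))), attr(x, "threshold")))
  invisible(x)
}
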