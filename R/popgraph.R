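# Population Graphs: conditional genetic covariance network over populations.
# Edges are pruned by edge-exclusion deviance against chi-square(1); what
# remains is the minimal edge set describing the among-population covariance
# structure.

#' Build a Population Graph from dominant marker data
#'
#' Individual 0/1 profiles are centered; population mean vectors are formed
#' and their among-population covariance matrix (loci as observations) is
#' converted to a correlation matrix and inverted to obtain partial
#' correlations. The edge-exclusion deviance for pair (i, j) is
#' \eqn{-N \ln(1 - \rho^2_{ij\cdot rest})}; edges whose deviance exceeds the
#' \eqn{\chi^2_1} critical value at `alpha` are retained. Node size is the
#' mean squared distance of individuals to their population centroid; edge
#' weight is \eqn{-\ln(\rho^2_{ij \cdot rest})}.
#'
#' The multiplier N defaults to the total number of individuals (the
#' convention of the original software); `n_convention = "loci"` instead
#' uses the number of loci, which is the number of observations the
#' correlation matrix is actually estimated from and is the calibrated
#' choice when loci and individuals counts differ markedly.
#'
#' @param x a [marker_matrix()]
#' @param hier a [hierarchy()]
#' @param alpha significance level of the edge-exclusion test
#' @param min_pop_size populations below this size are dropped (warning)
#' @param n_convention "individuals" (default) or "loci"
#' @return list of class `pop_graph`: `graph` (igraph), `nodes`
#'   (data.frame: population, n, within_variance, component), `edges`
#'   (data.frame: from, to, partial_corr, eed, p_value, weight, retained),
#'   `components`, `alpha`, `n_used`
#' @export
build_population_graph <- function(x, hier, alpha = 0.05, min_pop_size = 3,
                                   n_convention = c("individuals", "loci")) {
  n_convention <- match.arg(n_convention)
  stopifnot(inherits(hier, "hierarchy"))
  x <- drop_replicates(x)
  ids <- intersect(rownames(x), names(hier$pop))
  pop <- hier$pop[ids]
  sz <- table(pop)
  small <- names(sz)[sz < min_pop_size]
  if (length(small)) {
    warning("dropping population(s) below the size cut-off: ",
            paste(small, collapse = ", "))
    ids <- ids[!(pop %in% small)]
    pop <- pop[ids]
  }
  pops <- sort(unique(unname(pop)))
  P <- length(pops)
  if (P < 3) stop("need at least 3 populations of sufficient size")
  m <- unclass(x)[ids, , drop = FALSE]
  storage.mode(m) <- "double"
  m[is.na(m)] <- matrix(colMeans(m, na.rm = TRUE),
                        nrow(m), ncol(m), byrow = TRUE)[is.na(m)]
  means <- do.call(rbind, lapply(pops, function(pp) {
    colMeans(m[unname(pop) == pp, , drop = FALSE])
  }))
  rownames(means) <- pops
  # Among-population covariance with loci as observations. cov() removes each
  # population's own mean over loci; the per-locus grand mean must NOT be
  # removed first: that would make the P mean vectors sum to zero locus-wise
  # and the covariance exactly singular.
  C <- stats::cov(t(means))                 # P x P, loci as observations
  R <- stats::cov2cor(C)
  omega <- tryCatch(solve(R), error = function(e) {
    warning("singular among-population correlation matrix; ",
            "using ridge-regularized inverse")
    solve(R + diag(1e-8 * sum(diag(R)), P))
  })
  dmat <- diag(omega)
  pc <- -omega / sqrt(outer(dmat, dmat))
  diag(pc) <- 0
  n_used <- if (n_convention == "individuals") length(ids) else ncol(m)
  eed <- -n_used * log(pmax(1 - pc^2, .Machine$double.eps))
  crit <- stats::qchisq(1 - alpha, df = 1)
  within_var <- vapply(pops, function(pp) {
    sub <- m[unname(pop) == pp, , drop = FALSE]
    ctr <- colMeans(sub)
    mean(rowSums(sweep(sub, 2, ctr)^2))
  }, 0)
  ut <- which(upper.tri(pc), arr.ind = TRUE)
  edges <- data.frame(
    from = pops[ut[, 1]], to = pops[ut[, 2]],
    partial_corr = pc[ut],
    eed = eed[ut],
    p_value = stats::pchisq(eed[ut], df = 1, lower.tail = FALSE),
    weight = -log(pmax(pc[ut]^2, .Machine$double.eps)),
    retained = eed[ut] > crit,
    stringsAsFactors = FALSE)
  kept <- edges[edges$retained, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    kept[, c("from", "to", "weight", "partial_corr", "eed")],
    directed = FALSE,
    vertices = data.frame(name = pops, within_variance = within_var))
  comp <- igraph::components(g)
  structure(list(graph = g,
                 nodes = data.frame(population = pops,
                                    n = as.integer(sz[pops]),
                                    within_variance = within_var,
                                    component = comp$membership[pops],
                                    row.names = NULL),
                 edges = edges,
                 components = comp$no,
                 alpha = alpha, n_used = n_used),
            class = "pop_graph")
}

#' @export
print.pop_graph <- function(x, ...) {
  cat(sprintf("pop_graph: %d nodes, %d edges retained of %d (alpha = %g), %d component(s)\n",
              nrow(x$nodes), sum(x$edges$retained), nrow(x$edges),
              x$alpha, x$components))
  invisible(x)
}
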