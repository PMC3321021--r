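test_that("Nei-Li distance matches the formula and a brute-force oracle", {
  x <- mm(list(c(1, 1, 0, 1), c(1, 0, 0, 1)))
  d <- nei_li_distance(x)
  expect_equal(unname(d[1, 2]), 0.2)  # 1 - 2*2/(3+2)

  ident <- mm(list(c(1, 0, 1), c(1, 0, 1)))
  expect_equal(unname(nei_li_distance(ident)[1, 2]), 0)
  disj <- mm(list(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(unname(nei_li_distance(disj)[1, 2]), 1)

  x2 <- rand_mm(20, 200, seed = 31, miss = 0.05)
  d2 <- nei_li_distance(x2)
  m <- unclass(x2)
  for (pair in list(c(1, 2), c(3, 17), c(9, 20), c(5, 11))) {
    expect_equal(unname(d2[pair[1], pair[2]]),
                 oracle_nei_li(m[pair[1], ], m[pair[2], ]), tolerance = 1e-12)
  }

  # replicate rows are excluded by default
  xr <- marker_matrix(rbind(a = c(1, 0), b = c(0, 1), a_rep1 = c(1, 0)),
                      replicate_of = c(a_rep1 = "a"))
  expect_identical(rownames(nei_li_distance(xr)), c("a", "b"))

  # all-missing overlap is a hard error naming the pair
  xm <- mm(list(c(1, NA), c(NA, 1), c(1, 1)))
  expect_error(nei_li_distance(xm), "'s1' and 's2'")
})

test_that("p-distance handles gaps/ambiguities and matches a site loop", {
  ss <- sequence_set(c(a = "ACGT", b = "ACGA"))
  expect_equal(unname(p_distance(ss)["a", "b"]), 0.25)
  ss2 <- sequence_set(c(a = "AC-T", b = "ACGT"))
  expect_equal(unname(p_distance(ss2)["a", "b"]), 0)

  set.seed(5)
  rand_seq <- function() paste(sample(c("A", "C", "G", "T", "-", "N"), 60,
                                      replace = TRUE,
                                      prob = c(rep(0.23, 4), 0.05, 0.03)),
                               collapse = "")
  seqs <- setNames(replicate(10, rand_seq()), paste0("q", 1:10))
  d <- p_distance(sequence_set(seqs))
  for (i in 1:9) {
    expect_equal(unname(d[i, i + 1]), oracle_p_dist(seqs[i], seqs[i + 1]))
  }
  expect_error(p_distance(sequence_set(c(a = "----", b = "AAAA"))),
               "no comparable site")
})

test_that("neighbor joining is exact on 3 taxa and a hand-built 4-taxon tree", {
  # 3 taxa: closed-form star lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- neighbor_joining(d3)
  pl <- ape::cophenetic.phylo(tr3)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(pl, d3, tolerance = 1e-12, ignore_attr = TRUE)

  # additive 4-taxon case (AB | CD): external 1,2,3,4; internal 5
  tr <- ape::read.tree(text = "((A:1,B:2):5,(C:3,D:4):0);")
  d4 <- ape::cophenetic.phylo(tr)
  nj4 <- neighbor_joining(d4)
  expect_equal(as.numeric(ape::dist.topo(nj4, ape::unroot(tr))), 0)
  expect_equal(ape::cophenetic.phylo(nj4)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(neighbor_joining(matrix(c(0, 1, 1, 0), 2, 2)), "at least 3")
  dd <- d3; dd[1, 2] <- dd[2, 1] <- Inf
  expect_error(neighbor_joining(dd), "non-finite")
})

test_that("neighbor joining reconstructs random additive matrices exactly", {
  for (s in 1:25) {
    n <- sample(4:12, 1)
    cs <- random_additive_case(n, seed = 9000 + s)
    nj <- neighbor_joining(cs$d)
    expect_equal(as.numeric(ape::dist.topo(nj, ape::unroot(cs$tree))), 0)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(cs$d), colnames(cs$d)],
                 cs$d, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("locus bootstrap gives full support for a clean two-block split", {
  set.seed(12)
  block <- rbind(matrix(rep(c(1L, 0L), c(30, 30)), 4, 60, byrow = TRUE),
                 matrix(rep(c(0L, 1L), c(30, 30)), 4, 60, byrow = TRUE))
  rownames(block) <- c(paste0("x", 1:4), paste0("y", 1:4))
  colnames(block) <- paste0("L", 1:60)
  # small within-block noise so distances are non-degenerate
  noise <- matrix(rbinom(length(block), 1, 0.03), nrow(block))
  m <- (block + noise) %% 2L
  dimnames(m) <- dimnames(block)
  x <- marker_matrix(m)
  tr <- neighbor_joining(nei_li_distance(x),
                         bootstrap = list(markers = x, n_reps = 80, seed = 2))
  supp <- suppressWarnings(as.numeric(tr$node.label))
  # the x|y bipartition must appear with 100% support
  expect_true(any(supp == 100, na.rm = TRUE))
})

test_that("MOTU clustering is single-linkage, deterministic and monotone", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.02
  d["B", "C"] <- d["C", "B"] <- 0.02
  d["A", "C"] <- d["C", "A"] <- 0.05
  part <- motu_cluster(dist_matrix(d, "p_distance"), threshold = 0.03)
  expect_identical(length(unique(unclass(part))), 1L)
  expect_identical(as.vector(unclass(part)), rep("A", 3))  # smallest member id

  # threshold 0 on distinct sequences: all singletons
  ss <- simulate_sequences(1, 5, 300, within_div = 0.05, between_div = 0.5,
                           seed = 3)
  dd <- p_distance(ss)
  expect_identical(length(unique(unclass(motu_cluster(dd, 0)))), 5L)

  # permutation invariance and monotone non-increasing cluster count
  ss4 <- simulate_sequences(4, 5, 400, within_div = 0.005, between_div = 0.1,
                            seed = 4)
  d4 <- p_distance(ss4)
  part4 <- motu_cluster(d4, 0.03)
  perm <- sample(nrow(d4))
  d4p <- dist_matrix(as.matrix(d4)[perm, perm], "p_distance")
  part4p <- motu_cluster(d4p, 0.03)
  expect_equal(unclass(part4p)[names(part4)], unclass(part4),
               ignore_attr = TRUE)
  counts <- vapply(c(0, 0.005, 0.01, 0.03, 0.1, 0.5), function(th) {
    length(unique(unclass(motu_cluster(d4, th))))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_error(motu_cluster(d4, -0.1), "threshold")
})
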