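unit_square <- function() {
  matrix(c(-0.5, 0.5, 0.5, -0.5, -0.5, -0.5, 0.5, 0.5), 4, 2)
}

rigid_copy <- function(cfg, ang, sc, tr) {
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  sweep(sc * cfg %*% R, 2, tr, `+`)
}

test_that("centroid size of the unit square is sqrt(2)", {
  expect_equal(radiascan:::centroid_size(unit_square()), sqrt(2))
})

test_that("GPA removes translation, rotation and scale", {
  set.seed(91)
  base <- unit_square() + matrix(rnorm(8, 0, 0.05), 4, 2)
  copies <- array(NA_real_, c(4, 2, 3))
  copies[, , 1] <- base
  copies[, , 2] <- rigid_copy(base, 0.7, 2.5, c(3, -1))
  copies[, , 3] <- rigid_copy(base, -2.1, 0.3, c(-5, 2))
  ss <- gpa(copies)
  for (i in 2:3) {
    expect_lt(sqrt(sum((ss$aligned[, , i] - ss$aligned[, , 1])^2)), 1e-8)
  }
  # centroid sizes are reported in original units
  expect_equal(unname(ss$csize[2] / ss$csize[1]), 2.5, tolerance = 1e-9)
  # consensus is centered with unit centroid size
  expect_lt(max(abs(colMeans(ss$consensus))), 1e-9)
  expect_equal(sum(ss$consensus^2), 1, tolerance = 1e-9)

  degenerate <- array(0, c(4, 2, 2))
  expect_error(gpa(degenerate), "degenerate")
})

test_that("alignment is independent of specimen order", {
  lm <- simulate_landmarks(2, per_group = 8, shape_offset = 0.2,
                           noise_sd = 0.03, seed = 92)
  ss <- gpa(lm$coords)
  n <- dim(lm$coords)[3]
  flat <- radiascan:::flatten_shapes(ss)
  d1 <- as.matrix(dist(flat))
  perm <- sample(n)
  ssp <- gpa(lm$coords[, , perm])
  d2 <- as.matrix(dist(radiascan:::flatten_shapes(ssp)))
  expect_equal(d2, d1[perm, perm], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("shape PCA has the right rank and preserves distances", {
  # 2 distinct shapes: exactly one nonzero component
  lm2 <- simulate_landmarks(2, per_group = 1, shape_offset = 0.3,
                            noise_sd = 0, nuisance = TRUE, seed = 93)
  ss2 <- gpa(lm2$coords)
  pc2 <- shape_pca(ss2)
  expect_identical(ncol(pc2$scores), 1L)

  # identical shapes: error
  same <- array(rep(unit_square(), 3), c(4, 2, 3))
  expect_error(shape_pca(gpa(same)), "no shape variation")

  # scores reproduce pairwise distances of aligned shapes
  lm <- simulate_landmarks(3, per_group = 6, shape_offset = 0.2,
                           noise_sd = 0.03, seed = 94)
  ss <- gpa(lm$coords)
  pc <- shape_pca(ss)
  expect_equal(sum(pc$var_frac), 1, tolerance = 1e-9)
  d_scores <- as.matrix(dist(pc$scores))
  d_shapes <- as.matrix(dist(radiascan:::flatten_shapes(ss)))
  expect_equal(d_scores, d_shapes, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("CVA assignment separates distinct groups and degrades to chance", {
  lm <- simulate_landmarks(2, per_group = 15, shape_offset = 0.25,
                           noise_sd = 0.02, seed = 95)
  ss <- gpa(lm$coords)
  cva <- cva_assign(ss, lm$group)
  expect_gte(cva$overall_success, 95)

  # shuffled labels: near-chance success on average
  set.seed(96)
  succ <- vapply(1:15, function(i) {
    cva_assign(ss, sample(as.character(lm$group)))$overall_success
  }, 0)
  expect_lt(abs(mean(succ) - 50), 12)

  # both groups contain the same shapes: every specimen is exactly
  # equidistant from the two group means, hence ambiguous and not significant
  cfg <- unit_square()
  set.seed(97)
  trio <- lapply(1:3, function(i) cfg + matrix(rnorm(8, 0, 0.05), 4, 2))
  coords <- array(unlist(c(trio, trio)), c(4, 2, 6))
  ssd <- gpa(coords)
  res <- cva_assign(ssd, rep(c("A", "B"), each = 3), mode = "resubstitution")
  expect_true(all(res$table$ambiguous))
  expect_true(all(!res$table$significant))

  small <- cva_assign(ss, c(rep("A", 15), rep("B", 13), "C", "C"),
                      min_group_size = 3) |> suppressWarnings()
  expect_false("C" %in% small$table$true_group)
})

test_that("Goodall's F matches its degrees of freedom and null behavior", {
  # k = 10 landmarks, n = 10 + 10: df = (16, 288)
  lm <- simulate_landmarks(2, per_group = 10, n_landmarks = 10,
                           shape_offset = 0, noise_sd = 0.02, seed = 98)
  ss <- gpa(lm$coords)
  f <- goodall_f(ss, lm$group, "G1", "G2", n_perm = 99, seed = 1)
  expect_identical(f$df1, 16)
  expect_identical(f$df2, 288)
  expect_gt(f$p_perm, 0.01)  # no true difference

  # symmetry in group order
  f2 <- goodall_f(ss, lm$group, "G2", "G1", n_perm = 0)
  expect_equal(f2$F, f$F, tolerance = 1e-9)

  # identical groups: F = 0
  cfg <- unit_square()
  coords <- array(rep(cfg, 4), c(4, 2, 4))
  sid <- gpa(coords)
  f0 <- goodall_f(sid, c("A", "A", "B", "B"), "A", "B", n_perm = 0)
  expect_equal(f0$F, 0, tolerance = 1e-12)

  # null calibration: parametric p roughly uniform (small-scale check)
  ps <- vapply(1:25, function(s) {
    lmn <- simulate_landmarks(2, per_group = 8, n_landmarks = 6,
                              shape_offset = 0, noise_sd = 0.02,
                              seed = 1000 + s)
    ssn <- gpa(lmn$coords)
    goodall_f(ssn, lmn$group, "G1", "G2", n_perm = 0)$p_param
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the TPS reader parses LM blocks and IDs", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0.0 0.0", "1.0 0.0", "0.5 1.0", "ID=spec_a",
               "LM=3", "0.1 0.0", "1.1 0.0", "0.6 1.0", "ID=spec_b"), f)
  arr <- read_tps(f)
  expect_identical(dim(arr), c(3L, 2L, 2L))
  expect_identical(dimnames(arr)[[3]], c("spec_a", "spec_b"))
  expect_equal(arr[3, , "spec_b"], c(x = 0.6, y = 1.0))

  bad <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "0 0", "1 0", "x y", "ID=a"), bad)
  expect_error(suppressWarnings(read_tps(bad)), "malformed")
})
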