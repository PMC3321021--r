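test_that("score_profiles applies relative floor, detection threshold and bins", {
  # noise floor 1% x 500 = 5, so the 40-unit peak is retained (and forms a
  # bin) but stays below the 50-unit detection threshold: scored absent
  peaks <- data.frame(
    sample = c("s1", "s1", "s1", "s2", "s2"),
    size_b = c(100, 200, 300, 100, 200),
    height = c(10000, 500, 40, 9000, 500))
  x <- score_profiles(peaks)
  m <- unclass(x)
  expect_identical(ncol(x), 3L)
  expect_identical(unname(m["s1", ]), c(1L, 1L, 0L))
  expect_identical(unname(m["s2", ]), c(1L, 1L, 0L))

  # boundary: noise floor is >= — a peak at exactly 1% of the second-largest
  # peak is retained, and height exactly 50 is detected
  peaks2 <- data.frame(sample = "s1", size_b = c(100, 200, 300),
                       height = c(10000, 5000, 50))
  expect_identical(unname(unclass(score_profiles(peaks2))["s1", ]),
                   c(1L, 1L, 1L))

  # peaks outside [60, 550] silently excluded
  peaks3 <- data.frame(sample = "s1", size_b = c(55, 100, 200, 560),
                       height = c(8000, 8000, 5000, 9000))
  expect_identical(ncol(score_profiles(peaks3)), 2L)

  # < 2 peaks: all-absent with warning
  peaks4 <- rbind(peaks, data.frame(sample = "s3", size_b = 100, height = 5000))
  expect_warning(x4 <- score_profiles(peaks4), "fewer than 2 peaks")
  expect_true(all(unclass(x4)["s3", ] == 0L))
})

test_that("binning respects the maximum width cap", {
  # sizes 100, 100.5, 101.0: greedy left-to-right with cap 0.75 splits after
  # 100.5
  peaks <- data.frame(sample = rep(c("a", "b"), each = 2),
                      size_b = c(100, 200, 100.5, 101.0),
                      height = rep(5000, 4))
  x <- score_profiles(peaks)
  expect_identical(ncol(x), 3L)  # {100, 100.5}, {101.0}, {200}
})

test_that("repeatability counts concordant evaluable pairs and classifies evidence", {
  calls <- rbind(
    a      = c(1, 0, 1, NA),
    b      = c(1, 1, 0, 0),
    a_rep1 = c(1, 0, 0, 1),
    b_rep1 = c(0, 1, 0, NA))
  colnames(calls) <- paste0("L", 1:4)
  x <- marker_matrix(calls, replicate_of = c(a_rep1 = "a", b_rep1 = "b"))
  rep <- assess_repeatability(x)$per_marker
  expect_equal(rep$repeatability, c(0.5, 1, 0.5, NA))
  expect_equal(rep$n_pairs, c(2L, 2L, 2L, 0L))
  expect_equal(rep$confirmed_present, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rep$null_only, c(FALSE, FALSE, FALSE, FALSE))

  # all-absent pairs are concordant and flag null-only
  y <- marker_matrix(rbind(a = c(0, 1), a_rep1 = c(0, 1)),
                     replicate_of = c(a_rep1 = "a"))
  rep2 <- assess_repeatability(y)$per_marker
  expect_equal(rep2$repeatability, c(1, 1))
  expect_equal(rep2$null_only, c(TRUE, FALSE))
})

test_that("select_markers applies the four rules in order with a conserving ledger", {
  # 10 replicate pairs per construction below
  set.seed(2)
  n_pairs <- 10
  build <- function(orig, rep) {
    calls <- rbind(orig, rep)
    rownames(calls) <- c(sprintf("s%02d", 1:n_pairs),
                         sprintf("s%02d_rep1", 1:n_pairs))
    calls
  }
  # locus 1: repeatability 0.8 -> rule 1; locus 2: repeatable, confirmed,
  # but monomorphic (all 1) -> rule 4; locus 3: all absent -> rule 2
  # (null-only); locus 4: one (1,0) pair, repeatability 0.9, no confirmed
  # present/present pair -> rule 3; locus 5: monomorphic constant 1 ->
  # rule 4; locus 6: clean polymorphic, kept
  orig <- cbind(rep(1, 10), rep(1, 10), rep(0, 10),
                c(rep(0, 9), 1), rep(1, 10),
                c(rep(1, 5), rep(0, 5)))
  repl <- cbind(c(rep(1, 8), 0, 0), c(rep(1, 9), 1), rep(0, 10),
                rep(0, 10), rep(1, 10),
                c(rep(1, 5), rep(0, 5)))
  calls <- build(orig, repl)
  colnames(calls) <- paste0("L", 1:6)
  x <- marker_matrix(calls, replicate_of = setNames(
    sprintf("s%02d", 1:n_pairs), sprintf("s%02d_rep1", 1:n_pairs)))
  res <- select_markers(x)
  led <- res$report$dropped
  expect_identical(sum(led$n) + length(res$report$retained), ncol(x))
  expect_identical(res$report$retained, "L6")
  expect_identical(led$n[led$rule == "low_repeatability"], 1L)    # L1
  expect_identical(led$n[led$rule == "null_allele_only"], 1L)     # L3
  expect_identical(led$n[led$rule == "no_confirmed_present"], 1L) # L4
  expect_identical(led$n[led$rule == "monomorphic"], 2L)          # L2, L5

  # exact threshold boundary: repeatability 0.81 survives rule 1 ("less than
  # 81% ... excluded"); 81 of 100 pairs concordant, polymorphic, confirmed
  m81 <- cbind(L1 = c(rep(1, 60), rep(0, 40),          # originals
                      rep(1, 41), rep(0, 19), rep(0, 40)))  # replicates
  rownames(m81) <- c(sprintf("t%03d", 1:100), sprintf("t%03d_rep1", 1:100))
  x81 <- marker_matrix(m81, replicate_of = setNames(
    sprintf("t%03d", 1:100), sprintf("t%03d_rep1", 1:100)))
  rep81 <- assess_repeatability(x81)$per_marker
  expect_equal(rep81$repeatability, 0.81)
  res81 <- select_markers(x81)
  expect_true("L1" %in% res81$report$retained)

  # idempotence on its own output
  res2 <- select_markers(res$markers)
  expect_identical(res2$report$retained, res$report$retained)

  expect_error(select_markers(marker_matrix(
    rbind(a = c(1, 1), a_rep1 = c(0, 0)),
    replicate_of = c(a_rep1 = "a"))), "all loci removed")
})

test_that("genotyping error rate matches hand counts and the analytic rate", {
  x <- marker_matrix(rbind(a = c(1, 0, 1), b = c(1, 1, 0),
                           a_rep1 = c(1, 0, 0), b_rep1 = c(1, 0, 0)),
                     replicate_of = c(a_rep1 = "a", b_rep1 = "b"))
  # per-marker mismatch rates: 0/2, 1/2, 1/2 -> mean 33.33%
  expect_equal(genotyping_error_rate(x), 100 / 3, tolerance = 1e-12)
  expect_equal(genotyping_error_rate(x, method = "pooled"), 100 * 2 / 6,
               tolerance = 1e-12)

  perfect <- marker_matrix(rbind(a = c(1, 0), a_rep1 = c(1, 0)),
                           replicate_of = c(a_rep1 = "a"))
  expect_equal(genotyping_error_rate(perfect), 0)

  # order invariance
  x_shuf <- marker_matrix(unclass(x)[c(3, 1, 4, 2), ],
                          replicate_of = attr(x, "replicate_of"))
  expect_equal(genotyping_error_rate(x_shuf), genotyping_error_rate(x))

  expect_error(genotyping_error_rate(mm(list(c(1, 0)))), "no replicate pairs")
})

test_that("error-rate estimator is unbiased for the analytic discordance", {
  # e01 = e10 = e: every call disagrees with prob 2e(1-e) regardless of the
  # truth state; estimator averages per-marker rates
  dev <- vapply(1:12, function(s) {
    set.seed(800 + s)
    truth <- mm(asplit(matrix(rbinom(100 * 50, 1, 0.3), 100, 50), 1))
    noisy <- corrupt_and_replicate(truth, 0.04, 0.04, replicate_fraction = 1,
                                   seed = s)
    genotyping_error_rate(noisy) / 100 - 2 * 0.04 * 0.96
  }, 0)
  se <- sd(dev) / sqrt(length(dev))
  expect_lt(abs(mean(dev)), 2 * se + 0.002)
})
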