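test_that("empirical coverage and discovery reproduce the printed library table", {
  tab <- tilapia_library_counts()
  cov <- round(coverage_empirical(tab$hq_ests, tab$total), 4)
  disc <- round(discovery_rate(tab$hq_ests, tab$total), 3)

  # all 19 printed coverage values reproduce exactly at 4 decimals
  expect_equal(cov, tab$coverage_printed)

  # 18 of the 19 printed discovery values reproduce exactly at 3 decimals;
  # the Re4 row as printed is internally inconsistent (see below)
  consistent <- tab$library != "Re4"
  expect_equal(disc[consistent], tab$discovery_printed[consistent])

  # the printed Re4 discovery (1.309) contradicts the same row's printed
  # coverage 0.3390, which implies 1/(1-0.3390) = 1.513 = 11,298/7,468;
  # our value is the one consistent with the identity
  re4 <- which(tab$library == "Re4")
  expect_false(disc[re4] == tab$discovery_printed[re4])
  expect_equal(disc[re4], round(1 / (1 - tab$coverage_printed[re4]), 3))
})

test_that("coverage estimators satisfy their definitions and identities", {
  expect_equal(round(coverage_empirical(10051, 8180), 4), 0.1862)
  expect_equal(round(coverage_empirical(5032, 3451), 4), 0.3142)
  expect_equal(coverage_empirical(100, 100), 0)
  expect_error(coverage_empirical(10, 11), "n >= d")

  expect_equal(coverage_good_turing(50, 0), 1.0)
  expect_equal(coverage_good_turing(100, 100), 0.0)
  expect_equal(round(coverage_good_turing(10051, 6935), 4), 0.3100)
  expect_error(coverage_good_turing(10, 11), "n1")

  expect_equal(round(discovery_rate(116899, 56218), 3), 2.079)
  expect_equal(round(discovery_rate(2650, 1280), 3), 2.070)
  expect_equal(discovery_rate(7, 7), 1.0)
  expect_error(discovery_rate(5, 0), "d must be")

  # discovery == 1/(1 - coverage) to 1e-9 across random valid (n, d);
  # and coverage is scale-invariant
  set.seed(12)
  for (i in 1:200) {
    n <- sample(10:100000, 1)
    d <- sample(1:n, 1)
    expect_equal(discovery_rate(n, d),
                 1 / (1 - coverage_empirical(n, d)), tolerance = 1e-9)
    expect_identical(coverage_empirical(n, d),
                     coverage_empirical(10 * n, 10 * d))
  }
})

test_that("library reports round for display and keep full precision", {
  summ <- data.frame(library = c("L1", "L2"),
                     n = c(10051, 7), d = c(8180, 7),
                     n1 = c(6935, 7), contigs = c(1245, 0))
  rep <- library_report(summ)
  expect_equal(rep$coverage, c(0.1862, 0))
  expect_equal(rep$discovery, c(1.229, 1))
  expect_equal(rep$discovery_full[1], 10051 / 8180, tolerance = 1e-12)
  # permuting rows permutes the report only
  rep2 <- library_report(summ[2:1, ])
  expect_equal(rep2$library, c("L2", "L1"))
  expect_equal(rep2$coverage, rev(rep$coverage))
  # the Good-Turing variant uses singleton counts
  gt <- library_report(summ, estimator = "good_turing")
  expect_equal(gt$coverage[1], round(1 - 6935 / 10051, 4))
})

test_that("discovery curves accumulate rounds in order", {
  one <- data.frame(read_id = paste0("r", 1:6),
                    cluster_id = c("a", "a", "b", "c", "d", "d"),
                    round_id = rep("1", 6))
  dc <- discovery_curve(one)
  expect_equal(nrow(dc), 1)
  expect_equal(dc$discovery, discovery_rate(6, 4))

  # a second round duplicating round 1's genes doubles the discovery rate
  two <- rbind(one, transform(one, read_id = paste0("s", 1:6),
                              round_id = "2"))
  dc2 <- discovery_curve(two)
  expect_equal(dc2$discovery[2], 2 * dc2$discovery[1])
  expect_true(all(diff(dc2$cumulative_reads) > 0))

  untagged <- one; untagged$round_id <- NULL
  expect_error(discovery_curve(untagged), "round_id")
})

test_that("simulated discovery curves are nondecreasing in expectation", {
  p <- sample_abundances(60, 0, 1.5, seed = 44)
  n_rounds <- 4; per_round <- 50
  curves <- sapply(1:50, function(s) {
    set.seed(s + 900)
    genes <- sample.int(60, n_rounds * per_round, replace = TRUE, prob = p)
    asg <- data.frame(read_id = sprintf("r%03d", seq_along(genes)),
                      cluster_id = genes,
                      round_id = rep(1:n_rounds, each = per_round))
    discovery_curve(asg)$discovery
  })
  expect_true(all(diff(rowMeans(curves)) > 0))
})

test_that("fold reduction reproduces colony-filter arithmetic", {
  expect_equal(fold_reduction(360, 9000, 9, 9000), 40.0)
  expect_equal(fold_reduction(12, 100, 12, 100), 1.0)
  expect_equal(fold_reduction(100, 1000, 50, 2000), 4.0)
  expect_warning(f <- fold_reduction(10, 100, 0, 100), "infinite")
  expect_identical(f, Inf)
})

test_that("Good-Turing coverage is nearly unbiased for true resampling mass", {
  p <- sample_abundances(2000, 0, 1.5, seed = 77)
  n <- 5000
  bias <- vapply(1:100, function(s) {
    set.seed(s + 4000)
    genes <- sample.int(length(p), n, replace = TRUE, prob = p)
    counts <- tabulate(genes, nbins = length(p))
    est <- coverage_good_turing(n, sum(counts == 1))
    truth <- sum(p[counts > 0])   # P(next read hits a seen gene)
    est - truth
  }, numeric(1))
  expect_lt(abs(mean(bias)), 0.01)
})
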