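test_that("abundance sampling is a valid, seed-stable, skewable profile", {
  expect_equal(sample_abundances(1, 0, 2, seed = 7), 1)
  expect_equal(sample_abundances(1000, 0, 0, seed = 3), rep(1 / 1000, 1000))
  expect_error(sample_abundances(0, 0, 1, seed = 1), "n_genes")

  expect_identical(sample_abundances(500, 0, 2, seed = 11),
                   sample_abundances(500, 0, 2, seed = 11))

  # high log-sd produces the dominance structure of non-normalized libraries
  skewed <- vapply(1:20, function(s) {
    p <- sample_abundances(1000, 0, 2, seed = s)
    max(p) > 100 * stats::median(p)
  }, logical(1))
  expect_true(mean(skewed) > 0.9)
})

test_that("DSN normalization conserves mass, order, spread and entropy", {
  p <- c(0.9, 0.1)
  expect_equal(dsn_normalize(p, 0), p)
  expect_error(dsn_normalize(p, -1), "theta")

  # theta -> infinity flattens shares toward equality
  q <- dsn_normalize(p, 1e6)
  expect_equal(q[1] / q[2], 1, tolerance = 0.01)

  entropy <- function(x) -sum(x * log(x))
  for (s in 1:25) {
    pr <- sample_abundances(200, 0, stats::runif(1, 0.5, 2.5), seed = s)
    th <- stats::runif(1, 0, 500)
    qr <- dsn_normalize(pr, th)
    expect_equal(sum(qr), 1, tolerance = 1e-12)
    expect_identical(order(qr), order(pr))
    expect_lte(max(qr) / min(qr), max(pr) / min(pr) * (1 + 1e-12))
    expect_gte(entropy(qr), entropy(pr) - 1e-12)
  }
})

test_that("theta calibration round-trips the requested fold-reduction", {
  expect_equal(calibrate_theta(c(0.5, 0.5), 1, 1), 0)

  # closed-form check on an asymmetric two-gene profile:
  # share_after(theta) = q1/(q1+q2), q_i = p_i/(1 + theta p_i)
  p2 <- c(0.8, 0.2)
  th <- calibrate_theta(p2, 1, 1.5)
  q <- p2 / (1 + th * p2)
  expect_equal(p2[1] / (q[1] / sum(q)), 1.5, tolerance = 1e-3)

  # a symmetric profile cannot change shares: fold > 1 is unreachable
  expect_error(calibrate_theta(c(0.5, 0.5), 1, 2), "unreachable")

  # folds across [1, 100] on a skewed profile round-trip within 0.1%
  p <- sample_abundances(2000, 0, 3, seed = 9)
  g <- which.max(p)
  expect_gt(p[g] * length(p), 100)  # flattening limit admits fold 100
  for (fold in c(1.5, 2, 5, 20, 40, 100)) {
    th <- calibrate_theta(p, g, fold)
    achieved <- p[g] / dsn_normalize(p, th)[g]
    expect_equal(achieved, fold, tolerance = 1e-3)
  }
})

test_that("a calibrated DSN model reduces a dominant transcript 40-fold", {
  # profile with a gene at the pre-normalization share seen on colony
  # filters (360 positives of ~9,000 clones)
  p <- sample_abundances(3000, 0, 2, seed = 21)
  g <- which.max(p)
  target_share <- 360 / 9000
  p <- p * (1 - target_share) / (1 - p[g])
  p[g] <- target_share
  th <- calibrate_theta(p, g, 40)
  post <- dsn_normalize(p, th)[g]
  expect_equal(p[g] / post, 40, tolerance = 1e-3)
  expect_equal(post, 9 / 9000, tolerance = 1e-3)
})

test_that("expected distinct-gene count has its closed-form values", {
  p10 <- rep(0.1, 10)
  expect_equal(expected_distinct(p10, 0), 0)
  expect_equal(expected_distinct(rep(0.5, 2), 1), 1)
  expect_equal(expected_distinct(p10, 10), 10 * (1 - 0.9^10))
  expect_equal(expected_distinct(p10, 10), 6.5132, tolerance = 1e-4)
  # monotone nondecreasing in read count
  vals <- vapply(c(0, 1, 5, 20, 100, 1000), function(n)
    expected_distinct(p10, n), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("simulated read sets match the sampling model", {
  tx1 <- make_transcriptome(n_genes = 1, seed = 4)
  one <- simulate_reads(tx1, read_model(), n_reads = 1, seed = 4)
  expect_equal(nrow(one$reads), 1)
  expect_equal(one$truth$gene_id, 1)
  expect_error(simulate_reads(structure(list(n_genes = 0),
                                        class = "transcriptome"),
                              read_model(), 1), "transcriptome")

  # per-gene counts within 4 sigma of the binomial expectation
  tx <- make_transcriptome(n_genes = 50, mean_len = 400, sd_len = 30,
                           seed = 5)
  rm <- read_model(mean_len = 120, sd_len = 20, min_len = 60, max_len = 200)
  n <- 2000
  sim <- simulate_reads(tx, rm, n_reads = n, seed = 6,
                        p = rep(1 / 50, 50))
  counts <- tabulate(sim$truth$gene_id, nbins = 50)
  sigma <- sqrt(n * (1 / 50) * (49 / 50))
  expect_true(all(abs(counts - n / 50) <= 4 * sigma))

  # determinism: same seed, same config => identical output
  sim2 <- simulate_reads(tx, rm, n_reads = 50, seed = 17)
  sim3 <- simulate_reads(tx, rm, n_reads = 50, seed = 17)
  expect_identical(sim2, sim3)

  # qualities within contract and haplotypes carry the planted alleles
  q <- unlist(sim2$reads$quals)
  expect_true(all(q >= 0 & q <= 60))
})

test_that("empirical distinct-gene counts track the expectation", {
  tx <- make_transcriptome(n_genes = 40, mean_len = 350, sd_len = 20,
                           seed = 8)
  rm <- read_model(mean_len = 100, sd_len = 10, min_len = 60, max_len = 150)
  n_reads <- 200
  d <- vapply(1:50, function(s)
    length(unique(simulate_reads(tx, rm, n_reads, seed = s)$truth$gene_id)),
    numeric(1))
  expected <- expected_distinct(tx$abundances, n_reads)
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - expected), 3 * se + 1e-9)
})

test_that("transcriptome invariants: haplotypes differ only at planted SNPs", {
  tx <- make_transcriptome(n_genes = 25, seed = 13)
  expect_equal(sum(tx$abundances), 1, tolerance = 1e-9)
  expect_true(all(tx$abundances > 0))
  for (g in seq_len(tx$n_genes)) {
    a <- strsplit(tx$sequences[[g]][["a"]], "")[[1]]
    b <- strsplit(tx$sequences[[g]][["b"]], "")[[1]]
    diffs <- which(a != b) - 1L  # 0-based
    planted <- tx$planted_snps$offset[tx$planted_snps$gene == g]
    expect_setequal(diffs, planted)
  }
  # planted SSR tracts are exact tandem repeats at their coordinates
  for (i in seq_len(nrow(tx$planted_ssrs))) {
    r <- tx$planted_ssrs[i, ]
    s <- substr(tx$sequences[[r$gene]][["a"]], r$offset + 1,
                r$offset + r$length)
    expect_equal(s, substr(strrep(r$motif, 40), 1, r$length))
  }
})
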