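test_that("variant columns are called with gaps and N excluded", {
  aln <- c("ACGT", "ACGT", "ATGT", "ATGT")
  v <- call_variant_columns(aln, "c1")
  expect_equal(nrow(v), 1)
  expect_equal(v$column, 1)             # 0-based
  expect_equal(v$n_C, 2)
  expect_equal(v$n_T, 2)
  expect_true(v$passes_filter)
  expect_equal(v$class, "transition")

  # gaps and N never count as alleles: a column of {A, A, -, N} is invariant
  expect_equal(nrow(call_variant_columns(c("A", "A", "-", "N"))), 0)
  # but {A, -, N, G} still has two observed bases
  v2 <- call_variant_columns(c("A", "-", "N", "G"), min_count = 1)
  expect_equal(nrow(v2), 1)
  expect_true(v2$passes_filter)

  # majority base is the reference; ties break alphabetically
  v3 <- call_variant_columns(c("G", "G", "G", "T"), min_count = 1)
  expect_equal(v3$ref_allele, "G")
  expect_equal(v3$alt_allele, "T")
  v4 <- call_variant_columns(c("T", "T", "C", "C"), min_count = 1)
  expect_equal(v4$ref_allele, "C")

  expect_error(call_variant_columns(c("ACGT", "ACG")), "ragged")
  expect_error(call_variant_columns(c("ACXT", "ACGT")), "invalid")
})

test_that("called columns and counts match a per-column recount oracle", {
  set.seed(61)
  for (i in 1:300) {
    aln <- random_alignment(nrow = sample(3:12, 1), ncol = sample(5:60, 1))
    got <- call_variant_columns(aln, "c")
    want <- oracle_variant_columns(aln)
    expect_equal(got$column, want$column)
    expect_equal(got$n_A, want$n_A)
    expect_equal(got$n_C, want$n_C)
    expect_equal(got$n_G, want$n_G)
    expect_equal(got$n_T, want$n_T)
    # independently recheck the filter verdict on every candidate
    if (nrow(got) > 0) {
      cc <- as.matrix(want[, c("n_A", "n_C", "n_G", "n_T")])
      expect_identical(got$passes_filter, unname(rowSums(cc >= 2) >= 2))
    }
  }
})

test_that("the minimum-count filter is monotone and self-consistent", {
  set.seed(62)
  for (i in 1:30) {
    aln <- random_alignment(10, 50)
    cand <- call_variant_columns(aln, "c", min_count = 1)
    n_prev <- nrow(cand)
    for (mc in 1:5) {
      kept <- apply_min_count_filter(cand, min_count = mc)
      expect_lte(nrow(kept), n_prev)
      n_prev <- nrow(kept)
      if (nrow(kept) > 0) expect_true(all(kept$passes_filter))
    }
    # filtering candidates equals calling with the threshold built in
    cand2 <- call_variant_columns(aln, "c", min_count = 2)
    expect_equal(apply_min_count_filter(cand, 2)$column,
                 cand2$column[cand2$passes_filter])
  }
})

test_that("three well-supported alleles make a column multiallelic", {
  aln <- c("A", "A", "G", "G", "T", "T")
  v <- call_variant_columns(aln)
  expect_equal(v$class, "multiallelic")
  expect_true(v$passes_filter)
  s <- tstv_summary(apply_min_count_filter(v))
  expect_equal(s$n_multiallelic, 1)
  expect_equal(s$n_transition + s$n_transversion, 0)
  expect_true(is.na(s$fraction_transition))
  # a weakly supported third allele does not: {A:3, G:3, T:1} is biallelic
  v2 <- call_variant_columns(c("A", "A", "A", "G", "G", "G", "T"))
  expect_equal(v2$class, "transition")
})

test_that("substitutions classify by purine/pyrimidine identity", {
  pur <- c("A", "G"); pyr <- c("C", "T")
  for (a in c(pur, pyr)) for (b in c(pur, pyr)) {
    if (a == b) next
    want <- if ((a %in% pur) == (b %in% pur)) "transition" else "transversion"
    expect_identical(classify_substitution(a, b), want)
    expect_identical(classify_substitution(b, a),
                     classify_substitution(a, b))
  }
  expect_error(classify_substitution("A", "A"), "distinct")
  expect_error(classify_substitution("A", "X"), "A,C,G,T")
})

test_that("transition fractions reproduce survey-scale arithmetic", {
  # 1,329 transitions and 1,213 transversions give a 52% transition share
  expect_equal(round(100 * 1329 / (1329 + 1213)), 52)
  cand <- data.frame(class = c(rep("transition", 13),
                               rep("transversion", 12),
                               rep("multiallelic", 2)))
  s <- tstv_summary(cand)
  expect_equal(s$n_transition, 13)
  expect_equal(s$n_transversion, 12)
  expect_equal(s$n_multiallelic, 2)
  expect_equal(s$fraction_transition, 13 / 25)
  empty <- tstv_summary(data.frame(class = character(0)))
  expect_true(is.na(empty$fraction_transition))
})

test_that("filtered calls on simulated surveys recover exactly the planted
           sites with two reads per haplotype", {
  ok_fp <- TRUE; predicted_match <- TRUE; class_ok <- TRUE
  for (s in 1:8) {
    tx <- make_transcriptome(n_genes = 10, mean_len = 500, sd_len = 40,
                             snp_rate = 1, hap_b_freq = 0.5, seed = s)
    # error-free reads so every filtered call must be a planted allele
    rm <- read_model(mean_len = 350, sd_len = 60, min_len = 150,
                     max_len = 480, q_start = 60, q_slope = 0,
                     q_noise_sd = 0)
    sim <- simulate_reads(tx, rm, n_reads = 150, seed = s + 70)
    truth <- sim$truth
    aln <- align_cluster_reads(
      trimmed = sim$reads[, c("read_id", "bases")],
      assignment = data.frame(read_id = truth$read_id,
                              cluster_id = truth$gene_id),
      truth = truth,
      trim_report = data.frame(read_id = truth$read_id, kept_start = 0L))
    for (g in names(aln)) {
      calls <- apply_min_count_filter(call_variant_columns(aln[[g]], g))
      site <- tx$planted_snps[tx$planted_snps$gene == as.integer(g), ]
      rows <- truth[truth$gene_id == as.integer(g), ]
      # alignment column 0 sits at the leftmost read start on the transcript
      calls$column <- calls$column + min(rows$tx_start)
      # which planted sites have >= 2 covering reads of each haplotype?
      covers <- rows$tx_start <= site$offset &
        rows$tx_start + nchar(sim$reads$bases[match(rows$read_id,
                                                    sim$reads$read_id)]) >
          site$offset
      expect_cols <- site$offset[
        sum(covers & rows$haplotype == "a") >= 2 &
        sum(covers & rows$haplotype == "b") >= 2]
      if (!setequal(calls$column, expect_cols)) predicted_match <- FALSE
      if (!all(calls$column %in% site$offset)) ok_fp <- FALSE
      if (nrow(calls) == 1 &&
          !setequal(c(calls$ref_allele, calls$alt_allele),
                    c(site$allele_a, site$allele_b))) class_ok <- FALSE
    }
  }
  expect_true(ok_fp)
  expect_true(predicted_match)
  expect_true(class_ok)
})
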