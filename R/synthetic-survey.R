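#' Sample a skewed transcript-abundance profile
#'
#' Draws per-gene relative abundances from a lognormal prior and normalizes
#' them to a probability vector. A lognormal prior is the standard model for
#' bulk transcript abundance; `log_sd` controls the skew (0 gives a uniform
#' profile, 2 gives the heavy-tailed profiles typical of non-normalized cDNA
#' libraries, where a handful of transcripts dominate the pool).
#'
#' @param n_genes number of genes (>= 1).
#' @param log_mean,log_sd mean and sd of log abundance; `log_sd >= 0`.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return numeric vector of length `n_genes`, positive, summing to 1.
#' @export
sample_abundances <- function(n_genes, log_mean = 0, log_sd = 2, seed = 1L) {
  if (length(n_genes) != 1L || is.na(n_genes) || n_genes < 1)
    stop("n_genes must be a single count >= 1")
  if (log_sd < 0) stop("log_sd must be >= 0")
  n_genes <- as.integer(n_genes)
  if (n_genes == 1L) return(1)
  set.seed(as.integer(seed))
  x <- exp(stats::rnorm(n_genes, mean = log_mean, sd = log_sd))
  x / sum(x)
}

#' Apply a DSN-normalization kinetics model to an abundance profile
#'
#' Models cDNA normalization by duplex-specific nuclease (DSN): denatured
#' cDNA reassociates under ideal second-order (Cot) kinetics, the
#' double-stranded fraction -- formed preferentially by abundant transcripts
#' -- is degraded, and the surviving single-stranded fraction of transcript
#' i is `1 / (1 + theta * p_i)`, where `theta` is the dimensionless composite
#' k*C0*t (rate constant x total concentration x reassociation time).
#' Surviving amounts are renormalized to a probability vector.
#'
#' The map preserves abundance rank order, never increases the max/min
#' spread, and never decreases Shannon entropy; `theta = 0` is the identity.
#'
#' @param p probability vector (sums to 1).
#' @param theta reassociation extent, >= 0.
#' @return normalized probability vector, same length as `p`.
#' @export
dsn_normalize <- function(p, theta) {
  if (length(theta) != 1L || is.na(theta) || theta < 0)
    stop("theta must be a single value >= 0")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("p must be a probability vector summing to 1")
  q <- p / (1 + theta * p)
  q / sum(q)
}

#' Calibrate the reassociation extent for a target fold-reduction
#'
#' Finds `theta` such that [dsn_normalize()] reduces the share of one gene by
#' a requested factor, by monotone root finding on the bracket [0, 1e12].
#' The achievable fold is bounded: as `theta` grows the profile flattens
#' toward uniform, so the maximum fold for gene g is `p_g * n_genes`
#' (restricted to genes with positive abundance). An unreachable
#' `target_fold` is reported as an error rather than clipped.
#'
#' @param p probability vector.
#' @param gene index of the gene whose share is to be reduced.
#' @param target_fold requested reduction factor, >= 1.
#' @param tol relative tolerance on the achieved fold (default 1e-6).
#' @return `theta` (a single non-negative number).
#' @export
calibrate_theta <- function(p, gene, target_fold, tol = 1e-6) {
  if (gene < 1 || gene > length(p)) stop("gene index out of range")
  if (target_fold < 1) stop("target_fold must be >= 1")
  if (target_fold == 1) return(0)
  pos <- p > 0
  if (!pos[gene]) stop("target gene has zero abundance")
  max_fold <- p[gene] * sum(pos)
  if (target_fold >= max_fold)
    stop(sprintf(
      "target_fold %.4g unreachable: flattening limit for this gene is %.4g",
      target_fold, max_fold))
  achieved <- function(theta) p[gene] / dsn_normalize(p, theta)[gene]
  root <- stats::uniroot(function(th) achieved(th) - target_fold,
                         lower = 0, upper = 1e12,
                         tol = tol * target_fold, extendInt = "no")
  root$root
}

#' Build a synthetic transcriptome with planted SSRs and SNPs
#'
#' Generates `n_genes` random transcript sequences, each with two haplotypes
#' that differ only at planted SNP positions, and embeds perfect tandem SSR
#' tracts at known offsets. Each gene carries a CDS annotation
#' (5'UTR / ORF / 3'UTR layout) so planted SSRs have a known region class.
#' This is the ground truth every downstream stage is tested against.
#'
#' @param n_genes number of genes.
#' @param mean_len,sd_len transcript length distribution (bp); lengths are
#'   clipped below at 300 bp.
#' @param ssr_rate fraction of genes given one planted SSR tract.
#' @param snp_rate fraction of genes given one planted SNP.
#' @param hap_b_freq population frequency of haplotype b at planted SNPs.
#' @param seed integer seed.
#' @return a `transcriptome` list: `sequences` (list of 2-row character
#'   matrices, haplotype a/b), `abundances`, `cds` (data.frame gene,
#'   cds_start, cds_end; 0-based half-open), `planted_ssrs` (gene, offset,
#'   motif, length), `planted_snps` (gene, offset, allele_a, allele_b,
#'   hap_b_freq).
#' @export
make_transcriptome <- function(n_genes = 50, mean_len = 900, sd_len = 150,
                               ssr_rate = 0.3, snp_rate = 0.5,
                               hap_b_freq = 0.5, log_mean = 0, log_sd = 1.5,
                               seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  lens <- pmax(300L, as.integer(round(stats::rnorm(n_genes, mean_len, sd_len))))
  seqs_a <- vapply(lens, function(L)
    paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))

  # layout: 5'UTR is ~15% of the transcript, 3'UTR ~25%, ORF in between
  cds_start <- as.integer(round(lens * 0.15))
  cds_end   <- as.integer(round(lens * 0.75))

  ssr_genes <- sort(sample.int(n_genes, size = round(ssr_rate * n_genes)))
  ssr_units <- c("AC", "AG", "AAT", "ATCC", "AAC", "AGAT")
  planted_ssrs <- NULL
  for (g in ssr_genes) {
    unit <- sample(ssr_units, 1)
    n_units <- sample(7:12, 1)          # tract 14-48 bp; >= 24 for most units
    tract <- strrep(unit, n_units)
    if (nchar(tract) < 24) next
    # place the tract in one of the three regions, away from transcript ends
    off <- sample(seq.int(10L, lens[g] - nchar(tract) - 10L), 1)
    s <- seqs_a[g]
    # pad flanks with a non-repeat base so the planted tract stays maximal
    flank_l <- sample(setdiff(bases, substr(unit, nchar(unit), nchar(unit))), 1)
    flank_r <- sample(setdiff(bases, substr(unit, 1, 1)), 1)
    substr(s, off, off + nchar(tract) + 1L) <-
      paste0(flank_l, tract, flank_r)
    seqs_a[g] <- s
    planted_ssrs <- rbind(planted_ssrs, data.frame(
      gene = g, offset = off, motif = unit, length = nchar(tract)))
  }

  snp_genes <- sort(sample.int(n_genes, size = round(snp_rate * n_genes)))
  seqs_b <- seqs_a
  planted_snps <- NULL
  for (g in snp_genes) {
    cand <- seq.int(20L, min(400L, lens[g] - 20L))  # reachable by 5' reads
    ssr_g <- planted_ssrs[planted_ssrs$gene == g, , drop = FALSE]
    if (!is.null(planted_ssrs) && nrow(ssr_g) > 0) {
      # keep the SNP clear of planted tracts so both stay intact on both haplotypes
      for (j in seq_len(nrow(ssr_g)))
        cand <- setdiff(cand, seq.int(ssr_g$offset[j] - 1L,
                                      ssr_g$offset[j] + ssr_g$length[j] + 2L))
      if (length(cand) == 0) next
    }
    off <- if (length(cand) == 1) cand else sample(cand, 1)
    a <- substr(seqs_a[g], off, off)
    b <- sample(setdiff(bases, a), 1)
    substr(seqs_b[g], off, off) <- b
    planted_snps <- rbind(planted_snps, data.frame(
      gene = g, offset = off - 1L,  # 0-based
      allele_a = a, allele_b = b, hap_b_freq = hap_b_freq))
  }

  structure(list(
    n_genes = n_genes,
    sequences = Map(function(a, b) c(a = a, b = b), seqs_a, seqs_b),
    abundances = sample_abundances(n_genes, log_mean, log_sd,
                                   seed = as.integer(seed) + 1L),
    cds = data.frame(gene = seq_len(n_genes),
                     cds_start = cds_start, cds_end = cds_end),
    planted_ssrs = planted_ssrs,
    planted_snps = planted_snps
  ), class = "transcriptome")
}

#' Default 5'-read model
#'
#' Single-pass 5' Sanger reads: a small geometric offset from the transcript
#' 5' end, normally distributed read lengths, and a Phred quality profile
#' that decays linearly with cycle position plus bounded noise, clipped to
#' [2, 60]. Per-base substitution errors are injected at rate 10^(-Q/10).
#'
#' @param mean_len,sd_len,min_len,max_len read length distribution (bp).
#' @param start_geom_prob success probability of the geometric 5'-offset.
#' @param q_start,q_slope,q_noise_sd quality decay Q(pos) =
#'   q_start - q_slope * pos + noise, clipped to [2, 60].
#' @return a `read_model` list.
#' @export
read_model <- function(mean_len = 650, sd_len = 80, min_len = 60,
                       max_len = 900, start_geom_prob = 0.2,
                       q_start = 45, q_slope = 0.04, q_noise_sd = 2) {
  structure(list(mean_len = mean_len, sd_len = sd_len, min_len = min_len,
                 max_len = max_len, start_geom_prob = start_geom_prob,
                 q_start = q_start, q_slope = q_slope,
                 q_noise_sd = q_noise_sd),
            class = "read_model")
}

#' Simulate 5' EST reads from a transcriptome
#'
#' Draws genes proportional to `abundances` (optionally a normalized profile
#' passed via `p`), picks a haplotype per read, samples a 5'-anchored start
#' and a read length, generates decaying Phred qualities, and injects
#' substitution errors at the per-base rate implied by the quality. One seed
#' governs a single generator threaded through all sampling, so the same
#' seed and configuration give identical output.
#'
#' @param model a `transcriptome` from [make_transcriptome()].
#' @param rmodel a `read_model`.
#' @param n_reads number of reads (>= 1).
#' @param seed integer seed.
#' @param p optional abundance vector overriding `model$abundances`
#'   (e.g. a DSN-normalized profile).
#' @return list with `reads` (data.frame read_id, bases, quals list-column)
#'   and `truth` (data.frame read_id, gene_id, haplotype, true_start,
#'   true_end; 0-based half-open model-implied keep region).
#' @export
simulate_reads <- function(model, rmodel = read_model(), n_reads, seed = 1L,
                           p = NULL) {
  if (!inherits(model, "transcriptome") || model$n_genes < 1)
    stop("empty or invalid transcriptome")
  if (n_reads < 1) stop("n_reads must be >= 1")
  p <- if (is.null(p)) model$abundances else p
  stopifnot(length(p) == model$n_genes)
  set.seed(as.integer(seed))
  n_reads <- as.integer(n_reads)

  genes <- sample.int(model$n_genes, n_reads, replace = TRUE, prob = p)
  hapf <- if (is.null(model$planted_snps)) 0.5 else
    model$planted_snps$hap_b_freq[1]
  haps <- ifelse(stats::runif(n_reads) < hapf, "b", "a")
  starts <- stats::rgeom(n_reads, prob = rmodel$start_geom_prob)  # 0-based
  lens <- pmin(rmodel$max_len, pmax(rmodel$min_len, as.integer(
    round(stats::rnorm(n_reads, rmodel$mean_len, rmodel$sd_len)))))

  # model-implied keep region: positions whose noise-free expected error
  # stays within the default window threshold (Q where 10^(-Q/10) = 0.063)
  q_floor <- -10 * log10(0.063)
  keep_limit <- max(0, floor((rmodel$q_start - q_floor) / rmodel$q_slope))

  bases <- c("A", "C", "G", "T")
  out_bases <- character(n_reads)
  out_quals <- vector("list", n_reads)
  true_end <- integer(n_reads)
  for (i in seq_len(n_reads)) {
    tx <- model$sequences[[genes[i]]][[haps[i]]]
    txlen <- nchar(tx)
    s0 <- min(starts[i], txlen - rmodel$min_len)
    s0 <- max(s0, 0L)
    L <- min(lens[i], txlen - s0)
    seq_i <- strsplit(substr(tx, s0 + 1L, s0 + L), "")[[1]]
    pos <- seq_len(L)
    q <- rmodel$q_start - rmodel$q_slope * (pos - 1) +
      stats::rnorm(L, 0, rmodel$q_noise_sd)
    q <- as.integer(pmin(60, pmax(2, round(q))))
    err <- stats::runif(L) < 10^(-q / 10)
    if (any(err)) {
      seq_i[err] <- vapply(seq_i[err],
                           function(b) sample(setdiff(bases, b), 1),
                           character(1))
    }
    out_bases[i] <- paste(seq_i, collapse = "")
    out_quals[[i]] <- q
    true_end[i] <- min(L, keep_limit)
    starts[i] <- s0
  }

  ids <- sprintf("read%06d", seq_len(n_reads))
  reads <- data.frame(read_id = ids, bases = out_bases,
                      stringsAsFactors = FALSE)
  reads$quals <- out_quals
  truth <- data.frame(read_id = ids, gene_id = genes, haplotype = haps,
                      tx_start = starts,
                      true_start = 0L, true_end = true_end,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Expected number of distinct genes observed after n reads
#'
#' Under multinomial sampling with gene probabilities `p`, the expected
#' number of distinct genes seen in `n_reads` draws is
#' `sum_i (1 - (1 - p_i)^n)`. This is the expectation behind the
#' discovery-rate curves used to triage libraries by redundancy.
#'
#' @param p probability vector.
#' @param n_reads number of reads (>= 0).
#' @return expected distinct-gene count in [0, length(p)].
#' @export
expected_distinct <- function(p, n_reads) {
  if (n_reads < 0) stop("n_reads must be >= 0")
  sum(1 - (1 - p)^n_reads)
}

#' Write a simulated survey to disk
#'
#' Writes reads as Phred+33 FASTQ, the truth table as TSV (read_id, gene_id,
#' haplotype, true_start, true_end; 0-based half-open), and a run manifest
#' echoing all parameters.
#'
#' @param sim result of [simulate_reads()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param params named list echoed into the manifest.
#' @return invisibly, the paths written.
#' @export
write_survey <- function(sim, dir, prefix = "survey", params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fq <- file.path(dir, paste0(prefix, ".fastq"))
  tt <- file.path(dir, paste0(prefix, ".truth.tsv"))
  mf <- file.path(dir, paste0(prefix, ".manifest.json"))
  write_fastq(sim$reads, fq)
  con <- file(tt, "w")
  writeLines("# coordinates: 0-based half-open", con)
  utils::write.table(
    sim$truth[, c("read_id", "gene_id", "haplotype", "true_start", "true_end")],
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  jsonlite::write_json(c(params, list(n_reads = nrow(sim$reads))), mf,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(fastq = fq, truth = tt, manifest = mf))
}
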