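#' Default pipeline configuration
#'
#' All stages of the synthetic EST-survey pipeline with their default
#' parameters: survey size, DSN-normalization target, trimming thresholds
#' (bracket Q30, window 10 @ 0.063, pass rule 100 bases at mean Q20),
#' clustering (canonical 16-mers, 3 shared), SSR mining (unit 2-4 bp,
#' tract >= 24 bp) and the SNP allele-count filter (>= 2 per allele).
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = "pipeline_out",
    stage_from = "simulate",
    stage_to = "snp",
    n_genes = 60,
    n_reads = 1200,
    log_mean = 0,
    log_sd = 1.5,
    normalize = 1,              # 1: apply DSN model to the abundance profile
    target_fold = 40,           # fold-reduction of the most abundant gene
    hap_b_freq = 0.5,
    bracket_max_error = 0.001,
    window_len = 10,
    window_max_avg_error = 0.063,
    pass_min_len = 100,
    pass_min_avg_q = 20,
    k = 16,
    min_shared = 3,
    ssr_min_len = 24,
    snp_min_count = 2,
    hits_path = "",             # optional external 12-column hit file
    subject_lengths_path = ""
  )
}

resolve_config <- function(config) {
  defaults <- default_config()
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(config)] <- config
  defaults
}

pipeline_stages <- c("simulate", "trim", "cluster", "stats",
                     "completeness", "ssr", "snp")

#' Run the synthetic EST-survey pipeline
#'
#' Executes the stages simulate -> trim -> cluster -> stats -> completeness
#' -> ssr -> snp in order (any contiguous subrange selectable via
#' `stage_from` / `stage_to`; later stages read the artifacts earlier stages
#' wrote under `out_dir`). A manifest of all resolved parameters is written
#' on every run; identical config and seed give identical outputs.
#'
#' @param config named list of overrides, or the path of a key-value config
#'   file; see [default_config()] for keys. Unknown keys are errors.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- resolve_config(config)
  from <- match(cfg$stage_from, pipeline_stages)
  to <- match(cfg$stage_to, pipeline_stages)
  if (is.na(from) || is.na(to) || from > to)
    stop("invalid stage range: ", cfg$stage_from, " .. ", cfg$stage_to)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(cfg$out_dir, f)
  jsonlite::write_json(cfg, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  active <- pipeline_stages[from:to]
  log_stage <- function(s) message("[estsurvey] stage: ", s,
                                   " (seed=", cfg$seed, ")")

  if ("simulate" %in% active) {
    log_stage("simulate")
    tx <- make_transcriptome(n_genes = cfg$n_genes, log_mean = cfg$log_mean,
                             log_sd = cfg$log_sd, hap_b_freq = cfg$hap_b_freq,
                             seed = cfg$seed)
    p <- tx$abundances
    if (cfg$normalize >= 1) {
      top <- which.max(p)
      fold <- min(cfg$target_fold, 0.95 * p[top] * length(p))
      theta <- calibrate_theta(p, top, fold)
      message(sprintf("[estsurvey] DSN model: theta=%.3g (fold %.2f on gene %d)",
                      theta, fold, top))
      p <- dsn_normalize(p, theta)
    }
    sim <- simulate_reads(tx, read_model(), n_reads = cfg$n_reads,
                          seed = cfg$seed, p = p)
    write_survey(sim, cfg$out_dir, prefix = "survey", params = cfg)
    write_report_tsv(sim$truth, path("survey.truth.full.tsv"))
    seqs <- Biostrings::DNAStringSet(vapply(tx$sequences, `[[`, character(1), "a"))
    names(seqs) <- sprintf("gene%04d", seq_along(seqs))
    Biostrings::writeXStringSet(seqs, path("transcriptome.fasta"))
    write_report_tsv(tx$cds, path("cds.tsv"))
    if (!is.null(tx$planted_ssrs)) write_report_tsv(tx$planted_ssrs, path("planted_ssrs.tsv"))
    if (!is.null(tx$planted_snps)) write_report_tsv(tx$planted_snps, path("planted_snps.tsv"))
  }

  policy <- trim_policy(bracket_max_error = cfg$bracket_max_error,
                        windows = list(c(cfg$window_len,
                                         cfg$window_max_avg_error)),
                        pass_min_len = cfg$pass_min_len,
                        pass_min_avg_q = cfg$pass_min_avg_q)

  if ("trim" %in% active) {
    log_stage("trim")
    reads <- read_fastq(path("survey.fastq"))
    rep <- trim_reads(reads, policy)
    write_report_tsv(rep, path("trim_report.tsv"))
    keep <- which(rep$passed)
    trimmed <- reads[keep, , drop = FALSE]
    for (i in seq_along(keep)) {
      j <- keep[i]
      trimmed$bases[i] <- substr(reads$bases[j], rep$kept_start[j] + 1L,
                                 rep$kept_end[j])
      trimmed$quals[[i]] <- reads$quals[[j]][(rep$kept_start[j] + 1L):rep$kept_end[j]]
    }
    write_fastq(trimmed, path("trimmed.fastq"))
    message(sprintf("[estsurvey] pass rate: %.1f%% (%d/%d)",
                    100 * pass_rate(rep), sum(rep$passed), nrow(rep)))
  }

  if ("cluster" %in% active) {
    log_stage("cluster")
    trimmed <- read_fastq(path("trimmed.fastq"))
    asg <- cluster_reads(trimmed, k = as.integer(cfg$k),
                         min_shared = as.integer(cfg$min_shared))
    write_membership(asg, path("membership.tsv"))
  }

  if ("stats" %in% active) {
    log_stage("stats")
    asg <- read_membership(path("membership.tsv"))
    summ <- summarize_clusters(asg, library = "synthetic")
    rep <- library_report(summ)
    write_report_tsv(rep, path("redundancy_report.tsv"),
                     comment = "library clustering statistics")
    message(sprintf("[estsurvey] coverage %.4f, discovery %.3f reads/new sequence",
                    rep$coverage, rep$discovery))
  }

  if ("completeness" %in% active) {
    log_stage("completeness")
    if (nzchar(cfg$hits_path)) {
      hits <- read_tabular_hits(cfg$hits_path, cfg$subject_lengths_path)
    } else {
      hits <- synthesize_protein_hits(
        truth_path = path("survey.truth.full.tsv"),
        trim_report_path = path("trim_report.tsv"),
        cds_path = path("cds.tsv"))
    }
    best <- best_hit_per_query(hits)
    cls <- classify_completeness(best$subject_start, best$subject_end,
                                 best$subject_length)
    tab <- completeness_table(cls, bin_by_length(best$subject_length))
    out <- as.data.frame(tab$proportions)
    out <- cbind(class = rownames(out), out)
    write_report_tsv(out, path("completeness_table.tsv"),
                     comment = "proportions per protein size class")
    message(sprintf("[estsurvey] %.1f%% of queries complete on both ends",
                    100 * tab$overall_both))
  }

  if ("ssr" %in% active) {
    log_stage("ssr")
    seqs <- Biostrings::readDNAStringSet(path("transcriptome.fasta"))
    cds <- utils::read.table(path("cds.tsv"), sep = "\t", header = TRUE,
                             comment.char = "#")
    recs <- lapply(seq_along(seqs), function(i)
      find_ssrs(as.character(seqs[[i]]), seq_id = names(seqs)[i],
                min_len = as.integer(cfg$ssr_min_len)))
    recs <- do.call(rbind, recs)
    if (nrow(recs) > 0) {
      gi <- as.integer(sub("gene", "", recs$seq_id))
      recs$region <- classify_region(recs$start, recs$end,
                                     cds$cds_start[gi], cds$cds_end[gi])
    }
    write_report_tsv(recs, path("ssr.tsv"))
    s <- ssr_summary(recs)
    message(sprintf("[estsurvey] %d SSRs (di %d, tri %d, tetra %d)",
                    s$total, s$by_unit_length[["2"]], s$by_unit_length[["3"]],
                    s$by_unit_length[["4"]]))
  }

  if ("snp" %in% active) {
    log_stage("snp")
    asg <- read_membership(path("membership.tsv"))
    trimmed <- read_fastq(path("trimmed.fastq"))
    truth <- utils::read.table(path("survey.truth.full.tsv"), sep = "\t",
                               header = TRUE, comment.char = "#")
    trep <- utils::read.table(path("trim_report.tsv"), sep = "\t",
                              header = TRUE, comment.char = "#")
    alns <- align_cluster_reads(trimmed, asg, truth, trep)
    cands <- lapply(names(alns), function(cid)
      call_variant_columns(alns[[cid]], contig_id = cid,
                           min_count = as.integer(cfg$snp_min_count)))
    cands <- do.call(rbind, cands)
    if (is.null(cands) || nrow(cands) == 0) {
      message("[estsurvey] no candidate SNPs")
      cands <- call_variant_columns("A")[0, ]
    }
    filtered <- apply_min_count_filter(cands, as.integer(cfg$snp_min_count))
    write_report_tsv(cands, path("snp_candidates.tsv"),
                     comment = "column: 0-based alignment column")
    write_report_tsv(filtered, path("snp_filtered.tsv"),
                     comment = "column: 0-based alignment column")
    ts <- tstv_summary(filtered)
    message(sprintf("[estsurvey] %d candidates, %d pass filter; Ts %d / Tv %d (%.0f%% transitions)",
                    nrow(cands), nrow(filtered), ts$n_transition,
                    ts$n_transversion, 100 * ts$fraction_transition))
  }

  invisible(cfg$out_dir)
}

#' Synthesize protein hits from simulation truth
#'
#' Stands in for a translated protein search on synthetic data (labelled
#' synthetic: these are not alignments, they are derived from the known read
#' placements). Each passing read's overlap with its gene's CDS becomes a
#' hit on a synthetic protein of length (cds_end - cds_start)/3 amino acids,
#' with 1-based subject coordinates; overlaps under 30 nt are dropped.
#'
#' @param truth_path,trim_report_path,cds_path artifact paths from the
#'   simulate and trim stages.
#' @return data.frame compatible with [best_hit_per_query()].
#' @export
synthesize_protein_hits <- function(truth_path, trim_report_path, cds_path) {
  truth <- utils::read.table(truth_path, sep = "\t", header = TRUE,
                             comment.char = "#")
  trep <- utils::read.table(trim_report_path, sep = "\t", header = TRUE,
                            comment.char = "#")
  cds <- utils::read.table(cds_path, sep = "\t", header = TRUE,
                           comment.char = "#")
  m <- merge(truth, trep, by = "read_id")
  m <- m[m$passed, , drop = FALSE]
  g <- match(m$gene_id, cds$gene)
  cs <- cds$cds_start[g]; ce <- cds$cds_end[g]
  ts <- m$tx_start + m$kept_start
  te <- m$tx_start + m$kept_end
  os <- pmax(ts, cs); oe <- pmin(te, ce)
  keep <- (oe - os) >= 30
  plen <- pmax(1L, (ce - cs) %/% 3L)
  ss <- pmin(plen, pmax(1L, (os - cs) %/% 3L + 1L))
  se <- pmin(plen, pmax(ss, as.integer(ceiling((oe - cs) / 3))))
  data.frame(query_id = m$read_id[keep],
             subject_id = sprintf("prot%04d", m$gene_id[keep]),
             subject_start = ss[keep], subject_end = se[keep],
             subject_length = plen[keep],
             evalue = 10^(-pmin(180, (oe - os)[keep] / 3)),
             stringsAsFactors = FALSE)
}

#' Positional per-cluster alignments for co-anchored synthetic reads
#'
#' Synthetic reads from the same transcript are co-anchored by construction
#' (their transcript offsets are known), so a cluster's multiple alignment
#' is positional: each trimmed read is placed at offset
#' `tx_start + kept_start` and padded with gaps. Clusters with fewer than
#' two reads are skipped.
#'
#' @param trimmed reads table of trimmed reads.
#' @param assignment membership data.frame (read_id, cluster_id).
#' @param truth simulation truth table (read_id, tx_start).
#' @param trim_report trim report (read_id, kept_start).
#' @return named list of character vectors (aligned rows) per cluster.
#' @export
align_cluster_reads <- function(trimmed, assignment, truth, trim_report) {
  m <- merge(merge(trimmed[, c("read_id", "bases")], assignment,
                   by = "read_id"),
             merge(truth[, c("read_id", "tx_start")],
                   trim_report[, c("read_id", "kept_start")], by = "read_id"),
             by = "read_id")
  m$offset <- m$tx_start + m$kept_start
  out <- list()
  for (cid in unique(m$cluster_id)) {
    rows <- m[m$cluster_id == cid, , drop = FALSE]
    if (nrow(rows) < 2) next
    left <- min(rows$offset)
    width <- max(rows$offset + nchar(rows$bases)) - left
    aln <- vapply(seq_len(nrow(rows)), function(i) {
      pre <- rows$offset[i] - left
      post <- width - pre - nchar(rows$bases[i])
      paste0(strrep("-", pre), rows$bases[i], strrep("-", post))
    }, character(1))
    out[[as.character(cid)]] <- aln
  }
  out
}
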