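#!/usr/bin/env Rscript
# Stage 1: simulate a normalized EST survey.
#
# Draws a skewed transcript-abundance profile, calibrates the
# duplex-specific-nuclease (DSN) survivor model so the most abundant
# transcript is reduced ~40-fold, and samples 5'-anchored single-pass reads
# with decaying base quality. Artifacts land in results/survey/.

suppressPackageStartupMessages(library(estsurvey))

out_dir <- "results/survey"
run_pipeline(list(seed = 1, out_dir = out_dir, n_genes = 60, n_reads = 1200,
                  target_fold = 40, stage_from = "simulate",
                  stage_to = "simulate"))

truth <- utils::read.delim(file.path(out_dir, "survey.truth.full.tsv"),
                           comment.char = "#")
cat(sprintf("simulated %d reads from %d expressed genes\n",
            nrow(truth), length(unique(truth$gene_id))))
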