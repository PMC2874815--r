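#!/usr/bin/env Rscript
# Stage 2: quality-trim the simulated reads and cluster them.
#
# Trimming keeps, per read, the longest interval whose terminal bases meet
# the Q30 error bound and whose every 10-base window stays below a mean
# error of 0.063; a read passes if it retains 100 contiguous bases of mean
# quality >= Q20. Passing reads are clustered by shared canonical 16-mers
# (single linkage, 3 shared k-mers, low-complexity k-mers excluded).

suppressPackageStartupMessages(library(estsurvey))

out_dir <- "results/survey"
run_pipeline(list(seed = 1, out_dir = out_dir, n_genes = 60, n_reads = 1200,
                  target_fold = 40, stage_from = "trim",
                  stage_to = "cluster"))

trim <- utils::read.delim(file.path(out_dir, "trim_report.tsv"),
                          comment.char = "#")
cat(sprintf("pass rate: %.1f%% (%d of %d reads)\n",
            100 * mean(trim$passed), sum(trim$passed), nrow(trim)))
memb <- read_membership(file.path(out_dir, "membership.tsv"))
cat(sprintf("clusters: %d distinct among %d reads\n",
            length(unique(memb$cluster_id)), nrow(memb)))
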