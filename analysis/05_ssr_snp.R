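#!/usr/bin/env Rscript
# Stage 5: microsatellite mining and candidate-SNP calling.
#
# SSRs: maximal perfect 2-4 bp tandem repeats of >= 24 bp (homopolymers
# excluded, smallest generating unit reported). SNPs: alignment columns with
# two distinct bases, kept when at least two alleles are each observed
# twice; biallelic survivors are classed as transition or transversion.

suppressPackageStartupMessages(library(estsurvey))

out_dir <- "results/survey"
run_pipeline(list(seed = 1, out_dir = out_dir, n_genes = 60, n_reads = 1200,
                  target_fold = 40, stage_from = "ssr", stage_to = "snp"))

ssr <- utils::read.delim(file.path(out_dir, "ssr.tsv"), comment.char = "#")
summ <- ssr_summary(ssr)
cat(sprintf("SSR tracts: %d (di %d, tri %d, tetra %d)\n", summ$total,
            summ$by_unit_length[["2"]], summ$by_unit_length[["3"]],
            summ$by_unit_length[["4"]]))

filt <- utils::read.delim(file.path(out_dir, "snp_filtered.tsv"),
                          comment.char = "#")
ts <- tstv_summary(filt)
cat(sprintf("filtered SNPs: %d (transitions %d, transversions %d, %s)\n",
            nrow(filt), ts$n_transition, ts$n_transversion,
            if (is.na(ts$fraction_transition)) "no biallelic sites"
            else sprintf("%.0f%% transitions",
                         100 * ts$fraction_transition)))
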