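#' Per-library clustering counts from a 19-library tilapia EST survey
#'
#' Reference per-library counts (high-quality ESTs, contigs, singletons,
#' total unique sequences) for the two non-normalized and seventeen
#' DSN-normalized Nile tilapia cDNA libraries, together with the coverage
#' and discovery values as printed in the survey's clustering-statistics
#' table. These counts are the desk-check inputs for the redundancy
#' statistics: `coverage = 1 - total/hq_ests` and
#' `discovery = hq_ests/total` reproduce the printed columns.
#'
#' Note one internal inconsistency in the printed table: for the normalized
#' retina library (Re4) the printed discovery value (1.309) does not equal
#' `hq_ests/total` = 1.513 implied by its own printed coverage (0.3390);
#' every other row is self-consistent.
#'
#' @return data.frame with columns library, normalized, hq_ests, contigs,
#'   singletons, total, coverage_printed, discovery_printed.
#' @export
tilapia_library_counts <- function() {
  data.frame(
    library = c("Br3", "D0-4", "D5-15", "D16-40", "Gi1", "Gi2", "GOHD",
                "Ht2", "Ki3", "Li6", "Oe1", "Ov1", "Re3", "Re4", "Sk1",
                "Sm1", "Sp1", "St1", "Te2"),
    normalized = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
                   TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                   TRUE),
    hq_ests = c(10051, 7891, 8001, 8101, 5032, 4164, 3936, 4529, 5131,
                4360, 7983, 7988, 2650, 11298, 4406, 4434, 4389, 4498, 8057),
    contigs = c(1245, 991, 1045, 773, 576, 357, 367, 633, 526, 459, 797,
                772, 374, 2162, 714, 465, 964, 695, 1134),
    singletons = c(6935, 5517, 5171, 6294, 2875, 3206, 2806, 2954, 3871,
                   3306, 5866, 6221, 906, 5306, 2130, 3363, 2059, 2791, 5228),
    total = c(8180, 6508, 6216, 7067, 3451, 3563, 3173, 3587, 4397, 3765,
              6663, 6993, 1280, 7468, 2844, 3828, 3023, 3486, 6362),
    coverage_printed = c(0.1862, 0.1753, 0.2231, 0.1276, 0.3142, 0.1443,
                         0.1939, 0.2080, 0.1431, 0.1365, 0.1654, 0.1246,
                         0.5170, 0.3390, 0.3545, 0.1367, 0.3112, 0.2250,
                         0.2104),
    discovery_printed = c(1.229, 1.213, 1.287, 1.146, 1.458, 1.169, 1.240,
                          1.263, 1.167, 1.158, 1.198, 1.142, 2.070, 1.309,
                          1.549, 1.158, 1.452, 1.290, 1.266),
    stringsAsFactors = FALSE
  )
}

#' Project-wide aggregates from the tilapia EST survey
#'
#' The printed project totals used as desk-check inputs for the aggregate
#' statistics: read counts before/after trimming, assembly totals, the
#' rhodopsin colony-filter counts before/after DSN normalization, and the
#' SSR and SNP tallies.
#'
#' @return named list of counts.
#' @export
tilapia_survey_totals <- function() {
  list(
    reads_sequenced = 137654,
    reads_passing = 116899,
    contigs = 20190,
    singletons = 36028,
    unigenes = 56218,
    total_assembled_bp = 35168415,
    blot_positives_nonnormalized = 360,
    blot_clones_nonnormalized = 9000,
    blot_positives_normalized = 9,
    blot_clones_normalized = 9000,
    ssr_total = 1108,
    ssr_di = 592,
    ssr_tri = 319,
    ssr_tetra = 197,
    snp_candidates = 48309,
    snp_filtered = 2542,
    snp_transitions = 1329,
    snp_transversions = 1213
  )
}
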