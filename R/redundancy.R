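#' Empirical library coverage
#'
#' Coverage is the estimated probability that the next sequenced read
#' matches an already-observed sequence. The empirical estimator is
#' `1 - d/n` where `n` is the number of reads and `d` the number of
#' distinct sequences (contigs + singletons). This is the estimator behind
#' the per-library clustering statistics tables of EST surveys.
#'
#' @param n total reads (>= d >= 1).
#' @param d distinct sequences.
#' @return coverage in [0, 1).
#' @export
coverage_empirical <- function(n, d) {
  if (any(d > n) || any(d < 1)) stop("require n >= d >= 1")
  1 - d / n
}

#' Good-Turing library coverage
#'
#' The Good-Turing (Susko-Roger) estimator `1 - n1/n`, where `n1` is the
#' number of sequences observed exactly once (singletons). It estimates the
#' probability that the next read resamples an already-seen gene from the
#' singleton mass alone.
#'
#' @param n total reads (>= 1).
#' @param n1 singleton count (0 <= n1 <= n).
#' @return coverage in [0, 1].
#' @export
coverage_good_turing <- function(n, n1) {
  if (any(n < 1) || any(n1 > n) || any(n1 < 0)) stop("require n >= n1 >= 0, n >= 1")
  1 - n1 / n
}

#' Reads per new-sequence discovery
#'
#' The expected number of additional reads required to discover a new
#' sequence: `n/d`, identically `1 / (1 - coverage)` for the empirical
#' estimator.
#'
#' @param n total reads.
#' @param d distinct sequences (>= 1).
#' @return reads per discovery, >= 1.
#' @export
discovery_rate <- function(n, d) {
  if (any(d < 1)) stop("d must be >= 1")
  if (any(d > n)) stop("require n >= d")
  n / d
}

#' Per-library redundancy report
#'
#' One row per library with coverage and discovery under the chosen
#' estimator. Display columns are rounded to 4 (coverage) and 3 (discovery)
#' decimals as in standard clustering-statistics tables; full-precision
#' values are kept in `coverage_full` / `discovery_full`.
#'
#' @param summaries data.frame with columns library, n, d, n1, contigs
#'   (see [summarize_clusters()]).
#' @param estimator `"empirical"` (1 - d/n; the default, matching printed
#'   survey tables) or `"good_turing"` (1 - n1/n).
#' @return data.frame (library, hq_ests, contigs, singletons, total,
#'   coverage, discovery, coverage_full, discovery_full, estimator).
#' @export
library_report <- function(summaries, estimator = c("empirical", "good_turing")) {
  estimator <- match.arg(estimator)
  stopifnot(nrow(summaries) >= 1)
  cov <- if (estimator == "empirical")
    coverage_empirical(summaries$n, summaries$d)
  else coverage_good_turing(summaries$n, summaries$n1)
  disc <- 1 / (1 - cov)
  data.frame(library = summaries$library,
             hq_ests = summaries$n,
             contigs = summaries$contigs,
             singletons = summaries$n1,
             total = summaries$d,
             coverage = round(cov, 4),
             discovery = round(disc, 3),
             coverage_full = cov,
             discovery_full = disc,
             estimator = estimator,
             stringsAsFactors = FALSE)
}

#' Discovery-rate curve across sequencing rounds
#'
#' Given a cluster assignment whose reads are tagged with a totally ordered
#' sequencing round, computes the redundancy statistics on the cumulative
#' read set after each round, tracing how reads-per-discovery rises with
#' sequencing depth.
#'
#' @param assignment data.frame (read_id, cluster_id, round_id); every read
#'   must carry a round tag.
#' @return data.frame (round_id, cumulative_reads, distinct, coverage,
#'   discovery), one row per round in order.
#' @export
discovery_curve <- function(assignment) {
  if (!"round_id" %in% names(assignment) || anyNA(assignment$round_id))
    stop("every read must carry a round_id")
  rounds <- sort(unique(assignment$round_id))
  out <- lapply(seq_along(rounds), function(i) {
    cum <- assignment[assignment$round_id %in% rounds[1:i], ]
    n <- nrow(cum); d <- length(unique(cum$cluster_id))
    data.frame(round_id = rounds[i], cumulative_reads = n, distinct = d,
               coverage = coverage_empirical(n, d),
               discovery = discovery_rate(n, d))
  })
  do.call(rbind, out)
}

#' Normalization fold-reduction from hybridization counts
#'
#' The effectiveness statistic for library normalization from colony-filter
#' counts: the ratio of positive-clone frequencies before and after
#' normalization, `(pos_a/tot_a) / (pos_b/tot_b)`. Zero positives after
#' normalization give `Inf` with a warning rather than an error.
#'
#' @param pos_a,tot_a positives and total clones before normalization.
#' @param pos_b,tot_b positives and total clones after normalization.
#' @return fold reduction (>= 0, possibly Inf).
#' @export
fold_reduction <- function(pos_a, tot_a, pos_b, tot_b) {
  stopifnot(pos_a >= 0, pos_b >= 0, tot_a >= 1, tot_b >= 1)
  if (pos_b == 0) {
    warning("no positives after normalization; fold reduction is infinite")
    return(Inf)
  }
  (pos_a / tot_a) / (pos_b / tot_b)
}
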