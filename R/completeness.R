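#' Classify EST completeness against a matched protein entry
#'
#' An EST (or unigene) is 5'-complete when its translated alignment reaches
#' within `margin` amino acids of the protein's N-terminus
#' (`subject_start - 1 <= margin`) and 3'-complete when it reaches within
#' `margin` residues of the C-terminus (`subject_length - subject_end <=
#' margin`). Coordinates are 1-based inclusive on the protein.
#'
#' @param subject_start,subject_end aligned region on the protein (1-based
#'   inclusive), `1 <= start <= end <= length`.
#' @param subject_length protein length in amino acids.
#' @param margin allowed distance from the terminus (default 10 aa).
#' @return one of `"both"`, `"five_only"`, `"three_only"`, `"incomplete"`.
#' @export
classify_completeness <- function(subject_start, subject_end, subject_length,
                                  margin = 10) {
  bad <- subject_start < 1 | subject_end < subject_start |
    subject_end > subject_length
  if (any(bad)) stop("invalid protein coordinates")
  five <- (subject_start - 1) <= margin
  three <- (subject_length - subject_end) <= margin
  out <- ifelse(five & three, "both",
         ifelse(five, "five_only",
         ifelse(three, "three_only", "incomplete")))
  out
}

#' Bin a protein length into the standard size classes
#'
#' Classes: [1,250], [251,500], [501,750], [751,1000], [1001, Inf) amino
#' acids.
#'
#' @param subject_length protein length(s), >= 1.
#' @return ordered factor with levels `<=250`, `251-500`, `501-750`,
#'   `751-1000`, `>1000`.
#' @export
bin_by_length <- function(subject_length) {
  stopifnot(all(subject_length >= 1))
  cut(subject_length, breaks = c(0, 250, 500, 750, 1000, Inf),
      labels = c("<=250", "251-500", "501-750", "751-1000", ">1000"),
      ordered_result = TRUE)
}

#' Reduce multi-hit queries to a single best hit
#'
#' Lowest e-value wins; ties broken by higher subject coverage
#' (aligned residues / subject length), then lexicographic subject_id.
#'
#' @param hits data.frame with query_id, subject_id, subject_start,
#'   subject_end, subject_length, evalue.
#' @return data.frame with one row per query_id.
#' @export
best_hit_per_query <- function(hits) {
  stopifnot(nrow(hits) >= 1)
  cov <- (hits$subject_end - hits$subject_start + 1) / hits$subject_length
  ord <- order(hits$query_id, hits$evalue, -cov, hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Completeness proportions by protein size class
#'
#' The proportions of {both, five_only, three_only, incomplete} calls within
#' each protein size class, plus a totals row of counts and the overall
#' fraction complete on both ends. Each bin's proportions sum to 1 before
#' display rounding.
#'
#' @param class character vector of completeness calls.
#' @param length_bin matching size classes from [bin_by_length()].
#' @return list with `proportions` (4 x 5 matrix), `totals` (counts per
#'   bin) and `overall_both` (fraction of all calls that are "both").
#' @export
completeness_table <- function(class, length_bin) {
  stopifnot(length(class) >= 1, length(class) == length(length_bin))
  classes <- c("both", "five_only", "three_only", "incomplete")
  tab <- table(factor(class, levels = classes), length_bin)
  totals <- colSums(tab)
  prop <- sweep(tab, 2, pmax(totals, 1), "/")
  list(proportions = unclass(prop), totals = totals,
       overall_both = mean(class == "both"))
}

#' Read a 12-column tabular protein-hit file
#'
#' Standard tabular alignment columns (query, subject, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore) plus a
#' companion subject-length TSV (subject_id, length), since the 12-column
#' format does not carry subject length. Reverse-frame hits
#' (sstart > send) are excluded with a warning: protein N-terminus maps to
#' EST 5'-completeness only for forward-frame translated hits.
#'
#' @param path hit-file path.
#' @param subject_lengths_path TSV (subject_id, length) path.
#' @return data.frame with query_id, subject_id, subject_start, subject_end,
#'   subject_length, evalue (1-based inclusive protein coordinates).
#' @export
read_tabular_hits <- function(path, subject_lengths_path) {
  hits <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                            comment.char = "#")
  if (ncol(hits) != 12)
    stop("expected 12 tab-separated columns in ", path, ", found ", ncol(hits))
  names(hits) <- c("query_id", "subject_id", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                   "bitscore")
  lens <- utils::read.table(subject_lengths_path, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#",
                            col.names = c("subject_id", "length"))
  rev <- hits$sstart > hits$send
  if (any(rev)) {
    warning(sum(rev), " reverse-frame hit(s) excluded")
    hits <- hits[!rev, , drop = FALSE]
  }
  m <- match(hits$subject_id, lens$subject_id)
  if (anyNA(m))
    stop("subject(s) missing from length table: ",
         paste(unique(hits$subject_id[is.na(m)]), collapse = ", "))
  data.frame(query_id = hits$query_id, subject_id = hits$subject_id,
             subject_start = hits$sstart, subject_end = hits$send,
             subject_length = lens$length[m], evalue = hits$evalue,
             stringsAsFactors = FALSE)
}
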