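#' Find microsatellites (SSRs) in a nucleotide sequence
#'
#' Detects maximal perfect tandem repeats of 2-4 bp units with a minimum
#' tract length (default 24 bp, the standard Sputnik-style configuration
#' for EST mining). Tracts are reported at their smallest generating unit
#' (so ATATAT... is a dinucleotide AT, never a tetranucleotide ATAT),
#' homopolymer-equivalent units are excluded, N breaks tracts, and
#' overlapping tracts are resolved longest-first, then leftmost.
#'
#' @param sequence nucleotide string over {A,C,G,T,N}.
#' @param seq_id identifier recorded in the output.
#' @param min_unit,max_unit repeat-unit length range (default 2-4).
#' @param min_len minimum tract length in nucleotides (default 24).
#' @return data.frame (seq_id, start, end, unit, canonical_motif,
#'   unit_length, tract_length); coordinates 0-based half-open.
#' @export
find_ssrs <- function(sequence, seq_id = "seq", min_unit = 2L, max_unit = 4L,
                      min_len = 24L) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single character string")
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), unit = character(0),
                      canonical_motif = character(0),
                      unit_length = integer(0), tract_length = integer(0),
                      stringsAsFactors = FALSE)
  if (n < min_len) return(empty)
  valid <- chars %in% c("A", "C", "G", "T")   # N (or anything else) breaks tracts

  recs <- list()
  for (u in seq.int(min_unit, max_unit)) {
    if (n < u + 1L) next
    idx <- 1:(n - u)
    m <- chars[idx] == chars[idx + u] & valid[idx] & valid[idx + u]
    # maximal run of matches starting at i gives a tract of length run + u
    i <- 1L
    while (i <= n - u) {
      if (m[i]) {
        j <- i
        while (j <= n - u && m[j]) j <- j + 1L
        tract_len <- (j - i) + u
        if (tract_len >= min_len && tract_len >= 2L * u) {
          unit <- paste(chars[i:(i + u - 1L)], collapse = "")
          if (smallest_period(unit) == u)  # not homopolymer, not a multiple
            recs[[length(recs) + 1L]] <- data.frame(
              seq_id = seq_id, start = i - 1L, end = i - 1L + tract_len,
              unit = unit, canonical_motif = canonical_motif(unit),
              unit_length = u, tract_length = tract_len,
              stringsAsFactors = FALSE)
        }
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (length(recs) == 0) return(empty)
  out <- do.call(rbind, recs)
  # overlap resolution: longest tract wins, then leftmost, then shortest unit
  out <- out[order(-out$tract_length, out$start, out$unit_length), ]
  kept <- logical(0); sel <- integer(0)
  for (r in seq_len(nrow(out))) {
    s <- out$start[r]; e <- out$end[r]
    if (length(sel) == 0 ||
        all(e <= out$start[sel] | s >= out$end[sel])) sel <- c(sel, r)
  }
  out <- out[sort(sel), , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# smallest p with unit[i] == unit[i + p] for all i (p | nchar not required
# for general periods, but tandem-unit reduction only cares about divisors)
smallest_period <- function(unit) {
  u <- nchar(unit)
  chars <- strsplit(unit, "")[[1]]
  for (p in seq_len(u - 1L)) {
    if (u %% p != 0L) next
    if (all(chars == rep_len(chars[1:p], u))) return(p)
  }
  u
}

#' Canonical name of a repeat unit
#'
#' The lexicographically smallest string among all rotations of the unit and
#' all rotations of its reverse complement, so e.g. GT, TG, CA and AC all
#' canonicalize to AC, and TTA to AAT. Strand-symmetric by construction.
#'
#' @param unit repeat unit, length 2-4, over {A,C,G,T}.
#' @return canonical motif string.
#' @export
canonical_motif <- function(unit) {
  vapply(unit, function(u) {
    u <- toupper(u)
    chars <- strsplit(u, "")[[1]]
    if (!all(chars %in% c("A", "C", "G", "T")) || length(chars) < 1)
      stop("unit must be over {A,C,G,T}: ", u)
    rc <- chartr("ACGT", "TGCA", paste(rev(chars), collapse = ""))
    rots <- function(s) {
      k <- nchar(s)
      vapply(1:k, function(i) paste0(substr(s, i, k), substr(s, 1, i - 1L)),
             character(1))
    }
    min(c(rots(u), rots(rc)))
  }, character(1), USE.NAMES = FALSE)
}

#' Classify the gene region of an SSR tract
#'
#' Assigns the region of the tract midpoint relative to a CDS annotation on
#' the same sequence: before the CDS is 5'UTR, inside is ORF, after is
#' 3'UTR. With no annotation the region is left NA, never guessed.
#'
#' @param start,end tract coordinates, 0-based half-open.
#' @param cds_start,cds_end CDS coordinates, 0-based half-open
#'   (`0 <= cds_start < cds_end <= sequence length`); NA for unannotated.
#' @return character: `"5'UTR"`, `"ORF"`, `"3'UTR"`, or NA.
#' @export
classify_region <- function(start, end, cds_start, cds_end) {
  out <- rep(NA_character_, length(start))
  known <- !is.na(cds_start) & !is.na(cds_end)
  if (any(cds_start[known] >= cds_end[known]))
    stop("require cds_start < cds_end")
  mid <- (start + end) / 2
  out[known & mid < cds_start] <- "5'UTR"
  out[known & mid >= cds_start & mid < cds_end] <- "ORF"
  out[known & mid >= cds_end] <- "3'UTR"
  out
}

#' Summarize SSR records by unit length and canonical motif
#'
#' @param records data.frame from [find_ssrs()] (optionally with a `region`
#'   column).
#' @return list with `by_unit_length` (named counts for 2, 3, 4), `by_motif`
#'   (named counts, decreasing), `by_region` (if present) and `total`.
#' @export
ssr_summary <- function(records) {
  by_unit <- stats::setNames(integer(3), c("2", "3", "4"))
  if (nrow(records) > 0) {
    t1 <- table(records$unit_length)
    by_unit[names(t1)] <- as.integer(t1)
  }
  by_motif <- if (nrow(records) > 0)
    sort(table(records$canonical_motif), decreasing = TRUE) else table(character(0))
  out <- list(by_unit_length = by_unit,
              by_motif = by_motif,
              total = nrow(records))
  if ("region" %in% names(records) && nrow(records) > 0)
    out$by_region <- table(records$region, useNA = "ifany")
  stopifnot(sum(out$by_unit_length) == out$total)
  out
}
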