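#' Call candidate SNP columns from a per-cluster alignment
#'
#' Scans the columns of a multiple alignment (one row per read, equal
#' lengths, alphabet {A,C,G,T,N,-}) and reports every column where at least
#' two distinct unambiguous bases are observed. Gaps and N never count as
#' alleles. Each candidate carries its A/C/G/T allele counts, the
#' minimum-count filter verdict and, for biallelic candidates, the
#' transition/transversion class.
#'
#' @param alignment character vector of aligned sequences (equal length).
#' @param contig_id identifier recorded in the output.
#' @param min_count per-allele count for [apply_min_count_filter()]
#'   (default 2).
#' @return data.frame (contig_id, column, n_A, n_C, n_G, n_T, ref_allele,
#'   alt_allele, passes_filter, class); `column` is 0-based.
#' @export
call_variant_columns <- function(alignment, contig_id = "contig",
                                 min_count = 2L) {
  stopifnot(length(alignment) >= 1)
  L <- nchar(alignment)
  if (length(unique(L)) != 1) stop("ragged alignment: rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  bad <- !mat %in% c("A", "C", "G", "T", "N", "-")
  if (any(bad)) stop("invalid alignment character(s): ",
                     paste(unique(mat[bad]), collapse = ", "))
  bases <- c("A", "C", "G", "T")
  counts <- sapply(bases, function(b) colSums(mat == b))
  if (L[1] == 1) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, bases))
  n_alleles <- rowSums(counts >= 1)
  cand <- which(n_alleles >= 2)
  if (length(cand) == 0)
    return(data.frame(contig_id = character(0), column = integer(0),
                      n_A = integer(0), n_C = integer(0), n_G = integer(0),
                      n_T = integer(0), ref_allele = character(0),
                      alt_allele = character(0), passes_filter = logical(0),
                      class = character(0), stringsAsFactors = FALSE))
  cc <- counts[cand, , drop = FALSE]
  passes <- rowSums(cc >= min_count) >= 2
  # majority base is the reference; the next-most-frequent the alternative
  ord <- apply(cc, 1, function(x) order(-x, seq_along(x)))
  ref <- bases[ord[1, ]]
  alt <- bases[ord[2, ]]
  multi <- rowSums(cc >= min_count) >= 3
  cls <- vapply(seq_along(cand),
                function(i) classify_substitution(ref[i], alt[i]),
                character(1))
  cls[multi] <- "multiallelic"
  data.frame(contig_id = contig_id, column = cand - 1L,
             n_A = cc[, "A"], n_C = cc[, "C"], n_G = cc[, "G"],
             n_T = cc[, "T"],
             ref_allele = ref, alt_allele = alt,
             passes_filter = passes, class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Keep candidates where at least two alleles are each seen min_count times
#'
#' The standard confidence filter for EST-derived SNP candidates: a
#' candidate is retained only when each of (at least) two alternative bases
#' is represented at least `min_count` times. Raising `min_count` never
#' increases the number of kept candidates.
#'
#' @param candidates data.frame from [call_variant_columns()].
#' @param min_count minimum per-allele count (default 2).
#' @return the kept rows, with `passes_filter` recomputed at `min_count`.
#' @export
apply_min_count_filter <- function(candidates, min_count = 2L) {
  if (nrow(candidates) == 0) return(candidates)
  cc <- as.matrix(candidates[, c("n_A", "n_C", "n_G", "n_T")])
  keep <- rowSums(cc >= min_count) >= 2
  out <- candidates[keep, , drop = FALSE]
  if (nrow(out) > 0) {
    out$passes_filter <- TRUE
    out$class[rowSums(cc[keep, , drop = FALSE] >= min_count) >= 3] <- "multiallelic"
  }
  rownames(out) <- NULL
  out
}

#' Classify a base substitution as transition or transversion
#'
#' Transitions are purine-purine (A<->G) or pyrimidine-pyrimidine (C<->T)
#' substitutions; everything else is a transversion. Symmetric in its
#' arguments.
#'
#' @param base_a,base_b two distinct bases in {A,C,G,T}.
#' @return `"transition"` or `"transversion"`.
#' @export
classify_substitution <- function(base_a, base_b) {
  b <- toupper(c(base_a, base_b))
  if (!all(b %in% c("A", "C", "G", "T"))) stop("bases must be in {A,C,G,T}")
  if (b[1] == b[2]) stop("bases must be distinct")
  purine <- b %in% c("A", "G")
  if (purine[1] == purine[2]) "transition" else "transversion"
}

#' Transition/transversion summary of filtered SNP candidates
#'
#' Counts transitions and transversions among biallelic filtered candidates;
#' multiallelic candidates are excluded from the ratio and reported
#' separately. With no biallelic candidates the fraction is NA.
#'
#' @param candidates filtered data.frame (see [apply_min_count_filter()]).
#' @return list (n_transition, n_transversion, n_multiallelic,
#'   fraction_transition).
#' @export
tstv_summary <- function(candidates) {
  cls <- if (nrow(candidates) > 0) candidates$class else character(0)
  ts <- sum(cls == "transition")
  tv <- sum(cls == "transversion")
  list(n_transition = ts, n_transversion = tv,
       n_multiallelic = sum(cls == "multiallelic"),
       fraction_transition = if (ts + tv > 0) ts / (ts + tv) else NA_real_)
}
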