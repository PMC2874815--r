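#' Cluster reads by shared canonical k-mers
#'
#' Single-linkage clustering under the relation "two reads share at least
#' `min_shared` canonical (strand-collapsed) k-mers", a plumbing stand-in
#' for overlap assembly when working with truth-tracked synthetic reads.
#' Output is invariant to read input order; each cluster is labeled by its
#' lexicographically lowest member read_id and cluster ids are dense
#' integers in that label order.
#'
#' @param reads character vector of sequences, named by read_id (or a
#'   data.frame with `read_id` and `bases`).
#' @param k k-mer length (>= 8; default 16).
#' @param min_shared minimum shared canonical k-mers to link (default 3).
#' @return data.frame (read_id, cluster_id).
#' @export
cluster_reads <- function(reads, k = 16L, min_shared = 3L) {
  if (is.data.frame(reads)) {
    seqs <- stats::setNames(reads$bases, reads$read_id)
  } else seqs <- reads
  if (length(seqs) == 0) stop("reads must be nonempty")
  if (k < 8) stop("k must be >= 8")
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  n <- length(seqs)

  kmer_sets <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    starts <- 1:(L - k + 1L)
    chars <- strsplit(s, "")[[1]]
    # drop low-complexity k-mers: anything within 2 mismatches of a perfect
    # tandem repeat of period <= 4. Microsatellite tracts (and their
    # error-bearing copies) are shared across unrelated genes and would
    # spuriously link them -- the role repeat masking plays before real
    # assembly.
    near_periodic <- rep(FALSE, length(starts))
    for (p in 1:4) {
      mm <- as.integer(chars[1:(L - p)] != chars[(p + 1):L])
      w <- k - p                       # lag-p comparisons inside one k-mer
      cs <- c(0L, cumsum(mm))
      near_periodic <- near_periodic |
        (cs[starts + w] - cs[starts]) <= 2L
    }
    km <- substring(s, starts, starts + k - 1L)[!near_periodic]
    km <- km[!grepl("N", km, fixed = TRUE)]
    if (length(km) == 0) return(character(0))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
    unique(pmin(km, rc))
  })

  # union-find over reads linked through shared k-mers
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }

  all_km <- unlist(kmer_sets, use.names = FALSE)
  if (length(all_km) > 0) {
    codes <- match(all_km, unique(all_km))
    owner <- rep.int(seq_len(n), lengths(kmer_sets))
    groups <- split(owner, codes)                 # kmer code -> reads carrying it
    kcodes <- split(codes, owner)                 # read -> its kmer codes
    for (i in as.integer(names(kcodes))) {
      # k-mers are unique within a read, so multiplicity = shared k-mer count
      cand <- unlist(groups[as.character(kcodes[[i]])], use.names = FALSE)
      cnt <- tabulate(cand, nbins = n)
      for (j in which(cnt >= min_shared)) if (j > i) union2(i, j)
    }
  }

  root <- vapply(seq_len(n), find, integer(1))
  # label each component by its lexicographically lowest read_id
  label <- vapply(split(ids, root), min, character(1))
  comp_label <- label[as.character(root)]
  cluster_id <- as.integer(factor(comp_label, levels = sort(unique(comp_label))))
  data.frame(read_id = ids, cluster_id = cluster_id, stringsAsFactors = FALSE)
}

#' Summarize a cluster assignment into library counts
#'
#' Counts that feed the redundancy statistics: total reads n, distinct
#' clusters d, singletons n1 (clusters of size 1) and contigs (clusters of
#' size >= 2). Always d = n1 + contigs.
#'
#' @param assignment data.frame with `cluster_id` (and optionally
#'   `read_id`), or a vector of cluster labels.
#' @param library library name for the summary row.
#' @return one-row data.frame (library, n, d, n1, contigs).
#' @export
summarize_clusters <- function(assignment, library = "library") {
  labels <- if (is.data.frame(assignment)) assignment$cluster_id else assignment
  if (length(labels) == 0) stop("empty assignment")
  sizes <- table(labels)
  data.frame(library = library,
             n = length(labels),
             d = length(sizes),
             n1 = sum(sizes == 1),
             contigs = sum(sizes >= 2),
             stringsAsFactors = FALSE)
}

#' Read a cluster-membership table
#'
#' Tab-separated columns: read_id, cluster_id and optionally round_id.
#' Lines starting with `#` are ignored. Malformed lines and duplicate
#' read_ids are reported with their line numbers.
#'
#' @param path TSV file path.
#' @return data.frame (read_id, cluster_id[, round_id]).
#' @export
read_membership <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty membership file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2 | nf > 3)
  if (length(bad) > 0)
    stop("malformed membership line(s) ", paste(lineno[bad], collapse = ", "),
         " in ", path)
  out <- data.frame(read_id = vapply(parts, `[`, character(1), 1),
                    cluster_id = vapply(parts, `[`, character(1), 2),
                    stringsAsFactors = FALSE)
  if (any(nf == 3))
    out$round_id <- vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_,
                           character(1))
  dup <- duplicated(out$read_id)
  if (any(dup))
    stop("duplicate read_id(s) at line(s) ", paste(lineno[dup], collapse = ", "),
         " in ", path)
  out
}

#' Write a cluster-membership table
#' @param assignment data.frame (read_id, cluster_id[, round_id]).
#' @param path output TSV path.
#' @export
write_membership <- function(assignment, path) {
  cols <- intersect(c("read_id", "cluster_id", "round_id"), names(assignment))
  utils::write.table(assignment[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read contig membership from an ACE assembly file
#'
#' Parses the CO (contig) and AF (read placement) records of an ACE file as
#' produced by CAP3/phrap. Reads placed in a contig get that contig as their
#' cluster; if a companion `read_list` is supplied, listed reads absent from
#' the assembly are added as singletons (their own cluster).
#'
#' @param path ACE file path.
#' @param read_list optional character vector of all sequenced read ids.
#' @return data.frame (read_id, cluster_id).
#' @export
read_ace <- function(path, read_list = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty ACE file: ", path)
  co <- grepl("^CO ", lines)
  af <- grepl("^AF ", lines)
  if (!any(co)) stop("no CO records found in ", path)
  contig <- character(0); read <- character(0)
  current <- NA_character_
  for (i in which(co | af)) {
    f <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (f[1] == "CO") current <- f[2]
    else { contig <- c(contig, current); read <- c(read, f[2]) }
  }
  out <- data.frame(read_id = read, cluster_id = contig,
                    stringsAsFactors = FALSE)
  if (!is.null(read_list)) {
    extra <- setdiff(read_list, out$read_id)
    if (length(extra) > 0)
      out <- rbind(out, data.frame(read_id = extra, cluster_id = extra,
                                   stringsAsFactors = FALSE))
  }
  if (anyDuplicated(out$read_id))
    stop("duplicate read placements in ", path)
  out
}
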