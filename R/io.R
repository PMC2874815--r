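#' Read a Phred+33 FASTQ file into a reads table
#'
#' Qualities are decoded to integer Phred scores and validated against the
#' Sanger-read contract (0-60); out-of-range scores are rejected with the
#' offending read and position.
#'
#' @param path FASTQ file path.
#' @return data.frame (read_id, bases) with list-column `quals`.
#' @export
read_fastq <- function(path) {
  # Biostrings drops the (empty) FASTQ mcols with a warning; benign
  x <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
  quals <- suppressWarnings(as.list(as(Biostrings::quality(x), "IntegerList")))
  for (i in seq_along(quals)) {
    bad <- which(quals[[i]] < 0 | quals[[i]] > 60)
    if (length(bad) > 0)
      stop(sprintf("quality score %d out of range [0,60] in read '%s' at position %d",
                   quals[[i]][bad[1]], names(x)[i], bad[1]))
  }
  out <- data.frame(read_id = names(x), bases = as.character(x),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$quals <- quals
  out
}

#' Write a reads table as Phred+33 FASTQ
#'
#' @param reads data.frame (read_id, bases, list-column quals).
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  for (i in seq_len(nrow(reads))) {
    q <- reads$quals[[i]]
    if (any(q < 0 | q > 60))
      stop(sprintf("quality score out of range [0,60] in read '%s'",
                   reads$read_id[i]))
    if (length(q) != nchar(reads$bases[i]))
      stop("quality length != sequence length for read ", reads$read_id[i])
  }
  qstr <- vapply(reads$quals, function(q) intToUtf8(q + 33L), character(1))
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qstr))
  invisible(path)
}

#' Read a FASTA + QUAL pair into a reads table
#'
#' Sequences from the FASTA, integer Phred scores from the companion QUAL
#' file (FASTA-formatted whitespace-separated integers). Scores above 60 or
#' below 0 are rejected with their position.
#'
#' @param fasta_path,qual_path paths to the paired files.
#' @return data.frame (read_id, bases) with list-column `quals`.
#' @export
read_fasta_qual <- function(fasta_path, qual_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  lines <- readLines(qual_path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no records in QUAL file ", qual_path)
  id <- sub("^>(\\S+).*", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  body <- split(lines[!hdr], grp[!hdr])
  quals <- lapply(body, function(b) {
    v <- suppressWarnings(as.integer(unlist(strsplit(paste(b, collapse = " "),
                                                     "\\s+"))))
    v[!is.na(v)]
  })
  names(quals) <- id
  ids <- sub("^(\\S+).*", "\\1", names(seqs))
  m <- match(ids, id)
  if (anyNA(m)) stop("QUAL records missing for: ",
                     paste(ids[is.na(m)], collapse = ", "))
  quals <- quals[m]
  for (i in seq_along(quals)) {
    if (length(quals[[i]]) != Biostrings::width(seqs)[i])
      stop("QUAL length != sequence length for ", ids[i])
    bad <- which(quals[[i]] < 0 | quals[[i]] > 60)
    if (length(bad) > 0)
      stop(sprintf("quality score %d out of range [0,60] in '%s' at position %d",
                   quals[[i]][bad[1]], ids[i], bad[1]))
  }
  out <- data.frame(read_id = ids, bases = as.character(seqs),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$quals <- unname(quals)
  out
}

#' Read a key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values that parse
#' as numbers are returned numeric.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(list())
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) stop("malformed config line(s): ",
                     paste0("line ", lineno[bad], ": ", lines[bad],
                            collapse = "; "))
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(out, keys)
}

#' Write a report data.frame as TSV with a coordinate-convention header
#'
#' @param x data.frame.
#' @param path output path.
#' @param comment header comment line (coordinate convention etc.).
#' @export
write_report_tsv <- function(x, path,
                             comment = "coordinates: 0-based half-open") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
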