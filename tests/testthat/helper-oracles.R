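# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive results by exhaustive enumeration, never by
# calling the implementation under test.

# --- trimming -------------------------------------------------------------

oracle_bracket <- function(errors, max_error) {
  ok <- errors <= max_error
  if (!any(ok)) return(c(0L, 0L))
  c(min(which(ok)) - 1L, max(which(ok)))
}

# validity of interval [s, e] (1-based inclusive) under the window rules
oracle_interval_ok <- function(errors, s, e, windows) {
  len <- e - s + 1
  for (w in windows) {
    L <- w[1]; emax <- w[2]
    if (len < L) {
      if (mean(errors[s:e]) > emax) return(FALSE)
    } else {
      for (ws in s:(e - L + 1)) if (mean(errors[ws:(ws + L - 1)]) > emax)
        return(FALSE)
    }
  }
  TRUE
}

# longest (leftmost on ties) interval whose endpoint bases meet the bracket
# bound and which satisfies every window rule, by exhaustive search
oracle_trim <- function(errors, bracket_max, windows) {
  n <- length(errors)
  for (len in n:1) {
    for (s in 1:(n - len + 1)) {
      e <- s + len - 1
      if (errors[s] > bracket_max || errors[e] > bracket_max) next
      if (oracle_interval_ok(errors, s, e, windows))
        return(c(s - 1L, as.integer(e)))
    }
  }
  c(0L, 0L)
}

oracle_passes <- function(quals, min_len, min_q) {
  n <- length(quals)
  if (n < min_len) return(FALSE)
  for (s in 1:(n - min_len + 1)) for (e in (s + min_len - 1):n)
    if (mean(quals[s:e]) >= min_q) return(TRUE)
  FALSE
}

# --- SSR mining -----------------------------------------------------------

oracle_smallest_period <- function(unit) {
  u <- nchar(unit)
  ch <- strsplit(unit, "")[[1]]
  for (p in 1:(u - 1)) if (u %% p == 0 &&
                           identical(ch, rep_len(ch[1:p], u))) return(p)
  u
}

# every maximal perfect tandem tract, found by trying each (start, unit size)
oracle_ssrs <- function(sequence, min_unit = 2, max_unit = 4, min_len = 24) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  n <- length(ch)
  acgt <- ch %in% c("A", "C", "G", "T")
  recs <- list()
  for (u in min_unit:max_unit) {
    for (i in 1:max(1, n - 2 * u + 1)) {
      if (i + 2 * u - 1 > n) break
      # extend a tract anchored at i
      j <- i + u
      while (j <= n && ch[j] == ch[j - u] && acgt[j] && acgt[j - u]) j <- j + 1
      tract_len <- j - i
      if (tract_len < 2 * u || tract_len < min_len) next
      if (!all(acgt[i:(j - 1)])) next
      # maximal on the left?
      if (i > 1 && acgt[i - 1] && ch[i - 1] == ch[i - 1 + u]) next
      unit <- paste(ch[i:(i + u - 1)], collapse = "")
      if (oracle_smallest_period(unit) != u) next
      recs[[length(recs) + 1]] <- data.frame(
        start = i - 1L, end = i - 1L + tract_len, unit = unit,
        unit_length = u, tract_length = tract_len)
    }
  }
  if (length(recs) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      unit = character(0), unit_length = integer(0),
                      tract_length = integer(0)))
  out <- unique(do.call(rbind, recs))
  out <- out[order(-out$tract_length, out$start, out$unit_length), ]
  sel <- integer(0)
  for (r in seq_len(nrow(out))) {
    if (length(sel) == 0 ||
        all(out$end[r] <= out$start[sel] | out$start[r] >= out$end[sel]))
      sel <- c(sel, r)
  }
  out <- out[sort(sel), , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# random sequence with enough repeat content to exercise the finder
random_repeaty_seq <- function(len = 200) {
  bases <- c("A", "C", "G", "T")
  parts <- character(0)
  total <- 0
  while (total < len) {
    if (stats::runif(1) < 0.4) {
      unit <- paste(sample(bases, sample(1:4, 1), replace = TRUE),
                    collapse = "")
      part <- strrep(unit, sample(3:15, 1))
    } else {
      part <- paste(sample(c(bases, "N"), sample(5:30, 1), replace = TRUE,
                           prob = c(rep(0.245, 4), 0.02)), collapse = "")
    }
    parts <- c(parts, part)
    total <- total + nchar(part)
  }
  substr(paste(parts, collapse = ""), 1, len)
}

# --- SNP columns ----------------------------------------------------------

oracle_variant_columns <- function(alignment) {
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  out <- list()
  for (col in seq_len(ncol(mat))) {
    counts <- vapply(c("A", "C", "G", "T"),
                     function(b) sum(mat[, col] == b), integer(1))
    if (sum(counts >= 1) >= 2)
      out[[length(out) + 1]] <- data.frame(column = col - 1L,
                                           n_A = counts[["A"]],
                                           n_C = counts[["C"]],
                                           n_G = counts[["G"]],
                                           n_T = counts[["T"]])
  }
  if (length(out) == 0)
    return(data.frame(column = integer(0), n_A = integer(0),
                      n_C = integer(0), n_G = integer(0), n_T = integer(0)))
  do.call(rbind, out)
}

random_alignment <- function(nrow = 8, ncol = 40) {
  ref <- sample(c("A", "C", "G", "T"), ncol, replace = TRUE)
  rows <- vapply(seq_len(nrow), function(i) {
    r <- ref
    mut <- stats::runif(ncol) < 0.08
    r[mut] <- sample(c("A", "C", "G", "T", "N", "-"), sum(mut), replace = TRUE)
    paste(r, collapse = "")
  }, character(1))
  rows
}

# --- misc fixtures --------------------------------------------------------

random_read <- function(n = 60, q_lo = 2, q_hi = 45) {
  q <- sample(q_lo:q_hi, n, replace = TRUE)
  list(bases = paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                     collapse = ""),
       quals = q)
}
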