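#' Convert a Phred quality score to an error probability
#'
#' `e = 10^(-Q/10)`: Q30 is an error probability of 0.001, Q17 about 0.02,
#' Q0 is 1 (no information).
#'
#' @param q Phred score(s), >= 0.
#' @return error probability in (0, 1].
#' @export
phred_to_error <- function(q) {
  if (any(q < 0)) stop("Phred scores must be >= 0")
  10^(-q / 10)
}

#' Trimming policy
#'
#' Lucy-style trimming parameters. The bracket rule strips low-quality bases
#' from both ends until the terminal retained bases each have error
#' probability at or below `bracket_max_error` (default 0.001, i.e. Q30).
#' The window rule then keeps the longest contiguous stretch in which every
#' sliding window of each configured length has mean error at or below its
#' threshold (default one window: length 10, max mean error 0.063). A
#' trimmed read passes quality control when some contiguous run of at least
#' `pass_min_len` kept bases has mean Phred >= `pass_min_avg_q`
#' (defaults: 100 bases at mean Q20).
#'
#' @param bracket_max_error per-base error bound for the bracket rule.
#' @param windows list of `c(length, max_avg_error)` pairs.
#' @param pass_min_len,pass_min_avg_q passing-read rule.
#' @return a `trim_policy` list.
#' @export
trim_policy <- function(bracket_max_error = 0.001,
                        windows = list(c(10, 0.063)),
                        pass_min_len = 100, pass_min_avg_q = 20) {
  stopifnot(bracket_max_error > 0, bracket_max_error <= 1,
            all(vapply(windows, function(w) w[1] >= 1 && w[2] > 0 && w[2] <= 1,
                       logical(1))))
  structure(list(bracket_max_error = bracket_max_error, windows = windows,
                 pass_min_len = pass_min_len, pass_min_avg_q = pass_min_avg_q),
            class = "trim_policy")
}

#' Bracket trim: strip low-quality bases from both ends
#'
#' Returns the 0-based half-open interval obtained by stripping the longest
#' prefix and suffix such that the first and last retained bases each have
#' error probability <= `max_error`. The interval may be empty.
#'
#' @param errors per-base error probabilities.
#' @param max_error per-base bound.
#' @return integer `c(start, end)`, 0-based half-open.
#' @export
bracket_trim <- function(errors, max_error) {
  stopifnot(length(errors) >= 1)
  ok <- which(errors <= max_error)
  if (length(ok) == 0) return(c(0L, 0L))
  c(ok[1] - 1L, ok[length(ok)])
}

#' Window trim: longest interval passing all sliding-window error bounds
#'
#' Finds the longest contiguous interval in which every window of each
#' configured length has mean error <= its bound; intervals shorter than a
#' window length must satisfy that bound over the whole interval. Ties are
#' broken leftmost. Returns a 0-based half-open interval (possibly empty).
#'
#' @param errors per-base error probabilities.
#' @param windows list of `c(length, max_avg_error)` pairs.
#' @return integer `c(start, end)`, 0-based half-open.
#' @export
window_trim <- function(errors, windows = list(c(10, 0.063))) {
  longest_valid_interval(errors, windows, endpoint_ok = NULL)
}

# longest (leftmost on ties) interval in which every configured window rule
# holds and, when endpoint_ok is given, whose first and last base are both
# endpoint-eligible; returns 0-based half-open c(start, end)
longest_valid_interval <- function(errors, windows, endpoint_ok = NULL) {
  n <- length(errors)
  stopifnot(n >= 1)
  if (is.null(endpoint_ok)) endpoint_ok <- rep(TRUE, n)
  cs <- c(0, cumsum(errors))
  wlen <- vapply(windows, `[`, numeric(1), 1)
  wmax <- vapply(windows, `[`, numeric(1), 2)
  Lmax <- max(wlen)

  best <- c(0L, 0L)  # empty
  take <- function(s, e) {  # longest wins; leftmost on ties
    if ((e - s) > (best[2] - best[1])) best <<- c(s, e)
  }

  # prev_ok[e]: largest endpoint-eligible index <= e (0 if none)
  prev_ok <- cummax(ifelse(endpoint_ok, seq_len(n), 0L))

  # intervals of length >= Lmax: every spec's windows must all pass.
  if (n >= Lmax) {
    # nb[w, s]: largest 1-based inclusive end e such that all spec-w windows
    # inside [s, e] pass; windows s..(e - L + 1) must be ok, so with b the
    # first failing window start >= s, e <= b + L - 2.
    nb <- matrix(NA_integer_, nrow = length(windows), ncol = n + 1L)
    for (w in seq_along(windows)) {
      L <- wlen[w]
      nw <- n - L + 1L
      means <- (cs[(L + 1):(n + 1)] - cs[1:nw]) / L
      bad_at <- rep.int(nw + 1L, nw + 1L)  # sentinel: no bad window ahead
      nxt <- nw + 1L
      for (s in nw:1) {
        if (means[s] > wmax[w]) nxt <- s
        bad_at[s] <- nxt
      }
      nb[w, 1:(nw + 1L)] <- bad_at + L - 2L
    }
    for (s in 1:(n - Lmax + 1L)) {
      if (!endpoint_ok[s]) next
      e_lim <- min(n, nb[, s])       # 1-based inclusive end limit
      if (e_lim < s) next
      e <- prev_ok[e_lim]            # snap to an eligible endpoint
      if (e >= s && e - s + 1L >= Lmax) take(s - 1L, e)
    }
  }

  # intervals shorter than Lmax: whole-interval mean must satisfy every spec
  # whose window is longer than the interval; specs with window <= interval
  # length impose their sliding windows.
  max_short <- min(n, Lmax - 1L)
  if (max_short >= 1) {
    for (len in max_short:1) {
      if ((best[2] - best[1]) >= len) break
      for (s in 1:(n - len + 1L)) {
        if (!endpoint_ok[s] || !endpoint_ok[s + len - 1L]) next
        ok <- TRUE
        for (w in seq_along(windows)) {
          L <- wlen[w]
          if (len < L) {
            if ((cs[s + len] - cs[s]) / len > wmax[w]) { ok <- FALSE; break }
          } else {
            ws <- s:(s + len - L)
            if (any((cs[ws + L] - cs[ws]) / L > wmax[w])) { ok <- FALSE; break }
          }
        }
        if (ok) { take(s - 1L, s - 1L + len); break }
      }
    }
  }
  as.integer(best)
}

#' Trim a read: bracket rule composed with the window rule
#'
#' Returns the longest contiguous interval (leftmost on ties) in which the
#' first and last retained bases each meet the bracket error bound (the
#' bracket rule applied at the final clear range's ends) and every sliding
#' window meets its mean-error bound. This composition is idempotent, and
#' raising any quality score can never shrink the kept interval, since
#' lowering an error probability preserves the validity of every interval.
#' Coordinates are 0-based half-open; the interval may be empty.
#'
#' @param bases nucleotide string.
#' @param quals integer Phred scores, one per base.
#' @param policy a [trim_policy()].
#' @return integer `c(start, end)` kept interval.
#' @export
trim_read <- function(bases, quals, policy = trim_policy()) {
  stopifnot(nchar(bases) == length(quals))
  errors <- phred_to_error(quals)
  longest_valid_interval(errors, policy$windows,
                         endpoint_ok = errors <= policy$bracket_max_error)
}

#' Passing-read rule
#'
#' TRUE iff some contiguous run of at least `pass_min_len` kept bases has
#' mean Phred >= `pass_min_avg_q`. Uses the kept interval's qualities.
#'
#' @param quals integer Phred scores of the kept bases.
#' @param policy a [trim_policy()].
#' @return logical.
#' @export
passes_quality <- function(quals, policy = trim_policy()) {
  m <- policy$pass_min_len
  n <- length(quals)
  if (n < m) return(FALSE)
  # exists interval of length >= m with mean >= q0
  # <=> exists e >= m with P[e] - min_{j <= e-m} P[j] >= 0, P = cumsum(q - q0)
  P <- c(0, cumsum(quals - policy$pass_min_avg_q))
  prefmin <- cummin(P[1:(n - m + 1L)])
  any(P[(m + 1L):(n + 1L)] - prefmin >= 0)
}

#' Trim a table of reads and report pass/fail
#'
#' @param reads data.frame with `read_id`, `bases` and list-column `quals`.
#' @param policy a [trim_policy()].
#' @return data.frame (read_id, raw_len, kept_start, kept_end, passed);
#'   coordinates 0-based half-open.
#' @export
trim_reads <- function(reads, policy = trim_policy()) {
  n <- nrow(reads)
  ks <- integer(n); ke <- integer(n); ok <- logical(n)
  for (i in seq_len(n)) {
    kept <- trim_read(reads$bases[i], reads$quals[[i]], policy)
    ks[i] <- kept[1]; ke[i] <- kept[2]
    ok[i] <- if (ke[i] > ks[i])
      passes_quality(reads$quals[[i]][(ks[i] + 1):ke[i]], policy) else FALSE
  }
  data.frame(read_id = reads$read_id,
             raw_len = nchar(reads$bases),
             kept_start = ks, kept_end = ke, passed = ok,
             stringsAsFactors = FALSE)
}

#' Fraction of reads passing quality control
#'
#' @param passed logical vector (or a trim report data.frame with a
#'   `passed` column).
#' @return fraction passed in [0, 1].
#' @export
pass_rate <- function(passed) {
  if (is.data.frame(passed)) passed <- passed$passed
  if (length(passed) == 0) stop("empty read collection")
  mean(passed)
}
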