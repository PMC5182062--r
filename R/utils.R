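# Internal string / interval helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz))
    out[nz] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x[nz])))
  out
}

# base probabilities for a given GC fraction (AT split equally, GC split equally)
base_probs <- function(gc_fraction) {
  at <- (1 - gc_fraction) / 2
  gc <- gc_fraction / 2
  c(A = at, C = gc, G = gc, T = at)
}

random_dna <- function(n, gc_fraction = 0.221) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE, prob = base_probs(gc_fraction)),
        collapse = "")
}

# longest common prefix length of a (from position `from_a`) and b (from `from_b`),
# capped at `max_len`; binary search over substring equality keeps this fast for
# read-scale strings.
lcp_len <- function(a, b, from_a = 1L, from_b = 1L, max_len = NULL) {
  na <- nchar(a) - from_a + 1L
  nb <- nchar(b) - from_b + 1L
  hi <- min(na, nb)
  if (!is.null(max_len)) hi <- min(hi, max_len)
  if (hi <= 0L) return(0L)
  if (substr(a, from_a, from_a + hi - 1L) == substr(b, from_b, from_b + hi - 1L))
    return(as.integer(hi))
  lo <- 0L  # invariant: prefix of length lo matches, length hi does not
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (substr(a, from_a, from_a + mid - 1L) == substr(b, from_b, from_b + mid - 1L))
      lo <- mid else hi <- mid
  }
  as.integer(lo)
}

# longest common suffix length of a (ending at to_a) and b (ending at to_b)
lcs_len <- function(a, b, to_a = nchar(a), to_b = nchar(b), max_len = NULL) {
  hi <- min(to_a, to_b)
  if (!is.null(max_len)) hi <- min(hi, max_len)
  if (hi <= 0L) return(0L)
  if (substr(a, to_a - hi + 1L, to_a) == substr(b, to_b - hi + 1L, to_b))
    return(as.integer(hi))
  lo <- 0L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (substr(a, to_a - mid + 1L, to_a) == substr(b, to_b - mid + 1L, to_b))
      lo <- mid else hi <- mid
  }
  as.integer(lo)
}

# left-normalize a removal interval [d1, d2] (1-based inclusive) on sequence
# `seq`: removing [d1-1, d2-1] yields the same product iff seq[d1-1] == seq[d2].
left_normalize_removal <- function(seq, d1, d2) {
  while (d1 > 1L && substr(seq, d1 - 1L, d1 - 1L) == substr(seq, d2, d2)) {
    d1 <- d1 - 1L
    d2 <- d2 - 1L
  }
  c(d1, d2)
}

# maximal terminal direct repeat of removal [d1, d2]: longest common prefix of
# the removed sequence and the sequence immediately following the removal.
removal_tdr <- function(seq, d1, d2, cap = 10L) {
  t <- lcp_len(seq, seq, from_a = d1, from_b = d2 + 1L,
               max_len = min(cap, d2 - d1 + 1L))
  if (t == 0L) "" else substr(seq, d1, d1 + t - 1L)
}

delete_intervals <- function(seq, starts, ends) {
  if (length(starts) == 0L) return(seq)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  keep_start <- c(1L, ends + 1L)
  keep_end <- c(starts - 1L, nchar(seq))
  pieces <- substring(seq, keep_start, keep_end)
  paste(pieces[keep_end >= keep_start], collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
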