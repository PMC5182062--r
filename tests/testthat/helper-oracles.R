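# Independent brute-force oracles used to cross-check the implementation.

# exhaustive split-read caller: aligns every read by exact substring search
# (gregexpr) over all possible split points, with no seeding heuristics.
oracle_split_junctions <- function(reads, ref, min_piece = 25L,
                                   min_spanning = 3L) {
  w <- nchar(reads$seq[1])
  find_all <- function(pat, subject) {
    hits <- gregexpr(pat, subject, fixed = TRUE)[[1]]
    as.integer(hits[hits > 0])
  }
  rc1 <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  junctions <- list()
  for (i in seq_len(nrow(reads))) {
    for (seq in unique(c(reads$seq[i], rc1(reads$seq[i])))) {
      if (length(find_all(seq, ref))) next  # full match: not a split read
      removals <- character(0)
      for (s in min_piece:(w - min_piece)) {
        pre <- substr(seq, 1L, s)
        suf <- substr(seq, s + 1L, w)
        for (p in find_all(pre, ref)) {
          for (q in find_all(suf, ref)) {
            d1 <- p + s
            d2 <- q - 1L
            if (d2 < d1) next
            # left-normalize
            while (d1 > 1L &&
                   substr(ref, d1 - 1L, d1 - 1L) == substr(ref, d2, d2)) {
              d1 <- d1 - 1L; d2 <- d2 - 1L
            }
            removals <- c(removals, paste(d1, d2))
          }
        }
      }
      removals <- unique(removals)
      if (length(removals) == 1L)
        junctions[[length(junctions) + 1L]] <- removals
    }
  }
  if (!length(junctions)) return(character(0))
  tab <- table(unlist(junctions))
  names(tab)[tab >= min_spanning]
}

# exhaustive reverse-complement grouping of AT-only k-mers by pairwise
# comparison (no canonicalization shortcut)
oracle_rc_classes <- function(k) {
  words <- do.call(paste0, expand.grid(rep(list(c("A", "T")), k),
                                       stringsAsFactors = FALSE))
  rc1 <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  groups <- list()
  for (wd in words) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (any(groups[[gi]] == wd | groups[[gi]] == rc1(wd))) {
        groups[[gi]] <- unique(c(groups[[gi]], wd))
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- wd
  }
  groups
}

# random binary tree over n tips (ape), for parsimony cross-checks
random_tip_tree <- function(n) ape::rtree(n, rooted = TRUE, br = NULL)
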