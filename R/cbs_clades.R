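# Detection and clustering of duplicated Cbs-containing segments.
#
# Each Cbs contributes a nominal 415 bp segment (the motif plus 200 bp of
# flank on each side; closely spaced Cbs merge). All segment pairs are
# aligned locally (BLASTN-like scoring: match +1, mismatch -2, gap open 5,
# extend 2) through Biostrings::pairwiseAlignment; expectations follow the
# Karlin-Altschul form E = m n 2^-bits with lambda solved from the scoring
# scheme. Absolute E-values are not comparable to NCBI BLAST's; clustering
# thresholds are calibrated against a randomized-flank null instead of
# literal published cutoffs.

#' Extract Cbs-centred segments from a genome
#'
#' One segment per Cbs: the 15-bp motif plus `flank` bp on each side
#' (nominal 415 bp). Cbs whose starts are closer than `2 * flank` merge
#' into a single segment spanning all of them with outer flanks; segments
#' truncated by a chromosome end are flagged.
#'
#' @param genome named character vector.
#' @param hits genome-wide Cbs hits ([scan_cbs_genome()]).
#' @param flank flank width (default 200).
#' @return data.frame of segments: `segment_id`, `chromosome`, `start`,
#'   `end`, `sequence`, `cbs_offsets` (comma-joined 1-based offsets of each
#'   contained motif), `contained_cbs_count`, `truncated`.
#' @export
extract_segments <- function(genome, hits, flank = 200L) {
  rows <- list()
  for (chrom in unique(hits$chromosome)) {
    h <- hits[hits$chromosome == chrom, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    L <- nchar(genome[[chrom]])
    gap_prev <- c(Inf, diff(h$start))
    grp <- cumsum(gap_prev >= (CBS_LENGTH + 2L * flank))
    for (g in unique(grp)) {
      sub <- h[grp == g, , drop = FALSE]
      s <- max(1L, sub$start[1] - flank)
      e <- min(L, sub$end[nrow(sub)] + flank)
      rows[[length(rows) + 1L]] <- data.frame(
        segment_id = sprintf("%s_%d", chrom, sub$start[1]),
        chromosome = chrom, start = s, end = e,
        sequence = substr(genome[[chrom]], s, e),
        cbs_offsets = paste(sub$start - s + 1L, collapse = ","),
        contained_cbs_count = nrow(sub),
        truncated = (sub$start[1] - flank < 1L) | (sub$end[nrow(sub)] + flank > L),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Karlin-Altschul lambda for match/mismatch scoring over uniform base
# frequencies: solves sum_ij p_i p_j exp(lambda s_ij) = 1.
ka_lambda <- function(match = 1, mismatch = -2) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10))$root
}

align_pair <- function(seq1, seq2, off1, off2, submat, lambda, K,
                       gap_open, gap_ext, match, both_strands = TRUE) {
  best <- NULL
  for (orient in c("+", if (both_strands) "-")) {
    subj <- if (orient == "+") seq2 else revcomp(seq2)
    pa <- Biostrings::pairwiseAlignment(
      seq1, subj, type = "local", substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_ext)
    if (is.null(best) || Biostrings::score(pa) > best$score)
      best <- list(pa = pa, orient = orient, score = Biostrings::score(pa))
  }
  pa <- best$pa
  s <- best$score
  bits <- (lambda * s - log(K)) / log(2)
  ev <- nchar(seq1) * nchar(seq2) * 2^(-bits)
  pr <- c(IRanges::start(Biostrings::pattern(pa)),
          IRanges::end(Biostrings::pattern(pa)))
  sr <- c(IRanges::start(Biostrings::subject(pa)),
          IRanges::end(Biostrings::subject(pa)))
  if (best$orient == "-")  # subject range back to forward coordinates
    sr <- c(nchar(seq2) - sr[2] + 1L, nchar(seq2) - sr[1] + 1L)
  cbs_in <- function(off, rng)
    any(off >= rng[1] & (off + CBS_LENGTH - 1L) <= rng[2])
  list(score = s, bits = bits, evalue = ev,
       norm_score = s / (match * min(nchar(seq1), nchar(seq2))),
       cbs_aligned = cbs_in(off1, pr) && cbs_in(off2, sr),
       orientation = best$orient)
}

#' All-pairs local alignment of Cbs segments
#'
#' Aligns every unordered segment pair locally with affine gaps
#' (+1/-2, gap open 5, extend 2), computing the raw score, a bit score
#' `(lambda S - ln K) / ln 2`, an expectation `m n 2^-bits`, and the
#' normalized score (raw score over the self-score of the shorter segment).
#' An edge is retained for clustering only if the two Cbs motifs fall
#' inside the aligned regions (`cbs_aligned`).
#'
#' @param segments [extract_segments()] output.
#' @param match,mismatch,gap_open,gap_ext scoring scheme.
#' @param K Karlin-Altschul K (default 0.1; the absolute scale is
#'   calibrated against the randomized null, not against NCBI).
#' @param both_strands also try the reverse-complement orientation.
#' @return data.frame of edges: `seg1`, `seg2`, `score`, `bits`, `evalue`,
#'   `norm_score`, `cbs_aligned`, `orientation`.
#' @export
align_all_pairs <- function(segments, match = 1, mismatch = -2,
                            gap_open = 5, gap_ext = 2, K = 0.1,
                            both_strands = TRUE) {
  n <- nrow(segments)
  if (n < 2L) stop("need at least two segments")
  lambda <- ka_lambda(match, mismatch)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch)
  seqs <- segments$sequence
  offs <- lapply(strsplit(segments$cbs_offsets, ","), as.integer)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- align_pair(seqs[i], seqs[j], offs[[i]], offs[[j]], submat,
                      lambda, K, gap_open, gap_ext, match, both_strands)
      rows[[length(rows) + 1L]] <- data.frame(
        seg1 = segments$segment_id[i], seg2 = segments$segment_id[j],
        score = r$score, bits = r$bits, evalue = r$evalue,
        norm_score = r$norm_score, cbs_aligned = r$cbs_aligned,
        orientation = r$orientation, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Randomize the flanks of a Cbs segment
#'
#' Shuffles each non-Cbs region of the segment independently, preserving
#' its base composition exactly; the Cbs motifs themselves are kept intact.
#' Used to build the empirical null for clustering-threshold calibration
#' (three independent sets per the original protocol; vary `seed`).
#'
#' @param segment one row of [extract_segments()] output.
#' @param seed integer seed.
#' @return the segment row with a shuffled `sequence`.
#' @export
randomize_flanks <- function(segment, seed = 1L) {
  set.seed(seed)
  seq <- strsplit(segment$sequence, "")[[1]]
  offs <- as.integer(strsplit(segment$cbs_offsets, ",")[[1]])
  keep <- rep(FALSE, length(seq))
  for (o in offs) keep[o:(o + CBS_LENGTH - 1L)] <- TRUE
  bounds <- c(0L, which(keep), length(seq) + 1L)
  # shuffle each maximal non-Cbs run separately
  runs <- split(which(!keep), cumsum(keep)[!keep])
  for (r in runs) if (length(r) > 1L) seq[r] <- sample(seq[r])
  segment$sequence <- paste(seq, collapse = "")
  segment$segment_id <- paste0(segment$segment_id, "_shuffled")
  segment
}

#' Calibrate a clustering expectation threshold on the randomized null
#'
#' Aligns every original segment against its flank-randomized controls
#' (one control per seed) and returns the smallest null expectation
#' divided by `margin` as the recommended clustering threshold, together
#' with the null expectation distribution.
#'
#' @param segments [extract_segments()] output.
#' @param seeds integer seeds, one control set each (default 1:3).
#' @param margin safety factor below the best null expectation.
#' @param ... passed to [align_all_pairs()].
#' @return list: `threshold`, `null_evalues`.
#' @export
calibrate_threshold <- function(segments, seeds = 1:3, margin = 100,
                                match = 1, mismatch = -2, gap_open = 5,
                                gap_ext = 2, K = 0.1) {
  lambda <- ka_lambda(match, mismatch)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch)
  offs <- lapply(strsplit(segments$cbs_offsets, ","), as.integer)
  n <- nrow(segments)
  null_ev <- numeric(0)
  for (sd in seeds) {
    ctrl <- lapply(seq_len(n), function(i)
      randomize_flanks(segments[i, ], seed = sd + 101L * i))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      r <- align_pair(segments$sequence[i], ctrl[[j]]$sequence,
                      offs[[i]], offs[[j]], submat, lambda, K,
                      gap_open, gap_ext, match)
      if (r$cbs_aligned) null_ev <- c(null_ev, r$evalue)
    }
  }
  list(threshold = if (length(null_ev)) min(null_ev) / margin else 1e-18,
       null_evalues = null_ev)
}

#' Threshold clustering of segment similarity edges
#'
#' Connected components over edges whose expectation passes `threshold`
#' (and whose Cbs motifs aligned); components of size >= 2 are clades.
#'
#' @param edges [align_all_pairs()] output.
#' @param threshold expectation cutoff (default 1e-18; see
#'   [calibrate_threshold()]).
#' @return object of class `clade_set`: list of clades (character vectors
#'   of segment ids), with `method` attribute `"threshold-components"`.
#' @export
cluster_threshold <- function(edges, threshold = 1e-18) {
  keep <- edges[edges$cbs_aligned & edges$evalue <= threshold, , drop = FALSE]
  if (!nrow(keep))
    return(structure(list(), method = "threshold-components",
                     class = "clade_set"))
  g <- igraph::graph_from_data_frame(keep[, c("seg1", "seg2")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  clades <- split(names(comp$membership), comp$membership)
  clades <- clades[lengths(clades) >= 2L]
  structure(unname(lapply(clades, sort)), method = "threshold-components",
            class = "clade_set")
}

#' Markov-cluster-style clustering on normalized similarity scores
#'
#' Builds the symmetric normalized-score matrix over segments (self loops
#' at 1), then iterates expansion (matrix squaring) and inflation
#' (elementwise power + column renormalization) to convergence;
#' deterministic for a given inflation and iteration cap.
#'
#' @param edges [align_all_pairs()] output.
#' @param inflation inflation exponent (default 2).
#' @param min_norm_score drop edges below this normalized score.
#' @param max_iter iteration cap; non-convergence gives a warning.
#' @param tol convergence tolerance on the matrix change.
#' @return `clade_set` with method `"score-ratio-mcl"` (clades of size >= 2).
#' @export
cluster_score_ratio <- function(edges, inflation = 2, min_norm_score = 0.1,
                                max_iter = 100L, tol = 1e-8) {
  keep <- edges[edges$cbs_aligned & edges$norm_score >= min_norm_score, ,
                drop = FALSE]
  ids <- sort(unique(c(edges$seg1, edges$seg2)))
  n <- length(ids)
  M <- diag(1, n); dimnames(M) <- list(ids, ids)
  if (nrow(keep)) {
    M[cbind(keep$seg1, keep$seg2)] <- keep$norm_score
    M[cbind(keep$seg2, keep$seg1)] <- keep$norm_score
  }
  normalize <- function(m) sweep(m, 2L, pmax(colSums(m), 1e-300), "/")
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- normalize((M %*% M)^inflation)
    if (max(abs(M2 - M)) < tol) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged)
    warning("score-ratio clustering did not converge within ", max_iter,
            " iterations; reporting the partition at the cap")
  # attractor-based partition: connect i to attractors with mass
  adj <- M > 1e-6
  g <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
  comp <- igraph::components(g)
  clades <- split(ids, comp$membership)
  clades <- clades[lengths(clades) >= 2L]
  structure(unname(lapply(clades, sort)), method = "score-ratio-mcl",
            class = "clade_set")
}

#' @export
print.clade_set <- function(x, ...) {
  cat(sprintf("Clade set (%s): %d clade(s)\n", attr(x, "method"), length(x)))
  for (i in seq_along(x))
    cat(sprintf("  clade %d (%d): %s\n", i, length(x[[i]]),
                paste(x[[i]], collapse = ", ")))
  invisible(x)
}
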