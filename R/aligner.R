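# Built-in exact seed-and-extend aligner for simulated (error-free) data.
# Real data enters through SAM/PAF readers; the rearrangement logic operates
# downstream of alignment in either case, mirroring the use of external
# aligners for the genuine assemblies.
#
# align_reads(): full-length exact placement via matchPDict, with a
#   31-mer prefix/suffix seed + maximal ungapped extension fallback that
#   yields split (junction-spanning) and clipped (broken) read records.
# align_assemblies(): sampled 31-mer anchors chained on shared diagonals
#   into maximal colinear blocks between two assemblies.

SEED_LENGTH <- 31L

match_starts <- function(pd, subject) {
  m <- Biostrings::matchPDict(pd, subject)
  s <- Biostrings::startIndex(m)
  s[vapply(s, is.null, logical(1))] <- list(integer(0))
  s
}

#' Align reads to a reference by exact seed-and-extend
#'
#' Places each read on the reference: reads matching end-to-end at a unique
#' location become full alignments (multi-site matches are kept as a single
#' primary placement flagged ambiguous); unplaced reads are seeded with
#' their 31-mer prefix and suffix and extended maximally without gaps.
#' A read whose two pieces land colinearly on one reference sequence becomes
#' a split record with a left-normalized deletion interval (the removal that
#' reconciles read and reference); a read extending from only one seed
#' becomes a clipped record whose breakpoint marks where the alignment
#' stops mid-read.
#'
#' @param reads data.frame with `name` and `seq` (constant read length), as
#'   produced by [simulate_reads()].
#' @param reference named character vector of reference sequences.
#' @param min_piece minimum extended length for a split/clipped piece (bp).
#' @return list of data.frames: `full` (read, chrom, start, end, strand,
#'   ambiguous), `split` (read, chrom, strand, junction_start, junction_end,
#'   prefix_len, suffix_len, overlap), `clipped` (read, chrom, strand,
#'   position, direction, matched_len).
#' @export
align_reads <- function(reads, reference, min_piece = 25L) {
  stopifnot(nrow(reads) > 0L)
  w <- unique(nchar(reads$seq))
  if (length(w) != 1L) stop("reads must have constant length")
  if (w < SEED_LENGTH) stop("reads shorter than the 31-bp seed")
  chroms <- names(reference)
  subjects <- lapply(reference, Biostrings::DNAString)
  n <- nrow(reads)

  # candidate placements via 31-mer prefix seeds (both orientations in one
  # dictionary), verified by vectorized substring comparison
  seqs <- list(`+` = reads$seq, `-` = revcomp(reads$seq))
  pre <- c(substr(seqs[["+"]], 1L, SEED_LENGTH),
           substr(seqs[["-"]], 1L, SEED_LENGTH))
  pd_pre <- Biostrings::PDict(Biostrings::DNAStringSet(pre))
  # per-read verified full placements and per-orientation prefix anchors
  hit_read <- integer(0); hit_chrom <- character(0)
  hit_start <- integer(0); hit_strand <- character(0)
  anchor <- list()  # unverified prefix anchors for the split/clip phase
  for (ci in seq_along(chroms)) {
    st <- match_starts(pd_pre, subjects[[ci]])
    nh <- lengths(st)
    idx <- rep(seq_along(nh), nh)
    pos <- unlist(st, use.names = FALSE)
    if (!length(pos)) next
    strand <- ifelse(idx > n, "-", "+")
    ri <- ifelse(idx > n, idx - n, idx)
    rs <- character(length(ri))
    for (sd in c("+", "-")) {
      sel <- strand == sd
      if (any(sel)) rs[sel] <- seqs[[sd]][ri[sel]]
    }
    ok <- pos + w - 1L <= nchar(reference[[ci]]) &
      substring(reference[[ci]], pos, pos + w - 1L) == rs
    hit_read <- c(hit_read, ri[ok])
    hit_chrom <- c(hit_chrom, rep(chroms[ci], sum(ok)))
    hit_start <- c(hit_start, pos[ok])
    hit_strand <- c(hit_strand, strand[ok])
    anchor[[ci]] <- data.frame(ri = ri[!ok], pos = pos[!ok],
                               strand = strand[!ok],
                               chrom = chroms[ci], stringsAsFactors = FALSE)
  }
  hit_count <- tabulate(hit_read, nbins = n)
  first <- !duplicated(hit_read)
  prim <- data.frame(read = hit_read[first], chrom = hit_chrom[first],
                     start = hit_start[first], strand = hit_strand[first],
                     stringsAsFactors = FALSE)
  full <- data.frame(read = reads$name[prim$read],
                     chrom = prim$chrom,
                     start = prim$start,
                     end = prim$start + w - 1L,
                     strand = prim$strand,
                     ambiguous = hit_count[prim$read] > 1L,
                     stringsAsFactors = FALSE)

  # ---- seed the leftovers -------------------------------------------------
  placed <- hit_count > 0L
  rest <- which(!placed)
  split_rows <- list(); clip_rows <- list()
  if (length(rest)) {
    nr <- length(rest)
    cand_seqs <- c(seqs[["+"]][rest], seqs[["-"]][rest])
    cand_strand <- rep(c("+", "-"), each = nr)
    cand_idx <- rep(rest, 2L)
    pre_hits <- vector("list", 2L * nr)
    suf_hits <- vector("list", 2L * nr)
    pre_chrom <- vector("list", 2L * nr)
    suf_chrom <- vector("list", 2L * nr)
    # prefix anchors were already located above
    rest_lookup <- integer(n)
    rest_lookup[rest] <- seq_len(nr)
    for (ci in seq_along(chroms)) {
      a <- anchor[[ci]]
      if (is.null(a) || !nrow(a)) next
      a <- a[a$ri %in% rest, , drop = FALSE]
      for (k in seq_len(nrow(a))) {
        i <- rest_lookup[a$ri[k]] + if (a$strand[k] == "-") nr else 0L
        pre_hits[[i]] <- c(pre_hits[[i]], a$pos[k])
        pre_chrom[[i]] <- c(pre_chrom[[i]], a$chrom[k])
      }
    }
    suf <- substr(cand_seqs, w - SEED_LENGTH + 1L, w)
    pd_suf <- Biostrings::PDict(Biostrings::DNAStringSet(suf))
    for (ci in seq_along(chroms)) {
      sts <- match_starts(pd_suf, subjects[[ci]])
      for (i in which(lengths(sts) > 0L)) {
        suf_hits[[i]] <- c(suf_hits[[i]], sts[[i]])
        suf_chrom[[i]] <- c(suf_chrom[[i]], rep(chroms[ci], length(sts[[i]])))
      }
    }
    for (i in seq_along(cand_seqs)) {
      np <- length(pre_hits[[i]]); ns <- length(suf_hits[[i]])
      if (np == 0L && ns == 0L) next
      rseq <- cand_seqs[i]
      rd <- reads$name[cand_idx[i]]
      strand <- cand_strand[i]
      if (np == 1L && ns == 1L && pre_chrom[[i]][1] == suf_chrom[[i]][1]) {
        chrom <- pre_chrom[[i]][1]
        ref <- reference[[chrom]]
        p <- pre_hits[[i]][1]
        qe <- suf_hits[[i]][1] + SEED_LENGTH - 1L
        a <- lcp_len(rseq, ref, from_a = 1L, from_b = p, max_len = w)
        b <- lcs_len(rseq, ref, to_a = w, to_b = qe, max_len = w)
        d1 <- p + a
        d2 <- qe + a - w
        if (a + b >= w && d2 >= d1 && a >= min_piece && b >= min_piece &&
            qe > p) {
          norm <- left_normalize_removal(ref, d1, d2)
          split_rows[[length(split_rows) + 1L]] <- data.frame(
            read = rd, chrom = chrom, strand = strand,
            junction_start = norm[1], junction_end = norm[2],
            prefix_len = a, suffix_len = b, overlap = a + b - w,
            stringsAsFactors = FALSE)
          next
        }
      }
      if (np == 1L && ns == 0L) {
        chrom <- pre_chrom[[i]][1]
        p <- pre_hits[[i]][1]
        a <- lcp_len(rseq, reference[[chrom]], from_a = 1L, from_b = p,
                     max_len = w)
        if (a >= min_piece && a < w)
          clip_rows[[length(clip_rows) + 1L]] <- data.frame(
            read = rd, chrom = chrom, strand = strand,
            position = p + a - 1L, direction = "right", matched_len = a,
            stringsAsFactors = FALSE)
      } else if (ns == 1L && np == 0L) {
        chrom <- suf_chrom[[i]][1]
        qe <- suf_hits[[i]][1] + SEED_LENGTH - 1L
        b <- lcs_len(rseq, reference[[chrom]], to_a = w, to_b = qe,
                     max_len = w)
        if (b >= min_piece && b < w)
          clip_rows[[length(clip_rows) + 1L]] <- data.frame(
            read = rd, chrom = chrom, strand = strand,
            position = qe - b + 1L, direction = "left", matched_len = b,
            stringsAsFactors = FALSE)
      }
    }
  }
  empty_split <- data.frame(read = character(0), chrom = character(0),
                            strand = character(0), junction_start = integer(0),
                            junction_end = integer(0), prefix_len = integer(0),
                            suffix_len = integer(0), overlap = integer(0))
  empty_clip <- data.frame(read = character(0), chrom = character(0),
                           strand = character(0), position = integer(0),
                           direction = character(0), matched_len = integer(0))
  list(full = full,
       split = if (length(split_rows)) do.call(rbind, split_rows) else empty_split,
       clipped = if (length(clip_rows)) do.call(rbind, clip_rows) else empty_clip)
}

#' Per-base coverage of a reference by full-length read placements
#'
#' @param full the `full` component of [align_reads()] output (primary
#'   placements; duplicates collapse unless `keep_duplicates`).
#' @param ref_lengths named integer vector of reference lengths.
#' @param keep_duplicates keep reads with identical start/end/strand.
#' @return named list of integer coverage vectors.
#' @export
read_coverage <- function(full, ref_lengths, keep_duplicates = TRUE) {
  if (!keep_duplicates)
    full <- full[!duplicated(full[, c("chrom", "start", "end", "strand")]), ]
  out <- lapply(names(ref_lengths), function(chrom) {
    b <- full[full$chrom == chrom, , drop = FALSE]
    if (!nrow(b)) return(integer(ref_lengths[[chrom]]))
    as.integer(IRanges::coverage(IRanges::IRanges(b$start, b$end),
                                 width = ref_lengths[[chrom]]))
  })
  stats::setNames(out, names(ref_lengths))
}

#' Remove duplicate alignment records
#'
#' Collapses alignments with identical reference interval and strand,
#' emulating duplicate-read removal before broken-read site validation.
#'
#' @param aln a data.frame with `chrom`, `strand` and coordinate columns.
#' @export
dedupe_alignments <- function(aln) {
  cols <- intersect(c("chrom", "strand", "start", "end", "position",
                      "direction", "matched_len", "junction_start",
                      "junction_end", "prefix_len", "suffix_len"),
                    names(aln))
  aln[!duplicated(aln[, cols]), , drop = FALSE]
}

#' Align two assemblies into colinear blocks
#'
#' Samples 31-mer anchors along each germline (query) sequence, locates them
#' exactly in the somatic (subject) assembly on both strands, chains anchors
#' sharing a diagonal into runs, and extends each run maximally without
#' gaps. Blocks are exact matches, so identity is 100 by construction.
#'
#' @param mic named character vector, germline side (block `mic_*` fields).
#' @param mac named character vector, somatic side (block `mac_*` fields).
#' @param step anchor sampling stride (bp).
#' @param min_block minimum reported block length (bp).
#' @return data.frame of blocks: `mic_id`, `mic_start`, `mic_end`, `mac_id`,
#'   `mac_start`, `mac_end`, `strand`, `length`, `identity`.
#' @export
align_assemblies <- function(mic, mac, step = 50L, min_block = 100L) {
  rows <- list()
  mac_subjects <- lapply(mac, Biostrings::DNAString)
  for (q in names(mic)) {
    qseq <- mic[[q]]
    L <- nchar(qseq)
    if (L < SEED_LENGTH) next
    pos <- unique(c(seq(1L, L - SEED_LENGTH + 1L, by = step),
                    L - SEED_LENGTH + 1L))
    anchors <- substring(qseq, pos, pos + SEED_LENGTH - 1L)
    keep <- !grepl("N", anchors, fixed = TRUE)
    pos <- pos[keep]; anchors <- anchors[keep]
    if (!length(pos)) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(anchors))
    pd_rc <- Biostrings::PDict(Biostrings::DNAStringSet(revcomp(anchors)))
    rcq <- revcomp(qseq)
    for (s in names(mac)) {
      sseq <- mac[[s]]
      for (strand in c("+", "-")) {
        st <- match_starts(if (strand == "+") pd else pd_rc, mac_subjects[[s]])
        nh <- lengths(st)
        if (!any(nh > 0L)) next
        qpos <- rep(pos, nh)
        spos <- unlist(st, use.names = FALSE)
        # diagonal: constant for colinear anchors
        diag <- if (strand == "+") spos - qpos
          else spos + qpos  # rc anchor start in subject + query anchor start
        o <- order(diag, qpos)
        qpos <- qpos[o]; spos <- spos[o]; diag <- diag[o]
        run_id <- cumsum(c(TRUE, diff(diag) != 0L |
                             diff(qpos) > (step * 3L)))
        for (r in unique(run_id)) {
          sel <- run_id == r
          q1 <- min(qpos[sel]); q2 <- max(qpos[sel]) + SEED_LENGTH - 1L
          if (strand == "+") {
            s1 <- min(spos[sel]); s2 <- max(spos[sel]) + SEED_LENGTH - 1L
            # maximal ungapped extension at both ends
            ext_l <- lcs_len(qseq, sseq, to_a = q1 - 1L, to_b = s1 - 1L)
            ext_r <- lcp_len(qseq, sseq, from_a = q2 + 1L, from_b = s2 + 1L)
            q1 <- q1 - ext_l; s1 <- s1 - ext_l
            q2 <- q2 + ext_r; s2 <- s2 + ext_r
          } else {
            # anchor at query qpos maps to subject [sp, sp+30] reversed:
            # subject start corresponds to query end
            s1 <- min(spos[sel]); s2 <- max(spos[sel]) + SEED_LENGTH - 1L
            q1r <- min(qpos[sel]); q2r <- max(qpos[sel]) + SEED_LENGTH - 1L
            # rc-query coordinates: position i in rc == L - i + 1 in query
            rq1 <- L - q2r + 1L; rq2 <- L - q1r + 1L
            ext_l <- lcs_len(rcq, sseq, to_a = rq1 - 1L, to_b = s1 - 1L)
            ext_r <- lcp_len(rcq, sseq, from_a = rq2 + 1L, from_b = s2 + 1L)
            rq1 <- rq1 - ext_l; s1 <- s1 - ext_l
            rq2 <- rq2 + ext_r; s2 <- s2 + ext_r
            q1 <- L - rq2 + 1L; q2 <- L - rq1 + 1L
          }
          len <- q2 - q1 + 1L
          if (len >= min_block)
            rows[[length(rows) + 1L]] <- data.frame(
              mic_id = q, mic_start = q1, mic_end = q2,
              mac_id = s, mac_start = s1, mac_end = s2,
              strand = strand, length = len, identity = 100,
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mic_id = character(0), mic_start = integer(0),
               mic_end = integer(0), mac_id = character(0),
               mac_start = integer(0), mac_end = integer(0),
               strand = character(0), length = integer(0),
               identity = numeric(0))
  # merge blocks that extension made overlapping duplicates
  key <- paste(out$mic_id, out$mac_id, out$strand, out$mic_start, out$mic_end,
               out$mac_start, out$mac_end)
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
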