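# Derivation of the somatic (MAC) genome from a simulated germline genome:
# chromosome breakage at every Cbs, loss of the Cbs and its immediate flanks,
# telomere addition, IES excision with optional endpoint jitter, and omission
# of non-maintained segments.

telomere_seq <- function() paste(rep(TELOMERE_UNIT, TELOMERE_COPIES),
                                 collapse = "")

# zero-inflated discretized-Gaussian endpoint jitter
jitter_offsets <- function(n, cfg) {
  stay <- stats::runif(n) < cfg$excision_stay_prob
  d <- as.integer(round(stats::rnorm(n, 0, cfg$excision_endpoint_sd)))
  d[stay] <- 0L
  if (cfg$excision_endpoint_sd == 0) d[] <- 0L
  d
}

#' Derive the somatic genome from a simulated germline genome
#'
#' Applies the programmed rearrangements recorded in `truth` to the germline
#' sequences: each inter-Cbs segment becomes a somatic contig with the Cbs
#' and a 5-25 bp flank removed on each broken side, telomere repeats
#' (`CCCCAA` units) appended at breakage ends, all internal eliminated
#' sequences excised (one terminal-direct-repeat copy retained, endpoints
#' jittered by a zero-inflated discretized Gaussian), and non-maintained
#' segments omitted from the output but kept in the truth ledger.
#'
#' @param mic named character vector of germline chromosome sequences.
#' @param truth `rearrangement_truth` from [generate_mic_genome()].
#' @param config the [sim_config()] used for generation (controls jitter and
#'   telomere offsets).
#' @return list with `mac` (named character vector of somatic contigs) and
#'   `truth` updated with `mac_segments` and realized excision endpoints
#'   (`realized_start`/`realized_end` columns of `ies_intervals`).
#' @export
derive_mac_genome <- function(mic, truth, config = truth$config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  tel <- telomere_seq()
  seg_rows <- list()
  mac <- character(0)
  ies <- truth$ies_intervals
  ies$realized_start <- rep(NA_integer_, nrow(ies))
  ies$realized_end <- rep(NA_integer_, nrow(ies))

  for (chrom in names(mic)) {
    seq <- mic[[chrom]]
    L <- nchar(seq)
    cbs <- truth$cbs_sites[truth$cbs_sites$chromosome == chrom, , drop = FALSE]
    cbs <- cbs[order(cbs$start), , drop = FALSE]
    # sanity: no IES may span a Cbs
    ci <- ies[ies$chromosome == chrom, , drop = FALSE]
    for (j in seq_len(nrow(cbs)))
      if (any(ci$start <= cbs$start[j] & ci$end >= cbs$start[j]))
        stop("truth inconsistency: an IES spans a Cbs on ", chrom)
    bounds_start <- c(1L, cbs$end + 1L)
    bounds_end <- c(cbs$start - 1L, L)
    nmc <- truth$nmc_intervals[truth$nmc_intervals$chromosome == chrom, ,
                               drop = FALSE]
    for (s in seq_along(bounds_start)) {
      seg_start <- bounds_start[s]; seg_end <- bounds_end[s]
      left_cbs <- s > 1L          # bounded by a Cbs on the left?
      right_cbs <- s <= nrow(cbs)
      maintained <- !any(nmc$start == seg_start & nmc$end == seg_end)
      left_trim <- if (left_cbs)
        sample(config$telomere_offset_range[1]:config$telomere_offset_range[2], 1L)
      else 0L
      right_trim <- if (right_cbs)
        sample(config$telomere_offset_range[1]:config$telomere_offset_range[2], 1L)
      else 0L
      core_start <- seg_start + left_trim
      core_end <- seg_end - right_trim
      if (core_start > core_end)
        stop("segment on ", chrom, " too short for telomere-addition trimming")

      in_seg <- which(ies$chromosome == chrom &
                        ies$junction_start > core_start &
                        ies$junction_end < core_end)
      rs <- re <- integer(0)
      if (length(in_seg)) {
        dl <- jitter_offsets(length(in_seg), config)
        dr <- jitter_offsets(length(in_seg), config)
        rs <- ies$junction_start[in_seg] + dl
        re <- ies$junction_end[in_seg] + dr
        # truncate so realized removals stay inside the segment core and
        # endpoints never cross each other
        rs <- pmax(rs, core_start + 1L)
        re <- pmin(re, core_end - 1L)
        bad <- rs > re
        rs[bad] <- ies$junction_start[in_seg][bad]
        re[bad] <- ies$junction_end[in_seg][bad]
        ies$realized_start[in_seg] <- rs
        ies$realized_end[in_seg] <- re
      }
      contig_id <- sprintf("mac_%s_seg%02d", sub("^mic_", "", chrom), s)
      if (maintained) {
        core <- substr(seq, core_start, core_end)
        if (length(rs)) {
          o <- order(rs)
          if (any(re[o][-length(o)] >= rs[o][-1L]))
            stop("realized excisions overlap on ", chrom)
          core <- delete_intervals(core, rs - core_start + 1L, re - core_start + 1L)
        }
        mac[contig_id] <- paste0(if (left_cbs) tel else "", core,
                                 if (right_cbs) tel else "")
      }
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        mic_chromosome = chrom, mic_start = seg_start, mic_end = seg_end,
        mac_contig = contig_id, maintained = maintained,
        left_trim = left_trim, right_trim = right_trim,
        telomere_left = maintained && left_cbs,
        telomere_right = maintained && right_cbs,
        n_ies = length(in_seg), stringsAsFactors = FALSE)
    }
  }
  truth$ies_intervals <- ies
  truth$mac_segments <- do.call(rbind, seg_rows)
  rownames(truth$mac_segments) <- NULL
  list(mac = mac, truth = truth)
}

#' Exact length bookkeeping between germline and somatic genomes
#'
#' Computes the residual of the conservation identity
#' `len(MIC) - len(MAC, telomeres excluded) = sum(realized excised lengths)
#' + sum(Cbs + trimmed flanks) + sum(non-maintained segment lengths)`.
#' A correctly derived pair returns exactly zero.
#'
#' @param mic,mac named character vectors of sequences.
#' @param truth updated truth from [derive_mac_genome()].
#' @return integer residual (0 for an exact derivation).
#' @export
conservation_identity <- function(mic, mac, truth) {
  seg <- truth$mac_segments
  if (is.null(seg)) stop("truth has no somatic derivation; run derive_mac_genome()")
  tel_len <- nchar(telomere_seq())
  mac_len <- sum(nchar(mac)) -
    tel_len * sum(seg$telomere_left + seg$telomere_right)
  excised <- truth$ies_intervals
  excised <- excised[!is.na(excised$realized_start), , drop = FALSE]
  excised_len <- sum(excised$realized_end - excised$realized_start + 1L)
  cbs_len <- CBS_LENGTH * nrow(truth$cbs_sites)
  trim_len <- sum(seg$left_trim + seg$right_trim)
  nmc_seg <- seg[!seg$maintained, , drop = FALSE]
  nmc_len <- sum(nmc_seg$mic_end - nmc_seg$mic_start + 1L)
  # non-maintained segments contribute their whole length; their trims and
  # IESs never left the genome separately
  nmc_internal <- 0L
  if (nrow(nmc_seg)) {
    nmc_internal <- sum(nmc_seg$left_trim + nmc_seg$right_trim)
    for (j in seq_len(nrow(nmc_seg))) {
      inside <- excised$chromosome == nmc_seg$mic_chromosome[j] &
        excised$realized_start >= nmc_seg$mic_start[j] &
        excised$realized_end <= nmc_seg$mic_end[j]
      excised_len <- excised_len -
        sum(excised$realized_end[inside] - excised$realized_start[inside] + 1L)
    }
  }
  as.integer(sum(nchar(mic)) - mac_len -
               (excised_len + cbs_len + trim_len - nmc_internal + nmc_len))
}

#' Fragment a genome into scaffold-like pieces
#'
#' Cuts each chromosome at random positions to emulate an unfinished scaffold
#' assembly, for exercising cross-assembly tiling. Cut points avoid planted
#' eliminated regions, Cbs sites, and duplicated flanks when `truth` is
#' given, so each fragment end lies in unique somatic-destined sequence.
#'
#' @param genome named character vector.
#' @param n_fragments total number of fragments to produce (>= chromosomes).
#' @param truth optional `rearrangement_truth` for cut-point avoidance.
#' @param seed integer seed.
#' @param min_fragment minimum fragment length (bp).
#' @return list with `fragments` (named character vector, shuffled order and
#'   random orientation) and `layout` data frame (fragment, chromosome,
#'   start, end, orientation).
#' @export
fragment_genome <- function(genome, n_fragments, truth = NULL, seed = 1L,
                            min_fragment = 5000L) {
  set.seed(seed)
  n_chr <- length(genome)
  stopifnot(n_fragments >= n_chr)
  extra <- n_fragments - n_chr
  cuts_per <- diff(round(seq(0, extra, length.out = n_chr + 1L)))
  rows <- list()
  for (i in seq_along(genome)) {
    chrom <- names(genome)[i]
    L <- nchar(genome[[i]])
    ncut <- cuts_per[i]
    forbidden <- IRanges::IRanges(start = integer(0), end = integer(0))
    if (!is.null(truth)) {
      ies <- truth$ies_intervals[truth$ies_intervals$chromosome == chrom, ]
      cbs <- truth$cbs_sites[truth$cbs_sites$chromosome == chrom, ]
      nmc <- truth$nmc_intervals[truth$nmc_intervals$chromosome == chrom, ]
      # margins exceed the 1 kb block-acceptance length so that every
      # fragment terminus carries a full-length unique terminal alignment
      m <- 1200L
      forbidden <- IRanges::reduce(c(
        IRanges::IRanges(ies$start - m, ies$end + m),
        IRanges::IRanges(cbs$start - m, cbs$end + m),
        if (nrow(nmc)) IRanges::IRanges(nmc$start - m, nmc$end + m)
        else IRanges::IRanges()))
    }
    cuts <- integer(0)
    tries <- 0L
    while (length(cuts) < ncut && tries < 2000L) {
      cand <- sample(seq(min_fragment, L - min_fragment), 1L)
      ok <- !any(IRanges::overlapsAny(IRanges::IRanges(cand, cand), forbidden)) &&
        (length(cuts) == 0L || min(abs(cuts - cand)) >= min_fragment)
      if (ok) cuts <- c(cuts, cand)
      tries <- tries + 1L
    }
    if (length(cuts) < ncut)
      stop("could not place ", ncut, " cut points on ", chrom)
    b <- c(0L, sort(cuts), L)
    for (j in seq_len(length(b) - 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = chrom, start = b[j] + 1L, end = b[j + 1L],
        stringsAsFactors = FALSE)
  }
  layout <- do.call(rbind, rows)
  layout <- layout[sample(nrow(layout)), ]
  layout$fragment <- sprintf("scaffold%03d", seq_len(nrow(layout)))
  layout$orientation <- sample(c("+", "-"), nrow(layout), replace = TRUE)
  frags <- stats::setNames(vapply(seq_len(nrow(layout)), function(j) {
    s <- substr(genome[[layout$chromosome[j]]], layout$start[j], layout$end[j])
    if (layout$orientation[j] == "-") revcomp(s) else s
  }, character(1)), layout$fragment)
  rownames(layout) <- NULL
  list(fragments = frags, layout = layout[, c("fragment", "chromosome",
                                              "start", "end", "orientation")])
}
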