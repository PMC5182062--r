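# Breakage maps (inter-Cbs segments), non-maintained chromosome detection,
# and deletion-based centromere mapping.

#' Build a breakage map from Cbs hits
#'
#' Enumerates the inter-Cbs segments of a chromosome: the prospective somatic
#' chromosomes. Segments tile the chromosome (Cbs themselves excluded);
#' terminal segments are bounded by a chromosome end on one side.
#'
#' @param chromosome_length chromosome length in bp (or the sequence itself).
#' @param hits [scan_cbs()] hits for that chromosome.
#' @return object of class `breakage_map`: data.frame of segments with
#'   `chromosome`, `start`, `end`, `length`, `left_cbs`, `right_cbs` (row
#'   indices into `attr(,"hits")`, NA at chromosome ends), `type`
#'   (`terminal` or `internal`).
#' @export
breakage_map <- function(chromosome_length, hits) {
  if (is.character(chromosome_length) && nchar(chromosome_length[1]) > 20L)
    chromosome_length <- nchar(chromosome_length)
  chrom <- if (nrow(hits)) hits$chromosome[1] else "chr"
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  n <- nrow(hits)
  starts <- c(1L, hits$end + 1L)
  ends <- c(hits$start - 1L, as.integer(chromosome_length))
  seg <- data.frame(
    chromosome = chrom, start = starts, end = ends,
    length = ends - starts + 1L,
    left_cbs = c(NA_integer_, seq_len(n)),
    right_cbs = c(seq_len(n), NA_integer_),
    stringsAsFactors = FALSE)
  seg$type <- ifelse(is.na(seg$left_cbs) | is.na(seg$right_cbs),
                     "terminal", "internal")
  structure(seg, hits = hits, class = c("breakage_map", "data.frame"))
}

#' Detect non-maintained chromosomes from somatic-presence evidence
#'
#' A non-maintained chromosome (NMC) is an internal inter-Cbs segment that is
#' absent from the somatic genome: its fraction of bases covered by somatic
#' alignment falls below `max_covered_fraction`. Terminal segments are never
#' classified (the definition requires two bounding Cbs).
#'
#' @param bmap a [breakage_map()].
#' @param coverage per-base somatic alignment coverage of the chromosome:
#'   a numeric vector or `Rle` of chromosome length, or a precomputed
#'   per-segment covered fraction (length `nrow(bmap)`).
#' @param max_covered_fraction segments covered below this fraction count as
#'   absent (default 0.05).
#' @return the segments classified as NMCs, with a `covered_fraction` column.
#' @export
detect_nmcs <- function(bmap, coverage, max_covered_fraction = 0.05) {
  if (missing(coverage) || is.null(coverage))
    stop("somatic presence evidence (coverage) is required")
  if (length(coverage) == nrow(bmap) && is.numeric(coverage) &&
      all(coverage <= 1 + 1e-9)) {
    frac <- as.numeric(coverage)
  } else {
    cov <- as.numeric(coverage)
    if (length(cov) < max(bmap$end))
      stop("coverage vector shorter than the chromosome")
    frac <- vapply(seq_len(nrow(bmap)), function(i)
      mean(cov[bmap$start[i]:bmap$end[i]] > 0), numeric(1))
  }
  out <- as.data.frame(bmap)
  out$covered_fraction <- frac
  out[out$type == "internal" & out$covered_fraction < max_covered_fraction, ,
      drop = FALSE]
}

#' Per-base somatic coverage of germline chromosomes from alignment blocks
#'
#' @param blocks alignment block table (see [read_paf()] /
#'   [align_assemblies()]) with germline coordinates in `mic_start`/`mic_end`.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param min_length,min_identity block filters (defaults follow the
#'   cross-assembly alignment criteria: length > 1000 bp, identity > 95%).
#' @return named list of integer coverage vectors.
#' @export
mac_alignment_coverage <- function(blocks, chrom_lengths,
                                   min_length = 1000L, min_identity = 95) {
  blocks <- blocks[blocks$length >= min_length &
                     blocks$identity >= min_identity, , drop = FALSE]
  out <- lapply(names(chrom_lengths), function(chrom) {
    b <- blocks[blocks$mic_id == chrom, , drop = FALSE]
    cov <- integer(chrom_lengths[[chrom]])
    if (nrow(b)) {
      ir <- IRanges::IRanges(b$mic_start, b$mic_end)
      cov <- as.integer(IRanges::coverage(ir, width = chrom_lengths[[chrom]]))
    }
    cov
  })
  stats::setNames(out, names(chrom_lengths))
}

#' Map a centromere from viable arm-deletion strains
#'
#' Mitotically stable arm deletions never extend into the centromere; the
#' centromere is therefore bracketed by the most centromere-proximal Cbs
#' removed by a viable deletion on each arm. If no deletion touches a Cbs on
#' an arm, the innermost Cbs on that side of the chromosome midpoint is used.
#'
#' @param bmap a [breakage_map()] (its `hits` attribute provides Cbs
#'   positions), or a data.frame of Cbs hits with `start` positions.
#' @param deletions data.frame of viable deletions with `start`, `end` and
#'   `arm` (`"L"` or `"R"`).
#' @param chromosome_length total chromosome length (defaults to the last
#'   segment end of `bmap`).
#' @return list with `left_cbs`, `right_cbs` (hit rows), `cen_start`,
#'   `cen_end`, `cen_length`, `cen_midpoint`, `chromosome_midpoint`.
#' @export
map_centromere <- function(bmap, deletions,
                           chromosome_length = max(bmap$end)) {
  hits <- attr(bmap, "hits") %||% bmap
  hits <- hits[order(hits$start), , drop = FALSE]
  if (nrow(hits) < 2L) stop("centromere mapping needs Cbs on both arms")
  if (any(deletions$start <= 1 & deletions$end >= chromosome_length))
    stop("a deletion covers the whole chromosome; no viable centromere interval")
  covered <- function(pos, dels)
    vapply(pos, function(p) any(dels$start <= p & dels$end >= p), logical(1))
  delL <- deletions[deletions$arm == "L", , drop = FALSE]
  delR <- deletions[deletions$arm == "R", , drop = FALSE]
  mid <- chromosome_length / 2
  covL <- which(covered(hits$start, delL))
  covR <- which(covered(hits$start, delR))
  li <- if (length(covL)) max(covL) else max(which(hits$start < mid))
  ri <- if (length(covR)) min(covR) else min(which(hits$start > mid))
  if (li >= ri) stop("deletion evidence leaves no centromere interval")
  cen_start <- hits$start[li]
  cen_end <- hits$start[ri]
  list(left_cbs = hits[li, , drop = FALSE],
       right_cbs = hits[ri, , drop = FALSE],
       cen_start = cen_start, cen_end = cen_end,
       cen_length = cen_end - cen_start,
       cen_midpoint = (cen_start + cen_end) / 2,
       chromosome_midpoint = chromosome_length / 2)
}
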