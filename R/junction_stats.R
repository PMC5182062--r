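# Junction characterization: terminal direct repeats (TDRs), their
# composition and reverse-complement pattern groupings, excision-endpoint
# variability across a progeny pool, and the coding-region IES screen.

#' Detect the terminal direct repeat of an excision junction
#'
#' The TDR is the maximal sequence present at both termini of the eliminated
#' interval in the germline and once at the excision site in the soma:
#' equivalently, the longest common prefix of the removed sequence and the
#' sequence immediately following the removal (leftmost-placement
#' convention; capped at `cap` bp). When a somatic contig and the excision
#' offset are supplied, consistency of the somatic junction is verified.
#'
#' @param mic germline chromosome sequence.
#' @param junction_start,junction_end removed interval (1-based inclusive).
#' @param mac optional somatic sequence containing the excision site.
#' @param mac_junction optional position in `mac` of the last base before
#'   the excision site.
#' @param cap maximum TDR length searched (default 10).
#' @return list: `tdr` (possibly empty string), `tdr_length`.
#' @export
detect_tdr <- function(mic, junction_start, junction_end, mac = NULL,
                       mac_junction = NULL, cap = 10L) {
  if (junction_end < junction_start || junction_start < 1L ||
      junction_end > nchar(mic))
    stop("junction coordinates inconsistent with the sequence")
  tdr <- removal_tdr(mic, junction_start, junction_end, cap = cap)
  if (!is.null(mac) && !is.null(mac_junction)) {
    t <- nchar(tdr)
    want <- paste0(substr(mic, junction_start - 5L, junction_start - 1L),
                   substr(mic, junction_end + 1L, junction_end + t + 5L))
    got <- substr(mac, mac_junction - 4L, mac_junction + t + 5L)
    if (want != got)
      stop("somatic sequence inconsistent with the stated junction")
  }
  list(tdr = tdr, tdr_length = nchar(tdr))
}

#' TDR composition by length class, with logo input windows
#'
#' Computes the A+T fraction of terminal direct repeats per length class
#' 0..4 and extracts the junction windows used for sequence logos: the TDR
#' (or the junction point for class 0) plus `flank` bases on either side on
#' the germline, somatic-destined side left, eliminated side right.
#'
#' @param records IES records with `chromosome`, `junction_start`,
#'   `junction_end`, `tdr` columns.
#' @param mic named character vector of germline sequences.
#' @param flank flank width per side (default 6).
#' @return list: `at_fraction` (named by class 0..4), `windows` (list of
#'   character vectors of aligned windows per class).
#' @export
tdr_composition <- function(records, mic = NULL, flank = 6L) {
  if (!nrow(records)) stop("no records")
  lens <- nchar(records$tdr)
  at_fraction <- sapply(0:4, function(k) {
    s <- records$tdr[lens == k]
    if (k == 0L || !length(s)) return(NA_real_)
    ch <- unlist(strsplit(s, ""))
    mean(ch %in% c("A", "T"))
  })
  names(at_fraction) <- as.character(0:4)
  windows <- NULL
  if (!is.null(mic)) {
    windows <- lapply(0:4, function(k) {
      r <- records[lens == k, , drop = FALSE]
      if (!nrow(r)) return(character(0))
      vapply(seq_len(nrow(r)), function(i) {
        seq <- mic[[r$chromosome[i]]]
        s <- r$junction_start[i]
        substr(seq, s - flank, s + k + flank - 1L)
      }, character(1))
    })
    names(windows) <- as.character(0:4)
  }
  list(at_fraction = at_fraction, windows = windows)
}

#' Reverse-complement equivalence classes of AT-only k-mers
#'
#' Enumerates all `2^k` strings over {A,T} of length `k`, groups them with
#' their reverse complements (10/4/3 classes for k = 4/3/2), and tallies
#' observed TDRs per class, including zero-observation classes.
#'
#' @param records optional IES records with a `tdr` column to tally.
#' @param k word length, 2..4.
#' @return data.frame with `class` (slash-joined members), `members`,
#'   `count`, `frequency`.
#' @export
tdr_pattern_groups <- function(records = NULL, k) {
  if (!(k %in% 2:4)) stop("k must be 2, 3 or 4")
  words <- do.call(paste0, expand.grid(rep(list(c("A", "T")), k),
                                       stringsAsFactors = FALSE))
  canon <- vapply(words, function(wd) {
    rc <- revcomp(wd)
    if (rc < wd) rc else wd
  }, character(1), USE.NAMES = FALSE)
  classes <- split(words, canon)
  tally <- integer(length(classes))
  if (!is.null(records)) {
    obs <- records$tdr[nchar(records$tdr) == k]
    obs <- obs[grepl("^[AT]+$", obs)]
    for (i in seq_along(classes))
      tally[i] <- sum(obs %in% classes[[i]])
  }
  out <- data.frame(
    class = vapply(classes, function(m) paste(sort(unique(m)), collapse = "/"),
                   character(1)),
    members = lengths(lapply(classes, unique)),
    count = tally,
    stringsAsFactors = FALSE)
  out$frequency <- if (sum(tally) > 0) tally / sum(tally) else 0
  rownames(out) <- NULL
  out
}

#' Excision-endpoint variability relative to the parental junction
#'
#' Validates observed endpoint pairs (>= `min_reads` identical independent
#' reads), measures each validated junction's distance to the parental
#' junction as the sum of its left and right breakpoint offsets, and
#' aggregates a read-weighted distance histogram across sites.
#'
#' @param observed data.frame of observed endpoints per site
#'   (`ies_id`, `obs_start`, `obs_end`, `n_reads`), e.g. from
#'   [simulate_progeny_junctions()].
#' @param parental data.frame with `ies_id`, `junction_start`,
#'   `junction_end` (the parental reference; sites missing from it are
#'   skipped and counted).
#' @param min_reads validation threshold (default 3).
#' @return list: `profiles` (per-site `n_distinct_junctions`,
#'   `fraction_identical`), `distance_histogram` (read-weighted counts by
#'   distance), `fraction_identical`, `fraction_within_20bp`,
#'   `modal_distance`, `n_skipped`.
#' @export
excision_variability <- function(observed, parental, min_reads = 3L) {
  par_idx <- match(observed$ies_id, parental$ies_id)
  skipped <- unique(observed$ies_id[is.na(par_idx)])
  obs <- observed[!is.na(par_idx), , drop = FALSE]
  par_idx <- par_idx[!is.na(par_idx)]
  valid <- obs$n_reads >= min_reads
  obs <- obs[valid, , drop = FALSE]; par_idx <- par_idx[valid]
  if (!nrow(obs)) stop("no validated endpoints")
  dist <- abs(obs$obs_start - parental$junction_start[par_idx]) +
    abs(obs$obs_end - parental$junction_end[par_idx])
  h <- tapply(obs$n_reads, dist, sum)
  profiles <- do.call(rbind, lapply(split(seq_len(nrow(obs)), obs$ies_id),
    function(ix) data.frame(
      ies_id = obs$ies_id[ix[1]],
      n_distinct_junctions = length(ix),
      fraction_identical = sum(obs$n_reads[ix][dist[ix] == 0]) /
        sum(obs$n_reads[ix]),
      stringsAsFactors = FALSE)))
  rownames(profiles) <- NULL
  w <- obs$n_reads
  list(profiles = profiles,
       distance_histogram = h,
       fraction_identical = sum(w[dist == 0]) / sum(w),
       fraction_within_20bp = sum(w[dist <= 20]) / sum(w),
       modal_distance = as.integer(names(h)[which.max(h)]),
       n_skipped = length(skipped))
}

#' Screen coding-region IESs for piggyBac-like features
#'
#' Tests every exonic IES for the four features of precisely excised
#' coding-region elements: a TTAA terminal direct repeat, a terminal
#' inverted repeat internal to the TTAA matching the CACTTT consensus
#' (at most `max_mismatch` mismatches on each end), and exceptional
#' shortness (below the `length_quantile` quantile of all record lengths).
#'
#' @param records IES records with `context`, `tdr`, `length`, junction
#'   coordinates.
#' @param mic germline sequences.
#' @param max_mismatch allowed mismatches to the CACTTT consensus.
#' @param length_quantile shortness threshold quantile (default 0.01).
#' @return data.frame of exonic records with logical feature columns
#'   `tdr_ttaa`, `tir_cactt`, `short`.
#' @export
coding_ies_screen <- function(records, mic, max_mismatch = 2L,
                              length_quantile = 0.01) {
  ex <- records[records$context == "exonic", , drop = FALSE]
  if (!nrow(ex)) return(cbind(ex, tdr_ttaa = logical(0),
                              tir_cactt = logical(0), short = logical(0)))
  thr <- stats::quantile(records$length, length_quantile)
  cons <- strsplit("CACTTT", "")[[1]]
  mism <- function(s) {
    if (nchar(s) != 6L) return(Inf)
    sum(strsplit(s, "")[[1]] != cons)
  }
  ex$tdr_ttaa <- ex$tdr == "TTAA"
  ex$tir_cactt <- vapply(seq_len(nrow(ex)), function(i) {
    seq <- mic[[ex$chromosome[i]]]
    t <- nchar(ex$tdr[i])
    left <- substr(seq, ex$junction_start[i] + t, ex$junction_start[i] + t + 5L)
    right <- revcomp(substr(seq, ex$junction_end[i] - 5L, ex$junction_end[i]))
    mism(left) <= max_mismatch && mism(right) <= max_mismatch
  }, logical(1))
  ex$short <- ex$length <= thr
  ex
}
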