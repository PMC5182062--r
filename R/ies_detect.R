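# Internal eliminated sequence (IES) detection by three complementary
# alignment-evidence methods, and merging into a high-confidence set.
#
# Method 1: somatic reads aligned to the germline -- split reads whose two
#   colinear pieces bracket the eliminated interval.
# Method 2: germline reads aligned to the somatic assembly -- 'broken' reads
#   whose alignments terminate mid-read at the residual excision site.
# Method 3: germline<->somatic cross-assembly alignment -- adjacent colinear
#   blocks separated by a much larger gap on the germline side.

#' Split-read IES candidates (method 1)
#'
#' Groups split somatic-read alignments by their left-normalized deletion
#' interval on the germline; an interval supported by at least
#' `min_spanning` reads whose interior somatic-read coverage stays below
#' `max_internal_coverage` becomes a candidate. Candidates whose junctions
#' fall in assembly-gap (`N`) runs are rejected.
#'
#' @param aln [align_reads()] output for somatic reads vs the germline.
#' @param coverage per-base somatic read coverage of the germline
#'   ([read_coverage()]); required.
#' @param mic germline sequences (for the junction `N` check); optional.
#' @param min_spanning minimum spanning reads (default 3).
#' @param max_internal_coverage maximum mean somatic coverage inside the
#'   candidate (default 1.0).
#' @return data.frame of candidates: `chromosome`, `junction_start`,
#'   `junction_end`, `length`, `method`, `n_spanning`, `internal_coverage`,
#'   `junction_gap`.
#' @export
split_read_ies <- function(aln, coverage, mic = NULL, min_spanning = 3L,
                           max_internal_coverage = 1.0) {
  if (missing(coverage) || is.null(coverage))
    stop("a somatic-read coverage track over the germline is required")
  sp <- aln$split
  if (!nrow(sp)) return(empty_candidates())
  key <- paste(sp$chrom, sp$junction_start, sp$junction_end)
  groups <- split(sp, key)
  rows <- lapply(groups, function(g) {
    n <- length(unique(g$read))
    if (n < min_spanning) return(NULL)
    chrom <- g$chrom[1]
    d1 <- g$junction_start[1]; d2 <- g$junction_end[1]
    cov <- mean(coverage[[chrom]][d1:d2])
    if (cov >= max_internal_coverage) return(NULL)
    gap <- FALSE
    if (!is.null(mic)) {
      jbases <- paste0(substr(mic[[chrom]], d1, d1),
                       substr(mic[[chrom]], d2, d2))
      gap <- grepl("N", jbases, fixed = TRUE)
    }
    if (gap) return(NULL)
    data.frame(chromosome = chrom, junction_start = d1, junction_end = d2,
               length = d2 - d1 + 1L, method = 1L, n_spanning = n,
               internal_coverage = cov, junction_gap = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_candidates())
  out <- out[order(out$chromosome, out$junction_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(chromosome = character(0), junction_start = integer(0),
             junction_end = integer(0), length = integer(0),
             method = integer(0), n_spanning = integer(0),
             internal_coverage = numeric(0), junction_gap = logical(0))
}

#' Residual IES sites from broken germline reads (method 2)
#'
#' Clusters the breakpoints of germline reads whose alignment to the somatic
#' assembly terminates mid-read (single-linkage, `cluster_gap` bp). A
#' cluster is validated when it holds at least `min_total` broken reads with
#' at least one facing the site from each direction. The modal rightward-
#' and leftward-facing breakpoints usually overlap slightly; the overlap is
#' the terminal-direct-repeat evidence.
#'
#' @param aln [align_reads()] output for germline reads vs the somatic
#'   assembly (duplicates should be removed; see [dedupe_alignments()]).
#' @param min_total minimum broken reads per site (default 6).
#' @param cluster_gap breakpoint linkage distance (default 10 bp).
#' @return data.frame of sites: `mac_contig`, `left_mode`, `right_mode`,
#'   `overlap`, `n_broken`, `n_right_facing`, `n_left_facing`, `validated`.
#' @export
broken_read_sites <- function(aln, min_total = 6L, cluster_gap = 10L) {
  cl <- aln$clipped
  empty <- data.frame(mac_contig = character(0), left_mode = integer(0),
                      right_mode = integer(0), overlap = integer(0),
                      n_broken = integer(0), n_right_facing = integer(0),
                      n_left_facing = integer(0), validated = logical(0))
  if (is.null(cl) || !nrow(cl)) return(empty)
  rows <- list()
  for (contig in unique(cl$chrom)) {
    b <- cl[cl$chrom == contig, , drop = FALSE]
    b <- b[order(b$position), , drop = FALSE]
    cluster <- cumsum(c(TRUE, diff(b$position) > cluster_gap))
    for (k in unique(cluster)) {
      g <- b[cluster == k, , drop = FALSE]
      n_right <- sum(g$direction == "right")
      n_left <- sum(g$direction == "left")
      modal <- function(x) if (length(x)) as.integer(names(sort(
        table(x), decreasing = TRUE))[1]) else NA_integer_
      lm <- modal(g$position[g$direction == "right"])
      rm_ <- modal(g$position[g$direction == "left"])
      rows[[length(rows) + 1L]] <- data.frame(
        mac_contig = contig, left_mode = lm, right_mode = rm_,
        overlap = if (!is.na(lm) && !is.na(rm_)) lm - rm_ + 1L else NA_integer_,
        n_broken = nrow(g), n_right_facing = n_right, n_left_facing = n_left,
        validated = nrow(g) >= min_total && n_right >= 1L && n_left >= 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map validated residual sites to germline junction coordinates
#'
#' Locates each somatic residual site between the two cross-assembly blocks
#' that bracket it and converts the breakpoint pair into the germline
#' deletion interval (left-normalized when the germline sequence is given).
#'
#' @param sites validated rows from [broken_read_sites()].
#' @param blocks cross-assembly blocks ([align_assemblies()] or
#'   [read_paf()]), plus-strand colinear chains.
#' @param mic optional germline sequences for junction normalization.
#' @param tol maximum distance (bp) between a site breakpoint and the
#'   bracketing block ends (default 10).
#' @return candidate data.frame (`method = 2`) as in [split_read_ies()].
#' @export
residual_sites_to_candidates <- function(sites, blocks, mic = NULL, tol = 10L) {
  sites <- sites[sites$validated, , drop = FALSE]
  if (!nrow(sites)) return(empty_candidates())
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    b <- blocks[blocks$mac_id == s$mac_contig & blocks$strand == "+", ,
                drop = FALSE]
    b <- b[order(b$mac_start), , drop = FALSE]
    if (nrow(b) < 2L) next
    j <- which(abs(b$mac_end[-nrow(b)] - s$left_mode) <= tol &
                 abs(b$mac_start[-1L] - s$right_mode) <= tol)
    if (length(j) != 1L) next
    prev <- b[j, ]; nxt <- b[j + 1L, ]
    if (prev$mic_id != nxt$mic_id) next
    o <- prev$mac_end - nxt$mac_start + 1L  # TDR overlap between blocks
    d1 <- prev$mic_end + 1L - max(o, 0L)
    d2 <- nxt$mic_start - 1L
    if (d2 < d1) next
    if (!is.null(mic)) {
      norm <- left_normalize_removal(mic[[prev$mic_id]], d1, d2)
      d1 <- norm[1]; d2 <- norm[2]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chromosome = prev$mic_id, junction_start = d1, junction_end = d2,
      length = d2 - d1 + 1L, method = 2L, n_spanning = s$n_broken,
      internal_coverage = NA_real_, junction_gap = FALSE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_candidates())
  rownames(out) <- NULL
  out
}

#' Cross-assembly gap IES candidates (method 3)
#'
#' Walks colinear plus-strand block chains between one germline chromosome
#' and one somatic contig; an adjacent block pair whose germline-side gap
#' exceeds the somatic-side gap by more than `min_delta` bp marks an
#' eliminated interval. Inverted or rearranged pairs are skipped and
#' reported in the `skipped` attribute.
#'
#' @param blocks block table ([align_assemblies()] / [read_paf()]).
#' @param mic optional germline sequences for junction normalization.
#' @param min_delta minimum (germline gap - somatic gap) in bp (default 100).
#' @param min_block ignore blocks shorter than this (default 500 bp).
#' @return candidate data.frame (`method = 3`); junctions are exact when the
#'   somatic gap is non-positive, otherwise flagged `junction_gap`.
#' @export
assembly_gap_ies <- function(blocks, mic = NULL, min_delta = 100L,
                             min_block = 500L) {
  blocks <- blocks[blocks$length >= min_block, , drop = FALSE]
  rows <- list(); skipped <- 0L
  for (key in unique(paste(blocks$mic_id, blocks$mac_id))) {
    b <- blocks[paste(blocks$mic_id, blocks$mac_id) == key, , drop = FALSE]
    if (nrow(b) < 2L) next
    if (!all(b$strand == b$strand[1])) { skipped <- skipped + 1L; next }
    rev_chain <- b$strand[1] == "-"
    b <- b[order(b$mic_start), , drop = FALSE]
    for (j in seq_len(nrow(b) - 1L)) {
      prev <- b[j, ]; nxt <- b[j + 1L, ]
      mic_gap <- nxt$mic_start - prev$mic_end - 1L
      mac_gap <- if (rev_chain) prev$mac_start - nxt$mac_end - 1L
        else nxt$mac_start - prev$mac_end - 1L
      if (mic_gap < 0L) { skipped <- skipped + 1L; next }
      if (mic_gap - mac_gap <= min_delta) next
      d1 <- prev$mic_end + 1L
      d2 <- nxt$mic_start - 1L
      imprecise <- mac_gap > 0L || rev_chain
      if (!imprecise && !rev_chain) {
        d1 <- d1 + mac_gap  # mac_gap <= 0: overlap is the retained TDR
        if (!is.null(mic)) {
          norm <- left_normalize_removal(mic[[prev$mic_id]], d1, d2)
          d1 <- norm[1]; d2 <- norm[2]
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = prev$mic_id, junction_start = d1, junction_end = d2,
        length = d2 - d1 + 1L, method = 3L, n_spanning = NA_integer_,
        internal_coverage = NA_real_, junction_gap = imprecise,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_candidates()
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Merge method candidates into the high-confidence IES set
#'
#' Candidates from the three methods are merged when their junction pairs
#' agree within `merge_tol` (default 0: the high-confidence set demands
#' precise junctions). Records whose junctions fall in `N` runs, or that
#' carry a `junction_gap` flag, are demoted to provisional. The terminal
#' direct repeat of each record is read off the germline sequence.
#'
#' @param candidates list (or row-bound data.frame) of candidate sets from
#'   [split_read_ies()], [residual_sites_to_candidates()],
#'   [assembly_gap_ies()].
#' @param mic germline sequences.
#' @param merge_tol junction agreement tolerance in bp (default 0).
#' @return data.frame of IES records: junctions, `length`, `methods`
#'   (comma-joined), `tdr`, `confidence` (`high`/`provisional`).
#' @export
merge_high_confidence <- function(candidates, mic, merge_tol = 0L) {
  if (is.data.frame(candidates)) candidates <- list(candidates)
  all <- do.call(rbind, candidates)
  if (is.null(all) || !nrow(all))
    return(data.frame(chromosome = character(0), junction_start = integer(0),
                      junction_end = integer(0), length = integer(0),
                      methods = character(0), n_spanning = integer(0),
                      tdr = character(0), confidence = character(0)))
  all <- all[order(all$chromosome, all$junction_start, all$junction_end), ,
             drop = FALSE]
  merged <- list()
  used <- rep(FALSE, nrow(all))
  for (i in seq_len(nrow(all))) {
    if (used[i]) next
    same <- which(!used & all$chromosome == all$chromosome[i] &
                    abs(all$junction_start - all$junction_start[i]) <= merge_tol &
                    abs(all$junction_end - all$junction_end[i]) <= merge_tol)
    used[same] <- TRUE
    g <- all[same, , drop = FALSE]
    precise <- g[!g$junction_gap, , drop = FALSE]
    rep_row <- if (nrow(precise)) precise[1, ] else g[1, ]
    d1 <- rep_row$junction_start; d2 <- rep_row$junction_end
    chrom <- rep_row$chromosome
    tdr <- ""
    gapped <- all(g$junction_gap)
    if (!gapped && !is.null(mic[[chrom]])) {
      jb <- c(substr(mic[[chrom]], d1, d1), substr(mic[[chrom]], d2, d2))
      if (any(jb == "N")) gapped <- TRUE else
        tdr <- removal_tdr(mic[[chrom]], d1, d2)
    }
    merged[[length(merged) + 1L]] <- data.frame(
      chromosome = chrom, junction_start = d1, junction_end = d2,
      length = d2 - d1 + 1L,
      methods = paste(sort(unique(g$method)), collapse = ","),
      n_spanning = suppressWarnings(max(g$n_spanning, na.rm = TRUE)),
      tdr = tdr,
      confidence = if (gapped) "provisional" else "high",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, merged)
  out$n_spanning[!is.finite(out$n_spanning)] <- NA_integer_
  rownames(out) <- NULL
  out
}

#' Length statistics of an IES set
#'
#' @param records data.frame with a `length` column (bp).
#' @return list: `mean`, `median`, `min`, `max`, `fraction_1_to_10kb`, and
#'   `histogram` (counts over log2-spaced bins).
#' @export
length_stats <- function(records) {
  len <- records$length
  if (length(len) == 0L) stop("no records")
  edges <- 2^seq(floor(log2(max(min(len), 1))), ceiling(log2(max(len))))
  if (length(edges) < 2L) edges <- c(edges, edges * 2)
  h <- table(cut(len, breaks = unique(c(0, edges, Inf)), right = TRUE))
  list(mean = mean(len), median = stats::median(len),
       min = min(len), max = max(len),
       fraction_1_to_10kb = mean(len >= 1000 & len <= 10000),
       histogram = h)
}

#' Label IES genomic context from gene models
#'
#' An interval overlapping any coding exon base is `exonic`; otherwise one
#' contained in (or mostly covered by) an intron is `intronic`; otherwise
#' `intergenic`.
#'
#' @param records IES records with `chromosome`, `junction_start`,
#'   `junction_end` (or `start`/`end`).
#' @param genes gene table (`gene_id`, `chromosome`, `start`, `end`).
#' @param exons exon table (`gene_id`, `chromosome`, `start`, `end`).
#' @return `records` with a `context` column.
#' @export
classify_context <- function(records, genes, exons) {
  s <- records$junction_start %||% records$start
  e <- records$junction_end %||% records$end
  ctx <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    chrom <- records$chromosome[i]
    ex <- exons[exons$chromosome == chrom, , drop = FALSE]
    gn <- genes[genes$chromosome == chrom, , drop = FALSE]
    exonic <- any(ex$start <= e[i] & ex$end >= s[i])
    if (exonic) { ctx[i] <- "exonic"; next }
    in_gene <- gn$start <= s[i] & gn$end >= e[i]
    if (any(in_gene)) {
      gid <- gn$gene_id[which(in_gene)[1]]
      gex <- ex[ex$gene_id == gid, , drop = FALSE]
      # inside the gene but outside every exon: intronic
      ctx[i] <- "intronic"
    } else {
      # straddles a gene boundary without touching an exon: majority rule
      ov <- gn$start <= e[i] & gn$end >= s[i]
      if (any(ov)) {
        g <- gn[which(ov)[1], ]
        inside <- min(e[i], g$end) - max(s[i], g$start) + 1L
        ctx[i] <- if (inside > (e[i] - s[i] + 1L) / 2) "intronic" else "intergenic"
      } else ctx[i] <- "intergenic"
    }
  }
  records$context <- ctx
  records
}
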