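# Miniature germline (MIC) genome simulator with full rearrangement ground
# truth, and derivation of the corresponding somatic (MAC) genome.
#
# The generator plants three element types on an AT-rich background:
#   * isolated Cbs sites drawn from the published variant spectrum,
#   * tandem Cbs duplication loci (consecutive Cbs copies sharing a 200 bp
#     downstream flank) whose inter-Cbs spacers become non-maintained
#     chromosomes (NMCs),
#   * internal eliminated sequences (IESs) built as TDR + interior + TDR so
#     that one terminal direct repeat copy survives excision.
# Background bases adjacent to each IES are adjusted so the planted junction
# is the left-normalized one and the planted TDR is maximal; background hits
# of the Cbs family regex are disrupted so that planted motifs are the only
# family members present (scan recall = precision = 1 by construction).

GENE_FLANK <- 150L
INTRON_MARGIN <- 50L
TELOMERE_UNIT <- "CCCCAA"
TELOMERE_COPIES <- 20L
MIN_ELEMENT_GAP <- 400L
CBS_SEGMENT_FLANK <- 200L

# ---- element construction -------------------------------------------------

sample_tdr <- function(cfg) {
  k <- sample(0:4, 1L, prob = cfg$tdr_class_weights)
  if (k == 0L) return("")
  if (k >= 2L && stats::runif(1) < cfg$tdr_tt_bias)
    return(substr("TTAA", 1L, k))
  at <- if (k == 1L) 0.92 else cfg$tdr_at_fraction
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste(sample(DNA_BASES, k, replace = TRUE, prob = p), collapse = "")
}

sample_ies_length <- function(cfg, n = 1L) {
  par <- ies_lognormal_params(cfg)
  out <- integer(0)
  while (length(out) < n) {
    x <- round(stats::rlnorm(n * 2L, par["meanlog"], par["sdlog"]))
    x <- x[x >= cfg$ies_length_range[1] & x <= cfg$ies_length_range[2]]
    out <- c(out, as.integer(x))
  }
  out[seq_len(n)]
}

make_ies_element <- function(cfg, context) {
  if (context == "exonic") {
    # emulates the piggyBac-like coding-region elements: TTAA terminal direct
    # repeats, CACTTT terminal inverted repeat, exceptionally short
    L <- sample(136:250, 1L)
    tdr <- "TTAA"
    interior <- paste0("CACTTT",
                       random_dna(L - nchar(tdr) - 12L, cfg$gc_fraction),
                       "AAAGTG")
  } else {
    L <- sample_ies_length(cfg)
    tdr <- sample_tdr(cfg)
    interior <- random_dna(L - nchar(tdr), cfg$gc_fraction)
  }
  list(kind = "ies", seq = paste0(tdr, interior, tdr),
       removed_length = L, tdr = tdr, context = context)
}

make_cbs_element <- function(cfg) {
  variant <- sample(names(cfg$cbs_variant_weights), 1L,
                    prob = cfg$cbs_variant_weights)
  strand <- sample(c("+", "-"), 1L)
  crich <- variant_to_sequence(variant)
  list(kind = "cbs", seq = if (strand == "+") crich else revcomp(crich),
       variant = variant, strand = strand)
}

make_tandem_element <- function(cfg, locus_id) {
  variant <- sample(names(cfg$cbs_variant_weights), 1L,
                    prob = cfg$cbs_variant_weights)
  strand <- sample(c("+", "-"), 1L)
  crich <- variant_to_sequence(variant)
  motif <- if (strand == "+") crich else revcomp(crich)
  copies <- cfg$tandem_repeat_copies
  spacer <- cfg$tandem_spacer_length
  filler_len <- spacer - CBS_LENGTH - CBS_SEGMENT_FLANK
  if (filler_len < 100L)
    stop("tandem_spacer_length too short for Cbs + shared flank + unique filler")
  shared <- random_dna(CBS_SEGMENT_FLANK, cfg$gc_fraction)
  pieces <- character(0)
  for (ci in seq_len(copies)) {
    pieces <- c(pieces, motif, shared,
                if (ci < copies) random_dna(filler_len, cfg$gc_fraction))
  }
  seq <- paste(pieces, collapse = "")
  cbs_offsets <- 1L + (seq_len(copies) - 1L) * spacer
  list(kind = "tandem", seq = seq, variant = variant, strand = strand,
       copies = copies, spacer = spacer, cbs_offsets = cbs_offsets,
       locus_id = locus_id)
}

# ---- family-regex hygiene -------------------------------------------------

# allowed base sets per consensus position on the C-rich strand
cbs_allowed_sets <- function() {
  list(c("A", "T"), "A", "A", "A", "C", "C", "A", "A", "C", "C",
       c("C", "T"), "C", c("A", "C", "G", "T"), c("A", "C", "T"), c("A", "T"))
}

# raw both-strand overlapping scan returning starts and strands only
scan_cbs_raw <- function(seq) {
  L <- nchar(seq)
  fwd <- gregexpr(paste0("(?=", CBS_FAMILY_REGEX, ")"), seq, perl = TRUE)[[1]]
  fwd <- as.integer(fwd[fwd > 0])
  rc <- revcomp(seq)
  rev_hits <- gregexpr(paste0("(?=", CBS_FAMILY_REGEX, ")"), rc, perl = TRUE)[[1]]
  rev_hits <- as.integer(rev_hits[rev_hits > 0])
  rev_fwd_start <- L - rev_hits - CBS_LENGTH + 2L
  data.frame(start = c(fwd, rev_fwd_start),
             strand = rep(c("+", "-"), c(length(fwd), length(rev_fwd_start))),
             stringsAsFactors = FALSE)
}

# mutate one base of each non-planted family match so it leaves the family;
# `protect` are 1-based positions that must not be touched.
disrupt_spurious_cbs <- function(seq, planted_starts, protect) {
  allowed <- cbs_allowed_sets()
  for (iter in 1:12) {
    hits <- scan_cbs_raw(seq)
    spurious <- setdiff(hits$start, planted_starts)
    if (length(spurious) == 0L) return(seq)
    for (s in spurious) {
      hit <- hits[hits$start == s, , drop = FALSE][1, ]
      fixed <- FALSE
      for (off in c(4L, 5L, 8L, 9L, 1L, 2L, 3L, 6L, 7L, 10L, 11L, 13L, 14L)) {
        pos <- s + off            # forward coordinate of family offset `off`
        if (pos %in% protect) next
        fam_pos <- if (hit$strand == "+") off + 1L else CBS_LENGTH - off
        ok <- allowed[[fam_pos]]
        if (length(ok) == 4L) next          # fully degenerate position
        cur <- substr(seq, pos, pos)
        repl_crich <- setdiff(DNA_BASES, ok)[1]
        repl <- if (hit$strand == "+") repl_crich else revcomp(repl_crich)
        if (repl == cur) repl <- setdiff(setdiff(DNA_BASES, ok), cur)[1]
        if (is.na(repl)) next
        substr(seq, pos, pos) <- repl
        fixed <- TRUE
        break
      }
      if (!fixed)
        stop("could not disrupt a background Cbs-family match at ", s)
    }
  }
  stop("background Cbs-family disruption did not converge")
}

# ---- generator ------------------------------------------------------------

#' Generate a miniature germline genome with planted rearrangement features
#'
#' Builds `n_chromosomes` random AT-rich chromosomes carrying planted
#' chromosome breakage sequences (isolated and tandemly duplicated), internal
#' eliminated sequences with terminal direct repeats, and gene annotations
#' for junction-context labelling, and returns the sequences together with a
#' complete ground-truth ledger.
#'
#' @param config a [sim_config()] object.
#' @return list with `mic` (named character vector of chromosome sequences)
#'   and `truth` (a `rearrangement_truth` object: data frames `cbs_sites`,
#'   `ies_intervals`, `nmc_intervals`, `gene_intervals`, `gene_exons`, plus
#'   chromosome lengths and the configuration).
#' @export
generate_mic_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_chr <- config$n_chromosomes
  chr_names <- sprintf("mic_chr%d", seq_len(n_chr))

  # assign global element counts to chromosomes round-robin
  ies_contexts <- character(config$n_ies)
  n_ex <- round(config$exonic_fraction * config$n_ies)
  n_in <- round(config$intronic_fraction * config$n_ies)
  ies_contexts[] <- "intergenic"
  if (config$n_ies > 0) {
    idx <- sample(config$n_ies)
    if (n_ex > 0) ies_contexts[idx[seq_len(n_ex)]] <- "exonic"
    if (n_in > 0) ies_contexts[idx[n_ex + seq_len(n_in)]] <- "intronic"
  }
  ies_chr <- if (config$n_ies > 0)
    rep(seq_len(n_chr), length.out = config$n_ies) else integer(0)
  tandem_chr <- if (config$n_tandem_dup_cbs > 0)
    rep(seq_len(n_chr), length.out = config$n_tandem_dup_cbs) else integer(0)

  cbs_rows <- list(); ies_rows <- list(); nmc_rows <- list()
  gene_rows <- list(); exon_rows <- list()
  mic <- stats::setNames(character(n_chr), chr_names)
  gene_counter <- 0L

  for (ci in seq_len(n_chr)) {
    elements <- list()
    for (j in seq_len(config$n_cbs_per_chromosome))
      elements[[length(elements) + 1L]] <- make_cbs_element(config)
    for (t in which(tandem_chr == ci))
      elements[[length(elements) + 1L]] <- make_tandem_element(config, t)
    for (k in which(ies_chr == ci))
      elements[[length(elements) + 1L]] <- make_ies_element(config, ies_contexts[k])
    elements <- elements[sample(length(elements))]

    lens <- vapply(elements, function(e) nchar(e$seq), integer(1))
    n_el <- length(elements)
    extra_total <- config$chromosome_length - sum(lens) -
      MIN_ELEMENT_GAP * (n_el + 1L)
    if (extra_total < 0L)
      stop("cannot place ", n_el, " elements (", sum(lens),
           " bp) on chromosome ", chr_names[ci], " of length ",
           config$chromosome_length, " bp: chromosome too crowded")
    extras <- if (n_el >= 0L)
      as.integer(stats::rmultinom(1L, extra_total, rep(1, n_el + 1L))) else integer(0)
    gaps <- MIN_ELEMENT_GAP + extras

    pieces <- character(2L * n_el + 1L)
    starts <- integer(n_el)
    pos <- 0L
    for (j in seq_len(n_el)) {
      g <- random_dna(gaps[j], config$gc_fraction)
      pieces[2L * j - 1L] <- g
      pos <- pos + gaps[j]
      starts[j] <- pos + 1L
      pieces[2L * j] <- elements[[j]]$seq
      pos <- pos + lens[j]
    }
    pieces[2L * n_el + 1L] <- random_dna(gaps[n_el + 1L], config$gc_fraction)
    seq <- paste(pieces, collapse = "")

    protect <- integer(0)
    planted_starts <- integer(0)

    for (j in seq_len(n_el)) {
      el <- elements[[j]]
      S <- starts[j]
      if (el$kind == "cbs") {
        planted_starts <- c(planted_starts, S)
        protect <- c(protect, S:(S + CBS_LENGTH - 1L))
        cbs_rows[[length(cbs_rows) + 1L]] <- data.frame(
          chromosome = chr_names[ci], start = S, end = S + CBS_LENGTH - 1L,
          strand = el$strand, variant = el$variant,
          sequence = variant_to_sequence(el$variant),
          tandem_locus = NA_integer_, stringsAsFactors = FALSE)
      } else if (el$kind == "tandem") {
        abs_off <- S + el$cbs_offsets - 1L
        planted_starts <- c(planted_starts, abs_off)
        for (a in abs_off) protect <- c(protect, a:(a + CBS_LENGTH - 1L))
        for (a in abs_off)
          cbs_rows[[length(cbs_rows) + 1L]] <- data.frame(
            chromosome = chr_names[ci], start = a, end = a + CBS_LENGTH - 1L,
            strand = el$strand, variant = el$variant,
            sequence = variant_to_sequence(el$variant),
            tandem_locus = el$locus_id, stringsAsFactors = FALSE)
        for (u in seq_len(el$copies - 1L))
          nmc_rows[[length(nmc_rows) + 1L]] <- data.frame(
            chromosome = chr_names[ci],
            start = abs_off[u] + CBS_LENGTH,
            end = abs_off[u + 1L] - 1L,
            locus_id = el$locus_id, stringsAsFactors = FALSE)
      } else {
        L <- el$removed_length
        t <- nchar(el$tdr)
        E <- S + L + t - 1L
        # forbid junction left-shift and right-extension by fixing the two
        # background bases bracketing the element
        removed_last <- substr(seq, S + L - 1L, S + L - 1L)
        interior_first <- substr(seq, S + t, S + t)
        b1 <- S - 1L; b2 <- E + 1L
        if (substr(seq, b1, b1) == removed_last)
          substr(seq, b1, b1) <- sample(setdiff(DNA_BASES, removed_last), 1L)
        if (substr(seq, b2, b2) == interior_first)
          substr(seq, b2, b2) <- sample(setdiff(DNA_BASES, interior_first), 1L)
        protect <- c(protect, b1, b2, S:(S + t), (E - t):E, S + L - 1L)
        ies_rows[[length(ies_rows) + 1L]] <- data.frame(
          chromosome = chr_names[ci], start = S, end = E,
          junction_start = S, junction_end = S + L - 1L,
          length = L, tdr = el$tdr, tdr_length = t,
          context = el$context, stringsAsFactors = FALSE)
        if (el$context %in% c("intronic", "exonic")) {
          gene_counter <- gene_counter + 1L
          gid <- sprintf("gene%04d", gene_counter)
          gs <- S - GENE_FLANK; ge <- E + GENE_FLANK
          gene_rows[[length(gene_rows) + 1L]] <- data.frame(
            gene_id = gid, chromosome = chr_names[ci], start = gs, end = ge,
            strand = "+", stringsAsFactors = FALSE)
          if (el$context == "intronic") {
            exon_rows[[length(exon_rows) + 1L]] <- data.frame(
              gene_id = gid, chromosome = chr_names[ci],
              start = c(gs, E + INTRON_MARGIN + 1L),
              end = c(S - INTRON_MARGIN - 1L, ge), stringsAsFactors = FALSE)
          } else {
            exon_rows[[length(exon_rows) + 1L]] <- data.frame(
              gene_id = gid, chromosome = chr_names[ci],
              start = gs, end = ge, stringsAsFactors = FALSE)
          }
        }
      }
    }

    seq <- disrupt_spurious_cbs(seq, planted_starts, protect)
    mic[ci] <- seq
  }

  bind <- function(rows, proto) if (length(rows)) do.call(rbind, rows) else proto
  cbs_sites <- bind(cbs_rows, data.frame(
    chromosome = character(0), start = integer(0), end = integer(0),
    strand = character(0), variant = character(0), sequence = character(0),
    tandem_locus = integer(0)))
  cbs_sites <- cbs_sites[order(cbs_sites$chromosome, cbs_sites$start), ]
  rownames(cbs_sites) <- NULL
  ies_intervals <- bind(ies_rows, data.frame(
    chromosome = character(0), start = integer(0), end = integer(0),
    junction_start = integer(0), junction_end = integer(0), length = integer(0),
    tdr = character(0), tdr_length = integer(0), context = character(0)))
  if (nrow(ies_intervals)) {
    ies_intervals <- ies_intervals[order(ies_intervals$chromosome,
                                         ies_intervals$start), ]
    rownames(ies_intervals) <- NULL
    ies_intervals$ies_id <- sprintf("ies%04d", seq_len(nrow(ies_intervals)))
  } else ies_intervals$ies_id <- character(0)

  truth <- structure(list(
    cbs_sites = cbs_sites,
    ies_intervals = ies_intervals,
    nmc_intervals = bind(nmc_rows, data.frame(
      chromosome = character(0), start = integer(0), end = integer(0),
      locus_id = integer(0))),
    gene_intervals = bind(gene_rows, data.frame(
      gene_id = character(0), chromosome = character(0), start = integer(0),
      end = integer(0), strand = character(0))),
    gene_exons = bind(exon_rows, data.frame(
      gene_id = character(0), chromosome = character(0), start = integer(0),
      end = integer(0))),
    mac_segments = NULL,
    chrom_lengths = stats::setNames(nchar(mic), names(mic)),
    config = config), class = "rearrangement_truth")

  list(mic = mic, truth = truth)
}

#' @export
print.rearrangement_truth <- function(x, ...) {
  cat("Rearrangement ground truth:\n")
  cat(sprintf("  %d chromosomes (%s bp), %d Cbs sites, %d IESs, %d NMCs, %d genes\n",
              length(x$chrom_lengths),
              format(sum(x$chrom_lengths), big.mark = ","),
              nrow(x$cbs_sites), nrow(x$ies_intervals),
              nrow(x$nmc_intervals), nrow(x$gene_intervals)))
  if (!is.null(x$mac_segments))
    cat(sprintf("  somatic derivation: %d segments (%d maintained)\n",
                nrow(x$mac_segments), sum(x$mac_segments$maintained)))
  invisible(x)
}
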