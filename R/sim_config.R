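#' Configuration for the rearranged-genome simulator
#'
#' Builds a validated configuration for [generate_mic_genome()] and friends.
#' Defaults reproduce the empirical parameters of the *T. thermophila*
#' germline/soma system at miniature scale: micronuclear A+T content 77.9%
#' (`gc_fraction = 0.221`), the published Cbs variant spectrum
#' ([cbs_variant_counts()]), eliminated-segment lengths lognormal with mean
#' 3.78 kb and median 2.78 kb, telomere addition 5-25 bp outside each Cbs,
#' and AT-rich terminal direct repeats (97% A/T for lengths 2-4, 92% for
#' length 1) with an excess of the TT(A)(A) consensus.
#'
#' @param seed integer seed driving every random choice of the simulator.
#' @param n_chromosomes number of germline chromosomes.
#' @param chromosome_length length of each chromosome (bp).
#' @param gc_fraction G+C fraction of background sequence.
#' @param n_cbs_per_chromosome isolated (non-tandem) Cbs sites per chromosome.
#' @param cbs_variant_weights named numeric, probability of each Cbs variant
#'   label; defaults to the published counts normalised to 1.
#' @param n_ies total number of internal eliminated sequences in the genome.
#' @param ies_length_lognormal numeric `c(mean, median)` in bp of the
#'   eliminated-length distribution (lognormal parameterisation).
#' @param ies_length_range numeric `c(min, max)` truncation bounds (bp).
#' @param tdr_class_weights numeric length 5, probability of terminal direct
#'   repeat lengths 0..4 (no-TDR class largest).
#' @param tdr_at_fraction per-base A/T probability inside TDRs of length 2-4.
#' @param tdr_tt_bias probability that a TDR of length 2-4 is drawn as the
#'   TT / TTA / TTAA consensus rather than base-by-base.
#' @param excision_endpoint_sd standard deviation (bp) of excision endpoint
#'   jitter in the derived somatic genome.
#' @param excision_stay_prob probability that an endpoint reproduces the
#'   parental position exactly (zero-inflation of the jitter model).
#' @param telomere_offset_range integer `c(min, max)` bp trimmed between a Cbs
#'   and the telomere addition site on each side.
#' @param n_tandem_dup_cbs number of tandem Cbs duplication loci per genome;
#'   each contributes `tandem_repeat_copies` Cbs copies and
#'   `tandem_repeat_copies - 1` non-maintained chromosomes.
#' @param tandem_repeat_copies Cbs copies per tandem duplication locus.
#' @param tandem_spacer_length distance (bp) between consecutive Cbs starts in
#'   a tandem duplication locus.
#' @param intronic_fraction,exonic_fraction fraction of eliminated segments
#'   placed inside an annotated intron / coding exon (remainder intergenic).
#' @param read_length read length (bp) for simulated reads.
#' @param coverage fold coverage for simulated reads.
#' @param frag_insert insert size (bp) for paired-end simulation.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chromosome_length = 200000L,
                       gc_fraction = 0.221,
                       n_cbs_per_chromosome = 6L,
                       cbs_variant_weights = NULL,
                       n_ies = 45L,
                       ies_length_lognormal = c(mean = 3780, median = 2780),
                       ies_length_range = c(136, 20000),
                       tdr_class_weights = c(`0` = 0.35, `1` = 0.15, `2` = 0.15,
                                             `3` = 0.15, `4` = 0.20),
                       tdr_at_fraction = 0.97,
                       tdr_tt_bias = 0.4,
                       excision_endpoint_sd = 3,
                       excision_stay_prob = 0.25,
                       telomere_offset_range = c(5L, 25L),
                       n_tandem_dup_cbs = 1L,
                       tandem_repeat_copies = 2L,
                       tandem_spacer_length = 2000L,
                       intronic_fraction = 0.16,
                       exonic_fraction = 0.02,
                       read_length = 100L,
                       coverage = 10,
                       frag_insert = 600L) {
  if (is.null(cbs_variant_weights)) {
    tab <- cbs_variant_counts()
    cbs_variant_weights <- stats::setNames(tab$count / sum(tab$count), tab$variant)
  }
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              gc_fraction = gc_fraction,
              n_cbs_per_chromosome = as.integer(n_cbs_per_chromosome),
              cbs_variant_weights = cbs_variant_weights,
              n_ies = as.integer(n_ies),
              ies_length_lognormal = ies_length_lognormal,
              ies_length_range = ies_length_range,
              tdr_class_weights = tdr_class_weights,
              tdr_at_fraction = tdr_at_fraction,
              tdr_tt_bias = tdr_tt_bias,
              excision_endpoint_sd = excision_endpoint_sd,
              excision_stay_prob = excision_stay_prob,
              telomere_offset_range = as.integer(telomere_offset_range),
              n_tandem_dup_cbs = as.integer(n_tandem_dup_cbs),
              tandem_repeat_copies = as.integer(tandem_repeat_copies),
              tandem_spacer_length = as.integer(tandem_spacer_length),
              intronic_fraction = intronic_fraction,
              exonic_fraction = exonic_fraction,
              read_length = as.integer(read_length),
              coverage = coverage,
              frag_insert = as.integer(frag_insert))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1L, cfg$chromosome_length >= 1000L,
            cfg$gc_fraction > 0, cfg$gc_fraction < 1,
            cfg$coverage >= 0, cfg$read_length >= 32L)
  if (abs(sum(cfg$cbs_variant_weights) - 1) > 1e-9)
    stop("cbs_variant_weights must sum to 1")
  if (abs(sum(cfg$tdr_class_weights) - 1) > 1e-9)
    stop("tdr_class_weights must sum to 1")
  bad <- setdiff(names(cfg$cbs_variant_weights), c("canonical"))
  # every weighted variant label must round-trip through the family pattern
  seqs <- variant_to_sequence(names(cfg$cbs_variant_weights))
  if (!all(grepl(paste0("^", CBS_FAMILY_REGEX, "$"), seqs)))
    stop("cbs_variant_weights contains labels outside the Cbs family")
  if (length(cfg$telomere_offset_range) != 2L ||
      cfg$telomere_offset_range[1] > cfg$telomere_offset_range[2] ||
      cfg$telomere_offset_range[1] < 0L)
    stop("telomere_offset_range must be a non-decreasing pair of non-negative offsets")
  r <- cfg$ies_length_range
  if (r[1] < 20 || r[2] <= r[1]) stop("invalid ies_length_range")
  if (cfg$ies_length_lognormal[1] <= cfg$ies_length_lognormal[2] * 0.999)
    stop("lognormal mean must exceed the median")
  if (cfg$intronic_fraction + cfg$exonic_fraction > 1)
    stop("context fractions exceed 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Rearranged-genome simulator configuration\n")
  cat(sprintf("  %d chromosome(s) x %d bp, GC %.3f, seed %d\n",
              x$n_chromosomes, x$chromosome_length, x$gc_fraction, x$seed))
  cat(sprintf("  %d Cbs/chromosome + %d tandem duplication locus/loci (%d copies)\n",
              x$n_cbs_per_chromosome, x$n_tandem_dup_cbs, x$tandem_repeat_copies))
  cat(sprintf("  %d IESs, lognormal mean %.0f / median %.0f bp, jitter sd %.1f\n",
              x$n_ies, x$ies_length_lognormal[1], x$ies_length_lognormal[2],
              x$excision_endpoint_sd))
  invisible(x)
}

# lognormal meanlog/sdlog from (mean, median)
ies_lognormal_params <- function(cfg) {
  m <- cfg$ies_length_lognormal[[1]]
  med <- cfg$ies_length_lognormal[[2]]
  meanlog <- log(med)
  sdlog <- sqrt(2 * (log(m) - log(med)))
  c(meanlog = meanlog, sdlog = sdlog)
}
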