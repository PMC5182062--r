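# Shared simulation fixtures, generated once per session and cached in the
# global environment so every test file reuses the same objects.

fixture_cache <- function() {
  if (!exists(".micmac_fixtures", envir = globalenv()))
    assign(".micmac_fixtures", new.env(), envir = globalenv())
  get(".micmac_fixtures", envir = globalenv())
}

# medium two-chromosome genome with zero excision jitter: the workhorse for
# detection tests (exact junctions, tandem locus of three Cbs copies)
medium_sim <- function() {
  cache <- fixture_cache()
  if (is.null(cache$medium)) {
    cfg <- sim_config(seed = 7, n_chromosomes = 2, chromosome_length = 150000,
                      n_ies = 16, n_cbs_per_chromosome = 3,
                      n_tandem_dup_cbs = 1, tandem_repeat_copies = 3,
                      excision_endpoint_sd = 0)
    g <- generate_mic_genome(cfg)
    d <- derive_mac_genome(g$mic, g$truth, cfg)
    cache$medium <- list(cfg = cfg, mic = g$mic, mac = d$mac, truth = d$truth)
  }
  cache$medium
}

# medium fixture plus read alignments and cross-assembly blocks
medium_pipeline <- function() {
  cache <- fixture_cache()
  if (is.null(cache$pipeline)) {
    fx <- medium_sim()
    mac_reads <- simulate_reads(fx$mac, fx$cfg, read_length = 700,
                                coverage = 10)
    aln_mac <- align_reads(mac_reads, fx$mic)
    cov <- read_coverage(aln_mac$full, fx$truth$chrom_lengths)
    blocks <- align_assemblies(fx$mic, fx$mac)
    mic_reads <- simulate_reads(fx$mic, fx$cfg, read_length = 100,
                                coverage = 20, seed = 99)
    aln_mic <- align_reads(mic_reads, fx$mac)
    aln_mic$clipped <- dedupe_alignments(aln_mic$clipped)
    cache$pipeline <- c(fx, list(aln_mac = aln_mac, cov = cov,
                                 blocks = blocks, aln_mic = aln_mic))
  }
  cache$pipeline
}

junction_key <- function(df) {
  paste(df$chromosome, df$junction_start, df$junction_end)
}
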