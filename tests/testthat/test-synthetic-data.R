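# Rearranged-genome simulator: ground truth, determinism, somatic
# derivation, and conservation bookkeeping.

test_that("a featureless configuration yields pure random sequence", {
  cfg <- sim_config(seed = 2, n_chromosomes = 1, chromosome_length = 50000,
                    n_cbs_per_chromosome = 0, n_ies = 0, n_tandem_dup_cbs = 0)
  g <- generate_mic_genome(cfg)
  expect_equal(nrow(g$truth$cbs_sites), 0)
  expect_equal(nrow(g$truth$ies_intervals), 0)
  expect_equal(nrow(g$truth$nmc_intervals), 0)
  expect_equal(nchar(g$mic[[1]]), 50000)
  expect_equal(nrow(scan_cbs(g$mic[[1]])), 0)
  at <- mean(strsplit(g$mic[[1]], "")[[1]] %in% c("A", "T"))
  expect_lt(abs(at - (1 - cfg$gc_fraction)), 0.02)
})

test_that("canonical-only weights plant only the consensus C-rich sequence", {
  cfg <- sim_config(seed = 3, n_chromosomes = 1, chromosome_length = 60000,
                    n_cbs_per_chromosome = 8, n_ies = 0, n_tandem_dup_cbs = 0,
                    cbs_variant_weights = c(canonical = 1.0))
  g <- generate_mic_genome(cfg)
  expect_equal(nrow(g$truth$cbs_sites), 8)
  expect_true(all(g$truth$cbs_sites$sequence == "TAAACCAACCTCTTT"))
  expect_true(all(g$truth$cbs_sites$variant == "canonical"))
})

test_that("the simulator is byte-deterministic in its seed", {
  cfg1 <- sim_config(seed = 1, n_chromosomes = 1, chromosome_length = 40000,
                     n_ies = 4, n_cbs_per_chromosome = 2,
                     n_tandem_dup_cbs = 0)
  a <- generate_mic_genome(cfg1)
  b <- generate_mic_genome(cfg1)
  expect_identical(a$mic, b$mic)
  expect_identical(a$truth$ies_intervals, b$truth$ies_intervals)
  cfg2 <- sim_config(seed = 2, n_chromosomes = 1, chromosome_length = 40000,
                     n_ies = 4, n_cbs_per_chromosome = 2,
                     n_tandem_dup_cbs = 0)
  expect_false(identical(generate_mic_genome(cfg2)$mic, a$mic))
})

test_that("somatic derivation fragments at every Cbs and honours truth", {
  fx <- medium_sim()
  for (chrom in names(fx$mic)) {
    k <- sum(fx$truth$cbs_sites$chromosome == chrom)
    seg <- fx$truth$mac_segments[fx$truth$mac_segments$mic_chromosome == chrom, ]
    expect_equal(nrow(seg), k + 1)
  }
  # zero jitter: realized endpoints equal truth junctions exactly
  ies <- fx$truth$ies_intervals
  expect_equal(ies$realized_start, ies$junction_start)
  expect_equal(ies$realized_end, ies$junction_end)
  # non-maintained segments are absent from the somatic genome but ledgered
  nm <- fx$truth$mac_segments[!fx$truth$mac_segments$maintained, ]
  expect_equal(nrow(nm), nrow(fx$truth$nmc_intervals))
  expect_false(any(nm$mac_contig %in% names(fx$mac)))
  # every NMC is delimited by two consecutive truth Cbs
  for (j in seq_len(nrow(fx$truth$nmc_intervals))) {
    n <- fx$truth$nmc_intervals[j, ]
    cbs <- fx$truth$cbs_sites[fx$truth$cbs_sites$chromosome == n$chromosome, ]
    expect_true(any(cbs$end == n$start - 1) && any(cbs$start == n$end + 1))
  }
})

test_that("a tandem Cbs pair 800 bp apart leaves its spacer out of the soma", {
  cfg <- sim_config(seed = 5, n_chromosomes = 1, chromosome_length = 60000,
                    n_cbs_per_chromosome = 2, n_ies = 0,
                    n_tandem_dup_cbs = 1, tandem_repeat_copies = 2,
                    tandem_spacer_length = 800, excision_endpoint_sd = 0)
  g <- generate_mic_genome(cfg)
  d <- derive_mac_genome(g$mic, g$truth, cfg)
  nmc <- d$truth$nmc_intervals
  expect_equal(nrow(nmc), 1)
  expect_equal(nmc$end - nmc$start + 1, 800 - 15)  # spacer minus the Cbs
  spacer <- substr(g$mic[[1]], nmc$start, nmc$end)
  expect_false(any(vapply(d$mac, function(s) grepl(spacer, s, fixed = TRUE),
                          logical(1))))
})

test_that("germline-soma length bookkeeping is exact, with and without jitter", {
  fx <- medium_sim()
  expect_identical(conservation_identity(fx$mic, fx$mac, fx$truth), 0L)
  cfg <- fx$cfg
  cfg$excision_endpoint_sd <- 3
  d <- derive_mac_genome(fx$mic, fx$truth, cfg)
  expect_identical(conservation_identity(fx$mic, d$mac, d$truth), 0L)
})

test_that("telomere-addition trims stay inside the configured window", {
  fx <- medium_sim()
  seg <- fx$truth$mac_segments
  trims <- c(seg$left_trim[!is.na(seg$left_trim) & seg$left_trim > 0],
             seg$right_trim[!is.na(seg$right_trim) & seg$right_trim > 0])
  expect_true(all(trims >= 5 & trims <= 25))
  # somatic contigs carry telomere repeats at broken ends only
  tel <- strrep("CCCCAA", 20)
  with_tel <- seg[seg$maintained & seg$telomere_left, ]
  for (id in with_tel$mac_contig)
    expect_identical(substr(fx$mac[[id]], 1, nchar(tel)), tel)
})

test_that("read simulation matches the coverage arithmetic and the genome", {
  fx <- medium_sim()
  genome <- c(g1 = substr(fx$mic[[1]], 1, 100000))
  cfg <- fx$cfg
  reads <- simulate_reads(genome, cfg, read_length = 100, coverage = 10,
                          error_rate = 0)
  expect_equal(nrow(reads), round(10 * 100000 / 100))
  # error rate 0: every read is an exact substring of its source (either
  # orientation)
  pick <- reads$seq[seq(1, nrow(reads), length.out = 50)]
  hit <- vapply(pick, function(s)
    grepl(s, genome[[1]], fixed = TRUE) ||
      grepl(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s))), genome[[1]], fixed = TRUE), logical(1))
  expect_true(all(hit))
  expect_error(simulate_reads(genome, cfg, read_length = 200000,
                              coverage = 1), "exceeds")
})

test_that("long somatic reads span junction sequence absent from the germline", {
  fx <- medium_sim()
  ies <- fx$truth$ies_intervals[1, ]
  seg <- fx$truth$mac_segments
  seg <- seg[seg$mic_chromosome == ies$chromosome & seg$maintained &
               seg$mic_start <= ies$start & seg$mic_end >= ies$end, ]
  contig <- fx$mac[[seg$mac_contig[1]]]
  # locate the excision site on the somatic contig via the flanking sequence
  probe_left <- substr(fx$mic[[ies$chromosome]], ies$junction_start - 40,
                       ies$junction_start - 1)
  pos <- regexpr(probe_left, contig, fixed = TRUE)
  expect_gt(pos, 0)
  joined <- substr(contig, pos, pos + 79)  # 40 bp each side of the junction
  expect_false(grepl(joined, fx$mic[[ies$chromosome]], fixed = TRUE))
  expect_true(grepl(probe_left, fx$mic[[ies$chromosome]], fixed = TRUE))
})

test_that("planted variant frequencies follow the published spectrum", {
  # n >= 500 Cbs; compare each variant count with its binomial 99% interval
  cfg <- sim_config(seed = 13, n_chromosomes = 5, chromosome_length = 250000,
                    n_cbs_per_chromosome = 100, n_ies = 0,
                    n_tandem_dup_cbs = 0)
  g <- generate_mic_genome(cfg)
  n <- nrow(g$truth$cbs_sites)
  expect_gte(n, 500)
  w <- cfg$cbs_variant_weights
  counts <- table(factor(g$truth$cbs_sites$variant, levels = names(w)))
  for (v in names(w)) {
    ci <- qbinom(c(0.005, 0.995), n, w[[v]])
    expect_gte(counts[[v]], ci[1])
    expect_lte(counts[[v]], ci[2])
  }
})

test_that("crowded chromosomes fail with an explicit placement error", {
  cfg <- sim_config(seed = 1, n_chromosomes = 1, chromosome_length = 20000,
                    n_cbs_per_chromosome = 2, n_ies = 30,
                    n_tandem_dup_cbs = 0)
  expect_error(generate_mic_genome(cfg), "too crowded")
})
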