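# IES detection: the three evidence methods, merging, length statistics,
# and genomic-context labelling.

test_that("split-read candidates respect support and coverage thresholds", {
  mk_split <- function(n, d1 = 500L, d2 = 1500L)
    data.frame(read = sprintf("r%d", seq_len(n)), chrom = "c", strand = "+",
               junction_start = d1, junction_end = d2,
               prefix_len = 50L, suffix_len = 50L, overlap = 0L)
  cov0 <- list(c = rep(0L, 3000))
  aln2 <- list(split = mk_split(2))
  expect_equal(nrow(split_read_ies(aln2, cov0)), 0)   # two spanning reads
  aln5 <- list(split = mk_split(5))
  got <- split_read_ies(aln5, cov0)
  expect_equal(nrow(got), 1)
  expect_equal(got$n_spanning, 5)
  expect_equal(got$junction_start, 500)
  # internal somatic coverage 2.1x rejects the candidate
  cov_hi <- list(c = rep(2.1, 3000))
  expect_equal(nrow(split_read_ies(list(split = mk_split(4)), cov_hi)), 0)
  expect_error(split_read_ies(aln5, NULL), "coverage")
  # junction in an N run is rejected
  micN <- list(c = paste0(strrep("A", 499), "N", strrep("A", 2500)))
  names(micN) <- "c"
  expect_equal(nrow(split_read_ies(aln5, cov0, micN)), 0)
})

test_that("raising thresholds never adds split-read candidates", {
  fx <- medium_pipeline()
  base <- split_read_ies(fx$aln_mac, fx$cov, fx$mic, min_spanning = 3)
  stricter <- split_read_ies(fx$aln_mac, fx$cov, fx$mic, min_spanning = 5)
  expect_true(all(junction_key(stricter) %in% junction_key(base)))
  lower_cov <- split_read_ies(fx$aln_mac, fx$cov, fx$mic,
                              max_internal_coverage = 0.2)
  expect_true(all(junction_key(lower_cov) %in% junction_key(base)))
})

test_that("broken-read sites demand six reads from both directions within 10 bp", {
  mk_clip <- function(pos, dir)
    data.frame(read = sprintf("r%d", seq_along(pos)), chrom = "m",
               strand = "+", position = pos, direction = dir,
               matched_len = 60L)
  ok <- list(clipped = mk_clip(c(1000, 1001, 1003, 998, 999, 1002),
                               c("right", "right", "right",
                                 "left", "left", "left")))
  sites <- broken_read_sites(ok)
  expect_equal(nrow(sites), 1)
  expect_true(sites$validated)
  one_way <- list(clipped = mk_clip(rep(1000, 8) + 0:7, rep("right", 8)))
  expect_false(any(broken_read_sites(one_way)$validated))
  # two clusters 25 bp apart stay separate, each below threshold
  two <- list(clipped = mk_clip(c(1000, 1001, 1002, 1025, 1026, 1027),
                                rep(c("right", "left"), 3)))
  s2 <- broken_read_sites(two)
  expect_equal(nrow(s2), 2)
  expect_false(any(s2$validated))
})

test_that("cross-assembly gaps exceeding 100 bp become candidates", {
  mk_blocks <- function(mic_gap, mac_gap)
    data.frame(mic_id = "chr", mic_start = c(1, 2000 + mic_gap),
               mic_end = c(1999, 4000 + mic_gap),
               mac_id = "m", mac_start = c(1, 2000 + mac_gap),
               mac_end = c(1999, 4000 + mac_gap),
               strand = "+", length = 2000, identity = 100)
  big <- assembly_gap_ies(mk_blocks(1500, 8))
  expect_equal(nrow(big), 1)
  expect_equal(big$length, 1500)
  expect_true(big$junction_gap)  # positive somatic gap: imprecise junctions
  expect_equal(nrow(assembly_gap_ies(mk_blocks(60, 4))), 0)
  edge <- assembly_gap_ies(mk_blocks(104, 3))
  expect_equal(nrow(edge), 1)
})

test_that("method candidates merge into records with method provenance", {
  c1 <- data.frame(chromosome = "c", junction_start = 100L,
                   junction_end = 400L, length = 301L, method = 1L,
                   n_spanning = 5L, internal_coverage = 0,
                   junction_gap = FALSE)
  c3 <- c1; c3$method <- 3L; c3$n_spanning <- NA_integer_
  mic <- c(c = paste(rep("ACGT", 250), collapse = ""))
  rec <- merge_high_confidence(list(c1, c3), mic)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$methods, "1,3")
  expect_equal(rec$confidence, "high")
  # junction inside an N run demotes to provisional
  micN <- c(c = paste0(strrep("G", 99), "N", strrep("T", 900)))
  recN <- merge_high_confidence(list(c1), micN)
  expect_equal(recN$confidence, "provisional")
  # contradictory junctions are kept separate
  c1b <- c1; c1b$junction_start <- 120L
  rec2 <- merge_high_confidence(list(c1, c1b), mic)
  expect_equal(nrow(rec2), 2)
})

test_that("the merged high-confidence set equals truth on exact synthetic data", {
  fx <- medium_pipeline()
  cand1 <- split_read_ies(fx$aln_mac, fx$cov, fx$mic)
  cand3 <- assembly_gap_ies(fx$blocks, fx$mic)
  sites <- broken_read_sites(fx$aln_mic)
  cand2 <- residual_sites_to_candidates(sites, fx$blocks, fx$mic)
  rec <- merge_high_confidence(list(cand1, cand2, cand3), fx$mic)
  hc <- rec[rec$confidence == "high", ]
  truth <- fx$truth$ies_intervals
  expect_setequal(junction_key(hc), junction_key(truth))
  # junction error is zero and the terminal direct repeats match truth
  m <- match(junction_key(truth), junction_key(hc))
  expect_equal(hc$tdr[m], truth$tdr)
  # method concordance: every IES >= 500 bp is found by at least two methods
  n_methods <- lengths(strsplit(hc$methods[m], ","))
  expect_true(all(n_methods[truth$length >= 500] >= 2))
})

test_that("split-read calls match an exhaustive substring-matching oracle", {
  cfg <- sim_config(seed = 21, n_chromosomes = 1, chromosome_length = 9000,
                    n_cbs_per_chromosome = 1, n_ies = 3, n_tandem_dup_cbs = 0,
                    ies_length_lognormal = c(mean = 700, median = 600),
                    ies_length_range = c(136, 1500),
                    excision_endpoint_sd = 0)
  g <- generate_mic_genome(cfg)
  d <- derive_mac_genome(g$mic, g$truth, cfg)
  reads <- simulate_reads(d$mac, cfg, read_length = 150, coverage = 25)
  aln <- align_reads(reads, g$mic)
  cov <- read_coverage(aln$full, g$truth$chrom_lengths)
  called <- split_read_ies(aln, cov, g$mic)
  oracle <- oracle_split_junctions(reads, g$mic[[1]])
  expect_setequal(paste(called$junction_start, called$junction_end), oracle)
  expect_setequal(paste(called$junction_start, called$junction_end),
                  paste(g$truth$ies_intervals$junction_start,
                        g$truth$ies_intervals$junction_end))
})

test_that("length statistics are exact and respect the configured model", {
  expect_equal(length_stats(data.frame(length = c(100, 200, 300)))$mean, 200)
  expect_equal(length_stats(data.frame(length = c(100, 200, 300)))$median, 200)
  expect_equal(length_stats(data.frame(length = 136))$min, 136)
  expect_error(length_stats(data.frame(length = numeric(0))))
  fx <- medium_sim()
  st <- length_stats(fx$truth$ies_intervals)
  n <- nrow(fx$truth$ies_intervals)
  m <- fx$cfg$ies_length_lognormal[["mean"]]
  sdl <- ies_sd <- m * sqrt(exp((sqrt(2 * log(m / fx$cfg$ies_length_lognormal[["median"]])))^2) - 1)
  expect_lt(abs(st$mean - m), 3 * sdl / sqrt(n))
})

test_that("genomic context labels follow containment and overlap rules", {
  genes <- data.frame(gene_id = "g1", chromosome = "c", start = 1000,
                      end = 3000, strand = "+")
  exons <- data.frame(gene_id = "g1", chromosome = "c",
                      start = c(1200, 2500), end = c(1500, 3000))
  recs <- data.frame(chromosome = "c",
                     junction_start = c(5000, 1700, 1500, 400),
                     junction_end = c(5400, 2300, 1800, 1100))
  out <- classify_context(recs, genes, exons)
  expect_equal(out$context,
               c("intergenic",  # fully between genes
                 "intronic",    # inside the intron
                 "exonic",      # overlaps a coding exon by one base
                 "intergenic")) # straddles the gene edge, mostly outside
  fx <- medium_sim()
  lab <- classify_context(fx$truth$ies_intervals[, c("chromosome",
                                                     "junction_start",
                                                     "junction_end")],
                          fx$truth$gene_intervals, fx$truth$gene_exons)
  expect_equal(lab$context, fx$truth$ies_intervals$context)
})
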