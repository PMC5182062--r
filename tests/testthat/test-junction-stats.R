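# Junction statistics: terminal direct repeats, pattern groupings,
# excision variability, and the coding-region screen.

test_that("the maximal terminal direct repeat is read off the junction", {
  x <- "GGCGTCGGAC"; y <- "GGGTCAGGCC"
  interior <- "CACGGGTTGTCTGTGC"
  mic <- paste0(x, "TTAA", interior, "TTAA", y)
  d1 <- nchar(x) + 1L
  d2 <- nchar(x) + 4L + nchar(interior)  # removes one TTAA + interior
  r <- detect_tdr(mic, d1, d2)
  expect_equal(r$tdr, "TTAA")
  expect_equal(r$tdr_length, 4)
  # consistent somatic context passes, inconsistent errors
  mac <- paste0(x, "TTAA", y)
  expect_silent(detect_tdr(mic, d1, d2, mac = mac, mac_junction = nchar(x)))
  bad_mac <- paste0(x, "GGGG", y)
  expect_error(detect_tdr(mic, d1, d2, mac = bad_mac,
                          mac_junction = nchar(x)), "inconsistent")
  # no shared terminal sequence: length zero
  mic0 <- paste0(x, "CCCGGGTTGTCTGTGA", y)
  r0 <- detect_tdr(mic0, nchar(x) + 1L, nchar(x) + 16L)
  expect_equal(r0$tdr_length, 0)
  expect_error(detect_tdr(mic, 50, 10), "inconsistent")
})

test_that("TDR detection commutes with reverse-complementing the locus", {
  fx <- medium_sim()
  ies <- fx$truth$ies_intervals
  for (i in seq_len(min(6, nrow(ies)))) {
    seq <- fx$mic[[ies$chromosome[i]]]
    d1 <- ies$junction_start[i]; d2 <- ies$junction_end[i]
    expect_equal(detect_tdr(seq, d1, d2)$tdr, ies$tdr[i])
    # reverse-complement the locus: the removal seen from the other strand
    # is [L - d2', L - d1'] for the right-normalized variant; the maximal
    # overlap length is invariant
    L <- nchar(seq)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    t <- ies$tdr_length[i]
    rc_d1 <- L - (d2 + t) + 1L
    rc_d2 <- L - (d1 + t) + 1L
    r_rc <- detect_tdr(rc, rc_d1, rc_d2)
    expect_equal(r_rc$tdr_length, t)
    if (t > 0)
      expect_equal(r_rc$tdr, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ies$tdr[i]))))
  }
})

test_that("per-class AT fractions follow their definitions", {
  recs <- data.frame(tdr = c("TTAA", "TTAA", "GC", "AT", "T", ""))
  tc <- tdr_composition(recs)
  expect_equal(tc$at_fraction[["4"]], 1.0)
  expect_equal(tc$at_fraction[["2"]], 0.5)
  expect_true(is.na(tc$at_fraction[["0"]]))
  # synthetic defaults: classes 2-4 drawn at 97% A/T
  cfg <- sim_config(seed = 31, n_chromosomes = 3, chromosome_length = 250000,
                    n_ies = 150, n_cbs_per_chromosome = 2,
                    n_tandem_dup_cbs = 0,
                    ies_length_lognormal = c(mean = 1000, median = 900),
                    ies_length_range = c(136, 3000))
  g <- generate_mic_genome(cfg)
  tdrs <- g$truth$ies_intervals$tdr
  bases <- unlist(strsplit(tdrs[nchar(tdrs) %in% 2:4], ""))
  expect_gt(length(bases), 50)
  at <- mean(bases %in% c("A", "T"))
  ci <- qbinom(c(0.005, 0.995), length(bases), 0.97) / length(bases)
  expect_gte(at, ci[1])
})

test_that("reverse-complement classes of AT-only words are 10/4/3", {
  expect_equal(nrow(tdr_pattern_groups(k = 4)), 10)
  expect_equal(nrow(tdr_pattern_groups(k = 3)), 4)
  expect_equal(nrow(tdr_pattern_groups(k = 2)), 3)
  expect_error(tdr_pattern_groups(k = 5))
  for (k in 2:4) {
    got <- tdr_pattern_groups(k = k)
    expect_equal(sum(got$members), 2^k)  # classes partition all words
    oracle <- oracle_rc_classes(k)
    expect_equal(length(oracle), nrow(got))
    oracle_keys <- sort(vapply(oracle, function(m)
      paste(sort(m), collapse = "/"), character(1)))
    expect_equal(sort(got$class), oracle_keys)
  }
  # observed tallies land in the right classes
  recs <- data.frame(tdr = c("TTAA", "TTAA", "TT", "AA", "TAT"))
  g4 <- tdr_pattern_groups(recs, k = 4)
  expect_equal(g4$count[g4$class == "TTAA"], 2)
  g2 <- tdr_pattern_groups(recs, k = 2)
  expect_equal(g2$count[g2$class == "AA/TT"], 2)
})

test_that("excision variability profiles progeny endpoints against the parent", {
  par <- data.frame(ies_id = c("a", "b"), junction_start = c(100L, 900L),
                    junction_end = c(400L, 1600L))
  # all progeny identical to the parent
  obs <- data.frame(ies_id = c("a", "b"), obs_start = c(100L, 900L),
                    obs_end = c(400L, 1600L), n_reads = c(10L, 12L))
  ev <- excision_variability(obs, par)
  expect_equal(ev$fraction_identical, 1.0)
  expect_equal(ev$modal_distance, 0)
  expect_equal(names(ev$distance_histogram), "0")
  # endpoints shifted by +4 only: a single histogram bar at distance 4
  obs4 <- data.frame(ies_id = "a", obs_start = 104L, obs_end = 400L,
                     n_reads = 5L)
  ev4 <- excision_variability(obs4, par)
  expect_equal(names(ev4$distance_histogram), "4")
  # sub-threshold endpoints are not validated
  obs_thin <- rbind(obs, data.frame(ies_id = "a", obs_start = 150L,
                                    obs_end = 400L, n_reads = 2L))
  ev_thin <- excision_variability(obs_thin, par)
  expect_equal(sum(ev_thin$profiles$n_distinct_junctions), 2)
  # relaxing the validation threshold can only reveal more junctions
  ev_relaxed <- excision_variability(obs_thin, par, min_reads = 1)
  expect_gte(sum(ev_relaxed$profiles$n_distinct_junctions),
             sum(ev_thin$profiles$n_distinct_junctions))
  # sites without a parental reference are skipped and counted
  obs_orphan <- rbind(obs, data.frame(ies_id = "zz", obs_start = 1L,
                                      obs_end = 2L, n_reads = 9L))
  expect_equal(excision_variability(obs_orphan, par)$n_skipped, 1)
})

test_that("identical-fraction rises to one as jitter vanishes", {
  fx <- medium_sim()
  frac <- vapply(c(6, 3, 1, 0), function(s) {
    cfg <- fx$cfg
    cfg$excision_endpoint_sd <- s
    obs <- simulate_progeny_junctions(fx$truth, cfg, n_events = 25,
                                      depth = 50, seed = 404)
    excision_variability(obs, fx$truth$ies_intervals)$fraction_identical
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_equal(frac[4], 1.0)
})

test_that("the coding-region screen tests TTAA, CACTTT and shortness", {
  cfg <- sim_config(seed = 17, n_chromosomes = 1, chromosome_length = 150000,
                    n_ies = 20, n_cbs_per_chromosome = 2,
                    n_tandem_dup_cbs = 0, exonic_fraction = 0.2,
                    intronic_fraction = 0.2)
  g <- generate_mic_genome(cfg)
  recs <- g$truth$ies_intervals
  planted <- recs[recs$context == "exonic", ]
  expect_gte(nrow(planted), 2)
  out <- coding_ies_screen(recs, g$mic, length_quantile = 0.25)
  expect_true(all(out$context == "exonic"))
  expect_equal(nrow(out), nrow(planted))
  expect_true(all(out$tdr_ttaa))
  expect_true(all(out$tir_cactt))
  expect_true(all(out$short))
  # an exonic record without a TDR fails the TTAA feature
  fake <- planted[1, ]
  fake$tdr <- ""
  screened <- coding_ies_screen(rbind(planted, fake), g$mic,
                                length_quantile = 0.25)
  expect_false(screened$tdr_ttaa[nrow(screened)])
  # intronic records are out of scope for the screen
  intronic <- recs[recs$context == "intronic", , drop = FALSE]
  expect_equal(nrow(coding_ies_screen(intronic, g$mic)), 0)
})
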