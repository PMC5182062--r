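# Cbs scanning, variant classification, conservation, strand asymmetry,
# breakage maps, NMC detection, centromere mapping, and Fitch parsimony.

test_that("scanning finds family members on both strands with C-rich reporting", {
  flank <- "ACGGTGACGGATGATTGACCAGGTAG"
  hit <- scan_cbs(paste0(flank, "TAAACCAACCTCTTT", flank), "c")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, nchar(flank) + 1)
  expect_equal(hit$strand, "+")
  expect_equal(hit$variant, "canonical")
  expect_equal(hit$n_substitutions, 0)

  expect_equal(nrow(scan_cbs(strrep("A", 200))), 0)

  hit1a <- scan_cbs(paste0(flank, "AAAACCAACCTCTTT", flank), "c")
  expect_equal(hit1a$variant, "1A")
  expect_equal(hit1a$n_substitutions, 1)

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TAAACCAACCTCTTT")))
  hitm <- scan_cbs(paste0(flank, rc, flank), "c")
  expect_equal(hitm$strand, "-")
  expect_equal(hitm$sequence, "TAAACCAACCTCTTT")
  expect_equal(hitm$start, nchar(flank) + 1)

  # N never matches, even at the fully degenerate position 13
  expect_equal(nrow(scan_cbs(paste0(flank, "TAAACCAACCTCNTT", flank))), 0)
  expect_equal(nrow(scan_cbs(paste0(flank, "TAAACCAACCTNTTT", flank))), 0)
})

test_that("variant classification labels substitutions against the consensus", {
  expect_equal(classify_variant("TAAACCAACCTCTTT"),
               list(variant = "canonical", n_substitutions = 0L,
                    functional = TRUE))
  expect_equal(classify_variant("TAAACCAACCCCTTT")$variant, "11C")
  v <- classify_variant("AAAACCAACCTCTTA")
  expect_equal(v$variant, "1A,15A")
  expect_equal(v$n_substitutions, 2L)
  expect_error(classify_variant("TAAACC"), "15")
  v3 <- classify_variant("GGGACCAACCTCTTT")
  expect_equal(v3$n_substitutions, 3L)
  expect_false(v3$functional)
})

test_that("scanning the synthetic genome recovers truth exactly", {
  fx <- medium_sim()
  hits <- scan_cbs_genome(fx$mic)
  truth <- fx$truth$cbs_sites
  expect_equal(nrow(hits), nrow(truth))
  expect_equal(hits$start, truth$start)
  expect_equal(hits$strand, truth$strand)
  expect_equal(hits$variant, truth$variant)
  expect_equal(hits$sequence, truth$sequence)
})

test_that("conservation profile behaves as an information content", {
  expect_equal(conservation_profile(rep("ACGT", 5)), rep(2, 4))
  mixed <- c("AAAA", "CAAA", "GAAA", "TAAA")
  prof <- conservation_profile(mixed)
  expect_equal(prof[1], 0)
  expect_equal(prof[2:4], rep(2, 3))
  # permutation invariance and range
  seqs <- expand_variant_counts()
  p1 <- conservation_profile(seqs)
  p2 <- conservation_profile(sample(seqs))
  expect_equal(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 2))
  expect_error(conservation_profile(character(0)))
})

test_that("strand asymmetry counts substituted bases and tests the split", {
  even <- c(rep("TAAACCAACCCCTTT", 5),   # 11C
            rep("TAAACCAACCTCGTT", 5))   # 13G
  sa <- strand_asymmetry(even)
  expect_equal(sa$n_sub_to_C, 5)
  expect_equal(sa$n_sub_to_G, 5)
  expect_equal(sa$chi_square, 0)
  expect_equal(sa$p_value, 1)
  none <- strand_asymmetry(rep("AAAACCAACCTCTTT", 3))  # 1A only
  expect_true(is.na(none$chi_square))
  # total substitution bookkeeping: counts x n_substitutions decomposes into
  # C + G + A/T substitutions
  tab <- cbs_variant_counts()
  sa_all <- strand_asymmetry(expand_variant_counts(tab))
  expect_equal(sum(tab$count * tab$n_substitutions),
               sa_all$n_sub_to_C + sa_all$n_sub_to_G + sa_all$n_sub_to_AT)
})

test_that("breakage maps tile the chromosome between Cbs sites", {
  fx <- medium_sim()
  chrom <- names(fx$mic)[1]
  hits <- scan_cbs(fx$mic[[chrom]], chrom)
  bm <- breakage_map(nchar(fx$mic[[chrom]]), hits)
  expect_equal(nrow(bm), nrow(hits) + 1)
  expect_equal(bm$start[1], 1)
  expect_equal(bm$end[nrow(bm)], nchar(fx$mic[[chrom]]))
  # segments and Cbs together cover the chromosome without overlap
  expect_equal(sum(bm$length) + 15 * nrow(hits), nchar(fx$mic[[chrom]]))
  expect_equal(sum(bm$type == "terminal"), 2)

  none <- breakage_map(5000, hits[0, ])
  expect_equal(nrow(none), 1)
  expect_equal(none$length, 5000)

  three <- data.frame(chromosome = "c", start = c(100, 300, 900),
                      end = c(114, 314, 914), strand = "+",
                      sequence = "TAAACCAACCTCTTT", variant = "canonical",
                      n_substitutions = 0L)
  expect_equal(nrow(breakage_map(2000, three)), 4)
})

test_that("non-maintained segments are called from somatic absence", {
  fx <- medium_pipeline()
  mcov <- mac_alignment_coverage(fx$blocks, fx$truth$chrom_lengths)
  found <- do.call(rbind, lapply(names(fx$mic), function(ch) {
    bm <- breakage_map(nchar(fx$mic[[ch]]), scan_cbs(fx$mic[[ch]], ch))
    detect_nmcs(bm, mcov[[ch]])
  }))
  truth_key <- paste(fx$truth$nmc_intervals$chromosome,
                     fx$truth$nmc_intervals$start, fx$truth$nmc_intervals$end)
  found_key <- paste(found$chromosome, found$start, found$end)
  expect_setequal(found_key, truth_key)
  # a fully covered internal segment is never reported
  bm1 <- breakage_map(nchar(fx$mic[[1]]), scan_cbs(fx$mic[[1]], names(fx$mic)[1]))
  full <- detect_nmcs(bm1, rep(1L, nchar(fx$mic[[1]])))
  expect_equal(nrow(full), 0)
  # an uncovered terminal segment is excluded by definition
  zero <- detect_nmcs(bm1, rep(0L, nchar(fx$mic[[1]])))
  expect_false(any(zero$type == "terminal"))
  expect_error(detect_nmcs(bm1, NULL), "coverage")
})

test_that("centromeres are mapped from viable arm deletions", {
  # the published chromosome-1 interval: flanking Cbs at 13.98 / 23.24 Mb
  hits <- data.frame(chromosome = "chr1",
                     start = c(2.1, 8.5, 13.98, 23.24, 30.2, 33.1) * 1e6,
                     end = c(2.1, 8.5, 13.98, 23.24, 30.2, 33.1) * 1e6 + 14)
  dels <- data.frame(start = c(1, 1, 30e6, 23e6),
                     end = c(14.5e6, 9e6, 36.32e6, 36.32e6),
                     arm = c("L", "L", "R", "R"))
  cen <- map_centromere(hits, dels, chromosome_length = 36.32e6)
  expect_equal(cen$cen_length / 1e6, 9.26)
  expect_equal(cen$cen_midpoint / 1e6, 18.61)
  # deletions that touch no Cbs: innermost pair around the midpoint
  no_touch <- data.frame(start = c(1, 35e6), end = c(1.5e6, 36.32e6),
                         arm = c("L", "R"))
  cen2 <- map_centromere(hits, no_touch, chromosome_length = 36.32e6)
  expect_equal(cen2$cen_start, 13.98e6)
  expect_equal(cen2$cen_end, 23.24e6)
  expect_error(map_centromere(hits,
                              data.frame(start = 1, end = 36.4e6, arm = "L"),
                              chromosome_length = 36.32e6), "whole chromosome")
})

test_that("Fitch parsimony equals exhaustive enumeration on small trees", {
  tree <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(cbs_parsimony(tree, c(a = "canonical", b = "canonical",
                                     c = "canonical", d = "canonical")), 0)
  expect_equal(cbs_parsimony(tree, c(a = "canonical", b = "canonical",
                                     c = "canonical", d = "14C")), 1)
  # missing tips are unconstrained
  expect_equal(cbs_parsimony(tree, c(a = "1A", b = NA, c = "1A", d = NA)), 0)
  expect_error(cbs_parsimony(tree, c(a = NA, b = NA, c = NA, d = NA)))
  set.seed(42)
  states <- c("canonical", "1A", "11C")
  for (rep in 1:30) {
    n <- sample(3:6, 1)
    tr <- ape::rtree(n)
    tips <- stats::setNames(sample(states, n, replace = TRUE), tr$tip.label)
    if (runif(1) < 0.3) tips[sample(n, 1)] <- NA
    if (all(is.na(tips))) next
    expect_equal(cbs_parsimony(tr, tips), cbs_parsimony_bruteforce(tr, tips),
                 info = paste("tree", rep))
  }
})
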