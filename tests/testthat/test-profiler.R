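V4F <- "GTGCCAGCAGCCGCGGTAA"

read_tbl <- function(seqs, qual_char = "I") {
  tibble::tibble(id = sprintf("r%d", seq_along(seqs)), seq = seqs,
                 qual = strrep(qual_char, nchar(seqs)))
}

test_that("adapter read-through is trimmed by overlap suffix match", {
  adapter <- "GTCTCGTGGGCTCGGAGATG"
  body <- "ACGTACGTACGTACGTACGTACGTACGT"
  # full read-through: whole adapter removed
  full <- trim_adapters(read_tbl(paste0(body, adapter)), adapter)
  expect_equal(full$seq, body)
  expect_equal(nchar(full$qual), nchar(body))
  # no adapter: unchanged
  clean <- trim_adapters(read_tbl(body), adapter)
  expect_equal(clean$seq, body)
  expect_equal(clean$trimmed, 0L)
  # 10-base overlap with one mismatch (1/10 <= 0.1): trimmed
  ten <- substr(adapter, 1, 10)
  ten_mm <- paste0(substr(ten, 1, 9), "A")
  expect_equal(oracle_hamming(ten, ten_mm), 1)
  part <- trim_adapters(read_tbl(paste0(body, ten_mm)), adapter)
  expect_equal(part$seq, body)
  # 2 mismatches in a 10-base overlap (0.2 > 0.1): left alone
  ten_mm2 <- paste0("CA", substr(ten, 3, 10))
  stopifnot(oracle_hamming(ten, ten_mm2) == 2)
  keep <- trim_adapters(read_tbl(paste0(body, ten_mm2)), adapter)
  expect_equal(keep$seq, paste0(body, ten_mm2))
  # reads are never lengthened
  expect_true(all(nchar(full$seq) <= nchar(paste0(body, adapter))))
})

test_that("pairs merge by best ungapped overlap with quality consensus", {
  amp <- withr::with_seed(3, paste(sample(c("A", "C", "G", "T"), 332, TRUE),
                                   collapse = ""))
  # fully overlapping error-free pair reconstructs the 332-base amplicon
  m <- merge_pairs(read_tbl(amp), read_tbl(revcomp(amp)))
  expect_true(m$merged)
  expect_equal(nchar(m$seq), 332)
  expect_equal(m$seq, amp)
  # partially overlapping pair: merged length = len1 + len2 - overlap
  r1 <- substr(amp, 1, 200)
  r2 <- revcomp(substr(amp, 133, 332))
  mp <- merge_pairs(read_tbl(r1), read_tbl(r2))
  expect_equal(mp$overlap, 68L)
  expect_equal(nchar(mp$seq), 332)
  expect_equal(mp$seq, amp)
  # disjoint random sequences do not merge
  other <- withr::with_seed(4, paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                                     collapse = ""))
  md <- merge_pairs(read_tbl(substr(amp, 1, 200)), read_tbl(other))
  expect_false(md$merged)
  expect_true(is.na(md$seq))
})

test_that("consensus takes the higher-quality base at conflicts", {
  a <- "ACGTACGTACGTACGTACGTACGT"
  b <- a
  substr(b, 11, 11) <- "T"  # conflict at one position (G in read 1)
  # read 1 high quality, read 2 low quality -> read 1 base wins
  m1 <- merge_pairs(
    tibble::tibble(id = "r", seq = a, qual = strrep("I", 24)),
    tibble::tibble(id = "r", seq = revcomp(b), qual = strrep("#", 24)))
  expect_equal(m1$seq, a)
  # reversed qualities -> read 2 base wins
  m2 <- merge_pairs(
    tibble::tibble(id = "r", seq = a, qual = strrep("#", 24)),
    tibble::tibble(id = "r", seq = revcomp(b), qual = strrep("I", 24)))
  expect_equal(m2$seq, b)
})

test_that("primer-region profiling filters and counts correctly", {
  tail_seq <- "ACGTACGTAC"
  wt <- paste0(V4F, tail_seq)
  var1 <- paste0(sub("A$", "C", V4F), tail_seq)  # 3'-terminal A->C
  four <- paste0("CACA", substr(V4F, 5, 19), tail_seq)      # 4 mismatches
  short <- substr(V4F, 1, 10)
  em <- profile_primer_region(c(rep(wt, 8), var1, four, short), V4F)
  g <- glance(em)
  expect_equal(g$reads_total, 11)
  expect_equal(g$reads_pass_filter, 9)
  expect_equal(g$reads_failed_filter, 1)
  expect_equal(g$reads_short, 1)
  # column sums over bases equal passing reads at every position
  expect_true(all(em$A + em$C + em$G + em$T + em$N == 9))
  # the variant increments the terminal C count only
  expect_equal(em$C[em$distance_from_3prime == 1], 1)
  expect_equal(em$nonref_prop[em$distance_from_3prime == 1], 1 / 9)
  expect_true(all(em$nonref_prop[em$distance_from_3prime > 1] == 0))
})

test_that("degenerate reference positions match compatible bases", {
  ref <- "GTGCCAGCMGCCGCGGTAA"  # M = A or C at position 9
  reads <- c("GTGCCAGCAGCCGCGGTAA", "GTGCCAGCCGCCGCGGTAA",
             "GTGCCAGCGGCCGCGGTAA")
  em <- profile_primer_region(reads, ref, max_mm = 0)
  # G at the M position is a mismatch, A and C are not
  expect_equal(glance(em)$reads_pass_filter, 2)
  expect_true(is.na(em$nonref_prop[em$position == 9]))
  expect_true(all(!is.na(em$nonref_prop[em$position != 9])))
})

test_that("observed/expected ratios divide by pool composition", {
  cs <- test_constructs()
  em <- profile_run(cs, editing_profile(rep(1, 6)), n_reads = 20000, seed = 81)
  oe <- observed_over_expected(em, cs)
  expect_equal(nrow(oe), 19)
  expect_equal(oe$expected[oe$distance_from_3prime <= 10],
               rep(3 / 31, 10), tolerance = 1e-12)
  # outside the window no construct varies: undefined, not zero
  expect_true(all(is.na(oe$ratio[oe$distance_from_3prime > 10])))
  expect_true(all(oe$expected[oe$distance_from_3prime > 10] == 0))
  # ratio identity at covered positions
  expect_equal(oe$ratio[oe$distance_from_3prime == 1],
               oe$observed[oe$distance_from_3prime == 1] / (3 / 31))
  # non-uniform abundance changes the denominator accordingly
  ab <- even_abundance(cs)
  ab$proportion <- ifelse(cs$variant_pos == 1, 2 / 62, 1 / 31)
  ab$proportion <- ab$proportion / sum(ab$proportion)
  oe2 <- observed_over_expected(em, cs, abundance = ab)
  exp1 <- sum(ab$proportion[cs$variant_pos == 1])
  expect_equal(oe2$expected[oe2$distance_from_3prime == 1], exp1)
  # a window wider than the profiled region is a consistency error
  em5 <- profile_primer_region(substr(cs$insert_seq[1], 21, 40), "GTGCC")
  expect_error(observed_over_expected(em5, cs), "beyond")
})

test_that("reverse primer region shows no editing in standards runs", {
  cs <- test_constructs()
  scheme <- primer_scheme()
  run <- simulate_standards_run(cs, editing = editing_profile(rep(1, 10)),
                                cfg = sim_config(n_reads = 10000, seed = 82))
  merged <- merge_pairs(run$reads1, run$reads2)
  # the reverse primer region is the 3' end of the merged read, read from
  # the other strand
  em_rev <- profile_primer_region(revcomp(merged$seq[merged$merged]),
                                  scheme$rev_locus)
  expect_equal(nrow(em_rev), 20)
  expect_true(all(em_rev$nonref_prop == 0))
})

test_that("penalty folds are exact for proportional counts", {
  scheme <- primer_scheme()
  v <- enumerate_variants(V4F, 2)
  # 10 reads per class, exactly even: all folds 1 under both anchors
  reads <- rep(paste0(v$site, "ACGTACGTAC"), each = 10)
  for (anchor in c("wild_type", "whole_pool")) {
    pt <- penalty_analysis(reads, scheme, window = 2, anchor = anchor)
    expect_equal(pt$variants$fold, rep(1, 6))
    expect_equal(pt$positions$fold, rep(1, 2))
  }
  # an absent variant has fold 0; reads with >1 mismatch fall into `other`
  drop <- v$site[-(1:2)]  # drop wild type and first variant
  junk <- paste0("TTTT", substr(V4F, 5, 19), "ACGTACGTAC")
  pt2 <- penalty_analysis(c(paste0(rep(drop, each = 5), "ACGTACGTAC"),
                            rep(V4F, 5), junk),
                          scheme, window = 2)
  expect_equal(pt2$variants$fold[1], 0)
  expect_equal(glance(pt2)$other, 1)
  t <- glance(pt2)
  expect_equal(t$wild_type + t$pool_variants + t$other + t$short,
               t$reads_total)
  # no wild-type reads: undefined folds with a warning
  expect_warning(
    pt3 <- penalty_analysis(paste0(drop, "AC"), scheme, window = 2),
    "wild-type")
  expect_true(all(is.na(pt3$variants$fold)))
})

test_that("obs/exp recovers the editing efficiency and is monotone in it", {
  cs <- test_constructs()
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  for (seed in 1:2) {
    ratios <- vapply(grid, function(e) {
      em <- profile_run(cs, editing_profile(c(`3` = e)),
                        n_reads = 50000, seed = 90 + seed)
      oe <- observed_over_expected(em, cs)
      oe$ratio[oe$distance_from_3prime == 3]
    }, numeric(1))
    # with a_p = 1 the metric equals e_p under the generative model
    for (i in seq_along(grid)) {
      tol <- binom_tol(grid[i] * 3 / 31, 50000) / (3 / 31)
      expect_lt(abs(ratios[i] - grid[i]), max(tol, 1e-9))
    }
    expect_true(all(diff(ratios) > -0.02))
  }
})

test_that("a zero-editing profile stays at the sequencing-error floor", {
  cs <- test_constructs()
  em <- profile_run(cs, editing_profile(), n_reads = 30000, seed = 95,
                    error_rate = 0.005)
  oe <- observed_over_expected(em, cs)
  floor <- error_floor(em, window = 10)
  expect_lt(floor, 0.01)
  expect_true(all(oe$observed[oe$distance_from_3prime <= 10] <= 3 * floor))
})
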