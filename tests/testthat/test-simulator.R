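test_that("edited-base frequencies match the closed-form oracle", {
  cs <- test_constructs()
  e <- c(0.8, 0.3, 0.6, 1, 0, 0.5)
  a <- c(0.2, 0.9, 1, 0.5, 0.7)
  em <- profile_run(cs, editing_profile(e), penalty_profile(a),
                    n_reads = 50000, seed = 21)
  abund <- rep(1 / 31, 31)
  for (p in 1:6) {
    expected <- oracle_edit_freq(cs$variant_pos, abund, e, a, p)
    obs <- em$nonref_prop[em$distance_from_3prime == p]
    expect_lt(abs(obs - expected), binom_tol(expected, 50000))
  }
})

test_that("model limits behave: complete editing and no editing", {
  cs <- test_constructs()
  # e = 1 everywhere: per-position edited fraction equals pooled variant
  # abundance, 3/31 for the even pool
  em1 <- profile_run(cs, editing_profile(rep(1, 10)), n_reads = 30000,
                     seed = 31)
  for (p in 1:10) {
    obs <- em1$nonref_prop[em1$distance_from_3prime == p]
    expect_lt(abs(obs - 3 / 31), binom_tol(3 / 31, 30000))
  }
  # e = 0, a = 1: no edited bases at all before sequencing error, and
  # construct sampling matches the pool composition
  run0 <- simulate_standards_run(cs, editing = editing_profile(),
                                 cfg = sim_config(n_reads = 20000, seed = 32))
  em0 <- profile_primer_region(merge_pairs(run0$reads1, run0$reads2),
                               primer_scheme()$fwd_locus)
  expect_true(all(em0$nonref_prop == 0))
  shares <- table(run0$truth$construct_id) / 20000
  expect_true(all(abs(shares - 1 / 31) < binom_tol(1 / 31, 20000)))
})

test_that("two-construct pool recovers the derived closed form", {
  # {WT, variant at position 1}, even; e1 = 0.5, a1 = 0:
  # weight(var) = 0.5 * 0.5, weight(WT) = 0.5, so P(var) = 1/3 and every
  # sampled variant read is edited -> edited fraction 1/3 at position 1.
  expect_equal(oracle_edit_freq(c(0, 1), c(0.5, 0.5), 0.5, 0, 1), 1 / 3,
               tolerance = 1e-12)

  cs <- test_constructs(window = 10)
  ab <- tibble::tibble(construct_id = cs$construct_id,
                       proportion = ifelse(cs$construct_id %in%
                                             c("WT", "P01_C"), 0.5, 0))
  run <- simulate_standards_run(
    cs, abundance = ab, editing = editing_profile(c(`1` = 0.5)),
    penalty = penalty_profile(c(`1` = 0)),
    cfg = sim_config(n_reads = 30000, seed = 33))
  em <- profile_primer_region(merge_pairs(run$reads1, run$reads2),
                              primer_scheme()$fwd_locus)
  obs <- em$nonref_prop[em$distance_from_3prime == 1]
  expect_lt(abs(obs - 1 / 3), binom_tol(1 / 3, 30000))
  expect_lt(abs(mean(run$truth$construct_id == "P01_C") - 1 / 3),
            binom_tol(1 / 3, 30000))
  expect_true(all(run$truth$edited[run$truth$construct_id == "P01_C"]))
})

test_that("exonuclease block truncates the editable window", {
  cs <- test_constructs()
  em <- profile_run(cs, editing_profile(rep(1, 10), block_after = 3),
                    n_reads = 20000, seed = 34)
  expect_true(all(em$nonref_prop[em$distance_from_3prime > 3] == 0))
  for (p in 1:3) {
    obs <- em$nonref_prop[em$distance_from_3prime == p]
    expect_lt(abs(obs - 3 / 31), binom_tol(3 / 31, 20000))
  }
})

test_that("identical seed and config reproduce byte-identical output", {
  cs <- test_constructs(window = 3)
  cfg <- sim_config(n_reads = 500, error_rate = 0.01, seed = 9)
  r1 <- simulate_standards_run(cs, editing = editing_profile(rep(0.5, 3)),
                               cfg = cfg)
  r2 <- simulate_standards_run(cs, editing = editing_profile(rep(0.5, 3)),
                               cfg = cfg)
  expect_identical(r1$reads1, r2$reads1)
  expect_identical(r1$truth, r2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_run(r1, d1); write_sim_run(r2, d2)
  expect_identical(
    unname(tools::md5sum(file.path(d1, "standards_R1.fastq"))),
    unname(tools::md5sum(file.path(d2, "standards_R1.fastq"))))
  # annealing temperature is provenance only: the stream is unchanged
  cfg_t <- sim_config(n_reads = 500, error_rate = 0.01, seed = 9,
                      annealing_temp = 55)
  r3 <- simulate_standards_run(cs, editing = editing_profile(rep(0.5, 3)),
                               cfg = cfg_t)
  expect_identical(r1$reads1, r3$reads1)
})

test_that("ground truth is consistent with the emitted reads", {
  cs <- test_constructs()
  L <- nchar(primer_scheme()$fwd_locus)
  run <- simulate_standards_run(cs, editing = editing_profile(rep(0.5, 10)),
                                cfg = sim_config(n_reads = 2000, seed = 35))
  tr <- dplyr::left_join(
    run$truth,
    dplyr::select(cs, "construct_id", "variant_base"),
    by = "construct_id")
  pos5 <- L - tr$variant_pos + 1
  base_at <- substring(run$reads1$seq, pos5, pos5)
  ref_at <- substring(primer_scheme()$fwd_locus, pos5, pos5)
  is_var <- tr$variant_pos > 0
  expect_true(all(base_at[is_var & tr$edited] ==
                    tr$variant_base[is_var & tr$edited]))
  expect_true(all(base_at[is_var & !tr$edited] == ref_at[is_var & !tr$edited]))
})

test_that("variant-primer run mirrors the standards model", {
  tpl <- test_template()
  # complete reciprocal editing: every read shows the wild-type primer
  r1 <- simulate_variant_primer_run(
    tpl, window = 10, editing = editing_profile(rep(1, 10)),
    cfg = sim_config(n_reads = 5000, seed = 41))
  em <- profile_primer_region(merge_pairs(r1$reads1, r1$reads2),
                              primer_scheme()$fwd_locus)
  expect_true(all(em$nonref_prop == 0))

  # no editing, no penalty: even class shares
  r0 <- simulate_variant_primer_run(
    tpl, window = 10, cfg = sim_config(n_reads = 31000, seed = 42))
  shares <- table(r0$truth$primer_id) / 31000
  expect_true(all(abs(shares - 1 / 31) < binom_tol(1 / 31, 31000)))

  # full penalty at position 1 removes those primer classes entirely
  rp <- simulate_variant_primer_run(
    tpl, window = 10, penalty = penalty_profile(c(`1` = 0)),
    cfg = sim_config(n_reads = 10000, seed = 43))
  expect_equal(sum(rp$truth$variant_pos == 1), 0)
})

test_that("barcode reads follow the pool multinomially", {
  cs <- test_constructs()
  run <- simulate_barcode_reads(cs, cfg = sim_config(n_reads = 31000, seed = 51))
  expect_true(all(substr(run$reads1$seq, 1, 20) %in% cs$barcode))
  counts <- table(factor(run$truth$construct_id, levels = cs$construct_id))
  expect_true(all(abs(counts / 31000 - 1 / 31) < binom_tol(1 / 31, 31000)))

  solo <- tibble::tibble(construct_id = cs$construct_id,
                         proportion = as.numeric(cs$construct_id == "WT"))
  run1 <- simulate_barcode_reads(cs, abundance = solo,
                                 cfg = sim_config(n_reads = 200, seed = 52))
  expect_true(all(run1$truth$construct_id == "WT"))

  # at 1% error the fraction of reads with >= 3 barcode errors matches the
  # binomial closed form, so >= 99.9% stay assignable at the 2-mm threshold
  rer <- simulate_barcode_reads(
    cs, cfg = sim_config(n_reads = 31000, error_rate = 0.01, seed = 53))
  true_bc <- cs$barcode[match(rer$truth$construct_id, cs$construct_id)]
  d <- mapply(oracle_hamming, substr(rer$reads1$seq, 1, 20), true_bc)
  p3 <- 1 - sum(dbinom(0:2, 20, 0.01))
  expect_lt(abs(mean(d >= 3) - p3), binom_tol(p3, 31000) + 1e-4)
})

test_that("simulation rejects inconsistent pools and configs", {
  cs <- test_constructs(window = 2)
  bad <- tibble::tibble(construct_id = c("nope"), proportion = 1)
  expect_error(simulate_standards_run(cs, abundance = bad), "same pool")
  unnorm <- even_abundance(cs); unnorm$proportion <- unnorm$proportion * 2
  expect_error(simulate_standards_run(cs, abundance = unnorm), "sum to 1")
  expect_error(sim_config(error_rate = 0.5), "error_rate")
  expect_error(sim_config(n_reads = 0), "n_reads")
})
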