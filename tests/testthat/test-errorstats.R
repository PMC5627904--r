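test_that("error decomposition pools cigar events over the ref span", {
  tmpl <- make_template(80, seed = 1)
  perfect <- lapply(1:3, function(k) semiglobal_align(tmpl, tmpl))
  dec <- decompose_errors(perfect)
  expect_equal(c(dec$mismatch_pct, dec$insertion_pct, dec$deletion_pct,
                 dec$mean_error_pct), c(0, 0, 0, 0))

  # hand-counted synthetic alignment: ref span 4+1+2+1+2 = 10, one of each
  # event class -> 10% per component, 30% mean
  a <- structure(list(
    query_id = "q", ref_id = "r", score = 0,
    ref_start = 0L, ref_end = 10L,
    cigar = data.frame(op = c("=", "X", "I", "=", "D", "="),
                       len = c(4L, 1L, 1L, 2L, 1L, 2L)),
    strand = "+", identity_pct = 100 * 6 / 11, query = strrep("A", 8)),
    class = "alignment_result")
  dec1 <- decompose_errors(list(a))
  expect_equal(dec1$mismatch_pct, 10)
  expect_equal(dec1$insertion_pct, 10)
  expect_equal(dec1$deletion_pct, 10)
  expect_equal(dec1$mean_error_pct, 30)
  expect_equal(dec1$denominator, 10)

  expect_error(decompose_errors(list()), "input error")
  # mean always equals the exact sum of the components
  expect_equal(dec1$mean_error_pct,
               dec1$mismatch_pct + dec1$insertion_pct + dec1$deletion_pct)

  f <- withr::local_tempfile(fileext = ".json")
  write_decomposition_json(dec1, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$mean_error_pct, 30)
  expect_equal(j$denominator, 10)
})

test_that("decomposition recovers generative rates across seeds", {
  # homopolymer model off; alignment reshuffling merges some adjacent
  # indel pairs into mismatches, hence the tolerances
  tmpl <- make_template(300, seed = 2)
  prof <- error_profile(0.08, 0.04, 0.05, h0 = 0)
  for (sd in 1:5) {
    sim <- simulate_run(tmpl, prof, run_config(800, pass_fraction = 1,
                                               seed = sd))
    alns <- lapply(sim_records(sim), orient_and_align, ref = tmpl)
    dec <- decompose_errors(alns)
    expect_lt(abs(dec$mismatch_pct - 8), 1.5)
    expect_lt(abs(dec$insertion_pct - 4), 1.5)
    expect_lt(abs(dec$deletion_pct - 5), 1.5)
    expect_lt(abs(dec$mean_error_pct - 17), 2)
  }
})

test_that("coverage dips at homopolymer runs exactly when h0 > 0", {
  tmpl <- make_runny_template(seed = 5)

  # uniform synthetic coverage: ratio exactly 1
  alns <- lapply(1:10, function(k) semiglobal_align(tmpl, tmpl))
  prof_u <- coverage_profile(pileup_from_alignments(alns, tmpl))
  cvh <- coverage_vs_homopolymers(prof_u, min_run = 4)
  expect_equal(cvh$ratio, 1.0)

  run_ratio <- function(h0, seed) {
    p <- error_profile(0.08, 0.04, 0.05, h0 = h0)
    sim <- simulate_run(tmpl, p, run_config(300, pass_fraction = 1,
                                            seed = seed))
    alns <- lapply(sim_records(sim), orient_and_align, ref = tmpl)
    pile <- pileup_from_alignments(
      filter_alignments(alns, min_identity_pct = 70), tmpl)
    coverage_vs_homopolymers(coverage_profile(pile), min_run = 4)$ratio
  }
  expect_gt(run_ratio(0, seed = 7), 0.95)
  expect_lt(run_ratio(0, seed = 7), 1.05)
  expect_lt(run_ratio(0.05, seed = 7), 1.0)

  # degenerate masks are rejected
  allrun <- coverage_profile(pileup_from_alignments(
    list(semiglobal_align(seq_record("q", "AAAAAA"),
                          seq_record("ref", "AAAAAA"))),
    seq_record("ref", "AAAAAA")))
  expect_error(coverage_vs_homopolymers(allrun, min_run = 4), "degenerate")
})

test_that("per-channel normalisation reproduces the published run tables", {
  # storage-temperature runs
  expect_equal(unname(normalize_counts(
    run_counts(262, 226, 54380, 7873, 2163))), c(241, 35, 10))
  expect_equal(unname(normalize_counts(
    run_counts(494, 425, 141908, 33200, 8144))), c(334, 78, 19))
  expect_equal(unname(normalize_counts(
    run_counts(120, 128, 11594, 2307, 784))), c(91, 18, 6))
  expect_equal(unname(normalize_counts(
    run_counts(365, 353, 115673, 20529, 5652))), c(328, 58, 16))
  # protocol-comparison runs
  expect_equal(unname(normalize_counts(
    run_counts(480, 257, 170193, 10250, 3730))), c(662, 40, 15))
  expect_equal(unname(normalize_counts(
    run_counts(208, 203, 54512, 9536, 3441))), c(269, 47, 17))
  # identity when a single channel produced the reads
  expect_equal(unname(normalize_counts(run_counts(1, 1, 777, 10, 5))[1]), 777)
  expect_error(run_counts(1, 0, 10, 5, 2))
})

test_that("percentages of total reproduce the published cells half-up", {
  expect_equal(percent_of_total(33200, 141908), 23.4)
  expect_equal(percent_of_total(8144, 141908), 5.7)
  expect_equal(percent_of_total(2163, 54380), 4.0)
  expect_equal(percent_of_total(2307, 11594), 19.9)
  expect_equal(percent_of_total(784, 11594), 6.8)
  expect_equal(percent_of_total(20529, 115673), 17.7)
  expect_equal(percent_of_total(5652, 115673), 4.9)
  expect_equal(percent_of_total(10250, 170193), 6.0)
  expect_equal(percent_of_total(3730, 170193), 2.2)
  expect_equal(percent_of_total(9536, 54512), 17.5)
  expect_equal(percent_of_total(3441, 54512), 6.3)
  # later-chemistry pass rates, printed without decimals
  expect_equal(percent_of_total(98252, 160321, 0), 61)
  expect_equal(percent_of_total(205929, 300252, 0), 69)
  # aligned fraction of the quality-filtered set
  expect_equal(percent_of_total(977, 2660, 0), 37)
  expect_equal(percent_of_total(0, 10), 0.0)
  expect_error(percent_of_total(1, 0), "input error")
})

test_that("round_half_up rounds .5 away from zero at any precision", {
  expect_equal(round_half_up(240.5), 241)
  expect_equal(round_half_up(240.4999), 240)
  expect_equal(round_half_up(23.35, 1), 23.4)
  expect_equal(round_half_up(2.25, 1), 2.3)
  expect_equal(round_half_up(0.05, 1), 0.1)
})

test_that("run-statistics table combines raw, normalised and percentages", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\tchannels_qc\tchannels_with_reads\ttotal\td2\td2_pass",
               "minus20_a\t262\t226\t54380\t7873\t2163",
               "minus20_b\t494\t425\t141908\t33200\t8144"), f)
  counts <- read_run_counts(f)
  tab <- run_stats_table(counts)
  expect_equal(tab$label, c("minus20_a", "minus20_b"))
  expect_equal(tab$norm_total, c(241, 334))
  expect_equal(tab$pct_2d, c(14.5, 23.4))
  expect_equal(tab$pct_2d_pass, c(4.0, 5.7))
})
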