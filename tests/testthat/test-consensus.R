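test_that("POA consensus of replicated reads is the read itself", {
  r <- "ACGTTGCAAGTCCGTA"
  for (n in 1:10) {
    dc <- draft_consensus(lapply(seq_len(n), function(i)
      seq_record(paste0("r", i), r)))
    expect_equal(dc$seq, r)
    expect_equal(dc$source, "draft_poa")
    # node support along the consensus equals the number of reads
    expect_equal(unique(dc$per_position_freq), 1)
  }
  expect_error(draft_consensus(list()), "no reads")
})

test_that("draft consensus from noisy reads recovers the template", {
  tmpl <- make_template(300, seed = 3)
  sim <- simulate_run(tmpl, minion_profile("R7.4"),
                      run_config(100, pass_fraction = 1, seed = 3))
  dc <- draft_consensus(sim_records(sim))
  expect_gte(identity_to(dc$seq, tmpl), 99)
})

test_that("pileup counts walk the cigar correctly", {
  tmpl <- make_template(60, seed = 7)
  alns <- lapply(1:3, function(k) semiglobal_align(tmpl, tmpl))
  pile <- pileup_from_alignments(alns, tmpl)
  rb <- strsplit(tmpl$seq, "")[[1]]
  for (i in seq_len(60)) {
    expect_equal(unname(pile$counts[rb[i], i]), 3L)
  }
  expect_equal(sum(pile$counts["-", ]), 0)
  expect_length(pile$insertions, 0)
  expect_equal(pile$coverage, rep(3L, 60))

  # hand-built internal deletion, flanked well enough that no mismatch
  # variant ties its score: query lacks the C of AAACGTTT
  ref <- seq_record("ref", "AAACGTTT")
  q <- seq_record("q", "AAAGTTT")
  a <- semiglobal_align(q, ref)
  pile2 <- pileup_from_alignments(list(a), ref)
  expect_equal(a$cigar$op, c("=", "D", "="))
  expect_equal(sum(pile2$counts["-", ]), 1L)
  expect_equal(unname(pile2$counts["-", 4]), 1L)

  # mismatched reference id is a consistency error
  other <- seq_record("other", tmpl$seq)
  expect_error(pileup_from_alignments(alns, other), "consistency")
})

test_that("majority calls, tie rules, deletions and insertions", {
  ref <- seq_record("ref", "ACGTACGTAC")
  mk_pile <- function(counts, insertions = list()) {
    structure(list(ref_id = "ref", ref_seq = ref$seq, counts = counts,
                   insertions = insertions,
                   coverage = as.integer(colSums(counts)),
                   n_alignments = max(colSums(counts), 0L)),
              class = "pileup_matrix")
  }
  base_counts <- function() {
    counts <- matrix(0L, 5, 10, dimnames = list(c("A", "C", "G", "T", "-"),
                                                NULL))
    rb <- strsplit(ref$seq, "")[[1]]
    for (i in 1:10) counts[rb[i], i] <- 6L
    counts
  }

  # plain majority
  counts <- base_counts()
  counts[, 1] <- 0L; counts["A", 1] <- 5L; counts["C", 1] <- 1L
  cc <- call_consensus(mk_pile(counts))
  expect_equal(substr(cc$seq, 1, 1), "A")
  expect_equal(cc$per_position_freq[1], 5 / 6)

  # tie resolves toward the reference base
  counts <- base_counts()
  counts[, 1] <- 0L; counts["A", 1] <- 3L; counts["C", 1] <- 3L
  expect_equal(substr(call_consensus(mk_pile(counts))$seq, 1, 1), "A")

  # tie away from the reference resolves alphabetically
  counts <- base_counts()
  counts[, 2] <- 0L; counts["G", 2] <- 3L; counts["T", 2] <- 3L
  expect_equal(substr(call_consensus(mk_pile(counts))$seq, 2, 2), "G")

  # modal deletion drops the position
  counts <- base_counts()
  counts[, 4] <- 0L; counts["-", 4] <- 6L; counts["T", 4] <- 4L
  cc <- call_consensus(mk_pile(counts))
  expect_equal(nchar(cc$seq), 9)
  expect_equal(cc$seq, "ACGACGTAC")

  # deletion at exactly half the coverage is NOT modal (> 0.5 required)
  counts <- base_counts()
  counts[, 4] <- 0L; counts["-", 4] <- 5L; counts["T", 4] <- 5L
  expect_equal(nchar(call_consensus(mk_pile(counts))$seq), 10)

  # insertion emitted only above half the flanking coverage
  counts <- base_counts()
  ins <- list("3" = c(GG = 4L))
  cc <- call_consensus(mk_pile(counts, ins))
  expect_equal(cc$seq, "ACGGGTACGTAC")
  ins_low <- list("3" = c(GG = 3L))
  expect_equal(call_consensus(mk_pile(counts, ins_low))$seq, ref$seq)

  # low coverage emits the reference base, flagged
  counts <- base_counts()
  counts[, 7] <- 0L; counts["A", 7] <- 1L
  cc <- call_consensus(mk_pile(counts), min_coverage = 2)
  expect_equal(cc$seq, ref$seq)
  expect_equal(cc$low_coverage, 6L)
  expect_true(is.na(cc$per_position_freq[7]))

  expect_error(call_consensus(mk_pile(base_counts()[, 0, drop = FALSE])),
               "input error")
})

test_that("frequency-matrix TSV mirrors the pileup", {
  tmpl <- make_template(50, seed = 11)
  sim <- simulate_run(tmpl, minion_profile("R7.4"),
                      run_config(30, pass_fraction = 1, seed = 13))
  cons <- reference_consensus(sim_records(sim), tmpl)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_freq_matrix(cons, f)
  df <- read.delim(f)
  expect_equal(nrow(df), 50)
  expect_equal(df$position, 1:50)
  expect_equal(df$coverage, df$A + df$C + df$G + df$T + df$del)
  expect_true(all(df$called_freq > 0.5, na.rm = TRUE))
})

test_that("reference-guided consensus outvotes an imperfect reference", {
  tmpl <- make_template(300, seed = 17)
  sim <- simulate_run(tmpl, minion_profile("R7.4"),
                      run_config(300, pass_fraction = 1, seed = 17))
  # reference from a related individual: 3 substitutions off the truth
  refseq <- strsplit(tmpl$seq, "")[[1]]
  set.seed(18)
  pos <- sample(20:280, 3)
  for (p in pos) refseq[p] <- setdiff(c("A", "C", "G", "T"), refseq[p])[1]
  hit <- seq_record("related_species", paste(refseq, collapse = ""))
  cons <- reference_consensus(sim_records(sim), hit)
  expect_equal(cons$seq, tmpl$seq)  # the reads outvote the reference
  expect_equal(cons$ref_id, "related_species")
})

test_that("fail-tier-only reads still yield a perfect guided consensus", {
  # the field-sample situation: low yield, no usable pass reads, correct-
  # species reference available
  tmpl <- make_template(300, seed = 19)
  sim <- simulate_run(tmpl, minion_profile("R7.4"),
                      run_config(187, pass_fraction = 0, seed = 19))
  cons <- reference_consensus(sim_records(sim), tmpl, min_identity_pct = 60)
  expect_equal(cons$seq, tmpl$seq)
})

test_that("guided-consensus accuracy is monotone in coverage", {
  tmpl <- make_template(300, seed = 23)
  accuracy <- vapply(c(5, 20, 100, 900), function(n) {
    sim <- simulate_run(tmpl, minion_profile("R7.4"),
                        run_config(n, pass_fraction = 1, seed = 29))
    identity_to(reference_consensus(sim_records(sim), tmpl)$seq, tmpl)
  }, numeric(1))
  expect_true(all(diff(accuracy) >= 0))
  expect_equal(accuracy[4], 100)
})

test_that("reads identical to the reference reproduce it exactly", {
  tmpl <- make_template(150, seed = 31)
  reads <- lapply(1:20, function(k) seq_record(paste0("r", k), tmpl$seq))
  cons <- reference_consensus(reads, tmpl)
  expect_equal(cons$seq, tmpl$seq)
  expect_equal(unique(cons$per_position_freq), 1)
})

test_that("zero surviving alignments raise a diagnostic pipeline error", {
  tmpl <- make_template(100, seed = 37)
  junk <- list(seq_record("j", strrep("ACGT", 25)))
  expect_error(reference_consensus(junk, tmpl, min_identity_pct = 99),
               "0 of 1 alignments")
})
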