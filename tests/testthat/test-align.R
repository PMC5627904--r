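test_that("perfect self-alignment and the canonical one-insertion case", {
  r <- seq_record("r", "ACGTACGTAC")
  a <- semiglobal_align(r, r)
  expect_equal(a$score, 10)
  expect_equal(a$cigar, data.frame(op = "=", len = 10L))
  expect_equal(a$identity_pct, 100)
  expect_equal(c(a$ref_start, a$ref_end), c(0, 10))

  # extra G in the query: one length-1 insertion, placed 3'-most in the run
  a2 <- semiglobal_align(seq_record("q", "ACGGT"), seq_record("r", "ACGT"))
  expect_equal(a2$score, 2)  # 4 matches - gap open
  expect_equal(a2$cigar$op, c("=", "I", "="))
  expect_equal(a2$cigar$len, c(3L, 1L, 1L))
  expect_error(semiglobal_align(seq_record("q", "ACRT"), r), "alphabet")
})

test_that("scores equal the brute-force affine oracle on short random pairs", {
  set.seed(17)
  sc <- alignment_scoring()
  for (k in 1:200) {
    q <- random_dna(sample(2:8, 1))
    r <- random_dna(sample(2:8, 1))
    a <- semiglobal_align(seq_record("q", q), seq_record("r", r), sc)
    expect_equal(a$score, oracle_semiglobal_score(q, r, sc),
                 info = paste(q, "vs", r))
  }
})

test_that("CIGAR is well-formed and reconstructs the aligned query", {
  set.seed(23)
  tmpl <- make_template(200, seed = 31)
  sim <- simulate_run(tmpl, minion_profile("R7.4"),
                      run_config(40, pass_fraction = 1, revcomp_fraction = 0,
                                 seed = 19))
  for (s in sim_records(sim)) {
    a <- semiglobal_align(s, tmpl)
    cig <- a$cigar
    # no two adjacent entries share an op
    expect_true(all(cig$op[-1] != cig$op[-nrow(cig)]))
    # column sums: query side and reference side
    expect_equal(sum(cig$len[cig$op %in% c("=", "X", "I")]), nchar(s$seq))
    expect_equal(sum(cig$len[cig$op %in% c("=", "X", "D")]),
                 a$ref_end - a$ref_start)
    # identity over all columns
    expect_equal(a$identity_pct,
                 100 * sum(cig$len[cig$op == "="]) / sum(cig$len))
    # replaying the cigar against the reference reproduces the query
    ops <- rep(cig$op, cig$len)
    rb <- strsplit(substr(tmpl$seq, a$ref_start + 1, a$ref_end), "")[[1]]
    qb <- strsplit(a$query, "")[[1]]
    ri <- 0L; qi <- 0L
    rebuilt <- character(0)
    for (op in ops) {
      if (op %in% c("=", "X")) {
        ri <- ri + 1L; qi <- qi + 1L
        if (op == "=") rebuilt <- c(rebuilt, rb[ri])
        else rebuilt <- c(rebuilt, qb[qi])
      } else if (op == "I") {
        qi <- qi + 1L
        rebuilt <- c(rebuilt, qb[qi])
      } else ri <- ri + 1L
      if (op == "=") expect_equal(rb[ri], qb[qi])
    }
    expect_equal(paste(rebuilt, collapse = ""), a$query)
  }
})

test_that("alignment is invariant under joint reverse complement", {
  # score invariance holds for arbitrary pairs; identity invariance is
  # checked on read-vs-template pairs, where co-optimal alignments share
  # the same op multiset (unrelated random pairs admit co-optimal
  # alignments with different column counts)
  set.seed(29)
  for (k in 1:20) {
    q <- random_dna(60)
    r <- random_dna(80)
    a <- semiglobal_align(seq_record("q", q), seq_record("r", r))
    b <- semiglobal_align(seq_record("q", reverse_complement(q)),
                          seq_record("r", reverse_complement(r)))
    expect_equal(a$score, b$score)
  }
  tmpl <- make_template(200, seed = 101)
  sim <- simulate_run(tmpl, minion_profile("R7.4"),
                      run_config(25, pass_fraction = 1, revcomp_fraction = 0,
                                 seed = 103))
  for (s in sim_records(sim)) {
    a <- semiglobal_align(s, tmpl)
    b <- semiglobal_align(seq_record("q", reverse_complement(s$seq)),
                          seq_record("r", reverse_complement(tmpl$seq)))
    expect_equal(a$score, b$score)
    # co-optimal tracebacks may differ by a column or two either side
    expect_lt(abs(a$identity_pct - b$identity_pct), 0.5)
  }
})

test_that("orientation detection recovers the emitted strand", {
  tmpl <- make_template(300, seed = 37)
  sub <- seq_record("s", substr(tmpl$seq, 11, 60))
  a <- orient_and_align(seq_record("q", reverse_complement(sub$seq)), tmpl)
  expect_equal(a$strand, "-")
  expect_equal(a$identity_pct, 100)
  b <- orient_and_align(sub, tmpl)
  expect_equal(b$strand, "+")

  # simulated minus reads under the early-chemistry profile: strand
  # recovered in at least 99% of 1000 reads
  sim <- simulate_run(tmpl, minion_profile("R7.4"),
                      run_config(1000, pass_fraction = 1, seed = 41))
  truth <- vapply(sim, function(s) s$record$meta$strand, character(1))
  called <- vapply(sim_records(sim), function(r)
    orient_and_align(r, tmpl)$strand, character(1))
  expect_gte(mean(called == truth), 0.99)
})

test_that("alignment filtering applies both thresholds and keeps order", {
  expect_equal(filter_alignments(list()), list())
  tmpl <- make_template(150, seed = 43)
  good <- semiglobal_align(tmpl, tmpl)
  expect_length(filter_alignments(list(good), 75, 0.8), 1)
  bad <- good
  bad$identity_pct <- 70
  expect_length(filter_alignments(list(bad), min_identity_pct = 75), 0)

  sim <- simulate_run(tmpl, minion_profile("R7.4"),
                      run_config(300, pass_fraction = 0.5, seed = 47))
  alns <- lapply(sim_records(sim), orient_and_align, ref = tmpl)
  kept <- filter_alignments(alns, min_identity_pct = 75)
  frac <- length(kept) / length(alns)
  expect_gt(frac, 0)
  expect_lt(frac, 1)
  expect_equal(vapply(kept, `[[`, character(1), "query_id"),
               vapply(alns, `[[`, character(1), "query_id")[
                 vapply(alns, `[[`, numeric(1), "identity_pct") >= 75])
})

test_that("SAM and TSV exports carry flags, positions and NM", {
  tmpl <- make_template(120, seed = 53)
  sim <- simulate_run(tmpl, minion_profile("R7.4"), run_config(5, seed = 59))
  alns <- lapply(sim_records(sim), orient_and_align, ref = tmpl)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(alns, tmpl, f)
  lines <- readLines(f)
  expect_true(startsWith(lines[1], "@HD"))
  expect_true(grepl(paste0("SN:", tmpl$id), lines[2]))
  body <- lines[-(1:2)]
  expect_length(body, 5)
  fields <- strsplit(body, "\t")
  expect_true(all(vapply(fields, `[`, character(1), 2) %in% c("0", "16")))
  expect_true(all(grepl("^NM:i:[0-9]+$",
                        vapply(fields, `[`, character(1), 12))))
  expect_false(any(grepl("[=X]", vapply(fields, `[`, character(1), 6))))
  # flags match the simulator's emitted strand
  emitted <- vapply(sim, function(s) s$record$meta$strand, character(1))
  expect_equal(vapply(fields, `[`, character(1), 2),
               ifelse(emitted == "-", "16", "0"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_alignments_tsv(alns, tsv)
  df <- read.delim(tsv)
  expect_equal(nrow(df), 5)
  expect_true(all(grepl("^([0-9]+[=XID])+$", df$cigar)))
})
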