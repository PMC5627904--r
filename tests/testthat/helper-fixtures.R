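# Shared fixtures: deterministic random templates and an independent
# brute-force affine-gap alignment oracle (plain R, different formulation
# from the package's dynamic programming).

make_template <- function(len, seed, id = "template") {
  set.seed(seed)
  seq_record(id, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = ""))
}

# template with embedded long homopolymer runs, for dip analytics
make_runny_template <- function(seed, id = "runny") {
  set.seed(seed)
  chunks <- character(0)
  for (k in 1:8) {
    chunks <- c(chunks,
                paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                      collapse = ""),
                strrep(sample(c("A", "C", "G", "T"), 1), 6))
  }
  seq_record(id, paste(chunks, collapse = ""))
}

random_iupac_string <- function(len) {
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  paste(sample(codes, len, replace = TRUE), collapse = "")
}

# global affine alignment score, three-matrix recursion in plain R
oracle_global_affine <- function(q, r, sc) {
  m <- nchar(q); n <- nchar(r)
  if (n == 0L) return(sc$gap_open + (m - 1) * sc$gap_extend)
  qb <- strsplit(q, "")[[1]]; rb <- strsplit(r, "")[[1]]
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  Iq <- matrix(NEG, m + 1, n + 1)
  Dr <- matrix(NEG, m + 1, n + 1)
  M[1, 1] <- 0
  for (i in seq_len(m)) Iq[i + 1, 1] <- sc$gap_open + (i - 1) * sc$gap_extend
  for (j in seq_len(n)) Dr[1, j + 1] <- sc$gap_open + (j - 1) * sc$gap_extend
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (qb[i] == rb[j] && qb[i] != "N") sc$match else sc$mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], Iq[i, j], Dr[i, j])
      Iq[i + 1, j + 1] <- max(M[i, j + 1] + sc$gap_open,
                              Iq[i, j + 1] + sc$gap_extend,
                              Dr[i, j + 1] + sc$gap_open)
      Dr[i + 1, j + 1] <- max(M[i + 1, j] + sc$gap_open,
                              Dr[i + 1, j] + sc$gap_extend,
                              Iq[i + 1, j] + sc$gap_open)
    }
  }
  max(M[m + 1, n + 1], Iq[m + 1, n + 1], Dr[m + 1, n + 1])
}

# free reference end gaps == best global score over all reference substrings
# (including the empty substring: the query aligned entirely as insertions)
oracle_semiglobal_score <- function(q, r, sc = alignment_scoring()) {
  m <- nchar(q); n <- nchar(r)
  best <- sc$gap_open + (m - 1) * sc$gap_extend
  for (i in seq_len(n)) {
    for (j in i:n) {
      best <- max(best, oracle_global_affine(q, substr(r, i, j), sc))
    }
  }
  best
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# identity of a consensus (either orientation) against the truth
identity_to <- function(seq, truth) {
  orient_and_align(seq_record("q", seq), truth)$identity_pct
}
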