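# Synthetic 2D nanopore-like amplicon reads: per-base mismatch / insertion /
# deletion channels, run-granularity homopolymer length errors, pass/fail
# tiers and channel metadata, with full ground truth for downstream tests.

#' Define a read error profile
#'
#' Per-base substitution, insertion and deletion probabilities, a
#' homopolymer length-error coefficient and a pass/fail rate multiplier.
#' Two named presets are built in, reflecting early (R7.4) and later (R9.4)
#' flowcell chemistries: `minion_profile("R7.4")` uses 8% mismatch, 4%
#' insertion, 5% deletion; `minion_profile("R9.4")` uses 1.6% / 0.8% / 4.1%.
#'
#' For each maximal template homopolymer run of length `l >= 2`, with
#' probability `min(1, h0 * (l - 1))` the emitted copy of the run is
#' lengthened or shortened by one base (fair coin), in addition to the
#' per-base channels. Non-pass reads use all three per-base rates multiplied
#' by `fail_multiplier` (clipped to 1).
#'
#' @param p_mis,p_ins,p_del Per-base event probabilities in `[0, 1]`
#'   (`p_ins < 1`: insertions repeat geometrically).
#' @param h0 Homopolymer length-error coefficient (dimensionless, >= 0).
#' @param fail_multiplier Rate multiplier for fail-tier reads (>= 1).
#' @param name Profile label.
#' @return An object of class `error_profile`.
#' @export
error_profile <- function(p_mis, p_ins, p_del, h0 = 0.05,
                          fail_multiplier = 2, name = "custom") {
  stopifnot(p_mis >= 0, p_mis <= 1, p_ins >= 0, p_ins < 1,
            p_del >= 0, p_del <= 1, p_mis + p_del <= 1,
            h0 >= 0, fail_multiplier >= 1)
  structure(list(p_mis = p_mis, p_ins = p_ins, p_del = p_del, h0 = h0,
                 fail_multiplier = fail_multiplier, name = name),
            class = "error_profile")
}

#' @rdname error_profile
#' @param preset `"R7.4"` or `"R9.4"`.
#' @export
minion_profile <- function(preset = c("R7.4", "R9.4")) {
  preset <- match.arg(preset)
  switch(preset,
         "R7.4" = error_profile(0.08, 0.04, 0.05, h0 = 0.05, name = "R7.4"),
         "R9.4" = error_profile(0.016, 0.008, 0.041, h0 = 0.05, name = "R9.4"))
}

scale_profile <- function(profile, mult) {
  p_mis <- min(1, profile$p_mis * mult)
  p_del <- min(1, profile$p_del * mult)
  if (p_mis + p_del > 1) {  # renormalise degenerate clipping
    s <- p_mis + p_del
    p_mis <- p_mis / s; p_del <- p_del / s
  }
  error_profile(p_mis = p_mis,
                p_ins = min(0.99, profile$p_ins * mult),
                p_del = p_del,
                h0 = profile$h0,
                fail_multiplier = 1,
                name = paste0(profile$name, "_fail"))
}

#' Define a simulated run configuration
#'
#' @param n_reads Number of reads to emit (>= 1).
#' @param pass_fraction Probability a read is 2D-pass (default 0.3, the
#'   order of pass rates seen on early 2D amplicon runs).
#' @param n_channels Number of flowcell channels for the channel metadata.
#' @param revcomp_fraction Probability a read is emitted reverse-complemented.
#' @param seed Integer seed; a run is fully reproducible given the seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_reads, pass_fraction = 0.3, n_channels = 64L,
                       revcomp_fraction = 0.5, seed = 1L) {
  stopifnot(n_reads >= 1, pass_fraction >= 0, pass_fraction <= 1,
            n_channels >= 1, revcomp_fraction >= 0, revcomp_fraction <= 1)
  structure(list(n_reads = as.integer(n_reads),
                 pass_fraction = pass_fraction,
                 n_channels = as.integer(n_channels),
                 revcomp_fraction = revcomp_fraction,
                 seed = as.integer(seed)),
            class = "run_config")
}

other_bases <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))

#' Apply an error profile to a template once
#'
#' Generates one read from `template` under `profile`, using the current RNG
#' state (seed via [set.seed()] or use [simulate_run()] for reproducible
#' batches). Per template base, in order: the base is deleted with
#' probability `p_del`, otherwise emitted, substituted with probability
#' `p_mis` by a uniform pick among the other three bases; after every
#' template position a geometric run of uniform random bases is inserted
#' (each trial succeeding with probability `p_ins`). The homopolymer model
#' is then applied at run granularity (see [error_profile()]).
#'
#' @param template A [seq_record()] (non-empty).
#' @param profile An [error_profile()].
#' @param id Identifier for the generated read.
#' @return An object of class `simulated_read`: a list with `record` (the
#'   read as a [seq_record()]), `truth_edits` (named counts of applied
#'   substitutions / inserted bases / deleted bases) and `template_id`.
#' @export
mutate_template <- function(template, profile, id = "sim_1") {
  stopifnot(is_seq_record(template), nzchar(template$seq),
            inherits(profile, "error_profile"))
  b <- strsplit(template$seq, "", fixed = TRUE)[[1]]
  L <- length(b)
  del <- runif(L) < profile$p_del
  sub <- !del & (runif(L) < profile$p_mis)
  emitted <- b
  if (any(sub)) {
    pick <- ceiling(runif(sum(sub)) * 3)
    emitted[sub] <- mapply(function(base, k) other_bases[[base]][k],
                           b[sub], pick, USE.NAMES = FALSE)
  }
  emitted[del] <- ""
  if (profile$p_ins > 0) {
    nins <- rgeom(L, prob = 1 - profile$p_ins)
    ins <- vapply(nins, function(k) {
      if (k == 0) "" else
        paste(DNA_BASES[ceiling(runif(k) * 4)], collapse = "")
    }, character(1))
  } else {
    nins <- integer(L)
    ins <- character(L)
    ins[] <- ""
  }
  n_h_ins <- 0L; n_h_del <- 0L
  if (profile$h0 > 0) {
    runs <- annotate_homopolymers(template$seq, min_len = 2L)
    if (nrow(runs) > 0) {
      hit <- runif(nrow(runs)) < pmin(1, profile$h0 * (runs$length - 1))
      lengthen <- runif(nrow(runs)) < 0.5
      for (k in which(hit)) {
        span <- (runs$start[k] + 1L):(runs$start[k] + runs$length[k])
        if (lengthen[k]) {
          pos <- span[length(span)]
          emitted[pos] <- paste0(emitted[pos], runs$base[k])
          n_h_ins <- n_h_ins + 1L
        } else {
          cand <- span[emitted[span] == runs$base[k]]
          if (length(cand) > 0) {
            emitted[cand[length(cand)]] <- ""
            n_h_del <- n_h_del + 1L
          }
        }
      }
    }
  }
  seq <- paste(paste0(emitted, ins), collapse = "")
  structure(list(
    record = seq_record(id, if (nzchar(seq)) seq else "",
                        meta = list(template_id = template$id)),
    truth_edits = c(sub = sum(sub), ins = sum(nins) + n_h_ins,
                    del = sum(del) + n_h_del),
    template_id = template$id), class = "simulated_read")
}

#' Simulate a sequencing run
#'
#' Emits exactly `config$n_reads` reads from `template`. Each read is
#' independently assigned a tier (`pass` with probability `pass_fraction`;
#' fail-tier reads use the profile rates times `fail_multiplier`), a strand
#' (`-` with probability `revcomp_fraction`; the sequence is emitted reverse
#' complemented), and a uniform channel in `1..n_channels`. Read ids are
#' `sim_1 ... sim_n`. Fully reproducible given `config$seed`.
#'
#' @param template A [seq_record()].
#' @param profile An [error_profile()].
#' @param config A [run_config()].
#' @return List of `simulated_read`; each `record$meta` carries `channel`,
#'   `tier` and `strand`.
#' @export
simulate_run <- function(template, profile, config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  n <- config$n_reads
  tier <- ifelse(runif(n) < config$pass_fraction, "pass", "fail")
  strand <- ifelse(runif(n) < config$revcomp_fraction, "-", "+")
  channel <- ceiling(runif(n) * config$n_channels)
  fail_profile <- if (any(tier == "fail"))
    scale_profile(profile, profile$fail_multiplier) else NULL
  out <- vector("list", n)
  for (k in seq_len(n)) {
    pr <- if (tier[k] == "pass") profile else fail_profile
    sr <- mutate_template(template, pr, id = paste0("sim_", k))
    if (strand[k] == "-" && nzchar(sr$record$seq))
      sr$record$seq <- reverse_complement(sr$record$seq)
    sr$record$meta <- list(template_id = template$id, channel = channel[k],
                           tier = tier[k], strand = strand[k])
    sr$strand <- strand[k]
    out[[k]] <- sr
  }
  out
}

#' Extract the plain reads from simulator output
#'
#' @param sim List of `simulated_read` from [simulate_run()].
#' @return List of [seq_record()].
#' @export
sim_records <- function(sim) lapply(sim, `[[`, "record")

#' Write simulator ground truth as TSV
#'
#' Columns: read id, tier, strand, channel, substitutions, insertions,
#' deletions.
#'
#' @inheritParams sim_records
#' @param path Output path.
#' @export
write_truth <- function(sim, path) {
  df <- data.frame(
    id = vapply(sim, function(s) s$record$id, character(1)),
    tier = vapply(sim, function(s) s$record$meta$tier %||% "pass", character(1)),
    strand = vapply(sim, function(s) s$record$meta$strand %||% "+", character(1)),
    channel = vapply(sim, function(s) as.integer(s$record$meta$channel %||% 1L),
                     integer(1)),
    substitutions = vapply(sim, function(s) unname(s$truth_edits["sub"]), numeric(1)),
    insertions = vapply(sim, function(s) unname(s$truth_edits["ins"]), numeric(1)),
    deletions = vapply(sim, function(s) unname(s$truth_edits["del"]), numeric(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulated reads as FASTQ
#'
#' Quality strings are constant placeholders by tier (Phred 30 for pass, 10
#' for fail); the consensus caller never reads them.
#'
#' @inheritParams write_truth
#' @export
write_sim_fastq <- function(sim, path) {
  recs <- lapply(sim, function(s) {
    q <- if (identical(s$record$meta$tier, "fail")) 10L else 30L
    r <- s$record
    r$qual <- rep(q, nchar(r$seq))
    r
  })
  write_fastq(recs, path)
}

#' Generate decoy reference sequences by seeded mutation
#'
#' Substitutes a fixed fraction of positions (uniform pick among the other
#' three bases) to produce database decoys at a chosen divergence from a
#' template, e.g. `divergence = 0.1` for ~90% identity decoys.
#'
#' @param template A [seq_record()].
#' @param n Number of decoys.
#' @param divergence Fraction of positions substituted.
#' @param seed Integer seed.
#' @return List of [seq_record()] named `<template_id>_decoy<k>`.
#' @export
make_decoys <- function(template, n = 5L, divergence = 0.10, seed = 1L) {
  stopifnot(is_seq_record(template), n >= 1, divergence >= 0, divergence <= 1)
  set.seed(seed)
  b0 <- strsplit(template$seq, "", fixed = TRUE)[[1]]
  L <- length(b0)
  k <- max(1L, round(divergence * L))
  lapply(seq_len(n), function(i) {
    b <- b0
    pos <- sample.int(L, k)
    pick <- ceiling(runif(k) * 3)
    b[pos] <- mapply(function(base, j) other_bases[[base]][j], b[pos], pick,
                     USE.NAMES = FALSE)
    seq_record(paste0(template$id, "_decoy", i), paste(b, collapse = ""))
  })
}

#' Read a flat key=value simulator configuration file
#'
#' Recognised keys: `p_mis`, `p_ins`, `p_del`, `h0`, `fail_multiplier`,
#' `profile` (preset name, overridden by explicit rates), `n_reads`,
#' `pass_fraction`, `n_channels`, `revcomp_fraction`, `seed`.
#'
#' @param path Config file path.
#' @return List with elements `profile` ([error_profile()]) and `config`
#'   ([run_config()]); `config` is `NULL` when `n_reads` is absent.
#' @export
read_sim_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- as.list(setNames(trimws(vapply(kv, `[`, character(1), 2)),
                           trimws(vapply(kv, `[`, character(1), 1))))
  num <- function(key, default) if (key %in% names(vals))
    as.numeric(vals[[key]]) else default
  profile <- if ("profile" %in% names(vals) &&
                 !any(c("p_mis", "p_ins", "p_del") %in% names(vals))) {
    minion_profile(vals[["profile"]])
  } else {
    base <- if ("profile" %in% names(vals)) minion_profile(vals[["profile"]])
            else minion_profile("R7.4")
    error_profile(num("p_mis", base$p_mis), num("p_ins", base$p_ins),
                  num("p_del", base$p_del), h0 = num("h0", base$h0),
                  fail_multiplier = num("fail_multiplier", base$fail_multiplier),
                  name = vals[["profile"]] %||% "custom")
  }
  config <- if ("n_reads" %in% names(vals)) {
    run_config(num("n_reads", NA), pass_fraction = num("pass_fraction", 0.3),
               n_channels = num("n_channels", 64),
               revcomp_fraction = num("revcomp_fraction", 0.5),
               seed = num("seed", 1))
  } else NULL
  list(profile = profile, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
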