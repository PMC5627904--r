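# End-to-end orchestration: draft consensus -> database search -> realignment
# to the best hit -> majority-vote consensus -> final database search, with a
# machine-readable identification report.

#' Run the full barcoding pipeline
#'
#' Steps: (i) assemble a de novo draft consensus from the reads by
#' partial-order alignment; (ii) search the local barcode database with the
#' draft; (iii) realign the reads to the best hit; (iv) call the
#' per-position majority-vote consensus from the pileup; (v) re-search the
#' database with the final consensus. The draft and realignment stages use
#' the 2D-pass-tier reads only, falling back to all reads when fewer than
#' `min_pass` pass reads are available (low-yield field runs).
#'
#' Fully deterministic given its inputs: rerunning writes byte-identical
#' consensus and report (stage timings excluded).
#'
#' @param reads Path to a FASTA/FASTQ file or a list of [seq_record()].
#'   Simulated reads carry their tier in `meta$tier`; reads without tier
#'   metadata are treated as pass.
#' @param db Path to a multi-FASTA barcode database or a list of
#'   [seq_record()].
#' @param outdir Optional output directory; when given, writes
#'   `consensus.fasta`, `draft.fasta`, `freq_matrix.tsv`, `coverage.tsv`,
#'   `hits_draft.tsv`, `hits_final.tsv` and `report.json` (plus
#'   `alignments.sam` when `sam = TRUE`).
#' @param scoring An [alignment_scoring()].
#' @param min_identity_pct,min_query_frac Alignment filter thresholds.
#' @param min_coverage Minimum coverage for a frequency call.
#' @param max_draft_reads Reads fed to the draft POA stage.
#' @param k,top_n Database index / search parameters.
#' @param min_pass Minimum number of pass reads before falling back to all
#'   reads (default 20).
#' @param sam Also write a minimal SAM of the realignment.
#' @param verbose Log stage banners to standard error.
#' @return List with `consensus` (final `consensus_result`), `draft`
#'   (draft `consensus_result`), `report` (named list; see details), and
#'   `pileup`.
#' @export
run_pipeline <- function(reads, db, outdir = NULL,
                         scoring = alignment_scoring(),
                         min_identity_pct = 70, min_query_frac = 0.8,
                         min_coverage = 1L, max_draft_reads = 200L,
                         k = 11L, top_n = 25L, min_pass = 20L,
                         sam = FALSE, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message("[nanobar] ", ...)
  reads <- load_records(reads)
  db_records <- load_records(db)
  if (length(reads) == 0L) stop("input error: empty read set", call. = FALSE)
  if (length(db_records) == 0L) stop("input error: empty database", call. = FALSE)

  tiers <- vapply(reads, function(r) r$meta$tier %||% "pass", character(1))
  working <- reads[tiers == "pass"]
  used_tier <- "pass"
  if (length(working) < min_pass) {
    working <- reads
    used_tier <- "all"
    say("only ", sum(tiers == "pass"), " pass reads; using all ",
        length(reads), " reads")
  }

  say("stage i: draft consensus (POA) from ", length(working), " reads")
  draft <- draft_consensus(working, scoring, max_reads = max_draft_reads)
  t_draft <- proc.time()[["elapsed"]]

  say("stage ii: database search with the draft")
  dbi <- build_index(db_records, k = k)
  draft_rec <- seq_record("draft_consensus", draft$seq)
  hits1 <- search_db(draft_rec, dbi, top_n = top_n, scoring = scoring)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(draft_rec, file.path(outdir, "draft.fasta"))
  }
  if (length(hits1) == 0L)
    stop("pipeline error: no database hit for the draft consensus ",
         "(no identification); draft written when outdir is set",
         call. = FALSE)
  best <- dbi$records[[match(hits1[[1]]$subject_id,
                             vapply(dbi$records, `[[`, character(1), "id"))]]
  t_search1 <- proc.time()[["elapsed"]]

  say("stage iii+iv: realignment to '", best$id, "' and frequency consensus")
  final <- reference_consensus(working, best, scoring,
                               min_identity_pct = min_identity_pct,
                               min_query_frac = min_query_frac,
                               min_coverage = min_coverage)
  t_consensus <- proc.time()[["elapsed"]]

  say("stage v: database search with the final consensus")
  final_rec <- seq_record("final_consensus", final$seq)
  hits2 <- search_db(final_rec, dbi, top_n = top_n, scoring = scoring)
  t_search2 <- proc.time()[["elapsed"]]

  hit_summary <- function(h) if (length(h) == 0L) NULL else
    list(subject_id = h[[1]]$subject_id,
         identity_pct = h[[1]]$identity_pct,
         score = h[[1]]$score, kmer_hits = h[[1]]$kmer_hits,
         strand = h[[1]]$strand)
  report <- list(
    draft_best_hit = hit_summary(hits1),
    final_best_hit = hit_summary(hits2),
    draft_identity_pct = if (length(hits1)) hits1[[1]]$identity_pct else NA_real_,
    final_identity_pct = if (length(hits2)) hits2[[1]]$identity_pct else NA_real_,
    n_reads_in = length(reads),
    n_reads_used = length(working),
    n_reads_aligned = attr(final, "n_aligned"),
    consensus_len = nchar(final$seq),
    read_tier_used = used_tier,
    parameters = list(
      scoring = unclass(scoring),
      min_identity_pct = min_identity_pct, min_query_frac = min_query_frac,
      min_coverage = min_coverage, max_draft_reads = max_draft_reads,
      k = k, top_n = top_n, min_pass = min_pass),
    timings_sec = list(draft = t_draft - t0, search_draft = t_search1 - t_draft,
                       consensus = t_consensus - t_search1,
                       search_final = t_search2 - t_consensus))

  pile <- attr(final, "pileup")
  if (!is.null(outdir)) {
    write_fasta(final_rec, file.path(outdir, "consensus.fasta"))
    write_freq_matrix(final, file.path(outdir, "freq_matrix.tsv"))
    write_coverage_tsv(coverage_profile(pile),
                       file.path(outdir, "coverage.tsv"))
    write_hits_tsv(hits1, file.path(outdir, "hits_draft.tsv"))
    write_hits_tsv(hits2, file.path(outdir, "hits_final.tsv"))
    if (sam) write_sam(attr(final, "alignments"), best,
                       file.path(outdir, "alignments.sam"))
    report_out <- report
    report_out$timings_sec <- NULL  # keep report.json byte-reproducible
    jsonlite::write_json(report_out, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }

  list(consensus = final, draft = draft, report = report, pileup = pile,
       best_hit = best)
}

load_records <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    first <- readLines(x, n = 1L)
    if (startsWith(first, "@")) read_fastq(x) else read_fasta(x)
  } else {
    as_record_list(x)
  }
}
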