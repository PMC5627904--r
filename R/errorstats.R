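# Error decomposition vs a trusted reference, homopolymer coverage-dip
# analytics, and per-channel run-count normalisation with half-up rounding
# (the rounding used by the printed run tables).

#' Round half-up
#'
#' `round()` in R rounds half to even; yield tables round half away from
#' zero, so 240.5 -> 241 and 23.35 -> 23.4.
#'
#' @param x Non-negative numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Pooled error decomposition of alignments against a reference
#'
#' Pooled over all alignments (robust at low coverage):
#' `mismatch_pct = 100 * sum(mismatch columns) / sum(aligned reference span)`,
#' and likewise for inserted and deleted bases over the same denominator;
#' `mean_error_pct` is their exact sum. The denominator is the total aligned
#' reference span, which makes the deletion component comparable to a
#' per-reference-base deletion rate. A per-read breakdown is attached for
#' distributional reporting.
#'
#' @param alignments Non-empty list of `alignment_result`.
#' @return Object of class `error_decomposition`: `mismatch_pct`,
#'   `insertion_pct`, `deletion_pct`, `mean_error_pct`, `n_reads_used`,
#'   `denominator`, and `per_read` (data frame).
#' @export
decompose_errors <- function(alignments) {
  if (length(alignments) == 0L)
    stop("input error: no alignments", call. = FALSE)
  per <- lapply(alignments, function(a) {
    c(mm = sum(a$cigar$len[a$cigar$op == "X"]),
      ins = sum(a$cigar$len[a$cigar$op == "I"]),
      del = sum(a$cigar$len[a$cigar$op == "D"]),
      span = a$ref_end - a$ref_start)
  })
  m <- do.call(rbind, per)
  denom <- sum(m[, "span"])
  if (denom == 0)
    stop("input error: zero aligned reference span", call. = FALSE)
  mm <- 100 * sum(m[, "mm"]) / denom
  ins <- 100 * sum(m[, "ins"]) / denom
  del <- 100 * sum(m[, "del"]) / denom
  structure(list(mismatch_pct = mm, insertion_pct = ins, deletion_pct = del,
                 mean_error_pct = mm + ins + del,
                 n_reads_used = length(alignments), denominator = denom,
                 per_read = data.frame(
                   query_id = vapply(alignments, `[[`, character(1), "query_id"),
                   mismatch = m[, "mm"], insertion = m[, "ins"],
                   deletion = m[, "del"], ref_span = m[, "span"])),
            class = "error_decomposition")
}

#' @export
print.error_decomposition <- function(x, ...) {
  cat(sprintf(
    "<error decomposition> %d reads, %d aligned ref bases\n  mismatch %.2f%%  insertion %.2f%%  deletion %.2f%%  mean %.2f%%\n",
    x$n_reads_used, x$denominator, x$mismatch_pct, x$insertion_pct,
    x$deletion_pct, x$mean_error_pct))
  invisible(x)
}

#' Write an error decomposition as JSON
#'
#' @param dec An [decompose_errors()] result.
#' @param path Output path.
#' @export
write_decomposition_json <- function(dec, path) {
  stopifnot(inherits(dec, "error_decomposition"))
  jsonlite::write_json(
    list(mismatch_pct = dec$mismatch_pct, insertion_pct = dec$insertion_pct,
         deletion_pct = dec$deletion_pct, mean_error_pct = dec$mean_error_pct,
         n_reads_used = dec$n_reads_used, denominator = dec$denominator),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-position coverage with a homopolymer mask
#'
#' @param pileup A [pileup_from_alignments()] result.
#' @param min_len Minimum run length entering the mask (default 2, the
#'   annotation convention; the dip analysis re-masks at its own threshold).
#' @return Object of class `coverage_profile`: `coverage` (integer per
#'   reference position), `runs` (the homopolymer annotation of the
#'   reference), `ref_seq`, `ref_id`.
#' @export
coverage_profile <- function(pileup, min_len = 2L) {
  stopifnot(inherits(pileup, "pileup_matrix"))
  structure(list(coverage = pileup$coverage,
                 runs = annotate_homopolymers(pileup$ref_seq, min_len),
                 ref_seq = pileup$ref_seq, ref_id = pileup$ref_id),
            class = "coverage_profile")
}

run_mask <- function(profile, min_run) {
  n <- length(profile$coverage)
  mask <- logical(n)
  runs <- profile$runs[profile$runs$length >= min_run, , drop = FALSE]
  for (k in seq_len(nrow(runs)))
    mask[(runs$start[k] + 1L):(runs$start[k] + runs$length[k])] <- TRUE
  mask
}

#' Coverage over homopolymer runs vs elsewhere
#'
#' Nanopore reads lose aligned bases over homopolymer stretches, so coverage
#' dips there; this compares mean coverage at positions inside runs of
#' length >= `min_run` against all other positions. Run annotation marks
#' runs of two or more identical bases, but dips concentrate at longer runs,
#' hence the default analysis threshold of 4.
#'
#' @param profile A [coverage_profile()].
#' @param min_run Minimum run length counted as a run position (default 4).
#' @return List: `mean_cov_runs`, `mean_cov_nonruns`, `ratio`
#'   (runs / nonruns), `n_run_positions`.
#' @export
coverage_vs_homopolymers <- function(profile, min_run = 4L) {
  stopifnot(inherits(profile, "coverage_profile"))
  mask <- run_mask(profile, min_run)
  if (!any(mask) || all(mask))
    stop("input error: degenerate homopolymer mask (all or no positions)",
         call. = FALSE)
  mr <- mean(profile$coverage[mask])
  mn <- mean(profile$coverage[!mask])
  list(mean_cov_runs = mr, mean_cov_nonruns = mn, ratio = mr / mn,
       n_run_positions = sum(mask))
}

#' Write the coverage profile as TSV
#'
#' Columns: 1-based position, coverage, is_run (run length >= `min_run`).
#'
#' @inheritParams coverage_vs_homopolymers
#' @param path Output path.
#' @export
write_coverage_tsv <- function(profile, path, min_run = 4L) {
  mask <- run_mask(profile, min_run)
  df <- data.frame(position = seq_along(profile$coverage),
                   coverage = profile$coverage, is_run = mask)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run read-count bookkeeping
#'
#' Raw counts for one sequencing run: active channels at flowcell QC,
#' channels that produced reads, and total / 2D / 2D-pass read counts.
#'
#' @param channels_qc,channels_with_reads Channel counts.
#' @param total,d2,d2_pass Read counts (`d2_pass <= d2 <= total`).
#' @return Object of class `run_counts`.
#' @export
run_counts <- function(channels_qc, channels_with_reads, total, d2, d2_pass) {
  stopifnot(channels_with_reads >= 1, d2_pass <= d2, d2 <= total)
  structure(list(channels_qc = as.integer(channels_qc),
                 channels_with_reads = as.integer(channels_with_reads),
                 total = as.integer(total), d2 = as.integer(d2),
                 d2_pass = as.integer(d2_pass)),
            class = "run_counts")
}

#' Normalise run counts per channel with reads
#'
#' Divides each raw read count by the number of channels that produced
#' reads, rounding half-up to an integer: flowcells differ in health, so
#' reads-per-channel is the comparable yield unit.
#'
#' @param rc A [run_counts()].
#' @return Named integer vector `norm_total`, `norm_2d`, `norm_2d_pass`.
#' @export
normalize_counts <- function(rc) {
  stopifnot(inherits(rc, "run_counts"))
  if (rc$channels_with_reads < 1)
    stop("input error: zero channels", call. = FALSE)
  c(norm_total = as.integer(round_half_up(rc$total / rc$channels_with_reads)),
    norm_2d = as.integer(round_half_up(rc$d2 / rc$channels_with_reads)),
    norm_2d_pass = as.integer(round_half_up(rc$d2_pass / rc$channels_with_reads)))
}

#' Percentage of a total, half-up rounded
#'
#' @param part,total Non-negative integers, `part <= total`, `total >= 1`.
#' @param decimals Decimal places (default 1).
#' @return `100 * part / total`, rounded half-up.
#' @export
percent_of_total <- function(part, total, decimals = 1L) {
  if (length(total) != 1L || total < 1)
    stop("input error: total must be >= 1", call. = FALSE)
  stopifnot(part >= 0, part <= total)
  round_half_up(100 * part / total, decimals)
}

#' Read run counts from TSV
#'
#' Expects columns `label`, `channels_qc`, `channels_with_reads`, `total`,
#' `d2`, `d2_pass`.
#'
#' @param path TSV path.
#' @return Named list of [run_counts()].
#' @export
read_run_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "channels_qc", "channels_with_reads", "total", "d2",
            "d2_pass")
  stopifnot(all(need %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(k)
    run_counts(df$channels_qc[k], df$channels_with_reads[k], df$total[k],
               df$d2[k], df$d2_pass[k]))
  setNames(out, df$label)
}

#' Raw + normalised + percentage run-statistics table
#'
#' One row per run: the raw counts, the per-channel normalised counts, and
#' the 2D / 2D-pass percentages of total.
#'
#' @param counts Named list of [run_counts()] (e.g. from
#'   [read_run_counts()]).
#' @return Data frame.
#' @export
run_stats_table <- function(counts) {
  rows <- lapply(names(counts), function(nm) {
    rc <- counts[[nm]]
    nc <- normalize_counts(rc)
    data.frame(label = nm, channels_qc = rc$channels_qc,
               channels_with_reads = rc$channels_with_reads,
               total = rc$total, d2 = rc$d2, d2_pass = rc$d2_pass,
               pct_2d = percent_of_total(rc$d2, rc$total),
               pct_2d_pass = percent_of_total(rc$d2_pass, rc$total),
               norm_total = nc[["norm_total"]], norm_2d = nc[["norm_2d"]],
               norm_2d_pass = nc[["norm_2d_pass"]])
  })
  do.call(rbind, rows)
}
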