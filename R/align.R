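# Pairwise semi-global alignment of reads to a reference: affine gaps, free
# end gaps on the reference only (the read is contained in the amplicon
# reference frame), typed CIGAR, orientation detection, identity filtering,
# and minimal SAM / TSV export.

#' Alignment scoring scheme
#'
#' Match/mismatch scores and affine gap penalties (a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`). The defaults (+1/-1/-2/-1) are a
#' standard choice for noisy long reads.
#'
#' @param match,mismatch,gap_open,gap_extend Numeric scores; gap penalties
#'   must be negative.
#' @return A named list of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 1, mismatch = -1, gap_open = -2,
                              gap_extend = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open < 0, gap_extend < 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "alignment_scoring")
}

check_alignable <- function(rec, what) {
  stopifnot(is_seq_record(rec))
  if (!nzchar(rec$seq))
    stop(what, " '", rec$id, "' is empty", call. = FALSE)
  if (grepl("[^ACGTN]", rec$seq))
    stop("alphabet error: ", what, " '", rec$id,
         "' contains characters outside A/C/G/T/N", call. = FALSE)
}

ops_to_cigar <- function(ops) {
  r <- rle(strsplit(ops, "", fixed = TRUE)[[1]])
  data.frame(op = r$values, len = r$lengths, stringsAsFactors = FALSE)
}

#' Semi-global alignment of a query to a reference
#'
#' Affine-gap dynamic programming with free end gaps on the reference only:
#' the query is aligned end to end, the alignment may start and stop anywhere
#' on the reference. `N` scores as a mismatch against everything. The
#' traceback is deterministic (indels are placed as late on the query as
#' possible; see the methods vignette for the exact tie rules).
#'
#' Percent identity is computed BLAST-style over all alignment columns,
#' gap columns included.
#'
#' @param query,ref [seq_record()]s (non-empty, `A/C/G/T/N`).
#' @param scoring An [alignment_scoring()].
#' @return An object of class `alignment_result`: list with `query_id`,
#'   `ref_id`, `score`, `ref_start`/`ref_end` (0-based half-open), `cigar`
#'   (data frame of ops `=` match, `X` mismatch, `I` insertion, `D` deletion
#'   with lengths; no two adjacent rows share an op), `strand`,
#'   `identity_pct`, and `query` (the oriented query sequence, as aligned).
#' @export
semiglobal_align <- function(query, ref, scoring = alignment_scoring()) {
  check_alignable(query, "query")
  check_alignable(ref, "reference")
  res <- .semiglobal_cpp(query$seq, ref$seq, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend)
  cig <- ops_to_cigar(res$ops)
  ncol <- sum(cig$len)
  nmatch <- sum(cig$len[cig$op == "="])
  structure(list(query_id = query$id, ref_id = ref$id,
                 score = res$score,
                 ref_start = res$ref_start, ref_end = res$ref_end,
                 cigar = cig, strand = "+",
                 identity_pct = 100 * nmatch / ncol,
                 query = query$seq),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> %s vs %s [%s]  score=%g  id=%.1f%%  ref %d-%d\n",
              x$query_id, x$ref_id, x$strand, x$score, x$identity_pct,
              x$ref_start, x$ref_end))
  invisible(x)
}

#' Align a query in both orientations and keep the better
#'
#' 2D reads arrive on either strand: the query and its reverse complement are
#' both aligned and the higher-scoring result is returned with `strand` set
#' (`-` results carry the reverse-complemented, i.e. reference-oriented,
#' query sequence). Score ties resolve to `+`.
#'
#' @inheritParams semiglobal_align
#' @return An `alignment_result`.
#' @export
orient_and_align <- function(query, ref, scoring = alignment_scoring()) {
  fwd <- semiglobal_align(query, ref, scoring)
  rcq <- seq_record(query$id, reverse_complement(query$seq))
  rev <- semiglobal_align(rcq, ref, scoring)
  if (rev$score > fwd$score) {
    rev$strand <- "-"
    rev
  } else fwd
}

aligned_query_len <- function(aln)
  sum(aln$cigar$len[aln$cigar$op %in% c("=", "X", "I")])

#' Filter alignments on identity and aligned-query fraction
#'
#' @param alignments List of `alignment_result`.
#' @param min_identity_pct Minimum percent identity (gap-inclusive
#'   denominator), default 70.
#' @param min_query_frac Minimum fraction of the query covered by the
#'   alignment, default 0.8.
#' @return The surviving alignments, order preserved.
#' @export
filter_alignments <- function(alignments, min_identity_pct = 70,
                              min_query_frac = 0.8) {
  stopifnot(min_identity_pct >= 0, min_identity_pct <= 100,
            min_query_frac >= 0, min_query_frac <= 1)
  keep <- vapply(alignments, function(a) {
    a$identity_pct >= min_identity_pct &&
      aligned_query_len(a) / nchar(a$query) >= min_query_frac
  }, logical(1))
  alignments[keep]
}

#' Typed CIGAR as a compact string
#'
#' @param aln An `alignment_result`.
#' @param collapse_m Collapse `=`/`X` to SAM-classic `M`.
#' @return A string such as `"120=1X3I87="`.
#' @export
cigar_string <- function(aln, collapse_m = FALSE) {
  cig <- aln$cigar
  if (collapse_m) {
    op <- ifelse(cig$op %in% c("=", "X"), "M", cig$op)
    r <- rle(rep(op, cig$len))
    return(paste0(r$lengths, r$values, collapse = ""))
  }
  paste0(cig$len, cig$op, collapse = "")
}

#' Export alignments as minimal SAM
#'
#' One line per alignment: flag 0 (`+`) or 16 (`-`), 1-based POS, CIGAR with
#' `=`/`X` collapsed to `M`, and an `NM` tag (mismatches + inserted +
#' deleted bases). Sequences are written in reference orientation.
#'
#' @param alignments List of `alignment_result`.
#' @param ref Reference [seq_record()] (for the `@SQ` header).
#' @param path Output path.
#' @export
write_sam <- function(alignments, ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               paste0("@SQ\tSN:", ref$id, "\tLN:", nchar(ref$seq))), con)
  for (a in alignments) {
    nm <- sum(a$cigar$len[a$cigar$op %in% c("X", "I", "D")])
    writeLines(paste(a$query_id,
                     if (a$strand == "-") 16L else 0L,
                     a$ref_id, a$ref_start + 1L, 255L,
                     cigar_string(a, collapse_m = TRUE),
                     "*", 0L, 0L, a$query, "*",
                     paste0("NM:i:", nm), sep = "\t"), con)
  }
  invisible(path)
}

#' Export alignments as TSV with the full typed CIGAR
#'
#' @inheritParams write_sam
#' @export
write_alignments_tsv <- function(alignments, path) {
  df <- data.frame(
    query_id = vapply(alignments, `[[`, character(1), "query_id"),
    ref_id = vapply(alignments, `[[`, character(1), "ref_id"),
    strand = vapply(alignments, `[[`, character(1), "strand"),
    score = vapply(alignments, `[[`, numeric(1), "score"),
    ref_start = vapply(alignments, `[[`, integer(1), "ref_start"),
    ref_end = vapply(alignments, `[[`, integer(1), "ref_end"),
    identity_pct = vapply(alignments, `[[`, numeric(1), "identity_pct"),
    cigar = vapply(alignments, cigar_string, character(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
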