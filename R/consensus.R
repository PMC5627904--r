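# The two consensus generators: (a) de novo draft consensus by partial-order
# alignment, (b) reference-guided per-position nucleotide-frequency (majority
# vote) consensus from a pileup of realigned reads.

consensus_result <- function(seq, per_position_freq, source, ref_id = NA_character_,
                             low_coverage = integer(0), table = NULL,
                             insertions = NULL) {
  stopifnot(nzchar(seq))
  structure(list(seq = seq, per_position_freq = per_position_freq,
                 source = source, ref_id = ref_id,
                 low_coverage = low_coverage, table = table,
                 insertions = insertions),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  f <- x$per_position_freq
  cat(sprintf("<consensus:%s> %d bp, min called-base frequency %.3f\n",
              x$source, nchar(x$seq),
              if (all(is.na(f))) NA_real_ else min(f, na.rm = TRUE)))
  invisible(x)
}

#' De novo draft consensus by partial-order alignment
#'
#' Orients every read against the first read, seeds a partial-order graph
#' from the first read, aligns each subsequent read to the graph (affine-gap
#' dynamic programming over the topological order, same scoring contract as
#' [semiglobal_align()]) and fuses it in; the consensus is the heaviest path
#' by cumulative edge weight with node-support tie-break. At most `max_reads`
#' reads are used, taken deterministically as the first `max_reads` after
#' sorting by read id.
#'
#' This single-stage POA over full-length amplicon reads deliberately
#' replaces the overlap-correct-assemble chain used for genome-scale long
#' read data: a single-locus amplicon needs no genome assembler.
#'
#' @param reads List of [seq_record()] (>= 1, non-empty).
#' @param scoring An [alignment_scoring()].
#' @param max_reads Maximum reads fed to the graph (default 200).
#' @return A `consensus_result` with `source = "draft_poa"`;
#'   `per_position_freq` is node support divided by the number of reads used.
#' @export
draft_consensus <- function(reads, scoring = alignment_scoring(),
                            max_reads = 200L) {
  reads <- as_record_list(reads)
  if (length(reads) == 0L) stop("input error: no reads", call. = FALSE)
  for (r in reads) check_alignable(r, "read")
  ids <- vapply(reads, `[[`, character(1), "id")
  reads <- reads[order(ids)]
  if (length(reads) > max_reads) reads <- reads[seq_len(max_reads)]
  first <- reads[[1]]
  oriented <- vapply(reads, function(r) {
    if (identical(r$id, first$id)) return(r$seq)
    a <- orient_and_align(r, first, scoring)
    a$query  # reverse-complemented already when strand == "-"
  }, character(1))
  res <- .poa_consensus_cpp(oriented, scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_extend)
  consensus_result(res$seq, res$support / length(reads), source = "draft_poa")
}

#' Build a pileup matrix from alignments
#'
#' Walks each typed CIGAR, incrementing per-reference-position base counts at
#' match/mismatch columns, deletion counts at `D` columns, and insertion
#' counts keyed by the inter-position locus (number of reference bases
#' consumed before the insertion; locus `k` sits before 0-based reference
#' position `k`). Minus-strand alignments contribute their already-oriented
#' query.
#'
#' @param alignments List of `alignment_result`, all against `ref`.
#' @param ref Reference [seq_record()].
#' @return An object of class `pileup_matrix`: `counts` (5 x ref-length
#'   integer matrix, rows `A,C,G,T,-`), `insertions` (named list: locus ->
#'   named counts of inserted sequences), `coverage` (per-position total of
#'   base + deletion counts), `ref_id`, `ref_seq`, `n_alignments`.
#' @export
pileup_from_alignments <- function(alignments, ref) {
  stopifnot(is_seq_record(ref))
  n <- nchar(ref$seq)
  counts <- matrix(0L, nrow = 5, ncol = n,
                   dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  ins <- new.env(parent = emptyenv())
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = NA_integer_)
  for (a in alignments) {
    if (!identical(a$ref_id, ref$id))
      stop("consistency error: alignment of '", a$query_id,
           "' references '", a$ref_id, "', not '", ref$id, "'", call. = FALSE)
    if (a$ref_end > n)
      stop("consistency error: alignment of '", a$query_id,
           "' extends past the reference end", call. = FALSE)
    ops <- rep(a$cigar$op, a$cigar$len)
    qstep <- ops %in% c("=", "X", "I")
    rstep <- ops %in% c("=", "X", "D")
    qpos <- cumsum(qstep)
    rpos <- a$ref_start + cumsum(rstep)   # 1-based ref position of each r-consuming column
    qchars <- strsplit(a$query, "", fixed = TRUE)[[1]]
    isM <- ops %in% c("=", "X")
    if (any(isM)) {
      bi <- base_idx[qchars[qpos[isM]]]
      ok <- !is.na(bi)  # N bases are not counted
      idx <- (rpos[isM][ok] - 1L) * 5L + bi[ok]
      counts <- counts + matrix(tabulate(idx, nbins = 5L * n), nrow = 5)
    }
    isD <- ops == "D"
    if (any(isD)) {
      idx <- (rpos[isD] - 1L) * 5L + 5L
      counts <- counts + matrix(tabulate(idx, nbins = 5L * n), nrow = 5)
    }
    isI <- ops == "I"
    if (any(isI)) {
      w <- which(isI)
      # locus = reference bases consumed before the insertion column
      locus_all <- a$ref_start + cumsum(rstep)
      # group consecutive I columns into one inserted string per locus
      grp <- cumsum(c(TRUE, diff(w) != 1L))
      for (g in unique(grp)) {
        cols <- w[grp == g]
        key <- as.character(locus_all[cols[1]])
        sq <- paste(qchars[qpos[cols]], collapse = "")
        cur <- if (exists(key, envir = ins)) get(key, envir = ins) else integer(0)
        cur[sq] <- (if (sq %in% names(cur)) cur[[sq]] else 0L) + 1L
        assign(key, cur, envir = ins)
      }
    }
  }
  structure(list(ref_id = ref$id, ref_seq = ref$seq, counts = counts,
                 insertions = as.list(ins),
                 coverage = as.integer(colSums(counts)),
                 n_alignments = length(alignments)),
            class = "pileup_matrix")
}

#' Call a majority-vote consensus from a pileup
#'
#' Per reference position: below `min_coverage` the reference base is emitted
#' and the position flagged low-coverage (the reference bridges dropouts,
#' notably over homopolymer runs); if the deletion state is modal with
#' frequency > 0.5 nothing is emitted; otherwise the modal base is emitted,
#' ties broken toward the reference base, then alphabetically. An insertion
#' locus is emitted (its modal inserted sequence; lexicographic tie-break)
#' iff its total insertion count exceeds half the coverage at the preceding
#' position.
#'
#' @param pileup A [pileup_from_alignments()] result.
#' @param min_coverage Minimum coverage for a frequency call (>= 1).
#' @return A `consensus_result` with `source = "pileup"`: `seq`,
#'   `per_position_freq` (called-base frequency per emitted position, `NA`
#'   at low-coverage reference-filled positions), `low_coverage` (0-based
#'   reference positions filled from the reference), and `table`, the
#'   per-position frequency matrix (1-based position, reference base, counts
#'   `A/C/G/T/del`, coverage, called base, called frequency).
#' @export
call_consensus <- function(pileup, min_coverage = 1L) {
  stopifnot(inherits(pileup, "pileup_matrix"), min_coverage >= 1)
  n <- ncol(pileup$counts)
  if (n == 0L) stop("input error: empty pileup", call. = FALSE)
  refb <- strsplit(pileup$ref_seq, "", fixed = TRUE)[[1]]
  counts <- pileup$counts
  cov <- pileup$coverage
  called <- character(n)
  freq <- rep(NA_real_, n)
  low <- logical(n)
  for (i in seq_len(n)) {
    if (cov[i] < min_coverage) {
      called[i] <- refb[i]
      low[i] <- TRUE
      next
    }
    if (counts["-", i] / cov[i] > 0.5) {
      called[i] <- ""
      freq[i] <- counts["-", i] / cov[i]
      next
    }
    bc <- counts[DNA_BASES, i]
    top <- DNA_BASES[bc == max(bc)]
    pick <- if (refb[i] %in% top) refb[i] else top[1]  # top is alphabetical
    called[i] <- pick
    freq[i] <- bc[[pick]] / cov[i]
  }
  # insertions: modal inserted sequence where total count > 0.5 * flanking coverage
  ins_emit <- list()
  for (key in names(pileup$insertions)) {
    k <- as.integer(key)               # locus: before 0-based ref position k
    flank <- if (k >= 1) cov[k] else cov[1]
    tot <- sum(pileup$insertions[[key]])
    if (tot > 0.5 * flank) {
      tab <- pileup$insertions[[key]]
      modal <- sort(names(tab)[tab == max(tab)])[1]
      ins_emit[[key]] <- list(locus = k, seq = modal, count = tab[[modal]],
                              total = tot, flank_coverage = flank)
    }
  }
  # assemble: insertion locus k precedes reference position k; locus n trails
  pieces <- character(n)
  pf_parts <- vector("list", n + 1L)
  for (i in seq_len(n)) {
    pre <- ""
    pre_f <- numeric(0)
    key <- as.character(i - 1L)
    if (key %in% names(ins_emit)) {
      e <- ins_emit[[key]]
      pre <- e$seq
      pre_f <- rep(e$count / max(1L, e$flank_coverage), nchar(pre))
    }
    pieces[i] <- paste0(pre, called[i])
    pf_parts[[i]] <- c(pre_f,
                       if (nzchar(called[i])) (if (low[i]) NA_real_ else freq[i]))
  }
  tailpiece <- ""
  if (as.character(n) %in% names(ins_emit)) {
    e <- ins_emit[[as.character(n)]]
    tailpiece <- e$seq
    pf_parts[[n + 1L]] <- rep(e$count / max(1L, e$flank_coverage), nchar(tailpiece))
  }
  seq <- paste0(paste(pieces, collapse = ""), tailpiece)
  if (!nzchar(seq)) stop("input error: consensus is empty", call. = FALSE)
  pf <- unlist(pf_parts)
  tab <- data.frame(position = seq_len(n), ref_base = refb,
                    A = counts["A", ], C = counts["C", ], G = counts["G", ],
                    T = counts["T", ], del = counts["-", ],
                    coverage = cov, called = called,
                    called_freq = ifelse(low, NA_real_, freq),
                    low_coverage = low)
  consensus_result(seq, pf, source = "pileup", ref_id = pileup$ref_id,
                   low_coverage = which(low) - 1L, table = tab,
                   insertions = ins_emit)
}

#' Reference-guided consensus from raw reads
#'
#' The polishing stage of the pipeline: orient and align every read to the
#' retrieved reference, filter the alignments, build the pileup, and call
#' the majority-vote consensus. Because every position is voted on by the
#' reads, the consensus converges to the sequenced molecule even when the
#' reference comes from a related species.
#'
#' @param reads List of [seq_record()].
#' @param reference The database record to realign against ([seq_record()]).
#' @param scoring An [alignment_scoring()].
#' @param min_identity_pct,min_query_frac Passed to [filter_alignments()].
#' @param min_coverage Passed to [call_consensus()].
#' @return A `consensus_result` (source `"pileup"`) with attribute
#'   `n_aligned` giving the number of alignments surviving the filter.
#' @export
reference_consensus <- function(reads, reference,
                                scoring = alignment_scoring(),
                                min_identity_pct = 70, min_query_frac = 0.8,
                                min_coverage = 1L) {
  reads <- as_record_list(reads)
  alns <- lapply(reads, orient_and_align, ref = reference, scoring = scoring)
  kept <- filter_alignments(alns, min_identity_pct, min_query_frac)
  if (length(kept) == 0L)
    stop("pipeline error: 0 of ", length(alns), " alignments to '",
         reference$id, "' passed the filter (min identity ", min_identity_pct,
         "%, min query fraction ", min_query_frac, ")", call. = FALSE)
  pile <- pileup_from_alignments(kept, reference)
  out <- call_consensus(pile, min_coverage = min_coverage)
  attr(out, "n_aligned") <- length(kept)
  attr(out, "n_reads") <- length(reads)
  attr(out, "pileup") <- pile
  attr(out, "alignments") <- kept
  out
}

#' Export the per-position frequency matrix as TSV
#'
#' The data surface behind the per-position frequency/coverage plots:
#' 1-based position, reference base, counts `A/C/G/T/del`, coverage, called
#' base and called frequency.
#'
#' @param consensus A `consensus_result` from [call_consensus()].
#' @param path Output path.
#' @export
write_freq_matrix <- function(consensus, path) {
  stopifnot(!is.null(consensus$table))
  write.table(consensus$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
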