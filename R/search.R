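# Local barcode-database best-hit retrieval: k-mer prefilter over both query
# orientations, alignment-based ranking, percent-identity reporting. A local
# stand-in for remote database searches -- barcode-scale databases (1e2-1e4
# records) need no heavier indexing, and ranking is by alignment score
# rather than E-value.

#' Build a k-mer index over a barcode database
#'
#' Indexes every k-mer occurrence of every record (plus strand only; queries
#' are searched in both orientations instead, halving memory). Records
#' shorter than `k` are skipped with a warning.
#'
#' @param records List of [seq_record()] reference barcodes.
#' @param k K-mer size (>= 4; default 11).
#' @return Object of class `barcode_db`: `records`, `k`, and the index.
#' @export
build_index <- function(records, k = 11L) {
  records <- as_record_list(records)
  stopifnot(k >= 4)
  idx <- new.env(parent = emptyenv(), size = 4096L)
  n_pos <- 0L
  for (r in seq_along(records)) {
    s <- records[[r]]$seq
    L <- nchar(s)
    if (L < k) {
      warning("record '", records[[r]]$id, "' is shorter than k = ", k,
              "; skipped from the index", call. = FALSE)
      next
    }
    kmers <- substring(s, 1:(L - k + 1L), k:L)
    n_pos <- n_pos + length(kmers)
    for (km in kmers) {
      cur <- if (exists(km, envir = idx, inherits = FALSE))
        get(km, envir = idx, inherits = FALSE) else integer(0)
      assign(km, c(cur, r), envir = idx)
    }
  }
  structure(list(records = records, k = as.integer(k), index = idx,
                 n_positions = n_pos),
            class = "barcode_db")
}

kmer_hit_counts <- function(seq, db) {
  L <- nchar(seq)
  counts <- numeric(length(db$records))
  if (L < db$k) return(counts)
  kmers <- substring(seq, 1:(L - db$k + 1L), db$k:L)
  for (km in kmers) {
    if (exists(km, envir = db$index, inherits = FALSE)) {
      hits <- get(km, envir = db$index, inherits = FALSE)
      # one hit per query k-mer position per record containing the k-mer
      for (r in unique(hits)) counts[r] <- counts[r] + 1
    }
  }
  counts
}

#' Search a barcode database for the best-matching record
#'
#' Candidates are ranked by shared-k-mer count, taking the better of the two
#' query orientations; the top `top_n` candidates are then aligned with
#' [orient_and_align()] and hits returned sorted by alignment score
#' (descending), ties by subject id. Identity is over the full semi-global
#' alignment, gap columns included.
#'
#' @param query A [seq_record()] of length >= `db$k`.
#' @param db A [build_index()] result.
#' @param top_n Number of k-mer candidates to align (default 25).
#' @param scoring An [alignment_scoring()].
#' @return List of `search_hit` (possibly empty when no k-mer is shared):
#'   each has `query_id`, `subject_id`, `identity_pct`, `score`,
#'   `kmer_hits`, `strand` and the full `alignment`.
#' @export
search_db <- function(query, db, top_n = 25L, scoring = alignment_scoring()) {
  stopifnot(inherits(db, "barcode_db"), is_seq_record(query),
            nchar(query$seq) >= db$k)
  fwd <- kmer_hit_counts(query$seq, db)
  rev <- kmer_hit_counts(reverse_complement(query$seq), db)
  counts <- pmax(fwd, rev)
  cand <- which(counts > 0)
  if (length(cand) == 0L) return(list())
  cand <- cand[order(-counts[cand], cand)]
  cand <- head(cand, top_n)
  hits <- lapply(cand, function(r) {
    subj <- db$records[[r]]
    aln <- orient_and_align(query, subj, scoring)
    structure(list(query_id = query$id, subject_id = subj$id,
                   identity_pct = aln$identity_pct, score = aln$score,
                   kmer_hits = counts[r], strand = aln$strand,
                   alignment = aln),
              class = "search_hit")
  })
  ord <- order(-vapply(hits, `[[`, numeric(1), "score"),
               vapply(hits, `[[`, character(1), "subject_id"))
  hits[ord]
}

#' Similarity report for a hit list
#'
#' One row per hit, in hit order, identity to one decimal (half-up).
#'
#' @param hits List of `search_hit` from [search_db()].
#' @return Data frame with columns `subject_id`, `identity_pct`.
#' @export
identity_report <- function(hits) {
  data.frame(
    subject_id = vapply(hits, `[[`, character(1), "subject_id"),
    identity_pct = round_half_up(
      vapply(hits, `[[`, numeric(1), "identity_pct"), 1L))
}

#' Write hits as 6-column TSV
#'
#' Columns: query, subject, identity, score, kmer_hits, strand.
#'
#' @inheritParams identity_report
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  df <- data.frame(
    query = vapply(hits, `[[`, character(1), "query_id"),
    subject = vapply(hits, `[[`, character(1), "subject_id"),
    identity = round_half_up(vapply(hits, `[[`, numeric(1), "identity_pct"), 1L),
    score = vapply(hits, `[[`, numeric(1), "score"),
    kmer_hits = vapply(hits, `[[`, numeric(1), "kmer_hits"),
    strand = vapply(hits, `[[`, character(1), "strand"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
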