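# Sequence records, IUPAC alphabet, FASTA/FASTQ I/O, reverse complement,
# degenerate-primer matching (in-silico PCR) and homopolymer-run annotation.

DNA_BASES <- c("A", "C", "G", "T")
READ_ALPHABET <- c("A", "C", "G", "T", "N")

iupac_codes <- function() names(Biostrings::IUPAC_CODE_MAP)

#' Create a sequence record
#'
#' A lightweight container for a named nucleotide sequence with optional
#' per-base Phred qualities and free-form metadata (channel, tier, strand...).
#' Sequences are uppercased on ingest and must use the `A/C/G/T/N` alphabet;
#' `U` is rejected (DNA-only scope).
#'
#' @param id Record identifier (non-empty string).
#' @param seq Nucleotide sequence over `A,C,G,T,N`. May be empty only for
#'   degenerate simulator output; records entering alignment must be
#'   non-empty.
#' @param qual Optional integer vector of per-base qualities, same length as
#'   `seq`. Carried through I/O but not used by the consensus caller, which
#'   is count-based.
#' @param meta Optional named list of string metadata.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, seq, qual = NULL, meta = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("U", seq, fixed = TRUE))
    stop("alphabet error: 'U' not allowed (DNA-only)", call. = FALSE)
  if (nzchar(seq) && grepl("[^ACGTN]", seq))
    stop("alphabet error in record '", id, "': sequence contains characters outside A/C/G/T/N",
         call. = FALSE)
  if (!is.null(qual)) {
    qual <- as.integer(qual)
    if (length(qual) != nchar(seq))
      stop("record '", id, "': quality length (", length(qual),
           ") != sequence length (", nchar(seq), ")", call. = FALSE)
  }
  structure(list(id = id, seq = seq, qual = qual, meta = meta),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat("<seq_record> ", x$id, ": ", nchar(x$seq), " bp",
      if (!is.null(x$qual)) " (+qual)", "\n", sep = "")
  invisible(x)
}

is_seq_record <- function(x) inherits(x, "seq_record")

as_record_list <- function(x) {
  if (is_seq_record(x)) return(list(x))
  stopifnot(is.list(x), all(vapply(x, is_seq_record, logical(1))))
  x
}

#' Read / write FASTA
#'
#' Reads a (multi-)FASTA file into a list of [seq_record()]s, or writes one
#' out. Sequences are uppercased on ingest; empty sequences and characters
#' outside `A/C/G/T/N` raise a parse error naming the offending record index.
#' Round trip preserves ids, sequences and order (modulo line wrapping).
#'
#' @param path File path.
#' @param records List of [seq_record()] (or a single record).
#' @return `read_fasta`: list of `seq_record`. `write_fasta`: `path`,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path, format = "fasta")
  records_from_set(set, path)
}

records_from_set <- function(set, path, quals = NULL) {
  out <- vector("list", length(set))
  nms <- names(set)
  for (k in seq_along(set)) {
    id <- sub("\\s.*$", "", nms[k])
    if (is.na(id) || !nzchar(id))
      stop("parse error in '", path, "': record ", k, " has an empty header",
           call. = FALSE)
    s <- toupper(as.character(set[k])[[1]])
    if (!nzchar(s))
      stop("parse error in '", path, "': record ", k, " ('", id,
           "') has an empty sequence", call. = FALSE)
    if (grepl("[^ACGTN]", s))
      stop("parse error in '", path, "': record ", k, " ('", id,
           "') contains characters outside A/C/G/T/N", call. = FALSE)
    out[[k]] <- seq_record(id, s, qual = quals[[k]],
                           meta = list())
  }
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  records <- as_record_list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, character(1), "seq"))
  names(set) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read / write FASTQ (Phred+33)
#'
#' Four-line-per-record FASTQ. Qualities are decoded to integer Phred scores
#' (offset 33) and carried on the records; a sequence/quality length mismatch
#' is a parse error. An empty file yields an empty list.
#'
#' @inheritParams read_fasta
#' @return `read_fastq`: list of `seq_record` with `qual` set.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) return(list())
  # structural pre-scan: the FASTQ reader pads short quality strings, so a
  # sequence/quality length mismatch has to be caught on the raw lines
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) %% 4 != 0)
    stop("parse error in '", path, "': line count is not a multiple of 4",
         call. = FALSE)
  for (k in seq_len(length(lines) / 4)) {
    rec <- lines[(k - 1) * 4 + 1:4]
    if (!startsWith(rec[1], "@") || !startsWith(rec[3], "+"))
      stop("parse error in '", path, "': record ", k,
           " is not 4-line FASTQ", call. = FALSE)
    if (nchar(rec[2]) != nchar(rec[4]))
      stop("parse error in '", path, "': record ", k,
           " sequence/quality length mismatch", call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  qstr <- S4Vectors::mcols(set)$qualities
  quals <- lapply(as.character(qstr), function(qs) utf8ToInt(qs) - 33L)
  records_from_set(set, path, quals = quals)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(records, path) {
  records <- as_record_list(records)
  seqs <- vapply(records, `[[`, character(1), "seq")
  ids <- vapply(records, `[[`, character(1), "id")
  quals <- vapply(seq_along(records), function(k) {
    q <- records[[k]]$qual
    if (is.null(q)) q <- rep(30L, nchar(seqs[k]))
    intToUtf8(q + 33L)
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  invisible(path)
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Handles the full degenerate alphabet (R<->Y, K<->M, W and S self-
#' complementary, N->N). An involution: `reverse_complement(reverse_complement(s))`
#' is `s`.
#'
#' @param seq IUPAC nucleotide string.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) return(seq)
  if (grepl(paste0("[^", paste(iupac_codes(), collapse = ""), "]"), seq))
    stop("alphabet error: invalid IUPAC character in sequence", call. = FALSE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Does a concrete base match an IUPAC code?
#'
#' @param base One of `A/C/G/T`.
#' @param code A single IUPAC code; `N` matches everything.
#' @return Logical.
#' @export
iupac_match <- function(base, code) {
  stopifnot(length(base) == 1L, length(code) == 1L)
  base <- toupper(base); code <- toupper(code)
  if (!base %in% DNA_BASES)
    stop("alphabet error: base must be one of A/C/G/T", call. = FALSE)
  if (!code %in% iupac_codes())
    stop("alphabet error: '", code, "' is not an IUPAC code", call. = FALSE)
  grepl(base, Biostrings::IUPAC_CODE_MAP[[code]], fixed = TRUE)
}

#' Define a degenerate primer pair
#'
#' @param name Pair name.
#' @param fwd,rev Forward and reverse primer, 5'->3', IUPAC codes allowed.
#' @param expected_len Optional expected amplicon length (bp).
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(name, fwd, rev, expected_len = NA_integer_) {
  stopifnot(nzchar(name), nzchar(fwd), nzchar(rev))
  fwd <- toupper(fwd); rev <- toupper(rev)
  bad <- paste0("[^", paste(iupac_codes(), collapse = ""), "]")
  if (grepl(bad, fwd) || grepl(bad, rev))
    stop("alphabet error: primer contains non-IUPAC characters", call. = FALSE)
  structure(list(name = name, fwd = fwd, rev = rev,
                 expected_len = as.integer(expected_len)),
            class = "primer_pair")
}

#' Load primer pairs from a 5-column TSV
#'
#' Columns: `name`, `fwd`, `rev`, `gene`, `expected_len`. The barcode primer
#' pairs shipped with the package (16S and two CO1 pairs used for vertebrate
#' barcoding) are available via
#' `system.file("extdata", "barcode_primers.tsv", package = "nanobar")`.
#'
#' @param path TSV path.
#' @return Named list of [primer_pair()].
#' @export
read_primer_pairs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "fwd", "rev", "gene", "expected_len") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(k)
    primer_pair(df$name[k], df$fwd[k], df$rev[k], df$expected_len[k]))
  setNames(out, df$name)
}

#' In-silico PCR: locate a primer pair on a template
#'
#' Finds all intervals spanned by a forward-primer match and a downstream
#' match of the reverse complement of the reverse primer, allowing up to
#' `max_mismatch` mismatches per primer site. Degenerate (IUPAC) primer
#' positions match their expansion at zero mismatch cost, and template `N`
#' positions match any primer character. Intervals are 0-based half-open and
#' include both primer sequences; overlapping products are all reported
#' (downstream consumers typically keep the longest).
#'
#' @param template A [seq_record()].
#' @param pair A [primer_pair()].
#' @param max_mismatch Maximum mismatches tolerated per primer site (>= 0).
#' @return Data frame with columns `start`, `end` (0-based half-open), sorted
#'   by `start` then `end`; zero rows when no site is found.
#' @export
find_amplicon <- function(template, pair, max_mismatch = 0L) {
  stopifnot(is_seq_record(template), inherits(pair, "primer_pair"),
            max_mismatch >= 0)
  subj <- Biostrings::DNAString(template$seq)
  fh <- Biostrings::matchPattern(Biostrings::DNAString(pair$fwd), subj,
                                 max.mismatch = max_mismatch, fixed = FALSE)
  rh <- Biostrings::matchPattern(
    Biostrings::DNAString(reverse_complement(pair$rev)), subj,
    max.mismatch = max_mismatch, fixed = FALSE)
  if (length(fh) == 0L || length(rh) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  combos <- expand.grid(f = seq_along(fh), r = seq_along(rh))
  fs <- Biostrings::start(fh)[combos$f]; fe <- Biostrings::end(fh)[combos$f]
  rs <- Biostrings::start(rh)[combos$r]; re <- Biostrings::end(rh)[combos$r]
  keep <- rs > fe
  out <- data.frame(start = fs[keep] - 1L, end = re[keep])
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate homopolymer runs
#'
#' Maximal runs of identical `A/C/G/T` bases of length at least `min_len`,
#' 0-based, sorted by start and non-overlapping. Nanopore chemistry miscounts
#' run lengths, so these annotations drive the simulator's homopolymer error
#' model and the coverage-dip analytics.
#'
#' @param seq Nucleotide string or [seq_record()].
#' @param min_len Minimum run length to report (>= 2 for the standard
#'   annotation; internal callers may use 1).
#' @return Data frame with columns `start` (0-based), `length`, `base`.
#' @export
annotate_homopolymers <- function(seq, min_len = 2L) {
  if (is_seq_record(seq)) seq <- seq$seq
  stopifnot(is.character(seq), length(seq) == 1L, min_len >= 1)
  if (!nzchar(seq))
    return(data.frame(start = integer(0), length = integer(0),
                      base = character(0)))
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  start <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  keep <- r$lengths >= min_len & r$values %in% DNA_BASES
  out <- data.frame(start = start[keep], length = r$lengths[keep],
                    base = r$values[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
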