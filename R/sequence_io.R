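# FASTA/FASTQ/GFA input-output and basic strand handling.
#
# Records travel through the pipeline as a plain data.frame ("seq_tbl") with
# columns id, seq and (optionally) qual, so that every stage can be inspected
# and constructed in tests without touching disk. Parsing and serialisation
# are delegated to Biostrings; this layer adds the validation the assembler
# relies on (unique ids, seq/qual length agreement, DNA alphabet, U -> T).

#' Construct a sequence record table
#'
#' @param id character vector of record identifiers (non-empty, unique).
#' @param seq character vector of sequences over \code{A,C,G,T,N}
#'   (lowercase and \code{U} are normalised on input).
#' @param qual optional character vector of Sanger Phred+33 quality strings,
#'   same lengths as \code{seq}.
#' @return a \code{data.frame} with columns \code{id}, \code{seq}, \code{qual}.
#' @export
seq_tbl <- function(id, seq, qual = NULL) {
  id <- as.character(id)
  seq <- normalize_seq(as.character(seq))
  if (length(id) != length(seq)) {
    stop("id and seq must have equal length")
  }
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate sequence ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (is.null(qual)) {
    qual <- rep(NA_character_, length(seq))
  } else {
    qual <- as.character(qual)
    bad <- which(!is.na(qual) & nchar(qual) != nchar(seq))
    if (length(bad)) {
      stop("quality string length differs from sequence length for record ",
           id[bad[1]])
    }
  }
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

# Uppercase, map RNA U to T, and check the alphabet.
normalize_seq <- function(seq) {
  seq <- chartr("acgtun", "ACGTTN", seq)
  seq <- chartr("U", "T", seq)
  bad <- stringi::stri_detect_regex(seq, "[^ACGTN]")
  if (any(bad)) {
    stop("non-DNA characters in sequence(s): record index ",
         paste(utils::head(which(bad), 3L), collapse = ", "))
  }
  seq
}

#' Read sequences from FASTA or FASTQ
#'
#' Records are returned in file order; sequences are uppercased and RNA
#' \code{U} is mapped to \code{T}. Duplicate ids within one file are an
#' error. FASTQ records whose quality string length disagrees with the
#' sequence length raise a parse error naming the offending record and its
#' approximate line.
#'
#' @param path path to a (optionally gzipped) FASTA or FASTQ file.
#' @param format \code{"auto"} (from the extension), \code{"fasta"} or
#'   \code{"fastq"}.
#' @return a \code{\link{seq_tbl}} data.frame.
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") format <- guess_seq_format(path)
  if (format == "fastq") {
    # Biostrings does not validate sequence/quality length agreement, and
    # decoding a malformed record can fail deep inside as.character, so
    # the whole extraction is guarded
    parsed <- tryCatch({
      x <- Biostrings::readBStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
      list(x = x, qual = as.character(S4Vectors::mcols(x)$qualities),
           seqs = as.character(x))
    }, error = function(e) stop("malformed FASTQ in ", path, ": ",
                                conditionMessage(e), call. = FALSE))
    x <- parsed$x; qual <- parsed$qual; seqs <- parsed$seqs
    bad <- which(nchar(qual) != nchar(seqs))
    if (length(bad)) {
      i <- bad[1]
      stop("malformed FASTQ in ", path, ": quality length != sequence length ",
           "for record ", i, " (near line ", 4L * (i - 1L) + 1L, ")",
           call. = FALSE)
    }
  } else {
    x <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) stop("malformed FASTA in ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    qual <- NULL
    seqs <- as.character(x)
  }
  ids <- sub("\\s.*$", "", names(x))
  if (length(ids) == 0L) {
    return(seq_tbl(character(), character()))
  }
  seq_tbl(ids, seqs, qual)
}

guess_seq_format <- function(path) {
  p <- sub("\\.gz$", "", tolower(path))
  if (grepl("\\.(fq|fastq)$", p)) "fastq" else "fasta"
}

#' Write sequences to FASTA or FASTQ
#'
#' FASTA output is wrapped at 80 columns; re-parsing yields the same
#' records. FASTQ output requires qualities on every record.
#'
#' @param records a \code{\link{seq_tbl}} data.frame.
#' @param path output file path (\code{.gz} is honoured).
#' @param format \code{"fasta"} or \code{"fastq"}.
#' @param width FASTA line width.
#' @export
write_seqs <- function(records, path, format = c("fasta", "fastq"), width = 80L) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (any(!nzchar(records$seq))) {
    stop("refusing to write zero-length sequence (record ",
         records$id[which(!nzchar(records$seq))[1]], ")")
  }
  x <- Biostrings::BStringSet(records$seq)
  names(x) <- records$id
  if (format == "fastq") {
    if (is.null(records$qual) || any(is.na(records$qual))) {
      stop("FASTQ output requires qualities on every record")
    }
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(records$qual))
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta", width = width)
  }
  invisible(path)
}

#' Reverse complement
#'
#' Length-preserving involution over the alphabet \code{A,C,G,T,N}.
#'
#' @param seq character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
rc_seq <- function(seq) {
  bad <- stringi::stri_detect_regex(seq, "[^ACGTN]")
  if (any(bad)) stop("non-DNA characters in sequence(s)")
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", seq))
}

#' Export a unitig graph as GFA1
#'
#' One \code{S} line per unitig (with \code{KC} k-mer coverage tag) and one
#' \code{L} line per adjacency; adjacent unitigs overlap by exactly
#' \code{k - 1} bases, so every link carries the CIGAR \code{(k-1)M}.
#'
#' @param graph a \code{unitig_graph} (see \code{\link{condense}}).
#' @param path output file path.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "unitig_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  u <- graph$unitigs
  if (nrow(u)) {
    writeLines(sprintf("S\t%s\t%s\tKC:i:%d", u$id, u$seq,
                       as.integer(round(u$cov * (nchar(u$seq) - graph$k + 1L)))),
               con)
  }
  l <- graph$links
  if (!is.null(l) && nrow(l)) {
    writeLines(sprintf("L\t%s\t+\t%s\t+\t%dM", l$from, l$to, graph$k - 1L), con)
  }
  invisible(path)
}
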