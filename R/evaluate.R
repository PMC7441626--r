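# Assembly quality metrics against a reference transcript set: N50,
# transcript counts, x%-assembled gene counts, isoform recovery, and the
# transcript length histogram. Alignment of transcripts to references uses
# the same exact-anchor chaining engine as long-read threading, with an
# exact-match fast path.

#' N50 of a length set
#'
#' The smallest length L such that sequences of length >= L together
#' contain at least half of the total bases.
#'
#' @param lengths positive lengths (bp).
#' @return N50 in bp.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("n50 of an empty length set is undefined")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1L]]
}

#' Transcript length histogram
#'
#' @param lengths lengths in bp.
#' @param bin bin width in bp (default 10).
#' @return data.frame(bin_start, count); bins start at 0.
#' @export
length_histogram <- function(lengths, bin = 10L) {
  if (!length(lengths)) {
    return(data.frame(bin_start = integer(), count = integer()))
  }
  b <- (lengths %/% bin) * bin
  tb <- table(b)
  data.frame(bin_start = as.integer(names(tb)), count = as.integer(tb))
}

# Align query sequences to reference sequences by exact-anchor chaining.
# Returns data.table(query, ref, coverage, identity): per pair sharing
# chained anchors, coverage = chained reference span / reference length,
# identity = anchor-matched reference bases / chained span. Exact equality
# and substring containment short-circuit to coverage 1 (or ref coverage
# fraction) at identity 1.
align_to_reference <- function(query, refs, anchor_k = 13L, try_rc = TRUE) {
  nq <- length(query); nr <- length(refs)
  if (!nq || !nr) {
    return(data.table::data.table(query = integer(), ref = integer(),
                                  coverage = numeric(), identity = numeric()))
  }
  ref_kd <- extract_kmers(refs, anchor_k, positions = TRUE)
  idx <- data.table::data.table(anchor = ref_kd$kmer, ref = ref_kd$idx,
                                rpos_ref = ref_kd$pos)
  data.table::setkey(idx, anchor)
  score_one <- function(qseq, q) {
    if (nchar(qseq) < anchor_k) return(NULL)
    qk <- extract_kmers(qseq, anchor_k, positions = TRUE)
    hits <- idx[data.table::data.table(anchor = qk$kmer, qpos = qk$pos),
                on = "anchor", nomatch = NULL]
    if (!nrow(hits)) return(NULL)
    out <- hits[, {
      hh <- data.table::data.table(rpos = qpos, uid = "r", upos = rpos_ref)
      res <- chain_anchor_blocks(hh, anchor_k)
      ch <- res$chain
      rspan_start <- min(ch$ustart); rspan_end <- max(ch$uend) + anchor_k
      matched <- sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = ch$ustart + 1L, end = ch$uend + anchor_k))))
      span <- rspan_end - rspan_start
      list(coverage = matched / nchar(refs[.BY$ref]),
           identity = matched / span)
    }, by = "ref"]
    out[, "query" := q]
    out
  }
  parts <- vector("list", nq)
  for (q in seq_len(nq)) {
    qseq <- query[q]
    exact <- which(refs == qseq)
    if (length(exact)) {
      parts[[q]] <- data.table::data.table(ref = exact, coverage = 1,
                                           identity = 1, query = q)
      next
    }
    res <- score_one(qseq, q)
    if (try_rc) {
      res_rc <- score_one(rc_seq(qseq), q)
      res <- data.table::rbindlist(list(res, res_rc))
      if (nrow(res)) {
        res <- res[order(-coverage * identity)][!duplicated(ref)]
      }
    }
    parts[[q]] <- res
  }
  out <- data.table::rbindlist(parts, use.names = TRUE, fill = TRUE)
  if (!nrow(out)) {
    return(data.table::data.table(query = integer(), ref = integer(),
                                  coverage = numeric(), identity = numeric()))
  }
  out[, c("query", "ref", "coverage", "identity")]
}

#' x%-assembled gene counts
#'
#' A reference isoform is x%-assembled when at least one transcript aligns
#' to it covering at least x of its length at \code{min_identity}; a gene
#' counts at threshold x when any of its isoforms does.
#'
#' @param transcripts a \code{transcript_set} (or character vector of
#'   transcript sequences).
#' @param reference \code{\link{seq_tbl}} of reference isoform sequences.
#' @param genes gene id per reference record; defaults to stripping a
#'   trailing \code{.i<No>} from the isoform id.
#' @param thresholds coverage thresholds (default 0.50 and 0.95).
#' @param min_identity minimum alignment identity (default 0.95).
#' @return named integer vector of gene counts, one per threshold.
#' @export
assembled_gene_counts <- function(transcripts, reference, genes = NULL,
                                  thresholds = c(0.50, 0.95),
                                  min_identity = 0.95) {
  if (!nrow(reference)) stop("reference must be non-empty")
  tx <- if (is.character(transcripts)) transcripts else transcripts$seq
  if (is.null(genes)) genes <- sub("\\.i\\d+$", "", reference$id)
  al <- align_to_reference(tx, reference$seq)
  al <- al[identity >= min_identity]
  best <- rep(0, nrow(reference))
  if (nrow(al)) {
    bb <- al[, list(cov = max(coverage)), by = "ref"]
    best[bb$ref] <- bb$cov
  }
  out <- vapply(thresholds, function(th)
    length(unique(genes[best >= th - 1e-9])), 0L)
  names(out) <- sprintf("genes_%dpct", as.integer(round(100 * thresholds)))
  out
}

#' Isoform recovery against simulation ground truth
#'
#' Sensitivity = recovered truth isoforms / total truth isoforms;
#' precision = transcripts matching some truth isoform / total
#' transcripts. A transcript matches an isoform when alignment coverage of
#' the isoform and identity both reach their thresholds.
#'
#' @param transcripts a \code{transcript_set} or character vector of
#'   sequences.
#' @param truth \code{\link{seq_tbl}} of truth isoform sequences, or a
#'   \code{transcriptome}.
#' @param coverage,identity match thresholds (defaults 0.95).
#' @return list(sensitivity, precision, n_truth, n_transcripts,
#'   recovered ids).
#' @export
isoform_recovery <- function(transcripts, truth, coverage = 0.95,
                             identity = 0.95) {
  if (inherits(truth, "transcriptome")) {
    truth <- seq_tbl(truth$isoforms$isoform_id, truth$isoforms$seq)
  }
  tx <- if (is.character(transcripts)) transcripts else transcripts$seq
  if (!length(tx)) {
    return(list(sensitivity = 0, precision = NA_real_,
                n_truth = nrow(truth), n_transcripts = 0L,
                recovered = character()))
  }
  cov_th <- coverage; id_th <- identity
  al <- align_to_reference(tx, truth$seq)
  hit <- al[al$coverage >= cov_th - 1e-9 & al$identity >= id_th - 1e-9]
  recovered <- sort(unique(truth$id[hit$ref]))
  matched_tx <- unique(hit$query)
  list(sensitivity = length(recovered) / nrow(truth),
       precision = length(matched_tx) / length(tx),
       n_truth = nrow(truth), n_transcripts = length(tx),
       recovered = recovered)
}

#' Full metric panel for one assembly
#'
#' @param transcripts a \code{transcript_set} or character vector.
#' @param reference \code{\link{seq_tbl}} of reference isoforms (also used
#'   as recovery truth), or NULL for reference-free metrics only.
#' @param genes optional gene ids per reference record.
#' @param min_identity identity threshold for the assembled-gene counts.
#' @return list of metrics (n_transcripts, n_over_500bp, n50, genes_50pct,
#'   genes_95pct, isoform_sensitivity, isoform_precision,
#'   length_histogram).
#' @export
assembly_metrics <- function(transcripts, reference = NULL, genes = NULL,
                             min_identity = 0.95) {
  tx <- if (is.character(transcripts)) transcripts else transcripts$seq
  lens <- nchar(tx)
  out <- list(n_transcripts = length(tx),
              n_over_500bp = sum(lens > 500L),
              n50 = if (length(lens)) n50(lens) else NA_integer_,
              length_histogram = length_histogram(lens))
  if (!is.null(reference)) {
    gc <- assembled_gene_counts(tx, reference, genes,
                                min_identity = min_identity)
    rec <- isoform_recovery(tx, reference)
    out$genes_50pct <- unname(gc["genes_50pct"])
    out$genes_95pct <- unname(gc["genes_95pct"])
    out$isoform_sensitivity <- rec$sensitivity
    out$isoform_precision <- rec$precision
  }
  out
}

#' Side-by-side metric report for one or more assemblies
#'
#' One metric per row, one column per assembly (the two-column layout used
#' to contrast a hybrid assembly with its short-read-only baseline).
#'
#' @param assemblies named list of \code{transcript_set}s (or character
#'   vectors of sequences).
#' @param reference \code{\link{seq_tbl}} of reference isoforms or NULL.
#' @param genes optional gene ids per reference record.
#' @param path optional TSV output path.
#' @return data.frame with a \code{metric} column and one column per
#'   assembly.
#' @export
metrics_report <- function(assemblies, reference = NULL, genes = NULL,
                           path = NULL) {
  stopifnot(is.list(assemblies), length(assemblies) >= 1L,
            !is.null(names(assemblies)))
  rows <- c("n_transcripts", "n_over_500bp", "n50",
            if (!is.null(reference)) c("genes_50pct", "genes_95pct",
                                       "isoform_sensitivity",
                                       "isoform_precision"))
  cols <- lapply(assemblies, function(a) {
    m <- assembly_metrics(a, reference, genes)
    vapply(rows, function(r) as.numeric(m[[r]]), 0)
  })
  out <- data.frame(metric = rows, stringsAsFactors = FALSE)
  for (nm in names(cols)) out[[nm]] <- cols[[nm]]
  if (!is.null(path)) data.table::fwrite(out, path, sep = "\t")
  out
}
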