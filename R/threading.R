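# Full-length classification of long cDNA reads and threading of reads
# through the unitig graph as anchor chains.
#
# A read is full-length (FL) when both library adapters are found near its
# ends by sequence alignment at >= 70% similarity. Similarity of an adapter
# occurrence is (adapter_length - E) / adapter_length where E is the edit
# distance of the best fitting (infix) alignment of the whole adapter
# inside a terminal window of the read; gaps count as errors, and the
# decision threshold is evaluated in integer arithmetic so the 70%
# boundary is inclusive (a 10 bp adapter with exactly 3 mismatches passes).

#' Full-length detection parameters
#'
#' @param adapter5,adapter3 adapter sequences.
#' @param min_similarity minimum adapter similarity, default 0.70.
#' @param window_factor terminal search window, as a multiple of the
#'   adapter length (default 1.5).
#' @export
fl_params <- function(adapter5 = DEFAULT_ADAPTER5, adapter3 = DEFAULT_ADAPTER3,
                      min_similarity = 0.70, window_factor = 1.5) {
  if (!nzchar(adapter5) || !nzchar(adapter3)) stop("adapters must be non-empty")
  if (min_similarity <= 0 || min_similarity > 1) {
    stop("min_similarity must be in (0, 1]")
  }
  structure(list(adapter5 = normalize_seq(adapter5),
                 adapter3 = normalize_seq(adapter3),
                 min_similarity = min_similarity,
                 window_factor = window_factor),
            class = "fl_params")
}

# Fitting (infix) alignment of `pattern` inside `window`: the whole pattern
# is aligned against some substring of the window, minimising unit-cost
# edits. Returns list(edits, start, end): 0-based half-open matched span in
# the window (start == end when the window is empty).
fit_align <- function(pattern, window) {
  m <- nchar(pattern); wn <- nchar(window)
  if (wn == 0L) return(list(edits = m, start = 0L, end = 0L))
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  wc <- strsplit(window, "", fixed = TRUE)[[1]]
  D <- matrix(0L, m + 1L, wn + 1L)
  D[, 1L] <- 0:m
  cols <- 0:wn
  for (i in seq_len(m)) {
    sub <- D[i, 1:wn] + (pc[i] != wc)
    up <- D[i, 2:(wn + 1L)] + 1L
    cand <- c(D[i + 1L, 1L], pmin(sub, up))
    D[i + 1L, ] <- cummin(cand - cols) + cols
  }
  last <- D[m + 1L, ]
  jend <- which.min(last) - 1L          # smallest j on ties
  edits <- last[jend + 1L]
  # traceback for the matched span start
  i <- m; j <- jend
  while (i > 0L) {
    if (j > 0L && D[i + 1L, j + 1L] == D[i, j] + (pc[i] != wc[j])) {
      i <- i - 1L; j <- j - 1L
    } else if (D[i + 1L, j + 1L] == D[i, j + 1L] + 1L) {
      i <- i - 1L
    } else if (j > 0L && D[i + 1L, j + 1L] == D[i + 1L, j] + 1L) {
      j <- j - 1L
    } else {
      i <- i - 1L  # defensive; should not happen
    }
  }
  list(edits = as.integer(edits), start = as.integer(j), end = as.integer(jend))
}

# Integer-arithmetic similarity decision: detected iff
# edits <= floor(len * (1 - min_similarity) + eps).
adapter_detected <- function(edits, adapter_len, min_similarity) {
  edits <= floor(adapter_len * (1 - min_similarity) + 1e-9)
}

# Scan one oriented read for both adapters in terminal windows.
scan_adapters <- function(seq, params) {
  n <- nchar(seq)
  la5 <- nchar(params$adapter5); la3 <- nchar(params$adapter3)
  w5n <- min(n, as.integer(round(params$window_factor * la5)))
  w3n <- min(n, as.integer(round(params$window_factor * la3)))
  a5 <- fit_align(params$adapter5, substr(seq, 1L, w5n))
  a3 <- fit_align(params$adapter3, substr(seq, n - w3n + 1L, n))
  det5 <- adapter_detected(a5$edits, la5, params$min_similarity)
  det3 <- adapter_detected(a3$edits, la3, params$min_similarity)
  list(det5 = det5, det3 = det3,
       sim5 = 1 - a5$edits / la5, sim3 = 1 - a3$edits / la3,
       trim_from = if (det5) a5$end else 0L,
       trim_to = if (det3) (n - w3n + a3$start) else n)
}

#' Classify a long read as full-length and trim its adapters
#'
#' Each adapter is searched by best fitting alignment within a terminal
#' window (\code{window_factor} x adapter length) at the appropriate read
#' end, on both strands; the read is full-length iff both adapters reach
#' \code{min_similarity}. The trimmed read has all detected adapter spans
#' removed and is reported in sense orientation (reverse-complemented when
#' the adapters were found on the reverse strand). A read shorter than the
#' two adapters combined is returned untrimmed and not full-length.
#'
#' @param seq a single read sequence (character scalar).
#' @param params \code{\link{fl_params}}.
#' @return list(is_full_length, trimmed, strand, sim5, sim3).
#' @export
detect_full_length <- function(seq, params = fl_params()) {
  stopifnot(length(seq) == 1L, nzchar(seq))
  la5 <- nchar(params$adapter5); la3 <- nchar(params$adapter3)
  if (nchar(seq) < la5 + la3) {
    return(list(is_full_length = FALSE, trimmed = seq, strand = "+",
                sim5 = 0, sim3 = 0))
  }
  fwd <- scan_adapters(seq, params)
  rev <- scan_adapters(rc_seq(seq), params)
  score <- function(s) c(s$det5 + s$det3, s$sim5 + s$sim3)
  sf <- score(fwd); sr <- score(rev)
  use_rev <- (sr[1] > sf[1]) || (sr[1] == sf[1] && sr[2] > sf[2] + 1e-12)
  hit <- if (use_rev) rev else fwd
  oriented <- if (use_rev) rc_seq(seq) else seq
  trimmed <- substr(oriented, hit$trim_from + 1L, hit$trim_to)
  if (!nzchar(trimmed)) trimmed <- oriented
  list(is_full_length = hit$det5 && hit$det3, trimmed = trimmed,
       strand = if (use_rev) "-" else "+",
       sim5 = hit$sim5, sim3 = hit$sim3)
}

#' Build an anchor index over a unitig graph
#'
#' Exact \code{anchor_k}-mer positions in all unitig sequences, used for
#' anchor-and-chain threading. Anchors occurring more than \code{max_occ}
#' times (repeats) are dropped.
#'
#' @param graph a \code{unitig_graph}.
#' @param anchor_k anchor k-mer size (must be <= graph k).
#' @param max_occ repeat-occurrence cap.
#' @return data.table(anchor, uid, upos) keyed by anchor; upos is 0-based.
#' @export
build_anchor_index <- function(graph, anchor_k = 13L, max_occ = 16L) {
  stopifnot(inherits(graph, "unitig_graph"), anchor_k >= 4L)
  kd <- extract_kmers(graph$unitigs$seq, anchor_k, positions = TRUE)
  idx <- data.table::data.table(anchor = kd$kmer,
                                uid = graph$unitigs$id[kd$idx],
                                upos = kd$pos)
  occ <- idx[, list(n = .N), by = "anchor"]
  idx <- idx[occ[n <= max_occ], on = "anchor"][, c("anchor", "uid", "upos")]
  data.table::setkey(idx, anchor)
  attr(idx, "anchor_k") <- as.integer(anchor_k)
  idx
}

# Merge co-diagonal anchor hits into blocks and chain them collinearly by
# dynamic programming. hits: data.table(rpos, uid, upos). Returns the best
# chain as a data.table of blocks (uid, rstart, rend, ustart, uend, span)
# in read order, plus its score and covered read bases.
chain_anchor_blocks <- function(hits, ak, merge_gap = 50L, max_overlap = NULL) {
  if (!nrow(hits)) return(NULL)
  if (is.null(max_overlap)) max_overlap <- ak
  hits <- data.table::copy(hits)
  hits[, "diag" := rpos - upos]
  data.table::setorder(hits, uid, diag, rpos)
  new_block <- c(TRUE, hits$uid[-1L] != hits$uid[-nrow(hits)] |
                   hits$diag[-1L] != hits$diag[-nrow(hits)] |
                   hits$rpos[-1L] - hits$rpos[-nrow(hits)] > merge_gap)
  hits[, "block" := cumsum(new_block)]
  blocks <- hits[, list(uid = uid[1L], rstart = min(rpos), rend = max(rpos),
                        ustart = min(upos), uend = max(upos), n = .N),
                 by = "block"]
  blocks[, "span" := rend - rstart + ak]
  data.table::setorder(blocks, rstart, ustart, uid)
  nb <- nrow(blocks)
  # gain scoring: a block contributes only the read bases it covers beyond
  # the chain's current end, so near-duplicate blocks (the same read region
  # seen on several unitigs through their shared (k-1)-overlaps) gain
  # nothing and are not chained through
  rstart <- blocks$rstart; rend_x <- blocks$rend + ak
  ustart <- blocks$ustart; uend_x <- blocks$uend + ak
  uid <- blocks$uid; span <- blocks$span
  dp <- as.numeric(span)
  prev <- rep(NA_integer_, nb)
  if (nb > 1L) {
    for (i in 2:nb) {
      j <- seq_len(i - 1L)
      rgap <- rstart[i] - rend_x[j]
      # consecutive unitigs share a (k-1)-base overlap, so blocks from both
      # sides of a junction legitimately overlap on the read
      same <- uid[j] == uid[i]
      ok <- rgap >= -max_overlap & rend_x[i] > rend_x[j] &
        (!same | ustart[i] > uend_x[j] - ak)
      if (!any(ok)) next
      ugap <- ustart[i] - uend_x[j]
      cost <- ifelse(same, 0.05 * pmax(rgap, 0) + 0.5 * abs(rgap - ugap),
                     2 + 0.05 * pmax(rgap, 0))
      gain <- pmax(0, pmin(span[i], rend_x[i] - rend_x[j]))
      cand <- ifelse(ok, dp[j] + gain - cost, -Inf)
      b <- which.max(cand)
      if (cand[b] > dp[i] + 1e-9) {
        dp[i] <- cand[b]; prev[i] <- b
      }
    }
  }
  best <- which.max(dp)
  path <- integer(0); i <- best
  while (!is.na(i)) { path <- c(i, path); i <- prev[i] }
  chain <- blocks[path]
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = chain$rstart + 1L, end = chain$rend + ak))))
  list(chain = chain, score = dp[best], covered = covered)
}

# Depth-first search for a link path from `from` to `to` with at most
# max_mid intermediate unitigs; among candidates, pick the one whose
# spelled gap length is closest to read_gap. Returns character vector of
# intermediate uids, or NULL.
fill_link_gap <- function(graph, from, to, read_gap, max_mid = 4L) {
  adj <- split(graph$links$to, graph$links$from)
  ulen <- stats::setNames(nchar(graph$unitigs$seq), graph$unitigs$id)
  k <- graph$k
  best <- NULL; best_diff <- Inf
  recurse <- function(cur, mids, gap_len) {
    nbs <- adj[[cur]]
    if (is.null(nbs)) return()
    for (nb in nbs) {
      if (nb == to) {
        diff <- abs(gap_len - read_gap)
        if (diff < best_diff) { best_diff <<- diff; best <<- mids }
      } else if (length(mids) < max_mid && !(nb %in% mids)) {
        recurse(nb, c(mids, nb), gap_len + ulen[[nb]] - (k - 1L))
      }
    }
  }
  recurse(from, character(0), 0L)
  if (!is.null(best) && best_diff <= max(100L, abs(read_gap))) best else NULL
}

#' Thread a long read through the unitig graph
#'
#' Exact \code{anchor_k}-mer matches between the read and the unitigs are
#' merged into co-diagonal blocks and chained collinearly by gap-penalised
#' dynamic programming (ties broken by leftmost read coordinate). The
#' resulting unitig chain must be link-consistent; single missing links are
#' repaired by a bounded search for a connecting path whose length matches
#' the read gap, otherwise the chain is truncated at the break (keeping the
#' higher-scoring side). Returns \code{NULL} when the chained anchors cover
#' less than \code{min_aligned_fraction} of the read.
#'
#' @param seq a single read sequence (adapter-trimmed).
#' @param graph a \code{unitig_graph}.
#' @param index anchor index from \code{\link{build_anchor_index}} (built
#'   on the fly if NULL).
#' @param anchor_k anchor size (ignored when \code{index} is given).
#' @param min_aligned_fraction minimum fraction of read bases covered by
#'   the chained anchors.
#' @param try_rc also try the reverse-complemented read and keep the better
#'   orientation.
#' @return list(path, aligned_fraction, score, strand) or \code{NULL}.
#' @export
thread_long_read <- function(seq, graph, index = NULL, anchor_k = 13L,
                             min_aligned_fraction = 0.5, try_rc = TRUE) {
  stopifnot(inherits(graph, "unitig_graph"))
  if (nrow(graph$unitigs) == 0L) return(NULL)
  if (is.null(index)) index <- build_anchor_index(graph, anchor_k)
  ak <- attr(index, "anchor_k")
  thread_one <- function(s) {
    if (nchar(s) < ak) return(NULL)
    rk <- extract_kmers(s, ak, positions = TRUE)
    hits <- index[data.table::data.table(anchor = rk$kmer, rpos = rk$pos),
                  on = "anchor", nomatch = NULL]
    if (!nrow(hits)) return(NULL)
    res <- chain_anchor_blocks(hits[, c("rpos", "uid", "upos")], ak,
                               max_overlap = graph$k - 1L + ak)
    if (is.null(res)) return(NULL)
    seg <- repair_chain(res$chain, graph, ak)
    if (is.null(seg)) return(NULL)
    list(path = seg$path,
         aligned_fraction = min(1, chain_footprint(seg$blocks, ak) / nchar(s)),
         score = res$score, strand = "+")
  }
  fwd <- thread_one(seq)
  res <- fwd
  if (try_rc) {
    rev <- thread_one(rc_seq(seq))
    if (!is.null(rev) &&
        (is.null(fwd) || rev$aligned_fraction > fwd$aligned_fraction + 1e-9)) {
      rev$strand <- "-"
      res <- rev
    }
  }
  if (is.null(res) || res$aligned_fraction < min_aligned_fraction) return(NULL)
  res
}

# Read bases covered by the chained alignment: per maximal run of chain
# blocks on one unitig, the footprint spans first anchor start to last
# anchor end (indel-induced diagonal shifts inside a unitig do not
# interrupt the alignment); overlapping junction footprints count once.
chain_footprint <- function(blocks, ak) {
  run <- cumsum(c(TRUE, blocks$uid[-1L] != blocks$uid[-nrow(blocks)]))
  ext <- data.table::data.table(run = run, s = blocks$rstart,
                                e = blocks$rend + ak)[
    , list(s = min(s), e = max(e)), by = "run"]
  sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = ext$s + 1L, end = ext$e))))
}

# Turn a chained block list into a link-consistent unitig path. Consecutive
# blocks on the same unitig are collapsed; missing links between successive
# unitigs are filled by fill_link_gap when possible, otherwise the chain is
# split there and the segment covering the most read bases is kept.
repair_chain <- function(chain, graph, ak) {
  uids <- chain$uid
  keep <- c(TRUE, uids[-1L] != uids[-length(uids)])
  path <- uids[keep]
  block_first <- which(keep)
  block_last <- c(block_first[-1L] - 1L, nrow(chain))
  link_set <- paste(graph$links$from, graph$links$to)
  has_link <- function(u, v) paste(u, v) %in% link_set
  segments <- list()
  cur_path <- path[1L]; cur_from <- 1L
  if (length(path) > 1L) {
    for (t in 2:length(path)) {
      u <- path[t - 1L]; v <- path[t]
      if (has_link(u, v)) { cur_path <- c(cur_path, v); next }
      bi <- block_first[t]
      read_gap <- chain$rstart[bi] - (chain$rend[bi - 1L] + ak)
      mids <- fill_link_gap(graph, u, v, read_gap)
      if (!is.null(mids)) { cur_path <- c(cur_path, mids, v); next }
      segments[[length(segments) + 1L]] <-
        list(path = cur_path, from = cur_from, to = block_last[t - 1L])
      cur_path <- v; cur_from <- block_first[t]
    }
  }
  segments[[length(segments) + 1L]] <-
    list(path = cur_path, from = cur_from, to = nrow(chain))
  covered <- vapply(segments, function(sg)
    sum(chain$span[sg$from:sg$to]), 0)
  best <- segments[[which.max(covered)]]
  list(path = best$path, blocks = chain[best$from:best$to])
}

#' Classify and thread a set of long reads
#'
#' Runs \code{\link{detect_full_length}} and \code{\link{thread_long_read}}
#' over a read table, returning one alignment record per mappable read and
#' stage counts (reads in, FL fraction, mapped fraction).
#'
#' @param reads a \code{\link{seq_tbl}} of long reads.
#' @param graph a \code{unitig_graph}.
#' @param params \code{\link{fl_params}}.
#' @param anchor_k,min_aligned_fraction see \code{\link{thread_long_read}}.
#' @return list(alignments = list of records (read_id, path,
#'   aligned_fraction, is_full_length, strand), stats = list).
#' @export
thread_long_reads <- function(reads, graph, params = fl_params(),
                              anchor_k = 13L, min_aligned_fraction = 0.5) {
  stopifnot(is.data.frame(reads))
  index <- if (nrow(graph$unitigs)) build_anchor_index(graph, anchor_k) else NULL
  alns <- vector("list", nrow(reads))
  n_fl <- 0L; n_mapped <- 0L
  for (i in seq_len(nrow(reads))) {
    det <- detect_full_length(reads$seq[i], params)
    if (det$is_full_length) n_fl <- n_fl + 1L
    if (is.null(index)) next
    thr <- thread_long_read(det$trimmed, graph, index = index,
                            min_aligned_fraction = min_aligned_fraction)
    if (is.null(thr)) next
    n_mapped <- n_mapped + 1L
    alns[[i]] <- list(read_id = reads$id[i], path = thr$path,
                      aligned_fraction = thr$aligned_fraction,
                      is_full_length = det$is_full_length,
                      strand = thr$strand)
  }
  alns <- alns[!vapply(alns, is.null, TRUE)]
  list(alignments = alns,
       stats = list(n_reads = nrow(reads), n_full_length = n_fl,
                    n_mapped = n_mapped,
                    fl_fraction = if (nrow(reads)) n_fl / nrow(reads) else NA_real_,
                    mapped_fraction = if (nrow(reads)) n_mapped / nrow(reads) else NA_real_))
}

#' Write threaded alignments as TSV
#'
#' @param alignments alignment list from \code{\link{thread_long_reads}}.
#' @param path output TSV path.
#' @export
write_alignments_tsv <- function(alignments, path) {
  dt <- data.table::data.table(
    read_id = vapply(alignments, `[[`, "", "read_id"),
    chain = vapply(alignments, function(a) paste(a$path, collapse = ","), ""),
    strand = vapply(alignments, `[[`, "", "strand"),
    aligned_fraction = vapply(alignments, `[[`, 0, "aligned_fraction"),
    is_full_length = vapply(alignments, `[[`, TRUE, "is_full_length")
  )
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
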