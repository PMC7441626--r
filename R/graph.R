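# De Bruijn graph construction, cleanup, and unitig condensation.
#
# Edges are k-mers with coverage counts; nodes are their (k-1)-mer
# prefixes/suffixes. In strand-specific mode (the default; the libraries
# the assembler targets are strand-specific) k-mers are stored as observed
# on the sense strand -- mate 1 is reverse-complemented first under the
# dUTP convention -- so no canonicalization is applied. The non-stranded
# mode inserts both strands of every read and relies on
# reverse-complement-aware deduplication downstream.

# Extract all k-mers from a character vector of sequences.
# Returns a data.table with columns kmer (+ idx, pos when positions=TRUE;
# pos is 0-based).
extract_kmers <- function(seqs, k, positions = FALSE) {
  lens <- nchar(seqs)
  keep <- lens >= k
  seqs <- seqs[keep]; lens <- lens[keep]
  if (!length(seqs)) {
    return(if (positions)
      data.table::data.table(idx = integer(), pos = integer(), kmer = character())
      else data.table::data.table(kmer = character()))
  }
  orig_idx <- which(keep)
  noff <- max(lens) - k + 1L
  if (length(seqs) >= noff) {
    # many (short) sequences: one vectorised substr per offset
    parts <- vector("list", noff)
    for (s in seq_len(noff)) {
      sel <- lens >= s + k - 1L
      km <- substr(seqs[sel], s, s + k - 1L)
      parts[[s]] <- if (positions) {
        data.table::data.table(idx = orig_idx[sel], pos = s - 1L, kmer = km)
      } else data.table::data.table(kmer = km)
    }
    return(data.table::rbindlist(parts))
  }
  # few (long) sequences: one vectorised substring per sequence
  parts <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    starts <- seq_len(lens[i] - k + 1L)
    km <- substring(seqs[i], starts, starts + k - 1L)
    parts[[i]] <- if (positions) {
      data.table::data.table(idx = orig_idx[i], pos = starts - 1L, kmer = km)
    } else data.table::data.table(kmer = km)
  }
  data.table::rbindlist(parts)
}

#' Build a De Bruijn graph from short reads
#'
#' The edge set is every k-mer occurring at least \code{min_count} times
#' across the (orientation-normalised) reads; k-mers containing \code{N}
#' are skipped. In strand-specific mode reads are oriented to the
#' transcript sense strand first: with \code{orientation = "rf"} (dUTP
#' convention) mate 1 is reverse-complemented, with \code{"fr"} mate 2 is.
#' In non-stranded mode both strands of every read contribute k-mers.
#'
#' @param reads a \code{\link{seq_tbl}} (single-end / pre-oriented), or a
#'   list of two seq_tbls \code{list(r1, r2)} for paired-end input.
#' @param k odd k-mer size, \code{3 <= k <} read length.
#' @param min_count minimum k-mer multiplicity to keep an edge.
#' @param strand_specific logical.
#' @param orientation \code{"rf"} or \code{"fr"} mate orientation
#'   (strand-specific paired-end only).
#' @return a \code{dbg} object: list(k, edges = data.table(kmer, count),
#'   strand_specific).
#' @export
build_graph <- function(reads, k = 25L, min_count = 2L,
                        strand_specific = TRUE, orientation = c("rf", "fr")) {
  orientation <- match.arg(orientation)
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L) stop("k must be odd and >= 3")
  if (min_count < 1L) stop("min_count must be >= 1")
  if (is.data.frame(reads)) {
    seqs <- reads$seq
  } else {
    stopifnot(is.list(reads), length(reads) >= 1L)
    r1 <- reads[[1]]$seq
    r2 <- if (length(reads) >= 2L && !is.null(reads[[2]])) reads[[2]]$seq else character()
    if (strand_specific && length(r2)) {
      if (orientation == "rf") r1 <- rc_seq(r1) else r2 <- rc_seq(r2)
    }
    seqs <- c(r1, r2)
  }
  if (!strand_specific) seqs <- c(seqs, rc_seq(seqs))
  if (all(nchar(seqs) < k)) {
    warning("k exceeds every read length; graph is empty")
    return(structure(list(k = k,
                          edges = data.table::data.table(kmer = character(),
                                                         count = integer()),
                          strand_specific = strand_specific), class = "dbg"))
  }
  kd <- extract_kmers(seqs, k)
  if (any(stringi::stri_detect_fixed(seqs, "N"))) {
    kd <- kd[!stringi::stri_detect_fixed(kd$kmer, "N")]
  }
  edges <- kd[, list(count = .N), by = "kmer"][count >= min_count]
  data.table::setorder(edges, kmer)
  structure(list(k = k, edges = edges, strand_specific = strand_specific),
            class = "dbg")
}

#' @export
print.dbg <- function(x, ...) {
  cat(sprintf("De Bruijn graph: k=%d, %d edges (%s)\n", x$k, nrow(x$edges),
              if (x$strand_specific) "strand-specific" else "both strands"))
  invisible(x)
}

#' Simplify a De Bruijn graph
#'
#' Iterates two standard cleanup rules to a fixpoint: (1) tip clipping --
#' dead-end unitig chains of at most \code{tip_max_len} edges with mean
#' coverage below \code{cov_cutoff} are removed; (2) low-coverage edges
#' (count < \code{cov_cutoff}) that compete with a strictly
#' higher-coverage alternative edge at either endpoint node are removed.
#'
#' @param graph a \code{dbg}.
#' @param tip_max_len maximum tip length, in edges (default \code{2k}).
#' @param cov_cutoff coverage threshold; 0 disables cleanup.
#' @return a simplified \code{dbg}.
#' @export
simplify_graph <- function(graph, tip_max_len = 2L * graph$k, cov_cutoff = 5) {
  stopifnot(inherits(graph, "dbg"))
  if (cov_cutoff <= 0 || nrow(graph$edges) == 0L) return(graph)
  k <- graph$k
  repeat {
    n_before <- nrow(graph$edges)
    ug <- condense(graph)
    u <- ug$unitigs
    if (nrow(u)) {
      has_in <- u$id %in% ug$links$to
      has_out <- u$id %in% ug$links$from
      n_edges <- nchar(u$seq) - k + 1L
      tip <- xor(has_in, has_out) & n_edges <= tip_max_len & u$cov < cov_cutoff
      if (any(tip)) {
        drop_kmers <- extract_kmers(u$seq[tip], k)$kmer
        graph$edges <- graph$edges[!kmer %in% drop_kmers]
      }
    }
    e <- graph$edges
    if (nrow(e)) {
      pre <- substr(e$kmer, 1L, k - 1L)
      suf <- substr(e$kmer, 2L, k)
      max_out <- stats::ave(e$count, pre, FUN = max)
      max_in <- stats::ave(e$count, suf, FUN = max)
      weak <- e$count < cov_cutoff & (e$count < max_out | e$count < max_in)
      if (any(weak)) graph$edges <- e[!weak]
    }
    if (nrow(graph$edges) == n_before) break
  }
  graph
}

#' Condense a graph to unitigs
#'
#' Every maximal non-branching path of k-mer edges becomes one unitig whose
#' sequence spells the path; nodes with in- or out-degree other than 1
#' become unitig boundaries. Condensation is idempotent: applying
#' \code{condense} to a \code{unitig_graph} merges any remaining
#' single-in/single-out links (a no-op on its own output).
#'
#' @param graph a \code{dbg} or \code{unitig_graph}.
#' @return a \code{unitig_graph}: list(k, unitigs = data.table(id, seq,
#'   cov), links = data.table(from, to), strand_specific).
#' @export
condense <- function(graph) UseMethod("condense")

#' @export
condense.dbg <- function(graph) {
  k <- graph$k
  e <- graph$edges
  if (nrow(e) == 0L) {
    return(new_unitig_graph(k, data.table::data.table(id = character(),
                                                      seq = character(),
                                                      cov = numeric()),
                            data.table::data.table(from = character(),
                                                   to = character()),
                            graph$strand_specific))
  }
  kmer <- e$kmer; count <- e$count
  n <- length(kmer)
  pre <- substr(kmer, 1L, k - 1L)
  suf <- substr(kmer, 2L, k)
  nodes <- unique(c(pre, suf))
  pre_i <- match(pre, nodes); suf_i <- match(suf, nodes)
  outdeg <- tabulate(pre_i, length(nodes))
  indeg <- tabulate(suf_i, length(nodes))
  # unique out-edge index per node (valid only where outdeg == 1)
  out_edge <- integer(length(nodes))
  out_edge[pre_i] <- seq_len(n)
  # succ[i]: next edge in the same unitig, NA at boundaries
  thru <- outdeg[suf_i] == 1L & indeg[suf_i] == 1L
  succ <- ifelse(thru, out_edge[suf_i], NA_integer_)
  has_pred <- logical(n)
  has_pred[succ[!is.na(succ)]] <- TRUE
  visited <- logical(n)
  starts <- which(!has_pred)
  chains <- vector("list", n); nc <- 0L
  walk <- function(s) {
    idx <- integer(0)
    i <- s
    while (!is.na(i) && !visited[i]) {
      visited[i] <<- TRUE
      idx[length(idx) + 1L] <- i
      i <- succ[i]
    }
    idx
  }
  for (s in starts) {
    if (visited[s]) next
    nc <- nc + 1L
    chains[[nc]] <- walk(s)
  }
  # leftover pure cycles: break each at its lexicographically smallest k-mer
  if (!all(visited)) {
    left <- which(!visited)
    left <- left[order(kmer[left])]
    for (s in left) {
      if (visited[s]) next
      nc <- nc + 1L
      chains[[nc]] <- walk(s)
    }
  }
  chains <- chains[seq_len(nc)]
  useq <- vapply(chains, function(idx) {
    if (length(idx) == 1L) return(kmer[idx])
    paste0(kmer[idx[1L]],
           paste(substr(kmer[idx[-1L]], k, k), collapse = ""))
  }, "")
  ucov <- vapply(chains, function(idx) mean(count[idx]), 0)
  ord <- order(useq)
  chains <- chains[ord]; useq <- useq[ord]; ucov <- ucov[ord]
  ids <- sprintf("utg%06d", seq_along(chains))
  start_node <- vapply(chains, function(idx) pre[idx[1L]], "")
  end_node <- vapply(chains, function(idx) suf[idx[length(idx)]], "")
  lk <- data.table::data.table(end_node = end_node, from = ids)[
    data.table::data.table(start_node = start_node, to = ids),
    on = c(end_node = "start_node"), nomatch = NULL, allow.cartesian = TRUE]
  links <- lk[, c("from", "to")]
  data.table::setorder(links, from, to)
  new_unitig_graph(k, data.table::data.table(id = ids, seq = useq, cov = ucov),
                   links, graph$strand_specific)
}

#' @export
condense.unitig_graph <- function(graph) {
  g <- graph
  repeat {
    u <- g$unitigs; l <- g$links
    if (!nrow(l)) return(g)
    outdeg <- table(l$from); indeg <- table(l$to)
    merge_l <- l[outdeg[l$from] == 1L & indeg[l$to] == 1L & l$from != l$to]
    if (!nrow(merge_l)) return(g)
    ml <- merge_l[1L]
    i <- match(ml$from, u$id); j <- match(ml$to, u$id)
    ni <- nchar(u$seq[i]) - g$k + 1L; nj <- nchar(u$seq[j]) - g$k + 1L
    merged_seq <- paste0(u$seq[i], substring(u$seq[j], g$k))
    merged_cov <- (u$cov[i] * ni + u$cov[j] * nj) / (ni + nj)
    u$seq[i] <- merged_seq; u$cov[i] <- merged_cov
    l$from[l$from == ml$to] <- ml$from
    l <- l[!(l$from == ml$from & l$to == ml$to)]
    u <- u[-j]
    g <- new_unitig_graph(g$k, u, l, g$strand_specific)
  }
}

new_unitig_graph <- function(k, unitigs, links, strand_specific = TRUE) {
  structure(list(k = k, unitigs = unitigs, links = links,
                 strand_specific = strand_specific),
            class = "unitig_graph")
}

#' @export
print.unitig_graph <- function(x, ...) {
  cat(sprintf("Unitig graph: k=%d, %d unitigs (%d bp), %d links\n",
              x$k, nrow(x$unitigs), sum(nchar(x$unitigs$seq)), nrow(x$links)))
  invisible(x)
}

#' Graph summary statistics
#'
#' @param graph a \code{unitig_graph}.
#' @return one-row data.frame: unitigs, links, total bp, mean coverage.
#' @export
graph_stats <- function(graph) {
  stopifnot(inherits(graph, "unitig_graph"))
  data.frame(n_unitigs = nrow(graph$unitigs),
             n_links = nrow(graph$links),
             total_bp = sum(nchar(graph$unitigs$seq)),
             mean_cov = if (nrow(graph$unitigs)) mean(graph$unitigs$cov) else NA_real_)
}
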