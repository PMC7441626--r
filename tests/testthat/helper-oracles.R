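# Independent brute-force oracles used to pin expected values.
# These deliberately avoid the package's own code paths.

# Naive k-mer counting: character windows via substr in a plain loop.
oracle_kmer_counts <- function(seqs, k, min_count = 1L) {
  all <- character()
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) all <- c(all, substr(s, i, i + k - 1L))
  }
  all <- all[!grepl("N", all, fixed = TRUE)]
  tb <- table(all)
  tb[tb >= min_count]
}

# Naive condensation: start from single-edge unitigs and repeatedly merge
# the unique pair across any node with in-degree 1 and out-degree 1.
oracle_condense <- function(kmers, k) {
  units <- as.list(kmers)   # each unitig is a sequence
  repeat {
    pre <- vapply(units, function(s) substr(s, 1L, k - 2L + 1L), "")
    suf <- vapply(units, function(s) substr(s, nchar(s) - k + 2L, nchar(s)), "")
    merged <- FALSE
    for (i in seq_along(units)) {
      node <- suf[i]
      outs <- which(pre == node)
      ins <- which(suf == node)
      if (length(outs) == 1L && length(ins) == 1L && outs != ins) {
        j <- outs
        units[[ins]] <- paste0(units[[ins]], substring(units[[j]], k))
        units[[j]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  sort(unlist(units))
}

# Best adapter similarity in a window: minimum Levenshtein distance of the
# whole adapter against any window substring (utils::adist), as a fraction
# of the adapter length. Detection mirrors the inclusive integer rule.
oracle_adapter_sim <- function(adapter, window) {
  la <- nchar(adapter); wn <- nchar(window)
  if (wn == 0L) return(0)
  subs <- character()
  for (i in seq_len(wn)) {
    js <- i:min(wn, i + 2L * la)
    subs <- c(subs, substring(window, i, js))
  }
  1 - min(utils::adist(adapter, unique(subs))) / la
}

oracle_adapter_detected <- function(adapter, window, min_sim = 0.70) {
  la <- nchar(adapter)
  best_e <- la - round(oracle_adapter_sim(adapter, window) * la)
  best_e <= floor(la * (1 - min_sim) + 1e-9)
}

# Full-length decision oracle mirroring the both-strands / both-adapters
# rule with the same terminal windows as the implementation.
oracle_fl_decision <- function(seq, adapter5, adapter3, min_sim = 0.70,
                               window_factor = 1.5) {
  la5 <- nchar(adapter5); la3 <- nchar(adapter3)
  if (nchar(seq) < la5 + la3) return(FALSE)
  both <- function(s) {
    n <- nchar(s)
    w5 <- substr(s, 1L, min(n, round(window_factor * la5)))
    w3 <- substr(s, n - min(n, round(window_factor * la3)) + 1L, n)
    oracle_adapter_detected(adapter5, w5, min_sim) &&
      oracle_adapter_detected(adapter3, w3, min_sim)
  }
  both(seq) || both(rc_seq(seq))
}

# Exhaustive N50: the largest length L in the multiset such that sequences
# of length >= L hold at least half the total bases.
oracle_n50 <- function(lengths) {
  tot <- sum(lengths)
  ok <- vapply(sort(unique(lengths)), function(L)
    sum(lengths[lengths >= L]) >= tot / 2, TRUE)
  max(sort(unique(lengths))[ok])
}

# Exhaustive path enumeration oracle for threading: the path (up to
# max_len unitigs) whose spelling has the smallest edit distance to the
# read.
oracle_best_path <- function(read, graph, max_len = 4L) {
  ids <- graph$unitigs$id
  adj <- split(graph$links$to, graph$links$from)
  paths <- lapply(ids, function(i) i)
  all_paths <- paths
  for (d in seq_len(max_len - 1L)) {
    nxt <- list()
    for (p in paths) {
      for (v in adj[[p[length(p)]]]) nxt[[length(nxt) + 1L]] <- c(p, v)
    }
    if (!length(nxt)) break
    all_paths <- c(all_paths, nxt)
    paths <- nxt
  }
  spell <- vapply(all_paths, function(p) spell_path(p, graph), "")
  d <- as.vector(utils::adist(read, spell))
  all_paths[[which.min(d)]]
}

# Apply exactly e edits (substitutions) to a sequence at distinct positions.
mutate_n <- function(seq, e, positions = NULL) {
  if (e == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  if (is.null(positions)) positions <- sample(length(ch), e)
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
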