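# Shared in-code fixtures.

# A hand-built bubble unitig graph: head H -> {A | B} -> tail T, k = 5.
# Unitig sequences are constructed so that every link shares a real
# (k-1)-mer overlap.
bubble_graph <- function(k = 5L, seed = 99L) {
  set.seed(seed)
  core <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  h <- core(40)
  ov <- substr(h, 41 - (k - 1L), 40)           # head/branch overlap
  a <- paste0(ov, core(30))
  b <- paste0(ov, core(30))
  ova <- substr(a, nchar(a) - k + 2L, nchar(a))
  ovb <- substr(b, nchar(b) - k + 2L, nchar(b))
  t_core <- core(40)
  # both branches must flow into the same tail start node; rebuild branch
  # tails so they end with a common (k-1)-mer
  common <- core(k - 1L)
  a <- paste0(substr(a, 1L, nchar(a) - (k - 1L)), common)
  b <- paste0(substr(b, 1L, nchar(b) - (k - 1L)), common)
  tl <- paste0(common, t_core)
  u <- data.table::data.table(
    id = c("H", "A", "B", "T"),
    seq = c(h, a, b, tl),
    cov = c(40, 20, 20, 40))
  l <- data.table::data.table(from = c("H", "H", "A", "B"),
                              to = c("A", "B", "T", "T"))
  isoweave:::new_unitig_graph(k, u, l, TRUE)
}

# Alignment records as produced by thread_long_reads.
aln <- function(path, fl = FALSE, id = "r") {
  list(read_id = id, path = path, aligned_fraction = 1,
       is_full_length = fl, strand = "+")
}

# Error-free toy reads for the packaged two-isoform gene.
toy_reads <- function(seed = 42L, depth = 30) {
  tx <- simulate_toy_gene(seed = seed)
  cfg <- sim_config(seed = seed, short_depth = depth, short_subst_rate = 0,
                    long_depth = 0, long_error_rate = 0, fl_fraction = 1)
  sr <- simulate_short_reads(tx, cfg)
  lr <- seq_tbl(c("fl1", "fl2"),
                paste0(DEFAULT_ADAPTER5, tx$isoforms$seq, DEFAULT_ADAPTER3),
                strrep("I", nchar(tx$isoforms$seq) + 48L))
  list(tx = tx, sr = sr, lr = lr)
}
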