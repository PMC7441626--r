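test_that("build_graph enumerates k-mers with multiplicity thresholds", {
  g <- build_graph(seq_tbl("r1", "ACGTT"), k = 3L, min_count = 1L)
  expect_setequal(g$edges$kmer, c("ACG", "CGT", "GTT"))
  expect_true(all(g$edges$count == 1L))

  g2 <- build_graph(seq_tbl("r1", "ACGTT"), k = 3L, min_count = 2L)
  expect_equal(nrow(g2$edges), 0L)

  g3 <- build_graph(seq_tbl(c("a", "b"), c("ACGTT", "ACGTT")), k = 3L,
                    min_count = 2L)
  expect_true(all(g3$edges$count == 2L))

  # k-mers containing N are skipped
  gn <- build_graph(seq_tbl("r1", "ACNGT"), k = 3L, min_count = 1L)
  expect_equal(nrow(gn$edges), 0L)

  expect_warning(build_graph(seq_tbl("r1", "ACG"), k = 5L), "empty")
  expect_error(build_graph(seq_tbl("r1", "ACGTT"), k = 4L), "odd")
})

test_that("strand-specific paired-end input is oriented to the sense strand", {
  iso <- random_seq(60)
  r2 <- substr(iso, 1, 30)            # sense mate
  r1 <- rc_seq(substr(iso, 31, 60))   # antisense mate (dUTP)
  g <- build_graph(list(seq_tbl("p/1", r1), seq_tbl("p/2", r2)),
                   k = 7L, min_count = 1L, orientation = "rf")
  expected <- oracle_kmer_counts(c(substr(iso, 1, 30), substr(iso, 31, 60)), 7L)
  expect_setequal(g$edges$kmer, names(expected))
})

test_that("non-stranded mode inserts both strands", {
  g <- build_graph(seq_tbl("r", "ACGTTG"), k = 5L, min_count = 1L,
                   strand_specific = FALSE)
  expect_true(all(c("ACGTT", rc_seq("ACGTT")) %in% g$edges$kmer))
})

test_that("condense spells maximal non-branching paths", {
  # chain ACG -> CGT -> GTT over k = 4 edges {ACGT, CGTT}
  dbg <- structure(list(k = 4L,
                        edges = data.table::data.table(
                          kmer = c("ACGT", "CGTT"), count = c(1L, 1L)),
                        strand_specific = TRUE), class = "dbg")
  ug <- condense(dbg)
  expect_equal(ug$unitigs$seq, "ACGTT")
  expect_equal(nrow(ug$links), 0L)

  # out-degree 2 at a node makes a boundary: two distinct branch unitigs
  g2 <- build_graph(seq_tbl(c("a", "b"), c("AACGTA", "AACGTC")), k = 5L,
                    min_count = 1L)
  u2 <- condense(g2)
  expect_equal(nrow(u2$unitigs), 3L)
  expect_equal(nrow(u2$links), 2L)
  expect_setequal(spell_path("utg000001", u2),
                  u2$unitigs$seq[1])

  # idempotence
  expect_equal(condense(u2)$unitigs$seq, u2$unitigs$seq)
})

test_that("an error-free transcript with unique (k-1)-mers condenses to itself", {
  set.seed(11)
  for (i in 1:10) {
    s <- random_seq(150)
    k <- sample(c(15L, 17L, 21L), 1)
    km <- substring(s, 1:(nchar(s) - k + 2L), (k - 1L):nchar(s))
    if (anyDuplicated(km)) next
    ug <- condense(build_graph(seq_tbl("t", s), k = k, min_count = 1L))
    expect_equal(ug$unitigs$seq, s)
  }
})

test_that("condensation agrees with the naive oracle on random strings", {
  set.seed(21)
  for (i in 1:30) {
    s <- random_seq(sample(30:200, 1))
    for (k in c(5L, 7L, 9L)) {
      kc <- oracle_kmer_counts(s, k)
      ug <- condense(build_graph(seq_tbl("x", s), k = k, min_count = 1L))
      expect_setequal(ug$unitigs$seq, oracle_condense(names(kc), k))
      # the unitig k-mer multiset equals the edge multiset support
      spelled <- unlist(lapply(ug$unitigs$seq, function(u)
        substring(u, 1:(nchar(u) - k + 1L), k:nchar(u))))
      expect_setequal(spelled, names(kc))
      expect_equal(anyDuplicated(spelled), 0L)
    }
  }
})

test_that("simplify_graph clips low-coverage tips and keeps the backbone", {
  s <- random_seq(40)
  k <- 7L
  path_kmers <- substring(s, 1:(40 - k + 1L), k:40)
  # a 1-edge tip branching off the middle node with a different last base
  mid <- path_kmers[20]
  tip <- paste0(substr(mid, 1, k - 1L),
                setdiff(c("A", "C", "G", "T"), substr(mid, k, k))[1])
  dbg <- structure(list(k = k,
                        edges = data.table::data.table(
                          kmer = c(path_kmers, tip),
                          count = c(rep(10L, length(path_kmers)), 1L)),
                        strand_specific = TRUE), class = "dbg")
  data.table::setorder(dbg$edges, kmer)
  out <- simplify_graph(dbg, tip_max_len = 5L, cov_cutoff = 2)
  expect_setequal(out$edges$kmer, path_kmers)
  expect_equal(condense(out)$unitigs$seq, s)

  # a tip-free graph is a fixpoint; cov_cutoff = 0 disables cleanup
  clean <- structure(list(k = k,
                          edges = data.table::data.table(kmer = path_kmers,
                                                         count = 10L),
                          strand_specific = TRUE), class = "dbg")
  expect_equal(simplify_graph(clean, cov_cutoff = 2)$edges$kmer,
               clean$edges$kmer)
  expect_equal(simplify_graph(dbg, cov_cutoff = 0)$edges, dbg$edges)
})

test_that("graph_stats summarises a unitig graph", {
  g <- bubble_graph()
  st <- graph_stats(g)
  expect_equal(st$n_unitigs, 4L)
  expect_equal(st$n_links, 4L)
  expect_equal(st$total_bp, sum(nchar(g$unitigs$seq)))
})
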