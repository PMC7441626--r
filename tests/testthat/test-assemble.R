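test_that("spell_path emits each link overlap once", {
  g <- isoweave:::new_unitig_graph(
    4L, data.table::data.table(id = c("u1", "u2"),
                               seq = c("ACGTT", "GTTA"), cov = c(1, 1)),
    data.table::data.table(from = "u1", to = "u2"), TRUE)
  expect_equal(spell_path("u1", g), "ACGTT")
  expect_equal(spell_path(c("u1", "u2"), g), "ACGTTA")
  expect_error(spell_path(character(), g), "empty")
  expect_error(spell_path(c("u2", "u1"), g), "broken link")
  expect_error(spell_path("nope", g), "unknown")
})

test_that("multi-edge extension resolves a bubble into one path per isoform", {
  g <- bubble_graph()
  alns <- list(aln(c("H", "A", "T"), id = "r1"),
               aln(c("H", "B", "T"), id = "r2"))
  paths <- extend_paths(g, alns)
  steps <- lapply(paths, `[[`, "steps")
  expect_length(paths, 2L)
  expect_setequal(vapply(steps, paste, "", collapse = ">"),
                  c("H>A>T", "H>B>T"))
  expect_true(all(vapply(paths, `[[`, 0L, "support") == 1L))

  # without long-read evidence the short-read rule stops at the branch:
  # four single-unitig paths
  sr_paths <- extend_paths(g, list())
  expect_length(sr_paths, 4L)
  expect_true(all(vapply(sr_paths, function(p) length(p$steps), 0L) == 1L))

  # a single-unitig graph yields the single trivial path
  g1 <- isoweave:::new_unitig_graph(
    5L, data.table::data.table(id = "u", seq = random_seq(80), cov = 10),
    data.table::data.table(from = character(), to = character()), TRUE)
  expect_length(extend_paths(g1, list()), 1L)
})

test_that("phase-consistent support does not cross-multiply adjacent bubbles", {
  # two consecutive bubbles; reads phase A with C and B with D
  k <- 5L
  set.seed(12)
  mk <- function(n) random_seq(n)
  ov <- function(s) substr(s, nchar(s) - k + 2L, nchar(s))
  h <- mk(30); co <- mk(k - 1L); co2 <- mk(k - 1L)
  a <- paste0(ov(h), mk(20), co); b <- paste0(ov(h), mk(20), co)
  m <- paste0(co, mk(25), co2)
  cc <- paste0(co2, mk(20)); d <- paste0(co2, mk(20))
  u <- data.table::data.table(id = c("H", "A", "B", "M", "C", "D"),
                              seq = c(h, a, b, m, cc, d),
                              cov = 10)
  l <- data.table::data.table(from = c("H", "H", "A", "B", "M", "M"),
                              to = c("A", "B", "M", "M", "C", "D"))
  g <- isoweave:::new_unitig_graph(k, u, l, TRUE)
  alns <- list(aln(c("H", "A", "M", "C")), aln(c("H", "B", "M", "D")))
  paths <- extend_paths(g, alns)
  keys <- vapply(paths, function(p) paste(p$steps, collapse = ">"), "")
  expect_setequal(keys, c("H>A>M>C", "H>B>M>D"))
})

test_that("full-length paths are injected directly and deduplicated", {
  g <- bubble_graph()
  cand <- extend_paths(g, list())          # singles only
  fl <- list(aln(c("H", "A", "T"), fl = TRUE))
  merged <- inject_full_length_paths(cand, fl, g)
  expect_length(merged, length(cand) + 1L)
  injected <- merged[[length(merged)]]
  expect_true(injected$is_full_length)

  ded <- deduplicate_paths(merged, g)
  # H, A, B, T singles minus those contained... dedup is by sequence, so
  # all 5 distinct spellings remain
  expect_length(ded, 5L)

  # injecting a duplicate changes nothing after dedup
  again <- inject_full_length_paths(merged, fl, g)
  expect_length(deduplicate_paths(again, g), 5L)
  # empty FL set is the identity
  expect_identical(inject_full_length_paths(cand, list(), g), cand)
})

test_that("deduplication keys on spelled sequence and respects strand mode", {
  g <- bubble_graph()
  p1 <- graph_path(c("H", "A", "T"), support = 3L)
  p2 <- graph_path(c("H", "A", "T"), support = 1L, is_full_length = TRUE)
  ded <- deduplicate_paths(list(p1, p2), g)
  expect_length(ded, 1L)
  expect_equal(ded[[1]]$support, 3L)       # highest support survives
  expect_true(ded[[1]]$is_full_length)     # FL flag is inherited from group

  # distinct isoform paths sharing head/tail both survive
  ded2 <- deduplicate_paths(list(graph_path(c("H", "A", "T")),
                                 graph_path(c("H", "B", "T"))), g)
  expect_length(ded2, 2L)

  # strand-specific: a sequence and its reverse complement are distinct
  s <- random_seq(60)
  gss <- isoweave:::new_unitig_graph(
    5L, data.table::data.table(id = c("f", "r"), seq = c(s, rc_seq(s)),
                               cov = 1),
    data.table::data.table(from = character(), to = character()), TRUE)
  expect_length(deduplicate_paths(list(graph_path("f"), graph_path("r")),
                                  gss), 2L)
  gns <- isoweave:::new_unitig_graph(
    5L, gss$unitigs, gss$links, strand_specific = FALSE)
  expect_length(deduplicate_paths(list(graph_path("f"), graph_path("r")),
                                  gns), 1L)
})

test_that("hybrid assembly of the packaged toy recovers both isoforms exactly", {
  toy <- toy_reads()
  cfg <- assembly_config(seed = 1L)
  ts <- run_assembly(toy$sr$r1, toy$sr$r2, toy$lr, config = cfg)
  expect_setequal(ts$seq, toy$tx$isoforms$seq)
  expect_true(all(ts$is_full_length))

  # short-read-only mode recovers at most one full isoform
  sr_ts <- run_assembly(toy$sr$r1, toy$sr$r2, NULL, config = cfg)
  expect_lte(sum(sr_ts$seq %in% toy$tx$isoforms$seq), 1L)
})

test_that("adding full-length reads never removes a recovered true isoform", {
  toy <- toy_reads()
  cfg <- assembly_config(seed = 1L)
  both <- assemble_both(toy$sr$r1, toy$sr$r2, toy$lr, config = cfg)
  sr_true <- intersect(both$sr_only$seq, toy$tx$isoforms$seq)
  expect_true(all(sr_true %in% both$hybrid$seq))
})

test_that("every output transcript re-walks as a valid path; no duplicates", {
  toy <- toy_reads()
  ts <- run_assembly(toy$sr$r1, toy$sr$r2, toy$lr,
                     config = assembly_config(seed = 1L))
  g <- attr(ts, "graph")
  for (i in seq_len(nrow(ts))) {
    steps <- strsplit(ts$path[i], ",", fixed = TRUE)[[1]]
    expect_equal(spell_path(steps, g), ts$seq[i])
  }
  expect_equal(anyDuplicated(ts$seq), 0L)
})

test_that("identical inputs and config give byte-identical FASTA", {
  toy <- toy_reads()
  cfg <- assembly_config(seed = 7L)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_transcripts(run_assembly(toy$sr$r1, toy$sr$r2, toy$lr, config = cfg), f1)
  write_transcripts(run_assembly(toy$sr$r1, toy$sr$r2, toy$lr, config = cfg), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("an over-filtered graph yields an empty set with a warning", {
  toy <- toy_reads()
  cfg <- assembly_config(min_count = 10000L, seed = 1L)
  expect_warning(ts <- run_assembly(toy$sr$r1, toy$sr$r2, NULL, config = cfg))
  expect_equal(nrow(ts), 0L)
})
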