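test_that("simulators are pure functions of (inputs, seed)", {
  a <- make_transcriptome(n_genes = 3L, seed = 5L)
  b <- make_transcriptome(n_genes = 3L, seed = 5L)
  expect_identical(a$isoforms$seq, b$isoforms$seq)
  expect_identical(a$genes$gseq, b$genes$gseq)

  cfg <- sim_config(seed = 5L, short_depth = 5)
  expect_identical(simulate_short_reads(a, cfg)$r1$seq,
                   simulate_short_reads(a, cfg)$r1$seq)
  expect_identical(simulate_long_reads(a, cfg)$reads$seq,
                   simulate_long_reads(a, cfg)$reads$seq)
})

test_that("the toy gene's isoforms differ by exactly the skipped exon", {
  tx <- simulate_toy_gene(skip_len = 120L)
  lens <- nchar(tx$isoforms$seq)
  expect_equal(lens[1] - lens[2], 120L)
  # the skipped-exon isoform is head + tail of the primary
  expect_true(startsWith(tx$isoforms$seq[1],
                         substr(tx$isoforms$seq[2], 1, 350)))
})

test_that("intron retention isoforms contain the retained intron", {
  tx <- make_transcriptome(n_genes = 4L, isoforms_per_gene = c(2L, 2L),
                           event_mix = c(intron_retention = 1), seed = 3L)
  iso <- tx$isoforms
  for (g in unique(iso$gene_id)) {
    sub <- iso[iso$gene_id == g, ]
    alt <- sub[sub$event == "intron_retention", ]
    pri <- sub[sub$event == "primary", ]
    expect_gt(nchar(alt$seq[1]), nchar(pri$seq[1]))
    # locate the merged exon pair and the retained intron between them
    pe <- pri$exons[[1]]; ae <- alt$exons[[1]]
    expect_equal(nrow(ae), nrow(pe) - 1L)
    i <- which(!(pe[, 2] %in% c(ae[, 2], NA)))[1]  # first exon end lost
    gseq <- tx$genes$gseq[tx$genes$gene_id == g]
    intron <- substr(gseq, pe[i, 2] + 1L, pe[i + 1L, 1])
    expect_true(grepl(intron, alt$seq[1], fixed = TRUE))
    expect_false(grepl(intron, pri$seq[1], fixed = TRUE))
  }
})

test_that("infeasible event configurations raise config errors", {
  expect_error(make_transcriptome(n_genes = 1L, exon_count = c(1L, 1L),
                                  isoforms_per_gene = c(2L, 2L), seed = 1L),
               "infeasible")
  expect_error(make_transcriptome(n_genes = 1L, exon_count = c(2L, 2L),
                                  isoforms_per_gene = c(2L, 2L),
                                  event_mix = c(exon_skip = 1), seed = 1L),
               "infeasible")
  expect_error(sim_config(insert_mean = 100, short_read_length = 150),
               "insert_mean")
  expect_error(sim_config(short_subst_rate = 1.5), "rates")
})

test_that("error-free short reads are exact oriented isoform substrings", {
  tx <- make_transcriptome(n_genes = 2L, seed = 9L)
  cfg <- sim_config(seed = 9L, short_depth = 3, short_subst_rate = 0)
  sr <- simulate_short_reads(tx, cfg)
  isos <- tx$isoforms$seq
  in_iso <- function(s) any(grepl(s, isos, fixed = TRUE))
  # dUTP convention: mate 1 antisense, mate 2 sense
  expect_true(all(vapply(sr$r2$seq[1:25], in_iso, TRUE)))
  expect_true(all(vapply(rc_seq(sr$r1$seq[1:25]), in_iso, TRUE)))
  expect_false(any(vapply(sr$r1$seq[1:25], in_iso, TRUE)))
})

test_that("pair count follows depth x bp / (2 x read length)", {
  tx <- make_transcriptome(n_genes = 5L, seed = 2L)
  total <- sum(nchar(tx$isoforms$seq))
  cfg <- sim_config(seed = 2L, short_depth = 10, short_read_length = 100L,
                    insert_mean = 250L)
  sr <- simulate_short_reads(tx, cfg)
  expect_equal(nrow(sr$r1), round(10 * total / 200))
  expect_equal(nrow(sr$r1), nrow(sr$r2))
})

test_that("full-length long reads carry both adapters, truncated reads one", {
  tx <- make_transcriptome(n_genes = 2L, seed = 4L)
  cfg <- sim_config(seed = 4L, long_depth = 1, long_error_rate = 0,
                    fl_fraction = 1)
  lr <- simulate_long_reads(tx, cfg)
  expect_true(all(lr$truth$is_full_length))
  expect_true(all(startsWith(lr$reads$seq, cfg$adapter5)))
  expect_true(all(endsWith(lr$reads$seq, cfg$adapter3)))
  iso_of <- tx$isoforms$seq[match(lr$truth$isoform_id, tx$isoforms$isoform_id)]
  expect_identical(lr$reads$seq,
                   paste0(cfg$adapter5, iso_of, cfg$adapter3))

  cfg0 <- sim_config(seed = 4L, long_depth = 1, long_error_rate = 0,
                     fl_fraction = 0)
  lr0 <- simulate_long_reads(tx, cfg0)
  has5 <- startsWith(lr0$reads$seq, cfg0$adapter5)
  has3 <- endsWith(lr0$reads$seq, cfg0$adapter3)
  expect_true(all(xor(has5, has3)))
  det <- vapply(lr0$reads$seq, function(s)
    detect_full_length(s, fl_params())$is_full_length, TRUE)
  expect_false(any(det))
})

test_that("empirical error rates match configuration within 3 SE", {
  tx <- make_transcriptome(n_genes = 10L, seed = 6L)
  cfg <- sim_config(seed = 6L, short_depth = 8, short_subst_rate = 0.01)
  sr <- simulate_short_reads(tx, cfg)
  reads <- c(rc_seq(sr$r1$seq), sr$r2$seq)
  truth <- simulate_short_reads(tx, sim_config(seed = 6L, short_depth = 8,
                                               short_subst_rate = 0))
  clean <- c(rc_seq(truth$r1$seq), truth$r2$seq)
  # same seed stream => same fragments; mismatches are the injected errors
  expect_equal(nchar(reads), nchar(clean))
  nb <- sum(nchar(reads))
  expect_gt(nb, 1e5)
  mism <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, reads, clean))
  rate <- mism / nb
  se <- sqrt(0.01 * 0.99 / nb)
  expect_lt(abs(rate - 0.01), 3 * se)

  cfgl <- sim_config(seed = 6L, long_depth = 2, long_error_rate = 0.08,
                     fl_fraction = 1)
  lr <- simulate_long_reads(tx, cfgl)
  clean_lr <- paste0(cfgl$adapter5,
                     tx$isoforms$seq[match(lr$truth$isoform_id,
                                           tx$isoforms$isoform_id)],
                     cfgl$adapter3)
  nb <- sum(nchar(clean_lr))
  edits <- sum(mapply(function(a, b) utils::adist(a, b),
                      lr$reads$seq, clean_lr))
  # indels and adjacent substitutions can merge in an optimal alignment,
  # so edit distance slightly undercounts; allow a tolerant band
  expect_gt(edits / nb, 0.06)
  expect_lt(edits / nb, 0.09)
})

test_that("ground truth files are emitted alongside reads", {
  tx <- make_transcriptome(n_genes = 2L, seed = 8L)
  d <- withr::local_tempdir()
  write_truth(tx, d)
  expect_true(file.exists(file.path(d, "truth_isoforms.fasta")))
  tsv <- data.table::fread(file.path(d, "truth_exons.tsv"))
  expect_setequal(unique(tsv$isoform_id), tx$isoforms$isoform_id)
  fa <- read_seqs(file.path(d, "truth_isoforms.fasta"))
  expect_identical(fa$seq, tx$isoforms$seq)
  # exon table spells the isoform sequences (0-based half-open)
  one <- tsv[tsv$isoform_id == tx$isoforms$isoform_id[1], ]
  g <- tx$genes$gseq[tx$genes$gene_id == one$gene_id[1]]
  spelled <- paste(substring(g, one$exon_start + 1L, one$exon_end),
                   collapse = "")
  expect_equal(spelled, tx$isoforms$seq[1])
})
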