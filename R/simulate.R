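# Transcriptome and read simulation with known isoform ground truth.
#
# The generator emulates the data regime of a hybrid (Illumina + nanopore
# cDNA) experiment on a non-model plant: strand-specific 150 bp paired-end
# short reads at high depth and low substitution error, plus low-depth
# (~2x) long cDNA reads averaging several hundred bp, indel-dominated
# errors around 10%, ~93% of which span their source transcript end to end
# and carry both library adapters. Expression weights are log-normal so
# that lowly expressed isoforms -- the classic short-read failure mode --
# are present by construction.

#' Default 5' library adapter (synthetic 24-mer)
#' @export
DEFAULT_ADAPTER5 <- "ATCGCTACGTTGACCAGTCGAGCA"

#' Default 3' library adapter (synthetic 24-mer)
#' @export
DEFAULT_ADAPTER3 <- "TGGACGTCAATGCGATTACGCTGA"

# Derive a module-specific RNG stream from the run seed, keeping the result
# a valid 32-bit integer.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1103515245 + h * 1000003) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Read-simulation configuration
#'
#' Defaults reflect the library designs the simulator emulates:
#' strand-specific 150 bp paired-end short reads (dUTP-style: mate 1
#' antisense, mate 2 sense) at 50x with 0.5\% substitutions, and long cDNA
#' reads at 2x with 10\% indel-dominated error, 93\% of which are
#' full-length (both adapters present).
#'
#' @param seed integer RNG seed; every simulator output is a pure function
#'   of (inputs, seed).
#' @param short_read_length read length in bp.
#' @param insert_mean,insert_sd fragment (insert) length distribution, bp.
#' @param short_depth target fold coverage of the transcriptome by short
#'   read pairs.
#' @param short_subst_rate per-base substitution probability in short reads.
#' @param long_depth target fold coverage by long reads.
#' @param long_error_rate total per-base error probability in long reads,
#'   split across mismatch/insertion/deletion by \code{error_split}.
#' @param error_split length-3 non-negative weights (mismatch, insertion,
#'   deletion) summing to 1.
#' @param adapter5,adapter3 library adapter sequences ligated to the 5' and
#'   3' ends of full-length cDNA.
#' @param fl_fraction probability that a long read spans its whole source
#'   transcript (and therefore carries both adapters).
#' @param strand_specific logical; strand-specific libraries.
#' @return a validated \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       short_read_length = 150L,
                       insert_mean = 300L, insert_sd = 30L,
                       short_depth = 50, short_subst_rate = 0.005,
                       long_depth = 2, long_error_rate = 0.10,
                       error_split = c(mismatch = 0.4, insertion = 0.3, deletion = 0.3),
                       adapter5 = DEFAULT_ADAPTER5, adapter3 = DEFAULT_ADAPTER3,
                       fl_fraction = 0.93,
                       strand_specific = TRUE) {
  rates <- c(short_subst_rate, long_error_rate, fl_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (short_read_length <= 0 || short_depth <= 0 || long_depth < 0) {
    stop("lengths and depths must be positive")
  }
  if (insert_mean < short_read_length) {
    stop("insert_mean must be >= short_read_length")
  }
  if (!nzchar(adapter5) || !nzchar(adapter3)) stop("adapters must be non-empty")
  if (length(error_split) != 3L || any(error_split < 0)) {
    stop("error_split must be 3 non-negative weights")
  }
  structure(list(
    seed = as.integer(seed),
    short_read_length = as.integer(short_read_length),
    insert_mean = insert_mean, insert_sd = insert_sd,
    short_depth = short_depth, short_subst_rate = short_subst_rate,
    long_depth = long_depth, long_error_rate = long_error_rate,
    error_split = error_split / sum(error_split),
    adapter5 = normalize_seq(adapter5), adapter3 = normalize_seq(adapter3),
    fl_fraction = fl_fraction, strand_specific = isTRUE(strand_specific)
  ), class = "sim_config")
}

#' Generate a synthetic transcriptome with known isoform structure
#'
#' Each gene gets a random genomic sequence with alternating exons and
#' introns; the primary isoform uses all exons, and each additional isoform
#' differs from the primary by at least one sampled splicing event: exon
#' skipping, intron retention, alternative donor (exon 3' end extended into
#' the downstream intron) or alternative acceptor (exon 5' start moved into
#' the upstream intron). Expression weights are log-normal, normalised to
#' sum to 1 over the transcriptome. Exon coordinates are 0-based half-open
#' on the genomic sequence.
#'
#' @param n_genes number of genes.
#' @param isoforms_per_gene inclusive integer range \code{c(lo, hi)}.
#' @param exon_count inclusive range of exons per gene.
#' @param exon_len,intron_len inclusive bp ranges.
#' @param event_mix non-negative sampling weights over the four event types
#'   (named \code{exon_skip}, \code{intron_retention}, \code{alt_donor},
#'   \code{alt_acceptor}); need not sum to 1.
#' @param seed integer RNG seed.
#' @return a \code{transcriptome} object: list with \code{genes}
#'   (data.table: gene_id, gseq) and \code{isoforms} (data.table: gene_id,
#'   isoform_id, seq, weight, event, exons list-column of 2-col matrices).
#' @export
make_transcriptome <- function(n_genes = 30L,
                               isoforms_per_gene = c(2L, 3L),
                               exon_count = c(3L, 8L),
                               exon_len = c(80L, 300L),
                               intron_len = c(60L, 200L),
                               event_mix = c(exon_skip = 0.15,
                                             intron_retention = 0.35,
                                             alt_donor = 0.25,
                                             alt_acceptor = 0.25),
                               seed = 1L) {
  ev_names <- c("exon_skip", "intron_retention", "alt_donor", "alt_acceptor")
  if (is.null(names(event_mix))) names(event_mix) <- ev_names[seq_along(event_mix)]
  event_mix <- event_mix[ev_names]
  event_mix[is.na(event_mix)] <- 0
  names(event_mix) <- ev_names
  if (any(event_mix < 0) || sum(event_mix) <= 0) {
    stop("event_mix must be non-negative and not all zero")
  }
  rng <- function(r) if (r[1] >= r[2]) r[1] else sample(r[1]:r[2], 1L)
  if (max(isoforms_per_gene) > 1 && max(exon_count) < 2) {
    stop("infeasible config: alternative isoforms need >= 2 exons")
  }
  only <- names(event_mix)[event_mix > 0]
  if (identical(only, "exon_skip") && max(exon_count) < 3) {
    stop("infeasible config: exon_skip needs >= 3 exons")
  }
  with_seed(seed, {
    genes <- vector("list", n_genes)
    isos <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      gid <- sprintf("gene%03d", g)
      ne <- rng(exon_count)
      elens <- sample(exon_len[1]:exon_len[2], ne, replace = TRUE)
      ilens <- if (ne > 1) sample(intron_len[1]:intron_len[2], ne - 1L, replace = TRUE) else integer()
      # exon intervals, 0-based half-open
      starts <- integer(ne); ends <- integer(ne); pos <- 0L
      for (e in seq_len(ne)) {
        starts[e] <- pos; ends[e] <- pos + elens[e]
        pos <- ends[e] + if (e < ne) ilens[e] else 0L
      }
      gseq <- rand_seq(pos)
      primary <- cbind(start = starts, end = ends)
      n_iso <- rng(isoforms_per_gene)
      ex_list <- list(primary)
      ev_list <- "primary"
      tries <- 0L
      while (length(ex_list) < n_iso && tries < 50L) {
        tries <- tries + 1L
        ev <- sample_event(event_mix, ne)
        alt <- apply_splice_event(primary, ev, intron_len)
        if (is.null(alt)) next
        seqs_now <- vapply(c(ex_list, list(alt)), spell_exons, "", gseq = gseq)
        if (anyDuplicated(seqs_now)) next
        ex_list <- c(ex_list, list(alt))
        ev_list <- c(ev_list, ev)
      }
      if (length(ex_list) < n_iso && n_iso > 1 && length(ex_list) == 1L) {
        stop("infeasible config: could not generate an alternative isoform for ",
             gid, " (check event_mix vs exon_count)")
      }
      iso_seqs <- vapply(ex_list, spell_exons, "", gseq = gseq)
      genes[[g]] <- data.table::data.table(gene_id = gid, gseq = gseq)
      isos[[g]] <- data.table::data.table(
        gene_id = gid,
        isoform_id = sprintf("%s.i%d", gid, seq_along(ex_list)),
        seq = iso_seqs,
        event = ev_list,
        exons = ex_list
      )
    }
    isoforms <- data.table::rbindlist(isos)
    w <- stats::rlnorm(nrow(isoforms), meanlog = 0, sdlog = 1)
    isoforms[, "weight" := w / sum(w)]
    structure(list(genes = data.table::rbindlist(genes), isoforms = isoforms),
              class = "transcriptome")
  })
}

spell_exons <- function(exons, gseq) {
  paste(substring(gseq, exons[, 1] + 1L, exons[, 2]), collapse = "")
}

sample_event <- function(event_mix, ne) {
  feas <- c(exon_skip = ne >= 3, intron_retention = ne >= 2,
            alt_donor = ne >= 2, alt_acceptor = ne >= 2)
  w <- event_mix * feas
  if (sum(w) <= 0) stop("infeasible config: no splicing event possible with ",
                        ne, " exon(s)")
  sample(names(w), 1L, prob = w)
}

# Apply one splicing event to a primary exon table; returns NULL when the
# sampled site cannot host the event.
apply_splice_event <- function(exons, event, intron_len) {
  ne <- nrow(exons)
  if (event == "exon_skip") {
    i <- sample(2:(ne - 1L), 1L)
    return(exons[-i, , drop = FALSE])
  }
  i <- sample(seq_len(ne - 1L), 1L)  # intron i sits between exon i and i+1
  ilen <- exons[i + 1L, 1] - exons[i, 2]
  if (event == "intron_retention") {
    merged <- exons
    merged[i, 2] <- merged[i + 1L, 2]
    return(merged[-(i + 1L), , drop = FALSE])
  }
  if (ilen < 20L) return(NULL)
  d <- sample(10:(ilen - 10L), 1L)
  alt <- exons
  if (event == "alt_donor") alt[i, 2] <- alt[i, 2] + d
  else alt[i + 1L, 1] <- alt[i + 1L, 1] - d
  alt
}

#' The packaged two-isoform toy gene
#'
#' One gene whose two isoforms differ by a single skipped internal exon of
#' a configurable length; exon/intron sequences are random under the seed.
#' Small enough for exact end-to-end assembly checks: the error-free
#' short-read graph of either isoform has no repeated (k-1)-mers with
#' overwhelming probability.
#'
#' @param skip_len length of the skipped exon (bp).
#' @param flank_len length of the two flanking exons (bp).
#' @param seed RNG seed.
#' @return a \code{transcriptome} with one gene and two isoforms.
#' @export
simulate_toy_gene <- function(skip_len = 120L, flank_len = 350L, seed = 42L) {
  with_seed(derive_seed(seed, "toy"), {
    e1 <- rand_seq(flank_len); e2 <- rand_seq(skip_len); e3 <- rand_seq(flank_len)
    i1 <- rand_seq(100L); i2 <- rand_seq(100L)
    gseq <- paste0(e1, i1, e2, i2, e3)
    s2 <- flank_len + 100L
    s3 <- s2 + skip_len + 100L
    primary <- cbind(start = c(0L, s2, s3),
                     end = c(flank_len, s2 + skip_len, s3 + flank_len))
    skipped <- primary[-2, , drop = FALSE]
    isoforms <- data.table::data.table(
      gene_id = "gene001",
      isoform_id = c("gene001.i1", "gene001.i2"),
      seq = c(spell_exons(primary, gseq), spell_exons(skipped, gseq)),
      event = c("primary", "exon_skip"),
      exons = list(primary, skipped),
      weight = c(0.5, 0.5)
    )
    structure(list(genes = data.table::data.table(gene_id = "gene001", gseq = gseq),
                   isoforms = isoforms),
              class = "transcriptome")
  })
}

#' Simulate strand-specific paired-end short reads
#'
#' Fragments are drawn from isoforms proportional to weight x length with
#' normal insert sizes; in the dUTP-style convention mate 1 reads the
#' antisense strand and mate 2 the sense strand. Substitution errors are
#' i.i.d. per base. The pair count is
#' \code{round(short_depth * total transcript bp / (2 * read length))}.
#'
#' @param tx a \code{transcriptome}.
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{r1} and \code{r2} \code{\link{seq_tbl}}s and a
#'   \code{truth} data.table (read pair to isoform assignment).
#' @export
simulate_short_reads <- function(tx, config = sim_config()) {
  stopifnot(inherits(tx, "transcriptome"), inherits(config, "sim_config"))
  iso <- tx$isoforms
  L <- config$short_read_length
  lens <- nchar(iso$seq)
  total_bp <- sum(lens)
  n_pairs <- max(1L, round(config$short_depth * total_bp / (2 * L)))
  with_seed(derive_seed(config$seed, "short"), {
    pick <- sample.int(nrow(iso), n_pairs, replace = TRUE, prob = iso$weight * lens)
    ilen <- lens[pick]
    ins <- pmin(pmax(round(stats::rnorm(n_pairs, config$insert_mean, config$insert_sd)), L), ilen)
    # fragments are pieces of a complete cDNA molecule, so they are
    # truncated at the molecule boundaries: the sampling window may
    # overhang either end (keeping >= L bases of overlap) and is clamped,
    # which gives transcript termini the fragment-end density a physical
    # fragmentation produces
    slack <- pmax(0L, ins - L)
    raw <- floor(stats::runif(n_pairs) * (ilen - ins + 2 * slack + 1)) - slack
    start <- pmax(0L, raw)
    fend <- pmin(ilen, raw + ins)
    ins <- fend - start
    frag <- substring(iso$seq[pick], start + 1L, fend)
    r2 <- substring(frag, 1L, pmin(L, ins))            # sense
    r1 <- rc_seq(substring(frag, pmax(1L, ins - L + 1L), ins))  # antisense
    r1 <- add_substitutions(r1, config$short_subst_rate)
    r2 <- add_substitutions(r2, config$short_subst_rate)
    ids <- sprintf("sr%07d", seq_len(n_pairs))
    q1 <- strrep("I", nchar(r1)); q2 <- strrep("I", nchar(r2))
    list(
      r1 = seq_tbl(paste0(ids, "/1"), r1, q1),
      r2 = seq_tbl(paste0(ids, "/2"), r2, q2),
      truth = data.table::data.table(pair_id = ids, isoform_id = iso$isoform_id[pick],
                                     start = start, insert = ins)
    )
  })
}

# i.i.d. substitutions; each error replaces the base by one of the other 3.
add_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1L)
    }
  }
  seqs
}

#' Simulate long cDNA reads with adapters
#'
#' With probability \code{fl_fraction} a read spans its whole source
#' transcript and is flanked by both adapters
#' (\code{adapter5 + transcript + adapter3}); otherwise it is truncated at
#' a uniform point from the 5' or the 3' end (equal odds) and loses the
#' corresponding adapter. Errors are applied at \code{long_error_rate},
#' split across mismatch/insertion/deletion by \code{error_split}
#' (adapters included). Reads are drawn until the cumulative source bases
#' reach \code{long_depth x total transcript bp}.
#'
#' @param tx a \code{transcriptome}.
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{reads} (\code{\link{seq_tbl}}) and \code{truth}
#'   (data.table: read_id, isoform_id, is_full_length, trunc_end).
#' @export
simulate_long_reads <- function(tx, config = sim_config()) {
  stopifnot(inherits(tx, "transcriptome"), inherits(config, "sim_config"))
  iso <- tx$isoforms
  lens <- nchar(iso$seq)
  target <- config$long_depth * sum(lens)
  with_seed(derive_seed(config$seed, "long"), {
    picks <- integer(); fl <- logical(); cores <- character(); ends <- character()
    got <- 0
    while (got < target) {
      i <- sample.int(nrow(iso), 1L, prob = iso$weight * lens)
      isfl <- stats::runif(1) < config$fl_fraction
      s <- iso$seq[i]
      if (isfl) {
        core <- s; trunc_end <- "none"
      } else {
        lo <- min(30L, nchar(s))
        keep <- max(lo, floor(stats::runif(1) * nchar(s)) + 1L)
        if (stats::runif(1) < 0.5) {  # truncated at the 5' end
          core <- substring(s, nchar(s) - keep + 1L); trunc_end <- "5p"
        } else {
          core <- substring(s, 1L, keep); trunc_end <- "3p"
        }
      }
      picks <- c(picks, i); fl <- c(fl, isfl); cores <- c(cores, core)
      ends <- c(ends, trunc_end)
      got <- got + nchar(core)
    }
    raw <- ifelse(fl, paste0(config$adapter5, cores, config$adapter3),
                  ifelse(ends == "5p", paste0(cores, config$adapter3),
                         paste0(config$adapter5, cores)))
    reads <- vapply(raw, add_indel_errors, "",
                    rate = config$long_error_rate, split = config$error_split,
                    USE.NAMES = FALSE)
    ids <- sprintf("lr%06d", seq_along(reads))
    list(
      reads = seq_tbl(ids, reads, strrep("I", nchar(reads))),
      truth = data.table::data.table(read_id = ids,
                                     isoform_id = iso$isoform_id[picks],
                                     is_full_length = fl, trunc_end = ends)
    )
  })
}

# Mismatch/insertion/deletion errors at per-base rate `rate`, with the
# three event types hit in proportion `split`.
add_indel_errors <- function(seq, rate, split = c(0.4, 0.3, 0.3)) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  u <- stats::runif(n)
  t1 <- rate * split[1]; t2 <- t1 + rate * split[2]; t3 <- t2 + rate * split[3]
  mm <- u < t1
  ins <- u >= t1 & u < t2
  del <- u >= t2 & u < t3
  bases <- c("A", "C", "G", "T")
  if (any(mm)) {
    old <- match(ch[mm], bases)
    old[is.na(old)] <- sample.int(4L, sum(is.na(old)), replace = TRUE)
    ch[mm] <- bases[((old - 1L + sample.int(3L, sum(mm), replace = TRUE)) %% 4L) + 1L]
  }
  if (any(ins)) {
    ch[ins] <- paste0(ch[ins], sample(bases, sum(ins), replace = TRUE))
  }
  if (any(del)) ch[del] <- ""
  paste(ch, collapse = "")
}

#' Write simulation ground truth to disk
#'
#' Emits the truth isoform FASTA and a TSV exon/weight table (0-based
#' half-open genomic coordinates) next to the reads.
#'
#' @param tx a \code{transcriptome}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_truth <- function(tx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "truth_isoforms.fasta")
  write_seqs(seq_tbl(tx$isoforms$isoform_id, tx$isoforms$seq), fa, "fasta")
  rows <- tx$isoforms[, {
    ex <- exons[[1]]
    list(exon_index = seq_len(nrow(ex)), exon_start = ex[, 1], exon_end = ex[, 2],
         weight = weight[1], event = event[1])
  }, by = c("gene_id", "isoform_id")]
  tsv <- file.path(dir, "truth_exons.tsv")
  data.table::fwrite(rows, tsv, sep = "\t")
  invisible(c(fa, tsv))
}
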