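adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming truncates at the first adapter occurrence", {
  set.seed(10)
  insert <- paste(sample(c("A", "C", "G", "T"), 29, replace = TRUE),
                  collapse = "")
  full <- substr(paste0(insert, adapter, strrep("A", 50)), 1, 50)
  out <- trim_adapter(full, adapter)
  expect_identical(as.character(out), insert)
  # no adapter: unchanged
  clean <- strrep("ACGT", 12)
  expect_identical(as.character(trim_adapter(clean, adapter)), clean)
  # partial terminal adapter prefix (>= 5 nt) is also trimmed
  partial <- paste0(insert, substr(adapter, 1, 7))
  expect_identical(as.character(trim_adapter(partial, adapter)), insert)
  # a 4-nt terminal overlap is below the floor and left alone
  four <- paste0(insert, substr(adapter, 1, 4))
  expect_identical(as.character(trim_adapter(four, adapter)), four)
  # short insert is discarded
  short <- substr(paste0("ACGTACGT", adapter, strrep("A", 50)), 1, 50)
  out <- trim_adapter(short, adapter)
  expect_length(out, 0)
  expect_identical(attr(out, "n_discarded"), 1L)
})

test_that("rRNA depletion removes reads within two mismatches of rRNA", {
  set.seed(11)
  rrna <- synthetic_rrna()
  hit <- substr(rrna[[1]], 101, 130)
  hit2 <- mutate_seq(hit, 2)   # 2 mismatches: still removed
  miss <- mutate_seq(hit, 3)   # 3 mismatches: retained
  out <- filter_rrna(c(hit, hit2, miss), rrna)
  expect_identical(as.character(out), miss)
  expect_identical(attr(out, "n_removed"), 2L)
  expect_error(filter_rrna(c(hit), NULL), "rRNA")
})

test_that("planted contaminants are removed exactly", {
  set.seed(12)
  ts <- selenoprotein_reference()
  rrna <- synthetic_rrna()
  starts <- sample(500, 90)
  clean <- substr(rep(as.character(ts$seqs[[1]]), 90), starts, starts + 29)
  starts2 <- sample(1500, 10)
  cont <- substr(rep(rrna[[2]], 10), starts2, starts2 + 29)
  out <- filter_rrna(c(clean, cont), rrna)
  expect_identical(length(out), 90L)
  expect_identical(attr(out, "n_removed"), 10L)
})

test_that("align_unique reports unique best-stratum hits and drops multimappers", {
  set.seed(13)
  ts <- toy_ts(c(200, 200, 200), id = c("A", "B", "C"),
               gene = c("a", "b", "c"))
  seqs <- as.character(ts$seqs)
  r1 <- substr(seqs[1], 51, 80)
  a <- align_unique(r1, ts)
  expect_identical(nrow(a), 1L)
  expect_identical(a$transcript_id, "A")
  expect_identical(a$pos5, 50L)
  expect_identical(a$mismatches, 0L)
  # same sequence planted in two transcripts: multimapper, dropped
  seqs2 <- seqs
  substr(seqs2[2], 101, 130) <- r1
  ts2 <- transcript_set(seqs2, cbind(ts$anno, sec_codons = ""))
  a2 <- align_unique(r1, ts2)
  expect_identical(nrow(a2), 0L)
  expect_identical(unname(attr(a2, "stats")["n_multi"]), 1L)
  # a 1-mismatch copy elsewhere does not disqualify the exact hit
  # (uniqueness is judged within the minimal-mismatch stratum)
  seqs3 <- seqs
  substr(seqs3[3], 101, 130) <- mutate_seq(r1, 1)
  ts3 <- transcript_set(seqs3, cbind(ts$anno, sec_codons = ""))
  a3 <- align_unique(r1, ts3)
  expect_identical(a3$transcript_id, "A")
})

test_that("align_unique matches the exhaustive Hamming-scan oracle", {
  set.seed(14)
  ts <- toy_ts(rep(80, 5), id = paste0("T", 1:5), gene = paste0("g", 1:5))
  refs <- as.character(ts$seqs)
  reads <- character(500)
  for (i in seq_len(500)) {
    t <- sample(5, 1)
    len <- sample(c(18, 26:36), 1)  # includes reads below the seed length
    p <- sample(nchar(refs[t]) - len + 1, 1)
    r <- substr(refs[t], p, p + len - 1)
    k <- sample(0:3, 1)
    if (k > 0) r <- mutate_seq(r, k)
    reads[i] <- r
  }
  got <- align_unique(reads, ts)
  oracle <- lapply(reads, brute_align, refs = refs)
  keep <- vapply(oracle, function(o) o$hit && o$n_best == 1, TRUE)
  expect_identical(nrow(got), sum(keep))
  exp_df <- data.frame(
    transcript_id = names(refs)[vapply(oracle[keep], `[[`, 0, "tid")],
    pos5 = vapply(oracle[keep], `[[`, 0, "pos"),
    length = nchar(reads[keep]),
    mismatches = vapply(oracle[keep], `[[`, 0, "mm"))
  ord <- order(exp_df$transcript_id, exp_df$pos5, exp_df$length,
               exp_df$mismatches)
  exp_df <- exp_df[ord, ]
  expect_equal(got$transcript_id, exp_df$transcript_id)
  expect_equal(got$pos5, exp_df$pos5)
  expect_equal(got$mismatches, exp_df$mismatches)
  # order invariance
  perm <- sample(length(reads))
  got2 <- align_unique(reads[perm], ts)
  expect_equal(as.data.frame(got), as.data.frame(got2))
  # conservation: input = aligned + multi + unaligned (+ length-filtered)
  s <- attr(got, "stats")
  expect_identical(unname(s["n_input"]),
                   unname(s["n_aligned"] + s["n_multi"] + s["n_unaligned"] +
                          s["n_length_filtered"]))
})

test_that("every planted footprint is recovered at phi = 1 without contamination", {
  set.seed(15)
  cfg <- small_sim_config(footprint_library_size = 5e3, phasing = 1,
                          rrna_fraction = 0, seed = 99)
  sim <- simulate_footprints(cfg)
  r <- sim$reads[[1]]
  a <- process_reads(r, cfg$ts, adapter = cfg$adapter, rrna = cfg$rrna,
                     length_range = c(26, 36), sample_id = "s")
  expect_identical(nrow(a), length(r))
  truth1 <- sim$truth[sim$truth$sample_id == names(sim$reads)[1], ]
  got_by_tx <- table(a$transcript_id)
  for (i in seq_len(nrow(truth1))) {
    id <- truth1$transcript_id[i]
    got <- if (id %in% names(got_by_tx)) unname(got_by_tx[[id]]) else 0L
    expect_identical(got, truth1$n_reads[i])
  }
})

test_that("alignment tables round-trip through the TSV serialization", {
  set.seed(16)
  ts <- toy_ts(100)
  r <- substr(rep(as.character(ts$seqs[[1]]), 5), 1:5 * 10, 1:5 * 10 + 30)
  a <- align_unique(r, ts, sample_id = "s1")
  path <- tempfile(fileext = ".tsv")
  write_alignments(a, path)
  b <- read_alignments(path)
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
})

test_that("SAM import recovers transcript-space alignments", {
  set.seed(17)
  ts <- toy_ts(100)
  sam <- tempfile(fileext = ".sam")
  seq1 <- substr(as.character(ts$seqs[[1]]), 21, 50)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:TX1\tLN:%d", Biostrings::width(ts$seqs)[1]),
    sprintf("r1\t0\tTX1\t21\t255\t30M\t*\t0\t0\t%s\t*", seq1),
    sprintf("r2\t16\tTX1\t41\t255\t30M\t*\t0\t0\t%s\t*", seq1)), sam)
  a <- import_alignments_sam(sam, ts, sample_id = "ext")
  expect_identical(nrow(a), 1L)      # reverse-strand record dropped
  expect_identical(a$pos5, 20L)      # SAM 1-based -> 0-based
  expect_identical(a$length, 30L)
})
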