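mk_aln <- function(ts, pos5, id = ts$anno$id[1], len = 30L, sample = "s") {
  data.table::data.table(sample_id = sample, transcript_id = id,
                         pos5 = as.integer(pos5), length = len,
                         mismatches = 0L)
}

test_that("metagene profile places point masses and uniform reads correctly", {
  set.seed(40)
  ts <- toy_ts(200, utr5 = 60, utr3 = 60)     # CDS 600 nt > 400
  cs <- ts$anno$cds_start
  a <- mk_aln(ts, rep(cs - 13L, 50))
  mg <- metagene_profile(a, ts, "start")
  expect_equal(mg$fraction[mg$rel_pos == -13], 1.0)
  expect_true(all(mg$fraction[mg$rel_pos != -13] == 0))
  # uniform 5' ends -> flat profile at 1/window_width
  b <- mk_aln(ts, seq(cs - 50L, cs + 70L))
  mgu <- metagene_profile(b, ts, "start")
  expect_true(all(abs(mgu$fraction - 1 / 121) < 1e-12))
  # transcripts at or below the CDS length floor are excluded
  short <- toy_ts(120, utr5 = 60, utr3 = 60)  # CDS 360 nt
  expect_warning(mg2 <- metagene_profile(mk_aln(short, 10), short, "start"),
                 "no transcripts")
  expect_identical(nrow(mg2), 0L)
})

test_that("synthetic libraries show the 3-nt comb from -13 and offset 16", {
  cfg <- small_sim_config(genes = c("Sephs2", "Seln", "Alb", "Trf"),
                          footprint_library_size = 3e4, phasing = 1,
                          rrna_fraction = 0, seed = 41)
  sim <- simulate_footprints(cfg)
  aln <- data.table::rbindlist(process_all(sim, cfg))
  mg <- metagene_profile(aln, cfg$ts, "start")
  teeth <- mg$fraction[mg$rel_pos >= -13 & mg$rel_pos <= 20]
  on_comb <- (((-13):20) + 13) %% 3 == 0
  expect_true(all(teeth[on_comb] > 0))
  expect_true(all(teeth[!on_comb] == 0))
  expect_true(all(mg$fraction[mg$rel_pos < -13] == 0))
  expect_identical(infer_asite_offset(mg), 16L)
  # stop-anchored comb ends 16 nt upstream of the stop codon
  mgs <- metagene_profile(aln, cfg$ts, "stop")
  expect_gt(mgs$fraction[mgs$rel_pos == -16], 0)
  expect_true(all(mgs$fraction[mgs$rel_pos > -16] == 0))
})

test_that("onset at the start codon itself implies a 3-nt offset", {
  set.seed(42)
  ts <- toy_ts(200, utr5 = 60, utr3 = 60)
  cs <- ts$anno$cds_start
  pos <- rep(cs + 3L * (0:40), each = 5)     # 5' ends on codon boundaries
  mg <- metagene_profile(mk_aln(ts, pos), ts, "start")
  expect_identical(infer_asite_offset(mg), 3L)
})

test_that("planted A-site offsets 12-18 are recovered exactly at phi = 0.9", {
  for (d in 12:18) {
    cfg <- small_sim_config(genes = c("Sephs2", "Alb"),
                            footprint_library_size = 2e4, phasing = 0.9,
                            rrna_fraction = 0, asite_offset = d,
                            seed = 100 + d)
    sim <- simulate_footprints(cfg)
    aln <- process_all(sim, cfg)[[1]]
    mg <- metagene_profile(aln, cfg$ts, "start")
    expect_identical(infer_asite_offset(mg), as.integer(d))
  }
})

test_that("aperiodic profiles are rejected with instructions", {
  set.seed(43)
  ts <- toy_ts(200, utr5 = 60, utr3 = 60)
  a <- mk_aln(ts, sample(seq(ts$anno$cds_start - 40, ts$anno$cds_start + 60),
                         500, replace = TRUE))
  expect_error(infer_asite_offset(metagene_profile(a, ts, "start")),
               "periodicity")
})

test_that("phasing fractions sum to one, track phi, and are NA when empty", {
  set.seed(44)
  ts <- toy_ts(200, utr5 = 60, utr3 = 60)
  cs <- ts$anno$cds_start
  f <- phasing_fractions(mk_aln(ts, cs + 3L * (10:50)), ts, "cds")
  expect_equal(unname(f), c(1, 0, 0), ignore_attr = TRUE)
  # phi = 1 library: all mass on one frame
  cfg <- small_sim_config(genes = c("Sephs2", "Alb"),
                          footprint_library_size = 2e4,
                          phasing = 1, rrna_fraction = 0, seed = 45)
  aln <- process_all(simulate_footprints(cfg), cfg)[[1]]
  f1 <- phasing_fractions(aln, cfg$ts, "cds")
  expect_equal(max(f1), 1.0)
  expect_equal(sum(f1), 1.0)
  # phi = 0.7 with symmetric jitter: dominant fraction ~ 0.7 (binomial 3 sigma)
  cfg7 <- small_sim_config(genes = c("Sephs2", "Alb"),
                           footprint_library_size = 2e4,
                           phasing = 0.7, rrna_fraction = 0, seed = 46)
  aln7 <- process_all(simulate_footprints(cfg7), cfg7)[[1]]
  f7 <- phasing_fractions(aln7, cfg7$ts, "cds")
  n <- attr(f7, "n")
  expect_lt(abs(max(f7) - 0.7), 3 * sqrt(0.7 * 0.3 / n))
  expect_equal(sum(f7), 1.0)
  # empty region: undefined, not 0/0/0
  empty <- phasing_fractions(mk_aln(ts, integer(0)), ts, "utr3")
  expect_true(all(is.na(empty)))
  # Sec flank phasing is defined for selenoprotein libraries
  ph <- phasing_summary(aln, cfg$ts, asite_offset = 16)
  sec5 <- ph[ph$region == "five_prime_of_sec", ]
  expect_equal(sec5$f1 + sec5$f2 + sec5$f3, 1.0)
})

test_that("apply_offset shifts counts and conserves totals minus boundary drops", {
  set.seed(47)
  ts <- toy_ts(200, utr5 = 60, utr3 = 60)
  a <- mk_aln(ts, 100)
  prof <- apply_offset(a, ts, 16)
  expect_identical(prof$TX1[117], 1L)  # 0-based 116
  expect_identical(sum(prof$TX1), 1L)
  # offset 0 reproduces the raw 5' profile
  b <- mk_aln(ts, c(5, 5, 10))
  p0 <- apply_offset(b, ts, 0)
  expect_identical(p0$TX1[6], 2L)
  expect_identical(p0$TX1[11], 1L)
  # random alignments: conservation against a direct recount
  tlen <- Biostrings::width(ts$seqs)[1]
  pos <- sample(0:(tlen - 1), 400, replace = TRUE)
  pr <- apply_offset(mk_aln(ts, pos), ts, 16)
  in_range <- sum(pos + 16 < tlen)
  expect_identical(sum(pr$TX1), in_range)
  expect_identical(attr(pr, "n_dropped"), 400L - in_range)
  cnt <- table(factor(pos[pos + 16 < tlen] + 16, levels = 0:(tlen - 1)))
  expect_identical(unname(pr$TX1), unname(as.integer(cnt)))
})

test_that("metagene profile is invariant to transcript input order", {
  set.seed(48)
  cfg <- small_sim_config(genes = c("Sephs2", "Seln", "Alb"),
                          footprint_library_size = 1e4, rrna_fraction = 0,
                          seed = 49)
  aln <- process_all(simulate_footprints(cfg), cfg)[[1]]
  mg1 <- metagene_profile(aln, cfg$ts, "start")
  perm <- sample(nrow(aln))
  mg2 <- metagene_profile(aln[perm, ], cfg$ts, "start")
  expect_equal(mg1, mg2)
})
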