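#' Per-transcript site profiles with an A-site offset applied
#'
#' Each aligned read contributes one count at `pos5 + offset`, the predicted
#' first nucleotide of the ribosome's A-site codon. With `offset = 0` this
#' is the raw 5'-end profile. Reads whose offset site falls outside the
#' transcript are dropped and counted.
#'
#' @param alignments data.table from [align_unique()] (one sample)
#' @param ts [transcript_set]
#' @param offset nt from the 5' end to the first nt of the A-site codon
#' @return named list (by transcript id) of integer count vectors, one
#'   element per transcript nucleotide (position i = 0-based coordinate
#'   i-1); attributes `offset` and `n_dropped`.
#' @export
apply_offset <- function(alignments, ts, offset = 16L) {
  offset <- as.integer(offset)
  if (offset < 0) stop("offset must be >= 0")
  tlen <- stats::setNames(Biostrings::width(ts$seqs), ts$anno$id)
  profiles <- lapply(tlen, function(n) integer(n))
  dropped <- 0L
  if (nrow(alignments)) {
    site <- alignments$pos5 + offset
    keep <- site < tlen[alignments$transcript_id] & site >= 0L
    dropped <- sum(!keep)
    dt <- data.table::data.table(id = alignments$transcript_id[keep],
                                 site = site[keep])
    agg <- as.data.frame(dt[, .N, by = c("id", "site")])
    for (rows in split(seq_len(nrow(agg)), agg$id)) {
      nm <- agg$id[rows[1]]
      v <- profiles[[nm]]
      v[agg$site[rows] + 1L] <- agg$N[rows]
      profiles[[nm]] <- v
    }
  }
  attr(profiles, "offset") <- offset
  attr(profiles, "n_dropped") <- dropped
  profiles
}

#' Metagene profile of footprint 5' ends around the start or stop codon
#'
#' Fraction of read 5' ends at each position relative to the first
#' nucleotide of the start codon (or of the stop codon), summed over all
#' transcripts whose CDS exceeds `min_cds_nt`, normalized to sum to one over
#' the window.
#'
#' @param alignments data.table from [align_unique()]
#' @param ts [transcript_set]
#' @param anchor `"start"` or `"stop"`
#' @param window integer range of relative positions; defaults -50..70
#'   around the start and -70..35 around the stop.
#' @param min_cds_nt minimum CDS length (nt) for a transcript to contribute.
#' @return data.frame (rel_pos, count, fraction); empty with a warning if no
#'   transcript qualifies or no reads fall in the window.
#' @export
metagene_profile <- function(alignments, ts, anchor = c("start", "stop"),
                             window = NULL, min_cds_nt = 400L) {
  anchor <- match.arg(anchor)
  if (is.null(window))
    window <- if (anchor == "start") -50L:70L else -70L:35L
  a <- ts$anno
  cds_len <- a$cds_end - a$cds_start
  use <- a$id[cds_len > min_cds_nt]
  if (!length(use)) {
    warning("no transcripts with CDS > ", min_cds_nt, " nt")
    return(data.frame(rel_pos = integer(0), count = integer(0),
                      fraction = numeric(0)))
  }
  al <- alignments[alignments$transcript_id %in% use, ]
  anchor_pos <- if (anchor == "start") a$cds_start else a$cds_end - 3L
  names(anchor_pos) <- a$id
  rel <- al$pos5 - anchor_pos[al$transcript_id]
  rel <- rel[rel >= min(window) & rel <= max(window)]
  counts <- tabulate(rel - min(window) + 1L, nbins = length(window))
  tot <- sum(counts)
  if (tot == 0) warning("no reads in the metagene window")
  data.frame(rel_pos = as.integer(window), count = counts,
             fraction = if (tot > 0) counts / tot else rep(NA_real_, length(window)))
}

#' Infer the A-site offset from a start-anchored metagene profile
#'
#' Finds the onset of triplet periodicity: the first position in the window
#' where a tooth of the 3-nt comb stands out (the position and the tooth one
#' codon downstream each exceed twice their immediate neighbours and twice
#' the mean window level). An initiating ribosome holds the start codon in
#' its P site, so its A site is one codon downstream of the onset position:
#' the returned offset is `3 - onset`. For the canonical mammalian geometry
#' (onset at -13) this yields 16.
#'
#' @param profile data.frame from [metagene_profile()] with `anchor="start"`
#' @return offset in nt (read 5' end + offset = first nt of the A-site codon)
#' @export
infer_asite_offset <- function(profile) {
  f <- profile$fraction
  pos <- profile$rel_pos
  n <- length(f)
  if (!n || all(is.na(f)))
    stop("empty metagene profile; supply the offset manually")
  bg <- mean(f, na.rm = TRUE)
  tooth <- function(i) {
    if (i < 1 || i > n) return(0)
    lo <- if (i > 1) f[i - 1] else 0
    hi <- if (i < n) f[i + 1] else 0
    f[i] > 2 * bg && f[i] > 2 * lo && f[i] > 2 * hi
  }
  dominant <- frame_dominance(profile)
  if (is.na(dominant) || dominant < 1 / 3 + 0.1)
    stop("no detectable triplet periodicity (dominant frame fraction ",
         round(dominant, 3), "); supply the offset manually")
  for (i in seq_len(n - 3L)) {
    if (tooth(i) && tooth(i + 3L)) return(3L - pos[i])
  }
  stop("no periodicity onset found; supply the offset manually")
}

frame_dominance <- function(profile) {
  f <- profile$fraction
  if (all(is.na(f)) || sum(f, na.rm = TRUE) == 0) return(NA_real_)
  frames <- profile$rel_pos %% 3L
  by_frame <- vapply(0:2, function(k) sum(f[frames == k], na.rm = TRUE), 0)
  max(by_frame) / sum(by_frame)
}

#' Triplet phasing of footprint 5' ends by region
#'
#' Fraction of read 5' ends on each codon position (1, 2, 3), the frame
#' defined modulo 3 relative to the annotated CDS start - also for UTRs,
#' whose "codon positions" are read off the CDS frame. For the Sec flank
#' regions, a read belongs to the region if its A-site (5' end +
#' `asite_offset`) lies 5' resp. 3' of the first UGA-Sec codon within the
#' CDS; frame is still computed from the raw 5' end.
#'
#' @param alignments data.table from [align_unique()]
#' @param ts [transcript_set]
#' @param region one of `"cds"`, `"utr5"`, `"utr3"`, `"five_prime_of_sec"`,
#'   `"three_prime_of_sec"`
#' @param asite_offset used only to resolve the Sec flank regions
#' @return named numeric vector (f1, f2, f3) summing to 1, or all-NA if the
#'   region holds no reads (undefined, not 0/0/0); attribute `n` = read count.
#' @export
phasing_fractions <- function(alignments, ts,
                              region = c("cds", "utr5", "utr3",
                                         "five_prime_of_sec",
                                         "three_prime_of_sec"),
                              asite_offset = 16L) {
  region <- match.arg(region)
  a <- ts$anno
  cs <- stats::setNames(a$cds_start, a$id)
  ce <- stats::setNames(a$cds_end, a$id)
  tlen <- stats::setNames(Biostrings::width(ts$seqs), a$id)
  al <- alignments
  if (region %in% c("five_prime_of_sec", "three_prime_of_sec")) {
    sec1 <- vapply(a$id, function(id) first_sec_codon(ts, id), 0L)
    has <- names(sec1)[!is.na(sec1)]
    al <- al[al$transcript_id %in% has, ]
    sec_nt <- cs[al$transcript_id] + 3L * sec1[al$transcript_id]
    site <- al$pos5 + as.integer(asite_offset)
    inside <- site >= cs[al$transcript_id] & site < ce[al$transcript_id]
    sel <- if (region == "five_prime_of_sec") site < sec_nt else
      site >= sec_nt + 3L
    al <- al[inside & sel, ]
  } else {
    p <- al$pos5
    sel <- switch(region,
      cds = p >= cs[al$transcript_id] & p < ce[al$transcript_id],
      utr5 = p < cs[al$transcript_id],
      utr3 = p >= ce[al$transcript_id])
    al <- al[sel, ]
  }
  if (!nrow(al)) {
    out <- c(f1 = NA_real_, f2 = NA_real_, f3 = NA_real_)
    attr(out, "n") <- 0L
    return(out)
  }
  frame <- (al$pos5 - cs[al$transcript_id]) %% 3L
  tab <- tabulate(frame + 1L, nbins = 3L)
  out <- stats::setNames(tab / sum(tab), c("f1", "f2", "f3"))
  attr(out, "n") <- nrow(al)
  out
}

#' Phasing summary across region classes
#'
#' @param alignments data.table from [align_unique()]
#' @param ts [transcript_set]
#' @param regions region classes to tabulate
#' @param asite_offset passed to [phasing_fractions()]
#' @return data.frame (region, f1, f2, f3, n)
#' @export
phasing_summary <- function(alignments, ts,
                            regions = c("cds", "utr5", "utr3",
                                        "five_prime_of_sec",
                                        "three_prime_of_sec"),
                            asite_offset = 16L) {
  rows <- lapply(regions, function(r) {
    f <- phasing_fractions(alignments, ts, r, asite_offset)
    data.frame(region = r, f1 = f[1], f2 = f[2], f3 = f[3],
               n = attr(f, "n"), row.names = NULL)
  })
  do.call(rbind, rows)
}
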