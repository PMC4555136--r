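# Shared fixtures and independent oracles, built in code at test time.

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

# Random transcript with a clean single ORF and optional planted Sec codons.
toy_seq <- function(n_codons, sec = integer(0), utr5 = 20, utr3 = 20) {
  body <- c("ATG", sample(SENSE_CODONS, n_codons - 2, replace = TRUE))
  body[sec + 1] <- "TGA"
  paste0(paste(sample(c("A", "C", "G", "T"), utr5, replace = TRUE), collapse = ""),
         paste(c(body, "TAA"), collapse = ""),
         paste(sample(c("A", "C", "G", "T"), utr3, replace = TRUE), collapse = ""))
}

toy_ts <- function(n_codons, sec = integer(0), utr5 = 20, utr3 = 20,
                   id = "TX1", gene = "GeneX") {
  seqs <- vapply(seq_along(n_codons), function(i)
    toy_seq(n_codons[i], if (is.list(sec)) sec[[i]] else sec, utr5, utr3), "")
  names(seqs) <- id
  transcript_set(seqs, data.frame(
    id = id, gene = gene, cds_start = utr5, cds_end = utr5 + 3 * n_codons,
    sec_codons = vapply(if (is.list(sec)) sec else list(sec),
                        paste, "", collapse = ",")))
}

# Exhaustive Hamming-scan alignment oracle, independent of the package path.
brute_align <- function(read, refs, max_mm = 2) {
  best_mm <- max_mm + 1; n_best <- 0; best <- NULL
  rl <- nchar(read)
  rv <- strsplit(read, "")[[1]]
  for (t in seq_along(refs)) {
    sv <- strsplit(refs[[t]], "")[[1]]
    tl <- length(sv)
    if (tl < rl) next
    for (p in 0:(tl - rl)) {
      mm <- sum(sv[(p + 1):(p + rl)] != rv | rv == "N")
      if (mm < best_mm) {
        best_mm <- mm; n_best <- 1; best <- c(t, p)
      } else if (mm == best_mm) n_best <- n_best + 1
    }
  }
  if (best_mm > max_mm) return(list(hit = FALSE, n_best = 0))
  list(hit = TRUE, n_best = n_best, tid = best[1], pos = best[2], mm = best_mm)
}

# Mutate k positions of a sequence (guaranteed base changes).
mutate_seq <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  idx <- sample(length(v), k)
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

# Small two-condition simulation over a subset of the packaged panel.
small_sim_config <- function(genes = c("Gpx1", "Gpx4", "Sepw1", "Gapdh"),
                             ...) {
  panel <- rbind(selenoprotein_panel(), background_panel())
  panel <- panel[panel$gene %in% genes, ]
  ts <- selenoprotein_reference(panel = panel)
  sim_config(ts = ts, panel = panel, ...)
}

process_all <- function(sim, cfg, length_range = c(26, 36)) {
  out <- lapply(names(sim$reads), function(s)
    process_reads(sim$reads[[s]], cfg$ts, adapter = cfg$adapter,
                  rrna = cfg$rrna, length_range = length_range,
                  sample_id = s))
  names(out) <- names(sim$reads)
  out
}
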