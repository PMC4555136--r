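#' Total mapped reads in a sample
#'
#' The RPKM denominator: the number of uniquely aligned reads in the sample
#' (alignment to the reduced reference transcript set).
#'
#' @param alignments data.table from [align_unique()] (one sample)
#' @return integer count; error if zero (RPKM undefined).
#' @export
total_mapped <- function(alignments) {
  n <- nrow(alignments)
  if (n == 0L) stop("no mapped reads: RPKM is undefined for an empty sample")
  n
}

#' RPKM over one codon window
#'
#' Reads are assigned to a window iff their offset A-site first nucleotide
#' lies inside it (windows are half-open nucleotide intervals), making
#' windows additive and disjoint. RPKM = count / (window kb) / (total
#' mapped reads in millions).
#'
#' @param profiles per-transcript count vectors from [apply_offset()]
#' @param window one-row window data.frame (from [make_windows()] etc.)
#' @param total_mapped RPKM denominator, from [total_mapped()]
#' @return one-row data.frame (transcript_id, label, count, window_nt,
#'   total_mapped, rpkm); a non-analyzable window yields NA count/rpkm.
#' @export
window_rpkm <- function(profiles, window, total_mapped) {
  stopifnot(nrow(window) == 1L, total_mapped > 0)
  id <- window$transcript_id
  if (!window$analyzable) {
    return(data.frame(transcript_id = id, label = window$label,
                      count = NA_integer_, window_nt = NA_integer_,
                      total_mapped = total_mapped, rpkm = NA_real_,
                      stringsAsFactors = FALSE))
  }
  v <- profiles[[id]]
  if (is.null(v)) stop("no profile for transcript ", id)
  count <- sum(v[(window$start_nt + 1L):window$end_nt])
  nt <- window$end_nt - window$start_nt
  data.frame(transcript_id = id, label = window$label, count = count,
             window_nt = nt, total_mapped = total_mapped,
             rpkm = count / (nt / 1000) / (total_mapped / 1e6),
             stringsAsFactors = FALSE)
}

#' Windowed RPKM quantification for one sample
#'
#' @param profiles from [apply_offset()]
#' @param windows from [make_windows()]
#' @param total_mapped from [total_mapped()]
#' @param sample_id sample label
#' @return data.frame, one row per window (RegionQuant layout)
#' @export
quantify_windows <- function(profiles, windows, total_mapped,
                             sample_id = NA_character_) {
  rows <- lapply(seq_len(nrow(windows)), function(i)
    window_rpkm(profiles, windows[i, ], total_mapped))
  out <- do.call(rbind, rows)
  cbind(sample_id = sample_id, out, stringsAsFactors = FALSE)
}

#' Condition fold changes with propagation-of-error standard deviations
#'
#' For every gene x window, the RPKM mean and sample SD (divisor n-1) are
#' taken over biological replicates within each condition; the fold change
#' is mean(numerator condition) / mean(denominator condition) and its SD
#' follows the first-order (delta-method) propagation-of-error formula for
#' a ratio of independent means:
#' `fold_sd = fold * sqrt((sd_num/mean_num)^2 + (sd_den/mean_den)^2)`.
#' A zero denominator mean flags the fold as undefined rather than smoothed.
#'
#' @param quants row-bound [quantify_windows()] results over samples
#' @param samples sample sheet data.frame (sample_id, condition)
#' @param numerator,denominator condition labels; default fold is
#'   0.1Se-relative-to-0Se
#' @param gene_map optional named vector transcript_id -> gene symbol
#' @return data.frame (gene, label, mean/sd per condition, fold, fold_sd,
#'   flag); flag is `"ok"`, `"undefined"` (zero denominator) or
#'   `"not_analyzable"`.
#' @export
fold_change <- function(quants, samples, numerator = "0.1Se",
                        denominator = "0Se", gene_map = NULL) {
  q <- merge(quants, samples[, c("sample_id", "condition")], by = "sample_id")
  q$gene <- if (is.null(gene_map)) q$transcript_id else
    unname(gene_map[q$transcript_id])
  dt <- data.table::as.data.table(q)
  agg <- dt[, list(mean = mean(rpkm), sd = stats::sd(rpkm), n = .N),
            by = c("gene", "label", "condition")]
  num <- agg[agg$condition == numerator, ]
  den <- agg[agg$condition == denominator, ]
  m <- merge(num, den, by = c("gene", "label"), suffixes = c("_num", "_den"))
  m$sd_num <- ifelse(is.na(m$sd_num) & m$n_num == 1L, 0, m$sd_num)
  m$sd_den <- ifelse(is.na(m$sd_den) & m$n_den == 1L, 0, m$sd_den)
  fold <- m$mean_num / m$mean_den
  # first-order (delta-method) propagation for a ratio of independent means;
  # written unfactored so a zero numerator mean propagates to a finite SD
  fold_sd <- sqrt((m$sd_num / m$mean_den)^2 +
                  (m$mean_num * m$sd_den / m$mean_den^2)^2)
  flag <- rep("ok", nrow(m))
  flag[is.na(m$mean_num) | is.na(m$mean_den)] <- "not_analyzable"
  zero_den <- !is.na(m$mean_den) & m$mean_den == 0
  flag[zero_den] <- "undefined"
  fold[flag != "ok"] <- NA_real_
  fold_sd[flag != "ok"] <- NA_real_
  out <- data.frame(gene = m$gene, label = m$label,
                    mean_num = m$mean_num, sd_num = m$sd_num,
                    mean_den = m$mean_den, sd_den = m$sd_den,
                    fold = fold, fold_sd = fold_sd, flag = flag,
                    stringsAsFactors = FALSE)
  names(out)[3:6] <- c(paste0(c("mean_", "sd_"), numerator),
                       paste0(c("mean_", "sd_"), denominator))
  out[order(out$gene, out$label), ]
}

#' 3'/5' RPKM readthrough ratio
#'
#' The ratio of the RPKM downstream of the UGA-Sec codon to the RPKM
#' upstream of it, within one sample. Because ribosomes are lost to
#' termination at the UGA-Sec codon, ribosome density 3' of it tracks
#' full-length selenoprotein synthesis, and under uniform elongation the
#' ratio estimates the Sec readthrough efficiency rho. Undefined (flagged)
#' when the 5' RPKM is zero or either window is not analyzable.
#'
#' @param quants [quantify_windows()] result for one sample
#' @param gene_map optional named vector transcript_id -> gene
#' @return data.frame (sample_id, gene, rpkm_5prime, rpkm_3prime, ratio, flag)
#' @export
readthrough_ratio <- function(quants, gene_map = NULL) {
  five <- quants[quants$label == "five_prime_of_sec", ]
  three <- quants[quants$label == "three_prime_of_sec", ]
  m <- merge(five[, c("sample_id", "transcript_id", "rpkm")],
             three[, c("sample_id", "transcript_id", "rpkm")],
             by = c("sample_id", "transcript_id"), suffixes = c("_5", "_3"))
  flag <- rep("ok", nrow(m))
  flag[is.na(m$rpkm_5) | is.na(m$rpkm_3)] <- "not_analyzable"
  zero5 <- !is.na(m$rpkm_5) & m$rpkm_5 == 0
  flag[zero5] <- "undefined"
  ratio <- ifelse(flag == "ok", m$rpkm_3 / m$rpkm_5, NA_real_)
  gene <- if (is.null(gene_map)) m$transcript_id else
    unname(gene_map[m$transcript_id])
  data.frame(sample_id = m$sample_id, gene = gene,
             transcript_id = m$transcript_id,
             rpkm_5prime = m$rpkm_5, rpkm_3prime = m$rpkm_3,
             ratio = ratio, flag = flag, stringsAsFactors = FALSE)
}
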