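#' Simulation configuration
#'
#' Bundles the ground-truth parameters of the synthetic experiment: the
#' transcriptome, per-gene per-condition mRNA abundance theta (expected
#' fragments per nt, arbitrary units - each library is normalized to its
#' target size, as sequencing depth is set per library), per-gene
#' per-condition UGA-Sec readthrough efficiency rho (probability that a
#' ribosome reaching the first UGA-Sec continues instead of terminating),
#' footprint geometry (length distribution over 26-36 nt, 5' end to A-site
#' offset, triplet-phasing fidelity phi), rRNA contamination, and the
#' two-diet, two-replicate study layout.
#'
#' @param ts [transcript_set]; default the packaged synthetic selenoproteome.
#' @param panel parameter table with columns gene, theta0, theta_fold,
#'   rho_0Se, rho_0.1Se (matched to `ts` genes); default
#'   [selenoprotein_panel()] plus [background_panel()].
#' @param conditions condition labels; the second is taken as the
#'   Se-supplemented diet.
#' @param replicates biological replicates per condition.
#' @param footprint_library_size,rna_library_size expected reads per library.
#' @param footprint_lengths,footprint_length_weights footprint length
#'   distribution (nt); default peaks at 29-31 nt.
#' @param rna_fragment_lengths RNA fragment lengths (nt), uniform.
#' @param read_cycles sequencing cycles; fragments shorter than this carry
#'   the 3' adapter (and are padded), so trimming is exercised.
#' @param phasing phi, fraction of footprints whose 5' end sits exactly at
#'   the canonical offset; the remainder jitter +/-1 nt.
#' @param asite_offset nt from footprint 5' end to the first nt of the
#'   A-site codon.
#' @param rrna_fraction expected fraction of contaminant rRNA reads.
#' @param rrna rRNA sequences used to draw contaminants.
#' @param adapter 3' adapter sequence.
#' @param theta,rho optional gene x condition matrices overriding the panel.
#' @param seed integer seed; each sample derives its own stream from it.
#' @return list of class `sim_config`
#' @export
sim_config <- function(ts = selenoprotein_reference(),
                       panel = rbind(selenoprotein_panel(), background_panel()),
                       conditions = c("0Se", "0.1Se"),
                       replicates = 2L,
                       footprint_library_size = 2e5,
                       rna_library_size = 2e5,
                       footprint_lengths = 26:36,
                       footprint_length_weights = NULL,
                       rna_fragment_lengths = 80:120,
                       read_cycles = 50L,
                       phasing = 0.9,
                       asite_offset = 16L,
                       rrna_fraction = 0.1,
                       rrna = synthetic_rrna(),
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       theta = NULL, rho = NULL,
                       seed = 1L) {
  genes <- ts$anno$gene
  if (is.null(theta) || is.null(rho)) {
    i <- match(genes, panel$gene)
    if (anyNA(i)) stop("panel is missing genes: ",
                       paste(genes[is.na(i)], collapse = ", "))
    if (is.null(theta)) {
      theta <- cbind(panel$theta0[i], panel$theta0[i] * panel$theta_fold[i])
      dimnames(theta) <- list(genes, conditions)
    }
    if (is.null(rho)) {
      rho <- cbind(panel$rho_0Se[i], panel$rho_0.1Se[i])
      dimnames(rho) <- list(genes, conditions)
    }
  }
  if (is.null(footprint_length_weights))
    footprint_length_weights <- stats::dnorm(footprint_lengths, 30, 2)
  cfg <- list(ts = ts, conditions = conditions, replicates = as.integer(replicates),
              footprint_library_size = footprint_library_size,
              rna_library_size = rna_library_size,
              footprint_lengths = as.integer(footprint_lengths),
              footprint_length_weights = footprint_length_weights,
              rna_fragment_lengths = as.integer(rna_fragment_lengths),
              read_cycles = as.integer(read_cycles),
              phasing = phasing, asite_offset = as.integer(asite_offset),
              rrna_fraction = rrna_fraction, rrna = rrna, adapter = adapter,
              theta = theta, rho = rho, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg$ts, "transcript_set"),
            cfg$footprint_library_size > 0, cfg$rna_library_size > 0,
            cfg$asite_offset >= 0, cfg$replicates >= 1)
  if (cfg$phasing < 0 || cfg$phasing > 1) stop("phasing must be in [0,1]")
  if (cfg$rrna_fraction < 0 || cfg$rrna_fraction > 1)
    stop("rrna_fraction must be in [0,1]")
  if (any(cfg$theta < 0, na.rm = TRUE)) stop("abundances must be >= 0")
  rr <- cfg$rho[!is.na(cfg$rho)]
  if (any(rr < 0 | rr > 1)) stop("readthrough efficiencies must be in [0,1]")
  if (!identical(dim(cfg$theta), dim(cfg$rho)) ||
      !identical(rownames(cfg$theta), cfg$ts$anno$gene))
    stop("theta/rho must be gene x condition matrices over the transcript set")
  invisible(cfg)
}

sample_seed <- function(seed, sidx, stream) {
  (as.integer(seed) * 97L + sidx * 7919L + stream * 271L) %% 2147483562L
}

first_sec_codon <- function(ts, id) {
  s <- ts$sec[[id]]
  if (length(s)) s[1] else NA_integer_
}

finish_reads <- function(frags, cfg) {
  short <- nchar(frags) < cfg$read_cycles
  if (any(short)) {
    filled <- paste0(frags[short], cfg$adapter,
                     strrep("A", cfg$read_cycles))
    frags[short] <- substr(filled, 1L, cfg$read_cycles)
  }
  frags
}

draw_rrna_reads <- function(cfg, n) {
  if (n == 0L) return(character(0))
  refs <- cfg$rrna
  len <- nchar(refs)
  src <- sample(seq_along(refs), n, replace = TRUE, prob = len)
  rl <- sample(cfg$footprint_lengths, n, replace = TRUE,
               prob = cfg$footprint_length_weights)
  start <- floor(stats::runif(n) * (len[src] - rl)) + 1L
  substr(rep(unname(refs)[src], 1L), start, start + rl - 1L)
}

#' Simulate ribosome-footprint libraries with known ground truth
#'
#' Footprint 5' ends are placed codon-wise: every A-site codon from codon 1
#' (the start codon occupies the P site at initiation) through the stop
#' codon (occupied at termination) receives Poisson counts with per-codon
#' rate proportional to theta upstream of the first UGA-Sec codon and to
#' theta x rho downstream of it - a single Bernoulli readthrough branch at
#' the first Sec codon, uniform elongation otherwise. With probability phi
#' the 5' end sits exactly `asite_offset` nt upstream of the codon's first
#' nt, otherwise it jitters +/-1 nt. Lengths follow the configured 26-36 nt
#' distribution, rRNA contaminants are appended at the configured fraction,
#' and fragments shorter than the sequencing read length carry the adapter.
#'
#' @param cfg [sim_config()]
#' @param outdir if non-NULL, writes one gzipped FASTQ per sample plus
#'   `sim_truth_fp.tsv` and a YAML config echo.
#' @return list with `reads` (named list, one character vector per sample),
#'   `truth` (data.frame: sample, condition, replicate, gene, theta, rho,
#'   emitted read and per-window A-site counts) and `samples` (sample sheet).
#' @export
simulate_footprints <- function(cfg, outdir = NULL) {
  simulate_library(cfg, "fp", outdir)
}

#' Simulate total-RNA fragment libraries with known ground truth
#'
#' RNA fragments are drawn uniformly along each transcript (random
#' fragmentation with random-hexamer priming) with expected per-nt coverage
#' proportional to theta; Poisson sampling, no phasing and no 5'/3'
#' asymmetry around UGA-Sec codons.
#'
#' @inheritParams simulate_footprints
#' @return as [simulate_footprints()]
#' @export
simulate_rnaseq <- function(cfg, outdir = NULL) {
  simulate_library(cfg, "rna", outdir)
}

simulate_library <- function(cfg, libtype = c("fp", "rna"), outdir = NULL) {
  libtype <- match.arg(libtype)
  ts <- cfg$ts
  seqs <- as.character(ts$seqs)
  tlen <- nchar(seqs)
  nc <- n_codons(ts)
  lib_size <- if (libtype == "fp") cfg$footprint_library_size else
    cfg$rna_library_size
  samples <- expand.grid(replicate = seq_len(cfg$replicates),
                         condition = cfg$conditions,
                         stringsAsFactors = FALSE)[, 2:1]
  samples$sample_id <- sprintf("%s_%s_rep%d", libtype, samples$condition,
                               samples$replicate)
  windows <- make_windows(ts)
  reads_out <- vector("list", nrow(samples))
  names(reads_out) <- samples$sample_id
  truth <- list()
  for (s in seq_len(nrow(samples))) {
    cond <- samples$condition[s]
    set.seed(sample_seed(cfg$seed, s, if (libtype == "fp") 1L else 2L))
    th <- cfg$theta[, cond]
    rh <- cfg$rho[, cond]
    gene_frags <- vector("list", length(tlen))
    gene_truth <- vector("list", length(tlen))
    # per-gene expected rates, then joint normalization to library size
    rate <- vector("list", length(tlen))
    for (g in seq_along(tlen)) {
      id <- ts$anno$id[g]
      if (libtype == "fp") {
        cods <- seq.int(1L, nc[g] - 1L)      # A-site codons incl. stop
        w <- rep(th[g] * 3, length(cods))
        sec1 <- first_sec_codon(ts, id)
        if (!is.na(sec1)) w[cods > sec1] <- w[cods > sec1] * rh[g]
        rate[[g]] <- w
      } else {
        rate[[g]] <- rep(th[g], tlen[g])     # per-nt 5' end rate (uniform)
      }
    }
    tot <- sum(vapply(rate, sum, 0))
    scale <- lib_size * (1 - cfg$rrna_fraction) / tot
    for (g in seq_along(tlen)) {
      id <- ts$anno$id[g]
      cs <- ts$anno$cds_start[g]
      if (libtype == "fp") {
        cods <- seq.int(1L, nc[g] - 1L)
        counts <- stats::rpois(length(cods), rate[[g]] * scale)
        codv <- rep(cods, counts)
        n <- length(codv)
        if (n) {
          asite <- cs + 3L * codv
          jit <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                        prob = c((1 - cfg$phasing) / 2, cfg$phasing,
                                 (1 - cfg$phasing) / 2))
          p5 <- asite - cfg$asite_offset + jit
          rl <- sample(cfg$footprint_lengths, n, replace = TRUE,
                       prob = cfg$footprint_length_weights)
          ok <- p5 >= 0L & (p5 + rl) <= tlen[g]
          p5 <- p5[ok]; rl <- rl[ok]; asite <- asite[ok]
          gene_frags[[g]] <- substr(rep(seqs[g], length(p5)), p5 + 1L, p5 + rl)
          gene_truth[[g]] <- window_truth(windows, id, asite, ts$anno$gene[g],
                                          cond, samples$replicate[s],
                                          samples$sample_id[s], th[g], rh[g])
        } else {
          gene_truth[[g]] <- window_truth(windows, id, integer(0),
                                          ts$anno$gene[g], cond,
                                          samples$replicate[s],
                                          samples$sample_id[s], th[g], rh[g])
        }
      } else {
        n <- stats::rpois(1L, th[g] * tlen[g] * scale)
        if (n) {
          fl <- sample(cfg$rna_fragment_lengths, n, replace = TRUE)
          fl <- pmin(fl, tlen[g])
          p5 <- floor(stats::runif(n) * (tlen[g] - fl + 1L))
          rl <- pmin(fl, cfg$read_cycles)
          gene_frags[[g]] <- substr(rep(seqs[g], n), p5 + 1L, p5 + rl)
          site <- p5 + cfg$asite_offset
          site <- site[site < tlen[g]]
          gene_truth[[g]] <- window_truth(windows, id, site, ts$anno$gene[g],
                                          cond, samples$replicate[s],
                                          samples$sample_id[s], th[g], rh[g],
                                          n_emitted = n)
        } else {
          gene_truth[[g]] <- window_truth(windows, id, integer(0),
                                          ts$anno$gene[g], cond,
                                          samples$replicate[s],
                                          samples$sample_id[s], th[g], rh[g])
        }
      }
    }
    frags <- unlist(gene_frags, use.names = FALSE)
    n_rrna <- stats::rpois(1L, lib_size * cfg$rrna_fraction)
    frags <- c(frags, draw_rrna_reads(cfg, n_rrna))
    frags <- finish_reads(frags, cfg)
    frags <- frags[sample.int(length(frags))]
    names(frags) <- sprintf("%s.%07d", samples$sample_id[s], seq_along(frags))
    reads_out[[s]] <- frags
    tr <- do.call(rbind, gene_truth)
    tr$n_rrna <- n_rrna
    truth[[s]] <- tr
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  out <- list(reads = reads_out, truth = truth, samples = samples,
              libtype = libtype)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (sid in names(reads_out))
      write_fastq(reads_out[[sid]], file.path(outdir, paste0(sid, ".fastq.gz")))
    utils::write.table(truth, file.path(outdir, paste0("sim_truth_", libtype, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    echo_sim_config(cfg, file.path(outdir, "sim_config.yaml"))
  }
  out
}

window_truth <- function(windows, id, sites, gene, cond, rep, sid, th, rh,
                         n_emitted = length(sites)) {
  w <- windows[windows$transcript_id == id, ]
  cnt <- function(label) {
    r <- w[w$label == label, ]
    if (!nrow(r) || !r$analyzable) return(NA_integer_)
    sum(sites >= r$start_nt & sites < r$end_nt)
  }
  data.frame(sample_id = sid, condition = cond, replicate = rep, gene = gene,
             transcript_id = id, theta = th, rho = rh,
             n_reads = n_emitted,
             count_cds_core = cnt("cds_core"),
             count_five_prime = cnt("five_prime_of_sec"),
             count_three_prime = cnt("three_prime_of_sec"),
             stringsAsFactors = FALSE)
}

echo_sim_config <- function(cfg, path) {
  echo <- list(seed = cfg$seed, conditions = cfg$conditions,
               replicates = cfg$replicates,
               footprint_library_size = cfg$footprint_library_size,
               rna_library_size = cfg$rna_library_size,
               footprint_lengths = range(cfg$footprint_lengths),
               phasing = cfg$phasing, asite_offset = cfg$asite_offset,
               rrna_fraction = cfg$rrna_fraction, adapter = cfg$adapter,
               genes = rownames(cfg$theta),
               theta = apply(cfg$theta, 2, as.list),
               rho = apply(cfg$rho, 2, as.list))
  yaml::write_yaml(echo, path)
  invisible(path)
}
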