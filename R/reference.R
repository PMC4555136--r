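#' Mouse selenoprotein gene panel with synthetic coordinates
#'
#' The 25-mRNA panel (24 selenoprotein mRNAs plus Gapdh) used throughout the
#' package, one row per gene with its RefSeq accession, a CDS length in
#' codons (including the stop codon), 0-based Sec codon indices, and the
#' default simulation parameters: relative mRNA abundance `theta0` under the
#' selenium-deficient diet (arbitrary units, fragments per nt), the mRNA
#' abundance fold change `theta_fold` (0.1 ppm Se relative to 0 ppm Se), and
#' the UGA-Sec readthrough efficiencies `rho_0Se` / `rho_0.1Se`.
#'
#' Coordinates and CDS lengths are synthetic: they approximate the real
#' proteins (e.g. a C-terminal Sec for the thioredoxin reductases, Selk,
#' Sels, Seli and Selo; an N-terminal-proximal Sec for Sepw1; ten Sec codons
#' for Sepp1) but are not transcript annotations lifted from RefSeq, and the
#' packaged sequences built from them by [selenoprotein_reference()] are
#' random. Default abundances and fold changes encode the study conditions:
#' stress-related selenoprotein mRNAs (Gpx1, Selh, Selk, Sepw1) respond 2-4
#' fold to dietary Se, Sepp1 and Txnrd2 ~1.5 fold, housekeeping
#' selenoproteins under 1.5 fold; readthrough efficiencies are set so the
#' product of mRNA and readthrough fold changes reproduces the per-gene
#' 3' ribosome-density fold changes (15 for Gpx1, 13 for Sepx1, 6 for
#' Sepw1, 5 for Sephs2, 1.9 for Gpx4, about 2 elsewhere).
#'
#' @return data.frame, one row per gene.
#' @export
selenoprotein_panel <- function() {
  p <- read.csv(text = "
gene,accession,codons,sec,theta0,theta_fold,rho_0Se,rho_0.1Se
Gpx1,NM_008160.6,202,47,2.0,4.0,0.20,0.750
Gpx2,NM_030677.2,191,39,0.5,1.3,0.40,0.700
Gpx3,NM_008161.3,227,72,1.2,1.2,0.40,0.720
Gpx4,NM_008162.2,171,73,5.0,1.1,0.44,0.760
Txnrd1,NM_015762.2,500,498,2.5,1.1,0.85,0.900
Txnrd2,NM_013711.3,528,526,1.2,1.5,0.85,0.900
Txnrd3,NM_001178058.1,455,453,0.4,1.2,0.85,0.900
Dio1,NM_007860.3,258,126,1.5,1.3,0.35,0.750
Dio2,NM_010050.2,267,133,0.3,1.2,0.40,0.700
Dio3,NM_172119.2,279,144,0.3,1.1,0.40,0.780
Sepp1,NM_009155.3,381,59;300;318;330;345;352;367;369;372;376,6.0,1.5,0.50,0.750
Sepw1,NM_009156.2,89,13,3.0,3.0,0.40,0.800
Sepx1,NM_013759.2,117,95,6.0,1.3,0.08,0.800
Sephs2,NM_009266.3,449,60,2.0,1.2,0.18,0.750
Sep15,NM_053102.2,163,93,2.0,1.2,0.45,0.800
Selh,NM_001033166.2,117,44,1.0,3.8,0.55,0.720
Selk,NM_019979.2,95,92,1.2,2.5,0.50,0.750
Selm,NM_053267.2,146,48,0.8,1.2,0.42,0.730
Seln,NM_029100.2,558,428,0.6,1.1,0.45,0.850
Selo,NM_027905,669,667,0.5,1.1,0.85,0.900
Sels,NM_024439.3,189,187,1.0,1.3,0.85,0.900
Selt,NM_001040396.2,196,49,1.0,1.2,0.42,0.750
Selv,NM_175033.3,340,273,0.15,1.0,0.35,0.750
Seli,NM_027652.2,398,394,0.5,1.1,0.85,0.900
Gapdh,NM_008084.2,334,,8.0,1.0,NA,NA
", stringsAsFactors = FALSE)
  p$sec <- gsub(";", ",", p$sec)
  p
}

#' Liver-abundant background mRNAs for the simulated transcriptome
#'
#' Highly expressed non-selenoprotein mRNAs whose abundance does not respond
#' to dietary selenium. They provide the unchanged bulk against which RPKM
#' (a relative measure) is computed, emulating the genome-wide read total
#' the study normalized to; without them a 25-gene transcriptome would make
#' every selenoprotein fold change hostage to the selenoprotein-wide shift.
#' Symbols are liver-typical; sequences are synthetic.
#'
#' @return data.frame in the same layout as [selenoprotein_panel()].
#' @export
background_panel <- function() {
  read.csv(text = "
gene,accession,codons,sec,theta0,theta_fold,rho_0Se,rho_0.1Se
Alb,SYN_000001.1,609,,240,1.0,NA,NA
Ttr,SYN_000002.1,148,,100,1.0,NA,NA
Apoa1,SYN_000003.1,265,,80,1.0,NA,NA
Serpina1a,SYN_000004.1,414,,72,1.0,NA,NA
Fga,SYN_000005.1,790,,40,1.0,NA,NA
Ahsg,SYN_000006.1,346,,48,1.0,NA,NA
Trf,SYN_000007.1,698,,48,1.0,NA,NA
Apoe,SYN_000008.1,312,,60,1.0,NA,NA
Mup3,SYN_000009.1,181,,80,1.0,NA,NA
Actb,SYN_000010.1,376,,60,1.0,NA,NA
", stringsAsFactors = FALSE)
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

random_cds <- function(n_cod, sec_idx) {
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")), 1, paste, collapse = ""),
                   c("TAA", "TAG", "TGA"))
  cod <- sample(sense, n_cod - 2L, replace = TRUE)
  body <- c("ATG", cod)
  body[sec_idx + 1L] <- "TGA"   # 0-based codon index -> 1-based element
  paste(c(body, "TAA"), collapse = "")
}

random_nt <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                               collapse = "")

#' Build the packaged synthetic transcriptome
#'
#' Deterministically generates random transcript sequences for the panel
#' genes: a 5' UTR, a CDS with the annotated Sec codons planted as UGA (and
#' no other in-frame stop), and a 3' UTR. The same `build_seed` always
#' yields the same sequences, independent of the caller's RNG state.
#'
#' @param panel gene table as from [selenoprotein_panel()]; the default
#'   concatenates the selenoprotein panel with [background_panel()].
#' @param utr5,utr3 UTR lengths in nt.
#' @param build_seed RNG seed for sequence construction.
#' @return a [transcript_set]
#' @export
selenoprotein_reference <- function(panel = rbind(selenoprotein_panel(),
                                                  background_panel()),
                                    utr5 = 60L, utr3 = 150L,
                                    build_seed = 104729L) {
  with_local_seed(build_seed, {
    sec_list <- parse_sec_codons(panel$sec, panel$accession)
    seqs <- character(nrow(panel))
    for (i in seq_len(nrow(panel))) {
      seqs[i] <- paste0(random_nt(utr5),
                        random_cds(panel$codons[i], sec_list[[i]]),
                        random_nt(utr3))
    }
    names(seqs) <- panel$accession
    anno <- data.frame(id = panel$accession, gene = panel$gene,
                       cds_start = utr5,
                       cds_end = utr5 + 3L * panel$codons,
                       sec_codons = panel$sec,
                       stringsAsFactors = FALSE)
    transcript_set(seqs, anno)
  })
}

#' Synthetic rRNA contaminant reference
#'
#' Two random sequences standing in for the cytoplasmic rRNAs; used both to
#' draw contaminant reads in the simulator and as the depletion reference in
#' read processing. Synthetic, not the real mouse rRNA repeat.
#'
#' @param build_seed RNG seed
#' @return named character vector of two sequences
#' @export
synthetic_rrna <- function(build_seed = 224737L) {
  with_local_seed(build_seed, {
    c(rRNA_18S_synthetic = random_nt(1870L),
      rRNA_28S_synthetic = random_nt(4730L))
  })
}

#' Tissue selenium concentrations under the two diets
#'
#' Measured tissue selenium means (+/- SEM, n = 3 animals) for liver, lung
#' and plasma under the 0 ppm and 0.1 ppm Se diets; units are ug/g for
#' tissues and ug/mL for plasma. Packaged from the study's reported
#' measurements; these are inputs to the dietary-response arithmetic, not
#' computed by this package.
#'
#' @return data.frame (tissue, diet, mean, sem, n, unit)
#' @export
tissue_selenium <- function() {
  path <- system.file("extdata", "tissue_selenium.tsv", package = "ribosec",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Fold difference in tissue selenium between diets
#'
#' @param tissue one of `"liver"`, `"lung"`, `"plasma"`
#' @return ratio of the Se-adequate (0.1 ppm) to Se-deficient (0 ppm) mean
#'   tissue selenium concentration
#' @export
tissue_selenium_fold <- function(tissue = "liver") {
  se <- tissue_selenium()
  se <- se[se$tissue == tissue, ]
  if (nrow(se) != 2) stop("unknown tissue: ", tissue)
  se$mean[se$diet == "0.1Se"] / se$mean[se$diet == "0Se"]
}
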