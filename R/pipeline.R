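#' Pipeline run configuration
#'
#' Assembles and validates the configuration for an end-to-end run. The
#' default configuration simulates the two-diet study on the packaged
#' synthetic selenoproteome; supplying a `samples` sheet with FASTQ/SAM
#' paths instead analyzes external libraries.
#'
#' @param outdir output directory.
#' @param seed integer seed for every stochastic stage.
#' @param reference NULL for the packaged synthetic transcriptome, or
#'   `list(fasta =, annotation =)` paths for [load_transcripts()].
#' @param rrna NULL for the packaged synthetic rRNA, or a FASTA path.
#' @param adapter 3' adapter sequence.
#' @param offset `"infer"` to estimate the A-site offset from the
#'   start-anchored metagene, or an integer nt.
#' @param which_sec Sec codon used to split 5'/3' windows ("first" or a
#'   0-based codon index).
#' @param footprint_length_range length filter for footprint libraries, nt.
#' @param simulate logical; when TRUE `sim` overrides are passed to
#'   [sim_config()].
#' @param sim named list of [sim_config()] overrides
#'   (e.g. `footprint_library_size`).
#' @param samples when `simulate = FALSE`: data.frame (sample_id, libtype
#'   "fp"/"rna", condition, replicate, path) of FASTQ (or SAM: `*.sam`)
#'   inputs.
#' @param conditions condition labels, denominator first.
#' @param de list of DE thresholds: cpm_threshold, min_samples,
#'   fold_threshold, fdr_threshold.
#' @return list of class `run_config`
#' @export
pipeline_config <- function(outdir = tempfile("ribosec_run_"),
                            seed = 1L,
                            reference = NULL,
                            rrna = NULL,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            offset = "infer",
                            which_sec = "first",
                            footprint_length_range = c(26L, 36L),
                            simulate = TRUE,
                            sim = list(),
                            samples = NULL,
                            conditions = c("0Se", "0.1Se"),
                            de = list()) {
  de_def <- list(cpm_threshold = 1, min_samples = 3L,
                 fold_threshold = 1.5, fdr_threshold = 0.05)
  de <- utils::modifyList(de_def, de)
  if (!simulate) {
    if (is.null(samples)) stop("samples sheet required when simulate = FALSE")
    need <- c("sample_id", "libtype", "condition", "replicate", "path")
    if (!all(need %in% names(samples)))
      stop("samples sheet needs columns: ", paste(need, collapse = ", "))
    missing <- samples$path[!file.exists(samples$path)]
    if (length(missing))
      stop("input files not found: ", paste(missing, collapse = ", "))
  }
  if (!identical(offset, "infer")) offset <- as.integer(offset)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 reference = reference, rrna = rrna, adapter = adapter,
                 offset = offset, which_sec = which_sec,
                 footprint_length_range = footprint_length_range,
                 simulate = simulate, sim = sim, samples = samples,
                 conditions = conditions, de = de),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file
#' @param config run_config
#' @return a `run_config` (read) or `path` (write)
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$samples)) y$samples <- as.data.frame(y$samples)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  if (!is.null(y$samples)) y$samples <- as.list(y$samples)
  yaml::write_yaml(y, path)
  invisible(path)
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> process -> qc -> quant -> de -> report. Each
#' stage logs per-sample read counts; re-running with the same configuration
#' and seed reproduces every output table. Errors abort with the stage name
#' after writing a partial manifest.
#'
#' @param config [pipeline_config()] or path to its YAML serialization
#' @param stages subset of stages to run (earlier results are reloaded from
#'   `outdir` when a prerequisite stage is skipped)
#' @return result bundle (invisible list): transcript set, windows,
#'   alignments, processing stats, offset, QC tables, quantifications, fold
#'   changes, readthrough ratios, DE tables, simulation truth (if
#'   simulated), and output paths.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "process", "qc", "quant",
                                    "de", "report")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  on.exit(write_manifest(res, config), add = TRUE)

  res$ts <- stage_try("reference", {
    ts <- if (is.null(config$reference)) selenoprotein_reference() else
      load_transcripts(config$reference$fasta, config$reference$annotation)
    reduce_to_longest_isoform(ts)
  })
  res$windows <- make_windows(res$ts, config$which_sec)
  rrna <- if (is.null(config$rrna)) synthetic_rrna() else
    as_ref_seqs(config$rrna)

  reads <- NULL
  if ("simulate" %in% stages && config$simulate) {
    sim_out <- stage_try("simulate", {
      args <- utils::modifyList(
        list(ts = res$ts, conditions = config$conditions, rrna = rrna,
             adapter = config$adapter, seed = config$seed), config$sim)
      cfg <- do.call(sim_config, args)
      fastq_dir <- file.path(config$outdir, "fastq")
      fp <- simulate_footprints(cfg, outdir = fastq_dir)
      rna <- simulate_rnaseq(cfg, outdir = fastq_dir)
      list(fp = fp, rna = rna, cfg = cfg)
    })
    res$truth <- rbind(cbind(libtype = "fp", sim_out$fp$truth),
                       cbind(libtype = "rna", sim_out$rna$truth))
    reads <- c(sim_out$fp$reads, sim_out$rna$reads)
    res$samples <- rbind(cbind(sim_out$fp$samples, libtype = "fp"),
                         cbind(sim_out$rna$samples, libtype = "rna"))
  } else if (!config$simulate) {
    res$samples <- config$samples
  }

  if ("process" %in% stages) {
    proc <- stage_try("process", {
      aln <- list(); stats <- list()
      for (i in seq_len(nrow(res$samples))) {
        sid <- res$samples$sample_id[i]
        libtype <- res$samples$libtype[i]
        lr <- if (libtype == "fp") config$footprint_length_range else NULL
        input <- if (!is.null(reads)) reads[[sid]] else res$samples$path[i]
        a <- if (is.character(input) && length(input) == 1 &&
                 grepl("\\.sam$|\\.bam$", input, ignore.case = TRUE)) {
          import_alignments_sam(input, res$ts, sample_id = sid)
        } else {
          process_reads(input, res$ts, adapter = config$adapter, rrna = rrna,
                        length_range = lr, sample_id = sid)
        }
        st <- attr(a, "stats")
        if (!is.null(st))
          stats[[sid]] <- data.frame(sample_id = sid, stage = names(st),
                                     reads = as.integer(st))
        aln[[sid]] <- a
      }
      list(aln = data.table::rbindlist(aln), stats = data.table::rbindlist(stats))
    })
    res$alignments <- proc$aln
    res$stats <- proc$stats
    write_alignments(res$alignments, file.path(config$outdir, "alignments.tsv"))
    utils::write.table(res$samples[, setdiff(names(res$samples), "path")],
                       file.path(config$outdir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(res$stats))
      utils::write.table(res$stats, file.path(config$outdir, "processing_stats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    res$alignments <- read_alignments(file.path(config$outdir, "alignments.tsv"))
    res$samples <- utils::read.delim(file.path(config$outdir, "samples.tsv"),
                                     stringsAsFactors = FALSE)
  }

  fp_ids <- res$samples$sample_id[res$samples$libtype == "fp"]
  fp_aln <- res$alignments[res$alignments$sample_id %in% fp_ids, ]

  if ("qc" %in% stages) {
    stage_try("qc", {
      res$metagene_start <- metagene_profile(fp_aln, res$ts, "start")
      res$metagene_stop <- metagene_profile(fp_aln, res$ts, "stop")
      res$offset <- if (identical(config$offset, "infer"))
        infer_asite_offset(res$metagene_start) else config$offset
      res$phasing <- phasing_summary(fp_aln, res$ts,
                                     asite_offset = res$offset)
    })
  } else {
    res$offset <- if (identical(config$offset, "infer")) 16L else config$offset
  }

  if ("quant" %in% stages) {
    stage_try("quant", {
      gene_map <- stats::setNames(res$ts$anno$gene, res$ts$anno$id)
      quants <- list()
      for (sid in res$samples$sample_id) {
        a <- res$alignments[res$alignments$sample_id == sid, ]
        if (!nrow(a)) next
        prof <- apply_offset(a, res$ts, res$offset)
        quants[[sid]] <- quantify_windows(prof, res$windows, total_mapped(a),
                                          sample_id = sid)
      }
      res$quant <- do.call(rbind, quants)
      rna_ids <- res$samples$sample_id[res$samples$libtype == "rna"]
      qs <- function(ids, label) {
        q <- res$quant[res$quant$sample_id %in% ids & res$quant$label == label, ]
        q[!is.na(q$rpkm) | TRUE, ]
      }
      res$fold_rna_cds <- fold_change(qs(rna_ids, "cds_core"), res$samples,
                                      numerator = config$conditions[2],
                                      denominator = config$conditions[1],
                                      gene_map = gene_map)
      res$fold_fp_3prime <- fold_change(qs(fp_ids, "three_prime_of_sec"),
                                        res$samples,
                                        numerator = config$conditions[2],
                                        denominator = config$conditions[1],
                                        gene_map = gene_map)
      res$readthrough <- readthrough_ratio(
        res$quant[res$quant$sample_id %in% fp_ids, ], gene_map = gene_map)
    })
  }

  if ("de" %in% stages) {
    stage_try("de", {
      res$de <- list()
      res$replicate_correlation <- list()
      for (lt in unique(res$samples$libtype)) {
        ids <- res$samples$sample_id[res$samples$libtype == lt]
        if (length(ids) < config$de$min_samples) next
        a <- res$alignments[res$alignments$sample_id %in% ids, ]
        dt <- data.table::as.data.table(a)[, .N, by = c("sample_id", "transcript_id")]
        mat <- data.table::dcast(dt, transcript_id ~ sample_id,
                                 value.var = "N", fill = 0L)
        m <- as.matrix(mat[, -1]); rownames(m) <- mat$transcript_id
        gene_map <- stats::setNames(res$ts$anno$gene, res$ts$anno$id)
        rownames(m) <- unname(gene_map[rownames(m)])
        sheet <- res$samples[res$samples$sample_id %in% ids, ]
        ct <- count_table(m[, sheet$sample_id, drop = FALSE], sheet)
        res$de[[lt]] <- de_analysis(ct,
                                    numerator = config$conditions[2],
                                    denominator = config$conditions[1],
                                    cpm_threshold = config$de$cpm_threshold,
                                    min_samples = config$de$min_samples,
                                    fold_threshold = config$de$fold_threshold,
                                    fdr_threshold = config$de$fdr_threshold)
        res$replicate_correlation[[lt]] <- replicate_correlation(ct)
      }
    })
  }

  if ("report" %in% stages) {
    stage_try("report", {
      tabs <- make_figure_tables(res)
      for (nm in names(tabs))
        utils::write.table(tabs[[nm]],
                           file.path(config$outdir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(res$metagene_start)) {
        utils::write.table(res$metagene_start,
                           file.path(config$outdir, "metagene_start.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(res$metagene_stop,
                           file.path(config$outdir, "metagene_stop.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(res$phasing,
                           file.path(config$outdir, "phasing.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Result tables in the layout of the study's figures
#'
#' One table per panel: per-gene RNA RPKM fold changes with
#' propagation-of-error SDs, per-gene 3'-of-Sec footprint RPKM fold changes
#' (genes whose Sec windows are not analyzable are listed in the manifest
#' but absent here), per-sample readthrough ratios, and ranked top
#' up/down differential-expression tables per library type.
#'
#' @param res result bundle from [run_pipeline()]
#' @return named list of data.frames
#' @export
make_figure_tables <- function(res) {
  if (is.null(res$fold_rna_cds) || is.null(res$fold_fp_3prime))
    stop("quantification results missing; run the 'quant' stage first")
  tabs <- list()
  tabs$fig_rna_fold <- res$fold_rna_cds[res$fold_rna_cds$flag == "ok",
                                        c("gene", "fold", "fold_sd")]
  f3 <- res$fold_fp_3prime
  tabs$fig_3rpkm_fold <- f3[f3$flag == "ok", c("gene", "fold", "fold_sd")]
  tabs$readthrough <- res$readthrough
  for (lt in names(res$de %||% list())) {
    de <- res$de[[lt]]
    top <- rbind(utils::head(de[de$is_de & de$fold > 1, ], 18),
                 utils::tail(de[de$is_de & de$fold < 1, ], 18))
    tabs[[paste0("top_de_", lt)]] <- top
  }
  tabs
}

write_manifest <- function(res, config) {
  man <- list(
    package_version = as.character(utils::packageVersion("ribosec")),
    seed = config$seed,
    offset_nt = res$offset,
    conditions = config$conditions,
    n_transcripts = if (!is.null(res$ts)) length(res$ts) else NULL,
    not_analyzable = if (!is.null(res$windows)) {
      w <- res$windows
      unique(w$transcript_id[!w$analyzable & w$label != "cds_core"])
    } else NULL,
    read_conservation = if (!is.null(res$stats) && nrow(res$stats)) {
      s <- as.data.frame(res$stats)
      lapply(split(s, s$sample_id), function(d)
        stats::setNames(as.list(d$reads), d$stage))
    } else NULL)
  yaml::write_yaml(man, file.path(config$outdir, "manifest.yaml"))
  invisible(man)
}
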