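#' Assemble and validate a transcript set
#'
#' A `transcript_set` is the coordinate backbone of the pipeline: transcript
#' sequences together with CDS boundaries and the positions of UGA codons
#' recoded to selenocysteine (Sec). All coordinates are 0-based; nucleotide
#' intervals are half-open and codon indices count from the start codon
#' (codon 0 = AUG), so the "first 15 codons" of a coding sequence are codon
#' indices 0-14.
#'
#' Sec annotation is taken from the annotation table, never inferred from the
#' sequence: UGA is also the opal stop codon, and only curation can tell a
#' Sec codon from a terminator.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of
#'   transcript sequences (A/C/G/T/N), names = accessions.
#' @param anno data.frame with columns `id`, `gene`, `cds_start`, `cds_end`
#'   (0-based, half-open on nucleotides) and `sec_codons`, a comma-separated
#'   string (or list column) of 0-based codon indices relative to the start
#'   codon; empty for non-selenoproteins.
#' @return An object of class `transcript_set` with elements `seqs`
#'   (DNAStringSet), `anno` (data.frame) and `sec` (named list of integer
#'   vectors).
#' @export
transcript_set <- function(seqs, anno) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  stopifnot(methods::is(seqs, "DNAStringSet"))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("transcript sequences must carry unique names")
  req <- c("id", "gene", "cds_start", "cds_end")
  if (!all(req %in% names(anno)))
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  anno <- as.data.frame(anno, stringsAsFactors = FALSE)
  if (anyDuplicated(anno$id)) stop("duplicated accession in annotation")
  missing <- setdiff(anno$id, names(seqs))
  if (length(missing))
    stop("no sequence for annotated accession(s): ", paste(missing, collapse = ", "))
  seqs <- seqs[anno$id]
  sec <- parse_sec_codons(anno$sec_codons, anno$id)
  anno$sec_codons <- NULL
  obj <- structure(list(seqs = seqs, anno = anno, sec = sec),
                   class = "transcript_set")
  validate_transcripts(obj)
  obj
}

parse_sec_codons <- function(x, ids) {
  if (is.null(x)) x <- rep("", length(ids))
  out <- if (is.list(x)) {
    lapply(x, function(v) sort(unique(as.integer(v))))
  } else {
    lapply(as.character(x), function(s) {
      s <- trimws(s)
      if (is.na(s) || s == "" || s == ".") return(integer(0))
      sort(unique(as.integer(strsplit(s, ",")[[1]])))
    })
  }
  names(out) <- ids
  out
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts (%d with annotated Sec codons)\n",
              nrow(x$anno), sum(lengths(x$sec) > 0)))
  invisible(x)
}

#' @export
length.transcript_set <- function(x) nrow(x$anno)

#' @export
`[.transcript_set` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$anno$id)
  structure(list(seqs = x$seqs[i], anno = x$anno[i, , drop = FALSE],
                 sec = x$sec[i]),
            class = "transcript_set")
}

#' Number of codons in a CDS, including the stop codon
#' @param ts transcript_set
#' @param id accession (default: all)
#' @return integer vector
#' @export
n_codons <- function(ts, id = ts$anno$id) {
  a <- ts$anno[match(id, ts$anno$id), ]
  as.integer((a$cds_end - a$cds_start) / 3L)
}

validate_transcripts <- function(ts) {
  a <- ts$anno
  len <- Biostrings::width(ts$seqs)
  for (i in seq_len(nrow(a))) {
    id <- a$id[i]
    cl <- a$cds_end[i] - a$cds_start[i]
    if (a$cds_start[i] < 0 || cl <= 0 || cl %% 3L != 0L)
      stop(sprintf("%s: CDS length %d is not a positive multiple of 3", id, cl))
    if (len[i] < a$cds_end[i])
      stop(sprintf("%s: sequence length %d < cds_end %d", id, len[i], a$cds_end[i]))
    nc <- cl %/% 3L
    for (s in ts$sec[[id]]) {
      if (s < 0 || s >= nc - 1L)
        stop(sprintf("%s: Sec codon index %d not strictly within the CDS (stop codon index %d)",
                     id, s, nc - 1L))
      cod <- as.character(Biostrings::subseq(ts$seqs[[id]],
                                             a$cds_start[i] + 3L * s + 1L,
                                             a$cds_start[i] + 3L * s + 3L))
      if (cod != "TGA")
        stop(sprintf("%s: annotated Sec codon %d reads %s, expected TGA", id, s, cod))
    }
  }
  invisible(ts)
}

#' Load reference transcripts from FASTA plus an annotation table
#'
#' Records failing validation (CDS length not a multiple of 3, annotated Sec
#' index that is not a UGA triplet, sequence shorter than the CDS) are
#' rejected; by default rejection is an error naming the record, with
#' `on_invalid = "drop"` invalid records are dropped and reported via a
#' `"rejected"` attribute.
#'
#' @param fasta path to a transcript FASTA file, or a DNAStringSet.
#' @param annotation path to a TSV with columns
#'   `id, gene, cds_start, cds_end, sec_codons`, or a data.frame.
#' @param on_invalid `"error"` (default) or `"drop"`.
#' @return a [transcript_set]; with `on_invalid = "drop"`, attribute
#'   `rejected` is a data.frame of (id, reason).
#' @export
load_transcripts <- function(fasta, annotation, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  seqs <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta))
    Biostrings::readDNAStringSet(fasta) else Biostrings::DNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  anno <- if (is.data.frame(annotation)) annotation else
    utils::read.delim(annotation, stringsAsFactors = FALSE,
                      colClasses = c(sec_codons = "character"))
  if (on_invalid == "error") return(transcript_set(seqs, anno))
  keep <- logical(nrow(anno)); reason <- character(nrow(anno))
  for (i in seq_len(nrow(anno))) {
    res <- tryCatch({
      transcript_set(seqs[intersect(anno$id[i], names(seqs))],
                     anno[i, , drop = FALSE])
      NA_character_
    }, error = function(e) conditionMessage(e))
    keep[i] <- is.na(res)
    reason[i] <- if (is.na(res)) "" else res
  }
  ts <- transcript_set(seqs[anno$id[keep]], anno[keep, , drop = FALSE])
  attr(ts, "rejected") <- data.frame(id = anno$id[!keep],
                                     reason = reason[!keep],
                                     stringsAsFactors = FALSE)
  ts
}

#' Keep a single entry per gene: the longest isoform
#'
#' Mirrors the reduction of a RefSeq transcript FASTA to one representative
#' mRNA per gene symbol, retaining the isoform with maximal sequence length.
#' Ties are broken by accession order for determinism. Idempotent.
#'
#' @param ts transcript_set
#' @return transcript_set with one transcript per gene symbol
#' @export
reduce_to_longest_isoform <- function(ts) {
  if (length(ts) == 0) return(ts)
  len <- Biostrings::width(ts$seqs)
  ord <- order(ts$anno$gene, -len, ts$anno$id)
  first <- ord[!duplicated(ts$anno$gene[ord])]
  ts[sort(first)]
}

codon_window <- function(transcript_id, first_codon, last_codon, label,
                         cds_start) {
  data.frame(transcript_id = transcript_id,
             label = label,
             first_codon = as.integer(first_codon),
             last_codon = as.integer(last_codon),
             start_nt = as.integer(cds_start + 3L * first_codon),
             end_nt = as.integer(cds_start + 3L * (last_codon + 1L)),
             stringsAsFactors = FALSE)
}

#' CDS-core codon window
#'
#' The coding-sequence window used for CDS-level quantification, excluding
#' the first 15 and the last 3 codons (the stop codon and the two sense
#' codons preceding it) to avoid bias at initiation and termination.
#'
#' @param ts transcript_set
#' @param id accession
#' @return one-row data.frame (transcript_id, label, first_codon, last_codon,
#'   start_nt, end_nt); codon indices inclusive, nucleotide interval
#'   half-open.
#' @export
make_cds_core_window <- function(ts, id) {
  i <- match(id, ts$anno$id)
  if (is.na(i)) stop("unknown transcript: ", id)
  nc <- n_codons(ts, id)
  first <- 15L
  last <- nc - 1L - 3L          # stop codon index minus 3
  if (last < first)
    stop(sprintf("%s: CDS of %d codons too short for the core window", id, nc))
  codon_window(id, first, last, "cds_core", ts$anno$cds_start[i])
}

#' Codon windows flanking a UGA-Sec codon
#'
#' Ribosome density 5' of the Sec codon is quantified from codon 15 up to the
#' sixth codon preceding the UGA-Sec (i.e. the 5 codons immediately upstream
#' are excluded along with the first 15 codons of the CDS); density 3' of the
#' Sec codon is quantified from the second codon following the UGA-Sec to the
#' third codon preceding the stop codon. The UGA-Sec codon itself and its
#' exclusion flanks belong to neither window.
#'
#' A window that would be empty (Sec codon too close to the start, or to the
#' stop as for C-terminal Sec selenoproteins) is flagged not analyzable
#' rather than returned with inverted coordinates.
#'
#' @param ts transcript_set
#' @param id accession
#' @param which_sec which annotated Sec codon to split around: `"first"`
#'   (default, the 5'-most) or a 0-based codon index present in the
#'   transcript's Sec annotation.
#' @return two-row data.frame with labels `five_prime_of_sec` and
#'   `three_prime_of_sec` and a logical column `analyzable`.
#' @export
make_sec_windows <- function(ts, id, which_sec = "first") {
  i <- match(id, ts$anno$id)
  if (is.na(i)) stop("unknown transcript: ", id)
  secs <- ts$sec[[id]]
  if (!length(secs)) stop(id, " has no annotated Sec codon")
  sec <- if (identical(which_sec, "first")) secs[1] else {
    which_sec <- as.integer(which_sec)
    if (!which_sec %in% secs)
      stop(sprintf("%s: codon %d is not an annotated Sec codon", id, which_sec))
    which_sec
  }
  nc <- n_codons(ts, id)
  stop_idx <- nc - 1L
  cs <- ts$anno$cds_start[i]
  five <- c(15L, sec - 6L)
  three <- c(sec + 2L, stop_idx - 3L)
  mk <- function(b, label) {
    ok <- b[1] <= b[2]
    w <- codon_window(id, if (ok) b[1] else NA_integer_,
                      if (ok) b[2] else NA_integer_, label, cs)
    if (!ok) w$start_nt <- w$end_nt <- NA_integer_
    w$sec_codon <- sec
    w$analyzable <- ok
    w
  }
  rbind(mk(five, "five_prime_of_sec"), mk(three, "three_prime_of_sec"))
}

#' All quantification windows for a transcript set
#'
#' @param ts transcript_set
#' @param which_sec passed to [make_sec_windows()]
#' @return data.frame of windows (CDS core for every transcript long enough;
#'   Sec flank windows for every selenoprotein transcript), with an
#'   `analyzable` column. Transcripts whose CDS is too short for the core
#'   window get a non-analyzable `cds_core` row.
#' @export
make_windows <- function(ts, which_sec = "first") {
  out <- list()
  for (id in ts$anno$id) {
    core <- tryCatch(make_cds_core_window(ts, id), error = function(e) NULL)
    if (is.null(core)) {
      core <- codon_window(id, NA_integer_, NA_integer_, "cds_core",
                           ts$anno$cds_start[match(id, ts$anno$id)])
      core$start_nt <- core$end_nt <- NA_integer_
    }
    core$sec_codon <- NA_integer_
    core$analyzable <- !is.na(core$first_codon)
    out[[length(out) + 1L]] <- core
    if (length(ts$sec[[id]]))
      out[[length(out) + 1L]] <- make_sec_windows(ts, id, which_sec)
  }
  do.call(rbind, out)
}

#' Write windows as a BED-like TSV (0-based, half-open)
#' @param windows data.frame from [make_windows()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_windows_bed <- function(windows, path) {
  w <- windows[windows$analyzable, c("transcript_id", "start_nt", "end_nt", "label")]
  utils::write.table(w, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a validated transcript set
#'
#' Writes the sequences as FASTA and the annotation (with Sec codon indices
#' re-encoded as a comma-separated column) as TSV, the same formats
#' [load_transcripts()] reads.
#'
#' @param ts transcript_set
#' @param fasta,annotation output paths
#' @return invisibly, c(fasta, annotation)
#' @export
write_transcripts <- function(ts, fasta, annotation) {
  Biostrings::writeXStringSet(ts$seqs, fasta)
  a <- ts$anno
  a$sec_codons <- vapply(ts$sec[a$id], paste, "", collapse = ",")
  utils::write.table(a, annotation, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta, annotation))
}
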