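#' Read a FASTQ file into a character vector of sequences
#'
#' @param path FASTQ file, optionally gzipped.
#' @return character vector of read sequences, names = read ids.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads as FASTQ
#'
#' @param reads character vector of sequences; names become read ids
#'   (autogenerated if absent).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param quality single quality character replicated across each read.
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path, quality = "I") {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%08d", seq_along(reads))
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- ids
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep(quality, n), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Remove 3' sequencing adapters
#'
#' Each read is truncated at the first occurrence of the adapter: a full
#' adapter match anywhere in the read, or a match of at least `min_overlap`
#' nt between an adapter prefix and the read's 3' end (the adapter running
#' off the end of the sequencing window). Reads shorter than `min_length`
#' after trimming are discarded.
#'
#' @param reads character vector of read sequences
#' @param adapter adapter sequence (5' portion is what appears in reads)
#' @param min_overlap minimum adapter prefix match at the read end, nt
#' @param min_length post-trim length floor, nt
#' @return character vector of retained trimmed reads; attribute `n_discarded`
#'   counts reads dropped by the length floor.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L, min_length = 15L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  L <- nchar(reads)
  cut <- rep(Inf, length(reads))                 # 1-based position of adapter start
  full <- regexpr(adapter, reads, fixed = TRUE)
  hit <- full > 0
  cut[hit] <- full[hit]
  # partial adapter prefix at the read 3' end; longer overlaps cut earlier
  for (ov in seq(min(nchar(adapter) - 1L, max(L) - 1L), min_overlap)) {
    if (ov < min_overlap) break
    pref <- substr(adapter, 1L, ov)
    cand <- which(L >= ov & (L - ov + 1L) < cut)
    if (!length(cand)) next
    m <- substr(reads[cand], L[cand] - ov + 1L, L[cand]) == pref
    cut[cand[m]] <- L[cand[m]] - ov + 1L
  }
  trimmed <- reads
  fin <- is.finite(cut)
  trimmed[fin] <- substr(reads[fin], 1L, cut[fin] - 1L)
  keep <- nchar(trimmed) >= min_length
  out <- trimmed[keep]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Deplete rRNA-matching reads
#'
#' Any read with at least one alignment to the rRNA reference at
#' `max_mismatch` or fewer mismatches is removed; all unaligned reads are
#' retained.
#'
#' @param reads character vector of read sequences
#' @param rrna rRNA reference: named character vector, DNAStringSet, or FASTA
#'   path
#' @param max_mismatch mismatch ceiling for calling an rRNA hit
#' @return retained reads; attribute `n_removed`.
#' @export
filter_rrna <- function(reads, rrna, max_mismatch = 2L) {
  if (is.null(rrna)) stop("an rRNA reference is required for depletion")
  refs <- as_ref_seqs(rrna)
  if (!length(reads)) {
    out <- reads; attr(out, "n_removed") <- 0L; return(out)
  }
  u <- unique(unname(reads))
  res <- align_hamming_cpp(u, unname(refs), max_mm = as.integer(max_mismatch))
  hit <- (res$n_best > 0L)[match(unname(reads), u)]
  out <- reads[!hit]
  attr(out, "n_removed") <- sum(hit)
  out
}

as_ref_seqs <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(stats::setNames(as.character(x), names(x)))
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    s <- Biostrings::readDNAStringSet(x)
    names(s) <- sub("\\s.*$", "", names(s))
    return(stats::setNames(as.character(s), names(s)))
  }
  if (is.character(x)) return(x)
  stop("cannot interpret reference sequences")
}

#' Uniquely align reads to a transcript set
#'
#' Forward-strand Hamming alignment with at most `max_mismatch` mismatches.
#' A read is reported iff it has exactly one alignment position across all
#' transcripts within its minimal-mismatch stratum; reads with several
#' equally good positions are dropped as multi-mappers, reads with no
#' position at or under the mismatch ceiling as unaligned. The result is
#' invariant to read input order (alignments are returned sorted).
#'
#' @param reads character vector of read sequences
#' @param ts [transcript_set] (or named character vector of sequences)
#' @param max_mismatch mismatch ceiling (default 2)
#' @param length_range optional c(min, max) read-length filter applied before
#'   alignment (e.g. `c(26, 36)` for ribosome footprints); reads outside it
#'   are counted as length-filtered.
#' @param sample_id optional sample label stored in the output.
#' @return data.table (sample_id, transcript_id, pos5, length, mismatches),
#'   one row per uniquely aligned read, sorted; attribute `stats` is a named
#'   integer vector (n_input, n_length_filtered, n_aligned, n_multi,
#'   n_unaligned) satisfying input = length_filtered + aligned + multi +
#'   unaligned.
#' @export
align_unique <- function(reads, ts, max_mismatch = 2L, length_range = NULL,
                         sample_id = NA_character_) {
  refs <- if (inherits(ts, "transcript_set"))
    stats::setNames(as.character(ts$seqs), ts$anno$id) else as_ref_seqs(ts)
  n_input <- length(reads)
  reads <- unname(reads)
  n_lenfilt <- 0L
  if (!is.null(length_range)) {
    L <- nchar(reads)
    keep <- L >= length_range[1] & L <= length_range[2]
    n_lenfilt <- sum(!keep)
    reads <- reads[keep]
  }
  if (!length(reads)) {
    out <- empty_alignments()
    attr(out, "stats") <- c(n_input = n_input, n_length_filtered = n_lenfilt,
                            n_aligned = 0L, n_multi = 0L, n_unaligned = 0L)
    return(out)
  }
  u <- unique(reads)
  res <- align_hamming_cpp(u, unname(refs), max_mm = as.integer(max_mismatch))
  i <- match(reads, u)
  tid <- res$tid[i]; nbest <- res$n_best[i]
  unique_hit <- nbest == 1L
  out <- data.table::data.table(
    sample_id = sample_id,
    transcript_id = names(refs)[tid[unique_hit]],
    pos5 = res$pos[i][unique_hit],
    length = nchar(reads[unique_hit]),
    mismatches = res$mismatches[i][unique_hit])
  data.table::setorder(out, transcript_id, pos5, length, mismatches)
  attr(out, "stats") <- c(n_input = n_input, n_length_filtered = n_lenfilt,
                          n_aligned = sum(unique_hit),
                          n_multi = sum(nbest > 1L),
                          n_unaligned = sum(nbest == 0L))
  out
}

empty_alignments <- function() {
  data.table::data.table(sample_id = character(), transcript_id = character(),
                         pos5 = integer(), length = integer(),
                         mismatches = integer())
}

#' Full read-processing chain for one library
#'
#' Adapter trimming, optional footprint length selection, rRNA depletion and
#' unique alignment, with a per-stage read-count ledger.
#'
#' @param reads character vector of read sequences (or FASTQ path)
#' @param ts [transcript_set]
#' @param adapter adapter sequence; `NULL` skips trimming
#' @param rrna rRNA reference; `NULL` skips depletion
#' @param length_range length filter, e.g. `c(26, 36)` for footprints;
#'   `NULL` for RNA-Seq
#' @param max_mismatch mismatch ceiling
#' @param sample_id sample label
#' @return alignments as from [align_unique()]; `stats` attribute gains
#'   `n_trim_discarded` and `n_rrna_removed`.
#' @export
process_reads <- function(reads, ts, adapter = NULL, rrna = NULL,
                          length_range = NULL, max_mismatch = 2L,
                          sample_id = NA_character_) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fastq(reads)
  n_trim <- 0L; n_rrna <- 0L
  if (!is.null(adapter)) {
    reads <- trim_adapter(reads, adapter)
    n_trim <- attr(reads, "n_discarded")
  }
  if (!is.null(rrna)) {
    reads <- filter_rrna(reads, rrna, max_mismatch = max_mismatch)
    n_rrna <- attr(reads, "n_removed")
  }
  out <- align_unique(reads, ts, max_mismatch = max_mismatch,
                      length_range = length_range, sample_id = sample_id)
  s <- attr(out, "stats")
  attr(out, "stats") <- c(n_trim_discarded = n_trim, n_rrna_removed = n_rrna, s)
  out
}

#' Import transcript-space alignments from SAM/BAM
#'
#' Scale path for externally aligned libraries: reads a SAM or BAM whose
#' reference names match the transcript set, keeps forward-strand
#' single-locus records, and returns them in the package's alignment layout.
#' Requires the Rsamtools package.
#'
#' @param path SAM or BAM file (transcript coordinates)
#' @param ts [transcript_set]; reference names are checked against it
#' @param sample_id sample label
#' @return data.table as from [align_unique()]
#' @export
import_alignments_sam <- function(path, ts, sample_id = NA_character_) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required for SAM/BAM import")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "strand", "qwidth"),
                               flag = Rsamtools::scanBamFlag(
                                 isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE))
  a <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- a$strand == "+"
  rn <- as.character(a$rname[keep])
  unknown <- setdiff(unique(rn), ts$anno$id)
  if (length(unknown))
    stop("alignment references absent from the transcript set: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  out <- data.table::data.table(sample_id = sample_id,
                                transcript_id = rn,
                                pos5 = a$pos[keep] - 1L,
                                length = a$qwidth[keep],
                                mismatches = NA_integer_)
  data.table::setorder(out, transcript_id, pos5, length)
  out
}

#' Write / read the sorted alignment TSV
#' @param alignments data.table from [align_unique()]
#' @param path TSV path
#' @return `path` (write) or the alignments (read)
#' @export
write_alignments <- function(alignments, path) {
  data.table::fwrite(alignments, path, sep = "\t")
  invisible(path)
}

#' @rdname write_alignments
#' @export
read_alignments <- function(path) {
  data.table::fread(path, sep = "\t",
                    colClasses = list(character = c("sample_id", "transcript_id")))
}
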