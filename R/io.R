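# Reading and writing the external formats: FASTA/FASTQ read libraries,
# transcript and genome FASTA, BED6/GFF3 transcript loci, and the TSV
# alignment tables that downstream stages exchange.

ALN_HEADER <- "# pirnanet_alignments v1"

normalize_seqs <- function(seqs, path) {
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  w <- nchar(seqs)
  if (any(w == 0)) {
    bad <- which(w == 0)[1]
    stop(sprintf("parse error in '%s': record %d has no sequence", path, bad),
         call. = FALSE)
  }
  bad <- grep("[^ACGTN]", seqs)
  if (length(bad)) {
    stop(sprintf("parse error in '%s': record %d contains characters outside A/C/G/T/U/N",
                 path, bad[1]), call. = FALSE)
  }
  seqs
}

#' Load a small-RNA read library from FASTA or FASTQ
#'
#' Each record becomes one read with `count = 1` (a non-collapsed library).
#' Sequences are uppercased and U is converted to T, so RNA-alphabet input
#' is accepted. Quality strings are ignored.
#'
#' @param path path to the reads file
#' @param format `"auto"` (by file extension), `"fasta"` or `"fastq"`
#' @return data.frame with columns `id`, `seq`, `count`, `length`
#' @export
load_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (!file.exists(path)) stop(sprintf("reads file not found: '%s'", path), call. = FALSE)
  if (file.size(path) == 0) {
    warning(sprintf("reads file '%s' is empty; returning zero reads", path))
    return(data.frame(id = character(0), seq = character(0),
                      count = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop(sprintf("parse error in '%s' (%s format): %s",
                                     path, format, conditionMessage(e)), call. = FALSE)
  )
  seqs <- normalize_seqs(as.character(x), path)
  ids <- sub("\\s.*$", "", names(x))
  data.frame(id = ids, seq = unname(seqs), count = 1L,
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Load transcripts from FASTA
#'
#' @param path FASTA file of transcript sequences
#' @param kind transcript class, recycled over records: one of `"mRNA"`,
#'   `"lncRNA"`, `"unannotated"`
#' @return data.frame with columns `id`, `seq`, `kind`, `length`
#' @export
load_transcripts <- function(path, kind = "mRNA") {
  stopifnot(all(kind %in% c("mRNA", "lncRNA", "unannotated")))
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop(sprintf("parse error in '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  seqs <- normalize_seqs(as.character(x), path)
  out <- data.frame(id = sub("\\s.*$", "", names(x)), seq = unname(seqs),
                    kind = rep_len(kind, length(x)), length = nchar(seqs),
                    stringsAsFactors = FALSE)
  stopifnot_transcripts(out)
  out
}

#' Load a genome from FASTA
#'
#' @param path FASTA file; one record per chromosome/contig
#' @return named character vector of chromosome sequences
#' @export
load_genome <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- normalize_seqs(as.character(x), path)
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Load transcript genomic loci from BED6 or GFF3
#'
#' BED input (0-based half-open) is converted to the 1-based inclusive
#' coordinates used throughout the package; GFF3 is read as 1-based
#' inclusive. The transcript id is taken from the BED name column or the
#' GFF3 `ID` attribute.
#'
#' @param path a `.bed`, `.gff3` or `.gff` file
#' @return data.frame with columns `id`, `chrom`, `start`, `end`, `strand`
#' @export
load_transcript_loci <- function(path) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED" else "GFF3"
  gr <- rtracklayer::import(path, format = if (fmt == "BED") "BED" else "GFF3")
  ids <- if (fmt == "BED") gr$name else {
    if (!is.null(gr$ID)) gr$ID else gr$Name
  }
  if (is.null(ids) || any(is.na(ids)))
    stop(sprintf("'%s': every locus needs a name/ID attribute", path), call. = FALSE)
  df <- as.data.frame(gr)
  data.frame(
    id = as.character(ids),
    chrom = as.character(df$seqnames),
    start = df$start,
    end = df$end,
    strand = as.character(df$strand),
    stringsAsFactors = FALSE
  )
}

#' Write an alignment table to TSV
#'
#' The file carries a version line followed by a named column header, so
#' it can be re-read safely by [read_alignments()].
#'
#' @param alignments alignment data.frame (see [map_exact()])
#' @param path output path
#' @export
write_alignments <- function(alignments, path) {
  need <- c("read_id", "transcript_id", "strand", "five_prime", "mismatches")
  miss <- setdiff(need, names(alignments))
  if (length(miss)) stop("alignments lack column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(ALN_HEADER, con)
  utils::write.table(alignments[, union(need, names(alignments))], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an alignment table written by [write_alignments()]
#' @param path TSV path
#' @return alignment data.frame
#' @export
read_alignments <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, ALN_HEADER))
    stop(sprintf("'%s' is not a pirnanet alignment table (expected header '%s', found '%s')",
                 path, ALN_HEADER, first), call. = FALSE)
  out <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                           stringsAsFactors = FALSE, comment.char = "")
  need <- c("read_id", "transcript_id", "strand", "five_prime", "mismatches")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop(sprintf("'%s' is missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  out
}

#' Write named sequences as FASTA
#' @param seqs named character vector
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Write a read library as FASTQ, one record per copy
#'
#' Reads with `count > 1` are expanded into numbered copies
#' (`id/1`, `id/2`, ...) so the emitted library is non-collapsed. A
#' constant placeholder quality is used.
#'
#' @param reads reads data.frame
#' @param path output path
#' @export
write_reads_fastq <- function(reads, path) {
  stopifnot_reads(reads)
  n <- sum(reads$count)
  ids <- character(n)
  seqs <- character(n)
  k <- 0L
  for (i in seq_len(nrow(reads))) {
    cnt <- reads$count[i]
    idx <- k + seq_len(cnt)
    ids[idx] <- if (cnt == 1L) reads$id[i] else paste0(reads$id[i], "/", seq_len(cnt))
    seqs[idx] <- reads$seq[i]
    k <- k + cnt
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(w)
    paste(rep("I", w), collapse = ""), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}
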