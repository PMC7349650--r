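# Exact transcript mapping, the mismatch-tolerant reverse-complement
# target scan, and genome multiplicity. Coordinates are 1-based inclusive
# on transcripts; a sense read's five_prime is its lowest covered
# coordinate, an antisense read's five_prime is its highest.

# Build a PDict over variable-width read sequences. Exact matching with a
# trusted band of the minimum read width is lossless at max.mismatch = 0:
# head/tail residues outside the band are still required to match exactly.
build_pdict <- function(seqs) {
  ss <- Biostrings::DNAStringSet(seqs)
  w <- Biostrings::width(ss)
  if (length(unique(w)) == 1L) Biostrings::PDict(ss)
  else Biostrings::PDict(ss, tb.start = 1L, tb.width = min(w))
}

#' Map reads exactly to transcripts, both orientations
#'
#' Reports every exact (0-mismatch) occurrence of each read on each
#' transcript, sense and antisense. A read occurring at several sites
#' yields several alignment records. Reads containing N are skipped (N
#' never matches anything) and counted in a message.
#'
#' @param reads reads data.frame (`id`, `seq`, `count`)
#' @param transcripts transcripts data.frame (`id`, `seq`)
#' @return data.frame with columns `read_id`, `transcript_id`, `strand`
#'   (`"sense"`/`"antisense"`), `five_prime`, `mismatches` (all 0)
#' @export
map_exact <- function(reads, transcripts) {
  stopifnot_reads(reads)
  stopifnot_transcripts(transcripts)
  keep <- !grepl("N", reads$seq, fixed = TRUE)
  if (any(!keep))
    message(sum(!keep), " read(s) containing N skipped by the exact mapper")
  reads <- reads[keep, , drop = FALSE]
  if (!nrow(reads) || !nrow(transcripts)) return(empty_alignments())

  uniq <- unique(reads$seq)
  ids_by_seq <- split(reads$id, factor(reads$seq, levels = uniq))
  widths <- nchar(uniq)
  pd_f <- build_pdict(uniq)
  pd_r <- build_pdict(revcomp(uniq))

  out <- vector("list", 2L * nrow(transcripts))
  k <- 0L
  for (j in seq_len(nrow(transcripts))) {
    subj <- Biostrings::DNAString(transcripts$seq[j])
    st <- Biostrings::startIndex(Biostrings::matchPDict(pd_f, subj, max.mismatch = 0))
    hit <- which(lengths(st) > 0)
    if (length(hit)) {
      rows <- lapply(hit, function(i) {
        ids <- ids_by_seq[[i]]
        starts <- st[[i]]
        data.frame(read_id = rep(ids, each = length(starts)),
                   transcript_id = transcripts$id[j], strand = "sense",
                   five_prime = rep(starts, times = length(ids)),
                   mismatches = 0L, stringsAsFactors = FALSE)
      })
      k <- k + 1L; out[[k]] <- do.call(rbind, rows)
    }
    en <- Biostrings::endIndex(Biostrings::matchPDict(pd_r, subj, max.mismatch = 0))
    hit <- which(lengths(en) > 0)
    if (length(hit)) {
      rows <- lapply(hit, function(i) {
        ids <- ids_by_seq[[i]]
        ends <- en[[i]]
        data.frame(read_id = rep(ids, each = length(ends)),
                   transcript_id = transcripts$id[j], strand = "antisense",
                   five_prime = rep(ends, times = length(ids)),
                   mismatches = 0L, stringsAsFactors = FALSE)
      })
      k <- k + 1L; out[[k]] <- do.call(rbind, rows)
    }
  }
  if (k == 0L) return(empty_alignments())
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

# Hamming mismatch count of `pattern` against every window of `subject`
# of the same width. N never matches anything, including N.
mismatch_profile <- function(pattern, subject) {
  L <- nchar(pattern)
  n <- nchar(subject) - L + 1L
  if (n < 1L) return(integer(0))
  p <- charToRaw(pattern)
  s <- charToRaw(subject)
  rawN <- charToRaw("N")
  mm <- integer(n)
  for (i in seq_len(L)) {
    if (p[i] == rawN) {
      mm <- mm + 1L
    } else {
      seg <- s[i:(i + n - 1L)]
      mm <- mm + as.integer(seg != p[i] | seg == rawN)
    }
  }
  mm
}

# positions (window coordinates) where pattern and window disagree
mm_window_positions <- function(pattern, window) {
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  which(p != w | p == "N" | w == "N")
}

#' Mismatch-tolerant reverse-complement target search
#'
#' Finds every window of each target whose Hamming distance to the
#' reverse complement of a query lies within `[min_mm, max_mm]` — i.e.
#' every site where the query could anneal antisense to the target with
#' that many mispaired bases. Ungapped comparison at every offset
#' (substitutions only). Mismatch positions are reported in query
#' coordinates, position 1 being the query's 5' nucleotide.
#'
#' @param query_reads reads data.frame (or character vector of sequences)
#' @param target_transcripts transcripts data.frame
#' @param min_mm,max_mm inclusive mismatch bounds; `0 <= min_mm <= max_mm`
#'   and `max_mm` at most the query length minus one
#' @return data.frame with columns `read_id`, `transcript_id`, `strand`
#'   (always `"antisense"`), `five_prime` (highest covered target
#'   coordinate), `start`, `end`, `mismatches`, `mm_query_pos`
#'   (comma-separated query positions, `""` for none)
#' @export
search_rc_mismatched <- function(query_reads, target_transcripts, min_mm, max_mm) {
  if (is.character(query_reads)) {
    ids <- if (length(query_reads)) paste0("q", seq_along(query_reads))
           else character(0)
    query_reads <- data.frame(id = ids, seq = query_reads,
                              count = rep(1L, length(query_reads)),
                              stringsAsFactors = FALSE)
  }
  stopifnot_reads(query_reads)
  stopifnot_transcripts(target_transcripts)
  empty_sites <- data.frame(read_id = character(0), transcript_id = character(0),
                            strand = character(0), five_prime = integer(0),
                            start = integer(0), end = integer(0),
                            mismatches = integer(0), mm_query_pos = character(0),
                            stringsAsFactors = FALSE)
  if (!nrow(query_reads)) return(empty_sites)
  if (any(nchar(query_reads$seq) < 10))
    stop("queries shorter than 10 nt cannot define slicing geometry", call. = FALSE)
  if (!(min_mm >= 0 && min_mm <= max_mm))
    stop("need 0 <= min_mm <= max_mm", call. = FALSE)
  if (max_mm > min(nchar(query_reads$seq)) - 1L)
    stop("max_mm must be at most the query length minus one", call. = FALSE)

  uniq <- unique(query_reads$seq)
  ids_by_seq <- split(query_reads$id, factor(query_reads$seq, levels = uniq))
  rcq <- revcomp(uniq)

  out <- list()
  k <- 0L
  for (j in seq_len(nrow(target_transcripts))) {
    tseq <- target_transcripts$seq[j]
    for (i in seq_along(uniq)) {
      L <- nchar(uniq[i])
      mm <- mismatch_profile(rcq[i], tseq)
      w <- which(mm >= min_mm & mm <= max_mm)
      if (!length(w)) next
      pos_str <- vapply(w, function(s) {
        wp <- mm_window_positions(rcq[i], substr(tseq, s, s + L - 1L))
        paste(sort(L - wp + 1L), collapse = ",")
      }, "")
      ids <- ids_by_seq[[i]]
      nrep <- length(w)
      k <- k + 1L
      out[[k]] <- data.frame(
        read_id = rep(ids, each = nrep),
        transcript_id = target_transcripts$id[j],
        strand = "antisense",
        five_prime = rep(w + L - 1L, times = length(ids)),
        start = rep(w, times = length(ids)),
        end = rep(w + L - 1L, times = length(ids)),
        mismatches = rep(mm[w], times = length(ids)),
        mm_query_pos = rep(pos_str, times = length(ids)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (k == 0L) return(empty_sites)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genomic multiplicity of read sequences
#'
#' Counts exact occurrences of each distinct read sequence in the genome,
#' both strands. A sequence with multiplicity 1 is "genome-unique";
#' multiplicity 0 marks an extra-genomic read. Reads containing N get 0.
#'
#' @param reads reads data.frame or character vector of sequences
#' @param genome named character vector of chromosome sequences
#' @return named integer vector, one entry per distinct sequence
#' @export
genome_multiplicity <- function(reads, genome) {
  seqs <- if (is.character(reads)) reads else {
    stopifnot_reads(reads); reads$seq
  }
  uniq <- unique(seqs)
  mult <- setNames(integer(length(uniq)), uniq)
  ok <- !grepl("N", uniq, fixed = TRUE)
  if (any(ok) && length(genome)) {
    subj <- Biostrings::DNAStringSet(genome)
    pd_f <- build_pdict(uniq[ok])
    pd_r <- build_pdict(revcomp(uniq[ok]))
    cnt <- rowSums(Biostrings::vcountPDict(pd_f, subj, max.mismatch = 0)) +
      rowSums(Biostrings::vcountPDict(pd_r, subj, max.mismatch = 0))
    mult[uniq[ok]] <- as.integer(cnt)
  }
  mult
}

#' Genomic placements of genome-unique read sequences
#'
#' For every distinct read sequence that occurs exactly once in the
#' genome (both strands considered), reports where.
#'
#' @param reads reads data.frame or character vector of sequences
#' @param genome named character vector of chromosome sequences
#' @return data.frame with columns `seq`, `chrom`, `start`, `end`, `strand`
#' @export
genome_unique_placements <- function(reads, genome) {
  seqs <- if (is.character(reads)) reads else {
    stopifnot_reads(reads); reads$seq
  }
  mult <- genome_multiplicity(seqs, genome)
  uniq <- names(mult)[mult == 1L]
  if (!length(uniq))
    return(data.frame(seq = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  pd_f <- build_pdict(uniq)
  pd_r <- build_pdict(revcomp(uniq))
  hits <- list()
  k <- 0L
  for (chrom in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chrom]])
    st <- Biostrings::startIndex(Biostrings::matchPDict(pd_f, subj, max.mismatch = 0))
    for (i in which(lengths(st) > 0)) {
      k <- k + 1L
      hits[[k]] <- data.frame(seq = uniq[i], chrom = chrom, start = st[[i]],
                              end = st[[i]] + nchar(uniq[i]) - 1L, strand = "+",
                              stringsAsFactors = FALSE)
    }
    st <- Biostrings::startIndex(Biostrings::matchPDict(pd_r, subj, max.mismatch = 0))
    for (i in which(lengths(st) > 0)) {
      k <- k + 1L
      hits[[k]] <- data.frame(seq = uniq[i], chrom = chrom, start = st[[i]],
                              end = st[[i]] + nchar(uniq[i]) - 1L, strand = "-",
                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, hits)
  rownames(res) <- NULL
  res
}
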