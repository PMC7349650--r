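# Producing the analysis read set: size selection, bona fide filtering
# against structural RNAs, collapsing, multiplicity, RPM normalization and
# seeded random assignment of multi-mapping reads.

#' Size-select putative piRNAs
#'
#' piRNAs occupy the 24-29 nt band of the small-RNA length distribution;
#' shorter reads are dominated by miRNAs.
#'
#' @param reads reads data.frame
#' @param min_len,max_len inclusive length bounds (defaults 24 and 29 nt)
#' @return the subset of `reads` within the bounds
#' @export
select_by_length <- function(reads, min_len = 24, max_len = 29) {
  stopifnot_reads(reads)
  if (min_len > max_len)
    stop("config error: min_len must not exceed max_len", call. = FALSE)
  len <- nchar(reads$seq)
  out <- reads[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load a structural-RNA reference set
#'
#' The class of each reference (miRNA, rRNA, snRNA, tRNA) is inferred
#' from its FASTA header when possible, otherwise `"structural"`.
#'
#' @param path FASTA of structural RNA sequences
#' @return data.frame with columns `id`, `seq`, `class`
#' @export
load_structural_refs <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- normalize_seqs(as.character(x), path)
  ids <- sub("\\s.*$", "", names(x))
  cls <- rep("structural", length(ids))
  for (type in c("miRNA", "rRNA", "snRNA", "tRNA"))
    cls[grepl(type, ids, ignore.case = TRUE)] <- type
  data.frame(id = ids, seq = unname(seqs), class = cls, stringsAsFactors = FALSE)
}

#' Remove reads matching structural RNAs (bona fide filter)
#'
#' A read is removed when it matches any structural reference exactly
#' (0 mismatches), in either orientation. Removal counts per structural
#' class are attached as the `"removed_by_class"` attribute and reported
#' in a message.
#'
#' @param reads reads data.frame
#' @param structural_refs data.frame from [load_structural_refs()], or
#'   `NULL` (pass-through with a prominent warning)
#' @return the retained (bona fide) subset of `reads`
#' @export
bona_fide_filter <- function(reads, structural_refs = NULL) {
  stopifnot_reads(reads)
  if (is.null(structural_refs) || !nrow(structural_refs)) {
    warning("no structural-RNA reference set supplied: ",
            "bona fide filtering skipped, all reads retained", call. = FALSE)
    return(reads)
  }
  if (!nrow(reads)) return(reads)
  uniq <- unique(reads$seq)
  ok <- !grepl("N", uniq, fixed = TRUE)
  hit_class <- matrix(FALSE, nrow = length(uniq),
                      ncol = length(unique(structural_refs$class)),
                      dimnames = list(uniq, unique(structural_refs$class)))
  if (any(ok)) {
    subj <- Biostrings::DNAStringSet(structural_refs$seq)
    pd_f <- build_pdict(uniq[ok])
    pd_r <- build_pdict(revcomp(uniq[ok]))
    cnt <- Biostrings::vcountPDict(pd_f, subj, max.mismatch = 0) +
      Biostrings::vcountPDict(pd_r, subj, max.mismatch = 0)
    for (cl in colnames(hit_class)) {
      cols <- which(structural_refs$class == cl)
      hit_class[uniq[ok], cl] <- rowSums(cnt[, cols, drop = FALSE]) > 0
    }
  }
  removed_seq <- rownames(hit_class)[rowSums(hit_class) > 0]
  keep <- !(reads$seq %in% removed_seq)
  per_class <- vapply(colnames(hit_class), function(cl)
    sum(reads$count[reads$seq %in% rownames(hit_class)[hit_class[, cl]]]), 0)
  if (any(!keep))
    message("bona fide filter removed ", sum(reads$count[!keep]), " read copies (",
            paste(sprintf("%s: %d", names(per_class), as.integer(per_class)),
                  collapse = ", "), ")")
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_by_class") <- per_class
  out
}

#' Collapse a read library to distinct sequences
#'
#' All identical reads are reduced to one record whose `count` is the
#' summed number of copies; the total copy count is preserved. The id of
#' the first occurrence is kept as representative.
#'
#' @param reads reads data.frame
#' @return collapsed reads data.frame with pairwise-distinct `seq`
#' @export
collapse_reads <- function(reads) {
  stopifnot_reads(reads)
  if (!nrow(reads)) return(reads)
  first <- !duplicated(reads$seq)
  counts <- tapply(reads$count, factor(reads$seq, levels = reads$seq[first]), sum)
  out <- reads[first, , drop = FALSE]
  out$count <- as.integer(counts)
  out$length <- nchar(out$seq)
  rownames(out) <- NULL
  stopifnot(sum(out$count) == sum(reads$count))
  out
}

#' Library multiplicity: non-collapsed over collapsed count
#' @param reads reads data.frame (non-collapsed or with counts)
#' @return ratio of total copies to distinct sequences
#' @export
library_multiplicity <- function(reads) {
  stopifnot_reads(reads)
  n_distinct <- length(unique(reads$seq))
  if (n_distinct == 0) return(NA_real_)
  sum(reads$count) / n_distinct
}

#' Reads per million genome-mapped reads
#'
#' The denominator is the number of reads of the whole library that map
#' the genome with zero mismatches — one single denominator for every
#' per-transcript figure in the pipeline.
#'
#' @param count read copies (vectorized)
#' @param total_genome_mapped 0-mismatch genome-mapped copies of the library
#' @return `count * 1e6 / total_genome_mapped`
#' @export
rpm <- function(count, total_genome_mapped) {
  if (!isTRUE(total_genome_mapped > 0))
    stop("RPM denominator is zero: run genome mapping first ",
         "(genome_multiplicity) to obtain the genome-mapped total", call. = FALSE)
  count * 1e6 / total_genome_mapped
}

#' Randomly assign multi-mapping reads to single sites
#'
#' Each copy of a read is assigned uniformly at random among the read's
#' mapped sites; genome-unique reads always go to their single site. The
#' assignment is deterministic under a fixed seed and should be computed
#' once and cached so all downstream stages agree.
#'
#' @param alignments alignment data.frame (one row per site)
#' @param reads reads data.frame providing per-read copy `count`
#' @param seed integer RNG seed
#' @return list with `assigned` (the alignment rows plus an
#'   `assigned_count` column holding the copies given to each site) and
#'   `unmapped` (ids of reads with no site)
#' @export
assign_multimappers <- function(alignments, reads, seed) {
  stopifnot_reads(reads)
  counts <- setNames(reads$count, reads$id)
  mapped_ids <- intersect(reads$id, unique(alignments$read_id))
  unmapped <- setdiff(reads$id, mapped_ids)
  if (!length(mapped_ids)) {
    out <- alignments[0, , drop = FALSE]
    out$assigned_count <- integer(0)
    return(list(assigned = out, unmapped = unmapped))
  }
  aln <- alignments[alignments$read_id %in% mapped_ids, , drop = FALSE]
  # stable order: by read id then site, so the RNG stream is reproducible
  ord <- order(aln$read_id, aln$transcript_id, aln$strand, aln$five_prime)
  aln <- aln[ord, , drop = FALSE]
  idx_by_read <- split(seq_len(nrow(aln)), aln$read_id)
  assigned <- integer(nrow(aln))
  with_seed(seed, {
    for (id in names(idx_by_read)) {
      idx <- idx_by_read[[id]]
      n <- counts[[id]]
      if (length(idx) == 1L) {
        assigned[idx] <- n
      } else {
        assigned[idx] <- as.integer(stats::rmultinom(1, n, rep(1, length(idx))))
      }
    }
  })
  aln$assigned_count <- assigned
  rownames(aln) <- NULL
  list(assigned = aln, unmapped = unmapped)
}

#' Summarise a read library through the filtering stages
#'
#' @param total_reads copies in the raw library
#' @param total_genome_mapped 0-mismatch genome-mapped copies (RPM denominator)
#' @param bona_fide reads data.frame after length selection and the bona
#'   fide filter
#' @return list with the headline library tallies, including the
#'   non-collapsed/collapsed multiplicity ratio
#' @export
library_summary <- function(total_reads, total_genome_mapped, bona_fide) {
  collapsed <- length(unique(bona_fide$seq))
  list(
    total_reads = total_reads,
    total_genome_mapped = total_genome_mapped,
    bona_fide_count = sum(bona_fide$count),
    collapsed_count = collapsed,
    multiplicity = if (collapsed > 0) sum(bona_fide$count) / collapsed else NA_real_
  )
}
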