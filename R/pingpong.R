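# Per-transcript ping-pong signature: the 5'-overlap histogram between
# sense and antisense piRNAs, its bin-10 z-score and significance call,
# 1U/10A base biases, ping-pong partner extraction, TE/repeat attribution
# and the resulting transcript classification.

#' 5'-position weight vector for one strand of one transcript
#'
#' @param alignments alignment rows for a single transcript and strand
#' @param weights named numeric vector of per-read weights (copies for a
#'   non-collapsed profile, 1 per distinct sequence for a collapsed one);
#'   defaults to weight 1 per alignment row
#' @return named numeric vector, names = transcript 5' positions
#' @export
five_prime_weights <- function(alignments, weights = NULL) {
  if (!nrow(alignments)) return(setNames(numeric(0), character(0)))
  w <- if (is.null(weights)) rep(1, nrow(alignments))
       else unname(weights[alignments$read_id])
  tab <- tapply(w, alignments$five_prime, sum)
  setNames(as.numeric(tab), names(tab))
}

#' Sense/antisense 5'-overlap histogram
#'
#' `counts[d]` is the number of sense/antisense read pairs whose 5' ends
#' overlap by exactly `d` nt, i.e. whose 5' positions satisfy
#' `antisense_5p - sense_5p + 1 == d`. Computed as the weighted product
#' over shared positions; the window is fixed at `d = 1..dmax`. Only
#' non-negative overlaps consistent with slicer geometry are counted
#' (an antisense 5' upstream of the sense 5' is not).
#'
#' @param sense,antisense named numeric vectors of per-position read
#'   weight, as from [five_prime_weights()]
#' @param dmax largest overlap tallied (24 nt: the maximal overlap
#'   possible for all 24-29 nt piRNAs)
#' @return numeric vector of length `dmax`, names `"1".."dmax"`
#' @export
overlap_pair_counts <- function(sense, antisense, dmax = 24) {
  counts <- numeric(dmax)
  names(counts) <- seq_len(dmax)
  if (length(sense) && length(antisense)) {
    sp <- as.integer(names(sense))
    ap <- as.integer(names(antisense))
    for (d in seq_len(dmax)) {
      idx <- match(sp + d - 1L, ap)
      ok <- !is.na(idx)
      if (any(ok)) counts[d] <- sum(sense[ok] * antisense[idx[ok]])
    }
  }
  counts
}

#' z-score of a signal bin against the full histogram
#'
#' The bin of interest is compared with the mean and population standard
#' deviation of all bins, itself included. A zero standard deviation
#' (all bins equal, e.g. all zero) is a degenerate case: the z-score is
#' undefined and the profile can never be called significant.
#'
#' @param counts histogram vector (bins `1..length(counts)`)
#' @param signal_bin index of the bin of interest
#' @return list with `z` (NA when degenerate) and `degenerate`
#' @export
signature_z <- function(counts, signal_bin) {
  s <- pop_sd(counts)
  if (s == 0) return(list(z = NA_real_, degenerate = TRUE))
  list(z = (counts[[signal_bin]] - mean(counts)) / s, degenerate = FALSE)
}

#' Ping-pong z-score: bin 10 of the 1-24 nt overlap histogram
#' @param counts overlap histogram of length 24
#' @return list with `z` and `degenerate` (see [signature_z()])
#' @export
pingpong_z <- function(counts) {
  stopifnot(length(counts) == 24)
  signature_z(counts, 10L)
}

#' Ping-pong significance call
#'
#' Significant when the bin-10 z-score exceeds 1.96 (strictly) and the
#' total number of overlapping pairs in the 1-24 window is at least 30.
#'
#' @param z10 bin-10 z-score (NA for a degenerate histogram)
#' @param total_pairs sum of the overlap histogram
#' @param z_thresh z cut-off, default 1.96
#' @param min_pairs pair floor, default 30
#' @return logical
#' @export
call_significance <- function(z10, total_pairs, z_thresh = 1.96, min_pairs = 30) {
  !is.na(z10) && z10 > z_thresh && total_pairs >= min_pairs
}

#' 1U and 10A base signatures
#'
#' Percentage of reads carrying T (DNA for U) at position 1 and A at
#' position 10, weighted by `weights` when given (copies for the
#' non-collapsed figure; leave NULL with one row per distinct sequence
#' for the collapsed figure).
#'
#' @param seqs character vector of read sequences (>= 10 nt)
#' @param weights optional numeric weights, same length as `seqs`
#' @return list with `pct1U` and `pct10A` (NA on empty input)
#' @export
base_signature <- function(seqs, weights = NULL) {
  if (!length(seqs)) return(list(pct1U = NA_real_, pct10A = NA_real_))
  w <- if (is.null(weights)) rep(1, length(seqs)) else weights
  list(pct1U = pct_of(substr(seqs, 1, 1) == "T", w),
       pct10A = pct_of(substr(seqs, 10, 10) == "A", w))
}

#' Is a base-bias percentage "biased"?
#'
#' Strict: exactly 50% is not biased.
#'
#' @param pct percentage in `[0, 100]` (NA allowed)
#' @param threshold default 50
#' @return logical
#' @export
is_biased <- function(pct, threshold = 50) !is.na(pct) & pct > threshold

#' Flag reads having a ping-pong partner at exactly 10-nt 5'-overlap
#'
#' A sense read at 5' position p has a partner when some antisense read's
#' 5' sits at p + 9, and vice versa.
#'
#' @param alignments alignment rows for a single transcript
#' @return `alignments` with an added logical `has_partner` column
#' @export
pingpong_partners <- function(alignments) {
  out <- alignments
  sense_p <- unique(alignments$five_prime[alignments$strand == "sense"])
  anti_p <- unique(alignments$five_prime[alignments$strand == "antisense"])
  out$has_partner <- ifelse(
    alignments$strand == "sense",
    (alignments$five_prime + 9L) %in% anti_p,
    (alignments$five_prime - 9L) %in% sense_p
  )
  out
}

#' Does each sequence match a reference set within a mismatch budget?
#'
#' Ungapped scan of every offset of every reference, both orientations.
#'
#' @param seqs character vector of read sequences
#' @param refs character vector of reference sequences (e.g. a TE library)
#' @param max_mm largest Hamming distance accepted (default 3, the usual
#'   TE-matching tolerance for piRNAs)
#' @return logical vector along `seqs`
#' @export
matches_reference <- function(seqs, refs, max_mm = 3) {
  vapply(seqs, function(s) {
    for (ref in refs) {
      if (nchar(ref) < nchar(s)) next
      if (any(mismatch_profile(s, ref) <= max_mm)) return(TRUE)
      if (any(mismatch_profile(revcomp(s), ref) <= max_mm)) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

#' TE and genomic-repeat attribution of ping-pong reads
#'
#' Among the reads that have a ping-pong partner: the percentage matching
#' any TE at up to `te_max_mm` mismatches (either orientation), and the
#' percentage mapping repeated genomic sequence (multiplicity >= 2).
#'
#' @param pp_reads reads data.frame of ping-pong-partner reads
#' @param te_seqs character vector of TE sequences, or NULL (TE figure NA)
#' @param multiplicity named integer vector from [genome_multiplicity()]
#' @param te_max_mm mismatch tolerance for TE matching (default 3)
#' @return list with `pct_pp_te` and `pct_pp_repeat`
#' @export
te_and_repeat_attribution <- function(pp_reads, te_seqs, multiplicity,
                                      te_max_mm = 3) {
  if (!nrow(pp_reads))
    return(list(pct_pp_te = NA_real_, pct_pp_repeat = NA_real_))
  w <- pp_reads$count
  pct_te <- if (is.null(te_seqs)) NA_real_ else {
    uniq <- unique(pp_reads$seq)
    hit <- setNames(matches_reference(uniq, te_seqs, max_mm = te_max_mm), uniq)
    pct_of(hit[pp_reads$seq], w)
  }
  rep_flag <- multiplicity[pp_reads$seq] >= 2L
  list(pct_pp_te = pct_te, pct_pp_repeat = pct_of(rep_flag, w))
}

#' Classify a transcript by its ping-pong profile
#'
#' `noPP` without a significant 10-nt overlap signature; otherwise
#' `uniquePP` when more than 95% of its ping-pong reads are genome-unique
#' (intrinsic amplification from a single locus), else `repeatPP`.
#'
#' @param significant logical significance call
#' @param pct_unique_pp percentage of ping-pong reads that are genome-unique
#' @param unique_thresh default 95
#' @return one of `"noPP"`, `"uniquePP"`, `"repeatPP"`
#' @export
classify_transcript <- function(significant, pct_unique_pp, unique_thresh = 95) {
  if (!isTRUE(significant)) return("noPP")
  if (!is.na(pct_unique_pp) && pct_unique_pp > unique_thresh) "uniquePP" else "repeatPP"
}

#' Trans-ping-pong scan: mismatched external partners of a transcript
#'
#' Searches external (genome-unique, elsewhere-mapping) piRNAs against a
#' transcript in a reverse-complementary manner with mismatches, and keeps
#' annealing sites whose 5' stands at the 10-nt overlap distance from a
#' sense read's 5' on that transcript — sites where an external piRNA
#' could have guided the slicing that made the sense read.
#'
#' @param transcript one-row transcripts data.frame
#' @param external_reads reads data.frame of external piRNAs
#' @param sense_alignments sense alignment rows on `transcript`
#' @param min_mm,max_mm mismatch bounds (default 1-5)
#' @return annealing-site data.frame (see [search_rc_mismatched()]) with
#'   an added `cleavage_pos` column
#' @export
trans_pingpong_scan <- function(transcript, external_reads, sense_alignments,
                                min_mm = 1, max_mm = 5) {
  if (!nrow(external_reads)) {
    out <- search_rc_mismatched(character(0), transcript, min_mm, max_mm)
    out$cleavage_pos <- integer(0)
    return(out)
  }
  sites <- search_rc_mismatched(external_reads, transcript, min_mm, max_mm)
  sense_p <- unique(sense_alignments$five_prime[sense_alignments$strand == "sense"])
  keep <- (sites$five_prime - 9L) %in% sense_p
  out <- sites[keep, , drop = FALSE]
  out$cleavage_pos <- out$five_prime - 9L
  rownames(out) <- NULL
  out
}

# log-ratio of bona fide sense over antisense RPM with the 0.06
# pseudo-count convention on a zero side; NA when both sides are zero.
log_ratio_sense_antisense <- function(sense_rpm, antisense_rpm) {
  if (sense_rpm == 0 && antisense_rpm == 0) return(NA_real_)
  r <- if (sense_rpm == 0) (sense_rpm + 0.06) / antisense_rpm
  else if (antisense_rpm == 0) sense_rpm / (antisense_rpm + 0.06)
  else sense_rpm / antisense_rpm
  log(r)
}

#' Full ping-pong profile of one transcript
#'
#' Assembles the per-transcript figures: strand RPMs and their log-ratio,
#' the 5'-overlap histogram with its bin-10 z-score and significance
#' call, 1U/10A signatures for both strands on the non-collapsed and
#' collapsed read sets, genome-multiplicity breakdown, ping-pong-partner
#' percentages, TE/repeat attribution of the ping-pong reads, and the
#' transcript class.
#'
#' Pair counting uses read copies (the non-collapsed library) by default;
#' set `unit = "collapsed"` to weight each distinct sequence once. The
#' two units are never mixed within one profile.
#'
#' @param transcript_id id of the transcript profiled
#' @param alignments 0-mismatch alignment rows on this transcript
#' @param reads reads data.frame covering the aligned reads
#' @param multiplicity named vector from [genome_multiplicity()]
#' @param total_genome_mapped RPM denominator
#' @param te_seqs optional TE library (character vector)
#' @param unit `"noncollapsed"` (default) or `"collapsed"` pair counting
#' @param dmax overlap window (default 24)
#' @param z_thresh,min_pairs significance thresholds (1.96, 30)
#' @param te_max_mm TE-matching tolerance (3)
#' @return one-row data.frame of profile fields
#' @export
pingpong_profile <- function(transcript_id, alignments, reads, multiplicity,
                             total_genome_mapped, te_seqs = NULL,
                             unit = c("noncollapsed", "collapsed"),
                             dmax = 24, z_thresh = 1.96, min_pairs = 30,
                             te_max_mm = 3) {
  unit <- match.arg(unit)
  aln <- alignments[alignments$transcript_id == transcript_id, , drop = FALSE]
  reads_idx <- setNames(seq_len(nrow(reads)), reads$id)
  counts_by_id <- setNames(reads$count, reads$id)
  seq_by_id <- setNames(reads$seq, reads$id)

  sense <- aln[aln$strand == "sense", , drop = FALSE]
  anti <- aln[aln$strand == "antisense", , drop = FALSE]
  sense_copies <- sum(counts_by_id[unique(sense$read_id)])
  anti_copies <- sum(counts_by_id[unique(anti$read_id)])
  sense_rpm <- rpm(if (length(sense_copies)) sense_copies else 0, total_genome_mapped)
  antisense_rpm <- rpm(if (length(anti_copies)) anti_copies else 0, total_genome_mapped)

  pair_w <- if (unit == "noncollapsed") counts_by_id else {
    setNames(rep(1, nrow(reads)), reads$id)
  }
  hist_s <- five_prime_weights(sense, pair_w)
  hist_a <- five_prime_weights(anti, pair_w)
  counts <- overlap_pair_counts(hist_s, hist_a, dmax = dmax)
  total_pairs <- sum(counts)
  zres <- pingpong_z(counts)
  significant <- call_significance(zres$z, total_pairs, z_thresh, min_pairs)
  pct_overlap10 <- if (total_pairs > 0) 100 * counts[[10]] / total_pairs else NA_real_

  # base signatures per strand, non-collapsed (copy-weighted) and collapsed
  sig <- function(ids, collapsed) {
    ids <- unique(ids)
    if (!length(ids)) return(base_signature(character(0)))
    sq <- seq_by_id[ids]
    if (collapsed) {
      sq <- unique(sq)
      base_signature(sq)
    } else {
      base_signature(sq, counts_by_id[ids])
    }
  }
  s_nc <- sig(sense$read_id, FALSE); s_c <- sig(sense$read_id, TRUE)
  a_nc <- sig(anti$read_id, FALSE); a_c <- sig(anti$read_id, TRUE)

  # genome multiplicity of all mapped reads (copy-weighted)
  all_ids <- unique(aln$read_id)
  mult <- multiplicity[seq_by_id[all_ids]]
  w_all <- counts_by_id[all_ids]
  pct_unique <- pct_of(mult == 1L, w_all)
  pct_repeated <- pct_of(mult >= 2L, w_all)

  # ping-pong partners and attribution
  flagged <- pingpong_partners(aln)
  pp_ids_sense <- unique(flagged$read_id[flagged$strand == "sense" & flagged$has_partner])
  pp_ids_anti <- unique(flagged$read_id[flagged$strand == "antisense" & flagged$has_partner])
  pct_pp_sense <- pct_of(unique(sense$read_id) %in% pp_ids_sense,
                         counts_by_id[unique(sense$read_id)])
  pct_pp_anti <- pct_of(unique(anti$read_id) %in% pp_ids_anti,
                        counts_by_id[unique(anti$read_id)])
  pp_ids <- union(pp_ids_sense, pp_ids_anti)
  pp_reads <- reads[reads_idx[pp_ids], , drop = FALSE]
  attribution <- te_and_repeat_attribution(pp_reads, te_seqs, multiplicity,
                                           te_max_mm = te_max_mm)
  pct_unique_pp <- if (nrow(pp_reads))
    pct_of(multiplicity[pp_reads$seq] == 1L, pp_reads$count) else NA_real_
  class <- classify_transcript(significant, pct_unique_pp)

  out <- data.frame(
    transcript_id = transcript_id,
    n_sense = length(unique(sense$read_id)),
    n_antisense = length(unique(anti$read_id)),
    sense_rpm = sense_rpm, antisense_rpm = antisense_rpm,
    log_ratio_sense_antisense = log_ratio_sense_antisense(sense_rpm, antisense_rpm),
    total_pairs = total_pairs, count10 = counts[[10]],
    pct_overlap10 = pct_overlap10,
    z10 = zres$z, degenerate = zres$degenerate, significant = significant,
    pct1U_sense_nc = s_nc$pct1U, pct10A_sense_nc = s_nc$pct10A,
    pct1U_antisense_nc = a_nc$pct1U, pct10A_antisense_nc = a_nc$pct10A,
    pct1U_sense_coll = s_c$pct1U, pct10A_sense_coll = s_c$pct10A,
    pct1U_antisense_coll = a_c$pct1U, pct10A_antisense_coll = a_c$pct10A,
    pct_unique = pct_unique, pct_repeated = pct_repeated,
    pct_pp_partner_sense = pct_pp_sense, pct_pp_partner_antisense = pct_pp_anti,
    pct_pp_te = attribution$pct_pp_te, pct_pp_repeat = attribution$pct_pp_repeat,
    pct_unique_pp = pct_unique_pp,
    class = class,
    stringsAsFactors = FALSE
  )
  attr(out, "overlap_counts") <- counts
  out
}
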