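# Trigger-event inference: candidate-target selection, mismatch-tolerant
# trigger-site discovery, responder pairing by the 10-nt 5'-overlap rule,
# seed-mismatch profiling, trail/phasing detection and back-targeting
# classification. The slicer cuts its target between nucleotides 10 and
# 11 of the guide, so a trigger annealing with its 5' at target
# coordinate q creates responder 5' ends at q - 9 — even when base
# pairing only starts at guide position 2 or 3.

#' Select candidate target transcripts
#'
#' Transcripts matching strictly more than `min_rpm` RPM of genome-unique
#' sense-oriented piRNAs at zero mismatches.
#'
#' @param per_transcript data.frame with columns `transcript_id` and
#'   `unique_sense_rpm`
#' @param min_rpm threshold, default 3
#' @return character vector of transcript ids
#' @export
candidate_targets <- function(per_transcript, min_rpm = 3) {
  per_transcript$transcript_id[per_transcript$unique_sense_rpm > min_rpm]
}

#' Find trigger annealing sites on candidate targets
#'
#' Genome-unique transcript-derived piRNAs are aligned in a reverse
#' complementary manner, allowing `mm_range[1]` to `mm_range[2]`
#' mismatches, to the candidate targets. Sites on a query's own source
#' transcript(s) are excluded: a perfect self-match is trivial geometry,
#' not trans-targeting.
#'
#' @param trigger_reads reads data.frame of genome-unique query piRNAs
#' @param targets transcripts data.frame of candidate targets
#' @param sources data.frame with columns `read_id`, `transcript_id`
#'   naming each query's 0-mismatch sense source locus (or loci)
#' @param mm_range inclusive mismatch bounds, default `c(1, 5)`
#' @return annealing-site data.frame (see [search_rc_mismatched()])
#' @export
find_trigger_sites <- function(trigger_reads, targets, sources,
                               mm_range = c(1, 5)) {
  sites <- search_rc_mismatched(trigger_reads, targets, mm_range[1], mm_range[2])
  if (!nrow(sites)) return(sites)
  self_key <- paste(sources$read_id, sources$transcript_id)
  keep <- !(paste(sites$read_id, sites$transcript_id) %in% self_key)
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair responder piRNAs to a trigger annealing site
#'
#' The cleavage position implied by a site whose (antisense) 5' is at
#' target coordinate q is `q - 9`; responders are the sense 0-mismatch
#' reads whose 5' sits exactly there, giving the canonical 10-nt
#' 5'-overlap with the trigger.
#'
#' @param anneal_five_prime target coordinate of the trigger's 5' nt
#' @param sense_alignments sense 0-mm alignment rows on the target
#' @param reads reads data.frame (for counts, sequences)
#' @param multiplicity named vector from [genome_multiplicity()]
#' @param total_genome_mapped RPM denominator
#' @return list: `cleavage_pos`, `responder_ids`, `responder_rpm`,
#'   `responder_rpm_unique` (genome-unique responders only),
#'   `responder_pct1U`, `n_responders`
#' @export
pair_responders <- function(anneal_five_prime, sense_alignments, reads,
                            multiplicity, total_genome_mapped) {
  cleavage <- anneal_five_prime - 9L
  ids <- unique(sense_alignments$read_id[
    sense_alignments$strand == "sense" &
      sense_alignments$five_prime == cleavage])
  rr <- reads[reads$id %in% ids, , drop = FALSE]
  rpm_all <- rpm(sum(rr$count), total_genome_mapped)
  uniq <- multiplicity[rr$seq] == 1L
  rpm_uniq <- rpm(sum(rr$count[uniq]), total_genome_mapped)
  sig <- base_signature(rr$seq, rr$count)
  list(cleavage_pos = cleavage, responder_ids = ids,
       responder_rpm = rpm_all, responder_rpm_unique = rpm_uniq,
       responder_pct1U = sig$pct1U, n_responders = length(ids))
}

#' Seed-mismatch profile of a trigger annealing site
#'
#' The putative seed is trigger positions 2-11. Slicing tolerates
#' mismatches there, but the profile records them; a site with none is a
#' perfect-seed site.
#'
#' @param mm_query_pos mismatch positions in query coordinates (integer
#'   vector, or the comma-separated string stored in site tables)
#' @param seed_range seed positions, default `2:11`
#' @return list with `seed_mm_pos` (integer vector) and `perfect_seed`
#' @export
seed_profile <- function(mm_query_pos, seed_range = 2:11) {
  if (is.character(mm_query_pos)) {
    mm_query_pos <- if (!nzchar(mm_query_pos)) integer(0)
    else as.integer(strsplit(mm_query_pos, ",", fixed = TRUE)[[1]])
  }
  seed_mm <- sort(intersect(mm_query_pos, seed_range))
  list(seed_mm_pos = seed_mm, perfect_seed = length(seed_mm) == 0L)
}

#' Detect phased trail piRNAs downstream of a cleavage position
#'
#' Collects sense reads whose 5' lies in `(cleavage_pos, cleavage_pos +
#' window_nt]`, seeds the chain with the responder reads at the cleavage
#' position, and tallies head-to-tail distances `d = next_5' - prev_3'`
#' over `d = 1..bins`. Phased biogenesis shows up as enrichment at
#' `d = 1`, scored with the same z-statistic as the ping-pong bin (a
#' package-defined surrogate for the phasing call, labelled as such).
#'
#' @param cleavage_pos target coordinate of the responder 5'
#' @param transcript_len length of the target transcript
#' @param sense_alignments sense 0-mm alignment rows on the target
#' @param reads reads data.frame
#' @param total_genome_mapped RPM denominator
#' @param window_nt downstream window, default 1000
#' @param bins distance histogram width, default 50
#' @return list: `hist` (named vector `1..bins`), `z1`, `degenerate`,
#'   `trail_pct1U`, `trail_rpm`, `n_trail_reads`, `truncated`
#' @export
detect_trail <- function(cleavage_pos, transcript_len, sense_alignments, reads,
                         total_genome_mapped, window_nt = 1000, bins = 50) {
  truncated <- cleavage_pos + window_nt > transcript_len
  win_hi <- min(cleavage_pos + window_nt, transcript_len)
  sa <- sense_alignments[sense_alignments$strand == "sense", , drop = FALSE]
  len_by_id <- setNames(nchar(reads$seq), reads$id)
  cnt_by_id <- setNames(reads$count, reads$id)
  seq_by_id <- setNames(reads$seq, reads$id)

  chain <- sa[sa$five_prime >= cleavage_pos & sa$five_prime <= win_hi, , drop = FALSE]
  trail <- chain[chain$five_prime > cleavage_pos, , drop = FALSE]

  hist <- setNames(numeric(bins), seq_len(bins))
  if (nrow(chain) > 1) {
    p5 <- chain$five_prime
    p3 <- p5 + len_by_id[chain$read_id] - 1L
    starts <- sort(unique(p5))
    for (i in seq_len(nrow(chain))) {
      nxt <- starts[starts > p5[i]]
      if (!length(nxt)) next
      d <- nxt[1] - p3[i]
      if (d >= 1 && d <= bins) hist[d] <- hist[d] + 1
    }
  }
  zres <- if (nrow(trail)) signature_z(hist, 1L) else list(z = NA_real_, degenerate = TRUE)
  trail_ids <- unique(trail$read_id)
  sig <- base_signature(seq_by_id[trail_ids], cnt_by_id[trail_ids])
  list(hist = hist, z1 = zres$z, degenerate = zres$degenerate,
       trail_pct1U = sig$pct1U,
       trail_rpm = rpm(sum(cnt_by_id[trail_ids]), total_genome_mapped),
       n_trail_reads = length(trail_ids), truncated = truncated)
}

#' Classify back-targeting of an event's responders
#'
#' Responder piRNAs are searched reverse-complementarily (up to `max_mm`
#' mismatches) against the event's source transcript. A hit whose implied
#' cleavage position coincides with the original trigger read's 5' locus
#' would regenerate the trigger — trans-ping-pong amplification. A hit
#' elsewhere is a downstream/upstream back-target, reported with its
#' signed distance in nt from the trigger locus. No hit: `none`.
#'
#' @param responder_reads reads data.frame of the event's responders
#' @param source_transcript one-row transcripts data.frame (the trigger's
#'   source locus)
#' @param trigger_locus_5p the trigger read's sense 5' position on its
#'   source transcript
#' @param max_mm mismatch tolerance, default 5
#' @return list with `back_target` (`"trans_pingpong"`,
#'   `"downstream_backtarget"` or `"none"`) and `distance_nt` (signed;
#'   NA unless a back-target)
#' @export
classify_back_targeting <- function(responder_reads, source_transcript,
                                    trigger_locus_5p, max_mm = 5) {
  if (!nrow(responder_reads))
    return(list(back_target = "none", distance_nt = NA_real_))
  hits <- search_rc_mismatched(responder_reads, source_transcript, 0, max_mm)
  if (!nrow(hits))
    return(list(back_target = "none", distance_nt = NA_real_))
  implied <- hits$five_prime - 9L
  if (any(implied == trigger_locus_5p))
    return(list(back_target = "trans_pingpong", distance_nt = 0))
  d <- implied - trigger_locus_5p
  list(back_target = "downstream_backtarget",
       distance_nt = d[which.min(abs(d))])
}

#' Infer trigger events from a mapped, filtered read library
#'
#' End-to-end event inference: genome-unique reads that map mRNAs or
#' lncRNAs sense at 0 mismatches serve as trigger queries; candidate
#' targets are transcripts with more than `min_rpm_target` RPM of
#' genome-unique sense piRNAs; annealing sites within `mm_range`
#' mismatches are paired with responders by the 10-nt 5'-overlap rule;
#' events whose responder RPM exceeds `min_rpm_responder` are retained
#' and annotated with seed profile, trail phasing and back-target class.
#' Events sharing a target site and source are merged (their triggers
#' pooled). A read may be both responder and trigger; no exclusivity is
#' imposed.
#'
#' @param reads filtered reads data.frame
#' @param transcripts transcripts data.frame (with `kind`)
#' @param alignments 0-mm transcript alignments from [map_exact()]
#' @param multiplicity named vector from [genome_multiplicity()]
#' @param total_genome_mapped RPM denominator
#' @param min_rpm_target,min_rpm_responder RPM thresholds (both 3)
#' @param mm_range trigger-search mismatch bounds, default `c(1, 5)`
#' @param trail_window trail window in nt, default 1000
#' @param backtarget_max_mm tolerance for the back-target search (5)
#' @return data.frame of events, one row per (source, target, site);
#'   attribute `"trail_profiles"` holds the per-event phasing lists
#' @export
find_trigger_events <- function(reads, transcripts, alignments, multiplicity,
                                total_genome_mapped,
                                min_rpm_target = 3, min_rpm_responder = 3,
                                mm_range = c(1, 5), trail_window = 1000,
                                backtarget_max_mm = 5) {
  empty <- data.frame(
    event_id = character(0), source_transcript = character(0),
    target_transcript = character(0), anneal_five_prime = integer(0),
    anneal_start = integer(0), anneal_end = integer(0),
    mismatches = integer(0), mm_query_pos = character(0),
    seed_mm_pos = character(0), perfect_seed = logical(0),
    cleavage_pos = integer(0), n_responders = integer(0),
    responder_rpm = numeric(0), responder_rpm_unique = numeric(0),
    responder_pct1U = numeric(0), trail_rpm = numeric(0),
    n_trail_reads = integer(0), trail_z1 = numeric(0),
    trail_pct1U = numeric(0), back_target = character(0),
    back_target_distance = numeric(0), trigger_rpm = numeric(0),
    n_trigger_reads = integer(0), stringsAsFactors = FALSE)

  cnt_by_id <- setNames(reads$count, reads$id)
  seq_by_id <- setNames(reads$seq, reads$id)
  is_unique_read <- multiplicity[reads$seq] == 1L
  unique_ids <- reads$id[is_unique_read]

  sense0 <- alignments[alignments$strand == "sense" & alignments$mismatches == 0, ,
                       drop = FALSE]
  usense <- sense0[sense0$read_id %in% unique_ids, , drop = FALSE]

  # candidate targets: unique sense 0-mm RPM per transcript
  rpm_by_t <- tapply(cnt_by_id[usense$read_id[!duplicated(
    paste(usense$read_id, usense$transcript_id))]],
    usense$transcript_id[!duplicated(paste(usense$read_id, usense$transcript_id))],
    sum)
  per_t <- data.frame(transcript_id = names(rpm_by_t),
                      unique_sense_rpm = rpm(as.numeric(rpm_by_t), total_genome_mapped),
                      stringsAsFactors = FALSE)
  cand <- candidate_targets(per_t, min_rpm = min_rpm_target)
  if (!length(cand)) return(empty)
  targets <- transcripts[transcripts$id %in% cand, , drop = FALSE]

  # trigger queries: genome-unique reads mapping mRNA/lncRNA sense 0-mm
  genic <- transcripts$id[transcripts$kind %in% c("mRNA", "lncRNA")]
  sources <- usense[usense$transcript_id %in% genic,
                    c("read_id", "transcript_id", "five_prime"), drop = FALSE]
  query_ids <- unique(sources$read_id)
  if (!length(query_ids)) return(empty)
  queries <- reads[reads$id %in% query_ids, , drop = FALSE]

  sites <- find_trigger_sites(queries, targets, sources, mm_range = mm_range)
  if (!nrow(sites)) return(empty)

  # attach the (first) source locus of each trigger read
  src_first <- sources[!duplicated(sources$read_id), , drop = FALSE]
  src_t <- setNames(src_first$transcript_id, src_first$read_id)
  src_p <- setNames(src_first$five_prime, src_first$read_id)
  sites$source_transcript <- src_t[sites$read_id]
  key <- paste(sites$source_transcript, sites$transcript_id, sites$five_prime)

  tlen <- setNames(nchar(transcripts$seq), transcripts$id)
  rows <- list()
  trail_profiles <- list()
  for (kk in unique(key)) {
    grp <- sites[key == kk, , drop = FALSE]
    target_id <- grp$transcript_id[1]
    q <- grp$five_prime[1]
    t_sense <- sense0[sense0$transcript_id == target_id, , drop = FALSE]
    resp <- pair_responders(q, t_sense, reads, multiplicity, total_genome_mapped)
    if (!(resp$responder_rpm > min_rpm_responder)) next

    # representative trigger: highest-RPM member
    grp_cnt <- cnt_by_id[grp$read_id]
    rep_i <- which.max(grp_cnt)
    seed <- seed_profile(grp$mm_query_pos[rep_i])
    trail <- detect_trail(resp$cleavage_pos, tlen[[target_id]], t_sense, reads,
                          total_genome_mapped, window_nt = trail_window)
    src_id <- grp$source_transcript[1]
    resp_reads <- reads[reads$id %in% resp$responder_ids, , drop = FALSE]
    back <- classify_back_targeting(
      resp_reads, transcripts[transcripts$id == src_id, , drop = FALSE],
      trigger_locus_5p = src_p[[grp$read_id[rep_i]]],
      max_mm = backtarget_max_mm)

    eid <- sprintf("E%03d", length(rows) + 1L)
    rows[[eid]] <- data.frame(
      event_id = eid, source_transcript = src_id, target_transcript = target_id,
      anneal_five_prime = q, anneal_start = grp$start[1], anneal_end = grp$end[1],
      mismatches = grp$mismatches[rep_i], mm_query_pos = grp$mm_query_pos[rep_i],
      seed_mm_pos = paste(seed$seed_mm_pos, collapse = ","),
      perfect_seed = seed$perfect_seed,
      cleavage_pos = resp$cleavage_pos, n_responders = resp$n_responders,
      responder_rpm = resp$responder_rpm,
      responder_rpm_unique = resp$responder_rpm_unique,
      responder_pct1U = resp$responder_pct1U,
      trail_rpm = trail$trail_rpm, n_trail_reads = trail$n_trail_reads,
      trail_z1 = trail$z1, trail_pct1U = trail$trail_pct1U,
      back_target = back$back_target, back_target_distance = back$distance_nt,
      trigger_rpm = rpm(sum(grp_cnt[!duplicated(grp$read_id)]), total_genome_mapped),
      n_trigger_reads = length(unique(grp$read_id)),
      stringsAsFactors = FALSE)
    trail_profiles[[eid]] <- trail
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "trail_profiles") <- trail_profiles
  out
}
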