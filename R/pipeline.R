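# End-to-end orchestration: filter -> map -> ping-pong -> trigger ->
# network, with a read-conservation ledger, per-stage TSV artifacts and
# a summary mirroring the headline tallies (candidate transcripts,
# significant ping-pong transcripts, intrinsic ping-pong transcripts,
# networks, trigger events).

#' Default pipeline parameters
#'
#' All stage thresholds with their reference defaults: 24-29 nt size
#' selection; ping-pong significance at z > 1.96 with >= 30 pairs in the
#' 1-24 nt overlap window; candidate targets and event retention at
#' > 3 RPM; trigger search at 1-5 mismatches; TE matching at <= 3
#' mismatches; 5-kb flanks at > 0.5 RPM; base biases strict at > 50%;
#' trail window 1000 nt; one global RNG seed.
#'
#' @param ... overrides by name
#' @return named list of parameters
#' @export
pipeline_params <- function(...) {
  p <- list(
    min_len = 24, max_len = 29,
    z_thresh = 1.96, min_pairs = 30, dmax = 24,
    min_rpm_target = 3, min_rpm_responder = 3,
    mm_range = c(1, 5), te_max_mm = 3,
    flank_nt = 5000, flank_min_rpm = 0.5,
    bias_threshold = 50, unique_thresh = 95,
    trail_window = 1000, backtarget_max_mm = 5,
    min_shared = 1, pair_unit = "noncollapsed",
    rng_seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  p[names(over)] <- over
  p
}

#' Run the full analysis in memory
#'
#' Stages, in order: genome multiplicity and the RPM denominator; size
#' selection and the bona fide filter; exact transcript mapping (both
#' orientations); seeded multimapper assignment (cached on the result);
#' per-transcript ping-pong profiles and classification; trigger-event
#' inference; ping-pong network grouping and the snetDNA targeting graph;
#' optional 5-kb flank verification when transcript loci are given.
#'
#' @param reads reads data.frame (e.g. [load_reads()] or a
#'   `pirna_world$reads`)
#' @param transcripts transcripts data.frame with `kind`
#' @param genome named character vector of chromosome sequences
#' @param structural_refs optional structural-RNA reference data.frame
#' @param te_seqs optional TE library (character vector)
#' @param loci optional transcript genomic loci (for the flank check)
#' @param params list from [pipeline_params()]
#' @return object of class `pirna_run`
#' @export
pirna_analyze <- function(reads, transcripts, genome,
                          structural_refs = NULL, te_seqs = NULL, loci = NULL,
                          params = pipeline_params()) {
  stopifnot_reads(reads)
  stopifnot_transcripts(transcripts)
  ledger <- list(input = sum(reads$count))

  # genome mapping at 0 mm fixes the RPM denominator for the whole run
  mult <- genome_multiplicity(reads, genome)
  total_genome_mapped <- sum(reads$count[mult[reads$seq] >= 1L])
  if (total_genome_mapped == 0)
    stop("no read maps the genome at 0 mismatches; check inputs", call. = FALSE)

  sized <- select_by_length(reads, params$min_len, params$max_len)
  ledger$removed_by_length <- ledger$input - sum(sized$count)
  bona <- bona_fide_filter(sized, structural_refs)
  ledger$removed_as_structural <- sum(sized$count) - sum(bona$count)
  ledger$retained <- sum(bona$count)

  collapsed <- collapse_reads(bona)
  lib <- library_summary(ledger$input, total_genome_mapped, bona)

  aln <- map_exact(bona, transcripts)
  assignment <- assign_multimappers(aln, bona, seed = params$rng_seed)
  mapped_ids <- unique(aln$read_id)
  ledger$transcript_mapped <- sum(bona$count[bona$id %in% mapped_ids])
  ledger$transcript_unmapped <- ledger$retained - ledger$transcript_mapped

  profiled <- sort(unique(aln$transcript_id))
  profiles <- do.call(rbind, lapply(profiled, function(tid)
    pingpong_profile(tid, aln, bona, mult, total_genome_mapped,
                     te_seqs = te_seqs, unit = params$pair_unit,
                     dmax = params$dmax, z_thresh = params$z_thresh,
                     min_pairs = params$min_pairs,
                     te_max_mm = params$te_max_mm)))

  events <- find_trigger_events(bona, transcripts, aln, mult,
                                total_genome_mapped,
                                min_rpm_target = params$min_rpm_target,
                                min_rpm_responder = params$min_rpm_responder,
                                mm_range = params$mm_range,
                                trail_window = params$trail_window,
                                backtarget_max_mm = params$backtarget_max_mm)

  # ping-pong networks from the repeat-class transcripts' partner reads
  networks <- NULL
  if (!is.null(profiles) && any(profiles$class == "repeatPP")) {
    rep_ids <- profiles$transcript_id[profiles$class == "repeatPP"]
    seq_by_id <- setNames(bona$seq, bona$id)
    pp_sets <- list()
    footprints <- list()
    for (tid in rep_ids) {
      flagged <- pingpong_partners(aln[aln$transcript_id == tid, , drop = FALSE])
      hit <- flagged[flagged$has_partner, , drop = FALSE]
      pp_sets[[tid]] <- unique(seq_by_id[hit$read_id])
      if (nrow(hit)) {
        len <- nchar(seq_by_id[hit$read_id])
        lo <- ifelse(hit$strand == "sense", hit$five_prime,
                     hit$five_prime - len + 1L)
        footprints[[tid]] <- data.frame(
          transcript_id = tid, seq = seq_by_id[hit$read_id],
          start = lo, end = lo + len - 1L, stringsAsFactors = FALSE)
      }
    }
    networks <- group_pingpong_networks(pp_sets, min_shared = params$min_shared,
                                        footprints = do.call(rbind, footprints))
  }

  snet <- build_snet_network(events)

  flank <- NULL
  if (!is.null(loci) && !is.null(networks) && nrow(networks$membership)) {
    placements <- genome_unique_placements(bona, genome)
    cnt_by_seq <- tapply(bona$count, bona$seq, sum)
    placements$count <- as.integer(cnt_by_seq[placements$seq])
    net_loci <- loci[loci$id %in% networks$membership$transcript_id, , drop = FALSE]
    flank <- flank_unique_check(net_loci, placements, total_genome_mapped,
                                chrom_sizes = setNames(nchar(genome), names(genome)),
                                flank_nt = params$flank_nt,
                                min_rpm = params$flank_min_rpm)
  }

  summary_counts <- list(
    transcripts_piRNA_mapping = length(profiled),
    transcripts_over_3rpm = sum(profiles$sense_rpm + profiles$antisense_rpm >
                                  params$min_rpm_target),
    significant_pp = sum(profiles$significant),
    uniquePP = sum(profiles$class == "uniquePP"),
    repeatPP = sum(profiles$class == "repeatPP"),
    pingpong_networks = if (is.null(networks)) 0L
      else length(unique(networks$membership$network_id)),
    trigger_events = nrow(events))

  out <- list(
    params = params, ledger = ledger, library = lib,
    multiplicity = mult, total_genome_mapped = total_genome_mapped,
    reads = bona, collapsed = collapsed,
    alignments = aln, assignment = assignment,
    profiles = profiles, events = events,
    networks = networks, snet = snet, flank = flank,
    summary = summary_counts)
  class(out) <- "pirna_run"
  out
}

#' @export
print.pirna_run <- function(x, ...) {
  s <- x$summary
  cat("piRNA network analysis\n")
  cat(sprintf("  library: %d copies in, %d genome-mapped (0 mm), %d retained after filters\n",
              x$ledger$input, x$total_genome_mapped, x$ledger$retained))
  cat(sprintf("  library multiplicity (non-collapsed/collapsed): %.2f\n",
              x$library$multiplicity))
  cat(sprintf("  transcripts mapping piRNAs: %d\n", s$transcripts_piRNA_mapping))
  cat(sprintf("  significant ping-pong: %d (uniquePP %d, repeatPP %d)\n",
              s$significant_pp, s$uniquePP, s$repeatPP))
  cat(sprintf("  ping-pong networks: %d\n", s$pingpong_networks))
  cat(sprintf("  trigger events: %d\n", s$trigger_events))
  invisible(x)
}

#' @export
#' @method summary pirna_run
summary.pirna_run <- function(object, ...) {
  print(object)
  if (nrow(object$events)) {
    cat("\ntrigger events:\n")
    print(object$events[, c("event_id", "source_transcript", "target_transcript",
                            "cleavage_pos", "mismatches", "perfect_seed",
                            "responder_rpm", "back_target",
                            "back_target_distance")],
          row.names = FALSE)
  }
  if (!is.null(object$networks) && nrow(object$networks$membership)) {
    cat("\nping-pong networks:\n")
    print(object$networks$membership, row.names = FALSE)
  }
  invisible(object)
}

read_conservation_ok <- function(ledger) {
  ledger$input == ledger$removed_by_length + ledger$removed_as_structural +
    ledger$transcript_mapped + ledger$transcript_unmapped
}

#' Run the pipeline from a configuration (file-based orchestration)
#'
#' Loads the inputs named in the configuration, runs [pirna_analyze()]
#' and writes per-stage TSV artifacts, a run log with the
#' read-conservation ledger and the resolved configuration (for
#' provenance) into the output directory.
#'
#' @param config a YAML path or a named list with keys `reads`,
#'   `transcripts`, `genome`, optional `transcript_kinds` (TSV id/kind),
#'   `structural_refs`, `te_library`, `loci`, `out_dir`, and any
#'   [pipeline_params()] overrides under `params`
#' @return the `pirna_run`, invisibly
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("reads", "transcripts", "genome"))
    if (is.null(config[[key]]))
      stop("config error: missing required input path '", key, "'", call. = FALSE)
  out_dir <- config$out_dir %||% "pirnanet_out"
  params <- do.call(pipeline_params, config$params %||% list())

  reads <- load_reads(config$reads)
  transcripts <- load_transcripts(config$transcripts)
  if (!is.null(config$transcript_kinds)) {
    kinds <- utils::read.table(config$transcript_kinds, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    idx <- match(transcripts$id, kinds$id)
    transcripts$kind[!is.na(idx)] <- kinds$kind[idx[!is.na(idx)]]
  }
  genome <- load_genome(config$genome)
  structural <- if (!is.null(config$structural_refs))
    load_structural_refs(config$structural_refs) else NULL
  te <- if (!is.null(config$te_library))
    unname(load_genome(config$te_library)) else NULL
  loci <- if (!is.null(config$loci)) load_transcript_loci(config$loci) else NULL

  run <- pirna_analyze(reads, transcripts, genome, structural, te, loci, params)
  write_run(run, out_dir)
  resolved <- config
  resolved$params <- params
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
  invisible(run)
}

#' Write the artifacts of a run to a directory
#' @param run a `pirna_run`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignments(run$alignments, file.path(dir, "alignments.tsv"))
  utils::write.table(run$profiles, file.path(dir, "profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$events, file.path(dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(run$networks)) {
    utils::write.table(run$networks$membership,
                       file.path(dir, "pingpong_networks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(run$snet$edges, file.path(dir, "snet_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- c(
    sprintf("reads_in\t%d", run$ledger$input),
    sprintf("removed_by_length\t%d", run$ledger$removed_by_length),
    sprintf("removed_as_structural\t%d", run$ledger$removed_as_structural),
    sprintf("transcript_mapped\t%d", run$ledger$transcript_mapped),
    sprintf("transcript_unmapped\t%d", run$ledger$transcript_unmapped),
    sprintf("conservation_ok\t%s", read_conservation_ok(run$ledger)),
    sprintf("total_genome_mapped\t%d", run$total_genome_mapped))
  writeLines(log, file.path(dir, "run_log.tsv"))
  s <- run$summary
  yaml::write_yaml(s, file.path(dir, "summary.yaml"))
  invisible(dir)
}
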