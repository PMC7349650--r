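# Seeded synthetic worlds: a genome with embedded transcripts carrying
# planted ping-pong pairs, shared repeat families and trigger/responder/
# trail events, emitted together with a ground-truth manifest so every
# pipeline stage can be tested offline. Planting edits the transcript
# sequence (so exact mapping holds by construction) rather than mutating
# reads; mismatched trigger sites are created by editing the target
# window after copying the trigger's reverse complement, which guarantees
# the configured Hamming distance.

subst <- function(seq, at, value) {
  substr(seq, at, at + nchar(value) - 1L) <- value
  seq
}

# replace the base at `at` with `base`, or with a random base other than
# `avoid` when `base` is NULL
edit_base <- function(seq, at, base = NULL, avoid = NULL) {
  if (is.null(base)) base <- sample(setdiff(c("A", "C", "G", "T"), avoid), 1)
  subst(seq, at, base)
}

#' Simulation configuration
#'
#' Defaults define the reference study conditions of the generator: a
#' small genome carrying plain transcripts, two transcripts with intrinsic
#' ping-pong amplification (planted 10-nt 5'-overlap pairs from unique
#' sequence), three repeat families of 300 nt shared by three host
#' transcripts each (ping-pong networks), and one snetDNA network — one
#' trigger-producing source transcript targeting three transcripts, with
#' one trans-ping-pong reciprocal event and one downstream back-target at
#' 113 nt. Noiseless by default; background and structural contamination
#' are opt-in rates.
#'
#' @param seed RNG seed; every random choice flows from it
#' @param read_len planted piRNA length in nt (24-29)
#' @param genome_pad random nt between embedded transcripts
#' @param n_plain,plain_len transcripts without any planted structure
#' @param n_intrinsic,intrinsic_len,intrinsic_pairs intrinsic ping-pong
#'   transcripts and their planted pair count (>= 30 pairs makes the
#'   signature callable)
#' @param p10A_sense,p1U_antisense probability that the slicer-facing
#'   base of a planted pair is A; one transcript nucleotide realizes both
#'   the sense-10A and the antisense-1U signature, so these are coupled
#'   (`p1U_antisense` defaults to `p10A_sense` and is the operative one)
#' @param n_repeat_families,family_copies,repeat_len,repeat_pairs,host_len
#'   shared-repeat (ping-pong network) planting; repeat length must lie
#'   in 130-1130 nt
#' @param snet include the trigger-event network
#' @param source_len,target_len snetDNA transcript lengths
#' @param trigger_copies,responder_depth,trail_len,trail_depth copies per
#'   planted trigger read, responder read, and trail chain geometry
#' @param p1U_trail probability a trail read starts with U
#' @param trail_jitter nt of head-to-tail jitter between trail reads
#' @param backtarget_distance nt downstream of the trigger locus where
#'   the third event's responders back-target the source (113)
#' @param event_mm list of query-coordinate mismatch positions for the
#'   three planted trigger events (position 10 is kept intact so the
#'   slicer-facing base pairing is preserved)
#' @param background_reads uniform random reads added as noise
#' @param structural_reads contaminant reads drawn from the bundled
#'   synthetic structural-RNA decoys
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1, read_len = 26, genome_pad = 300,
                       n_plain = 4, plain_len = 1200,
                       n_intrinsic = 2, intrinsic_len = 1500, intrinsic_pairs = 40,
                       p10A_sense = 0.9, p1U_antisense = p10A_sense,
                       n_repeat_families = 3, family_copies = 3,
                       repeat_len = 300, repeat_pairs = 35, host_len = 1200,
                       snet = TRUE, source_len = 2000, target_len = 2000,
                       trigger_copies = 20, responder_depth = 60,
                       trail_len = 5, trail_depth = 10, p1U_trail = 0.9,
                       trail_jitter = 0, backtarget_distance = 113,
                       event_mm = list(c(14L, 20L), 15L, c(3L, 13L, 16L, 19L, 22L)),
                       background_reads = 0, structural_reads = 0) {
  cfg <- as.list(environment())
  if (read_len < 24 || read_len > 29)
    stop("config error: read_len must lie in 24-29 nt", call. = FALSE)
  if (repeat_len < 130 || repeat_len > 1130)
    stop("config error: repeat_len must lie in 130-1130 nt", call. = FALSE)
  if (repeat_len > host_len)
    stop("config error: repeat longer than its host transcript", call. = FALSE)
  for (p in c(p10A_sense, p1U_antisense, p1U_trail))
    if (p < 0 || p > 1) stop("config error: probabilities must lie in [0,1]",
                             call. = FALSE)
  if (intrinsic_len < 42 || intrinsic_pairs > intrinsic_len - 41)
    stop("config error: intrinsic transcript too short for the requested pairs",
         call. = FALSE)
  if (any(vapply(event_mm, function(x) any(x < 1 | x > read_len | x == 10), TRUE)))
    stop("config error: event mismatch positions must lie in 1..read_len, excluding 10",
         call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Plant ping-pong read pairs on a transcript
#'
#' Places `n_pairs` sense/antisense read pairs with exactly the 10-nt
#' 5'-overlap at distinct positions. The slicer-facing transcript base
#' (sense position 10 = antisense position 1, complemented) is set to A
#' with probability `p1U_antisense` — realizing the sense-10A and
#' antisense-1U biases — and to a non-A base otherwise. Reads are
#' extracted after all edits, so they map the returned transcript at
#' zero mismatches.
#'
#' @param transcript_seq transcript sequence (character scalar)
#' @param n_pairs number of pairs to plant
#' @param p10A_sense,p1U_antisense coupled bias probability (see
#'   [sim_config()])
#' @param read_len read length, default 26
#' @return list: `transcript` (edited sequence), `reads` (data.frame with
#'   `seq`, `count`, `strand`, `pair_pos`), `positions` (sense 5'
#'   positions used)
#' @export
plant_pingpong <- function(transcript_seq, n_pairs, p10A_sense = 0.9,
                           p1U_antisense = p10A_sense, read_len = 26) {
  L <- nchar(transcript_seq)
  lo <- read_len - 9L   # antisense window [p - (read_len - 10), p + 9] must start >= 1
  hi <- L - read_len + 1L
  if (n_pairs > 0 && hi - lo + 1L < n_pairs)
    stop("config error: transcript too short to plant ", n_pairs, " pairs",
         call. = FALSE)
  if (n_pairs == 0)
    return(list(transcript = transcript_seq,
                reads = data.frame(seq = character(0), count = integer(0),
                                   strand = character(0), pair_pos = integer(0),
                                   stringsAsFactors = FALSE),
                positions = integer(0)))
  pos <- sort(sample(lo:hi, n_pairs))
  biased <- stats::runif(n_pairs) < p1U_antisense
  for (i in seq_len(n_pairs)) {
    transcript_seq <- if (biased[i]) edit_base(transcript_seq, pos[i] + 9L, "A")
    else edit_base(transcript_seq, pos[i] + 9L, avoid = "A")
  }
  sense <- substr(rep(transcript_seq, n_pairs), pos, pos + read_len - 1L)
  anti <- revcomp(substr(rep(transcript_seq, n_pairs),
                         pos + 9L - read_len + 1L, pos + 9L))
  reads <- data.frame(
    seq = c(sense, anti), count = 1L,
    strand = rep(c("sense", "antisense"), each = n_pairs),
    pair_pos = rep(pos, 2), stringsAsFactors = FALSE)
  list(transcript = transcript_seq, reads = reads, positions = pos)
}

#' Plant one trigger/responder/trail event
#'
#' Edits the source so the trigger read carries 1U and 10A, copies the
#' trigger's reverse complement into the target window and applies the
#' requested mismatch positions (query coordinates), then derives the
#' responder at the implied cleavage position (anneal 5' - 9) and a
#' head-to-tail trail chain downstream. Optionally plants reciprocal
#' complementarity so the responders back-target the source either at the
#' trigger locus (`"trans"` — trans-ping-pong) or at a fixed distance
#' downstream of it (`"downstream"`).
#'
#' @param source_seq,target_seq transcript sequences
#' @param sp trigger 5' position on the source (>= 17 for `"trans"`)
#' @param tp anneal window start on the target
#' @param mm_positions query-coordinate mismatch positions (1-5 of them,
#'   position 10 excluded)
#' @param responder_depth,trail_len,trail_depth,p1U_trail,trail_jitter
#'   read depths and trail geometry
#' @param backtarget `"none"`, `"trans"` or `"downstream"`
#' @param backtarget_distance nt downstream of `sp` for `"downstream"`
#' @param backtarget_mm mismatch positions applied to the planted
#'   back-target window (default 5 positions, as for a 5-mismatch match)
#' @param trigger_copies copies of the trigger read
#' @param read_len read length
#' @return list: edited `source_seq` and `target_seq`, `reads`
#'   (data.frame `seq`, `count`, `category`), and `truth` (the event
#'   geometry: `sp`, `tp`, `anneal_five_prime`, `cleavage_pos`,
#'   `mm_positions`, `seed_mm`, `backtarget`, `backtarget_distance`)
#' @export
plant_trigger_event <- function(source_seq, target_seq, sp, tp, mm_positions,
                                responder_depth = 60, trail_len = 5,
                                trail_depth = 10, p1U_trail = 0.9,
                                trail_jitter = 0,
                                backtarget = c("none", "trans", "downstream"),
                                backtarget_distance = 113,
                                backtarget_mm = c(3L, 13L, 16L, 19L, 22L),
                                trigger_copies = 20, read_len = 26) {
  backtarget <- match.arg(backtarget)
  L <- read_len
  nmm <- length(mm_positions)
  if (nmm < 1 || nmm > 5)
    stop("mm_positions must hold 1 to 5 positions", call. = FALSE)
  if (any(mm_positions == 10))
    stop("a mismatch at query position 10 would break the slicer-facing pairing",
         call. = FALSE)
  if (backtarget == "trans" && sp < L - 9L)
    stop("trans back-targeting needs sp >= read_len - 9 so the reciprocal window fits",
         call. = FALSE)

  # trigger with 1U and 10A signatures
  source_seq <- edit_base(source_seq, sp, "T")
  source_seq <- edit_base(source_seq, sp + 9L, "A")
  trigger <- substr(source_seq, sp, sp + L - 1L)

  # target window: reverse complement of the trigger, then the mismatches
  w <- revcomp(trigger)
  for (qp in mm_positions) {
    wp <- L - qp + 1L
    w <- edit_base(w, wp, avoid = substr(w, wp, wp))
  }
  target_seq <- subst(target_seq, tp, w)
  anneal5p <- tp + L - 1L
  cleavage <- anneal5p - 9L

  ext <- L - 10L  # responder tail beyond the annealing window
  if (backtarget == "trans") {
    # responder continuation complementary to the nt upstream of the
    # trigger, so the responder anneals back at the trigger locus; one
    # mismatch is introduced so the responder stays genome-unique rather
    # than mapping the source antisense at 0 mm
    ext_seg <- revcomp(substr(source_seq, sp - ext, sp - 1L))
    ext_seg <- edit_base(ext_seg, 8L, avoid = substr(ext_seg, 8L, 8L))
    target_seq <- subst(target_seq, tp + L, ext_seg)
  }
  responder <- substr(target_seq, cleavage, cleavage + L - 1L)

  # phased trail chain, head-to-tail with optional jitter
  starts <- integer(trail_len)
  at <- cleavage
  for (k in seq_len(trail_len)) {
    jit <- if (trail_jitter > 0) sample(0:trail_jitter, 1) else 0L
    at <- at + L + jit
    starts[k] <- at
  }
  if (trail_len > 0 && starts[trail_len] + L - 1L > nchar(target_seq))
    stop("config error: trail chain runs past the target end; enlarge the target",
         call. = FALSE)
  u_draw <- stats::runif(trail_len) < p1U_trail
  for (k in seq_len(trail_len)) {
    target_seq <- if (u_draw[k]) edit_base(target_seq, starts[k], "T")
    else edit_base(target_seq, starts[k], avoid = "T")
  }
  trail <- substr(rep(target_seq, trail_len), starts, starts + L - 1L)

  if (backtarget == "downstream") {
    bw <- sp + backtarget_distance - ext   # window start on the source
    if (bw + L - 1L > nchar(source_seq))
      stop("config error: back-target window runs past the source end", call. = FALSE)
    if (bw <= sp + L - 1L && bw + L - 1L >= sp)
      stop("config error: back-target window overlaps the trigger locus", call. = FALSE)
    wb <- revcomp(responder)
    for (qp in backtarget_mm) {
      wp <- L - qp + 1L
      wb <- edit_base(wb, wp, avoid = substr(wb, wp, wp))
    }
    source_seq <- subst(source_seq, bw, wb)
  }

  reads <- data.frame(
    seq = c(trigger, responder, trail),
    count = c(trigger_copies, responder_depth, rep(trail_depth, trail_len)),
    category = c("trigger", "responder", rep("trail", trail_len)),
    stringsAsFactors = FALSE)
  truth <- list(sp = sp, tp = tp, anneal_five_prime = anneal5p,
                cleavage_pos = cleavage, mm_positions = sort(mm_positions),
                seed_mm = sort(intersect(mm_positions, 2:11)),
                backtarget = backtarget,
                backtarget_distance = if (backtarget == "downstream")
                  backtarget_distance else if (backtarget == "trans") 0 else NA_real_)
  list(source_seq = source_seq, target_seq = target_seq, reads = reads,
       truth = truth)
}

#' Generate a synthetic world: genome, transcripts, reads and manifest
#'
#' Deterministic under `config$seed`: the same configuration always
#' yields byte-identical sequences, reads and manifest.
#'
#' @param config a [sim_config()] object
#' @return object of class `pirna_world`: list with `genome` (named
#'   character), `transcripts` (data.frame `id`, `seq`, `kind`, `length`),
#'   `loci` (1-based genomic coordinates), `reads` (with `category` and
#'   `feature_id` columns), `manifest` (list: `reads`, `events`,
#'   `families`, `expected_classes`) and `config`
#' @export
make_world <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, build_world(config))
}

build_world <- function(cfg) {
  L <- cfg$read_len
  tx <- list()    # id -> list(seq, kind)
  reads <- list() # data.frames: seq, count, category, feature_id
  events <- list()
  fam_rows <- list()
  classes <- list()
  expected_net <- NULL

  add_tx <- function(id, seq, kind = "mRNA") tx[[id]] <<- list(seq = seq, kind = kind)

  for (i in seq_len(cfg$n_plain)) {
    id <- sprintf("plain_%02d", i)
    add_tx(id, random_dna(cfg$plain_len))
    classes[[id]] <- "noPP"
  }

  for (i in seq_len(cfg$n_intrinsic)) {
    id <- sprintf("intrinsic_%02d", i)
    pp <- plant_pingpong(random_dna(cfg$intrinsic_len), cfg$intrinsic_pairs,
                         cfg$p10A_sense, cfg$p1U_antisense, read_len = L)
    add_tx(id, pp$transcript)
    r <- pp$reads
    reads[[length(reads) + 1L]] <- data.frame(
      seq = r$seq, count = r$count,
      category = paste0("pp_", r$strand), feature_id = id,
      stringsAsFactors = FALSE)
    classes[[id]] <- "uniquePP"
  }

  for (f in seq_len(cfg$n_repeat_families)) {
    fam <- sprintf("fam%d", f)
    pp <- plant_pingpong(random_dna(cfg$repeat_len), cfg$repeat_pairs,
                         cfg$p10A_sense, cfg$p1U_antisense, read_len = L)
    members <- character(cfg$family_copies)
    for (cpy in seq_len(cfg$family_copies)) {
      id <- sprintf("host_%s_%02d", fam, cpy)
      members[cpy] <- id
      pre <- sample(50:(cfg$host_len - cfg$repeat_len - 50), 1)
      seq <- paste0(random_dna(pre), pp$transcript,
                    random_dna(cfg$host_len - cfg$repeat_len - pre))
      add_tx(id, seq)
      classes[[id]] <- "repeatPP"
    }
    r <- pp$reads
    reads[[length(reads) + 1L]] <- data.frame(
      seq = r$seq, count = r$count,
      category = paste0("pp_", r$strand), feature_id = fam,
      stringsAsFactors = FALSE)
    fam_rows[[fam]] <- data.frame(family_id = fam, transcript_id = members,
                                  stringsAsFactors = FALSE)
  }

  if (cfg$snet) {
    src <- random_dna(cfg$source_len)
    sp <- c(300L, 600L, 900L)
    back <- c("none", "trans", "downstream")
    tgt_kind <- c("mRNA", "lncRNA", "mRNA")
    tgt_ids <- c("snet_T1", "snet_T2", "snet_T3")
    for (e in 1:3) {
      ev <- plant_trigger_event(
        src, random_dna(cfg$target_len), sp = sp[e], tp = 500L,
        mm_positions = cfg$event_mm[[e]],
        responder_depth = cfg$responder_depth, trail_len = cfg$trail_len,
        trail_depth = cfg$trail_depth, p1U_trail = cfg$p1U_trail,
        trail_jitter = cfg$trail_jitter, backtarget = back[e],
        backtarget_distance = cfg$backtarget_distance,
        trigger_copies = cfg$trigger_copies, read_len = L)
      src <- ev$source_seq
      add_tx(tgt_ids[e], ev$target_seq, tgt_kind[e])
      classes[[tgt_ids[e]]] <- "noPP"
      reads[[length(reads) + 1L]] <- cbind(ev$reads,
        feature_id = sprintf("event%d", e), stringsAsFactors = FALSE)
      events[[e]] <- data.frame(
        event_id = sprintf("event%d", e), source_transcript = "snet_source",
        target_transcript = tgt_ids[e],
        sp = ev$truth$sp, anneal_five_prime = ev$truth$anneal_five_prime,
        cleavage_pos = ev$truth$cleavage_pos,
        mismatches = length(ev$truth$mm_positions),
        mm_positions = paste(ev$truth$mm_positions, collapse = ","),
        seed_mm = paste(ev$truth$seed_mm, collapse = ","),
        perfect_seed = length(ev$truth$seed_mm) == 0L,
        backtarget = c(none = "none", trans = "trans_pingpong",
                       downstream = "downstream_backtarget")[[ev$truth$backtarget]],
        backtarget_distance = ev$truth$backtarget_distance,
        responder_count = cfg$responder_depth,
        stringsAsFactors = FALSE)
    }
    add_tx("snet_source", src, "mRNA")
    classes[["snet_source"]] <- "noPP"
    # the trans-ping-pong plant implies a derived reciprocal event: the
    # responder acts as a trigger back onto the source, where the original
    # trigger reads are its responders
    trans_i <- which(back == "trans")
    if (length(trans_i)) {
      e <- trans_i[1]
      events[[length(events) + 1L]] <- data.frame(
        event_id = sprintf("event%d_reciprocal", e),
        source_transcript = tgt_ids[e], target_transcript = "snet_source",
        sp = 500L + L - 10L + 1L,      # responder 5' on its target
        anneal_five_prime = sp[e] + 9L,
        cleavage_pos = sp[e], mismatches = 1L,
        mm_positions = "18", seed_mm = "", perfect_seed = TRUE,
        backtarget = "trans_pingpong", backtarget_distance = 0,
        responder_count = cfg$trigger_copies, stringsAsFactors = FALSE)
    }
    expected_net <- data.frame(
      from = "snet_source", to = tgt_ids,
      type = ifelse(back == "trans", "trans_pingpong", "one_way"),
      stringsAsFactors = FALSE)
  }

  # optional uniform background noise on random transcripts
  tx_ids <- names(tx)
  if (cfg$background_reads > 0) {
    for (i in seq_len(cfg$background_reads)) {
      id <- sample(tx_ids, 1)
      tseq <- tx[[id]]$seq
      p <- sample(seq_len(nchar(tseq) - L + 1L), 1)
      s <- substr(tseq, p, p + L - 1L)
      if (stats::runif(1) < 0.5) s <- revcomp(s)
      reads[[length(reads) + 1L]] <- data.frame(
        seq = s, count = 1L, category = "noise", feature_id = id,
        stringsAsFactors = FALSE)
    }
  }

  if (cfg$structural_reads > 0) {
    decoys <- load_structural_refs(system.file("extdata",
      "structural_decoys_synthetic.fasta", package = "pirnanet", mustWork = TRUE))
    for (i in seq_len(cfg$structural_reads)) {
      j <- sample(nrow(decoys), 1)
      w <- sample(24:29, 1)
      p <- sample(seq_len(nchar(decoys$seq[j]) - w + 1L), 1)
      reads[[length(reads) + 1L]] <- data.frame(
        seq = substr(decoys$seq[j], p, p + w - 1L), count = 1L,
        category = "structural", feature_id = decoys$class[j],
        stringsAsFactors = FALSE)
    }
  }

  all_reads <- do.call(rbind, reads)
  all_reads <- data.frame(id = sprintf("r%05d", seq_len(nrow(all_reads))),
                          all_reads, length = nchar(all_reads$seq),
                          stringsAsFactors = FALSE)

  # genome: transcripts embedded in order with random padding between
  tx_df <- data.frame(id = tx_ids,
                      seq = vapply(tx, `[[`, "", "seq"),
                      kind = vapply(tx, `[[`, "", "kind"),
                      stringsAsFactors = FALSE)
  tx_df$length <- nchar(tx_df$seq)
  chrom <- character(2L * nrow(tx_df) + 1L)
  loci <- data.frame(id = tx_df$id, chrom = "chr1",
                     start = NA_integer_, end = NA_integer_, strand = "+",
                     stringsAsFactors = FALSE)
  at <- 0L
  pieces <- list()
  for (i in seq_len(nrow(tx_df))) {
    pad <- random_dna(cfg$genome_pad)
    pieces[[2L * i - 1L]] <- pad
    at <- at + nchar(pad)
    loci$start[i] <- at + 1L
    loci$end[i] <- at + tx_df$length[i]
    pieces[[2L * i]] <- tx_df$seq[i]
    at <- at + tx_df$length[i]
  }
  pieces[[length(pieces) + 1L]] <- random_dna(cfg$genome_pad)
  genome <- c(chr1 = paste(unlist(pieces), collapse = ""))

  manifest <- list(
    reads = all_reads[, c("id", "seq", "count", "category", "feature_id")],
    events = if (length(events)) do.call(rbind, events) else NULL,
    families = if (length(fam_rows)) do.call(rbind, fam_rows) else NULL,
    network = expected_net,
    expected_classes = data.frame(transcript_id = names(classes),
                                  expected_class = unlist(classes),
                                  stringsAsFactors = FALSE))
  rownames(manifest$expected_classes) <- NULL

  out <- list(genome = genome,
              transcripts = tx_df[, c("id", "seq", "kind", "length")],
              loci = loci,
              reads = all_reads[, c("id", "seq", "count", "length",
                                    "category", "feature_id")],
              manifest = manifest, config = cfg)
  class(out) <- "pirna_world"
  out
}

#' @export
print.pirna_world <- function(x, ...) {
  cat("synthetic piRNA world:", length(x$genome), "contig(s),",
      nrow(x$transcripts), "transcripts,",
      nrow(x$reads), "distinct reads (", sum(x$reads$count), "copies )\n")
  cat("read categories:\n")
  print(table(x$reads$category))
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Emits genome and transcript FASTA, a BED6 of transcript loci (0-based
#' half-open, converted from the internal 1-based coordinates), the
#' non-collapsed read library as FASTQ, the manifest tables as TSV and
#' the configuration as YAML.
#'
#' @param world a `pirna_world`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(world$genome, file.path(dir, "genome.fasta"))
  write_fasta(setNames(world$transcripts$seq, world$transcripts$id),
              file.path(dir, "transcripts.fasta"))
  bed <- data.frame(world$loci$chrom, world$loci$start - 1L, world$loci$end,
                    world$loci$id, 0L, world$loci$strand)
  utils::write.table(bed, file.path(dir, "transcripts.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_reads_fastq(world$reads, file.path(dir, "reads.fastq"))
  utils::write.table(world$transcripts[, c("id", "kind")],
                     file.path(dir, "transcript_kinds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(world$manifest)) {
    if (is.null(world$manifest[[nm]])) next
    utils::write.table(world$manifest[[nm]],
                       file.path(dir, paste0("manifest_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- world$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Null calibration: ping-pong calls on structureless transcripts
#'
#' Places sense and antisense reads uniformly at random on each of
#' `n_transcripts` simulated transcripts and applies the overlap
#' histogram, z-score and significance call. Under this null the
#' significant fraction should stay near the one-sided 5% implied by the
#' 1.96 threshold.
#'
#' @param n_transcripts number of null transcripts (default 200)
#' @param transcript_len transcript length (500)
#' @param n_sense,n_antisense reads per strand (40 each, enough that the
#'   pair floor of 30 is typically met)
#' @param seed RNG seed
#' @return data.frame with per-transcript `z10`, `total_pairs`,
#'   `significant`
#' @export
simulate_null_pingpong <- function(n_transcripts = 200, transcript_len = 500,
                                   n_sense = 40, n_antisense = 40, seed = 1) {
  with_seed(seed, {
    res <- lapply(seq_len(n_transcripts), function(i) {
      s <- table(sample(seq_len(transcript_len), n_sense, replace = TRUE))
      a <- table(sample(seq_len(transcript_len), n_antisense, replace = TRUE))
      counts <- overlap_pair_counts(
        setNames(as.numeric(s), names(s)),
        setNames(as.numeric(a), names(a)))
      z <- pingpong_z(counts)
      data.frame(z10 = if (z$degenerate) NA_real_ else z$z,
                 total_pairs = sum(counts),
                 significant = call_significance(z$z, sum(counts)))
    })
    do.call(rbind, res)
  })
}
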