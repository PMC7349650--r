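# Network assembly: grouping transcripts that share ping-pong piRNAs
# into ping-pong networks, verifying that network loci actually produce
# piRNAs via a 5-kb flank check, and building the directed snetDNA
# targeting graph from trigger events.

#' Group transcripts sharing ping-pong piRNAs into networks
#'
#' Two transcripts are connected when they share at least `min_shared`
#' identical ping-pong-partner read sequences; connected components are
#' the ping-pong networks. Singleton transcripts are not reported as
#' networks. Per network, the footprint span of the shared reads on each
#' member (min 5' to max 3') is reported — shared repeats are expected in
#' the 130-1130 nt range.
#'
#' @param pp_sets named list: transcript id -> character vector of its
#'   ping-pong read sequences
#' @param min_shared minimum shared sequences for an edge, default 1
#' @param footprints optional data.frame (`transcript_id`, `seq`, `start`,
#'   `end`) giving each shared read's placement, for span reporting
#' @return list with `membership` (data.frame `transcript_id`,
#'   `network_id`), `edges` (`from`, `to`, `n_shared`), `spans`
#'   (`network_id`, `transcript_id`, `span_start`, `span_end`,
#'   `span_nt`; NULL without footprints) and `graph` (igraph)
#' @export
group_pingpong_networks <- function(pp_sets, min_shared = 1, footprints = NULL) {
  ids <- sort(names(pp_sets))  # input-order invariance
  edges <- list()
  k <- 0L
  if (length(ids) > 1) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq((i + 1L), length(ids))) {
        shared <- length(intersect(pp_sets[[ids[i]]], pp_sets[[ids[j]]]))
        if (shared >= min_shared && shared > 0) {
          k <- k + 1L
          edges[[k]] <- data.frame(from = ids[i], to = ids[j],
                                   n_shared = shared, stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (k) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), n_shared = integer(0),
               stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  keep <- which(comp$csize >= 2)
  membership <- data.frame(transcript_id = ids,
                           component = comp$membership[ids],
                           stringsAsFactors = FALSE)
  membership <- membership[membership$component %in% keep, , drop = FALSE]
  # stable network ids, ordered by smallest member id
  if (nrow(membership)) {
    reps <- tapply(membership$transcript_id, membership$component, min)
    lvl <- names(sort(reps))
    membership$network_id <- paste0("net", match(as.character(membership$component), lvl))
    membership <- membership[order(membership$network_id, membership$transcript_id), ]
    membership$component <- NULL
  } else {
    membership <- data.frame(transcript_id = character(0),
                             network_id = character(0), stringsAsFactors = FALSE)
  }
  rownames(membership) <- NULL

  spans <- NULL
  if (!is.null(footprints) && nrow(membership)) {
    net_of <- setNames(membership$network_id, membership$transcript_id)
    fp <- footprints[footprints$transcript_id %in% membership$transcript_id, ,
                     drop = FALSE]
    if (nrow(fp)) {
      key <- paste(net_of[fp$transcript_id], fp$transcript_id)
      spans <- do.call(rbind, lapply(split(fp, key), function(d) {
        data.frame(network_id = net_of[[d$transcript_id[1]]],
                   transcript_id = d$transcript_id[1],
                   span_start = min(d$start), span_end = max(d$end),
                   span_nt = max(d$end) - min(d$start) + 1L,
                   stringsAsFactors = FALSE)
      }))
      rownames(spans) <- NULL
    }
  }
  list(membership = membership, edges = edges, spans = spans, graph = g)
}

#' Flank-inclusive genome-unique piRNA check for network loci
#'
#' A transcript locus counts as a genuine piRNA producer when
#' genome-unique reads within the locus extended by `flank_nt` up- and
#' downstream exceed `min_rpm` RPM. Flanks are truncated at contig edges.
#'
#' @param loci data.frame (`id`, `chrom`, `start`, `end`) of transcript
#'   genomic loci; transcripts without coordinates get NA with a warning
#' @param placements data.frame of genome-unique read placements
#'   (`chrom`, `start`, `end`) with a `count` column of read copies
#' @param total_genome_mapped RPM denominator
#' @param chrom_sizes named integer vector of contig lengths
#' @param flank_nt flank width, default 5000
#' @param min_rpm threshold, default 0.5 (strictly greater passes)
#' @return named logical vector along `loci$id` (NA when no coordinates)
#' @export
flank_unique_check <- function(loci, placements, total_genome_mapped,
                               chrom_sizes, flank_nt = 5000, min_rpm = 0.5) {
  out <- setNames(rep(NA, nrow(loci)), loci$id)
  for (i in seq_len(nrow(loci))) {
    if (is.na(loci$chrom[i]) || is.na(loci$start[i]) || is.na(loci$end[i])) {
      warning(sprintf("locus '%s' has no genomic coordinates; flank check is NA",
                      loci$id[i]), call. = FALSE)
      next
    }
    lo <- max(1L, loci$start[i] - flank_nt)
    hi <- min(chrom_sizes[[loci$chrom[i]]], loci$end[i] + flank_nt)
    inwin <- placements$chrom == loci$chrom[i] &
      placements$start <= hi & placements$end >= lo
    out[i] <- rpm(sum(placements$count[inwin]), total_genome_mapped) > min_rpm
  }
  out
}

#' Build the directed snetDNA targeting network from trigger events
#'
#' One directed edge per (source, target) pair of retained events.
#' Edges whose events are classified trans-ping-pong (responders
#' back-target the trigger locus), or that have a reciprocal counterpart,
#' are labelled `trans_pingpong`; the rest are `one_way`. Nodes carry
#' their percentage shares of total trigger and responder RPM.
#'
#' @param events event table from [find_trigger_events()]
#' @return object of class `snet_network`: list with `nodes`, `edges`
#'   and `graph` (igraph, directed)
#' @export
build_snet_network <- function(events) {
  if (!nrow(events)) {
    g <- igraph::make_empty_graph(directed = TRUE)
    out <- list(nodes = data.frame(transcript_id = character(0),
                                   pct_trigger_rpm = numeric(0),
                                   pct_responder_rpm = numeric(0),
                                   stringsAsFactors = FALSE),
                edges = data.frame(from = character(0), to = character(0),
                                   type = character(0), trigger_rpm = numeric(0),
                                   responder_rpm = numeric(0), n_events = integer(0),
                                   stringsAsFactors = FALSE),
                graph = g)
    class(out) <- "snet_network"
    return(out)
  }
  key <- paste(events$source_transcript, events$target_transcript, sep = "\r")
  # aggregate in first-appearance order so a collapsed reciprocal pair
  # keeps the direction of its earliest event, independent of locale
  agg <- lapply(unique(key), function(kk) {
    d <- events[key == kk, , drop = FALSE]
    data.frame(from = d$source_transcript[1], to = d$target_transcript[1],
               type = if (any(d$back_target == "trans_pingpong"))
                 "trans_pingpong" else "one_way",
               trigger_rpm = sum(d$trigger_rpm),
               responder_rpm = sum(d$responder_rpm),
               n_events = nrow(d), stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, agg)
  rownames(edges) <- NULL
  # reciprocal pairs collapse into one trans_pingpong edge
  rev_key <- paste(edges$to, edges$from)
  fwd_key <- paste(edges$from, edges$to)
  recip <- fwd_key %in% rev_key
  edges$type[recip] <- "trans_pingpong"
  if (any(recip)) {
    canon <- ifelse(edges$from < edges$to, fwd_key, rev_key)
    drop <- recip & duplicated(canon)
    for (i in which(drop)) {
      j <- which(canon == canon[i] & !drop)[1]
      edges$trigger_rpm[j] <- edges$trigger_rpm[j] + edges$trigger_rpm[i]
      edges$responder_rpm[j] <- edges$responder_rpm[j] + edges$responder_rpm[i]
      edges$n_events[j] <- edges$n_events[j] + edges$n_events[i]
    }
    edges <- edges[!drop, , drop = FALSE]
  }

  nodes_id <- sort(unique(c(edges$from, edges$to)))
  trig <- tapply(events$trigger_rpm, events$source_transcript, sum)
  resp <- tapply(events$responder_rpm, events$target_transcript, sum)
  tot_trig <- sum(events$trigger_rpm)
  tot_resp <- sum(events$responder_rpm)
  trig_n <- unname(as.numeric(trig[nodes_id])); trig_n[is.na(trig_n)] <- 0
  resp_n <- unname(as.numeric(resp[nodes_id])); resp_n[is.na(resp_n)] <- 0
  nodes <- data.frame(
    transcript_id = nodes_id,
    pct_trigger_rpm = 100 * trig_n / tot_trig,
    pct_responder_rpm = 100 * resp_n / tot_resp,
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes_id))
  out <- list(nodes = nodes, edges = edges, graph = g)
  class(out) <- "snet_network"
  out
}

#' @export
print.snet_network <- function(x, ...) {
  cat("snetDNA targeting network:", nrow(x$nodes), "transcripts,",
      nrow(x$edges), "edges (",
      sum(x$edges$type == "trans_pingpong"), "trans-ping-pong,",
      sum(x$edges$type == "one_way"), "one-way )\n")
  if (nrow(x$edges)) {
    arrows <- ifelse(x$edges$type == "trans_pingpong", "<->", "-->")
    cat(paste0("  ", x$edges$from, " ", arrows, " ", x$edges$to,
               "  [", x$edges$type, "]"), sep = "\n")
  }
  invisible(x)
}
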