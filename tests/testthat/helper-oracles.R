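# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (character vectors, double loops) so they share no
# code path with the implementation they check.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rc_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

tx_df <- function(seqs, ids = paste0("t", seq_along(seqs)), kind = "mRNA") {
  data.frame(id = ids, seq = seqs, kind = rep_len(kind, length(seqs)),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

reads_df <- function(seqs, ids = NULL, count = 1L) {
  if (is.null(ids))
    ids <- if (length(seqs)) paste0("r", seq_along(seqs)) else character(0)
  data.frame(id = ids, seq = seqs, count = rep_len(as.integer(count), length(seqs)),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

# all exact occurrences of read on tseq, both strands, by substring scan
brute_exact_hits <- function(read, tseq) {
  L <- nchar(read)
  hits <- list(); k <- 0L
  rcr <- rc_chr(read)
  for (s in seq_len(max(0L, nchar(tseq) - L + 1L))) {
    win <- substr(tseq, s, s + L - 1L)
    if (win == read) {
      k <- k + 1L
      hits[[k]] <- data.frame(strand = "sense", five_prime = s)
    }
    if (win == rcr) {
      k <- k + 1L
      hits[[k]] <- data.frame(strand = "antisense", five_prime = s + L - 1L)
    }
  }
  if (k == 0L) return(data.frame(strand = character(0), five_prime = integer(0)))
  do.call(rbind, hits)
}

# all-offset Hamming scan of revcomp(query) against tseq
brute_rc_hits <- function(query, tseq, min_mm, max_mm) {
  rcq <- strsplit(rc_chr(query), "")[[1]]
  tch <- strsplit(tseq, "")[[1]]
  L <- length(rcq)
  hits <- list(); k <- 0L
  for (s in seq_len(max(0L, length(tch) - L + 1L))) {
    win <- tch[s:(s + L - 1L)]
    mm <- sum(win != rcq | win == "N" | rcq == "N")
    if (mm >= min_mm && mm <= max_mm) {
      k <- k + 1L
      hits[[k]] <- data.frame(start = s, five_prime = s + L - 1L, mismatches = mm)
    }
  }
  if (k == 0L)
    return(data.frame(start = integer(0), five_prime = integer(0),
                      mismatches = integer(0)))
  do.call(rbind, hits)
}

# enumerate all sense x antisense pairs and bin their 5' overlap distance
brute_overlap_counts <- function(sense_pos, sense_w, anti_pos, anti_w, dmax = 24) {
  counts <- setNames(numeric(dmax), seq_len(dmax))
  for (i in seq_along(sense_pos)) {
    for (j in seq_along(anti_pos)) {
      d <- anti_pos[j] - sense_pos[i] + 1L
      if (d >= 1 && d <= dmax) counts[d] <- counts[d] + sense_w[i] * anti_w[j]
    }
  }
  counts
}

# mutate k distinct positions of a sequence (always to a different base)
mutate_seq <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
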