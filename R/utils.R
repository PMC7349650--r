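# Small internal helpers shared across modules.

#' Population standard deviation
#'
#' Divides by n, not n - 1. The overlap z-score treats the 24 (or 50)
#' histogram bins as the full background population, so the population
#' form is the right one.
#'
#' @param x numeric vector
#' @return non-negative scalar
#' @keywords internal
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of DNA strings
#'
#' Vectorized; accepts and returns plain character vectors. N is preserved.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N)
#' @return character vector of the same length
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence using the current RNG stream
#' @param n length in nt
#' @return single character string
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# weighted percentage of TRUE; NA when there is no weight at all
pct_of <- function(flag, w) {
  tot <- sum(w)
  if (tot <= 0) return(NA_real_)
  100 * sum(w[flag]) / tot
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# empty alignment table with the canonical column set
empty_alignments <- function() {
  data.frame(
    read_id = character(0), transcript_id = character(0),
    strand = character(0), five_prime = integer(0),
    mismatches = integer(0), stringsAsFactors = FALSE
  )
}

stopifnot_reads <- function(reads) {
  need <- c("id", "seq", "count")
  if (!is.data.frame(reads) || !all(need %in% names(reads)))
    stop("expected a reads data.frame with columns id, seq, count", call. = FALSE)
  invisible(reads)
}

stopifnot_transcripts <- function(transcripts) {
  need <- c("id", "seq")
  if (!is.data.frame(transcripts) || !all(need %in% names(transcripts)))
    stop("expected a transcripts data.frame with columns id, seq", call. = FALSE)
  if (anyDuplicated(transcripts$id))
    stop("transcript ids must be unique", call. = FALSE)
  if (any(!nzchar(transcripts$seq)))
    stop("transcript sequences must be non-empty", call. = FALSE)
  invisible(transcripts)
}
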