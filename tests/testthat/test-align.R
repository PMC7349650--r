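test_that("exact mapping places forced sense and antisense reads", {
  set.seed(10)
  tseq <- rand_dna(200)
  sense_read <- substr(tseq, 11, 36)
  anti_read <- rc_chr(substr(tseq, 11, 36))
  tx <- tx_df(tseq)

  aln <- map_exact(reads_df(sense_read), tx)
  expect_equal(aln$strand, "sense")
  expect_equal(aln$five_prime, 11)
  expect_equal(aln$mismatches, 0L)

  aln <- map_exact(reads_df(anti_read), tx)
  expect_equal(aln$strand, "antisense")
  expect_equal(aln$five_prime, 36)   # antisense 5' is the highest coordinate

  # a read present at two sites yields two records
  t2 <- paste0(rand_dna(20), sense_read, rand_dna(30), sense_read, rand_dna(20))
  aln <- map_exact(reads_df(sense_read), tx_df(t2))
  expect_equal(nrow(aln), 2)
  expect_equal(aln$five_prime, c(21, 77))
})

test_that("reads containing N are skipped by the exact mapper", {
  set.seed(11)
  tseq <- rand_dna(100)
  r <- substr(tseq, 10, 35)
  substr(r, 5, 5) <- "N"
  expect_message(aln <- map_exact(reads_df(r), tx_df(tseq)), "N")
  expect_equal(nrow(aln), 0)
})

test_that("exact mapping equals a naive all-offset scan on random instances", {
  set.seed(12)
  for (rep in 1:10) {
    tseqs <- replicate(2, rand_dna(400))
    # mix of planted sense, planted antisense and random reads
    reads <- character(9)
    for (i in 1:3) {
      p <- sample(1:370, 1)
      reads[i] <- substr(tseqs[1], p, p + 25)
      reads[i + 3] <- rc_chr(substr(tseqs[2], p, p + 25))
      reads[i + 6] <- rand_dna(26)
    }
    rd <- reads_df(reads)
    got <- map_exact(rd, tx_df(tseqs))
    for (j in 1:2) {
      for (i in seq_along(reads)) {
        exp <- brute_exact_hits(reads[i], tseqs[j])
        sub <- got[got$read_id == rd$id[i] & got$transcript_id == paste0("t", j), ]
        expect_equal(nrow(sub), nrow(exp))
        if (nrow(exp)) {
          expect_setequal(paste(sub$strand, sub$five_prime),
                          paste(exp$strand, exp$five_prime))
        }
      }
    }
  }
})

test_that("antisense coordinate law holds: five_prime - L + 1 is the window start", {
  run <- default_world_run()
  aln <- run$run$alignments
  anti <- aln[aln$strand == "antisense", ]
  seq_by_id <- setNames(run$run$reads$seq, run$run$reads$id)
  tx_by_id <- setNames(run$world$transcripts$seq, run$world$transcripts$id)
  expect_gt(nrow(anti), 0)
  pick <- anti[sample.int(nrow(anti), min(50, nrow(anti))), ]
  for (i in seq_len(nrow(pick))) {
    L <- nchar(seq_by_id[[pick$read_id[i]]])
    lo <- pick$five_prime[i] - L + 1
    expect_gte(lo, 1)
    win <- substr(tx_by_id[[pick$transcript_id[i]]], lo, pick$five_prime[i])
    expect_equal(rc_chr(win), seq_by_id[[pick$read_id[i]]])
  }
})

test_that("rc-mismatch search honours its bounds and reports positions", {
  set.seed(13)
  tseq <- rand_dna(300)
  q <- rc_chr(substr(tseq, 101, 126))  # perfect antisense annealer

  # 0-mm window excluded when min_mm = 1
  hits <- search_rc_mismatched(reads_df(q), tx_df(tseq), 1, 5)
  expect_false(any(hits$start == 101))

  # one substitution in the window -> one hit at mm = 1
  t2 <- tseq
  substr(t2, 110, 110) <- setdiff(c("A", "C", "G", "T"), substr(t2, 110, 110))[1]
  hits <- search_rc_mismatched(reads_df(q), tx_df(t2), 1, 5)
  h <- hits[hits$start == 101, ]
  expect_equal(nrow(h), 1)
  expect_equal(h$mismatches, 1L)
  expect_equal(h$five_prime, 126)
  # mismatch position in query coordinates: window pos 10 -> query 26-10+1
  expect_equal(h$mm_query_pos, "17")

  expect_error(search_rc_mismatched(reads_df("ACGTACGTA"), tx_df(tseq), 1, 5),
               "10 nt")
  expect_error(search_rc_mismatched(reads_df(q), tx_df(tseq), 3, 1), "min_mm")
})

test_that("rc-mismatch search equals brute-force Hamming over all offsets", {
  set.seed(14)
  for (rep in 1:8) {
    tseq <- rand_dna(350)
    qs <- c(
      # planted with controlled mismatch loads
      mutate_seq(rc_chr(substr(tseq, 51, 76)), sample(1:26, 2)),
      mutate_seq(rc_chr(substr(tseq, 201, 226)), sample(1:26, 5)),
      rand_dna(26), rand_dna(24))
    rd <- reads_df(qs)
    got <- search_rc_mismatched(rd, tx_df(tseq), 1, 5)
    for (i in seq_along(qs)) {
      exp <- brute_rc_hits(qs[i], tseq, 1, 5)
      sub <- got[got$read_id == rd$id[i], ]
      expect_equal(nrow(sub), nrow(exp))
      if (nrow(exp)) {
        o <- order(sub$start)
        expect_equal(sub$start[o], exp$start)
        expect_equal(sub$mismatches[o], exp$mismatches)
      }
    }
  }
})

test_that("rc-mismatch search at 0 mm reproduces the exact antisense mapper", {
  set.seed(15)
  tseq <- rand_dna(400)
  qs <- c(rc_chr(substr(tseq, 31, 56)), rc_chr(substr(tseq, 200, 226)),
          rand_dna(26))
  rd <- reads_df(qs)
  sites <- search_rc_mismatched(rd, tx_df(tseq), 0, 0)
  anti <- map_exact(rd, tx_df(tseq))
  anti <- anti[anti$strand == "antisense", ]
  expect_setequal(paste(sites$read_id, sites$five_prime),
                  paste(anti$read_id, anti$five_prime))
})

test_that("genome multiplicity counts both strands exactly", {
  set.seed(16)
  r <- rand_dna(26)
  r2 <- rand_dna(26)
  genome <- c(chr1 = paste0(rand_dna(100), r, rand_dna(100)),
              chr2 = paste0(rand_dna(50), rc_chr(r), rand_dna(50)))
  mult <- genome_multiplicity(c(r, r2), genome)
  expect_equal(unname(mult[r]), 2L)   # plus-strand copy and its reverse complement
  expect_equal(unname(mult[r2]), 0L)  # extra-genomic

  genome1 <- c(chr1 = paste0(rand_dna(100), r, rand_dna(100)))
  expect_equal(unname(genome_multiplicity(r, genome1)[r]), 1L)

  place <- genome_unique_placements(r, genome1)
  expect_equal(place$start, 101)
  expect_equal(place$strand, "+")
})
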