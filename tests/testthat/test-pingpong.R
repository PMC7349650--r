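test_that("overlap histogram bins the 5'-to-5' distance, sense to antisense", {
  # antisense 5' at 109 faces sense 5' at 100: overlap 10
  counts <- overlap_pair_counts(c("100" = 1), c("109" = 1))
  expect_equal(unname(counts[10]), 1)
  expect_equal(sum(counts), 1)

  # fully abutting 5' ends: overlap 1
  counts <- overlap_pair_counts(c("100" = 1), c("100" = 1))
  expect_equal(unname(counts[1]), 1)

  # antisense 5' upstream of sense 5' is not a slicer-compatible overlap
  counts <- overlap_pair_counts(c("100" = 1), c("95" = 1))
  expect_equal(sum(counts), 0)
})

test_that("overlap histogram and partner flags equal brute-force pair enumeration", {
  set.seed(30)
  for (rep in 1:10) {
    sp <- sample.int(500, 50, replace = TRUE)
    ap <- sample.int(500, 50, replace = TRUE)
    sw <- sample(1:3, 50, replace = TRUE)
    aw <- sample(1:3, 50, replace = TRUE)
    s_hist <- tapply(sw, sp, sum); a_hist <- tapply(aw, ap, sum)
    got <- overlap_pair_counts(setNames(as.numeric(s_hist), names(s_hist)),
                               setNames(as.numeric(a_hist), names(a_hist)))
    exp <- brute_overlap_counts(sp, sw, ap, aw)
    expect_equal(got, exp)

    aln <- data.frame(
      read_id = paste0("r", 1:100), transcript_id = "t1",
      strand = rep(c("sense", "antisense"), each = 50),
      five_prime = c(sp, ap), mismatches = 0L, stringsAsFactors = FALSE)
    flagged <- pingpong_partners(aln)
    brute <- logical(100)
    for (i in 1:50) brute[i] <- any(ap == sp[i] + 9L)
    for (j in 1:50) brute[50 + j] <- any(sp == ap[j] - 9L)
    expect_equal(flagged$has_partner, brute)
  }
})

test_that("ping-pong z-score uses the population sd with bin 10 in the background", {
  counts <- numeric(24); counts[10] <- 24
  z <- pingpong_z(counts)
  expect_false(z$degenerate)
  expect_equal(z$z, 23 / sqrt(23))

  expect_equal(pingpong_z(rep(7, 24))$z, NA_real_)  # sd 0: degenerate
  expect_true(pingpong_z(rep(7, 24))$degenerate)
  expect_true(pingpong_z(numeric(24))$degenerate)

  # a varying histogram whose bin 10 sits exactly at the mean: z = 0
  counts <- rep(c(0, 10), 12); counts[10] <- 5; counts[11] <- 5
  expect_equal(pingpong_z(counts)$z, 0)
})

test_that("significance needs z > 1.96 strictly and at least 30 pairs", {
  expect_true(call_significance(2.0, 30))
  expect_false(call_significance(1.96, 100))
  expect_false(call_significance(5.0, 29))
  expect_false(call_significance(NA_real_, 100))
})

test_that("1U/10A signatures are computed per position with a strict 50% bias rule", {
  s1 <- paste0("T", strrep("A", 8), "A", strrep("C", 14))  # 1U and 10A
  s2 <- paste0("G", strrep("A", 8), "G", strrep("C", 14))  # neither
  sig <- base_signature(c(s1, s2))
  expect_equal(sig$pct1U, 50)
  expect_equal(sig$pct10A, 50)
  expect_false(is_biased(sig$pct1U))      # exactly 50%: not biased
  expect_true(is_biased(50.1))

  sig <- base_signature(s1)
  expect_equal(sig$pct1U, 100)
  expect_equal(sig$pct10A, 100)

  # copy weighting
  sig <- base_signature(c(s1, s2), weights = c(3, 1))
  expect_equal(sig$pct1U, 75)

  empty <- base_signature(character(0))
  expect_true(is.na(empty$pct1U) && is.na(empty$pct10A))
})

test_that("TE attribution counts matches up to 3 mismatches, repeats by multiplicity", {
  set.seed(31)
  te <- rand_dna(300)
  hit3 <- mutate_seq(substr(te, 50, 75), sample(1:26, 3))
  miss4 <- mutate_seq(substr(te, 150, 175), sample(1:26, 4))
  exact <- substr(te, 200, 225)
  rd <- reads_df(c(hit3, miss4, exact))
  mult <- setNames(c(2L, 1L, 1L), rd$seq)

  out <- te_and_repeat_attribution(rd, te, mult)
  expect_equal(out$pct_pp_te, 100 * 2 / 3)      # 3 mm counted, 4 mm not
  expect_equal(out$pct_pp_repeat, 100 * 1 / 3)  # only the multiplicity-2 read

  # either orientation matches
  rc_read <- rc_chr(substr(te, 100, 125))
  expect_true(matches_reference(rc_read, te, max_mm = 0))

  out <- te_and_repeat_attribution(rd, NULL, mult)
  expect_true(is.na(out$pct_pp_te))
})

test_that("transcript classification follows significance then uniqueness", {
  expect_equal(classify_transcript(FALSE, 100), "noPP")
  expect_equal(classify_transcript(TRUE, 100), "uniquePP")
  expect_equal(classify_transcript(TRUE, 40), "repeatPP")
  expect_equal(classify_transcript(TRUE, 95), "repeatPP")   # strict > 95
})

test_that("trans-ping-pong scan keeps only sites at the 10-nt overlap geometry", {
  set.seed(32)
  tseq <- rand_dna(500)
  tx <- tx_df(tseq)
  sense_aln <- data.frame(read_id = "s1", transcript_id = "t1", strand = "sense",
                          five_prime = 100L, mismatches = 0L,
                          stringsAsFactors = FALSE)
  # external read annealing with its 5' at 109 (2 mismatches planted)
  ext <- mutate_seq(rc_chr(substr(tseq, 84, 109)), c(13, 20))
  hit <- trans_pingpong_scan(tx, reads_df(ext, ids = "x1"), sense_aln)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$five_prime, 109)
  expect_equal(hit$cleavage_pos, 100)
  expect_equal(hit$mismatches, 2L)

  # no external reads -> empty
  none <- trans_pingpong_scan(tx, reads_df(character(0)), sense_aln)
  expect_equal(nrow(none), 0)

  # randomized: flag set equals brute-force d == 10 filtering
  for (rep in 1:5) {
    t2 <- rand_dna(400)
    q <- mutate_seq(rc_chr(substr(t2, 175, 200)), sample(1:26, 3))
    sa <- data.frame(read_id = "s", transcript_id = "t1", strand = "sense",
                     five_prime = sample.int(380, 5), mismatches = 0L,
                     stringsAsFactors = FALSE)
    got <- trans_pingpong_scan(tx_df(t2), reads_df(q), sa)
    exp <- brute_rc_hits(q, t2, 1, 5)
    exp <- exp[(exp$five_prime - 9L) %in% sa$five_prime, ]
    expect_equal(sort(got$five_prime), sort(exp$five_prime))
  }
})

test_that("the per-transcript profile assembles RPMs, signatures and class", {
  set.seed(33)
  tseq <- rand_dna(400)
  pp <- plant_pingpong(tseq, n_pairs = 35, p10A_sense = 1)
  rd <- reads_df(pp$reads$seq)
  tx <- tx_df(pp$transcript)
  aln <- map_exact(rd, tx)
  mult <- setNames(rep(1L, nrow(rd)), rd$seq)
  prof <- pingpong_profile("t1", aln, rd, mult, total_genome_mapped = 70)
  expect_true(prof$significant)
  expect_equal(prof$class, "uniquePP")
  expect_gte(prof$count10, 35)
  expect_equal(prof$pct_unique, 100)
  expect_equal(prof$pct10A_sense_nc, 100)
  expect_equal(prof$pct1U_antisense_nc, 100)
  expect_gt(prof$pct_pp_partner_sense, 99)
  # log ratio: equal strands -> log(1) = 0
  expect_equal(prof$log_ratio_sense_antisense, 0)
})
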