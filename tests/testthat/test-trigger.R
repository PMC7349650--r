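test_that("candidate-target selection is strictly greater than 3 RPM", {
  tbl <- data.frame(transcript_id = c("a", "b", "c"),
                    unique_sense_rpm = c(3.0, 3.1, 0),
                    stringsAsFactors = FALSE)
  expect_equal(candidate_targets(tbl), "b")
  expect_equal(candidate_targets(tbl[0, ]), character(0))
})

test_that("trigger-site search excludes self loci and perfect complements", {
  set.seed(40)
  src <- rand_dna(400)
  tgt <- rand_dna(400)
  trig <- substr(src, 100, 125)
  # plant at 2 mm on the target, and a perfect complement elsewhere
  # mismatches at query positions 14 and 20 sit at window positions
  # 26 - 14 + 1 = 13 and 26 - 20 + 1 = 7
  tgt <- paste0(substr(tgt, 1, 49),
                mutate_seq(rc_chr(trig), c(13, 7)),
                substr(tgt, 76, 400))
  both <- tx_df(c(src, tgt), ids = c("src", "tgt"))
  sources <- data.frame(read_id = "q1", transcript_id = "src",
                        stringsAsFactors = FALSE)
  sites <- find_trigger_sites(reads_df(trig, ids = "q1"),
                              both, sources, mm_range = c(1, 5))
  expect_true(all(sites$transcript_id == "tgt"))  # self-locus excluded
  h <- sites[sites$start == 50, ]
  expect_equal(h$mismatches, 2L)
  expect_setequal(as.integer(strsplit(h$mm_query_pos, ",")[[1]]), c(14L, 20L))

  # a perfectly complementary window is not a trigger site at mm 1-5
  tgt0 <- paste0(strrep("A", 49), rc_chr(trig), strrep("C", 300))
  sites0 <- find_trigger_sites(reads_df(trig, ids = "q1"),
                               tx_df(tgt0, ids = "p"), sources, c(1, 5))
  expect_false(any(sites0$start == 50))
})

test_that("responder pairing implements the slicer geometry exactly", {
  set.seed(41)
  rd <- reads_df(c(paste0("T", rand_dna(25)), rand_dna(26)), ids = c("ok", "no"))
  sense_aln <- data.frame(read_id = c("ok", "no"), transcript_id = "t",
                          strand = "sense", five_prime = c(191L, 192L),
                          mismatches = 0L, stringsAsFactors = FALSE)
  mult <- setNames(c(1L, 1L), rd$seq)
  resp <- pair_responders(200L, sense_aln, rd, mult, total_genome_mapped = 100)
  expect_equal(resp$cleavage_pos, 191L)     # anneal 5' at 200 -> cut before 191
  expect_equal(resp$responder_ids, "ok")    # 192 is not a responder
  expect_equal(resp$responder_rpm, 1e4)
  expect_equal(resp$responder_pct1U, 100)
})

test_that("seed profile restricts mismatches to guide positions 2-11", {
  expect_true(seed_profile(c(14L, 20L))$perfect_seed)
  p <- seed_profile(c(5L, 14L))
  expect_false(p$perfect_seed)
  expect_equal(p$seed_mm_pos, 5L)
  expect_equal(seed_profile("3,13,16")$seed_mm_pos, 3L)
  expect_true(seed_profile("")$perfect_seed)
})

test_that("trail detection chains head-to-tail distances downstream", {
  set.seed(42)
  # responder 191-216 (26 nt), next read 5' at 217: d = 1
  rd <- reads_df(c(paste0("T", rand_dna(25)), paste0("T", rand_dna(25))),
                 ids = c("resp", "trail1"))
  aln <- data.frame(read_id = c("resp", "trail1"), transcript_id = "t",
                    strand = "sense", five_prime = c(191L, 217L),
                    mismatches = 0L, stringsAsFactors = FALSE)
  out <- detect_trail(191L, 2000L, aln, rd, total_genome_mapped = 100)
  expect_equal(unname(out$hist[1]), 1)
  expect_equal(out$n_trail_reads, 1)
  expect_equal(out$trail_pct1U, 100)

  # no downstream reads: empty profile, z1 undefined
  empty <- detect_trail(191L, 2000L, aln[1, ], rd[1, ], 100)
  expect_true(is.na(empty$z1))
  expect_equal(sum(empty$hist), 0)

  # window beyond the transcript end is truncated and flagged
  short <- detect_trail(191L, 300L, aln, rd, 100)
  expect_true(short$truncated)
  expect_equal(unname(short$hist[1]), 1)
})

test_that("planted phased trails give a strong d=1 signal with the planted 1U level", {
  run <- default_world_run()
  ev <- run$run$events
  planted <- ev[ev$source_transcript == "snet_source", ]
  expect_equal(nrow(planted), 3)
  expect_true(all(planted$trail_z1 > 1.96))
  # generator plants 1U at 90%: recovered within binomial error of 5 draws
  expect_true(all(abs(planted$trail_pct1U - 90) <= 30))
})

test_that("back-targeting classification separates trans-ping-pong from offsets", {
  set.seed(43)
  src <- rand_dna(600)
  tx <- tx_df(src, ids = "src")
  sp <- 300L

  # responder complementary across [sp-16, sp+9]: implied cleavage == sp
  trans_resp <- mutate_seq(rc_chr(substr(src, sp - 16, sp + 9)), 18)
  out <- classify_back_targeting(reads_df(trans_resp), tx, sp)
  expect_equal(out$back_target, "trans_pingpong")

  # complementary 113 nt downstream of the trigger locus
  w <- sp + 113L - 16L
  down_resp <- mutate_seq(rc_chr(substr(src, w, w + 25)), sample(12:26, 5))
  out <- classify_back_targeting(reads_df(down_resp), tx, sp)
  expect_equal(out$back_target, "downstream_backtarget")
  expect_equal(out$distance_nt, 113)

  # no complementarity within 5 mismatches
  out <- classify_back_targeting(reads_df(rand_dna(26)), tx, sp)
  expect_equal(out$back_target, "none")
  expect_equal(classify_back_targeting(reads_df(character(0)), tx, sp)$back_target,
               "none")
})

test_that("event inference recovers the manifest events with their geometry", {
  run <- default_world_run()
  ev <- run$run$events
  me <- run$world$manifest$events
  expect_setequal(
    paste(ev$source_transcript, ev$target_transcript, ev$cleavage_pos,
          ev$mismatches, ev$back_target),
    paste(me$source_transcript, me$target_transcript, me$cleavage_pos,
          me$mismatches, me$backtarget))
  # the 10-nt overlap is exact for every event
  expect_true(all(ev$anneal_five_prime - ev$cleavage_pos + 1L == 10L))
  # seed profiles match the planted mismatch positions
  m <- merge(ev, me,
             by.x = c("source_transcript", "target_transcript", "cleavage_pos"),
             by.y = c("source_transcript", "target_transcript", "cleavage_pos"))
  expect_equal(nrow(m), nrow(me))
  expect_equal(m$perfect_seed.x, m$perfect_seed.y)
  expect_equal(m$seed_mm_pos, m$seed_mm)
})
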