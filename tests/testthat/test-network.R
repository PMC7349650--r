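test_that("shared ping-pong reads group transcripts transitively", {
  sets <- list(A = c("s1"), B = c("s1", "s2"), C = c("s2"), D = c("s3"))
  nets <- group_pingpong_networks(sets)
  expect_equal(sort(nets$membership$transcript_id), c("A", "B", "C"))
  expect_equal(length(unique(nets$membership$network_id)), 1)
  # singletons are not networks
  expect_false("D" %in% nets$membership$transcript_id)

  none <- group_pingpong_networks(list(X = "a", Y = "b"))
  expect_equal(nrow(none$membership), 0)
})

test_that("grouping is invariant to transcript input order", {
  set.seed(50)
  seqs <- replicate(6, rand_dna(26))
  sets <- list(A = seqs[1:2], B = seqs[2:3], C = seqs[4], D = seqs[c(4, 5)],
               E = seqs[6])
  n1 <- group_pingpong_networks(sets)
  n2 <- group_pingpong_networks(rev(sets))
  expect_equal(n1$membership, n2$membership)
})

test_that("min_shared raises the edge floor", {
  sets <- list(A = c("s1", "s2"), B = c("s1", "s2", "s3"), C = c("s3"))
  n2 <- group_pingpong_networks(sets, min_shared = 2)
  expect_equal(sort(n2$membership$transcript_id), c("A", "B"))
})

test_that("simulated repeat families come back as exactly their planted networks", {
  run <- default_world_run()
  nets <- run$run$networks
  fam <- run$world$manifest$families
  expect_equal(length(unique(nets$membership$network_id)),
               length(unique(fam$family_id)))
  # memberships match family by family
  got <- split(nets$membership$transcript_id, nets$membership$network_id)
  exp <- split(fam$transcript_id, fam$family_id)
  match_count <- sum(vapply(exp, function(e)
    any(vapply(got, setequal, TRUE, y = e)), TRUE))
  expect_equal(match_count, length(exp))
  # shared-read footprints stay within the planted repeat length
  expect_true(all(nets$spans$span_nt <= run$world$config$repeat_len))
})

test_that("flank check honours the strict 0.5 RPM bound, flanks and contig edges", {
  loci <- data.frame(id = c("L1", "L2", "L3"), chrom = "chr1",
                     start = c(6000L, 20000L, 100L), end = c(7000L, 21000L, 200L),
                     stringsAsFactors = FALSE)
  sizes <- c(chr1 = 30000L)
  total <- 2e6
  # L1: exactly 0.5 RPM (1 copy of 2e6*0.5/1e6 = 1) -> FALSE (strict)
  # L2: reads only in the downstream flank -> TRUE with 2 copies
  placements <- data.frame(
    chrom = "chr1",
    start = c(6500L, 25900L, 25950L), end = c(6525L, 25925L, 25975L),
    count = c(1L, 1L, 1L), stringsAsFactors = FALSE)
  out <- flank_unique_check(loci[1:2, ], placements, total, sizes)
  expect_false(out[["L1"]])
  expect_true(out[["L2"]])

  # contig shorter than the flank: truncated interval still evaluated
  out3 <- flank_unique_check(loci[3, ], placements, total, c(chr1 = 400L))
  expect_false(out3[["L3"]])

  # no coordinates -> NA with warning
  nal <- data.frame(id = "Lx", chrom = NA, start = NA, end = NA)
  expect_warning(resNA <- flank_unique_check(nal, placements, total, sizes))
  expect_true(is.na(resNA[["Lx"]]))
})

test_that("enlarging the flank never flips a positive call to negative", {
  set.seed(51)
  for (rep in 1:20) {
    loci <- data.frame(id = "L", chrom = "chr1",
                       start = sample(5000:20000, 1), end = sample(20001:25000, 1))
    placements <- data.frame(chrom = "chr1",
                             start = sample.int(30000, 30), count = 1L)
    placements$end <- placements$start + 25L
    small <- flank_unique_check(loci, placements, 1e6, c(chr1 = 30000L),
                                flank_nt = 1000)
    big <- flank_unique_check(loci, placements, 1e6, c(chr1 = 30000L),
                              flank_nt = 8000)
    expect_true(!small[["L"]] || big[["L"]])
  }
})

test_that("snet graph labels one-way and trans-ping-pong edges and shares RPM", {
  ev <- data.frame(
    source_transcript = c("X", "X", "Z"),
    target_transcript = c("Y", "Z", "X"),
    back_target = c("none", "trans_pingpong", "trans_pingpong"),
    trigger_rpm = c(10, 20, 30), responder_rpm = c(100, 200, 50),
    stringsAsFactors = FALSE)
  net <- build_snet_network(ev)
  expect_equal(nrow(net$edges), 2)   # reciprocal pair collapsed
  xy <- net$edges[net$edges$to == "Y", ]
  expect_equal(xy$type, "one_way")
  xz <- net$edges[net$edges$to %in% c("Z", "X") & net$edges$from %in% c("X", "Z"), ]
  expect_equal(nrow(xz), 1)
  expect_equal(xz$type, "trans_pingpong")
  expect_equal(xz$n_events, 2)
  # every event lands in exactly one edge
  expect_equal(sum(net$edges$n_events), nrow(ev))
  # node shares sum to 100 on each axis
  expect_equal(sum(net$nodes$pct_trigger_rpm), 100)
  expect_equal(sum(net$nodes$pct_responder_rpm), 100)

  empty <- build_snet_network(ev[0, ])
  expect_equal(nrow(empty$edges), 0)
})

test_that("the simulated snet topology is recovered exactly", {
  run <- default_world_run()
  got <- run$run$snet$edges
  exp <- run$world$manifest$network
  expect_equal(nrow(got), nrow(exp))
  m <- merge(got, exp, by = c("from", "to"))
  expect_equal(nrow(m), nrow(exp))
  expect_equal(m$type.x, m$type.y)
})
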