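test_that("classify_reads separates vector-containing from passthrough", {
  set.seed(301)
  vec <- synthetic_vector(seed = 71)
  genome_piece <- rnd_dna(5000)
  vec_piece <- substr(vec$sequence, 4000, 5999)
  reads <- c(mix = paste0(genome_piece, vec_piece),
             plain = rnd_dna(4000))
  cl <- classify_reads(reads, vec)
  expect_equal(cl$vector_reads, "mix")
  expect_equal(cl$passthrough, "plain")
  empty <- classify_reads(character(0), vec)
  expect_length(empty$vector_reads, 0)
})

test_that("a read across a genome-vector junction yields two ordered segments", {
  set.seed(302)
  vec <- synthetic_vector(seed = 72)
  chrA <- rnd_dna(8000)
  read <- paste0(substr(chrA, 3001, 6000), substr(vec$sequence, 2000, 4500))
  aln <- align_local(c(r = read), c(chrA = chrA, vector = vec$sequence))
  sr <- segment_read("r", nchar(read), aln)
  expect_equal(nrow(sr$segments), 2L)
  expect_equal(sr$segments$target, c("chrA", "vector"))
  # raw endpoints may overshoot a junction by a couple of bases when the
  # x-drop extension picks up chance matches on the far side; downstream,
  # cluster medians and consensus re-anchoring absorb this
  expect_lte(abs(sr$segments$tstart[1] - 3001L), 3L)
  expect_lte(abs(sr$segments$tend[1] - 6000L), 3L)
  expect_lte(abs(sr$segments$tstart[2] - 2000L), 3L)
  expect_lte(abs(sr$segments$tend[2] - 4500L), 3L)
  expect_equal(nrow(sr$gaps), 0L)
})

test_that("a read with no alignments is one gap", {
  sr <- segment_read("r", 1000L, tdnascope:::empty_alignments())
  expect_equal(nrow(sr$segments), 0L)
  expect_equal(sr$gaps$start, 1L)
  expect_equal(sr$gaps$end, 1000L)
})

test_that("trimmed segments plus gaps exactly partition each read", {
  planted <- tiny_world(seed = 7)
  sim <- simulate_reads(planted$haplotypes,
                        read_sim_params(mean_depth = 8,
                                        error_rates = c(0, 0, 0), seed = 21))
  reads <- sim$reads
  cl <- classify_reads(reads, planted$vector)
  gal <- align_local(reads, unlist(planted$ref$chromosomes))
  seg_aln <- rbind(cl$vector_alignments[cl$vector_alignments$read_id %in% cl$vector_reads],
                   gal[gal$read_id %in% cl$vector_reads])
  segmented <- segment_reads(reads, seg_aln, read_ids = cl$vector_reads)
  expect_gt(length(segmented), 3)
  for (sr in segmented) {
    len <- nchar(reads[[sr$read_id]])
    ivs <- rbind(
      if (nrow(sr$segments)) sr$segments[, c("rstart", "rend")] else NULL,
      if (nrow(sr$gaps)) data.frame(rstart = sr$gaps$start, rend = sr$gaps$end) else NULL)
    ivs <- ivs[order(ivs$rstart), ]
    expect_equal(ivs$rstart[1], 1L)
    expect_equal(ivs$rend[nrow(ivs)], len)
    if (nrow(ivs) > 1) {
      expect_true(all(ivs$rstart[-1] == head(ivs$rend, -1) + 1L))
    }
  }
})

test_that("simulated vector-overlapping reads are recovered (origin oracle)", {
  planted <- tiny_world(seed = 8)
  sim <- simulate_reads(planted$haplotypes,
                        read_sim_params(mean_depth = 25,
                                        error_rates = c(0, 0, 0), seed = 22))
  cl <- classify_reads(sim$reads, planted$vector)
  # expected vector-containing reads from the origin log + truth layout
  lay <- planted$truth$layout
  vb <- lay[lay$kind == "vector", ]
  org <- sim$origin
  expected <- character(0)
  for (i in seq_len(nrow(org))) {
    o <- org[i]
    v <- vb[vb$hap == o$hap & vb$derivative == o$seq, ]
    if (!nrow(v)) next
    ov <- pmin(o$end, v$prod_end) - pmax(o$start, v$prod_start) + 1L
    if (any(ov >= 200)) expected <- c(expected, o$read_id)
  }
  expect_true(all(expected %in% cl$vector_reads))
})

test_that("contained alignments are dropped and overlaps trimmed at midpoints", {
  aln <- data.table::data.table(
    read_id = "r", rstart = c(1L, 100L, 401L), rend = c(500L, 200L, 900L),
    target = c("a", "b", "c"), tstart = c(1L, 1L, 1L),
    tend = c(500L, 101L, 500L), strand = "+",
    matches = c(500L, 100L, 500L), columns = c(500L, 100L, 500L),
    identity = 1, score = c(1000L, 200L, 1000L))
  sr <- segment_read("r", 900L, aln, overlap_tol = 30L)
  # the contained "b" alignment is dropped; a/c overlap [401,500] is split
  expect_equal(sr$segments$target, c("a", "c"))
  expect_equal(sr$segments$rend[1], 450L)
  expect_equal(sr$segments$rstart[2], 451L)
  # raw (untrimmed) coordinates are preserved
  expect_equal(sr$segments$raw_rend[1], 500L)
  expect_equal(sr$segments$raw_rstart[2], 401L)
})
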