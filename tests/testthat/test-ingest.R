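test_that("PAF written by the package round-trips through ingest", {
  set.seed(201)
  tgt <- rnd_dna(5000)
  reads <- c(r1 = substr(tgt, 101, 1100), r2 = rc(substr(tgt, 2001, 3200)))
  a <- align_local(reads, c(tg = tgt))
  path <- tempfile(fileext = ".paf")
  write_paf(a, setNames(nchar(reads), names(reads)), c(tg = nchar(tgt)), path)
  b <- ingest_alignments(path, format = "paf")
  expect_equal(b[, c("read_id", "rstart", "rend", "target", "tstart", "tend",
                     "strand", "matches", "columns")],
               a[order(read_id), c("read_id", "rstart", "rend", "target",
                                   "tstart", "tend", "strand", "matches",
                                   "columns")])
  expect_equal(b$score, a[order(read_id)]$score)
})

test_that("PAF minus strand keeps forward target coordinates", {
  line <- paste("r1", "100", "9", "59", "-", "tg", "1000", "199", "249",
                "48", "50", "60", sep = "\t")
  path <- tempfile(); writeLines(line, path)
  b <- ingest_alignments(path, format = "paf")
  expect_equal(b$strand, "-")
  expect_equal(c(b$rstart, b$rend), c(10L, 59L))   # 1-based inclusive
  expect_equal(c(b$tstart, b$tend), c(200L, 249L)) # forward coordinates
})

test_that("SAM soft clips are excluded from the read interval (CIGAR oracle)", {
  # forward record: 5S10M1D5M3S at pos 100 -> read interval [6,20],
  # target interval [100,115]; NM=2 with 1 del -> 14 matches / 16 columns
  sam1 <- paste("q1", "0", "tg", "100", "60", "5S10M1D5M3S", "*", "0", "0",
                paste(rep("A", 23), collapse = ""), "*", "NM:i:2", sep = "\t")
  # reverse record: 3S12M2S at pos 50; clips are in alignment orientation,
  # so on the read's own forward strand the leading clip is the 2S
  sam2 <- paste("q2", "16", "tg", "50", "60", "3S12M2S", "*", "0", "0",
                paste(rep("A", 17), collapse = ""), "*", sep = "\t")
  path <- tempfile()
  writeLines(c("@HD\tVN:1.6", sam1, sam2), path)
  b <- ingest_alignments(path, format = "sam")
  q1 <- b[b$read_id == "q1", ]
  expect_equal(c(q1$rstart, q1$rend), c(6L, 20L))
  expect_equal(c(q1$tstart, q1$tend), c(100L, 115L))
  expect_equal(q1$strand, "+")
  expect_equal(c(q1$matches, q1$columns), c(14L, 16L))
  q2 <- b[b$read_id == "q2", ]
  expect_equal(q2$strand, "-")
  expect_equal(c(q2$rstart, q2$rend), c(3L, 14L))
  expect_equal(c(q2$tstart, q2$tend), c(50L, 61L))
})

test_that("empty and malformed inputs behave as specified", {
  path <- tempfile(); writeLines(character(0), path)
  expect_equal(nrow(ingest_alignments(path, "paf")), 0L)
  expect_equal(nrow(ingest_alignments(path, "sam")), 0L)
  writeLines("only\tfive\tfields\there\tx", path)
  expect_error(ingest_alignments(path, "paf"), "line 1")
  # unmapped SAM records are skipped, not errors
  writeLines(paste("q", "4", "*", "0", "0", "*", "*", "0", "0", "AAAA", "*",
                   sep = "\t"), path)
  expect_equal(nrow(ingest_alignments(path, "sam")), 0L)
})
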