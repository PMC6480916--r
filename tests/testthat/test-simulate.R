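test_that("read_sim_params validates its inputs", {
  expect_error(read_sim_params(mean_depth = 0), "mean_depth")
  expect_error(read_sim_params(error_rates = c(0.5, 0, 0)))
  expect_error(read_sim_params(read_length = c(400, 100, 500)))
})

test_that("error-free reads are exact substrings of their haplotype", {
  ref <- build_reference(1, 120000, seed = 31)
  genome <- list(hap1 = unlist(ref$chromosomes))
  sim <- simulate_reads(genome, read_sim_params(mean_depth = 5,
                                                error_rates = c(0, 0, 0),
                                                seed = 9))
  for (i in seq_len(min(50, nrow(sim$origin)))) {
    o <- sim$origin[i]
    expected <- substr(genome$hap1[[o$seq]], o$start, o$end)
    if (o$strand == "-") expected <- rc(expected)
    expect_identical(unname(sim$reads[[o$read_id]]), expected)
  }
})

test_that("read count approximates depth x size / length", {
  ref <- build_reference(1, 300000, seed = 32)
  genome <- list(hap1 = unlist(ref$chromosomes))
  sim <- simulate_reads(genome, read_sim_params(
    mean_depth = 20, read_length = c(10000, 2000, 500),
    error_rates = c(0, 0, 0), seed = 10))
  expected_n <- 20 * 300000 / 10000
  expect_lt(abs(length(sim$reads) - expected_n), 0.08 * expected_n)
})

test_that("coverage is uniform over 100-kb interior windows", {
  ref <- build_reference(1, 400000, seed = 33)
  genome <- list(hap1 = unlist(ref$chromosomes))
  sim <- simulate_reads(genome, read_sim_params(mean_depth = 30,
                                                error_rates = c(0, 0, 0),
                                                seed = 11))
  org <- sim$origin
  for (w0 in c(50001, 150001, 250001)) {
    w1 <- w0 + 99999
    bases <- sum(pmax(0, pmin(org$end, w1) - pmax(org$start, w0) + 1))
    expect_lt(abs(bases / 1e5 - 30) / 30, 0.1)
  }
})

test_that("the same seed reproduces reads byte-identically", {
  planted <- tiny_world(seed = 6)
  p <- read_sim_params(mean_depth = 3, seed = 77)
  s1 <- simulate_reads(planted$haplotypes, p)
  s2 <- simulate_reads(planted$haplotypes, p)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$origin, s2$origin)
  s3 <- simulate_reads(planted$haplotypes, read_sim_params(mean_depth = 3, seed = 78))
  expect_false(identical(s1$reads, s3$reads))
  # FASTQ writing round-trips
  d <- tempfile(); paths <- write_simulation(s1, d)
  back <- tdnascope:::read_seqs(paths[["fastq"]])
  expect_identical(unname(back), unname(s1$reads))
  expect_error(simulate_reads(list(hap1 = character(0)),
                              read_sim_params(seed = 1)), "empty genome")
})

test_that("haplotypes are sampled in proportion to length", {
  ref <- build_reference(2, c(150000, 150000), seed = 34)
  genome <- list(hap1 = unlist(ref$chromosomes)["chr1"],
                 hap2 = unlist(ref$chromosomes)["chr2"])
  sim <- simulate_reads(genome, read_sim_params(mean_depth = 20,
                                                error_rates = c(0, 0, 0),
                                                seed = 12))
  tab <- table(sim$origin$hap)
  expect_lt(abs(tab[["hap1"]] - tab[["hap2"]]) / sum(tab), 0.15)
})
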