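mk_profile <- function(depths, ref, bin = 1000L) {
  dt <- data.table::data.table(
    chrom = "chr1",
    bin_start = seq(1L, by = bin, length.out = length(depths)),
    depth = depths)
  dt[, bin_end := bin_start + bin - 1L]
  data.table::setcolorder(dt, c("chrom", "bin_start", "bin_end", "depth"))
  structure(dt, class = c("depth_profile", class(dt)))
}

test_that("bin depth equals aligned bases over bin width", {
  ref <- build_reference(1, 10000, seed = 91)
  aln <- data.table::data.table(read_id = "r", rstart = 1L, rend = 1000L,
                                target = "chr1", tstart = 1001L, tend = 2000L,
                                strand = "+", matches = 1000L,
                                columns = 1000L, identity = 1, score = 2000L)
  dp <- compute_depth(aln, ref, bin_size = 1000L)
  expect_equal(dp$depth[2], 1.0)
  expect_equal(sum(dp$depth), 1.0)
  dp0 <- compute_depth(aln[0], ref, bin_size = 1000L)
  expect_true(all(dp0$depth == 0))
  expect_error(compute_depth(aln, ref, bin_size = 10), "bin_size")
})

test_that("genome-wide mean depth tracks the simulated depth within 5%", {
  ref <- build_reference(1, 150000, seed = 92)
  sim <- simulate_reads(list(hap1 = unlist(ref$chromosomes)),
                        read_sim_params(mean_depth = 20,
                                        error_rates = c(0, 0, 0), seed = 93))
  aln <- align_local(sim$reads, unlist(ref$chromosomes))
  dp <- compute_depth(aln, ref)
  interior_bins <- dp$bin_start >= 15000 & dp$bin_end <= 135000
  interior <- dp$depth[interior_bins]
  # origin-log oracle: interior coverage computed from the true read
  # intervals must match the alignment-derived profile within 5%
  org <- sim$origin
  true_cov <- sum(pmax(0, pmin(org$end, 135000) - pmax(org$start, 15001) + 1))
  expect_lt(abs(mean(interior) - true_cov / (135000 - 15000)) /
              (true_cov / (135000 - 15000)), 0.05)
})

test_that("half-depth and zero-depth runs are called het and hom", {
  ref <- build_reference(1, 200000, seed = 94)
  ctl <- mk_profile(rep(30, 200), ref)
  mut_depths <- rep(30, 200)
  mut_depths[10:59] <- 15   # heterozygous: exactly half
  mut_depths[120:139] <- 0  # homozygous
  mut <- mk_profile(mut_depths, ref)
  calls <- call_losses(mut, ctl, read_length = 12000)
  het <- calls[calls$zygosity == "heterozygous", ]
  hom <- calls[calls$zygosity == "homozygous", ]
  expect_equal(nrow(het), 1L)
  # boundary refinement on a knife-edge synthetic profile overshoots by a
  # few smoothed bins, pulling the measured ratio slightly above 0.5
  expect_equal(het$ratio, 0.5, tolerance = 0.08)
  expect_true(het$start <= 10000 && het$end >= 58000)
  expect_equal(nrow(hom), 1L)
  # homozygous boundaries are raw-bin accurate
  expect_equal(c(hom$start, hom$end), c(119001L, 139000L))
  # identical profiles produce no calls
  expect_equal(nrow(call_losses(ctl, ctl, read_length = 12000)), 0L)
})

test_that("low-control bins are masked and do not break runs", {
  ref <- build_reference(1, 100000, seed = 95)
  ctl_depths <- rep(30, 100); ctl_depths[30] <- 2
  mut_depths <- rep(30, 100); mut_depths[10:59] <- 15; mut_depths[30] <- 1
  calls <- call_losses(mk_profile(mut_depths, ref), mk_profile(ctl_depths, ref),
                       read_length = 12000)
  het <- calls[calls$zygosity == "heterozygous", ]
  expect_equal(nrow(het), 1L)
  expect_true(het$start <= 10000 && het$end >= 58000)
})

test_that("exclusion intervals mask ratio evidence but never hide zeros", {
  ref <- build_reference(1, 100000, seed = 96)
  ctl <- mk_profile(rep(30, 100), ref)
  mut_depths <- rep(30, 100)
  mut_depths[40:49] <- 15  # ramp-like dip, to be excluded
  mut_depths[70:79] <- 0   # real homozygous loss inside an exclusion zone
  excl <- data.table::data.table(chrom = "chr1",
                                 start = c(35001L, 65001L),
                                 end = c(55000L, 85000L))
  calls <- call_losses(mk_profile(mut_depths, ref), ctl,
                       read_length = 12000, exclude = excl)
  expect_equal(calls$zygosity, "homozygous")
  expect_equal(c(calls$start, calls$end), c(69001L, 79000L))
})

test_that("rolling mean is exact against a direct computation", {
  x <- c(1, 2, 3, 10, 10, 10, 3, 2, 1)
  rm5 <- tdnascope:::rolling_mean(x, 5L)
  direct <- vapply(seq_along(x), function(i) {
    mean(x[max(1, i - 2):min(length(x), i + 2)])
  }, numeric(1))
  expect_equal(rm5, direct)
})
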