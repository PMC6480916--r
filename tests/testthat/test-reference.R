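test_that("build_reference forces lengths and is seed-deterministic", {
  ref <- build_reference(1, 1000, gc = 0.5, seed = 7)
  expect_length(ref$chromosomes, 1)
  expect_equal(nchar(ref$chromosomes[[1]]), 1000L)
  ref2 <- build_reference(1, 1000, gc = 0.5, seed = 7)
  expect_identical(ref$chromosomes, ref2$chromosomes)
  ref3 <- build_reference(1, 1000, gc = 0.5, seed = 8)
  expect_false(identical(ref$chromosomes, ref3$chromosomes))
  expect_error(build_reference(1, 0), "positive")
  expect_error(build_reference(2, c(100, 100), names = c("a", "a")))
})

test_that("GC composition matches the target within 2% at scale", {
  # 4 x 500 kb at GC 0.36: observed GC must land in [0.34, 0.38]
  ref <- build_reference(4, rep(500000L, 4), gc = 0.36, seed = 1)
  gc <- vapply(ref$chromosomes, tdnascope:::gc_content, numeric(1))
  expect_true(all(gc >= 0.34 & gc <= 0.38))
})
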