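test_that("vector annotation validates borders and exposes the T-DNA span", {
  vec <- synthetic_vector(seed = 1)
  expect_equal(vec$lb_interval, c(10509L, 10524L))
  expect_equal(vec$rb_interval, c(2454L, 2478L))
  expect_equal(vec$tdna_span, c(2454L, 10524L))
  span_len <- tdna_fragment_length(vec$tdna_span[1], vec$tdna_span[2],
                                   inclusive = TRUE)
  expect_gte(span_len, vec$canonical_tdna_length_range[1])
  expect_lte(span_len, vec$canonical_tdna_length_range[2])
  expect_error(vector_annotation("ACGT"), "lb_interval")
  expect_error(synthetic_vector(length = 5000), "10524")
})

test_that("fragment extraction honours orientation and circularity", {
  vec <- synthetic_vector(seed = 2)
  s <- vec$sequence
  fwd <- tdna_fragment_seq(vec, 101, 200)
  expect_identical(fwd, substr(s, 101, 200))
  rev <- tdna_fragment_seq(vec, 200, 101)
  expect_identical(rev, rc(substr(s, 101, 200)))
  # wrapping across the circular origin, opt-in
  wrap <- tdna_fragment_seq(vec, vec$length - 9, 10, allow_wrap = TRUE)
  expect_identical(wrap, paste0(substr(s, vec$length - 9, vec$length),
                                substr(s, 1, 10)))
  expect_error(tdna_fragment_seq(vec, 0, 10), "outside")
  expect_error(tdna_fragment_seq(vec, 1, vec$length + 1), "outside")
})

test_that("fragment length conventions are distinct", {
  expect_equal(tdna_fragment_length(9144, 10320), 1176L)
  expect_equal(tdna_fragment_length(7240, 2523), 4717L)
  expect_equal(tdna_fragment_length(100, 100), 0L)
  expect_equal(tdna_fragment_length(100, 100, inclusive = TRUE), 1L)
})
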