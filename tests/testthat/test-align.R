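test_that("self-alignment is full-length at identity 1", {
  set.seed(101)
  t1 <- rnd_dna(1000)
  a <- align_local(c(r = t1), c(tg = t1))
  expect_equal(nrow(a), 1L)
  expect_equal(a$rstart, 1L); expect_equal(a$rend, 1000L)
  expect_equal(a$tstart, 1L); expect_equal(a$tend, 1000L)
  expect_equal(a$identity, 1)
  expect_equal(a$score, 2000L)
})

test_that("disjoint sequences yield no alignment and bad input errors", {
  set.seed(102)
  a <- align_local(c(r = rnd_dna(300)), c(tg = rnd_dna(2000)))
  expect_equal(nrow(a), 0L)
  expect_error(align_local(c(r = ""), c(tg = "ACGT")), "empty")
  expect_error(align_local(c(r = "ACGTACGTACGT"), c(tg = "ACGT"), k = 4),
               "k must be")
})

test_that("a planted exact match is recovered at its exact interval", {
  set.seed(103)
  tgt <- rnd_dna(2000)
  q <- paste0(rnd_dna(80), substr(tgt, 501, 650), rnd_dna(70))
  a <- align_local(c(r = q), c(tg = tgt))
  expect_equal(nrow(a), 1L)
  expect_equal(unname(c(a$rstart, a$rend, a$tstart, a$tend)),
               c(81L, 230L, 501L, 650L))
  expect_equal(a$identity, 1)
})

test_that("best local score equals the Smith-Waterman oracle on small instances", {
  set.seed(104)
  for (case in 1:6) {
    tgt <- rnd_dna(sample(200:300, 1))
    s0 <- sample(1:80, 1)
    len <- sample(100:180, 1)
    q <- mutate_subs(substr(tgt, s0, min(nchar(tgt), s0 + len)), 0.02)
    a <- align_local(c(r = q), c(tg = tgt), min_score = 20, min_chain_anchors = 1)
    expect_gt(nrow(a), 0)
    expect_equal(max(a$score), sw_oracle(q, tgt),
                 info = sprintf("case %d", case))
  }
})

test_that("reverse-complementing the query flips strand, same target interval", {
  set.seed(105)
  tgt <- rnd_dna(3000)
  q <- substr(tgt, 1001, 1800)
  fwd <- align_local(c(r = q), c(tg = tgt))
  rev <- align_local(c(r = rc(q)), c(tg = tgt))
  expect_equal(fwd$strand, "+")
  expect_equal(rev$strand, "-")
  expect_equal(rev$tstart, fwd$tstart)
  expect_equal(rev$tend, fwd$tend)
  expect_equal(rev$score, fwd$score)
})

test_that("identity tracks the injected substitution rate", {
  set.seed(106)
  tgt <- rnd_dna(20000)
  q <- mutate_subs(substr(tgt, 2001, 14000), 0.02)
  a <- align_local(c(r = q), c(tg = tgt))
  expect_equal(nrow(a), 1L)
  expect_gt(a$identity, 0.97)
  expect_lt(a$identity, 0.995)
})
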