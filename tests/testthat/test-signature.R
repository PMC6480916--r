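# Fixed flanks for handcrafted classifier cases: chosen so the ends share
# nothing (left ends ...TTACGT, right starts CCAATG...)
LEFT40 <- "TTGACCTAGGACGTTACCGGATCCTTAGCAGGCATTACGT"
RIGHT40 <- "CCAATGGCTTACGATCCGTAACGGTTCAGACCTTAGGCAT"

test_that("blunt, micro-homology, filler and long homology classify exactly", {
  # blunt: observed is the plain concatenation
  sig <- classify_junction(LEFT40, RIGHT40, paste0(LEFT40, RIGHT40))
  expect_equal(sig$kind, "blunt")
  expect_equal(sig$microhomology_len, 0L)

  # 4-bp micro-homology: right flank begins with the left flank's last 4
  right_mh <- paste0(substr(LEFT40, 37, 40), RIGHT40)
  obs <- paste0(LEFT40, RIGHT40)  # shared ACGT written once
  sig <- classify_junction(LEFT40, right_mh, obs)
  expect_equal(sig$kind, "microhomology")
  expect_equal(sig$microhomology_len, 4L)
  # maximality: the reported homology cannot be extended by one base
  expect_false(substr(LEFT40, 36, 40) == substr(right_mh, 1, 5))

  # 22-bp filler between the flanks
  filler <- "CTAGGTCCAAGTTAACGGATCC"
  sig <- classify_junction(LEFT40, RIGHT40, paste0(LEFT40, filler, RIGHT40))
  expect_equal(sig$kind, "filler")
  expect_equal(sig$filler_seq, filler)

  # 254-bp homology written once
  set.seed(501)
  H <- rnd_dna(254)
  left_h <- paste0(rnd_dna(60), H)
  right_h <- paste0(H, rnd_dna(60))
  sig <- classify_junction(left_h, right_h,
                           paste0(left_h, substr(right_h, 255, 314)),
                           mh_max = 20)
  expect_equal(sig$kind, "long_homology")
  expect_equal(sig$homology_len, 254L)

  # unanchored flanks are an error, not a silent wrong call
  expect_error(classify_junction(LEFT40, RIGHT40, rnd_dna(200)), "unanchored")
  expect_error(classify_junction("ACGT", RIGHT40, paste0(LEFT40, RIGHT40)),
               "flank")
})

test_that("planted (microhomology, filler) parameters are recovered exactly", {
  # 200 random genome-genome junctions planted by the generator; re-derive
  # each signature independently from the emitted haplotype and the edited
  # reference flanks
  vec <- synthetic_vector(seed = 90)
  valid <- rbind(data.frame(m = 0:7, f = 0L),
                 data.frame(m = 0L, f = c(3L, 22L)))
  cases <- valid[rep(seq_len(nrow(valid)), length.out = 200), ]
  set.seed(502)
  n_checked <- 0L
  for (i in seq_len(nrow(cases))) {
    m <- cases$m[i]; f <- cases$f[i]
    sig <- if (f > 0) sig_filler(rnd_dna(f)) else if (m > 0) sig_mh(m) else sig_blunt()
    ref <- build_reference(2, c(3000, 3000), seed = 5000 + i)
    spec <- architecture_spec(list(
      ev_bare_translocation(list("chr1", 1500L, "+"), list("chr2", 1500L, "-"),
                            sig, zygosity = "heterozygous")))
    p <- plant_architecture(ref, vec, spec)
    lay <- p$truth$layout
    jn <- p$truth$junctions[1]
    hit <- tdnascope:::find_junction_in_layout(
      lay[lay$hap == "hap1", ],
      tdnascope:::side(jn$src_a, jn$pos_a, jn$orient_a),
      tdnascope:::side(jn$src_b, jn$pos_b, jn$orient_b))
    der <- p$haplotypes$hap1[[hit$derivative]]
    obs <- substr(der, max(1, hit$prod_pos - 199), hit$prod_pos + 200)
    if (hit$flipped) obs <- rc(obs)
    seqs <- c(p$ref$chromosomes, list(vector = p$vector$sequence))
    left <- tdnascope:::side_seq_toward(seqs, tdnascope:::side(jn$src_a, jn$pos_a, jn$orient_a), 200L)
    right <- tdnascope:::side_seq_from(seqs, tdnascope:::side(jn$src_b, jn$pos_b, jn$orient_b), 200L)
    got <- classify_junction(left, right, obs)
    if (f > 0) {
      expect_equal(got$kind, "filler")
      expect_equal(nchar(got$filler_seq), f)
      expect_equal(got$filler_seq, sig$filler)
    } else if (m > 0) {
      expect_equal(got$kind, "microhomology")
      expect_equal(got$microhomology_len, m)
    } else {
      expect_equal(got$kind, "blunt")
    }
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 150L)
})

test_that("consensus reconstructs a junction window from noisy copies", {
  set.seed(503)
  truth <- rnd_dna(800)
  windows <- vapply(1:20, function(i) {
    w <- mutate_subs(truth, 0.02)
    # random truncation and shift, as read ends produce
    s <- sample(1:30, 1)
    substr(w, s, nchar(w) - sample(0:100, 1))
  }, character(1))
  cons <- tdnascope:::consensus_window(windows)
  expect_true(grepl(substr(truth, 40, 680), cons, fixed = TRUE))
})
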