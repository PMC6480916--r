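test_that("the replica architecture carries the documented inventory", {
  p <- yl_replica(chrom_length = 200000, seed = 11)
  truth <- p$truth

  # six vector-genome insertion loci (the intact insertion counts once)
  jn <- truth$junctions
  gv <- jn[(jn$src_a == "vector") != (jn$src_b == "vector"), ]
  genome_pos <- gv[, c("src_a", "pos_a")]
  # cluster genome sides within 100 bp into loci
  loci <- unique(genome_pos)
  merged <- 0L
  for (ch in unique(loci$src_a)) {
    ps <- sort(loci$pos_a[loci$src_a == ch])
    merged <- merged + sum(diff(ps) > 100) + 1L
  }
  expect_equal(merged, 6L)

  # one intact insertion spanning RB..LB, one truncation, two bridges
  archs <- truth$architectures
  types <- vapply(archs, `[[`, character(1), "type")
  expect_equal(sum(types == "insertion"), 1L)
  expect_equal(sum(types == "truncation"), 1L)
  expect_equal(sum(types == "translocation"), 2L)
  ins <- archs[[which(types == "insertion")]]
  expect_equal(unname(ins$fragments[1, ]), p$vector$tdna_span)

  # the two bridges use the printed fragment lists verbatim
  br <- archs[types == "translocation"]
  sizes <- vapply(br, function(a) nrow(a$fragments), integer(1))
  f4 <- br[[which(sizes == 4)]]$fragments
  f6 <- br[[which(sizes == 6)]]$fragments
  expect_equal(unname(f4), matrix(unlist(tdnascope:::YL_FRAGS_4), ncol = 2,
                                  byrow = TRUE))
  expect_equal(unname(f6), matrix(unlist(tdnascope:::YL_FRAGS_6), ncol = 2,
                                  byrow = TRUE))

  # one bare genome-genome translocation junction (TB) plus the
  # homozygous-deletion junction
  gg <- jn[jn$src_a != "vector" & jn$src_b != "vector", ]
  expect_equal(nrow(gg), 2L)
  tb <- gg[gg$src_a != gg$src_b | gg$orient_a == gg$orient_b, ]
  expect_equal(nrow(tb), 1L)
  expect_setequal(c(tb$src_a, tb$src_b), c("Chr2", "Chr8"))

  # losses: heterozygous terminal Chr9 fragment, homozygous TB->IS2 interval
  losses <- truth$losses
  het <- losses[losses$zygosity == "heterozygous" & losses$chrom == "Chr9", ]
  expect_equal(c(het$start, het$end), c(1L, 80000L))
  hom <- losses[losses$zygosity == "homozygous", ]
  expect_equal(hom$chrom, "Chr2")
  expect_equal(hom$end - hom$start + 1L, 16000L)  # 0.08 x 200 kb, TB->IS2 scaled

  # signature inventory: two fillers (22 and 3 bp), 254-bp homology at the
  # junction shared by both concatemers, 4-7 bp micro-homologies elsewhere
  expect_setequal(nchar(jn$filler_seq[jn$sig_kind == "filler"]), c(22L, 3L))
  hom254 <- jn[jn$sig_kind == "long_homology", ]
  expect_true(all(hom254$homology_len == 254L))
  expect_true(all(hom254$pos_a == 7239L & hom254$pos_b == 7919L))
  mh <- jn$mh_len[jn$sig_kind == "microhomology"]
  expect_true(all(mh >= 4 & mh <= 7))
})

test_that("the replica refuses undersized references", {
  ref <- build_reference(4, rep(100000L, 4), seed = 1)
  vec <- synthetic_vector(seed = 2)
  expect_error(yl_replica_spec(ref, vec), "too small")
  ref3 <- build_reference(3, rep(300000L, 3), seed = 1)
  expect_error(yl_replica_spec(ref3, vec), "too small")
})

test_that("replica generation is deterministic in the seed", {
  a <- yl_replica(chrom_length = 200000, seed = 3)
  b <- yl_replica(chrom_length = 200000, seed = 3)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$truth$junctions, b$truth$junctions)
})
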