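test_that("an intact insertion adds exactly the T-DNA length", {
  ref <- build_reference(1, 50000, seed = 41)
  vec <- synthetic_vector(seed = 42)
  spec <- architecture_spec(list(
    ev_insertion("chr1", 20000, list(vec$tdna_span),
                 list(sig_blunt(), sig_blunt()), zygosity = "heterozygous")))
  p <- plant_architecture(ref, vec, spec)
  tdna_len <- vec$tdna_span[2] - vec$tdna_span[1] + 1L
  expect_equal(nchar(p$haplotypes$hap1[[1]]), 50000L + tdna_len)
  expect_equal(nchar(p$haplotypes$hap2[[1]]), 50000L)  # heterozygous
})

test_that("a planted filler appears verbatim between flank and vector block", {
  ref <- build_reference(1, 40000, seed = 43)
  vec <- synthetic_vector(seed = 44)
  filler <- "CTAGGTCCAAGTTAACGGATCC"  # 22 bp
  spec <- architecture_spec(list(
    ev_insertion("chr1", 15000, list(c(3000, 6000)),
                 list(sig_filler(filler), sig_blunt()),
                 zygosity = "heterozygous")))
  p <- plant_architecture(ref, vec, spec)
  lay <- p$truth$layout
  fb <- lay[lay$kind == "filler", ]
  expect_equal(nrow(fb), 1L)
  der <- p$haplotypes$hap1[[fb$derivative]]
  expect_identical(substr(der, fb$prod_start, fb$prod_end), filler)
  # flanked by the chromosome up to the locus and the fragment after it
  expect_identical(substr(der, fb$prod_start - 20, fb$prod_start - 1),
                   substr(p$ref$chromosomes$chr1, 14981, 15000))
  expect_identical(substr(der, fb$prod_end + 1, fb$prod_end + 20),
                   substr(p$vector$sequence, 3000, 3019))
})

test_that("translocations put one genome-vector junction on each side", {
  ref <- build_reference(2, c(50000, 50000), seed = 45)
  vec <- synthetic_vector(seed = 46)
  spec <- architecture_spec(list(
    ev_translocation(list("chr1", 20001, "-"), list("chr2", 30001, "-"),
                     list(c(9144, 10320), c(7240, 2523)),
                     list(sig_blunt(), sig_mh(4), sig_blunt()),
                     zygosity = "heterozygous")))
  p <- plant_architecture(ref, vec, spec)
  jn <- p$truth$junctions
  gv <- jn[(jn$src_a != "vector") != (jn$src_b != "vector"), ]
  expect_equal(nrow(gv), 2L)
  expect_setequal(gv$src_a, c("chr1", "chr2"))
})

test_that("heterozygous events live on one haplotype, homozygous on both", {
  ref <- build_reference(2, c(60000, 60000), seed = 47)
  vec <- synthetic_vector(seed = 48)
  spec <- architecture_spec(list(
    ev_deletion("chr1", 20001, 30000, sig_blunt(), zygosity = "homozygous"),
    ev_deletion("chr2", 1, 15000, sig_blunt(), zygosity = "heterozygous")))
  p <- plant_architecture(ref, vec, spec)
  losses <- p$truth$losses
  expect_equal(losses[losses$chrom == "chr1", ]$zygosity, "homozygous")
  expect_equal(losses[losses$chrom == "chr2", ]$zygosity, "heterozygous")
  # the homozygous deletion junction is present on both haplotypes
  jn <- p$truth$junctions
  dj <- jn[jn$src_a == "chr1", ]
  expect_equal(dj$haps, "hap1,hap2")
  # haplotype 2 carries no trace of the heterozygous deletion
  expect_equal(nchar(p$haplotypes$hap2[[which(grepl("d02", names(p$haplotypes$hap2)))]]),
               60000L)
})

test_that("invalid specifications are rejected", {
  ref <- build_reference(1, 30000, seed = 49)
  vec <- synthetic_vector(seed = 50)
  expect_error(plant_architecture(ref, vec, architecture_spec(list(
    ev_insertion("chr1", 10000, list(c(100, vec$length + 50)),
                 list(sig_blunt(), sig_blunt()))))),
    "outside vector")
  expect_error(plant_architecture(ref, vec, architecture_spec(list(
    ev_insertion("chrX", 10000, list(c(100, 200)),
                 list(sig_blunt(), sig_blunt()))))),
    "unknown chromosome")
  # two events claiming the same breakpoint side overlap
  expect_error(plant_architecture(ref, vec, architecture_spec(list(
    ev_truncation("chr1", 10000, list(c(100, 600)), list(sig_blunt())),
    ev_bare_translocation(list("chr1", 10000, "+"), list("chr1", 20000, "-"),
                          sig_blunt())))),
    "overlapping events")
})

test_that("junction round-trip holds across random worlds", {
  # plant_architecture re-derives every junction from the emitted
  # haplotypes and errors on mismatch, so surviving construction IS the
  # round trip; assert the truth tables are internally consistent too
  for (seed in c(61, 62, 63)) {
    p <- tiny_world(seed = seed)
    jn <- p$truth$junctions
    expect_equal(nrow(jn), 3L)  # two insertion junctions + one bare junction
    lay <- p$truth$layout
    for (i in seq_len(nrow(jn))) {
      hit <- tdnascope:::find_junction_in_layout(
        lay[lay$hap == strsplit(jn$haps[i], ",")[[1]][1], ],
        tdnascope:::side(jn$src_a[i], jn$pos_a[i], jn$orient_a[i]),
        tdnascope:::side(jn$src_b[i], jn$pos_b[i], jn$orient_b[i]))
      expect_false(is.null(hit))
    }
  }
})
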