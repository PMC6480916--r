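# A scaled replica of the published yl rearrangement architecture.
#
# The replica keeps the documented inventory on four chromosomes named
# after the ones involved in the real mutant (Chr2, Chr8, Chr9, Chr11),
# with genome loci placed proportionally and vector fragment coordinates
# kept verbatim:
#
#   Chr2  --q1--------q2====q3--------q4------|       (5 fragments)
#   der1:  Chr2[1..q1] + truncated T-DNA                 (IS1, case 2)
#   der2:  Chr8[1..r1] + TB + revcomp(Chr2[q1+1..q2])    (bare TB junction)
#   hom:   Chr2[q2+1..q3] deleted from BOTH haplotypes   (the TB->IS2 40-kb
#          interval, scaled with the genome)
#   der3:  revcomp(Chr2[q3+1..q4]) + 4-fragment concatemer + Chr8[r2+1..]
#                                                        (IS2/IS4, case 3)
#   der4:  revcomp(Chr2[q4+1..]) + 6-fragment concatemer + Chr9[s1+1..]
#                                                        (IS3/IS5, case 3)
#   Chr9[1..s1] lost from haplotype 1 only               (heterozygous
#          terminal loss, the Chr9-1 analog)
#   Chr11: intact T-DNA (RB to LB) at t1 with a short locus deletion
#                                                        (IS6, case 1)
#
# All rearranged events are heterozygous (haplotype 1), matching a
# primary transformant; only the TB->IS2 interval is absent from both
# haplotypes (haplotype 2 carries it as a simple interior deletion).
#
# Junction signatures: a 22-bp filler at the first 4-fragment genome
# junction and a 3-bp filler at a vector junction of the 6-fragment
# concatemer; 254-bp homology at the 7239/7919 vector junction, which
# occurs in BOTH concatemers (the k/f analogs); 4-7-bp micro-homologies
# elsewhere; blunt joins at TB, the deletion junction and the LB-side
# insertion junction.

YL_FILLER_22 <- "CTAGGTCCAAGTTAACGGATCC"
YL_FILLER_3 <- "TCA"

YL_FRAGS_4 <- list(c(9144L, 10320L), c(7240L, 2523L),
                   c(2467L, 7239L), c(7919L, 7305L))
YL_FRAGS_6 <- list(c(9854L, 10334L), c(5396L, 2476L), c(9014L, 10354L),
                   c(10404L, 8306L), c(4099L, 7239L), c(7919L, 2697L))

#' Architecture specification replicating the yl mutant
#'
#' Builds a scaled replica of the published rearrangement: six
#' vector-genome insertion loci (one carrying an intact right-border to
#' left-border T-DNA), a 4-fragment and a 6-fragment concatemer bridge
#' with the printed vector coordinates, one chromosome truncation, one
#' bare genome-genome translocation junction (TB), one heterozygous
#' terminal loss and one homozygous interior deletion, with the reported
#' junction signatures (22-bp and 3-bp fillers, 254-bp homology at the
#' junction shared by both concatemers, 4-7-bp micro-homologies
#' elsewhere).
#'
#' Genome loci are placed at fixed fractions of the chromosome length, so
#' the architecture scales with the reference; vector coordinates are
#' kept verbatim. The short deletion at the intact-insertion locus is
#' configurable (`locus_deletion`, default 20 bp) because its real size
#' is not published.
#'
#' @param ref a [build_reference()] genome with at least 4 chromosomes of
#'   >= 200 kb; the first four are used in the roles of Chr2, Chr8, Chr9
#'   and Chr11
#' @param vector a [vector_annotation()] (pGWB2-style layout; see
#'   [synthetic_vector()])
#' @param locus_deletion bp deleted at the intact-insertion locus
#' @return an `architecture_spec` with attribute `loci` (the planted
#'   insertion-site table)
#' @export
yl_replica_spec <- function(ref, vector, locus_deletion = 20L) {
  chroms <- names(ref$chromosomes)
  if (length(chroms) < 4 || any(ref$lengths[chroms[1:4]] < 200000L)) {
    stop("reference too small: need >= 4 chromosomes of >= 200 kb")
  }
  c2 <- chroms[1]; c8 <- chroms[2]; c9 <- chroms[3]; c11 <- chroms[4]
  L2 <- ref$lengths[[c2]]; L8 <- ref$lengths[[c8]]
  L9 <- ref$lengths[[c9]]; L11 <- ref$lengths[[c11]]
  q1 <- as.integer(round(0.46 * L2)); q2 <- as.integer(round(0.524 * L2))
  q3 <- as.integer(round(0.604 * L2)); q4 <- as.integer(round(0.76 * L2))
  r1 <- as.integer(round(0.30 * L8)); r2 <- as.integer(round(0.64 * L8))
  s1 <- as.integer(round(0.40 * L9)); t1 <- as.integer(round(0.50 * L11))

  events <- list(
    # IS1: one-ended truncated T-DNA, truncates Chr2 (case 2)
    ev_truncation(c2, q1, list(c(3000L, 9000L)), list(sig_mh(4)),
                  zygosity = "heterozygous"),
    # TB: bare genome-genome translocation junction
    ev_bare_translocation(list(c8, r1, "+"), list(c2, q2, "+"), sig_blunt(),
                          zygosity = "heterozygous"),
    # TB -> IS2 interval: homozygous interior deletion
    ev_deletion(c2, q2 + 1L, q3, sig_blunt(), zygosity = "homozygous"),
    # IS2/IS4: 4-fragment concatemer bridging Chr2 and Chr8 (case 3)
    ev_translocation(list(c2, q3 + 1L, "-"), list(c8, r2 + 1L, "-"),
                     YL_FRAGS_4,
                     list(sig_filler(YL_FILLER_22), sig_mh(5), sig_mh(6),
                          sig_hom(254), sig_mh(4)),
                     zygosity = "heterozygous"),
    # IS3/IS5: 6-fragment concatemer bridging Chr2 and Chr9 (case 3)
    ev_translocation(list(c2, q4 + 1L, "-"), list(c9, s1 + 1L, "-"),
                     YL_FRAGS_6,
                     list(sig_mh(7), sig_mh(4), sig_mh(5),
                          sig_filler(YL_FILLER_3), sig_mh(6), sig_hom(254),
                          sig_mh(5)),
                     zygosity = "heterozygous"),
    # Chr9-1 analog: heterozygous terminal loss
    ev_deletion(c9, 1L, s1, sig_blunt(), zygosity = "heterozygous"),
    # IS6: intact T-DNA (RB..LB) with a short locus deletion (case 1)
    ev_insertion(c11, t1, list(vector$tdna_span), list(sig_mh(6), sig_blunt()),
                 zygosity = "heterozygous", locus_deletion = locus_deletion)
  )
  spec <- architecture_spec(events)
  attr(spec, "loci") <- data.table(
    is = paste0("IS", 1:6),
    chrom = c(c2, c2, c2, c8, c9, c11),
    pos = c(q1, q3 + 1L, q4 + 1L, r2 + 1L, s1 + 1L, t1),
    role = c("truncation", "bridge4_left", "bridge6_left",
             "bridge4_right", "bridge6_right", "intact_insertion"))
  attr(spec, "breakpoints") <- list(q1 = q1, q2 = q2, q3 = q3, q4 = q4,
                                    r1 = r1, r2 = r2, s1 = s1, t1 = t1)
  spec
}

#' Build the complete yl replica world
#'
#' Convenience wrapper: random reference (4 chromosomes) and synthetic
#' vector, replica architecture planted, ready for [simulate_reads()].
#'
#' @param chrom_length chromosome length in bp (>= 200 kb)
#' @param seed integer seed for reference and vector generation
#' @param gc reference GC fraction
#' @param locus_deletion see [yl_replica_spec()]
#' @return the [plant_architecture()] result, with the spec attached as
#'   `$spec`
#' @export
yl_replica <- function(chrom_length = 500000L, seed = 1L, gc = 0.36,
                       locus_deletion = 20L) {
  ref <- build_reference(4, rep(chrom_length, 4), gc = gc, seed = seed,
                         names = c("Chr2", "Chr8", "Chr9", "Chr11"))
  vec <- synthetic_vector(seed = seed + 1000L)
  spec <- yl_replica_spec(ref, vec, locus_deletion = locus_deletion)
  planted <- plant_architecture(ref, vec, spec)
  planted$spec <- spec
  planted
}
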