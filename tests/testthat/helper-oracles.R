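# Independent oracles used by the test suite. These deliberately share no
# code with the implementation paths they check.

# random DNA without going through the package generator
rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rc <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Brute-force affine-gap local alignment (Smith-Waterman / Gotoh) under the
# package's fixed scoring: match +2, mismatch -4, gap open -4, extend -2
# (a gap of length L costs 4 + 2*(L-1)). Returns the best local score.
sw_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) 2 else -4
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s)
      X[i, j] <- max(M[i - 1, j] - 4, X[i - 1, j] - 2, Y[i - 1, j] - 4)
      Y[i, j] <- max(M[i, j - 1] - 4, Y[i, j - 1] - 2, X[i, j - 1] - 4)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# all-pairs single-linkage clustering with per-axis tolerance; returns a
# canonical partition labelling (first occurrence order)
cluster_oracle <- function(pa, pb, tol) {
  n <- length(pa)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(pa[i] - pa[j]) <= tol && abs(pb[i] - pb[j]) <= tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}

# partition equality irrespective of label numbering
same_partition <- function(l1, l2) {
  identical(split(seq_along(l1), l1)[order(vapply(split(seq_along(l1), l1), min, integer(1)))],
            split(seq_along(l2), l2)[order(vapply(split(seq_along(l2), l2), min, integer(1)))])
}

# per-base error injection independent of the package's C++ error model
# (substitutions only; used where tests need errors the oracle controls)
mutate_subs <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

# small planted world reused by several files: one intact insertion plus a
# bare translocation on two chromosomes
tiny_world <- function(seed = 5, chrom = c(80000L, 60000L)) {
  ref <- build_reference(2, chrom, gc = 0.4, seed = seed)
  vec <- synthetic_vector(seed = seed + 100L)
  spec <- architecture_spec(list(
    ev_insertion("chr1", as.integer(chrom[1] / 2), list(vec$tdna_span),
                 list(sig_mh(5), sig_blunt()), zygosity = "heterozygous"),
    ev_bare_translocation(list("chr2", as.integer(chrom[2] * 0.4), "+"),
                          list("chr1", as.integer(chrom[1] * 0.8), "+"),
                          sig_mh(4), zygosity = "heterozygous")))
  planted <- plant_architecture(ref, vec, spec)
  planted$spec <- spec
  planted
}
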