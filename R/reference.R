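#' Build a random multi-chromosome reference genome
#'
#' A desk-scale stand-in for a plant reference assembly: independent
#' random chromosomes at a configurable GC content. Deterministic for a
#' fixed seed.
#'
#' @param n_chromosomes number of chromosomes
#' @param lengths integer vector of chromosome lengths in bp (recycled to
#'   `n_chromosomes`)
#' @param gc GC fraction
#' @param seed integer seed
#' @param names chromosome names; default `chr1..chrN`
#' @return a `reference_genome`: named list of chromosome sequences plus
#'   metadata
#' @export
build_reference <- function(n_chromosomes, lengths, gc = 0.36, seed = 1L,
                            names = NULL) {
  stopifnot(n_chromosomes >= 1)
  lengths <- rep_len(as.integer(lengths), n_chromosomes)
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  if (is.null(names)) names <- paste0("chr", seq_len(n_chromosomes))
  stopifnot(length(names) == n_chromosomes, !anyDuplicated(names))
  seqs <- with_seed(seed, {
    lapply(lengths, function(n) random_dna(n, gc))
  })
  names(seqs) <- names
  structure(list(chromosomes = seqs,
                 lengths = setNames(lengths, names),
                 gc = gc, seed = as.integer(seed)),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("reference_genome: %d chromosomes, %s bp total\n",
              length(x$chromosomes),
              format(sum(x$lengths), big.mark = ",")))
  invisible(x)
}

ref_chrom_names <- function(ref) names(ref$chromosomes)

ref_check_locus <- function(ref, chrom, pos) {
  if (!chrom %in% ref_chrom_names(ref)) stop("unknown chromosome: ", chrom)
  if (pos < 1 || pos > ref$lengths[[chrom]]) {
    stop(sprintf("locus %s:%d outside chromosome bounds", chrom, pos))
  }
  invisible(TRUE)
}
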