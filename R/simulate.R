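#' Read simulation parameters
#'
#' Long-read simulation settings: fold coverage, a log-normal read-length
#' distribution and independent per-base error rates. Defaults emulate a
#' long-read run at a gentle error rate (1% substitutions, 0.5%
#' insertions, 0.5% deletions, 12-kb mean reads); they are not a
#' platform-specific error profile.
#'
#' @param mean_depth expected aligned depth over the reference (both
#'   haplotypes of a diploid together), fold
#' @param read_length `c(mean, sd, min)` in bp of the read-length
#'   distribution (log-normal, truncated at `min`)
#' @param error_rates `c(substitution, insertion, deletion)` per-base
#'   probabilities, each in `[0, 0.2]`
#' @param seed integer seed; all randomness in [simulate_reads()] flows
#'   from it
#' @return a `read_sim_params` object
#' @export
read_sim_params <- function(mean_depth = 30,
                            read_length = c(12000, 6000, 500),
                            error_rates = c(0.01, 0.005, 0.005),
                            seed = 1L) {
  stopifnot(mean_depth > 0,
            length(read_length) == 3, all(read_length > 0),
            read_length[1] >= read_length[3],
            length(error_rates) == 3,
            all(error_rates >= 0), all(error_rates <= 0.2))
  structure(list(mean_depth = mean_depth,
                 read_length = read_length,
                 error_rates = error_rates,
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

#' Simulate long reads from a diploid genome
#'
#' Reads are sampled uniformly per base across both haplotypes (so a
#' locus present on both haplotypes receives the full `mean_depth` and a
#' heterozygous locus half of it), given a random strand, and passed
#' through an independent per-base substitution/insertion/deletion error
#' model. The per-read origin (haplotype, sequence, interval, strand) is
#' recorded so that simulations can serve as their own alignment oracle.
#'
#' Deterministic: the same `params$seed` reproduces byte-identical reads
#' and origin log.
#'
#' @param genome a diploid genome: `list(hap1 = <named character vector of
#'   sequences>, hap2 = ...)`, e.g. the `haplotypes` element returned by
#'   [plant_architecture()]. A plain named character vector is treated as
#'   haploid.
#' @param params a [read_sim_params()] object
#' @return list with `reads` (named character vector), `origin`
#'   (data.table: read_id, hap, seq, start, end, strand, length) and
#'   `params`
#' @export
simulate_reads <- function(genome, params = read_sim_params()) {
  stopifnot(inherits(params, "read_sim_params"))
  if (!is.list(genome)) genome <- list(hap1 = genome)
  haps <- names(genome)
  if (is.null(haps)) haps <- names(genome) <- paste0("hap", seq_along(genome))
  pool <- rbindlist(lapply(haps, function(h) {
    seqs <- genome[[h]]
    if (length(seqs) == 0) stop("empty genome")
    data.table(hap = h, seq = names(seqs), len = nchar(unname(seqs)))
  }))
  if (nrow(pool) == 0 || all(pool$len == 0)) stop("empty genome")
  total_target <- params$mean_depth * sum(pool$len) / length(haps)

  with_seed(params$seed, {
    mu_l <- params$read_length[1]; sd_l <- params$read_length[2]
    min_l <- params$read_length[3]
    sigma2 <- log(1 + (sd_l / mu_l)^2)
    n_est <- ceiling(1.3 * total_target / mu_l) + 10L
    lens <- integer(0)
    while (sum(lens) < total_target) {
      draw <- round(rlnorm(n_est, log(mu_l) - sigma2 / 2, sqrt(sigma2)))
      lens <- c(lens, pmax(as.integer(draw), as.integer(min_l)))
    }
    n <- which(cumsum(as.numeric(lens)) >= total_target)[1]
    lens <- lens[seq_len(n)]

    src_idx <- sample.int(nrow(pool), n, replace = TRUE,
                          prob = pool$len / sum(pool$len))
    starts <- floor(runif(n) * pool$len[src_idx]) + 1L
    ends <- pmin(starts + lens - 1L, pool$len[src_idx])
    strands <- ifelse(runif(n) < 0.5, "+", "-")

    origin <- data.table(
      read_id = sprintf("read%06d", seq_len(n)),
      hap = pool$hap[src_idx], seq = pool$seq[src_idx],
      start = starts, end = ends, strand = strands)
    origin[, length := end - start + 1L]

    seqs <- character(n)
    for (h in haps) {
      for (s in unique(origin[hap == h, seq])) {
        idx <- which(origin$hap == h & origin$seq == s)
        seqs[idx] <- substring(genome[[h]][[s]], origin$start[idx],
                               origin$end[idx])
      }
    }
    flip <- strands == "-"
    if (any(flip)) {
      seqs[flip] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[flip])))
    }
    er <- params$error_rates
    if (any(er > 0)) {
      seqs <- cpp_mutate_reads(seqs, er[1], er[2], er[3],
                               as.double(params$seed) * 2654435761)
    }
    names(seqs) <- origin$read_id
    list(reads = seqs, origin = origin, params = params)
  })
}

#' Write a simulation to disk
#'
#' Emits reads as FASTQ (fixed per-run quality derived from the error
#' rate) and the origin log as TSV.
#'
#' @param sim result of [simulate_reads()]
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @return named character vector of written paths
#' @export
write_simulation <- function(sim, dir, prefix = "reads") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  err <- sum(sim$params$error_rates)
  q <- if (err <= 0) 60L else min(60L, max(2L, round(-10 * log10(err))))
  qc <- rawToChar(as.raw(33L + q))
  fq <- file.path(dir, paste0(prefix, ".fastq"))
  tsv <- file.path(dir, paste0(prefix, ".origin.tsv"))
  write_fastq(sim$reads, fq, qual_char = qc)
  fwrite(sim$origin, tsv, sep = "\t")
  c(fastq = fq, origin = tsv)
}
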