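# Binned read depth and copy-loss calling.
#
# In a diploid, a fragment lost from one haplotype shows ~0.5x depth
# relative to a control sample, and an interval lost from both shows ~0x.
# Depth is computed from the same genome alignments used for segmentation,
# binned, and the mutant/control ratio is segmented into runs.

#' Binned depth profile from genome alignments
#'
#' Bin value = aligned bases overlapping the bin / bin width. Only
#' genome targets are counted (vector alignments are ignored).
#'
#' @param alignments alignment table ([align_local()] format) or a
#'   segments table
#' @param ref a [build_reference()] genome
#' @param bin_size bin width in bp (>= 100)
#' @return a `depth_profile`: data.table(chrom, bin_start, bin_end, depth)
#'   with attribute `total_mapped`
#' @export
compute_depth <- function(alignments, ref, bin_size = 1000L) {
  stopifnot(bin_size >= 100)
  aln <- as.data.table(alignments)
  if ("source" %in% names(aln) && !"target" %in% names(aln)) {
    setnames(aln, "source", "target")
  }
  aln <- aln[target %in% names(ref$chromosomes)]
  bins <- rbindlist(lapply(names(ref$chromosomes), function(ch) {
    L <- ref$lengths[[ch]]
    starts <- seq.int(1L, L, by = bin_size)
    data.table(chrom = ch, bin_start = starts,
               bin_end = pmin(starts + bin_size - 1L, L))
  }))
  bins[, depth := 0]
  total <- 0
  if (nrow(aln)) {
    for (ch in unique(aln$target)) {
      a <- aln[target == ch]
      L <- ref$lengths[[ch]]
      nb <- ceiling(L / bin_size)
      cover <- numeric(nb)
      b0 <- (pmax(a$tstart, 1L) - 1L) %/% bin_size + 1L
      b1 <- (pmin(a$tend, L) - 1L) %/% bin_size + 1L
      for (i in seq_len(nrow(a))) {
        s <- pmax(a$tstart[i], 1L); e <- pmin(a$tend[i], L)
        if (e < s) next
        total <- total + (e - s + 1L)
        for (b in b0[i]:b1[i]) {
          lo <- (b - 1L) * bin_size + 1L
          hi <- min(b * bin_size, L)
          cover[b] <- cover[b] + max(0L, min(e, hi) - max(s, lo) + 1L)
        }
      }
      width <- pmin(seq_len(nb) * bin_size, L) - (seq_len(nb) - 1L) * bin_size
      bins[chrom == ch, depth := cover / width]
    }
  }
  setattr(bins, "total_mapped", total)
  setattr(bins, "class", c("depth_profile", class(bins)))
  bins[]
}

#' Call heterozygous/homozygous losses from a depth ratio
#'
#' Homozygous losses are crisp (no mutant reads at all) and are called
#' from runs of raw bins with ratio <= `hom_max`, so their boundaries are
#' bin-accurate. Heterozygous losses sit at ratio ~0.5 where per-bin
#' noise is large -- long reads make adjacent bins strongly correlated --
#' so they are called on a rolling-mean ratio (window `smooth_bins`) and
#' must additionally pass a read-count z-test (`min_z`) against equal
#' coverage, which controls false positives that ratio-band runs alone
#' cannot. Bins whose control depth falls below `min_control_depth` are
#' masked: they neither support nor break a run.
#'
#' @param mutant,control `depth_profile` objects sharing the same binning
#' @param het_band `c(lo, hi)` smoothed-ratio band for heterozygous loss
#' @param hom_max raw-ratio ceiling for homozygous loss
#' @param min_event_bins minimum bins per call
#' @param min_control_depth mask bins with control depth below this
#' @param smooth_bins rolling-mean window for the heterozygous ratio,
#'   bins; choose >= 2 read lengths worth of bins
#' @param min_z minimum |z| of the region read-count test for
#'   heterozygous calls
#' @param read_length mean read length in bp, used to convert depth into
#'   effective read counts for the z-test
#' @param exclude optional data.table (chrom, start, end) of intervals to
#'   mask, typically +/- one read length around called breakpoints: a
#'   derivative molecule's end produces a coverage ramp about one read
#'   length long that mimics partial loss
#' @return data.table of loss calls: chrom, start, end, zygosity, n_bins,
#'   mutant_mean, control_mean, ratio
#' @export
call_losses <- function(mutant, control, het_band = c(0.35, 0.65),
                        hom_max = 0.1, min_event_bins = 5L,
                        min_control_depth = 10, smooth_bins = 25L,
                        min_z = 3.5, read_length = 12000, exclude = NULL) {
  m <- as.data.table(mutant); ct <- as.data.table(control)
  d <- merge(m, ct, by = c("chrom", "bin_start", "bin_end"),
             suffixes = c("_mut", "_ctl"))
  if (nrow(d) != nrow(m)) stop("mutant and control profiles do not share binning")
  setorder(d, chrom, bin_start)
  d[, masked := depth_ctl < min_control_depth]
  if (!is.null(exclude) && nrow(exclude)) {
    for (i in seq_len(nrow(exclude))) {
      d[chrom == exclude$chrom[i] & bin_start <= exclude$end[i] &
          bin_end >= exclude$start[i] & depth_mut > hom_max * pmax(depth_ctl, 1),
        masked := TRUE]
    }
  }
  d[, ratio := ifelse(masked, NA_real_, depth_mut / pmax(depth_ctl, 1e-9))]
  d[, `:=`(sm_mut = rolling_mean(depth_mut, smooth_bins),
           sm_ctl = rolling_mean(depth_ctl, smooth_bins)), by = chrom]
  d[, sm_ratio := sm_mut / pmax(sm_ctl, 1e-9)]
  # run construction uses only the band's upper bound: a heterozygous
  # region's smoothed ratio can wander well below 0.35 locally, and
  # "deeper loss than heterozygous" must not break the run as if it were
  # normal coverage; the homozygous state and the z-test bound the class
  # from below
  d[, state := fifelse(masked, "masked",
                fifelse(ratio <= hom_max, "homozygous",
                fifelse(sm_ratio <= het_band[2], "heterozygous", "normal")))]
  calls <- list()
  for (ch in unique(d$chrom)) {
    x <- d[chrom == ch]
    runs <- collapse_runs(x$state)
    for (r in runs) {
      if (!r$state %in% c("heterozygous", "homozygous")) next
      idx <- r$idx
      if (length(idx) < min_event_bins) next
      mut_mean <- mean(x$depth_mut[idx]); ctl_mean <- mean(x$depth_ctl[idx])
      if (r$state == "heterozygous") {
        # effective reads overlapping the region (depth x (W + L) / L)
        W <- x$bin_end[idx[length(idx)]] - x$bin_start[idx[1]] + 1L
        n_m <- mut_mean * (W + read_length) / read_length
        n_c <- ctl_mean * (W + read_length) / read_length
        phat <- n_m / (n_m + n_c)
        z <- abs(phat - 0.5) / sqrt(0.25 / (n_m + n_c))
        if (z < min_z) next
        # boundary refinement: the detection band truncates the region at
        # bins whose smoothed ratio wanders high, biasing the measured
        # ratio downward. Move each boundary to where the smoothed ratio
        # crosses the midpoint between the region's ratio and normal
        # coverage -- the approximately unbiased step-edge estimate.
        thr <- (mut_mean / max(ctl_mean, 1e-9) + 1) / 2
        lo <- idx[1]; hi <- idx[length(idx)]
        while (lo > 1L && !x$masked[lo - 1L] &&
               x$state[lo - 1L] != "homozygous" &&
               x$sm_ratio[lo - 1L] <= thr) lo <- lo - 1L
        while (lo < hi && x$sm_ratio[lo] > thr) lo <- lo + 1L
        while (hi < nrow(x) && !x$masked[hi + 1L] &&
               x$state[hi + 1L] != "homozygous" &&
               x$sm_ratio[hi + 1L] <= thr) hi <- hi + 1L
        while (hi > lo && x$sm_ratio[hi] > thr) hi <- hi - 1L
        idx <- setdiff(lo:hi, which(x$masked))
        if (length(idx) < min_event_bins) next
        mut_mean <- mean(x$depth_mut[idx]); ctl_mean <- mean(x$depth_ctl[idx])
      }
      calls[[length(calls) + 1L]] <- data.table(
        chrom = ch, start = x$bin_start[idx[1]], end = x$bin_end[idx[length(idx)]],
        zygosity = r$state, n_bins = length(idx),
        mutant_mean = mut_mean, control_mean = ctl_mean,
        ratio = mut_mean / ctl_mean)
    }
  }
  if (!length(calls)) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      zygosity = character(), n_bins = integer(),
                      mutant_mean = numeric(), control_mean = numeric(),
                      ratio = numeric()))
  }
  out <- rbindlist(calls)
  setorder(out, chrom, start)
  # grown regions may overlap; merge same-zygosity overlaps
  out[, grp := cumsum(c(1L, as.integer(!(chrom[-1] == chrom[-.N] &
                                           zygosity[-1] == zygosity[-.N] &
                                           start[-1] <= end[-.N] + 1L))))]
  out <- out[, .(chrom = chrom[1], start = min(start), end = max(end),
                 zygosity = zygosity[1], n_bins = sum(n_bins),
                 mutant_mean = sum(mutant_mean * n_bins) / sum(n_bins),
                 control_mean = sum(control_mean * n_bins) / sum(n_bins),
                 ratio = sum(mutant_mean * n_bins) / sum(control_mean * n_bins)),
             by = grp][, grp := NULL]
  out[]
}

# centred rolling mean, window truncated at the ends
rolling_mean <- function(x, w) {
  n <- length(x)
  if (n == 0 || w <= 1) return(x)
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# runs of equal state; masked bins are neutral (attached to the surrounding
# run when both neighbours agree, otherwise dropped)
collapse_runs <- function(state) {
  n <- length(state)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (state[i] == "masked") { i <- i + 1L; next }
    j <- i
    idx <- integer(0)
    cur <- state[i]
    while (j <= n && (state[j] == cur || state[j] == "masked")) {
      if (state[j] == cur) idx <- c(idx, j)
      j <- j + 1L
    }
    # trailing masked bins belong to no run
    runs[[length(runs) + 1L]] <- list(state = cur, idx = idx)
    i <- j
  }
  runs
}

#' Write a depth profile as three-column TSV (chrom, bin start, depth)
#' @param profile a `depth_profile`
#' @param path output file
#' @return the path, invisibly
#' @export
write_depth_tsv <- function(profile, path) {
  fwrite(as.data.table(profile)[, .(chrom, bin_start, depth)], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a mutant/control ratio track as bedGraph (0-based half-open)
#' @param mutant,control `depth_profile` objects sharing the same binning
#' @param path output file
#' @return the path, invisibly
#' @export
write_ratio_bedgraph <- function(mutant, control, path) {
  m <- as.data.table(mutant); ct <- as.data.table(control)
  d <- merge(m, ct, by = c("chrom", "bin_start", "bin_end"),
             suffixes = c("_mut", "_ctl"))
  setorder(d, chrom, bin_start)
  d[, ratio := ifelse(depth_ctl > 0, depth_mut / depth_ctl, NA_real_)]
  lines <- sprintf("%s\t%d\t%d\t%.4f", d$chrom, d$bin_start - 1L, d$bin_end,
                   d$ratio)
  writeLines(c("track type=bedGraph name=depth_ratio", lines), path)
  invisible(path)
}
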