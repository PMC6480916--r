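# Vector-containing read selection and read partitioning.
#
# A read from a rearranged region maps in pieces: blocks of vector sequence
# and blocks of chromosome sequence. Segmentation tiles each read with its
# best consistent set of local alignments (weighted interval scheduling on
# the read axis, with bounded overlaps to accommodate junction homologies),
# which turns every read into an ordered walk of (source, interval, strand)
# blocks. The walks are the raw material of breakpoint calling.

#' Select vector-containing reads
#'
#' A read is vector-containing iff some alignment to the vector spans at
#' least `min_vector_span` bp of the read at identity >=
#' `min_identity`. Reads mapping only to vector backbone (outside the
#' T-DNA borders) still count as vector-containing and are labelled by
#' their vector interval downstream; how to treat them is left to the
#' analyst.
#'
#' @param reads named character vector of read sequences
#' @param vector a [vector_annotation()]
#' @param min_vector_span minimum vector-aligned span on the read, bp
#' @param min_identity minimum alignment identity
#' @param align_params optional list of overrides for [align_local()]
#' @return list with `vector_reads` and `passthrough` (character vectors
#'   of read ids) and `vector_alignments` (alignment table)
#' @export
classify_reads <- function(reads, vector, min_vector_span = 200L,
                           min_identity = 0.8, align_params = list()) {
  stopifnot(min_vector_span > 0, min_identity > 0)
  if (!length(reads)) {
    return(list(vector_reads = character(), passthrough = character(),
                vector_alignments = empty_alignments()))
  }
  aln <- do.call(align_local, c(list(queries = reads,
                                     targets = c(vector = vector$sequence)),
                                align_params))
  ok <- aln[(rend - rstart + 1L) >= min_vector_span & identity >= min_identity]
  vec_ids <- unique(ok$read_id)
  list(vector_reads = vec_ids,
       passthrough = setdiff(names(reads), vec_ids),
       vector_alignments = aln)
}

#' Partition one read into an ordered walk of segments
#'
#' Picks the maximal-scoring consistent subset of the read's alignments
#' (vector and genome together) by dynamic programming on the read axis.
#' Two alignments may overlap on the read -- junction homologies make both
#' sides claim the shared bases -- and overlaps are trimmed at the midpoint
#' of the conflicted region for the read-partition bookkeeping, while the
#' full (untrimmed) target intervals are retained: breakpoint calling uses
#' the untrimmed extents, which is what makes homology-containing fragment
#' coordinates come out at their full printed extent. Alignments contained
#' within a higher-scoring alignment on the read are dropped. Ties are
#' broken deterministically (leftmost read start, then higher score).
#'
#' @param read_id the read's id
#' @param read_len the read's length, bp
#' @param alignments alignment rows for this read ([align_local()] format;
#'   the vector target must be named "vector")
#' @param overlap_tol read-interval overlaps up to this size are tolerated
#'   without scoring penalty
#' @param min_segment_len segments shorter than this after trimming are
#'   dropped
#' @return a `segmented_read`: list(read_id, segments, gaps); `segments`
#'   has trimmed read coordinates (`rstart`, `rend`), untrimmed
#'   (`raw_rstart`, `raw_rend`) and full target coordinates
#' @export
segment_read <- function(read_id, read_len, alignments, overlap_tol = 30L,
                         min_segment_len = 50L) {
  aln <- as.data.table(alignments)
  if (nrow(aln)) {
    setorder(aln, rstart, -score, rend)
    # drop read-interval-contained alignments with lower score
    keep <- rep(TRUE, nrow(aln))
    for (i in seq_len(nrow(aln))) {
      if (!keep[i]) next
      inside <- aln$rstart >= aln$rstart[i] & aln$rend <= aln$rend[i] &
        aln$score <= aln$score[i]
      inside[i] <- FALSE
      keep[inside & keep] <- FALSE
    }
    aln <- aln[keep]
  }
  n <- nrow(aln)
  if (n == 0) {
    return(structure(list(read_id = read_id,
                          segments = empty_segments(),
                          gaps = data.table(start = 1L, end = read_len)),
                     class = "segmented_read"))
  }
  len <- aln$rend - aln$rstart + 1L
  dp <- numeric(n); parent <- integer(n)
  for (i in seq_len(n)) {
    dp[i] <- aln$score[i]; parent[i] <- 0L
    for (j in seq_len(i - 1L)) {
      ov <- aln$rend[j] - aln$rstart[i] + 1L
      if (ov > min(len[i], len[j]) / 2) next       # too conflicted to chain
      pen <- if (ov > overlap_tol) 2L * ov else 0L
      cand <- dp[j] + aln$score[i] - pen
      if (cand > dp[i]) { dp[i] <- cand; parent[i] <- j }
    }
  }
  i <- which.max(dp)
  chain <- integer(0)
  while (i > 0) { chain <- c(i, chain); i <- parent[i] }
  seg <- aln[chain]
  seg[, `:=`(raw_rstart = rstart, raw_rend = rend)]
  # trim read-interval overlaps at the midpoint of the conflicted region
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      ov <- seg$rend[i - 1L] - seg$rstart[i] + 1L
      if (ov > 0) {
        cut <- seg$rstart[i] + ov %/% 2L
        seg[i - 1L, rend := cut - 1L]
        seg[i, rstart := cut]
      }
    }
  }
  seg <- seg[rend - rstart + 1L >= min_segment_len]
  seg[, order := seq_len(.N)]
  gaps <- segment_gaps(seg, read_len)
  structure(list(read_id = read_id, segments = seg[], gaps = gaps),
            class = "segmented_read")
}

empty_segments <- function() {
  x <- empty_alignments()
  x[, `:=`(raw_rstart = integer(), raw_rend = integer(), order = integer())]
  x[]
}

segment_gaps <- function(seg, read_len) {
  if (!nrow(seg)) return(data.table(start = 1L, end = read_len))
  gs <- integer(0); ge <- integer(0)
  cur <- 1L
  for (i in seq_len(nrow(seg))) {
    if (seg$rstart[i] > cur) { gs <- c(gs, cur); ge <- c(ge, seg$rstart[i] - 1L) }
    cur <- max(cur, seg$rend[i] + 1L)
  }
  if (cur <= read_len) { gs <- c(gs, cur); ge <- c(ge, read_len) }
  data.table(start = gs, end = ge)
}

#' Segment a set of reads
#'
#' @param reads named character vector (used for lengths)
#' @param alignments combined alignment table (vector target named
#'   "vector")
#' @param read_ids which reads to segment (default: all with alignments)
#' @inheritParams segment_read
#' @return named list of `segmented_read` objects
#' @export
segment_reads <- function(reads, alignments, read_ids = NULL,
                          overlap_tol = 30L, min_segment_len = 50L) {
  if (is.null(read_ids)) read_ids <- unique(alignments$read_id)
  aln_split <- split(as.data.table(alignments), by = "read_id")
  out <- lapply(read_ids, function(id) {
    segment_read(id, nchar(reads[[id]]),
                 if (!is.null(aln_split[[id]])) aln_split[[id]] else empty_alignments(),
                 overlap_tol = overlap_tol, min_segment_len = min_segment_len)
  })
  names(out) <- read_ids
  out
}

#' Segmented reads as a flat table
#'
#' One row per segment: read_id, order, trimmed and raw read coordinates,
#' source, source interval, strand. Suitable for TSV export.
#'
#' @param segmented named list from [segment_reads()]
#' @return a data.table
#' @export
segments_table <- function(segmented) {
  rows <- lapply(segmented, function(sr) {
    if (!nrow(sr$segments)) return(NULL)
    cbind(data.table(read_id = sr$read_id), sr$segments[, .(
      order, rstart, rend, raw_rstart, raw_rend,
      source = target, tstart, tend, strand, identity, score)])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.table(read_id = character(), order = integer(),
                      rstart = integer(), rend = integer(),
                      raw_rstart = integer(), raw_rend = integer(),
                      source = character(), tstart = integer(),
                      tend = integer(), strand = character(),
                      identity = numeric(), score = integer()))
  }
  rbindlist(rows)
}
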