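#' Local alignment of reads against targets (seed-chain-extend)
#'
#' A deterministic built-in local aligner for desk-scale problems:
#' exact-match k-mer seeds, single-linkage diagonal clustering, longest
#' increasing subsequence chaining, affine-gap stitching between anchors
#' and banded x-drop extension at the ends. Scoring is fixed package-wide
#' at match +2, mismatch -4, gap open -4, gap extend -2 (a gap of length L
#' costs `4 + 2*(L-1)`); identity is matches / alignment columns.
#'
#' Intended for reads at a few percent error against references of a few
#' megabases. Not a general-purpose mapper: no mapping quality, no
#' spliced alignment, no heuristics for high error rates.
#'
#' @param queries named character vector of read sequences (names = ids)
#' @param targets named character vector of target sequences
#' @param k seed k-mer size (>= 8)
#' @param min_chain_anchors minimum seeds in a chain
#' @param min_score minimum alignment score to report
#' @param max_gap maximum anchor-to-anchor gap within one chain, bp
#' @param max_occ k-mers occurring more often than this in the targets are
#'   skipped as repeats
#' @param band,xdrop,ext_max banded end-extension controls
#' @return a `data.table` of local alignments with columns `read_id`,
#'   `rstart`, `rend` (1-based inclusive on the read's forward strand),
#'   `target`, `tstart`, `tend` (forward target coordinates regardless of
#'   strand), `strand` (`"+"`/`"-"`), `matches`, `columns`, `identity`,
#'   `score`
#' @export
align_local <- function(queries, targets, k = 15L, min_chain_anchors = 3L,
                        min_score = 80L, max_gap = 200L, max_occ = 64L,
                        band = 64L, xdrop = 150L, ext_max = 400L) {
  if (length(queries) == 0) return(empty_alignments())
  if (any(nchar(queries) == 0) || any(nchar(targets) == 0)) {
    stop("empty query or target sequence")
  }
  if (k < 8) stop("k must be >= 8")
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  if (is.null(names(targets))) names(targets) <- paste0("t", seq_along(targets))
  raw <- cpp_align(unname(toupper(queries)), unname(toupper(targets)),
                   as.integer(k), as.integer(min_chain_anchors),
                   as.integer(min_score), as.integer(max_gap),
                   as.integer(max_occ), as.integer(band),
                   as.integer(xdrop), as.integer(ext_max))
  dt <- as.data.table(raw)
  if (nrow(dt) == 0) return(empty_alignments())
  out <- data.table(
    read_id = names(queries)[dt$query],
    rstart = dt$qstart, rend = dt$qend,
    target = names(targets)[dt$target],
    tstart = dt$tstart, tend = dt$tend,
    strand = ifelse(dt$strand == 0L, "+", "-"),
    matches = dt$matches, columns = dt$columns,
    identity = dt$matches / pmax(dt$columns, 1L),
    score = dt$score
  )
  setorder(out, read_id, rstart, -score)
  out[]
}

empty_alignments <- function() {
  data.table(read_id = character(), rstart = integer(), rend = integer(),
             target = character(), tstart = integer(), tend = integer(),
             strand = character(), matches = integer(), columns = integer(),
             identity = numeric(), score = integer())
}

#' Ingest external alignments (PAF or SAM)
#'
#' Normalizes minimap2-style PAF or text SAM into the internal alignment
#' table: 1-based inclusive intervals, target coordinates always on the
#' forward strand, read coordinates always on the read's own forward
#' strand, soft/hard-clipped bases excluded from the read interval.
#'
#' PAF `NM`-free records get `matches`/`columns` from columns 10-11.
#' For SAM, matches are approximated as aligned columns minus `NM` when
#' the `NM` tag is present (indel lengths are then removed from the
#' mismatch count), else as M-column count.
#'
#' @param path file path
#' @param format "paf" or "sam"
#' @return alignment `data.table` as in [align_local()] (score = NA for
#'   formats that do not carry one; PAF uses `AS` when present)
#' @export
ingest_alignments <- function(path, format = c("paf", "sam")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "sam") lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_alignments())
  if (format == "paf") ingest_paf(lines) else ingest_sam(lines)
}

ingest_paf <- function(lines) {
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) stop("malformed PAF record at line ", i)
    qs <- suppressWarnings(as.integer(f[3])); qe <- suppressWarnings(as.integer(f[4]))
    ts <- suppressWarnings(as.integer(f[8])); te <- suppressWarnings(as.integer(f[9]))
    if (anyNA(c(qs, qe, ts, te)) || !f[5] %in% c("+", "-")) {
      stop("malformed PAF record at line ", i)
    }
    score <- NA_integer_
    if (length(f) > 12) {
      as_tag <- grep("^AS:i:", f[13:length(f)], value = TRUE)
      if (length(as_tag)) score <- as.integer(sub("^AS:i:", "", as_tag[1]))
    }
    data.table(read_id = f[1],
               rstart = qs + 1L, rend = qe,           # PAF is 0-based half-open
               target = f[6], tstart = ts + 1L, tend = te,
               strand = f[5],
               matches = as.integer(f[10]), columns = as.integer(f[11]),
               identity = as.integer(f[10]) / max(as.integer(f[11]), 1L),
               score = score)
  })
  out <- rbindlist(rows)
  setorder(out, read_id, rstart)
  out[]
}

parse_cigar <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (ops[1] == -1) stop("unparseable CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = sub("^\\d+", "", toks))
}

ingest_sam <- function(lines) {
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop("malformed SAM record at line ", i)
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    if (anyNA(c(flag, pos))) stop("malformed SAM record at line ", i)
    if (bitwAnd(flag, 4L) == 4L) return(NULL)   # unmapped
    cig <- parse_cigar(f[6])
    ref_len <- sum(cig$len[cig$op %in% c("M", "D", "N", "=", "X")])
    read_aln_len <- sum(cig$len[cig$op %in% c("M", "I", "=", "X")])
    lead_clip <- if (cig$op[1] %in% c("S", "H")) cig$len[1] else 0L
    n_ops <- length(cig$op)
    tail_clip <- if (cig$op[n_ops] %in% c("S", "H")) cig$len[n_ops] else 0L
    read_len <- lead_clip + read_aln_len + tail_clip
    reverse <- bitwAnd(flag, 16L) == 16L
    # SEQ (and thus clips) are in alignment orientation; convert to the
    # read's own forward strand
    rstart <- if (!reverse) lead_clip + 1L else tail_clip + 1L
    rend <- rstart + read_aln_len - 1L
    m_cols <- sum(cig$len[cig$op %in% c("M", "=", "X")])
    indel <- sum(cig$len[cig$op %in% c("I", "D")])
    nm_tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    matches <- if (length(nm_tag)) {
      nm <- as.integer(sub("^NM:i:", "", nm_tag[1]))
      m_cols - max(nm - indel, 0L)
    } else m_cols
    columns <- m_cols + indel
    data.table(read_id = f[1], rstart = rstart, rend = rend,
               target = f[3], tstart = pos, tend = pos + ref_len - 1L,
               strand = if (reverse) "-" else "+",
               matches = matches, columns = columns,
               identity = matches / max(columns, 1L),
               score = NA_integer_, read_len = read_len)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_alignments())
  out <- rbindlist(rows)
  out[, read_len := NULL]
  setorder(out, read_id, rstart)
  out[]
}

#' Emit alignments as PAF
#'
#' @param aln alignment table from [align_local()]
#' @param read_lengths named integer vector of read lengths
#' @param target_lengths named integer vector of target lengths
#' @param path output file
#' @return the path, invisibly
#' @export
write_paf <- function(aln, read_lengths, target_lengths, path) {
  lines <- vapply(seq_len(nrow(aln)), function(i) {
    r <- aln[i]
    paste(r$read_id, read_lengths[[r$read_id]], r$rstart - 1L, r$rend,
          r$strand, r$target, target_lengths[[r$target]],
          r$tstart - 1L, r$tend, r$matches, r$columns, 60L,
          if (!is.na(r$score)) paste0("AS:i:", r$score) else "AS:i:0",
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
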