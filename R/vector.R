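#' Vector (plasmid) annotation
#'
#' Bundles a circular binary-vector sequence with its T-DNA border
#' coordinates. The T-DNA proper is the span from the start of the right
#' border (RB) forward (clockwise) to the end of the left border (LB);
#' integrated copies are frequently truncated far from the borders, which
#' is why downstream code works with arbitrary vector fragments rather
#' than the canonical span.
#'
#' Coordinates are 1-based inclusive on the forward strand of the given
#' (circular) sequence.
#'
#' @param sequence character scalar, the full circular vector sequence
#' @param lb_interval integer length-2, left-border interval
#' @param rb_interval integer length-2, right-border interval
#' @param canonical_tdna_length_range integer length-2, the expected length
#'   range in bp of an intact RB-to-LB T-DNA for this vector
#' @return an object of class `vector_annotation`
#' @export
vector_annotation <- function(sequence,
                              lb_interval = c(10509L, 10524L),
                              rb_interval = c(2454L, 2478L),
                              canonical_tdna_length_range = c(8031L, 8080L)) {
  n <- nchar(sequence)
  stopifnot(n > 0,
            all(lb_interval >= 1), all(lb_interval <= n),
            all(rb_interval >= 1), all(rb_interval <= n),
            lb_interval[1] <= lb_interval[2],
            rb_interval[1] <= rb_interval[2])
  obj <- structure(list(
    sequence = toupper(sequence),
    length = n,
    lb_interval = as.integer(lb_interval),
    rb_interval = as.integer(rb_interval),
    # intact T-DNA: RB start forward to LB end
    tdna_span = c(as.integer(rb_interval[1]), as.integer(lb_interval[2])),
    canonical_tdna_length_range = as.integer(canonical_tdna_length_range)
  ), class = "vector_annotation")
  span_len <- tdna_fragment_length(obj$tdna_span[1], obj$tdna_span[2],
                                   inclusive = TRUE)
  if (span_len < canonical_tdna_length_range[1] ||
      span_len > canonical_tdna_length_range[2]) {
    warning(sprintf("RB..LB span (%d bp) outside the canonical T-DNA length range [%d, %d]",
                    span_len, canonical_tdna_length_range[1],
                    canonical_tdna_length_range[2]))
  }
  obj
}

#' @export
print.vector_annotation <- function(x, ...) {
  cat(sprintf("vector_annotation: %d bp circular; LB [%d,%d]; RB [%d,%d]; T-DNA span %d..%d\n",
              x$length, x$lb_interval[1], x$lb_interval[2],
              x$rb_interval[1], x$rb_interval[2],
              x$tdna_span[1], x$tdna_span[2]))
  invisible(x)
}

#' Synthetic vector with the standard border layout
#'
#' Generates a random circular vector sequence whose border coordinates
#' match the pGWB2-style layout used throughout (LB 10,509-10,524 and
#' RB 2,454-2,478 on an 11-kb plasmid, intact T-DNA 8,071 bp). This is a
#' synthetic stand-in: only the coordinates, not the base content, mirror
#' the real construct.
#'
#' @param length total vector length in bp (must cover the borders)
#' @param gc GC fraction of the random sequence
#' @param seed integer seed; the same seed reproduces the same vector
#' @return a `vector_annotation`
#' @export
synthetic_vector <- function(length = 11000L, gc = 0.45, seed = 1L) {
  stopifnot(length >= 10524L)
  seq <- with_seed(seed, random_dna(length, gc))
  vector_annotation(seq)
}

#' T-DNA fragment orientation and length conventions
#'
#' A fragment is written `(start, end)` in 1-based vector coordinates;
#' `start > end` encodes reverse orientation (the fragment is the reverse
#' complement of vector `[end..start]`). `tdna_fragment_length()` with
#' `inclusive = FALSE` is the `|end - start|` convention used for summed
#' concatemer lengths (see [concatemer_length()]); `inclusive = TRUE`
#' counts bases.
#'
#' @param start,end 1-based vector coordinates
#' @param inclusive count both end bases (`|end-start|+1`) or not
#' @return integer length in bp
#' @export
tdna_fragment_length <- function(start, end, inclusive = FALSE) {
  abs(end - start) + as.integer(inclusive)
}

#' Extract the sequence of a T-DNA fragment from the vector
#'
#' Fragments with `start > end` are reverse-oriented. With
#' `allow_wrap = TRUE` a forward fragment whose interval crosses the
#' circular origin wraps around; wrapping is off by default because
#' integrated fragments observed in practice do not wrap.
#'
#' @param vector a `vector_annotation`
#' @param start,end 1-based vector coordinates (start > end = reverse)
#' @param allow_wrap permit fragments crossing the circular origin
#' @return character scalar fragment sequence (read 5'->3' as integrated)
#' @export
tdna_fragment_seq <- function(vector, start, end, allow_wrap = FALSE) {
  stopifnot(inherits(vector, "vector_annotation"))
  n <- vector$length
  if (start < 1 || start > n || end < 1 || end > n) {
    stop("fragment coordinate outside vector")
  }
  if (start <= end) {
    subseq_chr(vector$sequence, start, end)
  } else if (!allow_wrap) {
    revcomp(subseq_chr(vector$sequence, end, start))
  } else {
    # start > end with wrapping: forward fragment crossing the origin
    paste0(subseq_chr(vector$sequence, start, n),
           subseq_chr(vector$sequence, 1, end))
  }
}

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
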