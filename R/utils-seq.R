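# Sequence helpers shared across modules. Sequences are plain upper-case
# character scalars internally; Biostrings is used at the file-format
# boundary and for reverse complementation.

#' Reverse complement of a DNA string
#'
#' @param x character scalar (alphabet ACGT, case-insensitive)
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random DNA string with a target GC content
#'
#' Draws bases i.i.d. with P(G) = P(C) = gc/2. Uses the current RNG stream;
#' callers are responsible for seeding.
#'
#' @param n length in bp
#' @param gc GC fraction in `[0, 1]`
#' @return character scalar of length-n DNA
#' @keywords internal
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 1, gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' GC fraction of a DNA string
#' @keywords internal
gc_content <- function(x) {
  counts <- table(strsplit(x, "", fixed = TRUE)[[1]])
  gc <- sum(counts[names(counts) %in% c("G", "C")])
  gc / sum(counts)
}

# substring by 1-based inclusive interval
subseq_chr <- function(x, start, end) substr(x, start, end)

# overwrite bases of `x` at 1-based positions [start, start+nchar(value)-1]
replace_bases <- function(x, start, value) {
  stopifnot(start >= 1, start + nchar(value) - 1 <= nchar(x))
  paste0(substr(x, 1, start - 1), value, substr(x, start + nchar(value), nchar(x)))
}

# maximal k such that the last k bases of `left` equal the first k of `right`
max_overlap <- function(left, right, cap = nchar(right)) {
  cap <- min(cap, nchar(left), nchar(right))
  nl <- nchar(left)
  for (k in rev(seq_len(cap))) {
    if (substr(left, nl - k + 1, nl) == substr(right, 1, k)) return(k)
  }
  0L
}

#' Write sequences to FASTA
#' @param seqs named list or character vector of sequences
#' @param path output file
#' @return the path, invisibly
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read FASTA/FASTQ into a named character vector
#' @param path input file
#' @param format "auto" (sniff first byte), "fasta" or "fastq"
#' @return named character vector of sequences
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "@")) "fastq" else "fasta"
  }
  x <- if (format == "fastq") {
    Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    Biostrings::readDNAStringSet(path, format = "fasta")
  }
  out <- as.character(x)
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads to FASTQ with a fixed quality character
#' @param seqs named character vector of reads
#' @param path output file
#' @param qual_char quality character applied to every base
#' @return the path, invisibly
#' @export
write_fastq <- function(seqs, path, qual_char = "I") {
  ids <- names(seqs)
  lines <- character(4L * length(seqs))
  lines[seq(1, by = 4, length.out = length(seqs))] <- paste0("@", ids)
  lines[seq(2, by = 4, length.out = length(seqs))] <- unname(seqs)
  lines[seq(3, by = 4, length.out = length(seqs))] <- "+"
  lines[seq(4, by = 4, length.out = length(seqs))] <-
    vapply(nchar(seqs), function(n) strrep(qual_char, n), character(1))
  writeLines(lines, path)
  invisible(path)
}
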