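# NHEJ repair-signature classification at junctions.
#
# The observable at a junction is the joined sequence; comparing it with the
# two reference flanks distinguishes blunt joins, short micro-homologies
# (both sides share the junction-adjacent bases, written once), filler DNA
# (extra bases matching neither flank) and long homologies (the same
# mechanism as micro-homology but above the micro-homology cap; the
# 254-bp class).

#' Classify the repair signature of one junction
#'
#' Anchors the left reference flank's suffix and the right reference
#' flank's prefix in the observed junction sequence. The overlap of the
#' two anchored copies is homology (micro-homology up to `mh_max`, long
#' homology above); bases between them are filler; exact abutment is a
#' blunt join. Where a junction admits both a k-bp micro-homology and a
#' k-bp filler identical to flank sequence, micro-homology wins; repeats
#' are resolved by innermost anchor placement (minimal filler).
#'
#' @param left_ref_flank reference sequence ending at the junction, read
#'   toward it (left-to-right in junction orientation)
#' @param right_ref_flank reference sequence starting at the junction,
#'   read away from it
#' @param observed_junction_seq observed sequence spanning the junction
#'   with at least `flank_anchor` bp on each side
#' @param mh_max homologies longer than this are "long_homology"
#' @param flank_anchor exact-match anchor length in bp
#' @return a `junction_signature` list: kind ("blunt", "microhomology",
#'   "filler", "long_homology"), microhomology_len, filler_seq,
#'   homology_len, plus the anchored end/start offsets (`left_end`,
#'   `right_start`) within the observed sequence
#' @export
classify_junction <- function(left_ref_flank, right_ref_flank,
                              observed_junction_seq, mh_max = 20L,
                              flank_anchor = 30L) {
  if (nchar(left_ref_flank) < flank_anchor || nchar(right_ref_flank) < flank_anchor) {
    stop("flanks shorter than flank_anchor")
  }
  obs <- toupper(observed_junction_seq)
  nl <- nchar(left_ref_flank)
  la <- toupper(substr(left_ref_flank, nl - flank_anchor + 1L, nl))
  ra <- toupper(substr(right_ref_flank, 1L, flank_anchor))
  locc <- find_all(obs, la)
  rocc <- find_all(obs, ra)
  if (!length(locc) || !length(rocc)) {
    stop("unanchored junction: flank anchor not found in observed sequence")
  }
  # innermost placement: rightmost left anchor, leftmost right anchor
  e <- max(locc) + flank_anchor - 1L   # last base of the left side
  s <- min(rocc)                       # first base of the right side
  d <- s - e - 1L
  if (d > 0) {
    res <- list(kind = "filler", microhomology_len = 0L,
                filler_seq = substr(obs, e + 1L, s - 1L), homology_len = 0L)
  } else if (d == 0) {
    res <- list(kind = "blunt", microhomology_len = 0L, filler_seq = "",
                homology_len = 0L)
  } else {
    k <- -d
    shared <- substr(obs, s, e)
    lf_suffix <- substr(left_ref_flank, nl - k + 1L, nl)
    rf_prefix <- substr(right_ref_flank, 1L, k)
    if (k > nl || toupper(lf_suffix) != shared || toupper(rf_prefix) != shared) {
      stop("inconsistent anchoring: anchored copies overlap but flanks do not share the bases")
    }
    if (k <= mh_max) {
      res <- list(kind = "microhomology", microhomology_len = as.integer(k),
                  filler_seq = "", homology_len = 0L)
    } else {
      res <- list(kind = "long_homology", microhomology_len = 0L,
                  filler_seq = "", homology_len = as.integer(k))
    }
  }
  res$left_end <- e
  res$right_start <- s
  structure(res, class = "junction_signature")
}

# all 1-based start positions of fixed pattern `pat` in `x`
find_all <- function(x, pat) {
  out <- gregexpr(pat, x, fixed = TRUE)[[1]]
  if (out[1] == -1L) integer(0) else as.integer(out)
}

# ---------------------------------------------------------------------------
# consensus across junction-spanning reads
# ---------------------------------------------------------------------------

# Column-wise majority vote over read windows centred on the per-read
# junction boundary. Windows are offset-corrected against a template
# window by maximizing base agreement over shifts: reads traversing a
# junction in opposite directions record their boundary on opposite sides
# of any filler, so offsets up to filler length plus endpoint wobble must
# be absorbed (hence the generous default). Windows that cannot be
# aligned to the template at any shift (chimeras, mis-clustered
# observations) are excluded from the vote.
consensus_window <- function(windows, max_shift = 40L, min_agree = 0.7) {
  windows <- windows[nchar(windows) > 0]
  if (!length(windows)) return("")
  if (length(windows) == 1) return(windows[[1]])
  tmpl <- windows[[which.max(nchar(windows))]]
  tn <- nchar(tmpl)
  tv <- strsplit(tmpl, "", fixed = TRUE)[[1]]
  mats <- lapply(windows, function(w) {
    wv <- strsplit(w, "", fixed = TRUE)[[1]]
    best_shift <- 0L; best_score <- -1L; best_n <- 1L
    for (sh in seq(-max_shift, max_shift)) {
      idx_t <- seq_len(tn) ; idx_w <- idx_t + sh
      ok <- idx_w >= 1 & idx_w <= length(wv)
      if (sum(ok) < 50) next
      sc <- sum(tv[idx_t[ok]] == wv[idx_w[ok]])
      if (sc > best_score) { best_score <- sc; best_shift <- sh; best_n <- sum(ok) }
    }
    if (best_score / best_n < min_agree) return(NULL)
    out <- rep(NA_character_, tn)
    idx_t <- seq_len(tn); idx_w <- idx_t + best_shift
    ok <- idx_w >= 1 & idx_w <= length(wv)
    out[idx_t[ok]] <- wv[idx_w[ok]]
    out
  })
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (!length(mats)) return("")
  m <- do.call(rbind, mats)
  agree_sum <- 0; agree_n <- 0L
  cons <- apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_character_)
    tab <- sort(table(col), decreasing = TRUE)
    agree_sum <<- agree_sum + tab[[1]] / length(col)
    agree_n <<- agree_n + 1L
    names(tab)[1]
  })
  out <- paste(cons[!is.na(cons)], collapse = "")
  # mean column agreement: ~1 for substitution-only error (columns align),
  # substantially lower when indels shear the window alignment into a
  # mosaic. n_used records how many windows actually contributed: with
  # indel-dominated error most windows fail template alignment and the
  # "consensus" degenerates to a single read, which must not be trusted
  # for base-exact anchoring
  attr(out, "agreement") <- if (agree_n) agree_sum / agree_n else 0
  attr(out, "n_used") <- length(mats)
  out
}

#' Per-junction signature table from spanning reads
#'
#' Builds, for each called junction, a majority-vote consensus of the
#' read windows spanning it, re-anchors the junction against the
#' reference to refine the breakpoint coordinates to base precision, and
#' classifies the repair signature. Junctions without any spanning read
#' are reported with kind "uncalled".
#'
#' @param jset a `junction_set` from [call_breakpoints()]
#' @param reads named character vector of read sequences
#' @param seqs named list of source sequences: each reference chromosome
#'   plus `vector`
#' @param window half-window around the junction, bp (must exceed the
#'   longest homology of interest)
#' @param mh_max,flank_anchor see [classify_junction()]
#' @param refine_tol maximum coordinate correction searched during
#'   re-anchoring, bp
#' @param min_consensus_agree minimum mean column agreement of the
#'   consensus; below it the junction keeps its cluster-median
#'   coordinates and is reported "uncalled" (indel-dominated error makes
#'   the window alignment a mosaic that must not drive base-exact
#'   anchoring)
#' @return list with `junctions` (the refined junction table, signature
#'   columns added) and `consensus` (named character vector of consensus
#'   windows)
#' @export
signature_table <- function(jset, reads, seqs, window = 600L, mh_max = 20L,
                            flank_anchor = 30L, refine_tol = 25L,
                            min_consensus_agree = 0.95) {
  jn <- copy(jset$junctions)
  obs <- jset$observations
  jn[, `:=`(sig_kind = "uncalled", microhomology_len = NA_integer_,
            filler_seq = NA_character_, homology_len = NA_integer_)]
  cons_out <- setNames(character(nrow(jn)), jn$junction_id)
  for (i in seq_len(nrow(jn))) {
    J <- jn[i]
    o <- obs[cluster_id == J$cluster_id]
    if (!nrow(o)) next
    win <- character(0)
    for (r in seq_len(nrow(o))) {
      rec <- o[r]
      rs <- reads[[rec$read_id]]
      if (is.null(rs)) next
      lo <- max(1L, rec$read_boundary - window + 1L)
      hi <- min(nchar(rs), rec$read_boundary + window)
      w <- substr(rs, lo, hi)
      if (rec$flipped) w <- revcomp(w)
      win <- c(win, w)
    }
    cons <- consensus_window(win)
    cons_out[[J$junction_id]] <- as.character(cons)
    if (!nchar(cons)) next
    # an unreliable consensus -- low column agreement, or most windows
    # rejected so the "consensus" is essentially one raw read -- must not
    # drive base-exact re-anchoring: keep the cluster-median coordinates
    # and report the signature uncalled
    if (length(win) > 1 &&
        (attr(cons, "agreement") < min_consensus_agree ||
         attr(cons, "n_used") < max(2, length(win) / 2))) next
    ref <- refine_and_classify(J, as.character(cons), seqs, mh_max = mh_max,
                               flank_anchor = flank_anchor,
                               window = window, refine_tol = refine_tol)
    if (is.null(ref)) next
    jn[i, `:=`(pos_a = ref$pos_a, pos_b = ref$pos_b,
               sig_kind = ref$sig$kind,
               microhomology_len = ref$sig$microhomology_len,
               filler_seq = ref$sig$filler_seq,
               homology_len = ref$sig$homology_len)]
  }
  list(junctions = jn[], consensus = cons_out)
}

# Search small coordinate corrections for both sides so that the flank
# anchors match the consensus exactly; classify with the corrected flanks.
# Returns NULL when no correction anchors both sides.
#
# Because junction coordinates include shared (homologous) bases on both
# sides, an under-extended anchor still matches the consensus (it is a
# substring of the flank); the refined coordinate is therefore the MOST
# junction-ward extended position whose anchor still occurs.
refine_and_classify <- function(J, cons, seqs, mh_max, flank_anchor,
                                window, refine_tol) {
  a <- side(J$src_a, J$pos_a, J$orient_a)
  b <- side(J$src_b, J$pos_b, J$orient_b)
  # the consensus window reads a -> b by construction
  pa <- anchor_refine(cons, seqs, a, flank_anchor, refine_tol, left = TRUE)
  pb <- anchor_refine(cons, seqs, b, flank_anchor, refine_tol, left = FALSE)
  if (is.na(pa) || is.na(pb)) return(NULL)
  a$pos <- pa
  b$pos <- pb
  left <- side_seq_toward(seqs, a, window)
  right <- side_seq_from(seqs, b, window)
  sig <- tryCatch(classify_junction(left, right, cons, mh_max = mh_max,
                                    flank_anchor = flank_anchor),
                  error = function(e) NULL)
  if (is.null(sig)) return(NULL)
  # Validity: at a correctly placed junction the call is maximal -- the
  # source base just PAST the junction on the left side differs from the
  # first written base after it, and the source base just BEFORE the
  # right side's start differs from the last written base before it. A
  # consensus error near the junction makes the fully-extended anchor
  # fail and the scan retreat past it; at such a shifted placement the
  # skipped reference bases continue a flank and violate maximality, so
  # the refinement is rejected (the cluster median is kept and the
  # junction reported uncalled).
  shared <- max(sig$microhomology_len, sig$homology_len)
  first_after <- if (sig$kind == "filler") substr(sig$filler_seq, 1L, 1L) else {
    sb <- side_seq_from(seqs, b, shared + 1L)
    substr(sb, shared + 1L, shared + 1L)
  }
  last_before <- if (sig$kind == "filler") {
    substr(sig$filler_seq, nchar(sig$filler_seq), nchar(sig$filler_seq))
  } else {
    sa <- side_seq_toward(seqs, a, shared + 1L)
    substr(sa, 1L, 1L)
  }
  bey <- side_base_beyond(seqs, a, 1L)
  bef <- side_base_before(seqs, b, 1L)
  if ((!is.na(bey) && nzchar(first_after) && bey == first_after) ||
      (!is.na(bef) && nzchar(last_before) && bef == last_before)) {
    return(NULL)
  }
  list(pos_a = a$pos, pos_b = b$pos, sig = sig)
}

# refined source position of a side: scan candidate positions from the most
# junction-ward extension inward and return the first whose flank anchor
# occurs exactly in the consensus
anchor_refine <- function(cons, seqs, s, flank_anchor, refine_tol, left) {
  src_len <- nchar(seqs[[s$source]])
  # extension direction: for a left-of-junction side, extension grows the
  # segment end ("+" grows pos, "-" shrinks pos); for a right side it grows
  # the segment start backwards
  sign <- if (left) {
    if (s$orient == "+") 1L else -1L
  } else {
    if (s$orient == "-") -1L else 1L
  }
  for (d in seq(refine_tol, -refine_tol, by = -1L)) {
    pos <- s$pos + sign * d
    if (pos < 1 || pos > src_len) next
    s2 <- s; s2$pos <- pos
    anch <- if (left) side_seq_toward(seqs, s2, flank_anchor)
            else side_seq_from(seqs, s2, flank_anchor)
    if (nchar(anch) < flank_anchor) next
    if (length(find_all(cons, anch))) return(pos)
  }
  NA_integer_
}
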