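# Planted rearrangement architectures.
#
# An architecture is a list of events (insertions, truncations,
# translocations, bare translocations, deletions) whose junctions carry
# repair-signature specifications. plant_architecture() realizes the events
# as explicit haplotype sequences and emits a machine-readable truth set
# that downstream stages are scored against.
#
# Junction sides use one convention everywhere (generator, truth set and
# breakpoint caller): a side is (source, pos, orient) where orient "+"
# means the joined segment lies left of the breakpoint in source-forward
# coordinates and ends at pos; "-" means it lies right of the breakpoint
# and starts at pos. Coordinates at a homologous junction include the
# shared bases on BOTH sides (the convention the printed fragment lists
# follow), even though the product writes the homology once.

# ---------------------------------------------------------------------------
# junction signature specifications
# ---------------------------------------------------------------------------

#' Junction repair-signature specifications
#'
#' At most one of micro-homology and filler can be present at a junction;
#' homologies longer than the micro-homology cap are "long homology"
#' junctions (the 254-bp class).
#'
#' @param len homology length in bp
#' @param seq filler sequence (inserted verbatim between the two sides)
#' @return a `sig_spec` list: kind, mh_len, filler, homology_len
#' @export
sig_blunt <- function() sig_spec("blunt", 0L, "", 0L)

#' @rdname sig_blunt
#' @export
sig_mh <- function(len) sig_spec("microhomology", as.integer(len), "", 0L)

#' @rdname sig_blunt
#' @export
sig_filler <- function(seq) sig_spec("filler", 0L, toupper(seq), 0L)

#' @rdname sig_blunt
#' @export
sig_hom <- function(len) sig_spec("long_homology", 0L, "", as.integer(len))

sig_spec <- function(kind, mh_len, filler, homology_len) {
  stopifnot(kind %in% c("blunt", "microhomology", "filler", "long_homology"))
  if (kind == "microhomology") stopifnot(mh_len >= 1)
  if (kind == "filler") stopifnot(nchar(filler) >= 1)
  if (kind == "long_homology") stopifnot(homology_len >= 1)
  structure(list(kind = kind, mh_len = mh_len, filler = filler,
                 homology_len = homology_len), class = "sig_spec")
}

sig_shared_len <- function(sig) {
  if (sig$kind == "microhomology") sig$mh_len
  else if (sig$kind == "long_homology") sig$homology_len
  else 0L
}

# ---------------------------------------------------------------------------
# sides
# ---------------------------------------------------------------------------

side <- function(source, pos, orient) {
  stopifnot(orient %in% c("+", "-"))
  list(source = source, pos = as.integer(pos), orient = orient)
}

# fragment (s, e): s <= e forward, s > e reverse
frag_left_side <- function(s, e) if (s <= e) side("vector", s, "-") else side("vector", s, "+")
frag_right_side <- function(s, e) if (s <= e) side("vector", e, "+") else side("vector", e, "-")

side_rank <- function(s) {
  # genome before vector, then by name, position, orient
  paste(ifelse(s$source == "vector", "zzz_vector", s$source),
        sprintf("%012d", s$pos), s$orient)
}

# sequence reading INTO the junction when this side sits on the left
# (returned left-to-right, ending at the junction base)
side_seq_toward <- function(seqs, s, len) {
  src <- seqs[[s$source]]
  if (s$orient == "+") {
    subseq_chr(src, max(1L, s$pos - len + 1L), s$pos)
  } else {
    revcomp(subseq_chr(src, s$pos, min(nchar(src), s$pos + len - 1L)))
  }
}

# sequence reading AWAY from the junction when this side sits on the right
side_seq_from <- function(seqs, s, len) {
  src <- seqs[[s$source]]
  if (s$orient == "-") {
    subseq_chr(src, s$pos, min(nchar(src), s$pos + len - 1L))
  } else {
    revcomp(subseq_chr(src, max(1L, s$pos - len + 1L), s$pos))
  }
}

# overwrite the len junction-adjacent bases of side `s` (as read toward the
# junction from the left) with `value`
side_write_toward <- function(seqs, s, value) {
  len <- nchar(value)
  src <- seqs[[s$source]]
  if (s$orient == "+") {
    seqs[[s$source]] <- replace_bases(src, s$pos - len + 1L, value)
  } else {
    seqs[[s$source]] <- replace_bases(src, s$pos, revcomp(value))
  }
  seqs
}

# overwrite the base at distance `d` from the junction on side `s` (d = 1 is
# the junction base itself), `base` given in the side's toward-junction
# (left-of-junction) reading
side_write_base_at <- function(seqs, s, d, base) {
  src <- seqs[[s$source]]
  pos <- if (s$orient == "+") s$pos - d + 1L else s$pos + d - 1L
  value <- if (s$orient == "+") base else revcomp(base)
  seqs[[s$source]] <- replace_bases(src, pos, value)
  seqs
}

# same, with `base` given in the side's away-from-junction (right-of-junction)
# reading: position arithmetic is identical, the complement flips
side_write_base_from <- function(seqs, s, d, base) {
  src <- seqs[[s$source]]
  pos <- if (s$orient == "-") s$pos + d - 1L else s$pos - d + 1L
  value <- if (s$orient == "-") base else revcomp(base)
  seqs[[s$source]] <- replace_bases(src, pos, value)
  seqs
}

# source base at distance d PAST the junction on a left-of-junction side
# (product orientation); NA when outside the source
side_base_beyond <- function(seqs, s, d = 1L) {
  src <- seqs[[s$source]]
  pos <- if (s$orient == "+") s$pos + d else s$pos - d
  if (pos < 1 || pos > nchar(src)) return(NA_character_)
  b <- substr(src, pos, pos)
  if (s$orient == "+") b else revcomp(b)
}

side_write_base_beyond <- function(seqs, s, d, base) {
  src <- seqs[[s$source]]
  pos <- if (s$orient == "+") s$pos + d else s$pos - d
  value <- if (s$orient == "+") base else revcomp(base)
  seqs[[s$source]] <- replace_bases(src, pos, value)
  seqs
}

# source base at distance d BEFORE the start of a right-of-junction side
# (product orientation); NA when outside the source
side_base_before <- function(seqs, s, d = 1L) {
  src <- seqs[[s$source]]
  pos <- if (s$orient == "-") s$pos - d else s$pos + d
  if (pos < 1 || pos > nchar(src)) return(NA_character_)
  b <- substr(src, pos, pos)
  if (s$orient == "-") b else revcomp(b)
}

side_write_base_before <- function(seqs, s, d, base) {
  src <- seqs[[s$source]]
  pos <- if (s$orient == "-") s$pos - d else s$pos + d
  value <- if (s$orient == "-") base else revcomp(base)
  seqs[[s$source]] <- replace_bases(src, pos, value)
  seqs
}

# deterministic base choice avoiding `avoid` and the current value, with a
# round-rotated preference order so that conflicting constraints on one
# base cell cannot cycle forever
choose_base <- function(avoid, current, round) {
  bases <- c("A", "C", "G", "T")
  bases <- bases[((seq_len(4) + round - 2L) %% 4L) + 1L]
  for (b in bases) if (b != avoid && b != current) return(b)
  stop("no base available")  # unreachable
}

# ---------------------------------------------------------------------------
# event constructors
# ---------------------------------------------------------------------------

as_frag_matrix <- function(fragments) {
  if (is.null(fragments)) return(NULL)
  m <- matrix(as.integer(unlist(fragments)), ncol = 2, byrow = is.list(fragments))
  if (is.matrix(fragments)) m <- matrix(as.integer(fragments), ncol = 2)
  colnames(m) <- c("start", "end")
  m
}

new_event <- function(type, zygosity, ...) {
  stopifnot(zygosity %in% c("heterozygous", "homozygous"))
  structure(c(list(type = type, zygosity = zygosity), list(...)),
            class = "tdna_event")
}

#' Architecture events
#'
#' Constructors for the event types a planted architecture is made of.
#' `fragments` are T-DNA fragments as a list of `c(start, end)` vector
#' coordinate pairs (`start > end` = reverse orientation); `sigs` is a
#' list of [sig_blunt()]/[sig_mh()]/[sig_filler()]/[sig_hom()] specs, one
#' per junction walking from side A to side B (`n_fragments + 1` for
#' two-sided events, `n_fragments` for truncations, 1 for bare junctions
#' and deletions).
#'
#' @param chrom chromosome name
#' @param pos integer position (last retained base left of the break)
#' @param fragments list of fragment coordinate pairs
#' @param sigs list of signature specs
#' @param zygosity "heterozygous" or "homozygous"
#' @param locus_deletion bp deleted at the insertion locus (a short
#'   deletion around the insertion site)
#' @return a `tdna_event`
#' @export
ev_insertion <- function(chrom, pos, fragments, sigs,
                         zygosity = "heterozygous", locus_deletion = 0L) {
  fr <- as_frag_matrix(fragments)
  stopifnot(nrow(fr) >= 1, length(sigs) == nrow(fr) + 1)
  new_event("insertion", zygosity, chrom = chrom, pos = as.integer(pos),
            fragments = fr, sigs = sigs,
            locus_deletion = as.integer(locus_deletion))
}

#' @rdname ev_insertion
#' @param lost_interval optional `c(start, end)` interval lost with the
#'   truncation (defaults to nothing; the part beyond `pos` may instead be
#'   consumed by other events)
#' @export
ev_truncation <- function(chrom, pos, fragments, sigs,
                          zygosity = "heterozygous", lost_interval = NULL) {
  fr <- as_frag_matrix(fragments)
  stopifnot(nrow(fr) >= 1, length(sigs) == nrow(fr))
  new_event("truncation", zygosity, chrom = chrom, pos = as.integer(pos),
            fragments = fr, sigs = sigs, lost_interval = lost_interval)
}

#' @rdname ev_insertion
#' @param side_a,side_b genome sides, `list(chrom, pos, orient)` with
#'   orient "+" = the retained flank lies left of `pos` (and ends at it),
#'   "-" = it lies right of `pos` (and starts at it)
#' @export
ev_translocation <- function(side_a, side_b, fragments, sigs,
                             zygosity = "heterozygous") {
  fr <- as_frag_matrix(fragments)
  stopifnot(nrow(fr) >= 1, length(sigs) == nrow(fr) + 1)
  new_event("translocation", zygosity,
            side_a = do.call(side, side_a), side_b = do.call(side, side_b),
            fragments = fr, sigs = sigs)
}

#' @rdname ev_insertion
#' @param sig a single signature spec
#' @export
ev_bare_translocation <- function(side_a, side_b, sig,
                                  zygosity = "heterozygous") {
  new_event("bare_translocation", zygosity,
            side_a = do.call(side, side_a), side_b = do.call(side, side_b),
            fragments = NULL, sigs = list(sig))
}

#' @rdname ev_insertion
#' @param start,end deleted interval (1-based inclusive)
#' @export
ev_deletion <- function(chrom, start, end, sig = sig_blunt(),
                        zygosity = "heterozygous") {
  stopifnot(start >= 1, end >= start)
  new_event("deletion", zygosity, chrom = chrom, start = as.integer(start),
            end = as.integer(end), sigs = list(sig))
}

#' Bundle events into an architecture specification
#'
#' @param events list of `tdna_event` objects
#' @return an `architecture_spec`
#' @export
architecture_spec <- function(events) {
  stopifnot(all(vapply(events, inherits, logical(1), "tdna_event")))
  structure(list(events = events), class = "architecture_spec")
}

# ---------------------------------------------------------------------------
# event -> edge translation
# ---------------------------------------------------------------------------

# an edge joins two piece-end keys through an (optionally empty) chain of
# vector fragments; key "R|chrom|pos" = right end of the piece ending at
# pos, "L|chrom|pos" = left end of the piece starting at pos
key_of <- function(s) {
  if (s$orient == "+") paste("R", s$source, s$pos, sep = "|")
  else paste("L", s$source, s$pos, sep = "|")
}

event_edges <- function(ev, event_id, chrom_len = NA_integer_) {
  if (ev$type == "insertion") {
    a <- side(ev$chrom, ev$pos, "+")
    b <- side(ev$chrom, ev$pos + ev$locus_deletion + 1L, "-")
    list(list(event_id = event_id, type = ev$type, a = a, b = b,
              frags = ev$fragments, sigs = ev$sigs, conditional = FALSE))
  } else if (ev$type == "truncation") {
    a <- side(ev$chrom, ev$pos, "+")
    list(list(event_id = event_id, type = ev$type, a = a, b = NULL,
              frags = ev$fragments, sigs = ev$sigs, conditional = FALSE))
  } else if (ev$type == "translocation") {
    list(list(event_id = event_id, type = ev$type, a = ev$side_a,
              b = ev$side_b, frags = ev$fragments, sigs = ev$sigs,
              conditional = FALSE))
  } else if (ev$type == "bare_translocation") {
    list(list(event_id = event_id, type = ev$type, a = ev$side_a,
              b = ev$side_b, frags = NULL, sigs = ev$sigs,
              conditional = FALSE))
  } else if (ev$type == "deletion") {
    # terminal deletions have no junction: the chromosome simply ends early
    if (ev$start <= 1L || ev$end >= chrom_len) return(list())
    a <- side(ev$chrom, ev$start - 1L, "+")
    b <- side(ev$chrom, ev$end + 1L, "-")
    list(list(event_id = event_id, type = ev$type, a = a, b = b,
              frags = NULL, sigs = ev$sigs, conditional = TRUE))
  } else stop("unknown event type")
}

# ordered junction list of an edge, walking a -> b
edge_junctions <- function(edge) {
  fr <- edge$frags
  out <- list()
  if (is.null(fr)) {
    out[[1]] <- list(a = edge$a, b = edge$b, sig = edge$sigs[[1]])
  } else {
    n <- nrow(fr)
    prev <- edge$a
    for (i in seq_len(n)) {
      out[[i]] <- list(a = prev, b = frag_left_side(fr[i, 1], fr[i, 2]),
                       sig = edge$sigs[[i]])
      prev <- frag_right_side(fr[i, 1], fr[i, 2])
    }
    if (!is.null(edge$b)) {
      out[[n + 1]] <- list(a = prev, b = edge$b, sig = edge$sigs[[n + 1]])
    }
  }
  out
}

# ---------------------------------------------------------------------------
# signature realization: edit source sequences so each junction's two sides
# share exactly the specified homology (and nothing more)
# ---------------------------------------------------------------------------

apply_signature_edits <- function(seqs, junctions, max_rounds = 16L) {
  for (round in seq_len(max_rounds)) {
    changed <- FALSE
    for (j in junctions) {
      m <- sig_shared_len(j$sig)
      if (m > 0) {
        want <- side_seq_from(seqs, j$b, m)
        have <- side_seq_toward(seqs, j$a, m)
        if (nchar(want) < m) stop("flank too short for homology of ", m, " bp")
        if (have != want) {
          seqs <- side_write_toward(seqs, j$a, want)
          changed <- TRUE
        }
      }
      if (j$sig$kind != "filler") {
        # (1) the flank suffix/prefix overlap must be exactly m (a larger
        # value means the planted homology accidentally self-extends)
        cap <- m + 40L
        ov <- max_overlap(side_seq_toward(seqs, j$a, cap + 10L),
                          side_seq_from(seqs, j$b, cap + 10L), cap = cap)
        if (ov != m) {
          if (ov < m) stop("failed to realize homology at a junction (conflicting edits?)")
          fixed <- FALSE
          for (base in c("A", "C", "G", "T")) {
            trial <- side_write_base_at(seqs, j$a, m + 1L, base)
            ov2 <- max_overlap(side_seq_toward(trial, j$a, cap + 10L),
                               side_seq_from(trial, j$b, cap + 10L), cap = cap)
            if (ov2 == m) { seqs <- trial; fixed <- TRUE; changed <- TRUE; break }
          }
          if (!fixed) stop("cannot break accidental homology extension at a junction")
        }
      }
      # (2) break junction-slide ambiguity: the joined product must not be
      # explainable with the junction shifted by one base in either
      # direction. Writing the product ...alpha | shared/filler | beta...,
      # the left source's first base PAST the junction must differ from the
      # first written base after it, and the right source's base BEFORE its
      # start must differ from the last written base before it. Without
      # this, maximal anchoring (legitimately) reports a longer homology or
      # a shorter filler than was planted.
      first_after <- if (j$sig$kind == "filler") substr(j$sig$filler, 1L, 1L)
        else {
          sb <- side_seq_from(seqs, j$b, m + 1L)
          substr(sb, m + 1L, m + 1L)
        }
      last_before <- if (j$sig$kind == "filler") {
        fl <- j$sig$filler
        substr(fl, nchar(fl), nchar(fl))
      } else {
        sa <- side_seq_toward(seqs, j$a, m + 1L)
        substr(sa, 1L, 1L)
      }
      # each slide constraint is about a PAIR of bases differing; the
      # default edit target can be pinned by another junction's homology
      # copy (e.g. an insertion with no locus deletion, where one genome
      # base is junction-adjacent for both of its junctions), so after a
      # few rounds the editor switches to the pair's other cell
      bey <- side_base_beyond(seqs, j$a, 1L)
      if (!is.na(bey) && nzchar(first_after) && bey == first_after) {
        if (round <= 4L || j$sig$kind == "filler") {
          seqs <- side_write_base_beyond(seqs, j$a, 1L,
                                         choose_base(first_after, bey, round))
        } else {
          seqs <- side_write_base_from(seqs, j$b, m + 1L,
                                       choose_base(bey, first_after, round))
        }
        changed <- TRUE
      }
      bef <- side_base_before(seqs, j$b, 1L)
      if (!is.na(bef) && nzchar(last_before) && bef == last_before) {
        if (round <= 4L || j$sig$kind == "filler") {
          seqs <- side_write_base_before(seqs, j$b, 1L,
                                         choose_base(last_before, bef, round))
        } else {
          seqs <- side_write_base_at(seqs, j$a, m + 1L,
                                     choose_base(bef, last_before, round))
        }
        changed <- TRUE
      }
    }
    if (!changed) return(seqs)
  }
  stop("signature edits did not converge; junction specs conflict")
}

# ---------------------------------------------------------------------------
# haplotype assembly
# ---------------------------------------------------------------------------

# realize one haplotype given the edges that apply to it; returns derivative
# sequences plus layout/junction bookkeeping
assemble_haplotype <- function(seqs, ref_names, edges, lost, hap_name) {
  # boundaries per chromosome ("after base b")
  bnd <- setNames(lapply(ref_names, function(ch) integer(0)), ref_names)
  note_side <- function(s) {
    if (s$source == "vector") return()
    b <- if (s$orient == "+") s$pos else s$pos - 1L
    bnd[[s$source]] <<- c(bnd[[s$source]], b)
  }
  for (e in edges) {
    if (!is.null(e$a)) note_side(e$a)
    if (!is.null(e$b)) note_side(e$b)
  }
  for (li in lost) bnd[[li$chrom]] <- c(bnd[[li$chrom]], li$start - 1L, li$end)

  pieces <- rbindlist(lapply(ref_names, function(ch) {
    L <- nchar(seqs[[ch]])
    b <- sort(unique(pmin(pmax(bnd[[ch]], 0L), L)))
    b <- setdiff(b, c(0L, L))
    starts <- c(1L, b + 1L)
    ends <- c(b, L)
    data.table(chrom = ch, start = starts, end = ends)
  }))
  pieces[, id := .I]
  pieces[, lost := FALSE]
  for (li in lost) {
    hit <- pieces$chrom == li$chrom & pieces$start >= li$start & pieces$end <= li$end
    pieces[hit, lost := TRUE]
    covered <- pieces[hit, sum(end - start + 1L)]
    if (covered != li$end - li$start + 1L) {
      stop(sprintf("lost interval %s:%d-%d does not align with event boundaries",
                   li$chrom, li$start, li$end))
    }
  }

  # claims: key -> edge index (+ which side of the edge)
  claims <- new.env(parent = emptyenv())
  claim <- function(key, ei, slot, conditional) {
    if (!is.null(claims[[key]])) {
      if (conditional) return(FALSE)
      stop("overlapping events claim the same breakpoint side: ", key)
    }
    claims[[key]] <- list(edge = ei, slot = slot)
    TRUE
  }
  realized <- logical(length(edges))
  for (ei in seq_along(edges)) {
    e <- edges[[ei]]
    ka <- if (!is.null(e$a)) key_of(e$a) else NULL
    kb <- if (!is.null(e$b)) key_of(e$b) else NULL
    if (e$conditional) {
      # a deletion joins its flanks only if both are otherwise free
      if ((!is.null(ka) && !is.null(claims[[ka]])) ||
          (!is.null(kb) && !is.null(claims[[kb]]))) next
    }
    if (!is.null(ka)) claim(ka, ei, "a", FALSE)
    if (!is.null(kb)) claim(kb, ei, "b", FALSE)
    realized[ei] <- TRUE
  }

  piece_key <- function(p, end) {
    if (end == "L") paste("L", p$chrom, p$start, sep = "|")
    else paste("R", p$chrom, p$end, sep = "|")
  }
  lookup_piece <- function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (parts[1] == "L") {
      w <- which(pieces$chrom == parts[2] & pieces$start == as.integer(parts[3]))
    } else {
      w <- which(pieces$chrom == parts[2] & pieces$end == as.integer(parts[3]))
    }
    if (length(w) != 1) stop("dangling junction side at ", key,
                             " (locus outside bounds or inside a lost interval?)")
    w
  }
  for (key in ls(claims)) {
    w <- lookup_piece(key)
    if (pieces$lost[w]) stop("an event claims a side inside a lost interval: ", key)
  }

  visited <- rep(FALSE, nrow(pieces))
  walks <- list()
  layout <- list()
  jn_rows <- list()

  frag_seq_of <- function(fr_row) {
    s <- fr_row[1]; e <- fr_row[2]
    if (s <= e) subseq_chr(seqs[["vector"]], s, e)
    else revcomp(subseq_chr(seqs[["vector"]], e, s))
  }

  start_candidates <- pieces[lost == FALSE][order(chrom, start)]
  for (ci in seq_len(nrow(start_candidates))) {
    p0 <- start_candidates[ci]
    if (visited[p0$id]) next
    # choose a free end to start from (prefer left)
    kL <- piece_key(p0, "L"); kR <- piece_key(p0, "R")
    startend <- if (is.null(claims[[kL]])) "L" else if (is.null(claims[[kR]])) "R" else NA
    if (is.na(startend)) next  # interior of some walk; will be visited from its start
    der_name <- sprintf("%s_d%02d", hap_name, length(walks) + 1L)
    blocks <- list()
    prod_pos <- 0L
    emit <- function(kind, source, s, e, strand, seq) {
      blocks[[length(blocks) + 1L]] <<- list(kind = kind, source = source,
                                             s = s, e = e, strand = strand,
                                             seq = seq,
                                             prod_start = prod_pos + 1L,
                                             prod_end = prod_pos + nchar(seq))
      prod_pos <<- prod_pos + nchar(seq)
    }
    cur <- p0$id
    orient <- if (startend == "L") "+" else "-"
    pseq <- subseq_chr(seqs[[pieces$chrom[cur]]], pieces$start[cur], pieces$end[cur])
    if (orient == "-") pseq <- revcomp(pseq)
    emit("genome", pieces$chrom[cur], pieces$start[cur], pieces$end[cur], orient, pseq)
    visited[cur] <- TRUE
    repeat {
      p <- pieces[cur]
      far_key <- if (orient == "+") piece_key(p, "R") else piece_key(p, "L")
      cl <- claims[[far_key]]
      if (is.null(cl)) break
      e <- edges[[cl$edge]]
      forwardE <- (cl$slot == "a")
      fr <- e$frags
      sigs <- e$sigs
      jns <- edge_junctions(e)
      if (!forwardE) {
        if (!is.null(fr)) fr <- fr[rev(seq_len(nrow(fr))), c(2, 1), drop = FALSE]
        jns <- rev(lapply(jns, function(j) list(a = j$b, b = j$a, sig = j$sig)))
      }
      n_fr <- if (is.null(fr)) 0L else nrow(fr)
      for (i in seq_along(jns)) {
        j <- jns[[i]]
        jn_rows[[length(jn_rows) + 1L]] <- list(derivative = der_name,
                                                prod_pos = prod_pos,
                                                a = j$a, b = j$b, sig = j$sig,
                                                event_id = e$event_id,
                                                event_type = e$type)
        m <- sig_shared_len(j$sig)
        if (j$sig$kind == "filler") {
          emit("filler", "filler", NA_integer_, NA_integer_, "+", j$sig$filler)
        }
        if (i <= n_fr) {
          fs <- frag_seq_of(fr[i, ])
          if (m > 0) fs <- substr(fs, m + 1L, nchar(fs))
          strand <- if (fr[i, 1] <= fr[i, 2]) "+" else "-"
          emit("vector", "vector", fr[i, 1], fr[i, 2], strand, fs)
        }
      }
      if (is.null(e$b) && forwardE) break       # truncation: walk ends in the fragments
      if (is.null(e$a) && !forwardE) break
      # arrive at the partner genome side
      other_side <- if (forwardE) e$b else e$a
      nk <- key_of(other_side)
      w <- lookup_piece(nk)
      if (visited[w]) stop("cyclic architecture walk detected")
      m_last <- sig_shared_len(jns[[length(jns)]]$sig)
      cur <- w
      orient <- if (startsWith(nk, "L")) "+" else "-"
      pseq <- subseq_chr(seqs[[pieces$chrom[cur]]], pieces$start[cur], pieces$end[cur])
      if (orient == "-") pseq <- revcomp(pseq)
      if (m_last > 0) pseq <- substr(pseq, m_last + 1L, nchar(pseq))
      emit("genome", pieces$chrom[cur], pieces$start[cur], pieces$end[cur], orient, pseq)
      visited[cur] <- TRUE
    }
    walks[[der_name]] <- paste(vapply(blocks, `[[`, character(1), "seq"),
                               collapse = "")
    layout[[der_name]] <- rbindlist(lapply(blocks, function(b) {
      data.table(hap = hap_name, derivative = der_name, kind = b$kind,
                 source = b$source, src_start = b$s, src_end = b$e,
                 strand = b$strand, prod_start = b$prod_start,
                 prod_end = b$prod_end)
    }))
  }
  if (any(!visited & !pieces$lost)) {
    stop("architecture contains an unreachable cycle of pieces")
  }
  list(walks = walks,
       layout = if (length(layout)) rbindlist(layout) else data.table(),
       junctions = jn_rows,
       pieces = pieces,
       realized = realized)
}

# ---------------------------------------------------------------------------
# plant_architecture
# ---------------------------------------------------------------------------

#' Plant a rearrangement architecture into a diploid genome
#'
#' Realizes the events of an [architecture_spec()] as two explicit
#' haplotype sequence sets (heterozygous events on haplotype 1 only,
#' homozygous events on both) and emits a truth set with every planted
#' junction, fragment architecture and lost interval.
#'
#' Junction homologies are realized by editing the reference/vector
#' sequences so that the two sides genuinely share exactly the specified
#' bases; the returned `ref` and `vector` carry these edits and must be
#' used (in place of the inputs) for all downstream analysis and
#' simulation. Every realized junction is re-derived from the emitted
#' haplotype sequences and checked against its specification before the
#' function returns.
#'
#' @param ref a [build_reference()] genome
#' @param vector a [vector_annotation()]
#' @param spec an [architecture_spec()]
#' @param mh_max micro-homology cap used in the construction-time check
#' @return list with `haplotypes` (list hap1/hap2 of named derivative
#'   sequences), `truth` (a `tdna_truth`: junctions, architectures,
#'   losses, layout), `ref`, `vector`
#' @export
plant_architecture <- function(ref, vector, spec, mh_max = 20L) {
  stopifnot(inherits(ref, "reference_genome"),
            inherits(vector, "vector_annotation"),
            inherits(spec, "architecture_spec"))
  events <- spec$events
  # validate fragment coordinates
  for (ev in events) {
    if (!is.null(ev$fragments)) {
      if (any(ev$fragments < 1) || any(ev$fragments > vector$length)) {
        stop("fragment coordinate outside vector")
      }
    }
  }
  seqs <- c(ref$chromosomes, list(vector = vector$sequence))
  ev_chrom_len <- function(ev) {
    if (!is.null(ev$chrom)) ref$lengths[[ev$chrom]] else NA_integer_
  }
  edges_all <- unlist(lapply(seq_along(events), function(i) {
    event_edges(events[[i]], i, ev_chrom_len(events[[i]]))
  }), recursive = FALSE)
  # validate genome sides
  for (e in edges_all) {
    for (s in list(e$a, e$b)) {
      if (!is.null(s) && s$source != "vector") {
        if (!s$source %in% names(ref$chromosomes)) stop("unknown chromosome: ", s$source)
        if (s$pos < 0 || s$pos > ref$lengths[[s$source]] + 1L) {
          stop("locus outside chromosome bounds")
        }
      }
    }
  }
  all_junctions <- unlist(lapply(edges_all, edge_junctions), recursive = FALSE)
  seqs <- apply_signature_edits(seqs, all_junctions)

  lost_of <- function(evs) {
    out <- list()
    for (ev in evs) {
      if (ev$type == "deletion") {
        out[[length(out) + 1L]] <- list(chrom = ev$chrom, start = ev$start, end = ev$end)
      } else if (ev$type == "insertion" && ev$locus_deletion > 0) {
        out[[length(out) + 1L]] <- list(chrom = ev$chrom, start = ev$pos + 1L,
                                        end = ev$pos + ev$locus_deletion)
      } else if (ev$type == "truncation" && !is.null(ev$lost_interval)) {
        out[[length(out) + 1L]] <- list(chrom = ev$chrom,
                                        start = as.integer(ev$lost_interval[1]),
                                        end = as.integer(ev$lost_interval[2]))
      } else if (!is.null(ev$lost_intervals)) {
        for (li in ev$lost_intervals) {
          out[[length(out) + 1L]] <- list(chrom = li[[1]],
                                          start = as.integer(li[[2]]),
                                          end = as.integer(li[[3]]))
        }
      }
    }
    out
  }

  hap_events <- list(hap1 = events,
                     hap2 = Filter(function(e) e$zygosity == "homozygous", events))
  asm <- lapply(names(hap_events), function(h) {
    evs <- hap_events[[h]]
    edges <- unlist(lapply(seq_along(events), function(i) {
      if (events[[i]]$zygosity == "homozygous" || h == "hap1") {
        event_edges(events[[i]], i, ev_chrom_len(events[[i]]))
      }
    }), recursive = FALSE)
    edges <- edges[!vapply(edges, is.null, logical(1))]
    assemble_haplotype(seqs, names(ref$chromosomes), edges, lost_of(evs), h)
  })
  names(asm) <- names(hap_events)

  # truth junction table (deduplicated across haplotypes)
  jrows <- rbindlist(lapply(names(asm), function(h) {
    rows <- asm[[h]]$junctions
    if (!length(rows)) return(data.table())
    rbindlist(lapply(rows, function(r) {
      sides <- list(r$a, r$b)
      ord <- order(vapply(sides, side_rank, character(1)))
      a <- sides[[ord[1]]]; b <- sides[[ord[2]]]
      data.table(hap = h, derivative = r$derivative, prod_pos = r$prod_pos,
                 src_a = a$source, pos_a = a$pos, orient_a = a$orient,
                 src_b = b$source, pos_b = b$pos, orient_b = b$orient,
                 sig_kind = r$sig$kind, mh_len = r$sig$mh_len,
                 filler_seq = r$sig$filler, homology_len = r$sig$homology_len,
                 event_id = r$event_id, event_type = r$event_type)
    }))
  }))
  key_cols <- c("src_a", "pos_a", "orient_a", "src_b", "pos_b", "orient_b",
                "sig_kind", "mh_len", "filler_seq", "homology_len",
                "event_id", "event_type")
  junctions <- jrows[, .(haps = paste(sort(unique(hap)), collapse = ",")),
                     by = key_cols]
  setorderv(junctions, c("src_a", "pos_a", "src_b", "pos_b"))
  junctions[, junction_id := sprintf("J%02d", .I)]

  # truth architectures: events with fragments
  archs <- list()
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (is.null(ev$fragments)) next
    sides <- switch(ev$type,
      insertion = list(side(ev$chrom, ev$pos, "+"),
                       side(ev$chrom, ev$pos + ev$locus_deletion + 1L, "-")),
      truncation = list(side(ev$chrom, ev$pos, "+"), NULL),
      translocation = list(ev$side_a, ev$side_b))
    ord_fr <- ev$fragments
    # canonical reporting: walk from the canonically smaller genome side
    if (!is.null(sides[[2]]) &&
        side_rank(sides[[2]]) < side_rank(sides[[1]])) {
      sides <- rev(sides)
      ord_fr <- ord_fr[rev(seq_len(nrow(ord_fr))), c(2, 1), drop = FALSE]
      colnames(ord_fr) <- c("start", "end")
    }
    archs[[length(archs) + 1L]] <- list(event_id = i, type = ev$type,
                                        zygosity = ev$zygosity,
                                        side_a = sides[[1]], side_b = sides[[2]],
                                        fragments = ord_fr)
  }

  # losses: reference intervals absent from one or both haplotypes
  losses <- compute_losses(asm, names(ref$chromosomes),
                           setNames(nchar(seqs[names(ref$chromosomes)]),
                                    names(ref$chromosomes)))

  haplotypes <- lapply(asm, `[[`, "walks")
  layout <- rbindlist(lapply(asm, `[[`, "layout"))

  ref_out <- ref
  ref_out$chromosomes <- seqs[names(ref$chromosomes)]
  vec_out <- vector
  vec_out$sequence <- seqs[["vector"]]

  truth <- structure(list(junctions = junctions, architectures = archs,
                          losses = losses, layout = layout, events = events),
                     class = "tdna_truth")
  out <- list(haplotypes = haplotypes, truth = truth, ref = ref_out,
              vector = vec_out)
  verify_truth_signatures(out, mh_max = mh_max)
  out
}

compute_losses <- function(asm, chrom_names, chrom_lens) {
  pres <- lapply(asm, function(a) {
    p <- a$pieces[lost == FALSE]
    p[, .(chrom, start, end)]
  })
  rows <- list()
  for (ch in chrom_names) {
    cuts <- sort(unique(c(0L,
                          unlist(lapply(asm, function(a)
                            a$pieces[chrom == ch, c(start - 1L, end)])),
                          chrom_lens[[ch]])))
    starts <- head(cuts, -1) + 1L
    ends <- tail(cuts, -1)
    for (i in seq_along(starts)) {
      in_hap <- vapply(pres, function(p)
        any(p$chrom == ch & p$start <= starts[i] & p$end >= ends[i]),
        logical(1))
      n_absent <- sum(!in_hap)
      if (n_absent > 0) {
        rows[[length(rows) + 1L]] <- data.table(
          chrom = ch, start = starts[i], end = ends[i],
          zygosity = if (n_absent == 2L) "homozygous" else "heterozygous")
      }
    }
  }
  if (!length(rows)) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), zygosity = character()))
  }
  out <- rbindlist(rows)
  setorder(out, chrom, start)
  # merge adjacent same-zygosity intervals
  out[, grp := cumsum(c(1L, as.integer(
    !(chrom[-1] == chrom[-.N] & start[-1] == end[-.N] + 1L &
      zygosity[-1] == zygosity[-.N]))))]
  out <- out[, .(chrom = chrom[1], start = min(start), end = max(end),
                 zygosity = zygosity[1]), by = grp][, grp := NULL]
  out[]
}

# construction-time check: re-derive each realized junction from the emitted
# haplotype sequence and compare with its specification
verify_truth_signatures <- function(planted, mh_max = 20L, window = 600L,
                                    flank_anchor = 30L) {
  truth <- planted$truth
  seqs <- c(planted$ref$chromosomes, list(vector = planted$vector$sequence))
  lay <- truth$layout
  for (i in seq_len(nrow(truth$junctions))) {
    j <- truth$junctions[i]
    hap <- strsplit(j$haps, ",")[[1]][1]
    # locate this junction in a derivative of that haplotype
    a <- side(j$src_a, j$pos_a, j$orient_a)
    b <- side(j$src_b, j$pos_b, j$orient_b)
    hit <- find_junction_in_layout(lay[lay$hap == hap], a, b)
    if (is.null(hit)) stop("truth junction not found in layout: ", j$junction_id)
    der <- planted$haplotypes[[hap]][[hit$derivative]]
    lo <- max(1L, hit$prod_pos - window + 1L)
    hi <- min(nchar(der), hit$prod_pos + window)
    observed <- subseq_chr(der, lo, hi)
    # when the product traverses the junction b -> a, reverse-complementing
    # the window restores the canonical a -> b reading
    if (hit$flipped) observed <- revcomp(observed)
    left <- side_seq_toward(seqs, a, window)
    right <- side_seq_from(seqs, b, window)
    got <- classify_junction(left, right, observed, mh_max = mh_max,
                             flank_anchor = flank_anchor)
    want_kind <- j$sig_kind
    ok <- got$kind == want_kind &&
      got$microhomology_len == j$mh_len &&
      got$filler_seq == j$filler_seq &&
      got$homology_len == j$homology_len
    if (!ok) {
      stop(sprintf("junction %s failed construction-time verification (planted %s, derived %s)",
                   j$junction_id, want_kind, got$kind))
    }
  }
  invisible(TRUE)
}

# find the product position of junction (a,b) in a layout table; returns
# derivative, prod_pos (bases to the left of the junction) and whether the
# product traverses the junction b->a (flipped)
find_junction_in_layout <- function(lay, a, b) {
  if (!nrow(lay)) return(NULL)
  blk <- lay[lay$kind != "filler"]
  for (i in seq_len(nrow(blk) - 1L)) {
    x <- blk[i]; y <- blk[i + 1L]
    if (x$derivative != y$derivative) next
    sx <- block_right_side(x); sy <- block_left_side(y)
    if (side_eq(sx, a) && side_eq(sy, b)) {
      return(list(derivative = x$derivative, prod_pos = x$prod_end, flipped = FALSE))
    }
    if (side_eq(sx, b) && side_eq(sy, a)) {
      return(list(derivative = x$derivative, prod_pos = x$prod_end, flipped = TRUE))
    }
  }
  NULL
}

# vector blocks may store fragment coordinates with start > end (reverse
# orientation); normalize before deriving the junction-facing sides
block_right_side <- function(b) {
  lo <- min(b$src_start, b$src_end); hi <- max(b$src_start, b$src_end)
  if (b$strand == "+") side(b$source, hi, "+") else side(b$source, lo, "-")
}
block_left_side <- function(b) {
  lo <- min(b$src_start, b$src_end); hi <- max(b$src_start, b$src_end)
  if (b$strand == "+") side(b$source, lo, "-") else side(b$source, hi, "+")
}
side_eq <- function(x, y) {
  x$source == y$source && x$pos == y$pos && x$orient == y$orient
}

#' @export
print.tdna_truth <- function(x, ...) {
  cat(sprintf("tdna_truth: %d junctions, %d fragment architectures, %d lost intervals\n",
              nrow(x$junctions), length(x$architectures), nrow(x$losses)))
  invisible(x)
}
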