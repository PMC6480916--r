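# Breakpoint clustering, concatemer reconstruction, fragment graph and
# integration-event classification.
#
# Every adjacent segment pair within a segmented read is one breakpoint
# observation: two sides, each (source, position, orient). Observations are
# clustered (single linkage, both sides within a tolerance, matching
# orients) into junctions; junctions at a vector-containing locus are then
# chained along supporting reads into a concatemer architecture; genome-side
# breakpoints partition the chromosomes into a fragment graph; and the
# architectures plus bare junctions are classified under the
# double-stranded-break capture model.

# ---------------------------------------------------------------------------
# observations
# ---------------------------------------------------------------------------

# one row per adjacent segment pair, sides canonically ordered
breakpoint_observations <- function(segmented) {
  rows <- list()
  for (sr in segmented) {
    seg <- sr$segments
    if (nrow(seg) < 2) next
    for (i in seq_len(nrow(seg) - 1L)) {
      x <- seg[i]; y <- seg[i + 1L]
      # untrimmed target extents: junction coordinates include shared bases
      sa <- if (x$strand == "+") side(x$target, x$tend, "+") else side(x$target, x$tstart, "-")
      sb <- if (y$strand == "+") side(y$target, y$tstart, "-") else side(y$target, y$tend, "+")
      flipped <- side_rank(sa) > side_rank(sb)
      if (flipped) { tmp <- sa; sa <- sb; sb <- tmp }
      rows[[length(rows) + 1L]] <- data.table(
        read_id = sr$read_id,
        src_a = sa$source, pos_a = sa$pos, orient_a = sa$orient,
        src_b = sb$source, pos_b = sb$pos, orient_b = sb$orient,
        # read boundary between the trimmed segments, in read-forward coords,
        # and whether the read traverses the junction b -> a
        read_boundary = x$rend, flipped = flipped,
        read_order = i)
    }
  }
  if (!length(rows)) {
    return(data.table(read_id = character(), src_a = character(),
                      pos_a = integer(), orient_a = character(),
                      src_b = character(), pos_b = integer(),
                      orient_b = character(), read_boundary = integer(),
                      flipped = logical(), read_order = integer()))
  }
  rbindlist(rows)
}

# ---------------------------------------------------------------------------
# clustering
# ---------------------------------------------------------------------------

#' Cluster per-read breakpoint observations into junctions
#'
#' Adjacent segment pairs within each segmented read become breakpoint
#' observations; observations whose two sides agree in source and orient
#' and lie within `cluster_tol` bp on both sides are merged by single
#' linkage. The cluster representative is the per-side median. Junctions
#' supported by fewer than `min_support` reads are dropped.
#'
#' @param segmented named list of `segmented_read` objects (or a
#'   pre-computed observation table)
#' @param cluster_tol per-side clustering tolerance, bp
#' @param min_support minimum distinct supporting reads
#' @return a `junction_set`: list(junctions, observations). Junctions
#'   carry labels "a", "b", ... in report order (by source, then
#'   coordinate, genome sides first)
#' @export
call_breakpoints <- function(segmented, cluster_tol = 20L, min_support = 3L) {
  stopifnot(cluster_tol >= 0)
  obs <- if (is.data.frame(segmented)) as.data.table(segmented)
         else breakpoint_observations(segmented)
  if (!nrow(obs)) {
    return(structure(list(junctions = empty_junctions(),
                          observations = cbind(obs, data.table(cluster_id = integer()))),
                     class = "junction_set"))
  }
  obs[, grp := paste(src_a, orient_a, src_b, orient_b, sep = "|")]
  obs[, cluster_id := 0L]
  next_id <- 1L
  for (g in unique(obs$grp)) {
    idx <- which(obs$grp == g)
    o <- obs[idx]
    cl <- single_linkage_2d(o$pos_a, o$pos_b, cluster_tol)
    obs[idx, cluster_id := cl + next_id - 1L]
    next_id <- next_id + max(cl)
  }
  jn <- obs[, .(
    src_a = src_a[1], orient_a = orient_a[1],
    src_b = src_b[1], orient_b = orient_b[1],
    pos_a = as.integer(round(median(pos_a))),
    pos_b = as.integer(round(median(pos_b))),
    support = length(unique(read_id))
  ), by = cluster_id]
  jn <- jn[support >= min_support]
  if (!nrow(jn)) {
    return(structure(list(junctions = empty_junctions(),
                          observations = obs),
                     class = "junction_set"))
  }
  # canonical report order: genome sides before vector, then coordinates
  jn[, rank_a := paste(ifelse(src_a == "vector", "zzz_vector", src_a),
                       sprintf("%012d", pos_a))]
  jn[, rank_b := paste(ifelse(src_b == "vector", "zzz_vector", src_b),
                       sprintf("%012d", pos_b))]
  setorder(jn, rank_a, rank_b)
  jn[, `:=`(rank_a = NULL, rank_b = NULL)]
  jn[, junction_id := sprintf("J%02d", .I)]
  jn[, label := junction_labels(.N)]
  setcolorder(jn, c("junction_id", "label", "src_a", "pos_a", "orient_a",
                    "src_b", "pos_b", "orient_b", "support", "cluster_id"))
  structure(list(junctions = jn[], observations = obs),
            class = "junction_set")
}

empty_junctions <- function() {
  data.table(junction_id = character(), label = character(),
             src_a = character(), pos_a = integer(), orient_a = character(),
             src_b = character(), pos_b = integer(), orient_b = character(),
             support = integer(), cluster_id = integer())
}

# letters a..z, then aa, ab, ...
junction_labels <- function(n) {
  base <- letters
  if (n <= 26) return(base[seq_len(n)])
  extra <- as.vector(outer(base, base, function(a, b) paste0(a, b)))
  c(base, extra)[seq_len(n)]
}

# exact single linkage on two coordinates with per-axis tolerance `tol`;
# near-linear: after sorting by x, any linkable pair is within the x-window
single_linkage_2d <- function(x, y, tol) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  ord <- order(x, y)
  for (ii in seq_len(n)) {
    i <- ord[ii]
    jj <- ii - 1L
    while (jj >= 1L && x[i] - x[ord[jj]] <= tol) {
      j <- ord[jj]
      if (abs(y[i] - y[j]) <= tol) union_(i, j)
      jj <- jj - 1L
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}

#' @export
print.junction_set <- function(x, ...) {
  cat(sprintf("junction_set: %d junctions from %d observations\n",
              nrow(x$junctions), nrow(x$observations)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# concatemer reconstruction
# ---------------------------------------------------------------------------

#' Reconstruct the concatemer architecture at an insertion locus
#'
#' Starting from a genome-to-vector junction, follows the supporting
#' reads' segment walks through successive vector-to-vector junctions
#' until a vector-to-genome junction closes the architecture (or the
#' walk ends one-sided). At each step the successor junction is chosen by
#' maximal read support; a fork with comparable support sets the
#' `ambiguous` flag and the best-supported walk is returned.
#'
#' Fragments are reported walking from the given genome side, in the
#' (start, end) vector-coordinate convention with start > end encoding
#' reverse orientation; because junction coordinates carry the full
#' untrimmed extents, homologous junction bases are counted in both
#' adjacent fragments, matching how such fragment lists are printed.
#'
#' For a one-ended architecture (a truncation: the walk ends inside the
#' vector with no closing genome junction), the terminal fragment's far
#' end is estimated as the maximal vector extent observed among the
#' supporting reads' terminal segments, when `segmented` is supplied.
#'
#' @param jset a `junction_set`
#' @param locus_junction_id junction id of a genome-to-vector junction
#' @param segmented optional named list of `segmented_read` objects (for
#'   the one-ended terminal fragment)
#' @return a `concatemer_architecture`: list(locus_left, locus_right --
#'   sides; fragments -- matrix of (start, end); junction_ids; support;
#'   ambiguous)
#' @export
reconstruct_concatemer <- function(jset, locus_junction_id, segmented = NULL) {
  jn <- jset$junctions
  obs <- jset$observations
  J0 <- jn[junction_id == locus_junction_id]
  if (nrow(J0) != 1) stop("unknown junction id: ", locus_junction_id)
  genome_a <- J0$src_a != "vector"
  if (!(xor(J0$src_a == "vector", J0$src_b == "vector"))) {
    stop("locus junction must join genome and vector")
  }
  # orient the walk so it starts at the genome side: "forward" means
  # traversing the canonical junction a -> b
  walk_forward <- genome_a
  # per-read ordered junction walks (cluster ids with per-read direction)
  reads_walks <- read_walks(obs)
  cur_cluster <- J0$cluster_id
  cur_dir <- walk_forward
  chain <- list(list(cluster_id = cur_cluster, dir = cur_dir))
  ambiguous <- FALSE
  visited <- cur_cluster
  repeat {
    cur <- jn[cluster_id == chain[[length(chain)]]$cluster_id]
    out_side <- walk_exit_side(cur, chain[[length(chain)]]$dir)
    if (out_side$source != "vector") break  # reached the far genome side
    prev <- if (length(chain) >= 2) chain[[length(chain) - 1L]] else NULL
    succ <- walk_successors(reads_walks, chain[[length(chain)]]$cluster_id,
                            chain[[length(chain)]]$dir,
                            prev_cluster = if (is.null(prev)) NA else prev$cluster_id,
                            prev_dir = if (is.null(prev)) NA else prev$dir)
    succ <- succ[succ$cluster_id %in% jn$cluster_id, , drop = FALSE]
    succ <- succ[!succ$cluster_id %in% visited, , drop = FALSE]
    if (!nrow(succ)) break
    best <- succ[order(-succ$n, succ$cluster_id), ]
    if (nrow(best) > 1 && best$n[2] == best$n[1]) ambiguous <- TRUE
    step <- best[1, ]
    chain[[length(chain) + 1L]] <- list(cluster_id = step$cluster_id,
                                        dir = step$dir)
    visited <- c(visited, step$cluster_id)
  }
  # fragments between consecutive junctions
  jrows <- lapply(chain, function(s) {
    r <- jn[cluster_id == s$cluster_id]
    if (s$dir) r else flip_junction_row(r)
  })
  n <- length(jrows)
  frags <- NULL
  if (n >= 2) {
    frags <- matrix(0L, nrow = n - 1L, ncol = 2,
                    dimnames = list(NULL, c("start", "end")))
    for (i in seq_len(n - 1L)) {
      frags[i, ] <- c(jrows[[i]]$pos_b, jrows[[i + 1L]]$pos_a)
    }
  }
  last <- jrows[[n]]
  locus_right <- if (last$src_b != "vector") {
    side(last$src_b, last$pos_b, last$orient_b)
  } else NULL
  if (is.null(locus_right) && !is.null(segmented)) {
    # one-ended: estimate the terminal fragment from supporting reads
    far <- terminal_fragment_end(obs, segmented, last)
    if (!is.na(far)) {
      frags <- rbind(frags, c(last$pos_b, far))
      colnames(frags) <- c("start", "end")
    }
  }
  first <- jrows[[1]]
  structure(list(
    locus_left = side(first$src_a, first$pos_a, first$orient_a),
    locus_right = locus_right,
    fragments = frags,
    junction_ids = vapply(chain, function(s)
      jn[cluster_id == s$cluster_id]$junction_id, character(1)),
    support = min(vapply(chain, function(s)
      jn[cluster_id == s$cluster_id]$support, integer(1))),
    ambiguous = ambiguous
  ), class = "concatemer_architecture")
}

# maximal far extent of the vector segment entered through the last
# junction of a one-ended walk: for each observation of that junction,
# find the adjacent vector segment in the supporting read and take its
# coordinate away from the junction; the longest observed extent
# approximates the full truncated fragment
terminal_fragment_end <- function(obs, segmented, last_jrow) {
  o <- obs[cluster_id == last_jrow$cluster_id]
  enter_pos <- last_jrow$pos_b   # vector side entered by the walk
  best <- NA_integer_; best_len <- -1L
  for (i in seq_len(nrow(o))) {
    sr <- segmented[[o$read_id[i]]]
    if (is.null(sr)) next
    seg <- sr$segments[target == "vector"]
    for (k in seq_len(nrow(seg))) {
      s <- seg[k]
      # the segment whose near end matches the junction's vector side
      if (abs(s$tstart - enter_pos) <= 30L) {
        far <- s$tend; len <- s$tend - s$tstart
      } else if (abs(s$tend - enter_pos) <= 30L) {
        far <- s$tstart; len <- s$tend - s$tstart
      } else next
      if (len > best_len) { best_len <- len; best <- far }
    }
  }
  best
}

# present a junction row with sides swapped (walking b -> a)
flip_junction_row <- function(r) {
  data.table(junction_id = r$junction_id, label = r$label,
             src_a = r$src_b, pos_a = r$pos_b, orient_a = r$orient_b,
             src_b = r$src_a, pos_b = r$pos_a, orient_b = r$orient_a,
             support = r$support, cluster_id = r$cluster_id)
}

# the side out of which the walk continues
walk_exit_side <- function(jrow, dir) {
  if (dir) side(jrow$src_b, jrow$pos_b, jrow$orient_b)
  else side(jrow$src_a, jrow$pos_a, jrow$orient_a)
}

# per-read ordered walks: list of data.tables (cluster_id, fwd) in read order
read_walks <- function(obs) {
  if (!nrow(obs)) return(list())
  split(obs[order(read_order),
            .(read_id, cluster_id, fwd = !flipped, read_order)],
        by = "read_id")
}

# successors of a junction cluster across all read walks, with direction:
# a walk traversing cluster c in direction d contributes the next junction
# in the same traversal direction (or the previous one, inverted, when the
# read runs the other way).
#
# When `prev_cluster` is given, only occurrences where the read also
# contains the previous chain junction immediately before count: junctions
# shared verbatim between two concatemers (identical vector-side pairs at
# two different loci) would otherwise mix the walks of both loci.
walk_successors <- function(reads_walks, cluster, dir,
                            prev_cluster = NA, prev_dir = NA) {
  acc <- list()
  for (w in reads_walks) {
    hits <- which(w$cluster_id == cluster)
    for (h in hits) {
      same_dir <- (w$fwd[h] == dir)
      step <- if (same_dir) 1L else -1L
      if (!is.na(prev_cluster)) {
        pv <- h - step
        if (pv < 1L || pv > nrow(w)) next
        pv_dir <- if (same_dir) w$fwd[pv] else !w$fwd[pv]
        if (w$cluster_id[pv] != prev_cluster || pv_dir != prev_dir) next
      }
      nxt <- h + step
      if (nxt < 1L || nxt > nrow(w)) next
      acc[[length(acc) + 1L]] <- data.table(
        cluster_id = w$cluster_id[nxt],
        dir = if (same_dir) w$fwd[nxt] else !w$fwd[nxt])
    }
  }
  if (!length(acc)) return(data.frame(cluster_id = integer(), dir = logical(),
                                      n = integer()))
  dt <- rbindlist(acc)[, .(n = .N), by = .(cluster_id, dir)]
  as.data.frame(dt)
}

#' Total length of a concatemer architecture
#'
#' The sum over fragments of `|end - start|`: the convention under which
#' the published 4- and 6-fragment concatemers measure 11,279 and
#' 15,200 bp. (The +1-per-fragment inclusive convention would give
#' 11,283 and 15,206.)
#'
#' @param arch a `concatemer_architecture`, or a fragment matrix/list of
#'   (start, end) pairs
#' @return integer length in bp
#' @export
concatemer_length <- function(arch) {
  fr <- if (inherits(arch, "concatemer_architecture")) arch$fragments
        else as_frag_matrix(arch)
  if (is.null(fr) || nrow(fr) < 1) stop("architecture has no fragments")
  sum(abs(fr[, 2] - fr[, 1]))
}

#' @export
print.concatemer_architecture <- function(x, ...) {
  right <- if (is.null(x$locus_right)) "(one-ended)" else
    sprintf("%s:%d", x$locus_right$source, x$locus_right$pos)
  nf <- if (is.null(x$fragments)) 0L else nrow(x$fragments)
  cat(sprintf("concatemer: %s:%d -> %s; %d fragment(s), %d bp%s\n",
              x$locus_left$source, x$locus_left$pos, right, nf,
              if (nf) concatemer_length(x) else 0L,
              if (x$ambiguous) " [ambiguous]" else ""))
  if (nf) {
    cat(paste(sprintf("  (%d, %d)", x$fragments[, 1], x$fragments[, 2]),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# fragment graph
# ---------------------------------------------------------------------------

#' Build the chromosome fragment graph
#'
#' Genome-side breakpoints (merged within `gap_tol`, so that the two ends
#' of one chromosomal break count as one partition point) partition each
#' chromosome into fragments named "ChrN-k" left to right. Edges connect
#' fragments joined by reconstructed architectures (vector-bridged) or by
#' bare genome-genome junctions.
#'
#' @param jset a `junction_set`
#' @param ref a [build_reference()] genome (chromosome lengths)
#' @param architectures list of `concatemer_architecture` objects
#' @param gap_tol breakpoints closer than this merge into one partition
#'   point, bp
#' @return a `fragment_graph`: list(nodes, edges) data.tables
#' @export
build_fragment_graph <- function(jset, ref, architectures = list(),
                                 gap_tol = 100L) {
  jn <- jset$junctions
  sides <- rbindlist(list(
    jn[src_a != "vector", .(chrom = src_a, pos = pos_a, orient = orient_a)],
    jn[src_b != "vector", .(chrom = src_b, pos = pos_b, orient = orient_b)]))
  nodes <- rbindlist(lapply(names(ref$chromosomes), function(ch) {
    L <- ref$lengths[[ch]]
    ps <- sides[chrom == ch]
    # breakpoint position: after `pos` for "+", after `pos - 1` for "-"
    bps <- sort(unique(ifelse(ps$orient == "+", ps$pos, ps$pos - 1L)))
    bps <- bps[bps >= 1L & bps < L]
    merged <- integer(0)
    for (b in bps) {
      if (length(merged) && b - merged[length(merged)] <= gap_tol) next
      merged <- c(merged, b)
    }
    starts <- c(1L, merged + 1L)
    ends <- c(merged, L)
    data.table(chrom = ch, node = paste0(ch, "-", seq_along(starts)),
               start = starts, end = ends)
  }))
  node_of <- function(chrom, pos, orient) {
    # the node on the retained side of the breakpoint
    w <- which(nodes$chrom == chrom &
                 nodes$start - gap_tol - 1L <= pos & pos <= nodes$end + gap_tol)
    if (!length(w)) return(NA_character_)
    if (length(w) > 1) {
      w <- if (orient == "+") w[which.min(abs(nodes$end[w] - pos))]
           else w[which.min(abs(nodes$start[w] - pos))]
    }
    nodes$node[w[1]]
  }
  edges <- list()
  for (arch in architectures) {
    if (is.null(arch$locus_right)) next
    a <- arch$locus_left; b <- arch$locus_right
    edges[[length(edges) + 1L]] <- data.table(
      from = node_of(a$source, a$pos, a$orient),
      to = node_of(b$source, b$pos, b$orient),
      kind = "vector_bridge",
      n_fragments = if (is.null(arch$fragments)) 0L else nrow(arch$fragments),
      junctions = paste(arch$junction_ids, collapse = ","))
  }
  bare <- jn[src_a != "vector" & src_b != "vector"]
  for (i in seq_len(nrow(bare))) {
    r <- bare[i]
    edges[[length(edges) + 1L]] <- data.table(
      from = node_of(r$src_a, r$pos_a, r$orient_a),
      to = node_of(r$src_b, r$pos_b, r$orient_b),
      kind = "bare", n_fragments = 0L, junctions = r$junction_id)
  }
  edges <- if (length(edges)) rbindlist(edges) else
    data.table(from = character(), to = character(), kind = character(),
               n_fragments = integer(), junctions = character())
  structure(list(nodes = nodes, edges = edges), class = "fragment_graph")
}

#' @export
print.fragment_graph <- function(x, ...) {
  cat(sprintf("fragment_graph: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a fragment graph as DOT
#'
#' @param graph a `fragment_graph`
#' @param path output file
#' @return the path, invisibly
#' @export
write_graph_dot <- function(graph, path) {
  lines <- c("graph fragments {")
  for (i in seq_len(nrow(graph$nodes))) {
    n <- graph$nodes[i]
    lines <- c(lines, sprintf('  "%s" [label="%s\\n%d-%d"];',
                              n$node, n$node, n$start, n$end))
  }
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i]
    style <- if (e$kind == "vector_bridge") "solid" else "dashed"
    lines <- c(lines, sprintf('  "%s" -- "%s" [style=%s,label="%s"];',
                              e$from, e$to, style, e$kind))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# event classification
# ---------------------------------------------------------------------------

#' Classify integration events under the DSB capture model
#'
#' Three vector-mediated cases: (1) both genome sides of one architecture
#' are the two ends of a single chromosomal break (same chromosome,
#' coordinates within `gap_tol`) -- an intact insertion at one locus;
#' (2) only one genome side -- a chromosome truncation; (3) the two sides
#' on different chromosomes or distant loci -- a translocation bridge.
#' Bare genome-genome junctions are deletions when co-linear and on one
#' chromosome, otherwise bare translocations. Anything else is reported
#' as "complex" with a note.
#'
#' @param graph a `fragment_graph`
#' @param architectures list of `concatemer_architecture`
#' @param jset the `junction_set` the graph was built from
#' @param gap_tol case-1 locus tolerance, bp
#' @return data.table of events: case, chrom_a, pos_a, chrom_b, pos_b,
#'   n_fragments, length_bp, junctions, notes
#' @export
classify_events <- function(graph, architectures, jset, gap_tol = 100L) {
  rows <- list()
  for (arch in architectures) {
    a <- arch$locus_left; b <- arch$locus_right
    nf <- if (is.null(arch$fragments)) 0L else nrow(arch$fragments)
    len <- if (nf) concatemer_length(arch) else 0L
    if (is.null(b)) {
      cs <- "truncation"
      notes <- "one-ended architecture"
    } else if (a$source == b$source && abs(b$pos - a$pos) <= gap_tol &&
               a$orient != b$orient) {
      cs <- "intact_insertion"
      notes <- sprintf("single locus, %d bp between break ends", abs(b$pos - a$pos))
    } else if (!is.null(b)) {
      cs <- "translocation"
      notes <- if (a$source == b$source) "same chromosome, distant loci" else
        "different chromosomes"
    } else {
      cs <- "complex"
      notes <- "unclassifiable topology"
    }
    if (arch$ambiguous) notes <- paste(notes, "[ambiguous walk]")
    rows[[length(rows) + 1L]] <- data.table(
      case = cs, chrom_a = a$source, pos_a = a$pos,
      chrom_b = if (is.null(b)) NA_character_ else b$source,
      pos_b = if (is.null(b)) NA_integer_ else b$pos,
      n_fragments = nf, length_bp = len,
      junctions = paste(arch$junction_ids, collapse = ","), notes = notes)
  }
  bare <- jset$junctions[src_a != "vector" & src_b != "vector"]
  for (i in seq_len(nrow(bare))) {
    r <- bare[i]
    colinear <- r$src_a == r$src_b && r$orient_a == "+" && r$orient_b == "-" &&
      r$pos_b > r$pos_a
    cs <- if (colinear) "deletion" else "bare_translocation"
    rows[[length(rows) + 1L]] <- data.table(
      case = cs, chrom_a = r$src_a, pos_a = r$pos_a,
      chrom_b = r$src_b, pos_b = r$pos_b,
      n_fragments = 0L, length_bp = if (colinear) r$pos_b - r$pos_a - 1L else 0L,
      junctions = r$junction_id,
      notes = if (colinear) "co-linear same-chromosome join" else
        "genome-genome junction, no vector sequence")
  }
  if (!length(rows)) {
    return(data.table(case = character(), chrom_a = character(),
                      pos_a = integer(), chrom_b = character(),
                      pos_b = integer(), n_fragments = integer(),
                      length_bp = integer(), junctions = character(),
                      notes = character()))
  }
  out <- rbindlist(rows)
  setorder(out, chrom_a, pos_a)
  out[]
}
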