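# End-to-end orchestration: simulate/load -> align -> segment -> junctions
# -> signatures -> concatemers -> graph/events -> depth -> report.

default_params <- function() {
  list(
    k = 15L, min_chain_anchors = 3L, min_score = 80L, max_gap = 200L,
    min_vector_span = 200L, min_identity = 0.8,
    overlap_tol = 30L, min_segment_len = 50L,
    cluster_tol = 20L, min_support = 3L, gap_tol = 100L,
    window = 600L, mh_max = 20L, flank_anchor = 30L, refine_tol = 25L,
    min_sv_gap = 50L,
    bin_size = 1000L, het_band = c(0.35, 0.65), hom_max = 0.1,
    min_event_bins = 5L, min_control_depth = 10,
    smooth_bins = 25L, min_z = 3.5
  )
}

#' Pipeline configuration
#'
#' Inputs may be file paths (FASTA/FASTQ for reads, FASTA for reference
#' and vector) or in-memory objects (named character vector of reads, a
#' `reference_genome`, a `vector_annotation`). Threshold overrides are
#' merged over the documented defaults; every effective value is echoed
#' into the report for provenance.
#'
#' @param reads mutant reads (path or named character vector)
#' @param reference reference genome (path or `reference_genome`)
#' @param vector vector (path or `vector_annotation`)
#' @param control_reads optional control reads (path or named character
#'   vector); required for loss calling
#' @param out_dir output directory
#' @param seed integer seed recorded for provenance
#' @param params named list of threshold overrides (see
#'   `tdnascope:::default_params()`)
#' @param vector_borders LB/RB intervals used when `vector` is a FASTA
#'   path
#' @return a `pipeline_config`
#' @export
pipeline_config <- function(reads, reference, vector, control_reads = NULL,
                            out_dir = tempfile("tdnascope_"), seed = 1L,
                            params = list(),
                            vector_borders = list(lb = c(10509L, 10524L),
                                                  rb = c(2454L, 2478L))) {
  is_path <- function(x) is.character(x) && length(x) == 1 && is.null(names(x))
  for (x in list(reads, reference, vector, control_reads)) {
    if (!is.null(x) && is_path(x) && !file.exists(x)) {
      stop("input file does not exist: ", x)
    }
  }
  p <- utils::modifyList(default_params(), params)
  bad <- setdiff(names(params), names(default_params()))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  structure(list(reads = reads, reference = reference, vector = vector,
                 control_reads = control_reads, out_dir = out_dir,
                 seed = as.integer(seed), params = p,
                 vector_borders = vector_borders),
            class = "pipeline_config")
}

load_reads_input <- function(x) {
  if (is.character(x) && length(x) == 1 && is.null(names(x))) {
    if (!file.exists(x)) stop("input file does not exist: ", x)
    read_seqs(x)
  } else x
}

load_reference_input <- function(x) {
  if (inherits(x, "reference_genome")) return(x)
  if (!file.exists(x)) stop("input file does not exist: ", x)
  seqs <- read_seqs(x, format = "fasta")
  structure(list(chromosomes = as.list(seqs),
                 lengths = setNames(nchar(seqs), names(seqs)),
                 gc = NA_real_, seed = NA_integer_),
            class = "reference_genome")
}

load_vector_input <- function(x, borders) {
  if (inherits(x, "vector_annotation")) return(x)
  if (!file.exists(x)) stop("input file does not exist: ", x)
  seqs <- read_seqs(x, format = "fasta")
  vector_annotation(unname(seqs[1]), lb_interval = borders$lb,
                    rb_interval = borders$rb)
}

#' Run the full rearrangement pipeline
#'
#' Stages: align reads to the vector and the reference; select
#' vector-containing reads; segment them into walks; cluster breakpoints
#' into junctions; build per-junction consensus, refine coordinates and
#' classify repair signatures; reconstruct concatemer architectures at
#' every insertion locus; build the chromosome fragment graph and
#' classify integration events; compute binned depth and (when control
#' reads are provided) call heterozygous/homozygous losses. All
#' intermediates and a machine-readable report are written under
#' `config$out_dir`. Identical config and seed give an identical report.
#'
#' @param config a [pipeline_config()]
#' @return a `rearrangement_report` (list; see the `report.json` it
#'   writes)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- proc.time()[["elapsed"]]
  log_stage <- function(stage, t0) {
    message(sprintf("[tdnascope] %-12s %6.1f s", stage,
                    proc.time()[["elapsed"]] - t0))
  }

  t0 <- proc.time()[["elapsed"]]
  reads <- load_reads_input(config$reads)
  ref <- load_reference_input(config$reference)
  vec <- load_vector_input(config$vector, config$vector_borders)
  control <- if (!is.null(config$control_reads)) {
    load_reads_input(config$control_reads)
  } else NULL
  if (!length(reads)) stop("stage load: no reads")
  log_stage("load", t0)

  # --- alignment ---------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  ap <- list(k = p$k, min_chain_anchors = p$min_chain_anchors,
             min_score = p$min_score, max_gap = p$max_gap)
  vec_aln <- do.call(align_local, c(list(reads, c(vector = vec$sequence)), ap))
  genome_aln <- do.call(align_local, c(list(reads, unlist(ref$chromosomes)), ap))
  log_stage("align", t0)

  # --- vector-read selection and segmentation ----------------------------
  t0 <- proc.time()[["elapsed"]]
  vhit <- vec_aln[(rend - rstart + 1L) >= p$min_vector_span &
                    identity >= p$min_identity]
  vector_reads <- unique(vhit$read_id)
  # genome-genome junctions (bare translocations, deletions) live in reads
  # with split genome alignments and no vector content
  split_reads <- genome_aln[, .N, by = read_id][N >= 2L]$read_id
  seg_ids <- union(vector_reads, split_reads)
  seg_aln <- rbindlist(list(vec_aln[read_id %in% seg_ids],
                            genome_aln[read_id %in% seg_ids]))
  segmented <- segment_reads(reads, seg_aln, read_ids = seg_ids,
                             overlap_tol = p$overlap_tol,
                             min_segment_len = p$min_segment_len)
  log_stage("segment", t0)

  # --- junctions, signatures, refinement ---------------------------------
  t0 <- proc.time()[["elapsed"]]
  jset <- call_breakpoints(segmented, cluster_tol = p$cluster_tol,
                           min_support = p$min_support)
  # co-linear same-source joins with a tiny gap are split-alignment
  # artifacts, not structural junctions
  jset$junctions <- jset$junctions[!(src_a == src_b & orient_a == "+" &
                                       orient_b == "-" &
                                       pos_b - pos_a - 1L < p$min_sv_gap)]
  seqs <- c(ref$chromosomes, list(vector = vec$sequence))
  sig <- signature_table(jset, reads, seqs, window = p$window,
                         mh_max = p$mh_max, flank_anchor = p$flank_anchor,
                         refine_tol = p$refine_tol)
  jset$junctions <- sig$junctions
  log_stage("junctions", t0)

  # --- concatemer architectures ------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  gv <- jset$junctions[src_a != "vector" & src_b == "vector"]
  archs <- list()
  seen <- character(0)
  for (jid in gv$junction_id) {
    arch <- reconstruct_concatemer(jset, jid, segmented = segmented)
    key <- paste(sort(arch$junction_ids), collapse = "+")
    if (key %in% seen) next
    seen <- c(seen, key)
    archs[[length(archs) + 1L]] <- arch
  }
  # keep the walk starting from the canonically smaller genome side
  archs <- lapply(archs, canonical_architecture)
  loci <- insertion_loci(gv, p$gap_tol)
  log_stage("concatemers", t0)

  # --- graph and events --------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  graph <- build_fragment_graph(jset, ref, archs, gap_tol = p$gap_tol)
  events <- classify_events(graph, archs, jset, gap_tol = p$gap_tol)
  log_stage("events", t0)

  # --- depth and losses --------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  depth_mut <- compute_depth(genome_aln, ref, bin_size = p$bin_size)
  depth_ctl <- NULL; losses <- NULL
  if (!is.null(control)) {
    ctl_aln <- do.call(align_local, c(list(control, unlist(ref$chromosomes)), ap))
    depth_ctl <- compute_depth(ctl_aln, ref, bin_size = p$bin_size)
    rl <- mean(nchar(reads))
    # coverage ramps about one read length around breakpoints mimic
    # partial loss; mask them (homozygous-zero bins stay visible)
    bp_sides <- rbindlist(list(
      jset$junctions[src_a != "vector", .(chrom = src_a, pos = pos_a)],
      jset$junctions[src_b != "vector", .(chrom = src_b, pos = pos_b)]))
    excl <- if (nrow(bp_sides)) {
      bp_sides[, .(chrom, start = pmax(pos - as.integer(rl), 1L),
                   end = pos + as.integer(rl))]
    } else NULL
    losses <- call_losses(depth_mut, depth_ctl, het_band = p$het_band,
                          hom_max = p$hom_max,
                          min_event_bins = p$min_event_bins,
                          min_control_depth = p$min_control_depth,
                          smooth_bins = p$smooth_bins, min_z = p$min_z,
                          read_length = rl, exclude = excl)
  }
  log_stage("depth", t0)

  # --- report ------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  report <- structure(list(
    provenance = list(package = "tdnascope",
                      version = as.character(utils::packageVersion("tdnascope")),
                      seed = config$seed, params = p,
                      n_reads = length(reads),
                      n_control_reads = if (is.null(control)) 0L else length(control),
                      n_vector_reads = length(vector_reads)),
    loci = loci,
    junctions = jset$junctions,
    architectures = archs,
    events = events,
    losses = losses,
    graph = graph
  ), class = "rearrangement_report")
  write_pipeline_outputs(report, config, reads, ref, vec, segmented,
                         genome_aln, depth_mut, depth_ctl, sig)
  log_stage("report", t0)
  message(sprintf("[tdnascope] total        %6.1f s",
                  proc.time()[["elapsed"]] - t_start))
  report
}

# genome-vector junctions grouped into insertion loci (genome sides within
# gap_tol on one chromosome are one locus: the two ends of one break)
insertion_loci <- function(gv, gap_tol) {
  if (!nrow(gv)) {
    return(data.table(locus = character(), chrom = character(),
                      pos = integer(), n_junctions = integer(),
                      junctions = character()))
  }
  g <- copy(gv)
  setorder(g, src_a, pos_a)
  g[, grp := cumsum(c(1L, as.integer(!(src_a[-1] == src_a[-.N] &
                                         pos_a[-1] - pos_a[-.N] <= gap_tol))))]
  out <- g[, .(chrom = src_a[1], pos = min(pos_a), n_junctions = .N,
               junctions = paste(junction_id, collapse = ",")), by = grp]
  out[, locus := paste0("IS", .I)][, grp := NULL]
  setcolorder(out, c("locus", "chrom", "pos", "n_junctions", "junctions"))
  out[]
}

canonical_architecture <- function(arch) {
  a <- arch$locus_left; b <- arch$locus_right
  if (!is.null(b) && side_rank(b) < side_rank(a)) {
    fr <- arch$fragments
    if (!is.null(fr)) {
      fr <- fr[rev(seq_len(nrow(fr))), c(2, 1), drop = FALSE]
      colnames(fr) <- c("start", "end")
    }
    arch$locus_left <- b; arch$locus_right <- a
    arch$fragments <- fr
    arch$junction_ids <- rev(arch$junction_ids)
  }
  arch
}

write_pipeline_outputs <- function(report, config, reads, ref, vec,
                                   segmented, genome_aln, depth_mut,
                                   depth_ctl, sig) {
  od <- config$out_dir
  jn <- report$junctions
  fwrite(jn, file.path(od, "junctions.tsv"), sep = "\t")
  write_junctions_bedpe(jn, file.path(od, "junctions.bedpe"))
  fwrite(segments_table(segmented), file.path(od, "segments.tsv"), sep = "\t")
  rl <- setNames(nchar(reads), names(reads))
  tl <- c(setNames(unlist(ref$lengths), names(ref$chromosomes)),
          vector = vec$length)
  write_paf(rbindlist(list(genome_aln)), rl, tl, file.path(od, "alignments.paf"))
  cons <- sig$consensus[nchar(sig$consensus) > 0]
  if (length(cons)) write_fasta(as.list(cons), file.path(od, "junction_consensus.fasta"))
  arch_json <- lapply(report$architectures, function(a) {
    list(locus_left = a$locus_left,
         locus_right = a$locus_right,
         fragments = if (is.null(a$fragments)) list() else
           apply(a$fragments, 1, function(r) as.list(r), simplify = FALSE),
         length_bp = if (is.null(a$fragments)) 0L else concatemer_length(a),
         junctions = a$junction_ids, support = a$support,
         ambiguous = a$ambiguous)
  })
  jsonlite::write_json(arch_json, file.path(od, "architectures.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  fwrite(report$events, file.path(od, "events.tsv"), sep = "\t")
  write_depth_tsv(depth_mut, file.path(od, "depth_mutant.tsv"))
  if (!is.null(depth_ctl)) {
    write_depth_tsv(depth_ctl, file.path(od, "depth_control.tsv"))
    write_ratio_bedgraph(depth_mut, depth_ctl, file.path(od, "depth_ratio.bedgraph"))
  }
  if (!is.null(report$losses) && nrow(report$losses)) {
    bed <- report$losses[, .(chrom, start - 1L, end, zygosity)]
    fwrite(bed, file.path(od, "losses.bed"), sep = "\t", col.names = FALSE)
  }
  write_graph_dot(report$graph, file.path(od, "fragment_graph.dot"))
  fwrite(report$graph$nodes, file.path(od, "fragment_nodes.tsv"), sep = "\t")
  fwrite(report$graph$edges, file.path(od, "fragment_edges.tsv"), sep = "\t")
  # machine-readable report + text summary
  rep_json <- list(
    provenance = report$provenance,
    loci = report$loci,
    junctions = report$junctions,
    events = report$events,
    architectures = arch_json,
    losses = report$losses)
  jsonlite::write_json(rep_json, file.path(od, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  writeLines(format_report_text(report), file.path(od, "report.txt"))
  invisible(od)
}

#' Junctions as BEDPE (0-based half-open, one breakpoint per side)
#' @param junctions junction table
#' @param path output file
#' @return the path, invisibly
#' @export
write_junctions_bedpe <- function(junctions, path) {
  if (!nrow(junctions)) { writeLines(character(0), path); return(invisible(path)) }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t%s\t%s",
                   junctions$src_a, junctions$pos_a - 1L, junctions$pos_a,
                   junctions$src_b, junctions$pos_b - 1L, junctions$pos_b,
                   junctions$junction_id, junctions$support,
                   junctions$orient_a, junctions$orient_b)
  writeLines(lines, path)
  invisible(path)
}

format_report_text <- function(report) {
  out <- c("tdnascope rearrangement report",
           sprintf("reads: %d (%d vector-containing); seed %d",
                   report$provenance$n_reads, report$provenance$n_vector_reads,
                   report$provenance$seed),
           "",
           sprintf("Insertion loci: %d", nrow(report$loci)))
  for (i in seq_len(nrow(report$loci))) {
    l <- report$loci[i]
    out <- c(out, sprintf("  %s  %s:%s  (%d junction(s))", l$locus, l$chrom,
                          format(l$pos, big.mark = ","), l$n_junctions))
  }
  out <- c(out, "", sprintf("Events: %d", nrow(report$events)))
  for (i in seq_len(nrow(report$events))) {
    e <- report$events[i]
    loc_b <- if (is.na(e$chrom_b)) "(one-ended)" else
      sprintf("%s:%s", e$chrom_b, format(e$pos_b, big.mark = ","))
    extra <- if (e$n_fragments > 0) {
      sprintf(" [%d fragment(s), %s bp]", e$n_fragments,
              format(e$length_bp, big.mark = ","))
    } else ""
    out <- c(out, sprintf("  %-17s %s:%s -> %s%s", e$case, e$chrom_a,
                          format(e$pos_a, big.mark = ","), loc_b, extra))
  }
  if (!is.null(report$losses) && nrow(report$losses)) {
    out <- c(out, "", sprintf("Loss calls: %d", nrow(report$losses)))
    for (i in seq_len(nrow(report$losses))) {
      l <- report$losses[i]
      out <- c(out, sprintf("  %-13s %s:%s-%s  ratio %.2f", l$zygosity,
                            l$chrom, format(l$start, big.mark = ","),
                            format(l$end, big.mark = ","), l$ratio))
    }
  }
  out
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat(paste(format_report_text(x), collapse = "\n"), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# scoring against a truth set
# ---------------------------------------------------------------------------

#' Score a pipeline report against a simulator truth set
#'
#' Junction precision/recall with coordinate tolerance; per-architecture
#' exact-fragment-list flags; loss-call overlap. Truth junctions sharing
#' identical sides (the same physical join planted by two events, like
#' the homologous junction both concatemers contain) count once.
#'
#' @param report a `rearrangement_report`
#' @param truth a `tdna_truth` from [plant_architecture()]
#' @param tol coordinate match tolerance, bp (use the pipeline's
#'   `cluster_tol`)
#' @param min_loss_len ignore planted losses shorter than this, bp
#' @return list: junctions (precision, recall, mean_abs_error, n_called,
#'   n_truth), architectures (data.table with exact_match flags), losses
#'   (data.table with matched flags)
#' @export
compare_to_truth <- function(report, truth, tol = 20L, min_loss_len = 5000L) {
  called <- report$junctions
  tj <- unique(truth$junctions[, .(src_a, pos_a, orient_a, src_b, pos_b,
                                   orient_b)])
  match_one <- function(r) {
    hit <- tj[src_a == r$src_a & orient_a == r$orient_a &
                src_b == r$src_b & orient_b == r$orient_b &
                abs(pos_a - r$pos_a) <= tol & abs(pos_b - r$pos_b) <= tol]
    if (nrow(hit)) abs(hit$pos_a[1] - r$pos_a) + abs(hit$pos_b[1] - r$pos_b)
    else NA_integer_
  }
  errs <- vapply(seq_len(nrow(called)), function(i) match_one(called[i]),
                 numeric(1))
  tp <- sum(!is.na(errs))
  truth_hit <- vapply(seq_len(nrow(tj)), function(i) {
    r <- tj[i]
    any(called$src_a == r$src_a & called$orient_a == r$orient_a &
          called$src_b == r$src_b & called$orient_b == r$orient_b &
          abs(called$pos_a - r$pos_a) <= tol & abs(called$pos_b - r$pos_b) <= tol)
  }, logical(1))
  junctions <- list(
    precision = if (nrow(called)) tp / nrow(called) else NA_real_,
    recall = if (nrow(tj)) sum(truth_hit) / nrow(tj) else NA_real_,
    mean_abs_error = if (tp) mean(errs[!is.na(errs)]) else NA_real_,
    n_called = nrow(called), n_truth = nrow(tj))

  arch_rows <- lapply(truth$architectures, function(ta) {
    fr_t <- ta$fragments
    best <- NULL
    for (ca in report$architectures) {
      if (ca$locus_left$source != ta$side_a$source ||
          abs(ca$locus_left$pos - ta$side_a$pos) > tol) next
      best <- ca; break
    }
    exact <- !is.null(best) && !is.null(best$fragments) &&
      nrow(best$fragments) == nrow(fr_t) &&
      all(best$fragments == fr_t)
    data.table(event_id = ta$event_id, type = ta$type,
               n_fragments_truth = nrow(fr_t),
               found = !is.null(best),
               n_fragments_called = if (is.null(best) || is.null(best$fragments))
                 0L else nrow(best$fragments),
               exact_match = exact)
  })
  architectures <- rbindlist(arch_rows)

  tl <- truth$losses[end - start + 1L >= min_loss_len]
  loss_rows <- lapply(seq_len(nrow(tl)), function(i) {
    r <- tl[i]
    called_l <- report$losses
    m <- NULL
    if (!is.null(called_l) && nrow(called_l)) {
      cand <- called_l[chrom == r$chrom & zygosity == r$zygosity &
                         start <= r$end & end >= r$start]
      if (nrow(cand)) m <- cand[1]
    }
    data.table(chrom = r$chrom, start = r$start, end = r$end,
               zygosity = r$zygosity, matched = !is.null(m),
               start_error = if (is.null(m)) NA_integer_ else abs(m$start - r$start),
               end_error = if (is.null(m)) NA_integer_ else abs(m$end - r$end),
               ratio = if (is.null(m)) NA_real_ else m$ratio)
  })
  losses <- if (length(loss_rows)) rbindlist(loss_rows) else
    data.table(chrom = character(), start = integer(), end = integer(),
               zygosity = character(), matched = logical(),
               start_error = integer(), end_error = integer(), ratio = numeric())
  list(junctions = junctions, architectures = architectures, losses = losses)
}
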