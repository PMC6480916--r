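make_obs <- function(pa, pb, reads = paste0("r", seq_along(pa))) {
  data.table::data.table(
    read_id = reads, src_a = "chr1", pos_a = as.integer(pa), orient_a = "+",
    src_b = "vector", pos_b = as.integer(pb), orient_b = "-",
    read_boundary = 100L, flipped = FALSE, read_order = 1L)
}

test_that("observations within tolerance merge to one junction (oracle case)", {
  set.seed(401)
  pa <- 10000L + sample(-3:3, 12, TRUE)
  pb <- 500L + sample(-2:2, 12, TRUE)
  js <- call_breakpoints(make_obs(pa, pb), cluster_tol = 20L, min_support = 3L)
  expect_equal(nrow(js$junctions), 1L)
  expect_equal(js$junctions$support, 12L)
  expect_equal(js$junctions$pos_a, as.integer(round(median(pa))))
  expect_equal(js$junctions$pos_b, as.integer(round(median(pb))))
})

test_that("distant observations stay separate; empty input is empty", {
  js <- call_breakpoints(make_obs(c(1000, 2000), c(500, 500)),
                         cluster_tol = 20L, min_support = 1L)
  expect_equal(nrow(js$junctions), 2L)
  empty <- call_breakpoints(list())
  expect_equal(nrow(empty$junctions), 0L)
})

test_that("clustering equals brute-force single linkage on random instances", {
  for (seed in c(402, 403, 404)) {
    set.seed(seed)
    n_clusters <- sample(3:6, 1)
    centers_a <- sample(seq(1000, 900000, by = 1500), n_clusters)
    centers_b <- sample(seq(100, 10000, by = 300), n_clusters)
    idx <- sample(n_clusters, 150, TRUE)
    pa <- centers_a[idx] + sample(-10:10, 150, TRUE)
    pb <- centers_b[idx] + sample(-10:10, 150, TRUE)
    impl <- tdnascope:::single_linkage_2d(pa, pb, 20L)
    orac <- cluster_oracle(pa, pb, 20L)
    expect_true(same_partition(impl, orac))
  }
})

test_that("concatemer length follows the sum-of-absolute-spans convention", {
  expect_equal(concatemer_length(list(c(100, 100))), 0L)
  expect_error(concatemer_length(list()), "no fragments")
  # invariant under flipping the whole architecture
  set.seed(405)
  for (i in 1:10) {
    fr <- matrix(sample(1:11000, 8), ncol = 2)
    flipped <- fr[rev(seq_len(nrow(fr))), c(2, 1), drop = FALSE]
    expect_equal(concatemer_length(fr), concatemer_length(flipped))
  }
})

test_that("fragment graph partitions chromosomes exactly and names nodes", {
  ref <- build_reference(2, c(100000, 80000), seed = 51)
  jn <- data.table::data.table(
    junction_id = c("J01", "J02"), label = c("a", "b"),
    src_a = c("chr1", "chr1"), pos_a = c(30000L, 60000L),
    orient_a = c("+", "+"),
    src_b = c("vector", "chr2"), pos_b = c(500L, 40000L),
    orient_b = c("-", "-"), support = c(5L, 5L), cluster_id = 1:2)
  jset <- structure(list(junctions = jn,
                         observations = data.table::data.table()),
                    class = "junction_set")
  g <- build_fragment_graph(jset, ref)
  expect_equal(g$nodes$node[g$nodes$chrom == "chr1"],
               c("chr1-1", "chr1-2", "chr1-3"))
  for (ch in c("chr1", "chr2")) {
    nd <- g$nodes[g$nodes$chrom == ch, ]
    expect_equal(sum(nd$end - nd$start + 1L), unname(ref$lengths[[ch]]))
  }
  # bare chr1-chr2 junction becomes an edge with no vector annotation
  expect_equal(g$edges$kind, "bare")
  # no junctions -> one node per chromosome, no edges
  g0 <- build_fragment_graph(structure(list(junctions = tdnascope:::empty_junctions(),
                                            observations = data.table::data.table()),
                                       class = "junction_set"), ref)
  expect_equal(nrow(g0$nodes), 2L)
  expect_equal(nrow(g0$edges), 0L)
})

test_that("event classification follows the three-case break model", {
  ref <- build_reference(2, c(100000, 80000), seed = 52)
  jset <- structure(list(junctions = tdnascope:::empty_junctions(),
                         observations = data.table::data.table()),
                    class = "junction_set")
  g <- build_fragment_graph(jset, ref)
  mk_arch <- function(left, right) {
    structure(list(locus_left = left, locus_right = right,
                   fragments = matrix(c(100L, 200L), ncol = 2),
                   junction_ids = "J01", support = 5L, ambiguous = FALSE),
              class = "concatemer_architecture")
  }
  s <- tdnascope:::side
  archs <- list(
    mk_arch(s("chr1", 30000L, "+"), s("chr1", 30021L, "-")),  # case 1
    mk_arch(s("chr1", 50000L, "+"), NULL),                    # case 2
    mk_arch(s("chr1", 70000L, "+"), s("chr2", 20000L, "-")))  # case 3
  ev <- classify_events(g, archs, jset)
  expect_setequal(ev$case, c("intact_insertion", "truncation", "translocation"))
  # bare junction classification: co-linear same-chromosome -> deletion,
  # anything else -> bare_translocation
  jn <- data.table::data.table(
    junction_id = c("J01", "J02"), label = c("a", "b"),
    src_a = c("chr1", "chr1"), pos_a = c(10000L, 40000L),
    orient_a = c("+", "+"),
    src_b = c("chr1", "chr2"), pos_b = c(25000L, 60000L),
    orient_b = c("-", "+"), support = c(4L, 4L), cluster_id = 1:2)
  jset2 <- structure(list(junctions = jn,
                          observations = data.table::data.table()),
                     class = "junction_set")
  ev2 <- classify_events(build_fragment_graph(jset2, ref), list(), jset2)
  expect_equal(ev2$case[ev2$pos_a == 10000], "deletion")
  expect_equal(ev2$case[ev2$pos_a == 40000], "bare_translocation")
})
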