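# independent per-pair IBS recount from genotype strings
ibs_oracle <- function(gt) {
  n <- ncol(gt)
  parse1 <- function(g) {
    p <- strsplit(g, "[/|]")[[1L]]
    if (any(p == ".")) NULL else sort(as.integer(p))
  }
  d <- base::matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    num <- 0; cnt <- 0L
    for (s in seq_len(nrow(gt))) {
      gi <- parse1(gt[s, i]); gj <- parse1(gt[s, j])
      if (is.null(gi) || is.null(gj)) next
      shared <- 0L
      pool <- gj
      for (a in gi) {
        hit <- match(a, pool)
        if (!is.na(hit)) { shared <- shared + 1L; pool <- pool[-hit] }
      }
      num <- num + (1 - shared / 2); cnt <- cnt + 1L
    }
    d[i, j] <- d[j, i] <- if (cnt) num / cnt else 1
  }
  d
}

test_that("IBS distances match hand values and the recount oracle", {
  m <- matrix_from_gt(rbind(c("0/0", "0/0", "1/1", "0/1"),
                            c("0/0", "0/0", "1/1", "0/1")))
  D <- ibs_distance_matrix(m)
  expect_equal(D["t01", "t02"], 0)        # identical everywhere
  expect_equal(D["t01", "t03"], 1)        # opposite homozygotes at every site
  expect_equal(D["t01", "t04"], 0.5)
  expect_equal(D["t04", "t04"], 0)
  # random fixture vs brute-force recount
  set.seed(11)
  gt <- base::matrix(sample(c("0/0", "0/1", "1/1", "./."), 100 * 20,
                            replace = TRUE, prob = c(0.4, 0.2, 0.3, 0.1)),
                     100, 20)
  mr <- matrix_from_gt(gt)
  expect_equal(unname(ibs_distance_matrix(mr)), ibs_oracle(gt), tolerance = 1e-12)
  expect_error(ibs_distance_matrix(matrix_from_gt(c("0/0"))),
               class = "snpscope_parameter")
})

test_that("distance matrix is invariant under sample relabelling", {
  set.seed(12)
  gt <- base::matrix(sample(c("0/0", "0/1", "1/1"), 40 * 6, replace = TRUE), 40, 6)
  m <- matrix_from_gt(gt)
  D <- ibs_distance_matrix(m)
  perm <- sample(ncol(gt))
  Dp <- ibs_distance_matrix(matrix_from_gt(gt[, perm]))
  expect_equal(unname(Dp), unname(D[perm, perm]), tolerance = 1e-12)
})

test_that("neighbour joining recovers the worked additive 4-taxon case", {
  D <- base::matrix(c(0, 3, 5, 6,
                      3, 0, 6, 7,
                      5, 6, 0, 7,
                      6, 7, 7, 0), 4, 4,
                    dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tree <- neighbor_joining(D)
  # path lengths reproduce the additive matrix exactly
  expect_equal(as.matrix(ape::cophenetic.phylo(tree))[rownames(D), colnames(D)],
               D, tolerance = 1e-12)
  # topology ((A,B),(C,D)): A,B form a cherry, C,D form a cherry
  coph <- ape::cophenetic.phylo(tree)
  expect_equal(unname(coph["A", "B"]), 3)
  expect_equal(unname(coph["C", "D"]), 7)
  leaf_edges <- setNames(tree$edge.length[match(seq_along(tree$tip.label),
                                                tree$edge[, 2L])], tree$tip.label)
  expect_equal(unname(leaf_edges[c("A", "B", "C", "D")]), c(1, 2, 3, 4))
  internal <- tree$edge[, 2L] > length(tree$tip.label)
  expect_equal(unname(tree$edge.length[internal]), 1)
})

test_that("3-leaf NJ solves the closed-form system", {
  D <- base::matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
                    dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(D)
  expect_equal(tree$Nnode, 1L)
  expect_equal(as.matrix(ape::cophenetic.phylo(tree))[rownames(D), colnames(D)],
               D, tolerance = 1e-12)
})

test_that("NJ is invariant to input label order", {
  set.seed(5)
  rt <- ape::rtree(8, rooted = FALSE)
  rt$edge.length <- runif(length(rt$edge.length), 0.1, 5)
  D <- as.matrix(ape::cophenetic.phylo(rt))
  t1 <- neighbor_joining(D)
  perm <- sample(nrow(D))
  t2 <- neighbor_joining(D[perm, perm])
  labs <- rownames(D)
  expect_equal(as.matrix(ape::cophenetic.phylo(t1))[labs, labs],
               as.matrix(ape::cophenetic.phylo(t2))[labs, labs], tolerance = 1e-9)
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})

test_that("classical MDS reconstructs Euclidean configurations", {
  # 3 points pairwise distance 1
  D <- base::matrix(1, 3, 3) - diag(3)
  co <- classical_mds(D, 2)
  expect_equal(unname(as.matrix(dist(co))), unname(D), tolerance = 1e-9)
  # random planar point sets round-trip within 1e-6
  set.seed(3)
  pts <- base::matrix(rnorm(14 * 2), 14, 2)
  Dp <- as.matrix(dist(pts))
  co2 <- classical_mds(Dp, 2)
  expect_equal(unname(as.matrix(dist(co2))), unname(Dp), tolerance = 1e-6)
  # k = 1 on collinear points is exact
  line <- cbind(c(0, 1, 2.5, 7), 0)
  Dl <- as.matrix(dist(line))
  expect_equal(unname(as.matrix(dist(classical_mds(Dl, 1)))), unname(Dl),
               tolerance = 1e-9)
  # sign convention: largest-magnitude coordinate positive on each axis
  for (ax in 1:2) expect_gte(co2[which.max(abs(co2[, ax])), ax], 0)
  # all-zero distances are not an error
  expect_equal(unname(classical_mds(base::matrix(0, 3, 3), 2)),
               base::matrix(0, 3, 2))
})

test_that("write_newick quotes awkward labels and round-trips through ape", {
  D <- base::matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3)
  rownames(D) <- colnames(D) <- c("Chinese Spring", "B", "C")
  tree <- neighbor_joining(D)
  s <- write_newick(tree)
  expect_match(s, "'Chinese Spring'", fixed = TRUE)
  expect_match(s, ";$")
  back <- ape::read.tree(text = s)
  # ape keeps the quote characters verbatim; strip them for comparison
  expect_setequal(gsub("'", "", back$tip.label), tree$tip.label)
  # random trees: path-length matrices survive the round trip
  set.seed(9)
  for (i in 1:5) {
    rt <- ape::rtree(6, rooted = FALSE)
    D6 <- as.matrix(ape::cophenetic.phylo(rt))
    t6 <- neighbor_joining(D6)
    b6 <- ape::read.tree(text = write_newick(t6))
    labs <- t6$tip.label
    expect_equal(as.matrix(ape::cophenetic.phylo(b6))[labs, labs],
                 as.matrix(ape::cophenetic.phylo(t6))[labs, labs],
                 tolerance = 1e-6)
  }
})
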