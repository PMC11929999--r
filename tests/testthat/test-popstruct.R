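toy_loci <- function() {
  loci <- data.frame(locus_id = 1:3, chrom = "1", start = c(1, 100, 200),
                     end = c(50, 150, 250), cnv_type = "loss",
                     n_members = c(2L, 1L, 1L), n_samples = c(2L, 1L, 1L))
  members <- data.frame(locus_id = c(1L, 1L, 2L, 3L),
                        call_row = 1:4,
                        sample_id = c("a1", "a2", "a1", "b1"),
                        tool = "t")
  list(loci = loci, members = members)
}

test_that("binary matrix marks locus membership per sample", {
  m <- binary_matrix(toy_loci(), toy_sheet())
  expect_equal(dim(m), c(7, 3))
  expect_equal(unname(m["a1", ]), c(1L, 1L, 0L))
  expect_equal(unname(m["b1", ]), c(0L, 0L, 1L))
  expect_equal(unname(m["c1", ]), c(0L, 0L, 0L))
  bad <- toy_loci()
  bad$members$sample_id[1] <- "ghost"
  expect_error(binary_matrix(bad, toy_sheet()), "absent from sheet")
})

test_that("Jaccard distances follow set arithmetic", {
  m <- rbind(s1 = c(1L, 1L, 0L), s2 = c(1L, 0L, 1L), s3 = c(1L, 1L, 0L),
             s4 = c(0L, 0L, 1L))
  colnames(m) <- paste0("l", 1:3)
  d <- cnv_distance(m)
  expect_equal(unclass(d)["s1", "s2"], 1 - 1/3)
  expect_equal(unclass(d)["s1", "s3"], 0)          # identical rows
  expect_equal(unclass(d)["s3", "s4"], 1)          # disjoint non-empty rows
  expect_true(all(diag(unclass(d)) == 0))
  expect_equal(unclass(d), t(unclass(d)))
  # column order is irrelevant
  d2 <- cnv_distance(m[, c(3, 1, 2)])
  expect_equal(unclass(d2), unclass(d))
  # empty-union pair falls back to zero with a warning
  m0 <- rbind(s1 = c(0L, 0L), s2 = c(0L, 0L), s3 = c(1L, 0L))
  expect_warning(d0 <- cnv_distance(m0), "empty presence union")
  expect_equal(unclass(d0)["s1", "s2"], 0)
  # simple matching counts disagreement fraction
  ds <- cnv_distance(m, metric = "simple_matching")
  expect_equal(unclass(ds)["s1", "s2"], 2/3)
})

test_that("classical scaling recovers a collinear configuration", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(c("p1", "p2", "p3"), c("p1", "p2", "p3")))
  coords <- classical_mds(d, k = 1)
  got <- sort(coords[, 1])
  expect_equal(got, c(-1, 0, 1), tolerance = 1e-9, ignore_attr = TRUE)
  # equidistant points embed equidistantly
  de <- matrix(1, 3, 3) - diag(3)
  dimnames(de) <- list(letters[1:3], letters[1:3])
  ce <- classical_mds(de, k = 2)
  pd <- as.matrix(dist(ce))
  off <- pd[upper.tri(pd)]
  expect_equal(max(off) - min(off), 0, tolerance = 1e-9)
  # coincident samples stay coincident
  dc <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  cc <- classical_mds(dc, k = 1)
  expect_equal(cc["x", 1], cc["y", 1], tolerance = 1e-9)
  expect_error(classical_mds(d, k = 0), "positive")
})

test_that("classical scaling recovers planted Euclidean configurations", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    d <- as.matrix(dist(X))
    dimnames(d) <- list(paste0("p", 1:n), paste0("p", 1:n))
    Y <- classical_mds(d, k = 2)
    expect_lt(procrustes_residual(X, Y), 1e-8)
  }
})

test_that("the MDS sign convention is deterministic", {
  set.seed(100)
  X <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(dist(X)); dimnames(d) <- list(paste0("p", 1:8), paste0("p", 1:8))
  c1 <- classical_mds(d, 2); c2 <- classical_mds(d, 2)
  expect_identical(c1, c2)
  for (j in 1:2) expect_gte(c1[which.max(abs(c1[, j])), j], 0)
})

test_that("neighbour joining solves the three-taxon closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj <- neighbor_joining(d)
  paths <- ape::cophenetic.phylo(nj$phylo)
  expect_equal(paths[rownames(d), colnames(d)], d, tolerance = 1e-12)
  # pendant branches A=1, B=2, C=3
  bl <- nj$phylo$edge.length[match(1:3, nj$phylo$edge[, 2])]
  expect_equal(sort(bl), c(1, 2, 3))
})

test_that("neighbour joining is exact on additive matrices", {
  set.seed(55)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    tree <- ape::rtree(n)
    tree$edge.length <- runif(length(tree$edge.length), 0.05, 2)
    d <- ape::cophenetic.phylo(tree)
    ord <- sample(n)
    d <- d[ord, ord]
    nj <- neighbor_joining(d)
    got <- ape::cophenetic.phylo(nj$phylo)
    expect_equal(got[rownames(d), colnames(d)], d, tolerance = 1e-9)
  }
})

test_that("neighbour joining agrees with the reference implementation", {
  set.seed(56)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    X <- matrix(rnorm(n * 3), n)
    d <- as.matrix(dist(X))
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    ours <- neighbor_joining(d)$phylo
    ref <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(ours)[rownames(d), colnames(d)],
                 ape::cophenetic.phylo(ref)[rownames(d), colnames(d)],
                 tolerance = 1e-9)
  }
})

test_that("degenerate and malformed distance inputs are handled", {
  # two taxa: one edge carrying the full distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  nj2 <- neighbor_joining(d2)
  expect_equal(ape::cophenetic.phylo(nj2$phylo)["A", "B"], 0.4)
  asym <- matrix(c(0, 1, 2, 0), 2)
  expect_error(neighbor_joining(asym), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2)
  expect_error(neighbor_joining(neg), "nonnegative")
  # emitted Newick re-parses to the same tree
  d <- as.matrix(dist(matrix(rnorm(12), 6)))
  dimnames(d) <- list(paste0("t", 1:6), paste0("t", 1:6))
  nj <- neighbor_joining(d)
  reparsed <- ape::read.tree(text = nj$newick)
  expect_equal(ape::dist.topo(reparsed, nj$phylo), 0, ignore_attr = TRUE)
  expect_equal(sort(reparsed$tip.label), paste0("t", 1:6))
})

test_that("region-structured data separates regions more than breeds", {
  run <- default_pipeline_run()
  m <- read_matrix_tsv(file.path(run$out_dir, "union_binary_matrix.tsv"))
  sheet <- read_sample_sheet(file.path(run$out_dir, "input", "samples.tsv"))
  d <- unclass(cnv_distance(m))
  same_breed <- outer(sheet$breed, sheet$breed, "==")
  same_region <- outer(sheet$region, sheet$region, "==")
  ut <- upper.tri(d)
  within_breed <- mean(d[ut & same_breed])
  between_region <- mean(d[ut & !same_region])
  expect_gt(between_region, within_breed)
})
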