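# Path-length matrix of a phylo tree: independent check that NJ output
# reproduces additive input distances.
tree_path_dists <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d))]
}

test_that("p-distance uses pairwise deletion and hand-counted differences", {
  aln <- aligned_seqs(c("a", "b"), c("AAAA", "AATT"))
  expect_equal(p_distance(aln, "a", "b"), 0.5)
  aln2 <- aligned_seqs(c("a", "b"), c("A-AA", "AGAC"))
  # comparable columns {1,3,4}, one difference -> 1/3
  expect_equal(p_distance(aln2, 1, 2), 1 / 3)
  ident <- aligned_seqs(c("a", "b"), c("ACDE", "ACDE"))
  expect_equal(p_distance(ident, 1, 2), 0)
  nogap <- aligned_seqs(c("a", "b"), c("A--", "-GG"))
  expect_error(p_distance(nogap, 1, 2), "no mutually ungapped")
})

test_that("the Kimura correction matches its closed form and saturates", {
  expect_equal(kimura_correction(0), 0, ignore_attr = TRUE)
  expect_equal(as.numeric(kimura_correction(0.1)), -log(1 - 0.1 - 0.01 / 5))
  expect_equal(as.numeric(kimura_correction(0.1)), 0.107585210680,
               tolerance = 1e-10)
  p <- seq(0, 0.7, by = 0.05)
  d <- as.numeric(kimura_correction(p))
  expect_true(all(d >= p))          # correction only inflates distances
  expect_warning(out <- kimura_correction(0.9), "saturated")
  expect_equal(as.numeric(out), 10)
  expect_true(attr(out, "saturated"))
})

test_that("3-taxon NJ solves the closed-form star", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  lens <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                          tr$tip.label)
  expect_equal(lens[["A"]], 0)
  expect_equal(lens[["B"]], 2)
  expect_equal(lens[["C"]], 4)
})

test_that("NJ is exact on additive matrices (4 and 8 taxa)", {
  skip_if_not_installed("phangorn")
  # 4 taxa from a known tree
  gen4 <- ape::read.tree(text = "((A:1,B:2):1.5,(C:0.5,D:3):1);")
  d4 <- tree_path_dists(gen4)
  tr4 <- nj_tree(d4)
  expect_equal(phangorn::RF.dist(ape::unroot(gen4), tr4), 0)
  expect_equal(tree_path_dists(tr4), d4, tolerance = 1e-9)

  # random 8-taxon tree with positive branch lengths
  set.seed(8)
  gen8 <- ape::rtree(8, br = function(n) runif(n, 0.2, 2))
  d8 <- tree_path_dists(gen8)
  tr8 <- nj_tree(d8)
  expect_equal(phangorn::RF.dist(ape::unroot(gen8), tr8), 0)
  expect_equal(tree_path_dists(tr8), d8, tolerance = 1e-9)
})

test_that("our NJ agrees topologically with the ape reference on noisy input", {
  skip_if_not_installed("phangorn")
  set.seed(12)
  for (rep in 1:5) {
    n <- 7
    base <- tree_path_dists(ape::rtree(n, br = function(k) runif(k, 0.3, 1.5)))
    noise <- matrix(runif(n * n, 0, 0.02), n, n)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    d <- base + noise
    ours <- nj_tree(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(phangorn::RF.dist(ours, ref), 0)
  }
})

test_that("taxon order changes labels only, never topology", {
  skip_if_not_installed("phangorn")
  set.seed(5)
  gen <- ape::rtree(6, br = function(n) runif(n, 0.2, 1.5))
  d <- tree_path_dists(gen)
  perm <- sample(nrow(d))
  tr1 <- nj_tree(d)
  tr2 <- nj_tree(d[perm, perm])
  expect_equal(phangorn::RF.dist(tr1, tr2), 0)
})

test_that("degenerate all-equal distances resolve deterministically", {
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  tr1 <- nj_tree(d)
  tr2 <- nj_tree(d)
  expect_equal(ape::write.tree(tr1), ape::write.tree(tr2))
  expect_equal(sort(tr1$tip.label), LETTERS[1:4])
})

test_that("negative NJ branch lengths are clamped and flagged", {
  d <- matrix(c(0, 1, 5, 5,
                1, 0, 5, 5,
                5, 5, 0, 1,
                5, 5, 1, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  # perturb to force a negative internal estimate
  d["A", "C"] <- d["C", "A"] <- 2
  expect_warning(tr <- nj_tree(d), "clamped")
  expect_true(all(tr$edge.length >= 0))
  expect_true(attr(tr, "clamped"))
})

test_that("Newick output round-trips to an isomorphic tree", {
  skip_if_not_installed("phangorn")
  set.seed(20)
  gen <- ape::rtree(20, br = function(n) runif(n, 0.1, 2))
  d <- tree_path_dists(gen)
  tr <- nj_tree(d)
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tf)
  back <- read_newick(tf)
  expect_equal(phangorn::RF.dist(tr, back), 0)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))

  two <- nj_tree(matrix(c(0, 3, 3, 0), 2, 2,
                        dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(sort(two$tip.label), c("A", "B"))
  expect_equal(sum(two$edge.length), 3)
})

test_that("NJ on p-distances recovers the generating topology", {
  skip_if_not_installed("phangorn")
  gen <- ape::read.tree(text = paste0(
    "((((t1:0.1,t2:0.1):0.15,(t3:0.1,t4:0.1):0.15):0.2,",
    "(t5:0.1,t6:0.1):0.3):0.1,(t7:0.2,t8:0.2):0.2);"))
  aln <- evolve_on_tree(gen, sequence_length = 2000, seed = 77)
  tr <- aln_nj_tree(aln)
  expect_equal(phangorn::RF.dist(ape::unroot(gen), tr), 0)
})

test_that("well-separated groups form monophyletic clusters in the NJ tree", {
  skip_if_not_installed("phangorn")
  # 5 groups of 3 tips on long inter-group stems: every group must appear
  # as a bipartition of the tree, mirroring kingdom-level clustering
  stem <- function(g) sprintf("(%s_1:0.05,(%s_2:0.05,%s_3:0.05):0.05):1.0",
                              g, g, g)
  txt <- sprintf("(%s,%s,(%s,(%s,%s):0.3):0.3);",
                 stem("ar"), stem("b"), stem("f"), stem("p"), stem("an"))
  gen <- ape::read.tree(text = txt)
  aln <- evolve_on_tree(gen, sequence_length = 1500, seed = 13)
  tr <- aln_nj_tree(aln)
  for (g in c("ar", "b", "f", "p", "an")) {
    tips <- grep(paste0("^", g, "_"), tr$tip.label, value = TRUE)
    expect_true(ape::is.monophyletic(tr, tips))
  }
})
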