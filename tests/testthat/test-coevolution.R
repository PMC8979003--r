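test_that("pairwise distances follow p and Poisson definitions with pairwise deletion", {
  al <- protein_alignment(c("x", "y"), c("AAAA", "AAAA"))
  expect_equal(unname(pairwise_distances(al)["x", "y"]), 0)

  al2 <- protein_alignment(c("x", "y"), c("AAAA", "AAAT"))
  expect_equal(unname(pairwise_distances(al2)["x", "y"]), 0.25)

  al3 <- protein_alignment(c("x", "y"), c("AAAA", "AATT"))
  expect_equal(unname(pairwise_distances(al3, "poisson")["x", "y"]),
               -log(0.5))

  # gap columns are deleted pairwise: only 2 comparable columns, 1 mismatch
  al4 <- protein_alignment(c("x", "y"), c("A-AT", "AAA-"))
  expect_equal(unname(pairwise_distances(al4)["x", "y"]), 0)
  al5 <- protein_alignment(c("x", "y"), c("A-GT", "CA--"))
  expect_equal(unname(pairwise_distances(al5)["x", "y"]), 1)

  expect_error(pairwise_distances(
    protein_alignment(c("x", "y"), c("A---", "-AAA"))), "comparable")
  expect_error(pairwise_distances(
    protein_alignment(c("x", "y"), c("AAAA", "CCCC")), "poisson"),
    "undefined")
})

test_that("neighbor joining is exact on additive matrices", {
  # all three unrooted 4-taxon topologies, explicit branch lengths
  quartet <- function(pairing) {
    el <- c(a = 0.11, b = 0.23, c = 0.17, d = 0.31, i = 0.4)
    taxa <- c("a", "b", "c", "d")
    d <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
    sisters <- function(x, y) x %in% pairing == y %in% pairing
    for (x in taxa) for (y in taxa) {
      if (x == y) next
      d[x, y] <- el[x] + el[y] + if (sisters(x, y)) 0 else el["i"]
    }
    d
  }
  for (pairing in list(c("a", "b"), c("a", "c"), c("a", "d"))) {
    dm <- quartet(pairing)
    tr <- nj_tree(dm)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-12)
  }
  # random additive matrices from 5-8 taxon trees round-trip exactly
  set.seed(31)
  for (n in 5:8) {
    tr0 <- ape::rtree(n)
    tr0$edge.length <- runif(nrow(tr0$edge), 0.05, 1)
    dm <- ape::cophenetic.phylo(tr0)
    tr <- nj_tree(dm)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-10)
  }
})

test_that("star-like equidistant matrices give zero internal branches", {
  taxa <- letters[1:5]
  dm <- matrix(1, 5, 5, dimnames = list(taxa, taxa)); diag(dm) <- 0
  tr <- suppressMessages(nj_tree(dm))
  tip_edges <- tr$edge[, 2] <= length(tr$tip.label)
  expect_true(all(abs(tr$edge.length[!tip_edges]) < 1e-12))
  expect_error(nj_tree(dm[1:3, 1:3]), "at least 4")
})

test_that("tiny metric perturbations do not change the inferred topology", {
  set.seed(32)
  tr0 <- ape::rtree(5)
  tr0$edge.length <- runif(nrow(tr0$edge), 0.1, 1)
  dm <- ape::cophenetic.phylo(tr0)
  pert <- dm + matrix(runif(25, -1e-9, 1e-9), 5, 5)
  pert <- (pert + t(pert)) / 2; diag(pert) <- 0
  expect_equal(ape::dist.topo(nj_tree(dm), nj_tree(pert)), 0,
               ignore_attr = TRUE)
})

test_that("newick serialization round-trips the leaf set", {
  set.seed(33)
  tr <- ape::unroot(ape::rtree(6))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)
})

test_that("mirror-tree correlation is exact, affine-invariant and symmetric", {
  set.seed(34)
  tr <- ape::rtree(8)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
  dm <- ape::cophenetic.phylo(tr)
  expect_equal(mirror_tree_score(dm, dm)$r, 1)
  expect_equal(mirror_tree_score(dm, 3 * dm + 0.2)$r, 1)

  dm2 <- dm + matrix(abs(rnorm(64, 0, 0.3)), 8, 8)
  dm2 <- (dm2 + t(dm2)) / 2; diag(dm2) <- 0
  s12 <- mirror_tree_score(dm, dm2)
  s21 <- mirror_tree_score(dm2, dm)
  expect_equal(s12$r, s21$r)
  expect_equal(s12$n_pairs, s12$shared_taxa * (s12$shared_taxa - 1) / 2)

  # invariance under a consistent taxon permutation
  p <- sample(rownames(dm))
  expect_equal(mirror_tree_score(dm[p, p], dm2)$r, s12$r)

  expect_error(mirror_tree_score(dm[1:3, 1:3], dm), "shared taxa")
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(mirror_tree_score(z, z), "zero variance")
})

test_that("glance and tidy expose the mirror-tree fit", {
  set.seed(35)
  tr <- ape::rtree(6); tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
  dm <- ape::cophenetic.phylo(tr)
  s <- mirror_tree_score(dm, dm)
  g <- glance(s)
  expect_equal(g$r, 1)
  expect_equal(nrow(tidy(s)), g$n_pairs)
})

test_that("alignment concatenation joins shared taxa and preserves p-distance under self-concatenation", {
  a <- protein_alignment(paste0("t", 1:6), replicate(6, random_dna(20)))
  b <- protein_alignment(paste0("t", 2:7), replicate(6, random_dna(30)))
  expect_message(cc <- concatenate_alignments(a, b), "dropped 2")
  expect_equal(nrow(cc), 5L)
  expect_equal(unique(nchar(cc$seq)), 50L)

  self <- concatenate_alignments(a[1:4, ], a[1:4, ])
  expect_equal(pairwise_distances(self), pairwise_distances(a[1:4, ]))

  expect_error(concatenate_alignments(a[1:3, ], b[4:6, ]), "shared taxa")
})
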