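test_that("Poisson distances follow the closed form and complete deletion", {
  # identical sequences: zero distance
  pd0 <- poissonDistance(c(a = "ACDE", b = "ACDE"))
  expect_identical(as.matrix(pd0)["a", "b"], 0)

  # one mismatch in four sites: p = 0.25, d = -ln(0.75)
  pd <- poissonDistance(c(a = "ACDE", b = "ACDF"))
  expect_equal(as.matrix(pd)["a", "b"], -log(0.75), tolerance = 1e-12)
  expect_identical(usedSites(pd), 4L)

  # a gap column is removed for all taxa before comparison
  pd2 <- poissonDistance(c(a = "A-CD", b = "ABCD"))
  expect_identical(usedSites(pd2), 3L)
  expect_identical(as.matrix(pd2)["a", "b"], 0)

  # X counts as missing data under complete deletion
  pd3 <- poissonDistance(c(a = "AXCD", b = "AYCE"))
  expect_identical(usedSites(pd3), 3L)
  expect_equal(as.matrix(pd3)["a", "b"], -log(1 - 1 / 3), tolerance = 1e-12)

  expect_error(poissonDistance(c(a = "AAAA", b = "CCCC")), "saturated")
  expect_error(poissonDistance(c(a = "--", b = "AA")), "zero columns")
  expect_error(poissonDistance(c(a = "AA", b = "AAA")), "equal aligned length")
})

test_that("d(p) dominates p and increases strictly on a grid", {
  ps <- seq(0.05, 0.95, by = 0.05)
  ds <- -log(1 - ps)
  expect_true(all(ds > ps))
  expect_true(all(diff(ds) > 0))
  # the same values arise through the alignment path
  for (k in seq(0, 19)) {
    n <- 20
    a <- strrep("A", n)
    b <- paste0(strrep("C", k), strrep("A", n - k))
    got <- as.matrix(poissonDistance(c(x = a, y = b)))["x", "y"]
    expect_equal(got, -log(1 - k / n), tolerance = 1e-12)
  }
})

test_that("two-taxon tree reduces to a path of length d12", {
  d <- matrix(c(0, 1.6, 1.6, 0), 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  tr <- njTree(d)
  expect_identical(sort(tr$tip.label), c("A", "B"))
  expect_equal(sum(tr$edge.length), 1.6)
  expect_equal(unname(ape::cophenetic.phylo(tr)["A", "B"]), 1.6)
})

test_that("NJ recovers an additive 4-taxon tree with exact branch lengths", {
  gen <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  dm <- ape::cophenetic.phylo(gen)
  tr <- njTree(dm)
  expect_setequal(treeSplits(tr), treeSplits(gen))
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
                       - dm)), 0, tolerance = 1e-12)
  # tip edges carry the generating limb lengths
  limb <- tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])]
  names(limb) <- tr$tip.label
  expect_equal(limb[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3, D = 1))
})

test_that("NJ output is invariant to taxon input order (lexicographic ties)", {
  set.seed(15)
  cs <- randomAdditiveCase(6)
  perm <- sample(rownames(cs$dm))
  t1 <- njTree(cs$dm)
  t2 <- njTree(cs$dm[perm, perm])
  expect_setequal(treeSplits(t1), treeSplits(t2))
  expect_equal(ape::cophenetic.phylo(t1)[perm, perm],
               ape::cophenetic.phylo(t2)[perm, perm], tolerance = 1e-12)
})

test_that("NJ matches the reference implementation on random additive matrices", {
  set.seed(77)
  for (k in 1:10) {
    cs <- randomAdditiveCase(sample(4:8, 1))
    mine <- njTree(cs$dm)
    ref <- ape::unroot(ape::nj(cs$dm))
    expect_setequal(treeSplits(mine), treeSplits(ref))
    expect_setequal(treeSplits(mine), treeSplits(cs$tree))
  }
})

test_that("invalid distance matrices are rejected", {
  m <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(njTree(m), "symmetric")
  m2 <- matrix(c(0, -1, -1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(njTree(m2), "nonnegative")
})

test_that("bootstrap supports are percentages with expected degeneracies", {
  tt <- ape::read.tree(
    text = "(((A:0.02,B:0.02):0.02,C:0.04):0.4,((D:0.02,E:0.02):0.02,F:0.04):0.4);")
  aln <- simulateAlignment(tt, 300, substRate = 1, seed = 4)

  one <- bootstrapSupport(aln, nReplicates = 1, seed = 2)
  expect_true(all(attr(one, "splitSupport") %in% c(0, 100)))

  b1 <- bootstrapSupport(aln, nReplicates = 30, seed = 5)
  b2 <- bootstrapSupport(aln, nReplicates = 30, seed = 5)
  expect_identical(attr(b1, "splitSupport"), attr(b2, "splitSupport"))

  # invariance to taxon input order
  perm <- rev(seq_along(aln))
  b3 <- bootstrapSupport(aln[perm], nReplicates = 30, seed = 5)
  expect_identical(attr(b1, "splitSupport"), attr(b3, "splitSupport"))

  # supports land on the tree as node labels
  expect_identical(length(b1$node.label), b1$Nnode)
})

test_that("representative picking cuts long edges and honours anchors", {
  # two tight 3-leaf clades joined by one long internal edge
  tt <- ape::read.tree(
    text = "(((A:0.1,B:0.12):0.05,C:0.3):1.0,((D:0.1,E:0.12):0.05,F:0.3):1.0);")

  reps <- pickRepresentatives(tt, 2)
  groups <- attr(reps, "groups")
  expect_length(reps, 2)
  expect_setequal(groups[[1]], c("A", "B", "C"))
  expect_setequal(groups[[2]], c("D", "E", "F"))
  # brute-force medoid per clade from all-pairs path lengths
  pd <- ape::cophenetic.phylo(tt)
  med <- function(g) g[which.min(colSums(pd[g, g]))]
  expect_identical(reps[1], med(c("A", "B", "C")))
  expect_identical(reps[2], med(c("D", "E", "F")))

  # anchors take precedence over the medoid
  repsA <- pickRepresentatives(tt, 2, anchors = c("C", "F"))
  expect_setequal(repsA, c("C", "F"))

  # k equal to the leaf count selects every leaf
  expect_setequal(pickRepresentatives(tt, 6), tt$tip.label)

  expect_error(pickRepresentatives(tt, 0), "kClades")
  expect_error(pickRepresentatives(tt, 7), "leaf count")
  expect_error(pickRepresentatives(tt, 2, anchors = "ZZ"), "not in tree")
})

test_that("representative picking always returns k taxa in distinct groups", {
  set.seed(91)
  for (k in 1:5) {
    cs <- randomAdditiveCase(sample(5:9, 1))
    tr <- cs$tree
    kc <- sample(seq_len(length(tr$tip.label)), 1)
    reps <- pickRepresentatives(tr, kc)
    groups <- attr(reps, "groups")
    expect_length(reps, kc)
    expect_identical(anyDuplicated(reps), 0L)
    expect_identical(sort(unlist(groups)), sort(tr$tip.label))
    for (i in seq_along(reps))
      expect_true(reps[i] %in% groups[[i]])
  }
})
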