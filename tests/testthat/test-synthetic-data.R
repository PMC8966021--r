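test_that("production curve saturates at the plateau and is seed-deterministic", {
  p <- simulateProductionCurve(fermDays, 2000, seed = 1, noiseSd = 0)
  expect_equal(titer(p)[length(fermDays)], 2000, tolerance = 0.01)
  expect_true(all(diff(titer(p)) >= 0))

  a <- simulateProductionCurve(fermDays, 2000, seed = 42, noiseSd = 0.1)
  b <- simulateProductionCurve(fermDays, 2000, seed = 42, noiseSd = 0.1)
  expect_identical(titer(a), titer(b))
  expect_true(all(diff(titer(a)) >= 0))

  c1 <- simulateProductionCurve(fermDays, 2000, seed = 1, noiseSd = 0.1)
  c2 <- simulateProductionCurve(fermDays, 2000, seed = 2, noiseSd = 0.1)
  expect_false(identical(titer(c1), titer(c2)))

  expect_error(simulateProductionCurve(numeric(0), 2000), "nonempty")
  expect_error(simulateProductionCurve(fermDays, 0), "plateauTiter")
})

test_that("planted correlated genes are exactly linear in titer at zero noise", {
  cfg <- simConfig(nGenes = 60, nPlantedCorrelated = 8, noiseSd = 0, seed = 11)
  prod <- fixtureProduction()
  sim <- simulateExpression(cfg, prod)
  gt <- sim$groundTruth$plantedCorrelated
  expect_length(gt, 8)
  for (g in gt) {
    r <- cor(fpkm(sim$expression)[g, ], titer(prod))
    expect_equal(r^2, 1, tolerance = 1e-12)
  }
  # background genes are never perfectly titer-shaped
  bg <- setdiff(geneIds(sim$expression), gt)
  r2bg <- vapply(bg, function(g) {
    v <- fpkm(sim$expression)[g, ]
    if (var(v) == 0) 0 else cor(v, titer(prod))^2
  }, numeric(1))
  expect_true(all(r2bg < 0.995))
})

test_that("empty planted set and referential integrity of ground truth", {
  cfg <- simConfig(nGenes = 30, nPlantedCorrelated = 0, nPlantedTemporal = 0,
                   noiseSd = 0.1, seed = 2)
  sim <- simulateExpression(cfg, fixtureProduction())
  expect_length(sim$groundTruth$plantedCorrelated, 0)
  expect_length(sim$groundTruth$plantedTemporal, 0)

  cfg2 <- simConfig(nGenes = 100, nPlantedCorrelated = 7,
                    nPlantedTemporal = 5, noiseSd = 0.1, seed = 3)
  sim2 <- simulateExpression(cfg2, fixtureProduction())
  ids <- geneIds(sim2$expression)
  expect_true(all(sim2$groundTruth$plantedCorrelated %in% ids))
  expect_true(all(sim2$groundTruth$plantedTemporal %in% ids))
  expect_length(intersect(sim2$groundTruth$plantedCorrelated,
                          sim2$groundTruth$plantedTemporal), 0)
})

test_that("planted temporal promoters are low early and >= 8-fold up late", {
  cfg <- simConfig(nGenes = 50, nPlantedCorrelated = 0, nPlantedTemporal = 10,
                   noiseSd = 0, seed = 5)
  sim <- simulateExpression(cfg, fixtureProduction())
  days <- sampleDays(sim$expression)
  m <- fpkm(sim$expression)
  for (g in sim$groundTruth$plantedTemporal) {
    early <- mean(m[g, days <= 2])
    late <- mean(m[g, days >= 6])
    expect_gte(late / early, 8)
  }
})

test_that("genome ground truth is planted as advertised", {
  cfg <- simConfig(seed = 13)
  g <- simulateGenome(cfg)
  ids <- g$annotation$ID
  expect_identical(names(g$proteins), ids)
  expect_true(all(g$groundTruth$abcSystems$gene %in% ids))
  expect_true(all(g$groundTruth$familyLabels$gene %in% ids))

  # TMD-bearing members of complete systems carry detectable stretches
  sys <- g$groundTruth$abcSystems
  tmdGenes <- sys$gene[sys$role == "TMD-bearing" &
                       sys$completeness == "complete"]
  for (tg in tmdGenes)
    expect_gte(length(predictTmHelices(as.character(g$proteins[[tg]]))), 4)
  # generator plants 6 stretches and the predictor counts exactly 6
  expect_identical(
    length(predictTmHelices(as.character(g$proteins[[tmdGenes[1]]]))), 6L)

  # NBD-bearing members carry a Walker A motif
  nbdGenes <- sys$gene[sys$role == "NBD-bearing"]
  for (ng in nbdGenes)
    expect_true(attr(detectNbd(as.character(g$proteins[[ng]])), "hasNbd"))

  # intergenic spacing supports full 500-bp promoter extraction after the
  # first gene
  starts <- GenomicRanges::start(g$annotation)
  ends <- GenomicRanges::end(g$annotation)
  expect_true(all(starts[-1] - ends[-length(ends)] - 1 >= 600))
  # no cassette restriction site anywhere on the contig
  contig <- as.character(g$genome[[1]])
  for (site in c("GAATTC", "ACTAGT", "TCTAGA"))
    expect_false(grepl(site, contig, fixed = TRUE))
})

test_that("a decoy-only genome yields zero transporter calls", {
  cfg <- simConfig(nAbcComplete = 0, nAbcCompletable = 0, nAbcIncomplete = 0,
                   nMfs = 0, nDecoys = 25, seed = 4)
  g <- simulateGenome(cfg)
  calls <- classifyTransporters(g$annotation, g$proteins)
  expect_identical(nrow(calls), 25L)
  expect_true(all(calls$family == "none"))
  expect_identical(nrow(assembleAbcSystems(calls, g$annotation)), 0L)
})

test_that("genome output is byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    b <- simulateBundle(simConfig(seed = 21, nPlantedTemporal = 4))
    writeBundle(b, d)
  }
  for (f in c("genome.fasta", "annotation.gff3", "proteins.faa",
              "expression.tsv", "production.tsv", "ground_truth.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("alignment evolution respects rate zero, length and branch checks", {
  tr <- ape::read.tree(text = "((A:0.2,B:0.2):0.2,(C:0.2,D:0.2):0.2);")
  aln0 <- simulateAlignment(tr, 40, substRate = 0, seed = 1)
  expect_identical(length(unique(as.character(aln0))), 1L)
  expect_identical(unique(Biostrings::width(aln0)), 40L)

  aln1 <- simulateAlignment(tr, 1, substRate = 1, seed = 1)
  expect_identical(unique(Biostrings::width(aln1)), 1L)

  bad <- tr; bad$edge.length[2] <- 0
  expect_error(simulateAlignment(bad, 10, 1, 1), "non-positive")
  expect_error(simulateAlignment(tr, 0, 1, 1), "nSites")

  expect_identical(as.character(simulateAlignment(tr, 100, 0.5, seed = 9)),
                   as.character(simulateAlignment(tr, 100, 0.5, seed = 9)))
})

test_that("NJ on evolved alignments recovers the generating 4-taxon topology", {
  tr <- ape::read.tree(
    text = "((A:0.15,B:0.15):0.1,(C:0.15,D:0.15):0.1);")
  want <- treeSplits(tr)
  hits <- 0
  nSeeds <- 20
  for (s in seq_len(nSeeds)) {
    aln <- simulateAlignment(tr, 2000, substRate = 1, seed = s)
    got <- treeSplits(njTree(poissonDistance(aln)))
    hits <- hits + setequal(got, want)
  }
  expect_gte(hits / nSeeds, 0.95)
})
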