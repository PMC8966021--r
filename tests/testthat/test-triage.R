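test_that("hydropathy scan calls planted stretches and rejects polar runs", {
  expect_length(predictTmHelices(strrep("D", 30)), 0)

  # a single isoleucine run flanked by aspartate: exactly one helix
  h <- predictTmHelices(paste0(strrep("D", 20), strrep("I", 25),
                               strrep("D", 20)))
  expect_length(h, 1)
  # the call covers the I-run (positions 21-45)
  expect_lte(IRanges::start(h), 21)
  expect_gte(IRanges::end(h), 45)
  expect_gte(IRanges::width(h), 19)

  # planted multi-stretch architectures are counted exactly
  expect_length(predictTmHelices(mkTmProteinFix(4)), 4)
  expect_length(predictTmHelices(mkTmProteinFix(6)), 6)
  expect_length(predictTmHelices(mkTmProteinFix(12)), 12)

  # X is tolerated (scored 0), shorter-than-window sequences give no call
  expect_length(predictTmHelices("DDXDD"), 0)
  expect_error(predictTmHelices(""), "empty")
  expect_error(predictTmHelices("DDDBZJDDD"), "B")
})

test_that("Walker A detection reports all disjoint motif positions", {
  one <- detectNbd(paste0(strrep("N", 5), "GPSGSGKST", strrep("N", 5)))
  expect_identical(nrow(one), 1L)
  expect_identical(one$start, 6L)
  expect_true(attr(one, "hasNbd"))

  expect_false(attr(detectNbd(strrep("A", 40)), "hasNbd"))

  two <- detectNbd(paste0("GPSGSGKST", strrep("N", 20), "ARRRRGKSN"))
  expect_identical(nrow(two), 2L)
  expect_identical(two$start, c(1L, 30L))
  expect_true(two$end[1] < two$start[2])
})

test_that("classification rules fire with auditable evidence", {
  ann <- data.frame(
    gene = c("g1", "g2", "g3"),
    product = c("ABC transporter ATP-binding protein",
                "MFS multidrug efflux permease",
                "30S ribosomal protein"),
    stringsAsFactors = FALSE)
  prot <- c(g1 = mkNbdProteinFix(), g2 = mkTmProteinFix(12),
            g3 = mkDecoyProteinFix())
  calls <- classifyTransporters(ann, prot)
  expect_identical(nrow(calls), 3L)

  expect_identical(calls$family[calls$gene == "g1"], "ABC")
  ev1 <- as.list(calls$evidence)[[which(calls$gene == "g1")]]
  expect_true("fam:abc_keyword" %in% ev1)
  expect_true("fam:nbd_motif_self" %in% ev1)

  expect_identical(calls$family[calls$gene == "g2"], "MFS")
  expect_identical(calls$substrate_class[calls$gene == "g2"], "drug-multi")
  expect_identical(calls$tm_helix_count[calls$gene == "g2"], 12L)

  expect_identical(calls$family[calls$gene == "g3"], "none")
  expect_identical(calls$substrate_class[calls$gene == "g3"], "none")

  # protein without an annotation record is an error
  expect_error(classifyTransporters(ann[1:2, ], prot), "annotation record")
})

test_that("ABC keyword without structural corroboration is not called ABC", {
  ann <- data.frame(gene = c("lone", "far1", "far2"),
                    product = c("ABC transporter permease",
                                "hypothetical protein",
                                "hypothetical protein"),
                    stringsAsFactors = FALSE)
  prot <- c(lone = mkTmProteinFix(6), far1 = mkDecoyProteinFix(),
            far2 = mkDecoyProteinFix())
  calls <- classifyTransporters(ann, prot)
  expect_false(calls$family[calls$gene == "lone"] == "ABC")
})

test_that("adjacent half-transporter partners assemble into one complete system", {
  ann <- data.frame(
    gene = paste0("g", 1:4),
    product = c("hypothetical protein",
                "ABC transporter ATP-binding protein",
                "ABC transporter permease",
                "hypothetical protein"),
    stringsAsFactors = FALSE)
  prot <- c(g1 = mkDecoyProteinFix(), g2 = mkNbdProteinFix(),
            g3 = mkTmProteinFix(6), g4 = mkDecoyProteinFix())
  calls <- classifyTransporters(ann, prot)
  sys <- assembleAbcSystems(calls, ann)
  expect_identical(nrow(sys), 1L)
  expect_setequal(as.list(sys$members)[[1]], c("g2", "g3"))
  expect_identical(sys$completeness, "complete")
})

test_that("neighbourhood completion honours the window and recruits at most once", {
  # TM donor 3 genes away: out of reach at window 2, reached at window 3
  ann <- data.frame(
    gene = paste0("g", 1:5),
    product = c("ABC transporter ATP-binding protein",
                "hypothetical protein", "hypothetical protein",
                "putative membrane protein", "hypothetical protein"),
    stringsAsFactors = FALSE)
  prot <- c(g1 = mkNbdProteinFix(), g2 = mkDecoyProteinFix(),
            g3 = mkDecoyProteinFix(), g4 = mkTmProteinFix(6),
            g5 = mkDecoyProteinFix())
  calls <- classifyTransporters(ann, prot)
  sys2 <- assembleAbcSystems(calls, ann, neighborhoodWindow = 2)
  expect_identical(sys2$completeness, "incomplete")
  sys3 <- assembleAbcSystems(calls, ann, neighborhoodWindow = 3)
  expect_identical(sys3$completeness, "tmd_completed_from_neighborhood")
  expect_true("g4" %in% as.list(sys3$members)[[1]])
})

test_that("widening the window never downgrades completeness", {
  g <- simulateGenome(simConfig(seed = 17))
  calls <- classifyTransporters(g$annotation, g$proteins)
  s2 <- assembleAbcSystems(calls, g$annotation, neighborhoodWindow = 2)
  s4 <- assembleAbcSystems(calls, g$annotation, neighborhoodWindow = 4)
  # systems may merge with a wider window, but none may lose a domain:
  # the number of incomplete systems can only shrink
  expect_lte(sum(s4$completeness == "incomplete"),
             sum(s2$completeness == "incomplete"))
})

test_that("triage output partitions the proteome", {
  g <- simulateGenome(simConfig(seed = 19))
  calls <- classifyTransporters(g$annotation, g$proteins)
  expect_identical(nrow(calls), length(g$annotation))
  expect_identical(anyDuplicated(calls$gene), 0L)
  sys <- assembleAbcSystems(calls, g$annotation)
  allMembers <- unlist(as.list(sys$members))
  expect_identical(anyDuplicated(allMembers), 0L)
})

test_that("planted family labels are recovered exactly", {
  g <- simulateGenome(simConfig(seed = 23))
  calls <- classifyTransporters(g$annotation, g$proteins)
  gt <- g$groundTruth$familyLabels
  got <- calls$family[match(gt$gene, calls$gene)]
  expect_identical(got, gt$family)
})

test_that("family fraction summarises printed triage counts", {
  ff <- familyFraction(c(ABC = 2, MFS = 3), c(4, 2))
  expect_identical(ff$total, 6)
  expect_identical(ff$nFamily, 5)
  expect_equal(ff$percent, 83.3)
  expect_error(familyFraction(c(ABC = 1), 0), "positive")
})
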