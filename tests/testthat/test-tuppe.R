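test_that("fold-change profiles are zero at t0 and follow pseudocount arithmetic", {
  es <- ExpressionSeries(
    rbind(const = rep(9, 6), doubling = 16 * 2^(0:5), zero0 = c(0, 63, 63, 63, 63, 63)),
    fermDays)
  fc <- foldChangeProfiles(es)
  expect_identical(unname(fc[, 1]), c(0, 0, 0))
  expect_true(all(fc["const", ] == 0))
  expect_equal(unname(fc["doubling", ]), 0:5, tolerance = 0.1)
  expect_equal(unname(fc["zero0", 2]), 6)  # log2((63+1)/(0+1))

  # near pc -> 0 the profile is invariant to global scaling
  es2 <- ExpressionSeries(5 * fpkm(es) + 0, fermDays)
  fcSmall <- foldChangeProfiles(es, pseudocount = 1e-9)
  fcSmall2 <- foldChangeProfiles(es2, pseudocount = 1e-9)
  expect_equal(fcSmall["doubling", ], fcSmall2["doubling", ],
               tolerance = 1e-6)
})

test_that("promoter clustering pairs titer-shaped genes with the production profile", {
  prod <- fixtureProduction()
  ti <- titer(prod)
  # mirror: a gene whose fold-change magnitude profile equals the
  # production one exactly; earlyPeak: oppositely timed (all change in
  # logarithmic phase); plus dull background genes
  m <- rbind(mirror = ti,
             earlyPeak = c(10, 300, 10, 10, 10, 10),
             flat1 = rep(50, 6), flat2 = rep(80, 6),
             high = c(500, 480, 510, 490, 505, 500))
  es <- ExpressionSeries(m, fermDays)
  cl <- clusterTemporalPromoters(es, prod, ratioMin = 4)
  expect_identical(cl$clusters[["mirror"]], cl$clusters[[".production"]])
  expect_false(cl$clusters[["earlyPeak"]] == cl$clusters[[".production"]])
  expect_true("mirror" %in% cl$selected)
  expect_false("high" %in% cl$selected)

  constProd <- ProductionProfile(fermDays, rep(5, 6))
  expect_error(clusterTemporalPromoters(es, constProd), "zero variance")
})

test_that("promoter selection is invariant to gene input order", {
  prod <- fixtureProduction()
  sim <- simulateExpression(
    simConfig(nGenes = 120, nPlantedCorrelated = 0, nPlantedTemporal = 8,
              noiseSd = 0.1, seed = 6), prod)
  es <- sim$expression
  perm <- sample(nrow(es))
  esPerm <- ExpressionSeries(fpkm(es)[perm, ], sampleDays(es))
  a <- clusterTemporalPromoters(es, prod)
  b <- clusterTemporalPromoters(esPerm, prod)
  expect_setequal(a$selected, b$selected)
})

test_that("planted temporal promoters are recovered with high sensitivity", {
  sens <- numeric(20)
  for (s in 1:20) {
    cfg <- simConfig(nGenes = 500, nPlantedCorrelated = 0,
                     nPlantedTemporal = 10, noiseSd = 0.1, seed = s)
    prod <- simulateProductionCurve(cfg@timepoints, 2000, seed = s,
                                    noiseSd = 0)
    sim <- simulateExpression(cfg, prod)
    cl <- clusterTemporalPromoters(sim$expression, prod)
    sens[s] <- mean(sim$groundTruth$plantedTemporal %in% cl$selected)
  }
  expect_gte(mean(sens), 0.9)
})

test_that("strength gradient picks quantile-spanning promoters", {
  strengths <- stats::setNames(as.numeric(1:100), sprintf("g%03d", 1:100))
  sel <- selectStrengthGradient(strengths, 5)
  expect_identical(nrow(sel), 5L)
  expect_equal(sel$strength[1], 1)
  expect_equal(sel$strength[5], 100)
  expect_true(sel$strength[2] %in% c(25, 26))
  expect_true(sel$strength[3] %in% c(50, 51))
  expect_true(sel$strength[4] %in% c(75, 76))
  # the quantile rule with one promoter selects the median, not the max
  one <- selectStrengthGradient(strengths, 1)
  expect_true(one$strength %in% c(50, 51))
  # exactly n candidates: all returned, sorted by strength
  five <- stats::setNames(c(30, 10, 50, 20, 40), paste0("p", 1:5))
  expect_identical(selectStrengthGradient(five, 5)$strength,
                   c(10, 20, 30, 40, 50))
  expect_error(selectStrengthGradient(five, 6), "too few")
})

test_that("promoter extraction follows GFF3 coordinate conventions", {
  contig <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                  collapse = "")
  genome <- Biostrings::DNAStringSet(c(contig_1 = contig))
  ann <- GenomicRanges::GRanges(
    "contig_1",
    IRanges::IRanges(start = c(1001, 1, 100), end = c(1200, 90, 200)),
    strand = c("+", "+", "-"))
  ann$ID <- c("fwd", "atStart", "rev")

  p <- extractPromoter(genome, ann, "fwd", 500)
  expect_identical(as.character(p), substr(contig, 501, 1000))

  expect_warning(pEmpty <- extractPromoter(genome, ann, "atStart"), "empty")
  expect_identical(length(pEmpty), 0L)

  # reverse gene ending at 200 on a 400-bp contig: revcomp of 201-400
  genome400 <- Biostrings::DNAStringSet(c(contig_1 = substr(contig, 1, 400)))
  expect_warning(pRev <- extractPromoter(genome400, ann, "rev", 500),
                 "truncated to 200")
  expect_identical(
    as.character(pRev),
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(contig, 201, 400)))))

  expect_error(extractPromoter(genome, ann, "nope"), "not found")
})

test_that("cassette assembly enforces junction architecture", {
  con <- assembleTuppe(c(P1 = "ATGCATGCAT"), c(Ra = "AGGAGG"),
                       c(e1 = "ATGAAACCCTAA"))
  expect_identical(length(cassetteSeq(con)),
                   6L + 10L + 6L + 6L + 12L + 6L)
  j <- junctions(con)
  expect_identical(unname(j["EcoRI"]), 1L)
  expect_identical(unname(j["SpeI"]), 6L + 10L + 6L + 1L)
  expect_identical(unname(j["XbaI"]), 6L + 10L + 6L + 6L + 12L + 1L)
  s <- as.character(cassetteSeq(con))
  expect_identical(substr(s, j["EcoRI"], j["EcoRI"] + 5), "GAATTC")
  expect_identical(substr(s, j["SpeI"], j["SpeI"] + 5), "ACTAGT")
  expect_identical(substr(s, j["XbaI"], j["XbaI"] + 5), "TCTAGA")

  # internal site in a part: error naming part, site and offset
  expect_error(assembleTuppe(c(P1 = "ATGCAT"), c(Ra = "AGGAGG"),
                             c(bad = "ATGGAATTCTAA")),
               "exporter.*EcoRI.*offset 4")
  # site arising across a junction is also rejected
  expect_error(assembleTuppe(c(P1 = "ATGGAATT"), c(Rx = "CAAA"),
                             c(e1 = "ATGTAA")),
               "EcoRI")
})

test_that("library enumeration is the full product with reported failures", {
  proms <- stats::setNames(rep("ATGCAT", 5), paste0("P", 1:5))
  rbs <- stats::setNames(c("AGGAGG", "AGGAGA", "AGGCGG", "AGGTGG", ""),
                         c("Ra", "Rb", "Rc", "Rd", "Rn"))
  lib <- enumerateLibrary(proms, rbs, c(MiltAB2 = "ATGAAATAA"))
  expect_identical(length(lib), 25L)
  expect_identical(nrow(failures(lib)), 0L)
  ids <- vapply(constructs(lib), slot, character(1), "constructId")
  expect_identical(anyDuplicated(ids), 0L)

  lib2 <- enumerateLibrary(c(P1 = "ATGC", P2 = "GGCC"),
                           c(Ra = "AGGAGG", Rb = "AGGAGA"),
                           c(ok = "ATGTAA", bad = "ATGGAATTCTAA"))
  expect_identical(length(lib2), 4L)
  expect_identical(nrow(failures(lib2)), 4L)
  expect_true(all(failures(lib2)$exporter == "bad"))
  expect_identical(length(lib2) + nrow(failures(lib2)), 8L)

  expect_error(enumerateLibrary(character(0), rbs, c(e = "ATG")), "nonempty")
})

test_that("a written library round-trips through FASTA with its junction maps", {
  lib <- enumerateLibrary(
    c(P1 = "ATGCAT", P2 = "CCGGTT"),
    c(Ra = "AGGAGG", Rn = ""),
    c(sysA = "ATGAAACCCTAA"))
  path <- withr::local_tempfile(fileext = ".fasta")
  writeTuppeFasta(lib, path)
  back <- readTuppeFasta(path)
  expect_identical(length(back), length(lib))
  for (id in names(constructs(lib))) {
    expect_identical(junctions(constructs(back)[[id]]),
                     junctions(constructs(lib)[[id]]))
    expect_identical(as.character(cassetteSeq(constructs(back)[[id]])),
                     as.character(cassetteSeq(constructs(lib)[[id]])))
  }
})
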