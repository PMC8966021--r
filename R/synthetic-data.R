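#' @include AllClasses.R utils.R
NULL

.AA20 <- setdiff(.aaAlphabet, "X")
# Hydrophilic residues used for non-membrane segments; excludes G and K so
# a Walker A motif ([AG]x4GK[ST]) can never arise by chance, and excludes
# all strongly hydrophobic residues so no spurious transmembrane stretch
# can be detected.
.bgAlphabet <- c("D", "E", "N", "Q", "R", "S", "T", "P", "H", "Y")
# Planted transmembrane stretches: 21 residues of the hydrophobic alphabet,
# inside the detection range of a 19-residue Kyte-Doolittle window.
.tmAlphabet <- c("I", "L", "V", "F", "M", "A")
.tmStretchLen <- 21L

# ---------------------------------------------------------------------------
# Production curve
# ---------------------------------------------------------------------------

#' Simulate a logistic product-titer time course
#'
#' Generates a saturating (logistic) production curve of the kind seen in
#' fed-batch macrolide fermentations: negligible titer during logarithmic
#' growth, a steep main production stage around days 3--8, and a plateau.
#' Optional multiplicative log-normal measurement noise is applied and the
#' series is then forced monotone nondecreasing (running maximum), as titer
#' accumulates.
#'
#' @param timepoints Numeric vector of sampling days (nonempty, increasing).
#' @param plateauTiter Plateau titer in mg/l (> 0). Default 2000.
#' @param seed Integer seed; the series is deterministic for a fixed seed.
#' @param noiseSd Log-scale standard deviation of multiplicative noise.
#'   Default 0.05 (about 5% coefficient of variation). Use 0 for a noise-free
#'   curve.
#' @param midpoint,rate Logistic midpoint (day) and rate; defaults 3.5 and
#'   1.5 place >99% of the plateau at day 8.
#' @return A [ProductionProfile-class].
#' @examples
#' simulateProductionCurve(c(0.75, 2, 3, 4, 6, 8), 2000, seed = 1)
#' @export
simulateProductionCurve <- function(timepoints, plateauTiter = 2000, seed = 1,
                                    noiseSd = 0.05, midpoint = 3.5, rate = 1.5) {
  if (length(timepoints) == 0) stop("timepoints must be nonempty")
  if (plateauTiter <= 0) stop("plateauTiter must be > 0")
  tp <- as.numeric(timepoints)
  base <- plateauTiter / (1 + exp(-rate * (tp - midpoint)))
  if (noiseSd > 0) {
    set.seed(stageSeed(seed, "production"))
    base <- base * exp(stats::rnorm(length(tp), 0, noiseSd))
    base <- cummax(base)
  }
  ProductionProfile(tp, base)
}

# ---------------------------------------------------------------------------
# Expression matrix
# ---------------------------------------------------------------------------

# Build an FPKM matrix for the given gene ids. correlatedIds get profiles
# linear in the (realized) titer with positive slope; temporalIds get a
# temporal-promoter profile (low before day ~3, >= 8-fold up by day 6-8
# before noise); everything else gets a background archetype profile that is
# smooth in time and, noise-free, never reaches r^2 > 0.995 against a
# saturating titer curve. Assumes the RNG has been seeded by the caller.
.buildExpression <- function(ids, correlatedIds, temporalIds, tp, titerVec,
                             noiseSd) {
  n <- length(ids)
  nt <- length(tp)
  m <- matrix(0, nrow = n, ncol = nt, dimnames = list(ids, as.character(tp)))
  # background archetypes: stationary-phase transcriptomes are dominated by
  # growth-associated genes shutting down, with smaller induced sets
  archetypes <- c(flat = 0.30, decline = 0.30, earlyPeak = 0.15,
                  lateRise = 0.15, lateDecline = 0.10)
  for (i in seq_len(n)) {
    id <- ids[i]
    if (id %in% correlatedIds) {
      a <- stats::runif(1, 0, 5)
      finalTarget <- stats::rlnorm(1, meanlog = log(100), sdlog = 0.5)
      b <- finalTarget / max(titerVec)
      m[i, ] <- a + b * titerVec
    } else if (id %in% temporalIds) {
      b0 <- stats::runif(1, 1, 5)
      fold <- stats::runif(1, 10, 20)
      s <- 1 / (1 + exp(-2 * (tp - 4.5)))
      m[i, ] <- b0 * (1 + (fold - 1) * s)
    } else {
      lev <- stats::rlnorm(1, meanlog = log(10), sdlog = 1.5)
      arch <- sample(names(archetypes), 1, prob = archetypes)
      m[i, ] <- switch(arch,
        flat = rep(lev, nt),
        decline = lev * exp(-stats::runif(1, 0.2, 0.8) * (tp - tp[1])),
        earlyPeak = {
          peakDay <- stats::runif(1, 1.5, 3)
          lev * (0.15 + exp(-(tp - peakDay)^2 / 2))
        },
        lateRise = lev * exp(stats::runif(1, 0.2, 0.6) * (tp - tp[nt])),
        lateDecline = lev * (0.15 + exp(-(tp - tp[nt])^2 / 8)))
    }
  }
  if (noiseSd > 0)
    m <- m * exp(matrix(stats::rnorm(n * nt, 0, noiseSd), nrow = n))
  m
}

#' Simulate a time-course expression matrix with planted signal
#'
#' Emits an FPKM matrix in which a planted set of genes tracks the product
#' titer linearly (FPKM = a + b * titer, b > 0, before noise), a second
#' planted set follows a temporal-promoter pattern (low during logarithmic
#' phase, at least 8-fold up by days 6--8 before noise), and all remaining
#' genes follow smooth background temporal programs independent of the
#' titer. Multiplicative log-normal noise of log-sd `noiseSd` is applied
#' independently to every cell.
#'
#' @param config A [SimConfig-class]; `nGenes`, `timepoints`,
#'   `nPlantedCorrelated`, `nPlantedTemporal`, `noiseSd` and `seed` are used.
#' @param production A [ProductionProfile-class] sampled at
#'   `config` timepoints.
#' @return A list with elements `expression` (an [ExpressionSeries-class])
#'   and `groundTruth` (list with character vectors `plantedCorrelated` and
#'   `plantedTemporal`).
#' @examples
#' cfg <- simConfig(nGenes = 50, nPlantedCorrelated = 5, noiseSd = 0, seed = 1)
#' prod <- simulateProductionCurve(cfg@timepoints, noiseSd = 0)
#' sim <- simulateExpression(cfg, prod)
#' sim$groundTruth$plantedCorrelated
#' @export
simulateExpression <- function(config, production) {
  stopifnot(is(config, "SimConfig"), is(production, "ProductionProfile"))
  validObject(config)
  if (!isTRUE(all.equal(sampleDays(production), config@timepoints)))
    stop("production timepoints must match config timepoints")
  set.seed(stageSeed(config@seed, "expression"))
  ids <- sprintf("SBG_%05d", seq_len(config@nGenes))
  corr <- sort(sample(ids, config@nPlantedCorrelated))
  temp <- sort(sample(setdiff(ids, corr), config@nPlantedTemporal))
  m <- .buildExpression(ids, corr, temp, config@timepoints, titer(production),
                        config@noiseSd)
  list(expression = ExpressionSeries(m, config@timepoints),
       groundTruth = list(plantedCorrelated = corr, plantedTemporal = temp))
}

# ---------------------------------------------------------------------------
# Genome
# ---------------------------------------------------------------------------

.randBg <- function(n) paste(sample(.bgAlphabet, n, replace = TRUE),
                             collapse = "")
.randTm <- function() paste(sample(.tmAlphabet, .tmStretchLen, replace = TRUE),
                            collapse = "")

# protein builders; nStretch transmembrane stretches separated by >= 25
# hydrophilic residues so hydropathy runs never merge
.mkTmProtein <- function(nStretch) {
  parts <- c(.randBg(30),
             unlist(lapply(seq_len(nStretch),
                           function(i) c(.randTm(), .randBg(25)))))
  paste(parts, collapse = "")
}
.mkNbdProtein <- function() paste0(.randBg(40), "GPSGSGKST", .randBg(150))
.mkDecoyProtein <- function() .randBg(sample(180:320, 1))

.decoyProducts <- c(
  "30S ribosomal protein S4", "DNA gyrase subunit A",
  "hypothetical protein", "chaperonin GroEL",
  "elongation factor Tu", "DNA-directed RNA polymerase subunit beta",
  "citrate synthase", "hypothetical protein",
  "transcriptional regulator, TetR family", "enoyl-CoA hydratase",
  "glyceraldehyde-3-phosphate dehydrogenase", "ribosome recycling factor")

# Remove every EcoRI/SpeI/XbaI site from a DNA string by mutating the third
# base of each occurrence; iterate until clean (mutation can create a new
# site at an overlapping offset).
.scrubSites <- function(dna) {
  sites <- c("GAATTC", "ACTAGT", "TCTAGA")
  swap <- c(A = "C", C = "G", G = "T", T = "A")
  repeat {
    hit <- FALSE
    for (s in sites) {
      p <- gregexpr(s, dna, fixed = TRUE)[[1]]
      if (p[1] != -1) {
        hit <- TRUE
        for (pos in p)
          substr(dna, pos + 2, pos + 2) <- swap[[substr(dna, pos + 2, pos + 2)]]
      }
    }
    if (!hit) return(dna)
  }
}

#' Simulate a single-contig genome with planted transporter architecture
#'
#' Emits a genome (DNA), its gene annotation and the encoded proteins, with
#' planted ground truth exercising every rule of the transporter triage:
#' complete ABC exporter systems (an ABC permease with six hydrophobic
#' transmembrane stretches next to an ABC ATP-binding protein carrying a
#' Walker A motif), systems missing one domain whose partner sits within two
#' genes but carries no ABC annotation (neighbourhood-completable), systems
#' missing a domain with no recruitable neighbour (incomplete),
#' 12-transmembrane-helix MFS efflux proteins, and soluble decoys. Planted
#' membrane stretches are 21 residues of the hydrophobic alphabet
#' {I,L,V,F,M,A}; non-membrane segments use a hydrophilic alphabet that can
#' produce neither a spurious transmembrane window nor a Walker A motif.
#' Genes sit on one contig, non-overlapping, with >= 600 bp intergenic gaps
#' (the first gene starts at base 201 so 500-bp promoter extraction is
#' exercised both truncated and full). The contig is free of
#' EcoRI/SpeI/XbaI sites so extracted parts are cassette-ready.
#'
#' @param config A [SimConfig-class]; the `nAbc*`, `nMfs`, `nDecoys` and
#'   `seed` fields are used. `nDecoys` must be large enough to insulate the
#'   planted blocks (two decoys between consecutive blocks).
#' @return List with elements `annotation` (a
#'   [GenomicRanges::GRanges] with `ID` and `product` columns), `proteins`
#'   (an [Biostrings::AAStringSet] named by gene id), `genome` (a
#'   [Biostrings::DNAStringSet] with one contig) and `groundTruth` (list
#'   with `abcSystems`, a data.frame of gene id, system id, role and
#'   completeness, and `familyLabels`, a data.frame of gene id and family).
#' @examples
#' g <- simulateGenome(simConfig(nAbcComplete = 2, nAbcCompletable = 1,
#'                               nAbcIncomplete = 1, nMfs = 2, nDecoys = 20,
#'                               seed = 3))
#' g$groundTruth$abcSystems
#' @export
simulateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(stageSeed(config@seed, "genome"))

  nTmdComp <- ceiling(config@nAbcCompletable / 2)
  nNbdComp <- config@nAbcCompletable - nTmdComp
  nBlocks <- config@nAbcComplete + config@nAbcCompletable +
    config@nAbcIncomplete + config@nMfs
  needed <- if (nBlocks > 0) 2L * (nBlocks - 1L) + nTmdComp + 1L else 0L
  if (config@nDecoys < needed)
    stop("nDecoys too small: need at least ", needed,
         " to insulate the planted blocks, got ", config@nDecoys)

  # blocks of gene specs: list(product, kind); kinds drive sequence building
  blocks <- list()
  gtSys <- list()
  sysN <- 0L
  addSys <- function(genes, roles, completeness) {
    sysN <<- sysN + 1L
    data.frame(system_id = sprintf("SYS_%03d", sysN), gene = genes,
               role = roles, completeness = completeness,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(config@nAbcComplete))
    blocks[[length(blocks) + 1L]] <- list(
      kind = "complete",
      genes = list(
        list(product = "ABC transporter multidrug efflux permease",
             type = "tmd"),
        list(product = "multidrug ABC transporter ATP-binding protein",
             type = "nbd")))
  for (i in seq_len(nTmdComp))
    blocks[[length(blocks) + 1L]] <- list(
      kind = "tmd_completable",
      genes = list(
        list(product = "ABC transporter ATP-binding protein", type = "nbd"),
        list(product = .decoyProducts[1 + i %% length(.decoyProducts)],
             type = "decoy"),
        list(product = "putative membrane protein", type = "tmd")))
  for (i in seq_len(nNbdComp))
    blocks[[length(blocks) + 1L]] <- list(
      kind = "nbd_completable",
      genes = list(
        list(product = "ABC transporter permease", type = "tmd"),
        list(product = "putative P-loop nucleotide-binding protein",
             type = "nbd")))
  for (i in seq_len(config@nAbcIncomplete))
    blocks[[length(blocks) + 1L]] <- list(
      kind = "incomplete",
      genes = list(
        list(product = "ABC transporter ATP-binding protein", type = "nbd")))
  for (i in seq_len(config@nMfs))
    blocks[[length(blocks) + 1L]] <- list(
      kind = "mfs",
      genes = list(
        list(product = "MFS multidrug efflux transporter", type = "mfs")))
  if (length(blocks) > 1) blocks <- blocks[sample(length(blocks))]

  # lay out: leading decoy, two decoys between blocks, leftovers at the end
  decoyPool <- config@nDecoys
  specs <- list()
  pushDecoy <- function(k) {
    for (j in seq_len(k)) {
      if (decoyPool <= 0L) return(invisible(NULL))
      decoyPool <<- decoyPool - 1L
      specs[[length(specs) + 1L]] <<- list(
        product = .decoyProducts[1 + length(specs) %% length(.decoyProducts)],
        type = "decoy", kind = "decoy")
    }
  }
  pushDecoy(1L)
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    for (g in b$genes)
      specs[[length(specs) + 1L]] <- c(g, list(kind = b$kind))
    if (bi < length(blocks)) pushDecoy(2L)
  }
  if (decoyPool > 0L) { pushDecoy(decoyPool) }

  nGenes <- length(specs)
  ids <- sprintf("SBG_%05d", seq_len(nGenes) * 5L)

  # proteins + ground truth bookkeeping
  proteins <- character(nGenes)
  family <- character(nGenes)
  for (i in seq_len(nGenes)) {
    sp <- specs[[i]]
    proteins[i] <- switch(sp$type,
      tmd = .mkTmProtein(6L),
      nbd = .mkNbdProtein(),
      mfs = .mkTmProtein(12L),
      decoy = .mkDecoyProtein())
    family[i] <- switch(sp$kind,
      complete = "ABC", tmd_completable = if (sp$type == "nbd") "ABC" else "none",
      nbd_completable = if (grepl("^ABC", sp$product)) "ABC" else "none",
      incomplete = "ABC", mfs = "MFS", decoy = "none")
  }

  # ABC system ground truth, walking the laid-out specs
  gt <- list()
  i <- 1L
  while (i <= nGenes) {
    k <- specs[[i]]$kind
    if (k == "complete") {
      gt[[length(gt) + 1L]] <- addSys(ids[c(i, i + 1L)],
        c("TMD-bearing", "NBD-bearing"), "complete")
      i <- i + 2L
    } else if (k == "tmd_completable") {
      gt[[length(gt) + 1L]] <- addSys(ids[c(i, i + 2L)],
        c("NBD-bearing", "TMD-bearing"), "tmd_completed_from_neighborhood")
      i <- i + 3L
    } else if (k == "nbd_completable") {
      gt[[length(gt) + 1L]] <- addSys(ids[c(i, i + 1L)],
        c("TMD-bearing", "NBD-bearing"), "nbd_completed_from_neighborhood")
      i <- i + 2L
    } else if (k == "incomplete") {
      gt[[length(gt) + 1L]] <- addSys(ids[i], "NBD-bearing", "incomplete")
      i <- i + 1L
    } else i <- i + 1L
  }
  abcSystems <- if (length(gt)) do.call(rbind, gt) else
    data.frame(system_id = character(), gene = character(),
               role = character(), completeness = character())

  # coordinates: first gene at 201 (truncated promoter), gaps >= 600 bp
  protLen <- nchar(proteins)
  geneLen <- 3L * protLen + 3L
  starts <- integer(nGenes)
  pos <- 201L
  for (i in seq_len(nGenes)) {
    starts[i] <- pos
    gap <- 600L + as.integer(floor(stats::runif(1) * 300))
    pos <- pos + geneLen[i] + gap
  }
  ends <- starts + geneLen - 1L
  planted <- vapply(specs, function(s) s$kind != "decoy", logical(1))
  strands <- ifelse(planted, "+", sample(c("+", "-"), nGenes, replace = TRUE))

  contigLen <- ends[nGenes] + 600L
  dna <- paste(sample(c("A", "C", "G", "T"), contigLen, replace = TRUE),
               collapse = "")
  dna <- .scrubSites(dna)

  products <- vapply(specs, function(s) s$product, character(1))
  gr <- GenomicRanges::GRanges(
    seqnames = "contig_1",
    ranges = IRanges::IRanges(start = starts, end = ends),
    strand = strands)
  gr$type <- "gene"
  gr$ID <- ids
  gr$product <- products

  aa <- Biostrings::AAStringSet(stats::setNames(proteins, ids))
  genome <- Biostrings::DNAStringSet(c(contig_1 = dna))

  list(annotation = gr, proteins = aa, genome = genome,
       groundTruth = list(
         abcSystems = abcSystems,
         familyLabels = data.frame(gene = ids, family = family,
                                   stringsAsFactors = FALSE)))
}

# ---------------------------------------------------------------------------
# Alignment evolution
# ---------------------------------------------------------------------------

#' Evolve an alignment along a tree under the Poisson model
#'
#' Each site evolves independently: along a branch of length b, the number
#' of substitution events is Poisson with mean `substRate * b`, and each
#' event replaces the residue with one of the 19 other amino acids, chosen
#' uniformly. The root sequence is uniform over the 20 amino acids. No
#' indels are produced, so the alignment length equals `nSites`.
#'
#' @param tree An [ape::phylo] tree with strictly positive branch lengths.
#' @param nSites Alignment length (>= 1).
#' @param substRate Expected substitutions per site per unit branch length.
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @return An [Biostrings::AAStringSet] of the tip sequences, named by tip
#'   label.
#' @examples
#' tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
#' simulateAlignment(tr, nSites = 50, substRate = 1, seed = 1)
#' @export
simulateAlignment <- function(tree, nSites, substRate = 1, seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length <= 0)) stop("non-positive branch length")
  if (nSites < 1) stop("nSites must be >= 1")
  set.seed(stageSeed(seed, "alignment"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  tr <- ape::reorder.phylo(tree, "cladewise")
  seqs <- vector("list", ntip + tr$Nnode)
  seqs[[root]] <- sample(.AA20, nSites, replace = TRUE)
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    s <- seqs[[parent]]
    if (substRate > 0) {
      nev <- stats::rpois(nSites, substRate * tr$edge.length[e])
      for (i in which(nev > 0))
        for (k in seq_len(nev[i]))
          s[i] <- sample(setdiff(.AA20, s[i]), 1)
    }
    seqs[[child]] <- s
  }
  tips <- vapply(seqs[seq_len(ntip)], paste, character(1), collapse = "")
  Biostrings::AAStringSet(stats::setNames(tips, tree$tip.label))
}

# ---------------------------------------------------------------------------
# Bundle
# ---------------------------------------------------------------------------

#' Simulate a coherent genome + expression + production bundle
#'
#' Generates a genome with [simulateGenome()], a production curve on the
#' configured timepoints, and an expression matrix over exactly the genome's
#' genes, so that cross-references validate: the titer-correlated planted
#' set is the member genes of the planted *complete* ABC exporter systems
#' (the exporters whose transcription tracks production), and the planted
#' temporal-promoter profiles are assigned to `nPlantedTemporal` decoy
#' genes.
#'
#' @param config A [SimConfig-class].
#' @param plateauTiter Plateau titer passed to [simulateProductionCurve()].
#' @param productionNoiseSd Measurement noise of the titer curve.
#' @return List with `genome` (the [simulateGenome()] result), `production`,
#'   `expression` and `groundTruth` (planted sets plus the genome ground
#'   truth).
#' @examples
#' b <- simulateBundle(simConfig(nAbcComplete = 2, nAbcCompletable = 1,
#'                               nAbcIncomplete = 1, nMfs = 2, nDecoys = 20,
#'                               nPlantedTemporal = 3, seed = 7))
#' names(b)
#' @export
simulateBundle <- function(config, plateauTiter = 2000,
                           productionNoiseSd = 0.02) {
  g <- simulateGenome(config)
  production <- simulateProductionCurve(config@timepoints, plateauTiter,
                                        seed = config@seed,
                                        noiseSd = productionNoiseSd)
  set.seed(stageSeed(config@seed, "bundle-expression"))
  ids <- g$annotation$ID
  sys <- g$groundTruth$abcSystems
  corr <- sort(unique(sys$gene[sys$completeness == "complete"]))
  decoys <- g$groundTruth$familyLabels$gene[
    g$groundTruth$familyLabels$family == "none"]
  decoys <- setdiff(decoys, sys$gene)
  nTemp <- min(config@nPlantedTemporal, length(decoys))
  temp <- sort(sample(decoys, nTemp))
  m <- .buildExpression(ids, corr, temp, config@timepoints,
                        titer(production), config@noiseSd)
  list(genome = g, production = production,
       expression = ExpressionSeries(m, config@timepoints),
       groundTruth = c(g$groundTruth,
                       list(plantedCorrelated = corr, plantedTemporal = temp)))
}
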