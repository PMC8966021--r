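#' @include AllGenerics.R
#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom Biostrings DNAString
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
NULL

# ---------------------------------------------------------------------------
# ExpressionSeries
# ---------------------------------------------------------------------------

#' Time-course expression matrix
#'
#' An `ExpressionSeries` is a [SummarizedExperiment::SummarizedExperiment]
#' with a single assay `"fpkm"` (genes in rows, timepoints in columns) and a
#' numeric `day` column in `colData`. Days must be strictly increasing,
#' FPKM values nonnegative with no missing cells.
#'
#' @slot .Data inherited from SummarizedExperiment.
#' @seealso [ExpressionSeries()], [fpkm()], [sampleDays()]
#' @export
setClass("ExpressionSeries", contains = "SummarizedExperiment")

setValidity("ExpressionSeries", function(object) {
  msg <- character()
  if (!"fpkm" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'fpkm' is required")
  else {
    m <- SummarizedExperiment::assay(object, "fpkm")
    if (anyNA(m)) msg <- c(msg, "FPKM matrix contains missing cells")
    else if (any(m < 0)) msg <- c(msg, "FPKM values must be nonnegative")
    if (is.null(rownames(m))) msg <- c(msg, "gene ids (rownames) are required")
  }
  if (!"day" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a numeric 'day' column")
  else {
    d <- SummarizedExperiment::colData(object)$day
    if (anyNA(d) || !is.numeric(d)) msg <- c(msg, "'day' must be numeric without NA")
    else if (any(diff(d) <= 0)) msg <- c(msg, "timepoints (days) must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionSeries
#'
#' @param fpkm Numeric matrix of FPKM values, genes in rows (rownames are
#'   gene ids), one column per timepoint.
#' @param days Numeric vector of sampling days, strictly increasing, one per
#'   column of `fpkm`.
#' @return An [ExpressionSeries-class] object.
#' @examples
#' es <- ExpressionSeries(
#'   matrix(1:12, nrow = 2, dimnames = list(c("g1", "g2"), NULL)),
#'   days = c(0.75, 2, 3, 4, 6, 8))
#' fpkm(es)
#' sampleDays(es)
#' @export
ExpressionSeries <- function(fpkm, days) {
  fpkm <- as.matrix(fpkm)
  storage.mode(fpkm) <- "double"
  if (length(days) != ncol(fpkm))
    stop("length(days) must equal ncol(fpkm)")
  colnames(fpkm) <- as.character(days)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = fpkm),
    colData = S4Vectors::DataFrame(day = as.numeric(days)))
  new("ExpressionSeries", se)
}

#' @rdname fpkm
#' @export
setMethod("fpkm", "ExpressionSeries", function(x)
  SummarizedExperiment::assay(x, "fpkm"))

#' @rdname sampleDays
#' @export
setMethod("sampleDays", "ExpressionSeries", function(x)
  SummarizedExperiment::colData(x)$day)

#' @rdname geneIds
#' @export
setMethod("geneIds", "ExpressionSeries", function(x) rownames(x))

# ---------------------------------------------------------------------------
# ProductionProfile
# ---------------------------------------------------------------------------

#' Product-titer time course
#'
#' Titer of the fermentation product (mg/l) over an ordered series of
#' sampling days.
#'
#' @slot day Numeric vector of days, strictly increasing.
#' @slot titer Numeric vector of titers (mg/l), nonnegative.
#' @seealso [ProductionProfile()], [simulateProductionCurve()]
#' @export
setClass("ProductionProfile",
  representation(day = "numeric", titer = "numeric"))

setValidity("ProductionProfile", function(object) {
  msg <- character()
  if (length(object@day) != length(object@titer))
    msg <- c(msg, "day and titer must have equal length")
  if (length(object@day) == 0) msg <- c(msg, "at least one timepoint required")
  if (length(object@day) > 1 && any(diff(object@day) <= 0))
    msg <- c(msg, "days must be strictly increasing")
  if (anyNA(object@titer) || any(object@titer < 0))
    msg <- c(msg, "titer must be nonnegative without NA")
  if (length(msg)) msg else TRUE
})

#' Construct a ProductionProfile
#'
#' @param day Numeric vector of sampling days, strictly increasing.
#' @param titer Numeric vector of product titers (mg/l), same length.
#' @return A [ProductionProfile-class] object.
#' @examples
#' ProductionProfile(c(3, 4, 6, 8), c(200, 800, 1800, 2000))
#' @export
ProductionProfile <- function(day, titer)
  new("ProductionProfile", day = as.numeric(day), titer = as.numeric(titer))

#' @rdname sampleDays
#' @export
setMethod("sampleDays", "ProductionProfile", function(x) x@day)

#' @rdname titer
#' @export
setMethod("titer", "ProductionProfile", function(x) x@titer)

setMethod("show", "ProductionProfile", function(object) {
  cat("ProductionProfile with", length(object@day), "timepoints\n")
  cat("  days : ", paste(object@day, collapse = ", "), "\n", sep = "")
  cat("  titer: ", paste(signif(object@titer, 4), collapse = ", "),
      " (mg/l)\n", sep = "")
})

# ---------------------------------------------------------------------------
# ScreenThresholds
# ---------------------------------------------------------------------------

#' Thresholds for the expression--titer correlation screen
#'
#' The three filters of the screen: squared Pearson correlation with the
#' production curve, regression slope on min-max-scaled axes, and final-day
#' expression level. All comparisons are strict (`>`).
#'
#' @slot r2Min Minimum squared Pearson correlation, in (0, 1]. Default 0.995.
#' @slot slopeMin Minimum regression slope on min-max-scaled axes. Default 0.05.
#' @slot log10FpkmMin Minimum log10 FPKM at the last timepoint. Default 1.
#' @slot window Length-2 numeric, inclusive day range used for the
#'   correlation (the production stage). Default `c(3, 8)`.
#' @seealso [screenThresholds()], [filterCandidates()]
#' @export
setClass("ScreenThresholds",
  representation(r2Min = "numeric", slopeMin = "numeric",
                 log10FpkmMin = "numeric", window = "numeric"))

setValidity("ScreenThresholds", function(object) {
  msg <- character()
  if (length(object@r2Min) != 1 || object@r2Min <= 0 || object@r2Min > 1)
    msg <- c(msg, "r2Min must be a single value in (0, 1]")
  if (length(object@window) != 2 || diff(object@window) <= 0)
    msg <- c(msg, "window must be c(first_day, last_day) with first < last")
  if (length(msg)) msg else TRUE
})

#' Construct screen thresholds
#'
#' @param r2Min,slopeMin,log10FpkmMin,window See [ScreenThresholds-class].
#' @return A [ScreenThresholds-class] object.
#' @examples
#' screenThresholds()
#' @export
screenThresholds <- function(r2Min = 0.995, slopeMin = 0.05,
                             log10FpkmMin = 1, window = c(3, 8))
  new("ScreenThresholds", r2Min = r2Min, slopeMin = slopeMin,
      log10FpkmMin = log10FpkmMin, window = as.numeric(window))

setMethod("show", "ScreenThresholds", function(object) {
  cat("ScreenThresholds: r2 >", object@r2Min, "| slope >", object@slopeMin,
      "| log10 final FPKM >", object@log10FpkmMin,
      "| window", object@window[1], "-", object@window[2], "d\n")
})

# ---------------------------------------------------------------------------
# PoissonDistances
# ---------------------------------------------------------------------------

#' Poisson-corrected pairwise protein distances
#'
#' Symmetric matrix of distances d = -ln(1 - p), where p is the proportion
#' of differing sites after complete deletion of alignment columns
#' containing gaps or missing data, plus the number of surviving columns.
#'
#' @slot distances Symmetric numeric matrix with zero diagonal, labelled by
#'   taxon.
#' @slot usedSites Integer, number of alignment columns surviving complete
#'   deletion.
#' @seealso [poissonDistance()], [njTree()]
#' @export
setClass("PoissonDistances",
  representation(distances = "matrix", usedSites = "integer"))

setValidity("PoissonDistances", function(object) {
  msg <- character()
  m <- object@distances
  if (nrow(m) != ncol(m)) msg <- c(msg, "distance matrix must be square")
  else {
    if (any(abs(m - t(m)) > 1e-12)) msg <- c(msg, "distance matrix must be symmetric")
    if (any(diag(m) != 0)) msg <- c(msg, "diagonal must be zero")
    if (any(m < 0)) msg <- c(msg, "distances must be nonnegative")
    if (is.null(rownames(m))) msg <- c(msg, "taxon labels required")
  }
  if (object@usedSites < 1L) msg <- c(msg, "usedSites must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname usedSites
#' @export
setMethod("usedSites", "PoissonDistances", function(x) x@usedSites)

#' @describeIn PoissonDistances-class coerce to a plain matrix.
#' @param x,... passed on.
#' @export
setMethod("as.matrix", "PoissonDistances", function(x, ...) x@distances)

setMethod("show", "PoissonDistances", function(object) {
  cat("PoissonDistances over", nrow(object@distances), "taxa,",
      object@usedSites, "sites after complete deletion\n")
  print(round(object@distances, 4))
})

# ---------------------------------------------------------------------------
# SimConfig
# ---------------------------------------------------------------------------

#' Configuration of the synthetic-data generator
#'
#' Study conditions for the simulated time-course transcriptome and genome:
#' number of genes, sampling days, planted signal sizes, noise level and
#' planted transporter architecture. One master `seed` drives all stages;
#' per-stage streams are derived deterministically so stages can be
#' regenerated independently.
#'
#' @slot nGenes Number of genes in the expression matrix.
#' @slot timepoints Sampling days, strictly increasing
#'   (default 0.75, 2, 3, 4, 6, 8).
#' @slot nPlantedCorrelated Genes whose profile is linear in the titer.
#' @slot nPlantedTemporal Genes with a temporal-promoter profile (low in
#'   logarithmic phase, >= 8-fold up by day 6-8 before noise).
#' @slot noiseSd Standard deviation (log scale) of the multiplicative
#'   log-normal noise applied per FPKM cell.
#' @slot nAbcComplete Planted complete ABC exporter systems (TMD gene +
#'   NBD gene, adjacent).
#' @slot nAbcCompletable Planted ABC systems missing one domain that can be
#'   recruited from a neighbouring (within 2 genes) non-ABC protein.
#' @slot nAbcIncomplete Planted ABC systems missing a domain with no
#'   recruitable neighbour.
#' @slot nMfs Planted 12-transmembrane-helix MFS efflux proteins.
#' @slot nDecoys Soluble non-transporter decoy proteins.
#' @slot seed Master random seed (integer).
#' @seealso [simConfig()], [simulateExpression()], [simulateGenome()]
#' @export
setClass("SimConfig",
  representation(nGenes = "integer", timepoints = "numeric",
                 nPlantedCorrelated = "integer", nPlantedTemporal = "integer",
                 noiseSd = "numeric",
                 nAbcComplete = "integer", nAbcCompletable = "integer",
                 nAbcIncomplete = "integer", nMfs = "integer",
                 nDecoys = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  counts <- c(object@nGenes, object@nPlantedCorrelated, object@nPlantedTemporal,
              object@nAbcComplete, object@nAbcCompletable, object@nAbcIncomplete,
              object@nMfs, object@nDecoys)
  if (any(counts < 0L)) msg <- c(msg, "all counts must be >= 0")
  if (length(object@timepoints) < 2 || any(diff(object@timepoints) <= 0))
    msg <- c(msg, "timepoints must be strictly increasing (length >= 2)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (object@nPlantedCorrelated + object@nPlantedTemporal > object@nGenes)
    msg <- c(msg, "planted genes cannot exceed nGenes")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param nGenes,timepoints,nPlantedCorrelated,nPlantedTemporal,noiseSd
#'   Expression-matrix conditions; see [SimConfig-class].
#' @param nAbcComplete,nAbcCompletable,nAbcIncomplete,nMfs,nDecoys
#'   Genome architecture conditions; see [SimConfig-class].
#' @param seed Master seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' simConfig(nGenes = 100, nPlantedCorrelated = 5, seed = 1)
#' @export
simConfig <- function(nGenes = 1000, timepoints = c(0.75, 2, 3, 4, 6, 8),
                      nPlantedCorrelated = 10, nPlantedTemporal = 0,
                      noiseSd = 0.1, nAbcComplete = 5, nAbcCompletable = 3,
                      nAbcIncomplete = 3, nMfs = 10, nDecoys = 50, seed = 1)
  new("SimConfig", nGenes = as.integer(nGenes),
      timepoints = as.numeric(timepoints),
      nPlantedCorrelated = as.integer(nPlantedCorrelated),
      nPlantedTemporal = as.integer(nPlantedTemporal),
      noiseSd = as.numeric(noiseSd),
      nAbcComplete = as.integer(nAbcComplete),
      nAbcCompletable = as.integer(nAbcCompletable),
      nAbcIncomplete = as.integer(nAbcIncomplete),
      nMfs = as.integer(nMfs), nDecoys = as.integer(nDecoys),
      seed = as.integer(seed))

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes over days",
      paste(object@timepoints, collapse = ","), "\n")
  cat("  planted: ", object@nPlantedCorrelated, " titer-correlated, ",
      object@nPlantedTemporal, " temporal promoters; noiseSd ",
      object@noiseSd, "\n", sep = "")
  cat("  genome: ", object@nAbcComplete, " complete / ",
      object@nAbcCompletable, " completable / ", object@nAbcIncomplete,
      " incomplete ABC, ", object@nMfs, " MFS, ", object@nDecoys,
      " decoys; seed ", object@seed, "\n", sep = "")
})

# ---------------------------------------------------------------------------
# TuppeConstruct / TuppeLibrary
# ---------------------------------------------------------------------------

#' One assembled TuPPE cassette
#'
#' A promoter--RBS--exporter expression cassette with fixed restriction-site
#' junctions: `GAATTC` (EcoRI) + promoter + RBS + `ACTAGT` (SpeI) +
#' exporter CDS + `TCTAGA` (XbaI). The junction map records the 1-based
#' start position of each site; a valid cassette contains each site exactly
#' once, at its designed junction.
#'
#' @slot constructId Character id, `TuPPE_<promoter>_<rbs>_<exporter>`.
#' @slot promoterId,rbsId,exporterId Part identifiers.
#' @slot sequence The assembled [Biostrings::DNAString].
#' @slot junctionMap Named integer vector (`EcoRI`, `SpeI`, `XbaI`).
#' @seealso [assembleTuppe()], [enumerateLibrary()]
#' @export
setClass("TuppeConstruct",
  representation(constructId = "character", promoterId = "character",
                 rbsId = "character", exporterId = "character",
                 sequence = "DNAString", junctionMap = "integer"))

setValidity("TuppeConstruct", function(object) {
  msg <- character()
  if (!identical(sort(names(object@junctionMap)), c("EcoRI", "SpeI", "XbaI")))
    msg <- c(msg, "junctionMap must name EcoRI, SpeI and XbaI")
  if (length(msg)) msg else TRUE
})

#' @rdname cassetteSeq
#' @export
setMethod("cassetteSeq", "TuppeConstruct", function(x) x@sequence)

#' @rdname junctions
#' @export
setMethod("junctions", "TuppeConstruct", function(x) x@junctionMap)

setMethod("show", "TuppeConstruct", function(object) {
  cat("TuppeConstruct", object@constructId, "(",
      length(object@sequence), "bp )\n")
  cat("  parts    : P=", object@promoterId, " R=", object@rbsId,
      " exporter=", object@exporterId, "\n", sep = "")
  j <- object@junctionMap
  cat("  junctions: EcoRI@", j["EcoRI"], " SpeI@", j["SpeI"],
      " XbaI@", j["XbaI"], "\n", sep = "")
})

#' A combinatorial TuPPE cassette library
#'
#' The result of enumerating promoter x RBS x exporter combinations:
#' successfully assembled constructs plus a report of combinations whose
#' parts failed validation (never silently dropped).
#'
#' @slot constructs List of [TuppeConstruct-class] objects.
#' @slot failures data.frame with columns `promoter`, `rbs`, `exporter`,
#'   `message`, one row per failed combination.
#' @seealso [enumerateLibrary()]
#' @export
setClass("TuppeLibrary",
  representation(constructs = "list", failures = "data.frame"))

#' @rdname constructs
#' @export
setMethod("constructs", "TuppeLibrary", function(x) x@constructs)

#' @rdname failures
#' @export
setMethod("failures", "TuppeLibrary", function(x) x@failures)

#' @describeIn TuppeLibrary-class number of assembled constructs.
#' @param x a TuppeLibrary.
#' @export
setMethod("length", "TuppeLibrary", function(x) length(x@constructs))

setMethod("show", "TuppeLibrary", function(object) {
  cat("TuppeLibrary:", length(object@constructs), "constructs,",
      nrow(object@failures), "failed combinations\n")
})
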