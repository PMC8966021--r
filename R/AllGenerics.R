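NULL

#' Extract the FPKM matrix
#'
#' @param x An [ExpressionSeries-class] object.
#' @return A numeric matrix, genes in rows, timepoints in columns.
#' @export
setGeneric("fpkm", function(x) standardGeneric("fpkm"))

#' Sampling days of a time-course object
#'
#' @param x An [ExpressionSeries-class] or [ProductionProfile-class] object.
#' @return Numeric vector of days, strictly increasing.
#' @export
setGeneric("sampleDays", function(x) standardGeneric("sampleDays"))

#' Product titer series
#'
#' @param x A [ProductionProfile-class] object.
#' @return Numeric vector of titers (mg/l), one per sampling day.
#' @export
setGeneric("titer", function(x) standardGeneric("titer"))

#' Gene identifiers
#'
#' @param x An [ExpressionSeries-class] object.
#' @return Character vector of gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Alignment columns surviving complete deletion
#'
#' @param x A [PoissonDistances-class] object.
#' @return Integer count of alignment columns used for the distances.
#' @export
setGeneric("usedSites", function(x) standardGeneric("usedSites"))

#' Assembled cassette sequence
#'
#' @param x A [TuppeConstruct-class] object.
#' @return A [Biostrings::DNAString] with the full cassette sequence.
#' @export
setGeneric("cassetteSeq", function(x) standardGeneric("cassetteSeq"))

#' Restriction-site junction map of a cassette
#'
#' @param x A [TuppeConstruct-class] object.
#' @return Named integer vector with the 1-based start positions of the
#'   EcoRI, SpeI and XbaI sites.
#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))

#' Successfully assembled constructs of a library
#'
#' @param x A [TuppeLibrary-class] object.
#' @return List of [TuppeConstruct-class] objects.
#' @export
setGeneric("constructs", function(x) standardGeneric("constructs"))

#' Assembly failures of a library
#'
#' @param x A [TuppeLibrary-class] object.
#' @return A data.frame with one row per part combination that failed
#'   validation, including the error message.
#' @export
setGeneric("failures", function(x) standardGeneric("failures"))
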