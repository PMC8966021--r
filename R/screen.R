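#' @include AllClasses.R utils.R
NULL

# Default lexicon marking product strings that do NOT count as a defined
# annotation. Editable via the `undefinedLexicon` argument of
# filterCandidates().
.undefinedLexicon <- c("hypothetical protein", "unknown function",
                       "uncharacteri[sz]ed", "DUF[0-9]+",
                       "conserved protein of unknown")

#' Correlate time-course expression with product titer
#'
#' For every gene, computes the squared Pearson correlation between its
#' FPKM series and the titer series over the production-stage window, the
#' least-squares regression slope, the FPKM at the last timepoint and its
#' log10. By default the slope is computed after min-max scaling both
#' series to \[0, 1\], making the conventional 0.05 threshold scale-free
#' across expression magnitudes; `slopeMode = "raw"` gives the slope in
#' FPKM per (mg/l) instead. Genes with zero variance over the window get
#' `r_squared = 0` and `slope = 0` rather than NaN, so downstream filters
#' behave deterministically.
#'
#' @param x An [ExpressionSeries-class].
#' @param production A [ProductionProfile-class]. Its timepoints must cover
#'   the same days as `x` within the window; a mismatch is an error naming
#'   the missing days.
#' @param window Inclusive day range used for the correlation; default
#'   `c(3, 8)`, the main production stage. At least 3 shared timepoints are
#'   required.
#' @param slopeMode `"scaled"` (default) or `"raw"`, see above.
#' @return A [S4Vectors::DataFrame] with one row per gene (rownames are
#'   gene ids) and columns `r_squared`, `slope`, `final_fpkm`,
#'   `log10_final_fpkm` (NA where `final_fpkm` is 0).
#' @examples
#' prod <- ProductionProfile(c(3, 4, 6, 8), c(200, 800, 1800, 2000))
#' es <- ExpressionSeries(
#'   matrix(2 * c(200, 800, 1800, 2000) + 5, nrow = 1,
#'          dimnames = list("g1", NULL)),
#'   days = c(3, 4, 6, 8))
#' correlateExpression(es, prod)
#' @export
correlateExpression <- function(x, production, window = c(3, 8),
                                slopeMode = c("scaled", "raw")) {
  stopifnot(is(x, "ExpressionSeries"), is(production, "ProductionProfile"))
  slopeMode <- match.arg(slopeMode)
  dx <- sampleDays(x)
  dp <- sampleDays(production)
  wx <- dx[dx >= window[1] & dx <= window[2]]
  wp <- dp[dp >= window[1] & dp <= window[2]]
  missing <- c(setdiff(wx, wp), setdiff(wp, wx))
  if (length(missing))
    stop("timepoint mismatch within window; days missing from one input: ",
         paste(sort(unique(missing)), collapse = ", "))
  shared <- wx
  if (length(shared) < 3)
    stop("need at least 3 shared timepoints within the window, got ",
         length(shared))
  m <- fpkm(x)[, dx %in% shared, drop = FALSE]
  y <- titer(production)[dp %in% shared]

  yc <- y - mean(y)
  sy2 <- sum(yc^2)
  mc <- m - rowMeans(m)
  sx2 <- rowSums(mc^2)
  cross <- as.numeric(mc %*% yc)
  r2 <- numeric(nrow(m))
  ok <- sx2 > 0 & sy2 > 0
  r2[ok] <- (cross[ok]^2) / (sx2[ok] * sy2)

  slope <- numeric(nrow(m))
  if (slopeMode == "scaled") {
    ys <- .minMax(y)
    ysc <- ys - mean(ys)
    sys2 <- sum(ysc^2)
    if (sys2 > 0) {
      rng <- apply(m, 1, function(v) diff(range(v)))
      msc <- (m - apply(m, 1, min)) / ifelse(rng == 0, 1, rng)
      msc <- msc - rowMeans(msc)
      slope <- as.numeric(msc %*% ysc) / sys2
      slope[!ok] <- 0
    }
  } else {
    if (sy2 > 0) slope[ok] <- cross[ok] / sy2
  }

  finalFpkm <- fpkm(x)[, ncol(fpkm(x))]
  out <- S4Vectors::DataFrame(
    r_squared = r2, slope = slope, final_fpkm = finalFpkm,
    log10_final_fpkm = ifelse(finalFpkm > 0, log10(finalFpkm), NA_real_),
    row.names = rownames(m))
  out
}

#' Filter and rank screen candidates
#'
#' Applies the three screen filters with strict inequalities -- squared
#' correlation, slope and final-day expression level -- plus, when an
#' annotation is supplied, a defined-annotation filter that drops genes
#' whose product string matches the hypothetical-protein lexicon.
#' Survivors are ranked by `r_squared` (descending), ties by `slope`
#' (descending), then gene id.
#'
#' @param stats The [S4Vectors::DataFrame] returned by
#'   [correlateExpression()].
#' @param thresholds A [ScreenThresholds-class]; default [screenThresholds()]
#'   (r2 > 0.995, slope > 0.05, log10 final FPKM > 1).
#' @param annotation Optional named character vector (or a
#'   [GenomicRanges::GRanges] with `ID` and `product` columns) mapping gene
#'   id to product string. When `NULL` the defined-annotation filter is
#'   skipped with a warning.
#' @param undefinedLexicon Regular expressions identifying undefined
#'   annotations.
#' @return The subset of `stats` rows passing all filters, ranked; rownames
#'   are the candidate gene ids.
#' @seealso [correlateExpression()], [screenThresholds()]
#' @export
filterCandidates <- function(stats, thresholds = screenThresholds(),
                             annotation = NULL,
                             undefinedLexicon = .undefinedLexicon) {
  stopifnot(is(thresholds, "ScreenThresholds"))
  pass <- stats$r_squared > thresholds@r2Min &
    stats$slope > thresholds@slopeMin &
    !is.na(stats$log10_final_fpkm) &
    stats$log10_final_fpkm > thresholds@log10FpkmMin
  if (is.null(annotation)) {
    warning("no annotation supplied; defined-annotation filter skipped")
  } else {
    if (methods::is(annotation, "GRanges"))
      annotation <- stats::setNames(annotation$product, annotation$ID)
    prod <- annotation[rownames(stats)]
    rx <- paste(undefinedLexicon, collapse = "|")
    defined <- !is.na(prod) & nzchar(prod) &
      !grepl(rx, prod, ignore.case = TRUE)
    pass <- pass & defined
  }
  out <- stats[which(pass), , drop = FALSE]
  ord <- order(-out$r_squared, -out$slope, rownames(out))
  out[ord, , drop = FALSE]
}

#' Late-stage upregulation of a mutant relative to its parent
#'
#' Compares per-gene expression of a high-producer mutant against its
#' parent over the late production stage, reporting
#' `log2((mutant FPKM + 1) / (parent FPKM + 1))` for every late-window day
#' (pseudocount 1 guards FPKM of 0). A gene is flagged when its *minimum*
#' late-window log2 fold change is at least `log2(foldMin)`, i.e. it is
#' consistently upregulated across the whole late stage.
#'
#' @param mutant,parent [ExpressionSeries-class] objects sharing gene ids
#'   and the late-window timepoints. Genes present in only one matrix are
#'   ignored; fully disjoint gene sets are an error.
#' @param lateWindow Inclusive day range of the late production stage;
#'   default `c(6, 8)`.
#' @param foldMin Fold-change threshold; default 4. `foldMin = 1` flags
#'   every gene with mutant >= parent on all late days.
#' @param pseudocount Added to both FPKM values before the ratio; default 1.
#' @return A [S4Vectors::DataFrame] with one `lfc_day_*` column per late
#'   day, `min_lfc`, and logical `flagged`; rownames are the shared gene
#'   ids.
#' @export
lateStageUpregulation <- function(mutant, parent, lateWindow = c(6, 8),
                                  foldMin = 4, pseudocount = 1) {
  stopifnot(is(mutant, "ExpressionSeries"), is(parent, "ExpressionSeries"))
  shared <- intersect(geneIds(mutant), geneIds(parent))
  if (length(shared) == 0) stop("mutant and parent share no gene ids")
  dm <- sampleDays(mutant)
  dp <- sampleDays(parent)
  days <- intersect(dm[dm >= lateWindow[1] & dm <= lateWindow[2]],
                    dp[dp >= lateWindow[1] & dp <= lateWindow[2]])
  if (length(days) == 0) stop("no shared timepoints in the late window")
  mm <- fpkm(mutant)[shared, dm %in% days, drop = FALSE]
  pm <- fpkm(parent)[shared, dp %in% days, drop = FALSE]
  lfc <- log2((mm + pseudocount) / (pm + pseudocount))
  colnames(lfc) <- paste0("lfc_day_", days)
  minLfc <- apply(lfc, 1, min)
  S4Vectors::DataFrame(lfc, min_lfc = minLfc,
                       flagged = minLfc >= log2(foldMin),
                       row.names = shared)
}
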