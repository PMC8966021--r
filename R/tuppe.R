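#' @include AllClasses.R utils.R
NULL

.reSites <- c(EcoRI = "GAATTC", SpeI = "ACTAGT", XbaI = "TCTAGA")

#' Log2 fold-change profiles relative to the first timepoint
#'
#' Normalizes every gene's FPKM series to its value at the first timepoint:
#' `value(t) = log2((FPKM_t + pc) / (FPKM_t0 + pc))` with pseudocount `pc`
#' guarding zeros. The value at t0 is exactly 0 by construction. The
#' magnitude series used for promoter clustering is the elementwise
#' absolute value of the result.
#'
#' @param x An [ExpressionSeries-class].
#' @param pseudocount Added to numerator and denominator; default 1.
#' @return Numeric matrix of signed log2 fold changes, genes in rows,
#'   same dimnames as `fpkm(x)`.
#' @examples
#' es <- ExpressionSeries(matrix(c(16, 32, 64), 1,
#'                               dimnames = list("g", NULL)), c(1, 2, 3))
#' foldChangeProfiles(es)
#' @export
foldChangeProfiles <- function(x, pseudocount = 1) {
  stopifnot(is(x, "ExpressionSeries"))
  m <- fpkm(x)
  log2((m + pseudocount) / (m[, 1] + pseudocount))
}

.productionFoldChange <- function(production, days, pseudocount = 1) {
  ti <- titer(production)
  pd <- sampleDays(production)
  # resample the titer onto the profile timepoints
  y <- stats::approx(pd, ti, xout = days, rule = 2)$y
  log2((y + pseudocount) / (y[1] + pseudocount))
}

#' Mine temporal promoters by clustering against the production profile
#'
#' Implements promoter mining for tunable exporter expression: every
#' gene's fold-change magnitude profile (|log2 fold change| relative to
#' the first timepoint) is clustered together with the production curve's
#' own fold-change profile, using correlation distance (1 - Pearson r
#' between magnitude profiles) and average-linkage agglomeration. The
#' selected candidates are the genes that (a) share the production
#' profile's cluster at the `cutHeight` cut and (b) pass the temporal
#' gate: mean FPKM over the logarithmic-phase days at or below the
#' `lowQuantile` quantile of all genes (low strength while the culture
#' grows) and late/early FPKM ratio of at least `ratioMin` (strong
#' upregulation in the production stage).
#'
#' Genes are processed in lexicographic order internally, so the result is
#' invariant to the input row order.
#'
#' @param x An [ExpressionSeries-class] with at least 2 genes.
#' @param production A [ProductionProfile-class]; resampled to the
#'   expression timepoints by linear interpolation. A production profile
#'   with zero variance is an error.
#' @param cutHeight Dendrogram cut height on the correlation-distance
#'   scale (0 = identical shape, 2 = perfectly anti-correlated);
#'   default 0.25.
#' @param logPhaseMaxDay Days `<=` this value count as logarithmic phase;
#'   default 2.
#' @param lateMinDay Days `>=` this value count as the late production
#'   stage; default 6.
#' @param lowQuantile Quantile of the all-gene logarithmic-phase mean FPKM
#'   that a candidate may not exceed; default 0.5.
#' @param ratioMin Minimum late/early FPKM ratio; default 4.
#' @param pseudocount Pseudocount for fold changes and the ratio; default 1.
#' @return List with `selected` (character vector of selected gene ids),
#'   `clusters` (named cluster assignment including the `.production`
#'   pseudo-profile) and `stats` (per-gene DataFrame with the gate
#'   quantities).
#' @export
clusterTemporalPromoters <- function(x, production, cutHeight = 0.25,
                                     logPhaseMaxDay = 2, lateMinDay = 6,
                                     lowQuantile = 0.5, ratioMin = 4,
                                     pseudocount = 1) {
  stopifnot(is(x, "ExpressionSeries"), is(production, "ProductionProfile"))
  if (nrow(x) < 2) stop("at least 2 genes required")
  days <- sampleDays(x)
  prodFc <- .productionFoldChange(production, days, pseudocount)
  if (stats::var(prodFc) == 0)
    stop("production profile has zero variance")
  ord <- order(rownames(x))
  m <- fpkm(x)[ord, , drop = FALSE]
  lfc <- abs(log2((m + pseudocount) / (m[, 1] + pseudocount)))
  prof <- rbind(lfc, .production = abs(prodFc))

  cors <- suppressWarnings(stats::cor(t(prof)))
  cors[is.na(cors)] <- 0       # zero-variance profiles: treat as unrelated
  diag(cors) <- 1
  d <- stats::as.dist(1 - cors)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cutHeight)
  prodCluster <- cl[[".production"]]

  early <- days <= logPhaseMaxDay
  late <- days >= lateMinDay
  if (!any(early) || !any(late))
    stop("timepoints do not cover both logarithmic and late phase")
  earlyMean <- rowMeans(m[, early, drop = FALSE])
  lateMean <- rowMeans(m[, late, drop = FALSE])
  ratio <- (lateMean + pseudocount) / (earlyMean + pseudocount)
  lowGate <- earlyMean <= stats::quantile(earlyMean, lowQuantile)
  genes <- rownames(m)
  inProd <- cl[genes] == prodCluster
  sel <- genes[inProd & lowGate & ratio >= ratioMin]
  list(selected = sel,
       clusters = cl,
       stats = S4Vectors::DataFrame(
         cluster = cl[genes], early_mean_fpkm = earlyMean,
         late_early_ratio = ratio, in_production_cluster = inProd,
         low_early = lowGate, selected = genes %in% sel,
         row.names = genes))
}

#' Select promoters along a strength gradient
#'
#' Ranks candidate promoters by strength (by convention, the FPKM of the
#' donor gene at the final timepoint) and picks the candidates nearest the
#' `nPromoters` evenly spaced quantiles of the candidate strength
#' distribution, inclusive of minimum and maximum, so the selected set
#' spans the available dynamic range. With `nPromoters = 1` the quantile
#' rule selects the median (not the maximum). Each candidate is picked at
#' most once (targets are filled in quantile order); ties are broken by
#' gene id.
#'
#' @param candidates Named numeric vector of strengths, or a data.frame
#'   with `gene` and `strength` columns.
#' @param nPromoters Number of promoters to select; default 5. Fewer
#'   candidates than `nPromoters` is an error stating both counts.
#' @return data.frame with `gene`, `strength` and `quantile_target`
#'   columns, ordered by increasing strength.
#' @examples
#' selectStrengthGradient(stats::setNames(1:100, sprintf("g%03d", 1:100)), 5)
#' @export
selectStrengthGradient <- function(candidates, nPromoters = 5) {
  if (is.data.frame(candidates))
    candidates <- stats::setNames(candidates$strength, candidates$gene)
  if (is.null(names(candidates))) stop("candidates must be named")
  if (length(candidates) < nPromoters)
    stop("too few candidates: ", length(candidates), " available, ",
         nPromoters, " requested")
  probs <- if (nPromoters == 1) 0.5 else seq(0, 1, length.out = nPromoters)
  targets <- stats::quantile(candidates, probs, type = 7, names = FALSE)
  ord <- order(names(candidates))
  candidates <- candidates[ord]
  picked <- character(0)
  targetOf <- numeric(0)
  for (tg in targets) {
    avail <- setdiff(names(candidates), picked)
    dists <- abs(candidates[avail] - tg)
    best <- avail[order(dists, avail)][1]
    picked <- c(picked, best)
    targetOf <- c(targetOf, tg)
  }
  out <- data.frame(gene = picked, strength = unname(candidates[picked]),
                    quantile_target = targetOf, stringsAsFactors = FALSE)
  out[order(out$strength, out$gene), , drop = FALSE]
}

#' Extract the native promoter upstream of a gene
#'
#' Returns the `length`-bp sequence immediately upstream of a gene's
#' coding start, honouring GFF3 1-based inclusive coordinates: for a
#' forward-strand gene starting at s, bases `[max(1, s - length), s - 1]`;
#' for a reverse-strand gene ending at e, the reverse complement of
#' `[e + 1, min(contig_end, e + length)]`. The returned window abuts the
#' start codon, so the donor gene's native RBS is part of the promoter
#' fragment. A window truncated by the contig edge triggers a warning.
#'
#' @param genome A [Biostrings::DNAStringSet] (contigs) or single
#'   [Biostrings::DNAString].
#' @param annotation A [GenomicRanges::GRanges] with an `ID` column.
#' @param geneId Gene to extract the promoter of; an unknown id is an
#'   error.
#' @param length Window length in bp; default 500.
#' @return A [Biostrings::DNAString] of at most `length` bp (possibly
#'   empty for a gene at the contig start).
#' @export
extractPromoter <- function(genome, annotation, geneId, length = 500) {
  stopifnot(methods::is(annotation, "GRanges"))
  if (methods::is(genome, "DNAString"))
    genome <- Biostrings::DNAStringSet(stats::setNames(
      as.character(genome), as.character(GenomeInfoDb::seqnames(annotation)[1])))
  hit <- which(annotation$ID == geneId)
  if (length(hit) == 0) stop("gene id not found in annotation: ", geneId)
  gr <- annotation[hit[1]]
  contig <- as.character(GenomeInfoDb::seqnames(gr))
  if (!contig %in% names(genome)) stop("contig not in genome: ", contig)
  seqLen <- length(genome[[contig]])
  if (as.character(GenomicRanges::strand(gr)) == "-") {
    s <- GenomicRanges::end(gr) + 1L
    e <- min(seqLen, GenomicRanges::end(gr) + length)
    if (s > e) {
      warning("promoter of ", geneId, " is empty (gene at contig end)")
      return(Biostrings::DNAString(""))
    }
    out <- Biostrings::reverseComplement(
      Biostrings::subseq(genome[[contig]], s, e))
  } else {
    e <- GenomicRanges::start(gr) - 1L
    s <- max(1L, GenomicRanges::start(gr) - length)
    if (e < s) {
      warning("promoter of ", geneId, " is empty (gene at contig start)")
      return(Biostrings::DNAString(""))
    }
    out <- Biostrings::subseq(genome[[contig]], s, e)
  }
  if (length(out) < length)
    warning("promoter of ", geneId, " truncated to ", length(out), " bp")
  out
}

#' Extract an exporter coding region, preserving operonic spacing
#'
#' For a multi-gene exporter system (e.g. the two half-transporter genes
#' of an ABC exporter) the genomic block from the start of the first
#' member to the end of the last member is extracted in genome order with
#' the native intergenic spacing preserved, mirroring the cloning of whole
#' operonic fragments. All members must share contig and strand; for
#' minus-strand systems the reverse complement is returned.
#'
#' @inheritParams extractPromoter
#' @param geneIds Member gene ids, any order.
#' @return A [Biostrings::DNAString].
#' @export
extractExporterRegion <- function(genome, annotation, geneIds) {
  stopifnot(methods::is(annotation, "GRanges"))
  hit <- match(geneIds, annotation$ID)
  if (anyNA(hit))
    stop("gene id(s) not in annotation: ",
         paste(geneIds[is.na(hit)], collapse = ", "))
  gr <- annotation[hit]
  contig <- unique(as.character(GenomeInfoDb::seqnames(gr)))
  strand <- unique(as.character(GenomicRanges::strand(gr)))
  if (length(contig) != 1 || length(strand) != 1)
    stop("exporter members must share contig and strand")
  if (methods::is(genome, "DNAString"))
    genome <- Biostrings::DNAStringSet(stats::setNames(
      as.character(genome), contig))
  s <- min(GenomicRanges::start(gr))
  e <- max(GenomicRanges::end(gr))
  out <- Biostrings::subseq(genome[[contig]], s, e)
  if (strand == "-") out <- Biostrings::reverseComplement(out)
  out
}

.findSite <- function(seqChar, site) {
  p <- gregexpr(site, seqChar, fixed = TRUE)[[1]]
  if (p[1] == -1) integer(0) else as.integer(p)
}

#' Assemble one TuPPE cassette
#'
#' Concatenates `GAATTC` (EcoRI) + promoter + RBS + `ACTAGT` (SpeI) +
#' exporter CDS + `TCTAGA` (XbaI), after validating that no part contains
#' any of the three recognition sites internally (the error names the
#' part, the site and the offset). The assembled cassette is re-scanned:
#' each site must occur exactly once, at its designed junction (a site
#' arising across a part boundary is also an error). For a native-RBS
#' design pass an empty RBS sequence: the promoter window already abuts
#' the start codon, so the donor's own RBS is carried by the promoter
#' part.
#'
#' @param promoter,rbs,exporter Named parts: each a single-element named
#'   character vector or named [Biostrings::DNAString]-like; names become
#'   the part ids. `rbs` may have an empty sequence (native RBS).
#' @return A [TuppeConstruct-class].
#' @examples
#' assembleTuppe(c(P1 = "ATGCAT"), c(Ra = "AGGAGG"), c(exp1 = "ATGAAATAA"))
#' @export
assembleTuppe <- function(promoter, rbs, exporter) {
  partSeq <- function(p, what) {
    if (methods::is(p, "XStringSet")) p <- as.character(p)
    if (methods::is(p, "XString"))
      stop(what, " must be a *named* sequence (use a named character or ",
           "DNAStringSet of length 1)")
    if (length(p) != 1 || is.null(names(p)))
      stop(what, " must be a single named sequence")
    stats::setNames(toupper(as.character(p)), names(p))
  }
  promoter <- partSeq(promoter, "promoter")
  rbs <- partSeq(rbs, "rbs")
  exporter <- partSeq(exporter, "exporter")
  parts <- list(promoter = promoter, rbs = rbs, exporter = exporter)
  for (pn in names(parts)) {
    s <- parts[[pn]]
    for (sn in names(.reSites)) {
      pos <- .findSite(unname(s), .reSites[[sn]])
      if (length(pos))
        stop("part '", pn, "' (", names(s), ") contains an internal ", sn,
             " site at offset ", pos[1])
    }
  }
  pSeq <- unname(promoter); rSeq <- unname(rbs); eSeq <- unname(exporter)
  cassette <- paste0(.reSites[["EcoRI"]], pSeq, rSeq, .reSites[["SpeI"]],
                     eSeq, .reSites[["XbaI"]])
  jm <- c(EcoRI = 1L,
          SpeI = 6L + nchar(pSeq) + nchar(rSeq) + 1L,
          XbaI = 12L + nchar(pSeq) + nchar(rSeq) + nchar(eSeq) + 1L)
  for (sn in names(.reSites)) {
    pos <- .findSite(cassette, .reSites[[sn]])
    if (!identical(pos, unname(jm[sn])))
      stop("assembled cassette does not contain exactly one ", sn,
           " site at its designed junction (found at: ",
           paste(pos, collapse = ", "), ")")
  }
  new("TuppeConstruct",
      constructId = paste("TuPPE", names(promoter), names(rbs),
                          names(exporter), sep = "_"),
      promoterId = names(promoter), rbsId = names(rbs),
      exporterId = names(exporter),
      sequence = Biostrings::DNAString(cassette),
      junctionMap = jm)
}

#' Enumerate a combinatorial TuPPE cassette library
#'
#' Full Cartesian product of promoters x RBS parts x exporters, each
#' combination assembled with [assembleTuppe()]. Combinations whose parts
#' fail validation (internal restriction site) are reported in the
#' `failures` table, never silently dropped; the number of constructs plus
#' failures always equals the product of the part-list sizes.
#'
#' @param promoters,rbsParts,exporters Named character vectors (or
#'   [Biostrings::DNAStringSet]s) of part sequences; all nonempty lists.
#'   An RBS part may have an empty sequence (native RBS).
#' @return A [TuppeLibrary-class].
#' @examples
#' lib <- enumerateLibrary(c(P1 = "ATGC", P2 = "GGCC"),
#'                         c(Ra = "AGGAGG"), c(e1 = "ATGTAA"))
#' length(lib)
#' @export
enumerateLibrary <- function(promoters, rbsParts, exporters) {
  asVec <- function(x, what) {
    if (methods::is(x, "XStringSet")) x <- as.character(x)
    if (length(x) == 0) stop(what, " list must be nonempty")
    if (is.null(names(x))) stop(what, " parts must be named")
    x
  }
  promoters <- asVec(promoters, "promoter")
  rbsParts <- asVec(rbsParts, "rbs")
  exporters <- asVec(exporters, "exporter")
  cons <- list()
  fails <- list()
  for (pi in names(promoters)) for (ri in names(rbsParts))
    for (ei in names(exporters)) {
      res <- tryCatch(
        assembleTuppe(stats::setNames(promoters[pi], pi),
                      stats::setNames(rbsParts[ri], ri),
                      stats::setNames(exporters[ei], ei)),
        error = function(e) conditionMessage(e))
      if (methods::is(res, "TuppeConstruct"))
        cons[[res@constructId]] <- res
      else
        fails[[length(fails) + 1L]] <- data.frame(
          promoter = pi, rbs = ri, exporter = ei, message = res,
          stringsAsFactors = FALSE)
    }
  new("TuppeLibrary", constructs = cons,
      failures = if (length(fails)) do.call(rbind, fails) else
        data.frame(promoter = character(), rbs = character(),
                   exporter = character(), message = character(),
                   stringsAsFactors = FALSE))
}

#' Write a TuPPE library as annotated multi-FASTA
#'
#' Headers carry the part ids and the junction map
#' (`EcoRI=..;SpeI=..;XbaI=..`) so a library round-trips through FASTA.
#'
#' @param library A [TuppeLibrary-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @seealso [readTuppeFasta()]
#' @export
writeTuppeFasta <- function(library, path) {
  stopifnot(methods::is(library, "TuppeLibrary"))
  lines <- unlist(lapply(constructs(library), function(con) {
    j <- junctions(con)
    c(sprintf(">%s promoter=%s;rbs=%s;exporter=%s;EcoRI=%d;SpeI=%d;XbaI=%d",
              con@constructId, con@promoterId, con@rbsId, con@exporterId,
              j[["EcoRI"]], j[["SpeI"]], j[["XbaI"]]),
      as.character(cassetteSeq(con)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Re-parse a TuPPE library from annotated FASTA
#'
#' Reconstructs each construct from its sequence and header; the junction
#' map is re-derived by locating the restriction sites in the sequence and
#' checked against the header annotation (a mismatch is an error), so a
#' written library is guaranteed to round-trip.
#'
#' @param path FASTA file written by [writeTuppeFasta()].
#' @return A [TuppeLibrary-class] (with an empty failures table).
#' @export
readTuppeFasta <- function(path) {
  lines <- readLines(path)
  hIdx <- grep("^>", lines)
  cons <- list()
  for (k in seq_along(hIdx)) {
    header <- sub("^>", "", lines[hIdx[k]])
    to <- if (k < length(hIdx)) hIdx[k + 1] - 1 else length(lines)
    seq <- paste(lines[(hIdx[k] + 1):to], collapse = "")
    id <- sub(" .*", "", header)
    meta <- sub("^[^ ]+ ", "", header)
    kv <- strsplit(strsplit(meta, ";")[[1]], "=")
    vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                            vapply(kv, `[`, character(1), 1))
    jm <- vapply(c("EcoRI", "SpeI", "XbaI"),
                 function(sn) .findSite(seq, .reSites[[sn]])[1], integer(1))
    declared <- as.integer(vals[c("EcoRI", "SpeI", "XbaI")])
    if (!identical(unname(jm), declared))
      stop("junction map mismatch for ", id, ": sequence gives ",
           paste(jm, collapse = "/"), ", header declares ",
           paste(declared, collapse = "/"))
    cons[[id]] <- new("TuppeConstruct", constructId = id,
                      promoterId = unname(vals[["promoter"]]),
                      rbsId = unname(vals[["rbs"]]),
                      exporterId = unname(vals[["exporter"]]),
                      sequence = Biostrings::DNAString(seq),
                      junctionMap = jm)
  }
  new("TuppeLibrary", constructs = cons,
      failures = data.frame(promoter = character(), rbs = character(),
                            exporter = character(), message = character(),
                            stringsAsFactors = FALSE))
}
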