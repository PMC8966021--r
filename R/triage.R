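#' @include AllClasses.R utils.R
NULL

#' Predict transmembrane helices by Kyte-Doolittle hydropathy
#'
#' Sliding-window hydropathy scan in the classic membrane-protein setting:
#' window length 19, mean Kyte-Doolittle hydropathy, cutoff 1.6. Maximal
#' runs of window centers whose mean exceeds the cutoff are called as
#' helices (each run expanded to the full extent of its windows, so every
#' call is at least 19 residues); overlapping calls are merged. This is a
#' deterministic, network-free approximation of an HMM-based topology
#' predictor, adequate for the planted hydrophobic stretches of the
#' synthetic genome and for coarse triage of real proteomes.
#'
#' @param sequence A protein sequence (character or
#'   [Biostrings::AAString]); the 20 amino acids plus X (scored 0).
#'   Empty sequences and illegal characters are errors.
#' @param windowSize Hydropathy window length; default 19.
#' @param cutoff Mean-hydropathy cutoff; default 1.6.
#' @return An [IRanges::IRanges] of helix spans (1-based, inclusive);
#'   `length()` of the result is the helix count.
#' @examples
#' predictTmHelices(strrep("D", 20)) # no helix
#' predictTmHelices(paste0(strrep("D", 20), strrep("I", 25), strrep("D", 20)))
#' @export
predictTmHelices <- function(sequence, windowSize = 19, cutoff = 1.6) {
  s <- .checkProtein(sequence)
  n <- nchar(s)
  if (n < windowSize) return(IRanges::IRanges())
  sc <- .kdScale[strsplit(s, "")[[1]]]
  cs <- cumsum(c(0, sc))
  wmean <- (cs[(windowSize + 1):(n + 1)] - cs[1:(n - windowSize + 1)]) /
    windowSize
  # wmean[i] is the window starting at residue i
  hot <- wmean > cutoff
  if (!any(hot)) return(IRanges::IRanges())
  r <- rle(hot)
  endsIdx <- cumsum(r$lengths)
  startsIdx <- endsIdx - r$lengths + 1L
  keep <- which(r$values)
  spans <- IRanges::IRanges(start = startsIdx[keep],
                            end = endsIdx[keep] + windowSize - 1L)
  IRanges::reduce(spans)
}

#' Detect Walker A (P-loop) motifs
#'
#' Scans a protein for the Walker A nucleotide-binding motif
#' `[AG]-x(4)-G-K-[ST]`, the signature of the ABC transporter NBD ATPase
#' core. Walker B is deliberately not used: it is too degenerate for a
#' keyword-scale tool.
#'
#' @param sequence Protein sequence as for [predictTmHelices()].
#' @param pattern Regular expression for the motif; configurable.
#' @return A data.frame with columns `start`, `end`, `match`
#'   (zero rows if none); attribute `hasNbd` is TRUE iff at least one hit.
#' @examples
#' detectNbd(paste0(strrep("N", 10), "GPSGSGKST", strrep("N", 10)))
#' @export
detectNbd <- function(sequence, pattern = "[AG].{4}GK[ST]") {
  s <- .checkProtein(sequence)
  m <- gregexpr(pattern, s, perl = TRUE)[[1]]
  if (m[1] == -1) {
    out <- data.frame(start = integer(), end = integer(),
                      match = character(), stringsAsFactors = FALSE)
  } else {
    len <- attr(m, "match.length")
    out <- data.frame(start = as.integer(m),
                      end = as.integer(m) + len - 1L,
                      match = substring(s, m, m + len - 1L),
                      stringsAsFactors = FALSE)
  }
  attr(out, "hasNbd") <- nrow(out) > 0
  out
}

# keyword -> substrate class lexicon, shipped as an editable packaged
# resource (inst/extdata/substrate_lexicon.tsv)
.loadSubstrateLexicon <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "substrate_lexicon.tsv",
                        package = "TuppeMiner")
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

.familyKeywords <- list(
  ABC = c("\\bABC\\b", "ATP-binding"),
  MFS = c("\\bMFS\\b", "major facilitator"),
  RND = c("\\bRND\\b", "resistance-nodulation"),
  DMT = c("\\bDMT\\b", "drug/metabolite transporter"),
  AbgT = c("\\bAbgT\\b", "aminobenzoyl-glutamate"),
  NbcE = c("\\bNbcE\\b", "novobiocin exporter"),
  `I-PPI` = c("\\bI-PPI\\b", "prolyl:peptidyl isomerase"),
  SanA = c("\\bSanA\\b", "vancomycin-sensitivity"))

# normalize annotation input (GRanges with ID/product, or data.frame with
# gene/product columns) to a data.frame in genome order
.normalizeAnnotation <- function(annotation) {
  if (methods::is(annotation, "GRanges")) {
    ord <- order(as.integer(GenomicRanges::start(annotation)))
    data.frame(gene = annotation$ID[ord],
               product = annotation$product[ord],
               stringsAsFactors = FALSE)
  } else {
    ann <- as.data.frame(annotation, stringsAsFactors = FALSE)
    if (!all(c("gene", "product") %in% colnames(ann)))
      stop("annotation must have 'gene' and 'product' columns")
    ann[, c("gene", "product")]
  }
}

#' Classify a proteome's putative efflux transporters
#'
#' Applies an ordered, first-match-wins rule list to every protein so each
#' call is auditable through its `evidence` field: (1) a substrate-class
#' keyword lexicon on the annotation product string (drug-multi,
#' drug-specific, dye, sterol, toxin); (2) family assignment by keyword
#' plus structural corroboration -- ABC requires a Walker A motif in the
#' protein itself or in an adjacent gene, MFS requires 10--14 predicted
#' transmembrane helices; RND, DMT, AbgT, NbcE, I-PPI and SanA are
#' keyword-only. Proteins with a substrate hit but no family rule get
#' family `other`; proteins matching nothing get `none`. Every input
#' protein appears exactly once in the output.
#'
#' @param annotation A [GenomicRanges::GRanges] with `ID` and `product`
#'   columns, or a data.frame with `gene` and `product`, in genome order.
#' @param proteins Named [Biostrings::AAStringSet] (or character vector)
#'   covering every annotated gene; a protein without an annotation record
#'   is an error.
#' @param lexicon Substrate lexicon data.frame (`keyword`, `class`);
#'   default is the packaged resource.
#' @return A [S4Vectors::DataFrame] with one row per protein: `gene`,
#'   `family`, `substrate_class` (comma-collapsed subset), `tm_helix_count`,
#'   `has_nbd` and `evidence` (a [IRanges::CharacterList] of fired rule
#'   ids).
#' @seealso [assembleAbcSystems()], [predictTmHelices()], [detectNbd()]
#' @export
classifyTransporters <- function(annotation, proteins, lexicon = NULL) {
  ann <- .normalizeAnnotation(annotation)
  if (is.null(lexicon)) lexicon <- .loadSubstrateLexicon()
  nm <- names(proteins)
  prot <- as.character(proteins)
  if (is.null(names(prot))) names(prot) <- nm
  if (is.null(names(prot))) stop("proteins must be named by gene id")
  missing <- setdiff(ann$gene, names(prot))
  if (length(missing))
    stop("no protein sequence for annotated gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  orphan <- setdiff(names(prot), ann$gene)
  if (length(orphan))
    stop("protein without annotation record: ",
         paste(utils::head(orphan, 5), collapse = ", "))

  n <- nrow(ann)
  tmCount <- integer(n)
  hasNbd <- logical(n)
  for (i in seq_len(n)) {
    p <- prot[[ann$gene[i]]]
    tmCount[i] <- length(predictTmHelices(p))
    hasNbd[i] <- attr(detectNbd(p), "hasNbd")
  }

  family <- character(n)
  substrate <- vector("list", n)
  evidence <- vector("list", n)
  for (i in seq_len(n)) {
    product <- ann$product[i]
    ev <- character()
    # rule 1: substrate-class lexicon
    cls <- character()
    for (j in seq_len(nrow(lexicon))) {
      if (grepl(lexicon$keyword[j], product, ignore.case = TRUE)) {
        cls <- c(cls, lexicon$class[j])
        ev <- c(ev, paste0("kw:", lexicon$keyword[j]))
      }
    }
    cls <- unique(cls)
    # drug-multi dominates drug-specific when both keywords fire
    if ("drug-multi" %in% cls) cls <- setdiff(cls, "drug-specific")
    # rule 2: family, first match wins
    fam <- "none"
    for (f in names(.familyKeywords)) {
      if (any(vapply(.familyKeywords[[f]], grepl, logical(1), x = product,
                     ignore.case = TRUE))) {
        if (f == "ABC") {
          nbdNear <- hasNbd[i] ||
            (i > 1 && hasNbd[i - 1]) || (i < n && hasNbd[i + 1])
          if (!nbdNear) next
          ev <- c(ev, "fam:abc_keyword",
                  if (hasNbd[i]) "fam:nbd_motif_self" else
                    "fam:nbd_motif_adjacent")
        } else if (f == "MFS") {
          if (tmCount[i] < 10 || tmCount[i] > 14) next
          ev <- c(ev, "fam:mfs_keyword", "fam:tm_count_10_14")
        } else {
          ev <- c(ev, paste0("fam:", tolower(f), "_keyword"))
        }
        fam <- f
        break
      }
    }
    if (fam == "none" && length(cls)) fam <- "other"
    family[i] <- fam
    substrate[[i]] <- if (length(cls)) sort(cls) else "none"
    evidence[[i]] <- ev
  }
  S4Vectors::DataFrame(
    gene = ann$gene, family = family,
    substrate_class = vapply(substrate, paste, character(1), collapse = ","),
    tm_helix_count = tmCount, has_nbd = hasNbd,
    evidence = IRanges::CharacterList(evidence))
}

#' Assemble ABC exporter systems and complete missing domains
#'
#' Groups contiguous ABC-family genes (gene-order gap at most
#' `neighborhoodWindow`) into exporter systems, then classifies each
#' system's architecture: members with >= 4 predicted transmembrane
#' helices are TMD-bearing, members with a Walker A motif are NBD-bearing
#' (a fused half-transporter is both). A system lacking a TMD (or NBD)
#' member searches the non-ABC genes within `neighborhoodWindow` positions
#' of the system for a protein with >= 4 transmembrane helices (or a
#' Walker A motif) and, if found, recruits the nearest one, labelling the
#' system `tmd_completed_from_neighborhood` (or `nbd_completed_...`);
#' otherwise the system is `incomplete`. Grouping uses gene-order
#' adjacency, not base-pair distance, mirroring locus-tag neighbourhood
#' reasoning. A recruited gene joins only one system.
#'
#' @param calls Output of [classifyTransporters()] (must cover every gene).
#' @param annotation As for [classifyTransporters()]; defines gene order.
#' @param neighborhoodWindow Maximum gene-order gap, default 2.
#' @return A [S4Vectors::DataFrame] with one row per system: `system_id`,
#'   `members`, `tmd_members`, `nbd_members` (each a
#'   [IRanges::CharacterList]) and `completeness` (one of `complete`,
#'   `tmd_completed_from_neighborhood`, `nbd_completed_from_neighborhood`,
#'   `incomplete`).
#' @export
assembleAbcSystems <- function(calls, annotation, neighborhoodWindow = 2) {
  ann <- .normalizeAnnotation(annotation)
  idx <- match(ann$gene, calls$gene)
  if (anyNA(idx)) stop("calls must cover every annotated gene")
  calls <- calls[idx, ]
  n <- nrow(ann)
  abcIdx <- which(calls$family == "ABC")
  if (length(abcIdx) == 0)
    return(S4Vectors::DataFrame(
      system_id = character(), members = IRanges::CharacterList(),
      tmd_members = IRanges::CharacterList(),
      nbd_members = IRanges::CharacterList(),
      completeness = character()))
  grp <- cumsum(c(1L, diff(abcIdx) > neighborhoodWindow))
  systems <- split(abcIdx, grp)

  isTmd <- calls$tm_helix_count >= 4
  isNbd <- calls$has_nbd
  recruited <- logical(n)

  rows <- lapply(seq_along(systems), function(si) {
    mem <- systems[[si]]
    tmd <- mem[isTmd[mem]]
    nbd <- mem[isNbd[mem]]
    completeness <- "complete"
    if (length(tmd) == 0 || length(nbd) == 0) {
      wantTmd <- length(tmd) == 0
      lo <- max(1L, min(mem) - neighborhoodWindow)
      hi <- min(n, max(mem) + neighborhoodWindow)
      cand <- setdiff(lo:hi, which(calls$family == "ABC"))
      cand <- cand[!recruited[cand]]
      cand <- cand[if (wantTmd) isTmd[cand] else isNbd[cand]]
      if (length(cand)) {
        dist <- vapply(cand, function(j) min(abs(j - mem)), numeric(1))
        best <- cand[order(dist, calls$gene[cand])][1]
        recruited[best] <<- TRUE
        mem <- sort(c(mem, best))
        if (wantTmd) tmd <- best else nbd <- best
        completeness <- if (wantTmd) "tmd_completed_from_neighborhood"
          else "nbd_completed_from_neighborhood"
      } else {
        completeness <- "incomplete"
      }
    }
    list(members = calls$gene[mem], tmd = calls$gene[tmd],
         nbd = calls$gene[nbd], completeness = completeness)
  })
  S4Vectors::DataFrame(
    system_id = sprintf("ABC_SYS_%03d", seq_along(rows)),
    members = IRanges::CharacterList(lapply(rows, `[[`, "members")),
    tmd_members = IRanges::CharacterList(lapply(rows, `[[`, "tmd")),
    nbd_members = IRanges::CharacterList(lapply(rows, `[[`, "nbd")),
    completeness = vapply(rows, `[[`, character(1), "completeness"))
}

#' Family fraction of a drug-efflux triage report
#'
#' The summary statistic of a transporter triage: what fraction of the
#' putative drug-efflux proteins belongs to the named transporter
#' families. Applied, for instance, to a genome with 74 putative
#' multiple-drug and 57 specific-drug efflux proteins of which 46 are ABC
#' and 58 MFS superfamily members, it reports 131 proteins total and a
#' family coverage of 79.4%.
#'
#' @param familyCounts Named numeric vector of per-family member counts
#'   (e.g. `c(ABC = 46, MFS = 58)`).
#' @param substrateCounts Numeric vector of drug-efflux protein counts by
#'   substrate class (e.g. `c(74, 57)`); the total is their sum.
#' @return List with `total` (drug-efflux proteins), `nFamily` (sum of
#'   family counts), `fraction` (raw) and `percent` (rounded to one
#'   decimal, report-style).
#' @examples
#' familyFraction(c(ABC = 46, MFS = 58), c(74, 57))
#' @export
familyFraction <- function(familyCounts, substrateCounts) {
  total <- sum(substrateCounts)
  if (total <= 0) stop("total drug-efflux count must be positive")
  nFam <- sum(familyCounts)
  frac <- nFam / total
  list(total = total, nFamily = nFam, fraction = frac,
       percent = round(100 * frac, 1))
}
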