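#' @include AllClasses.R io.R screen.R triage.R phylo.R tuppe.R
NULL

#' Validate a pipeline input set
#'
#' Structural checks before a run: GFF3 well-formedness (9 tab-separated
#' columns on every feature line, reported with line numbers), FASTA/GFF3
#' cross-references (every annotated gene has a protein and vice versa),
#' expression gene ids a subset of the annotation, timepoint consistency
#' between expression and production over the screen window, and sequence
#' alphabets. This is a reporting operation: it never throws for content
#' problems, it returns them.
#'
#' @param paths Named list/vector with any of `expression`, `production`,
#'   `gff`, `proteins`, `genome` (missing entries skip their checks).
#' @param window Screen window used for the timepoint consistency check.
#' @return data.frame of issues with columns `severity`, `stage`, `item`,
#'   `message`; zero rows means a clean bundle.
#' @export
validateInputs <- function(paths, window = c(3, 8)) {
  paths <- as.list(paths)
  issues <- list()
  add <- function(severity, stage, item, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, stage = stage, item = item, message = message,
      stringsAsFactors = FALSE)

  for (p in names(paths))
    if (!file.exists(paths[[p]]))
      add("error", "inputs", p, paste0("file does not exist: ", paths[[p]]))

  gff <- NULL
  if (!is.null(paths$gff) && file.exists(paths$gff)) {
    lines <- readLines(paths$gff)
    feat <- which(!grepl("^#", lines) & nzchar(lines))
    nf <- vapply(strsplit(lines[feat], "\t"), length, integer(1))
    for (k in which(nf != 9))
      add("error", "gff", paths$gff,
          sprintf("line %d: expected 9 tab-separated columns, found %d",
                  feat[k], nf[k]))
    gff <- tryCatch(rtracklayer::import(paths$gff, format = "gff3"),
                    error = function(e) {
                      add("error", "gff", paths$gff,
                          paste0("parse failure: ", conditionMessage(e)))
                      NULL
                    })
    if (!is.null(gff) && is.null(gff$ID))
      add("error", "gff", paths$gff, "no ID attribute on any feature")
  }

  prot <- NULL
  if (!is.null(paths$proteins) && file.exists(paths$proteins)) {
    prot <- tryCatch(Biostrings::readAAStringSet(paths$proteins),
                     error = function(e) {
                       add("error", "proteins", paths$proteins,
                           conditionMessage(e)); NULL
                     })
    if (!is.null(prot)) {
      badChars <- vapply(as.character(prot), function(s)
        length(setdiff(unique(strsplit(toupper(s), "")[[1]]),
                       c(.aaAlphabet, "*", "-"))) > 0, logical(1))
      for (id in names(prot)[badChars])
        add("error", "proteins", id, "illegal residue characters")
    }
  }

  if (!is.null(gff) && !is.null(prot)) {
    ids <- gff$ID[!is.na(gff$ID)]
    protIds <- sub(" .*", "", names(prot))
    for (id in setdiff(ids, protIds))
      add("error", "cross-reference", id, "annotated gene without protein")
    for (id in setdiff(protIds, ids))
      add("warning", "cross-reference", id, "protein without annotation")
  }

  es <- NULL
  if (!is.null(paths$expression) && file.exists(paths$expression)) {
    es <- tryCatch(readExpressionTsv(paths$expression),
                   error = function(e) {
                     add("error", "expression", paths$expression,
                         conditionMessage(e)); NULL
                   })
  }
  if (!is.null(es) && !is.null(gff)) {
    ids <- gff$ID[!is.na(gff$ID)]
    for (id in setdiff(geneIds(es), ids))
      add("error", "cross-reference", id,
          "expression row with unknown gene id")
  }
  if (!is.null(es) && !is.null(paths$production) &&
      file.exists(paths$production)) {
    pp <- tryCatch(readProductionTsv(paths$production),
                   error = function(e) {
                     add("error", "production", paths$production,
                         conditionMessage(e)); NULL
                   })
    if (!is.null(pp)) {
      de <- sampleDays(es); dp <- sampleDays(pp)
      we <- de[de >= window[1] & de <= window[2]]
      wp <- dp[dp >= window[1] & dp <= window[2]]
      mismatch <- sort(unique(c(setdiff(we, wp), setdiff(wp, we))))
      if (length(mismatch))
        add("error", "timepoints", paste(mismatch, collapse = ","),
            "timepoints within the screen window differ between expression and production")
      if (length(we) < 3)
        add("error", "timepoints", paths$expression,
            "fewer than 3 timepoints in the screen window")
    }
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), stage = character(),
               item = character(), message = character(),
               stringsAsFactors = FALSE)
}

#' Assemble a pipeline configuration
#'
#' Bundles input paths, stage thresholds and the master seed for
#' [runPipeline()]. All randomness of a run flows from `seed`.
#'
#' @param expression,production,gff,proteins,genome,rbs,alignment Input
#'   file paths (`alignment` and `rbs` optional; without an alignment the
#'   phylogenetic stage is skipped with a log entry, and without an RBS
#'   table the packaged synthetic library is used).
#' @param outDir Output directory.
#' @param thresholds A [ScreenThresholds-class].
#' @param neighborhoodWindow ABC system grouping window (genes).
#' @param bootstrapReplicates Bootstrap replicates for the tree stage.
#' @param kClades,anchors Representative-picking parameters.
#' @param nPromoters Promoters on the strength gradient.
#' @param promoterLength Upstream window (bp).
#' @param cutHeight,ratioMin,lowQuantile Temporal-promoter gates, see
#'   [clusterTemporalPromoters()].
#' @param seed Master seed.
#' @return A list of class `tuppePipelineConfig`.
#' @export
pipelineConfig <- function(expression, production, gff, proteins, genome,
                           rbs = NULL, alignment = NULL, outDir = "tuppe_out",
                           thresholds = screenThresholds(),
                           neighborhoodWindow = 2, bootstrapReplicates = 100,
                           kClades = 4, anchors = character(),
                           nPromoters = 5, promoterLength = 500,
                           cutHeight = 0.25, ratioMin = 4, lowQuantile = 0.5,
                           seed = 1) {
  cfg <- list(expression = expression, production = production, gff = gff,
              proteins = proteins, genome = genome, rbs = rbs,
              alignment = alignment, outDir = outDir,
              thresholds = thresholds,
              neighborhoodWindow = neighborhoodWindow,
              bootstrapReplicates = bootstrapReplicates, kClades = kClades,
              anchors = anchors, nPromoters = nPromoters,
              promoterLength = promoterLength, cutHeight = cutHeight,
              ratioMin = ratioMin, lowQuantile = lowQuantile,
              seed = as.integer(seed))
  class(cfg) <- "tuppePipelineConfig"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the exporter-mining and cassette-design pipeline end to end
#'
#' Executes screen (expression--titer correlation and filtering), triage
#' (transporter classification and ABC system assembly/completion), the
#' phylogenetic stage (Poisson-distance NJ tree with bootstrap supports
#' and branch-diversified representative picking; skipped with a log entry
#' when no alignment is configured) and design (temporal-promoter mining,
#' strength gradient, promoter extraction and combinatorial cassette
#' assembly). All intermediate tables are written under `outDir`, plus a
#' machine-readable JSON run report; a rerun with the same configuration
#' and inputs is byte-identical. Any stage error aborts with the stage
#' name and cause.
#'
#' @param config A [pipelineConfig()] list.
#' @return The run report (named list) invisibly; also written to
#'   `<outDir>/report.json`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "tuppePipelineConfig"))
  if (!dir.exists(config$outDir)) dir.create(config$outDir, recursive = TRUE)
  report <- list(seed = config$seed, stages = list(), warnings = list())
  logw <- function(stage, msg)
    report$warnings[[length(report$warnings) + 1L]] <<-
      list(stage = stage, message = msg)

  # -- screen ---------------------------------------------------------------
  screenRes <- .stage("screen", {
    es <- readExpressionTsv(config$expression)
    pp <- readProductionTsv(config$production)
    ann <- rtracklayer::import(config$gff, format = "gff3")
    stats <- correlateExpression(es, pp, window = config$thresholds@window)
    cand <- withCallingHandlers(
      filterCandidates(stats, config$thresholds, annotation = ann),
      warning = function(w) {
        logw("screen", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    utils::write.table(
      data.frame(gene_id = rownames(stats), as.data.frame(stats)),
      file.path(config$outDir, "screen_stats.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene_id = rownames(cand), as.data.frame(cand)),
      file.path(config$outDir, "screen_candidates.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(es = es, pp = pp, ann = ann, stats = stats, cand = cand)
  })
  report$stages$screen <- list(
    n_genes = nrow(screenRes$stats),
    n_candidates = nrow(screenRes$cand),
    candidates = rownames(screenRes$cand))

  # -- triage ---------------------------------------------------------------
  triageRes <- .stage("triage", {
    prot <- Biostrings::readAAStringSet(config$proteins)
    names(prot) <- sub(" .*", "", names(prot))
    calls <- classifyTransporters(screenRes$ann, prot)
    systems <- assembleAbcSystems(calls, screenRes$ann,
                                  config$neighborhoodWindow)
    callsDf <- data.frame(
      gene = calls$gene, family = calls$family,
      substrate_class = calls$substrate_class,
      tm_helix_count = calls$tm_helix_count, has_nbd = calls$has_nbd,
      evidence = vapply(as.list(calls$evidence), paste, character(1),
                        collapse = ","))
    utils::write.table(callsDf, file.path(config$outDir, "triage_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sysDf <- data.frame(
      system_id = systems$system_id,
      members = vapply(as.list(systems$members), paste, character(1),
                       collapse = ","),
      tmd_members = vapply(as.list(systems$tmd_members), paste, character(1),
                           collapse = ","),
      nbd_members = vapply(as.list(systems$nbd_members), paste, character(1),
                           collapse = ","),
      completeness = systems$completeness)
    utils::write.table(sysDf, file.path(config$outDir, "abc_systems.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(prot = prot, calls = calls, systems = systems)
  })
  usable <- triageRes$systems$completeness != "incomplete"
  report$stages$triage <- list(
    n_proteins = nrow(triageRes$calls),
    n_transporter_calls = sum(triageRes$calls$family != "none"),
    n_abc_systems = nrow(triageRes$systems),
    n_mfs = sum(triageRes$calls$family == "MFS"),
    completeness = as.list(table(triageRes$systems$completeness)),
    candidate_abc_systems = triageRes$systems$system_id[usable],
    candidate_abc_genes =
      sort(unique(unlist(as.list(triageRes$systems$members[usable])))),
    candidate_mfs_genes =
      sort(triageRes$calls$gene[triageRes$calls$family == "MFS"]))

  # -- phylo (optional) -----------------------------------------------------
  if (!is.null(config$alignment)) {
    phyloRes <- .stage("phylo", {
      aln <- Biostrings::readAAStringSet(config$alignment)
      names(aln) <- sub(" .*", "", names(aln))
      dm <- poissonDistance(aln)
      tr <- bootstrapSupport(aln, nReplicates = config$bootstrapReplicates,
                             seed = config$seed)
      reps <- pickRepresentatives(tr, min(config$kClades,
                                          length(tr$tip.label)),
                                  anchors = intersect(config$anchors,
                                                      tr$tip.label))
      ape::write.tree(tr, file.path(config$outDir, "nj_tree.nwk"))
      utils::write.table(
        data.frame(taxon = rownames(as.matrix(dm)), as.matrix(dm),
                   check.names = FALSE),
        file.path(config$outDir, "poisson_distances.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      list(dm = dm, tree = tr, reps = reps)
    })
    report$stages$phylo <- list(
      n_taxa = length(phyloRes$tree$tip.label),
      used_sites = usedSites(phyloRes$dm),
      dropped_replicates = attr(phyloRes$tree, "droppedReplicates"),
      representatives = as.character(phyloRes$reps))
  } else {
    logw("phylo", "no alignment configured; phylogenetic stage skipped")
    report$stages$phylo <- list(skipped = TRUE)
    phyloRes <- NULL
  }

  # -- design ---------------------------------------------------------------
  designRes <- .stage("design", {
    genome <- Biostrings::readDNAStringSet(config$genome)
    names(genome) <- sub(" .*", "", names(genome))
    clus <- clusterTemporalPromoters(
      screenRes$es, screenRes$pp, cutHeight = config$cutHeight,
      ratioMin = config$ratioMin, lowQuantile = config$lowQuantile)
    if (length(clus$selected) < config$nPromoters)
      stop("only ", length(clus$selected), " temporal promoter candidates; ",
           config$nPromoters, " required")
    strengths <- fpkm(screenRes$es)[clus$selected, ncol(fpkm(screenRes$es))]
    grad <- selectStrengthGradient(strengths, config$nPromoters)
    promoters <- character(0)
    for (g in grad$gene) {
      p <- withCallingHandlers(
        extractPromoter(genome, screenRes$ann, g,
                        length = config$promoterLength),
        warning = function(w) {
          logw("design", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      promoters[[g]] <- as.character(p)
    }
    rbsPath <- if (!is.null(config$rbs)) config$rbs else
      system.file("extdata", "rbs_library_synthetic.tsv",
                  package = "TuppeMiner")
    rbs <- readRbsTsv(rbsPath)
    # exporters: complete(d) ABC systems, members cloned as one operonic
    # fragment each
    sys <- triageRes$systems
    use <- which(sys$completeness != "incomplete")
    exporters <- character(0)
    for (k in use) {
      ids <- sort(as.list(sys$members)[[k]])
      seq <- tryCatch(
        as.character(extractExporterRegion(genome, screenRes$ann, ids)),
        error = function(e) { logw("design", conditionMessage(e)); NULL })
      if (!is.null(seq)) exporters[[sys$system_id[k]]] <- seq
    }
    if (length(exporters) == 0) stop("no usable exporter regions")
    lib <- enumerateLibrary(promoters, rbs, exporters)
    writeTuppeFasta(lib, file.path(config$outDir, "tuppe_library.fasta"))
    utils::write.table(
      data.frame(
        construct = vapply(constructs(lib), methods::slot, character(1),
                           "constructId"),
        promoter = vapply(constructs(lib), methods::slot, character(1),
                          "promoterId"),
        rbs = vapply(constructs(lib), methods::slot, character(1), "rbsId"),
        exporter = vapply(constructs(lib), methods::slot, character(1),
                          "exporterId"),
        length_bp = vapply(constructs(lib), function(con)
          length(cassetteSeq(con)), integer(1))),
      file.path(config$outDir, "tuppe_manifest.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(clus = clus, grad = grad, lib = lib)
  })
  report$stages$design <- list(
    n_temporal_candidates = length(designRes$clus$selected),
    gradient = designRes$grad$gene,
    n_constructs = length(designRes$lib),
    n_failures = nrow(failures(designRes$lib)))

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  writeLines(json, file.path(config$outDir, "report.json"))
  invisible(report)
}
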