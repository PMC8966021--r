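#' @include AllClasses.R utils.R
NULL

#' Read and write expression, production, RBS and result tables
#'
#' The on-disk dialects are plain TSV: expression tables have a `gene_id`
#' column plus one column per timepoint labelled by day; production tables
#' have `day` and `titer_mg_per_l`; RBS libraries have `name` and
#' `sequence` (empty sequence allowed for a native-RBS placeholder).
#'
#' @param path File path.
#' @return `readExpressionTsv` an [ExpressionSeries-class];
#'   `readProductionTsv` a [ProductionProfile-class]; `readRbsTsv` a named
#'   character vector of RBS sequences.
#' @name tuppe-io
NULL

#' @rdname tuppe-io
#' @export
readExpressionTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  if (nrow(df) == 0) stop("expression table is empty: ", path)
  if (!"gene_id" %in% colnames(df))
    stop("expression table must have a 'gene_id' column")
  days <- suppressWarnings(as.numeric(setdiff(colnames(df), "gene_id")))
  if (anyNA(days))
    stop("expression column names other than gene_id must be numeric days")
  m <- as.matrix(df[, setdiff(colnames(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  ExpressionSeries(m[, order(days), drop = FALSE], sort(days))
}

#' @rdname tuppe-io
#' @param x Object to write.
#' @export
writeExpressionTsv <- function(x, path) {
  stopifnot(is(x, "ExpressionSeries"))
  df <- data.frame(gene_id = geneIds(x), fpkm(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", as.character(sampleDays(x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tuppe-io
#' @export
readProductionTsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  if (!all(c("day", "titer_mg_per_l") %in% colnames(df)))
    stop("production table must have 'day' and 'titer_mg_per_l' columns")
  ProductionProfile(df$day, df$titer_mg_per_l)
}

#' @rdname tuppe-io
#' @export
writeProductionTsv <- function(x, path) {
  stopifnot(is(x, "ProductionProfile"))
  utils::write.table(
    data.frame(day = sampleDays(x), titer_mg_per_l = titer(x)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tuppe-io
#' @export
readRbsTsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = "character")
  if (!all(c("name", "sequence") %in% colnames(df)))
    stop("RBS table must have 'name' and 'sequence' columns")
  stats::setNames(toupper(df$sequence), df$name)
}

#' Write a ground-truth table for test harnesses
#'
#' Long-format TSV of everything the synthetic-data generator planted:
#' one row per (category, gene) with optional system/role/completeness or
#' family columns.
#'
#' @param groundTruth The `groundTruth` list of [simulateBundle()],
#'   [simulateGenome()] or [simulateExpression()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeGroundTruthTsv <- function(groundTruth, path) {
  rows <- list()
  add <- function(category, gene, system_id = "", role = "",
                  completeness = "", family = "") {
    if (length(gene))
      rows[[length(rows) + 1L]] <<- data.frame(
        category = category, gene = gene, system_id = system_id,
        role = role, completeness = completeness, family = family,
        stringsAsFactors = FALSE)
  }
  add("planted_correlated", groundTruth$plantedCorrelated)
  add("planted_temporal_promoter", groundTruth$plantedTemporal)
  if (!is.null(groundTruth$abcSystems)) {
    s <- groundTruth$abcSystems
    add("abc_system", s$gene, system_id = s$system_id, role = s$role,
        completeness = s$completeness)
  }
  if (!is.null(groundTruth$familyLabels)) {
    f <- groundTruth$familyLabels
    add("family_label", f$gene, family = f$family)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(), gene = character(),
               system_id = character(), role = character(),
               completeness = character(), family = character())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated bundle to a directory
#'
#' Emits the full plain-text input set for a pipeline run: genome FASTA,
#' GFF3 annotation, protein FASTA, expression and production TSVs and the
#' ground-truth TSV. Output is byte-identical for a fixed configuration.
#'
#' @param bundle A [simulateBundle()] result.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fasta"),
    gff = file.path(dir, "annotation.gff3"),
    proteins = file.path(dir, "proteins.faa"),
    expression = file.path(dir, "expression.tsv"),
    production = file.path(dir, "production.tsv"),
    groundTruth = file.path(dir, "ground_truth.tsv"))
  Biostrings::writeXStringSet(bundle$genome$genome, paths[["genome"]])
  rtracklayer::export(bundle$genome$annotation, paths[["gff"]],
                      format = "gff3")
  Biostrings::writeXStringSet(bundle$genome$proteins, paths[["proteins"]])
  writeExpressionTsv(bundle$expression, paths[["expression"]])
  writeProductionTsv(bundle$production, paths[["production"]])
  writeGroundTruthTsv(bundle$groundTruth, paths[["groundTruth"]])
  invisible(paths)
}
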