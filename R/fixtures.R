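#' Bundled reference study tables
#'
#' The package ships transcriptions of the summary tables of a published
#' targeted mtDNA resequencing study of 436 haploid samples, used as a
#' reference surface for the annotation and enrichment statistics:
#' \describe{
#'   \item{gene model}{the 15 non-tRNA mitochondrial genes with standard
#'     rCRS heavy-strand coordinates and strands, and the study's reported
#'     gene lengths carried verbatim in `length` (the reported lengths run
#'     one bp above the coordinate spans; they are reproduced, not
#'     recomputed, because they are the enrichment denominators).}
#'   \item{enrichment}{the per-gene distinct-variant counts and the
#'     reported \eqn{r_g} (variants/Mb) and \eqn{r_w} columns.}
#'   \item{deleterious}{the 24 variants called deleterious by SIFT and
#'     probably damaging by PolyPhen, with codon and amino-acid changes.}
#'   \item{unknown}{the 35 variants absent from the MITOMAP catalog
#'     (32 substitutions, 3 indels).}
#'   \item{catalog}{exactly the variant keys the study tables mark as
#'     catalog-Known (a stand-in for a MITOMAP extract).}
#'   \item{conserved, predictions, rsids}{the conservation flags,
#'     SIFT/PolyPhen categories and rsIDs printed in those tables.}
#' }
#'
#' @name studyFixture
#' @return `studyFixtureFiles()` returns a named character vector of file
#'   paths; the loaders return the parsed objects.
NULL

#' @rdname studyFixture
#' @export
studyFixtureFiles <- function() {
  files <- c(genes = "study_genes.tsv", enrichment = "study_enrichment.tsv",
             deleterious = "study_deleterious.tsv",
             unknown = "study_unknown.tsv", catalog = "study_catalog.tsv",
             conserved = "study_conserved.txt",
             predictions = "study_predictions.tsv",
             rsids = "study_rsids.tsv")
  vapply(files, function(f)
    system.file("extdata", f, package = "mitovar", mustWork = TRUE), "")
}

#' @rdname studyFixture
#' @export
studyGeneModel <- function() {
  genome <- mitoGenome("rCRS", length = 16569L, circular = TRUE)
  loadGeneModel(studyFixtureFiles()[["genes"]], genome)
}

#' @rdname studyFixture
#' @export
studyEnrichmentInputs <- function() {
  tab <- .readTsv(studyFixtureFiles()[["enrichment"]], "enrichment fixture")
  tab$length <- as.integer(tab$length)
  tab$n_variants <- as.integer(tab$n_variants)
  tab
}

#' @rdname studyFixture
#' @export
studyDeleteriousVariants <- function() {
  tab <- .readTsv(studyFixtureFiles()[["deleterious"]], "variant fixture")
  tab$position <- as.integer(tab$position)
  tab$carrier_count <- as.integer(tab$carrier_count)
  tab
}

#' @rdname studyFixture
#' @export
studyUnknownVariants <- function() {
  tab <- .readTsv(studyFixtureFiles()[["unknown"]], "variant fixture")
  tab$position <- as.integer(tab$position)
  tab
}

#' @rdname studyFixture
#' @export
studyCatalog <- function() readCatalog(studyFixtureFiles()[["catalog"]])

#' @rdname studyFixture
#' @export
studyConserved <- function()
  readConservedPositions(studyFixtureFiles()[["conserved"]])

#' @rdname studyFixture
#' @export
studyPredictions <- function()
  readPredictions(studyFixtureFiles()[["predictions"]])

#' @rdname studyFixture
#' @export
studyRsids <- function() readRsids(studyFixtureFiles()[["rsids"]])

#' Deduplicated union of the two study variant lists
#'
#' Merges the deleterious-concordant list (24 variants) and the
#' catalog-Unknown list (35 variants) on the variant key; the two keys
#' present in both lists are kept once, giving 57 distinct variants with
#' their carrier counts (1 for unknown-list-only variants except the one
#' reported twice).
#'
#' @return aggregated-variant-style data.frame (`position`, `ref`, `alt`,
#'   `carrier_count`) ready for [annotateVariants()].
#' @export
studyVariantUnion <- function() {
  del <- studyDeleteriousVariants()
  unk <- studyUnknownVariants()
  key <- function(d) paste(d$position, d$ref, d$alt, sep = ":")
  extra <- unk[!key(unk) %in% key(del), , drop = FALSE]
  out <- rbind(
    del[, c("position", "ref", "alt", "carrier_count")],
    data.frame(position = extra$position, ref = extra$ref, alt = extra$alt,
               carrier_count = extra$carrier_count,
               stringsAsFactors = FALSE))
  out <- out[order(out$position, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Copy the bundled study fixture into a directory
#'
#' @param dir target directory (created if needed).
#' @return named vector of the copied paths, invisibly.
#' @export
writeStudyFixture <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  src <- studyFixtureFiles()
  dst <- file.path(dir, basename(src))
  names(dst) <- names(src)
  file.copy(src, dst, overwrite = TRUE)
  invisible(dst)
}
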