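#' @title Core classes for mitochondrial variant analysis
#' @name mitovar-classes
#' @description S4 containers for the circular mitochondrial genome, its gene
#'   model, and per-gene enrichment results. Per-sample calls and study-wide
#'   variants are carried as plain data.frames with documented schemas (see
#'   [readVcfCalls()] and [aggregateCalls()]).
NULL

.BIOTYPES <- c("protein_coding", "Mt_rRNA", "Mt_tRNA", "other")
.GENOTYPE_CLASSES <- c("hom_ref", "het", "hom_alt", "missing")
.FILTER_REASONS <- c("het_genotype", "strand_imbalance", "no_alt_support",
                     "missing_genotype", "pass")
.EFFECTS <- c("synonymous", "missense", "nonsense", "stop_loss",
              "non_coding", "intergenic", "frameshift_candidate")
.SIFT_LEVELS <- c("deleterious", "tolerated")
.POLYPHEN_LEVELS <- c("probably_damaging", "possibly_damaging", "benign")

.CALL_COLS <- c("sample_id", "position", "ref", "alt", "genotype_class",
                "alt_fwd", "alt_rev", "depth")
.GENE_COLS <- c("symbol", "biotype", "start", "end", "strand", "length")

#' MitoGenome: a (usually circular) mitochondrial reference genome
#'
#' Holds the genome name, its length in bp, circularity, and optionally the
#' heavy-strand nucleotide sequence. All coordinates in the package are
#' 1-based, fully inclusive, on the heavy strand.
#'
#' @slot name character(1) genome identifier.
#' @slot length integer(1) genome length in bp.
#' @slot circular logical(1) whether coordinates wrap past `length`.
#' @slot sequence character(1) nucleotide sequence (A/C/G/T/N) of exactly
#'   `length` characters, or `NA` when no sequence is attached.
#'
#' @exportClass MitoGenome
setClass("MitoGenome",
  representation(name = "character", length = "integer",
                 circular = "logical", sequence = "character"),
  prototype(name = "mt", length = 1L, circular = TRUE,
            sequence = NA_character_))

setValidity("MitoGenome", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a non-empty string")
  if (length(object@length) != 1L || is.na(object@length) || object@length < 1L)
    msg <- c(msg, "'length' must be a positive integer")
  if (length(object@circular) != 1L || is.na(object@circular))
    msg <- c(msg, "'circular' must be TRUE or FALSE")
  if (length(object@sequence) != 1L)
    msg <- c(msg, "'sequence' must be a single string or NA")
  else if (!is.na(object@sequence)) {
    if (nchar(object@sequence) != object@length)
      msg <- c(msg, sprintf("sequence has %d characters but length is %d",
                            nchar(object@sequence), object@length))
    if (grepl("[^ACGTN]", object@sequence))
      msg <- c(msg, "sequence may only contain A/C/G/T/N")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MitoGenome
#'
#' @param name genome identifier.
#' @param length genome length in bp; may be omitted when `sequence` is given.
#' @param circular logical; mitochondrial genomes are circular (default).
#' @param sequence optional nucleotide string (or `Biostrings::DNAString`);
#'   upper-cased on input.
#' @return A [MitoGenome-class] object.
#' @examples
#' mitoGenome("toy", sequence = "ACGTACGTACGT")
#' @export
mitoGenome <- function(name, length = NULL, circular = TRUE, sequence = NULL) {
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (is.null(length)) length <- nchar(sequence)
  } else {
    sequence <- NA_character_
  }
  if (is.null(length))
    stop("either 'length' or 'sequence' must be supplied")
  new("MitoGenome", name = as.character(name), length = as.integer(length),
      circular = as.logical(circular), sequence = sequence)
}

#' MitoGeneModel: gene annotation of a mitochondrial genome
#'
#' An ordered collection of gene records over a [MitoGenome-class].
#' Overlapping genes are permitted (mtDNA has overlapping ORFs) and a gene
#' whose `end < start` spans the circular origin. The `length` column is the
#' *reported* gene length used as the enrichment denominator; it is carried
#' verbatim from the input table and never recomputed from coordinates (the
#' two may disagree; the coordinate span is used only for interval logic).
#'
#' @slot genome a [MitoGenome-class].
#' @slot genes data.frame with columns `symbol`, `biotype`
#'   (protein_coding/Mt_rRNA/Mt_tRNA/other), `start`, `end`, `strand`
#'   (`+`/`-`), `length` (reported length, bp).
#'
#' @exportClass MitoGeneModel
setClass("MitoGeneModel",
  representation(genome = "MitoGenome", genes = "data.frame"))

setValidity("MitoGeneModel", function(object) {
  g <- object@genes
  msg <- character()
  missing_cols <- setdiff(.GENE_COLS, names(g))
  if (length(missing_cols))
    return(paste("gene table lacks columns:",
                 paste(missing_cols, collapse = ", ")))
  if (nrow(g)) {
    if (anyDuplicated(g$symbol))
      msg <- c(msg, "gene symbols must be unique")
    if (!all(g$biotype %in% .BIOTYPES))
      msg <- c(msg, paste("biotype must be one of",
                          paste(.BIOTYPES, collapse = "/")))
    if (!all(g$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    L <- object@genome@length
    bad <- g$start < 1L | g$start > L | g$end < 1L | g$end > L
    if (any(bad))
      msg <- c(msg, sprintf("gene(s) %s have coordinates outside 1..%d",
                            paste(g$symbol[bad], collapse = ", "), L))
    if (any(g$length <= 0L))
      msg <- c(msg, "reported gene length must be positive")
    if (!object@genome@circular && any(g$end < g$start))
      msg <- c(msg, "end < start requires a circular genome")
  }
  if (length(msg)) msg else TRUE
})

#' EnrichmentReport: per-gene variant-enrichment results
#'
#' One row per included gene with the distinct-variant count \eqn{N_x}, the
#' carrier sum \eqn{\sum_i n_i}, the global enrichment rate
#' \eqn{r_g = N_x / l_x \times 1000} (variants/Mb) and the weighted rate
#' \eqn{r_w = \sum_i n_i / l_x} (optionally \eqn{\times 1000}), plus the
#' report-level means, Shapiro-Wilk normality test of \eqn{r_g}, and the
#' conventions used.
#'
#' @slot rows data.frame with columns `gene`, `biotype`, `length`,
#'   `n_variants`, `carrier_sum`, `r_g`, `r_w`, `percentile`.
#' @slot meanRg,meanRw numeric(1) arithmetic means over included rows.
#' @slot shapiroW,shapiroP numeric(1) Shapiro-Wilk statistic and p-value for
#'   the `r_g` column (`NA` when fewer than 3 rows or degenerate).
#' @slot excludedBiotypes character; biotypes left out (default `Mt_tRNA`).
#' @slot rwScale character(1), `"per_bp"` or `"per_Mb"`.
#' @slot percentileMethod character(1), see [percentilePosition()].
#'
#' @exportClass EnrichmentReport
setClass("EnrichmentReport",
  representation(rows = "data.frame", meanRg = "numeric", meanRw = "numeric",
                 shapiroW = "numeric", shapiroP = "numeric",
                 excludedBiotypes = "character", rwScale = "character",
                 percentileMethod = "character"))

setValidity("EnrichmentReport", function(object) {
  need <- c("gene", "biotype", "length", "n_variants", "carrier_sum",
            "r_g", "r_w", "percentile")
  missing_cols <- setdiff(need, names(object@rows))
  if (length(missing_cols))
    return(paste("rows lack columns:", paste(missing_cols, collapse = ", ")))
  r <- object@rows
  if (nrow(r)) {
    if (any(r$n_variants == 0L & (r$r_g != 0 | r$carrier_sum != 0)))
      return("a gene with zero variants must have r_g = 0 and carrier_sum = 0")
    if (any(r$n_variants > 0L & r$carrier_sum < r$n_variants))
      return("carrier_sum must be >= n_variants (each variant has >= 1 carrier)")
  }
  if (!object@rwScale %in% c("per_bp", "per_Mb"))
    return("rwScale must be 'per_bp' or 'per_Mb'")
  TRUE
})
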