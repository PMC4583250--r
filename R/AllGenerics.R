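#' @name mitovar-accessors
#' @title Accessors for mitovar classes
#' @param x a mitovar object.
#' @description Slot access goes through these accessors, never through `@`.
NULL

#' @rdname mitovar-accessors
#' @export
setGeneric("genomeName", function(x) standardGeneric("genomeName"))
#' @rdname mitovar-accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname mitovar-accessors
#' @export
setGeneric("genomeCircular", function(x) standardGeneric("genomeCircular"))
#' @rdname mitovar-accessors
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))
#' @rdname mitovar-accessors
#' @export
setGeneric("hasSequence", function(x) standardGeneric("hasSequence"))
#' @rdname mitovar-accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname mitovar-accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))
#' @rdname mitovar-accessors
#' @export
setGeneric("modelGenome", function(x) standardGeneric("modelGenome"))
#' @rdname mitovar-accessors
#' @export
setGeneric("enrichmentRows", function(x) standardGeneric("enrichmentRows"))
#' @rdname mitovar-accessors
#' @export
setGeneric("rwScale", function(x) standardGeneric("rwScale"))

#' @rdname mitovar-accessors
setMethod("genomeName", "MitoGenome", function(x) x@name)
#' @rdname mitovar-accessors
setMethod("genomeLength", "MitoGenome", function(x) x@length)
#' @rdname mitovar-accessors
setMethod("genomeCircular", "MitoGenome", function(x) x@circular)
#' @rdname mitovar-accessors
setMethod("genomeSequence", "MitoGenome", function(x) x@sequence)
#' @rdname mitovar-accessors
setMethod("hasSequence", "MitoGenome", function(x) !is.na(x@sequence))

#' @rdname mitovar-accessors
setMethod("geneTable", "MitoGeneModel", function(x) x@genes)
#' @rdname mitovar-accessors
setMethod("geneSymbols", "MitoGeneModel", function(x) x@genes$symbol)
#' @rdname mitovar-accessors
setMethod("modelGenome", "MitoGeneModel", function(x) x@genome)
#' @rdname mitovar-accessors
setMethod("genomeLength", "MitoGeneModel", function(x) x@genome@length)
#' @rdname mitovar-accessors
setMethod("hasSequence", "MitoGeneModel", function(x) hasSequence(x@genome))

#' @rdname mitovar-accessors
setMethod("enrichmentRows", "EnrichmentReport", function(x) x@rows)
#' @rdname mitovar-accessors
setMethod("rwScale", "EnrichmentReport", function(x) x@rwScale)

setMethod("show", "MitoGenome", function(object) {
  cat(sprintf("MitoGenome '%s': %d bp, %s%s\n", object@name, object@length,
              if (object@circular) "circular" else "linear",
              if (hasSequence(object)) ", with sequence" else ""))
})

setMethod("show", "MitoGeneModel", function(object) {
  g <- object@genes
  cat(sprintf("MitoGeneModel on '%s' (%d bp): %d gene(s)\n",
              object@genome@name, object@genome@length, nrow(g)))
  if (nrow(g)) {
    tab <- table(g$biotype)
    cat("  ", paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                    collapse = ", "), "\n", sep = "")
  }
})

setMethod("show", "EnrichmentReport", function(object) {
  cat(sprintf(
    "EnrichmentReport: %d gene(s); mean r_g = %.1f variants/Mb, mean r_w = %.2f (%s)\n",
    nrow(object@rows), object@meanRg, object@meanRw, object@rwScale))
  if (!is.na(object@shapiroP))
    cat(sprintf("  Shapiro-Wilk on r_g: W = %.4f, p = %.4f\n",
                object@shapiroW, object@shapiroP))
  if (length(object@excludedBiotypes))
    cat("  excluded biotypes:",
        paste(object@excludedBiotypes, collapse = ", "), "\n")
})
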