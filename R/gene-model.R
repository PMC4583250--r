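#' Build a gene model from a data.frame
#'
#' @param genes data.frame with columns `symbol`, `biotype`, `start`, `end`,
#'   `strand`, `length`. `length` is the reported gene length used as the
#'   enrichment denominator and is taken verbatim, never recomputed from the
#'   coordinates. A record with `end < start` spans the circular origin.
#' @param genome a [MitoGenome-class].
#' @return A [MitoGeneModel-class].
#' @examples
#' g <- mitoGenome("toy", 2000)
#' geneModel(data.frame(symbol = "G1", biotype = "protein_coding",
#'                      start = 101, end = 400, strand = "+", length = 300),
#'           g)
#' @export
geneModel <- function(genes, genome) {
  stopifnot(is(genome, "MitoGenome"))
  if (nrow(genes)) {
    genes$symbol <- as.character(genes$symbol)
    genes$biotype <- as.character(genes$biotype)
    genes$strand <- as.character(genes$strand)
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
    genes$length <- as.integer(genes$length)
  } else {
    genes <- data.frame(symbol = character(), biotype = character(),
                        start = integer(), end = integer(),
                        strand = character(), length = integer(),
                        stringsAsFactors = FALSE)
  }
  rownames(genes) <- NULL
  new("MitoGeneModel", genome = genome, genes = genes[, .GENE_COLS])
}

#' Load a gene model from a tab-separated file
#'
#' The file must have a header line `symbol biotype start end strand length`
#' (tab-separated; lines starting with `#` are ignored). Positions are
#' 1-based inclusive heavy-strand coordinates; `length` is the reported gene
#' length in bp used by the enrichment statistics.
#'
#' @param path path to the TSV file.
#' @param genome a [MitoGenome-class] the coordinates refer to.
#' @return A [MitoGeneModel-class].
#' @export
loadGeneModel <- function(path, genome) {
  tab <- .readTsv(path, "gene model")
  .assertCols(tab, .GENE_COLS, sprintf("gene table '%s'", path))
  for (col in c("start", "end", "length")) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad))
      stop(sprintf("gene table '%s': non-integer '%s' on data line %d",
                   path, col, bad[1]), call. = FALSE)
    if (anyNA(v))
      stop(sprintf("gene table '%s': missing '%s' on data line %d",
                   path, col, which(is.na(v))[1]), call. = FALSE)
    tab[[col]] <- v
  }
  geneModel(tab, genome)
}

# logical matrix-free containment test: which genes cover a single position
.geneCovers <- function(genes, position) {
  s <- genes$start
  e <- genes$end
  ifelse(s <= e, position >= s & position <= e,
         position >= s | position <= e)   # spans circular origin
}

#' Locate the gene(s) covering a position
#'
#' Returns every gene whose interval contains the position, honouring
#' circular wrap-around for genes with `end < start`. mtDNA genes overlap, so
#' more than one record can be returned; zero rows means intergenic.
#'
#' @param model a [MitoGeneModel-class].
#' @param position 1-based position (scalar).
#' @return data.frame of gene records (possibly zero rows).
#' @export
locateGenes <- function(model, position) {
  stopifnot(is(model, "MitoGeneModel"), length(position) == 1L)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > genomeLength(model))
    stop(sprintf("position %s outside 1..%d", position, genomeLength(model)),
         call. = FALSE)
  genes <- geneTable(model)
  if (!nrow(genes)) return(genes)
  out <- genes[.geneCovers(genes, position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# vectorised gene assignment: list of symbol vectors, one per position
.genesAtPositions <- function(model, positions) {
  genes <- geneTable(model)
  L <- genomeLength(model)
  positions <- as.integer(positions)
  if (any(is.na(positions) | positions < 1L | positions > L))
    stop(sprintf("position outside 1..%d", L), call. = FALSE)
  if (!nrow(genes)) return(rep(list(character()), length(positions)))
  lapply(positions, function(p) genes$symbol[.geneCovers(genes, p)])
}

# coordinate-derived span of each gene (bp), honouring circular wrap
.geneSpan <- function(model) {
  g <- geneTable(model)
  L <- genomeLength(model)
  ifelse(g$end >= g$start, g$end - g$start + 1L, L - g$start + 1L + g$end)
}
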