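#' Classify a variant by allele shape
#'
#' Single-base equal-length alleles are substitutions; `ref` a strict prefix
#' of `alt` is an insertion; `alt` a strict prefix of `ref` a deletion;
#' anything else (multi-base replacements) is `complex`.
#'
#' @param ref,alt allele strings (vectorised).
#' @return character vector in
#'   `substitution`/`insertion`/`deletion`/`complex`.
#' @examples
#' classifyVariantType(c("C", "T", "GA"), c("A", "TA", "G"))
#' @export
classifyVariantType <- function(ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  .checkAlleles(ref, alt)
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr == 1L & na == 1L, "substitution",
    ifelse(nr < na & substr(alt, 1L, nr) == ref, "insertion",
      ifelse(na < nr & substr(ref, 1L, na) == alt, "deletion", "complex")))
}

#' Known-variant catalog status
#'
#' @param position,ref,alt variant key fields (vectorised).
#' @param catalog data.frame of known keys from [readCatalog()], or `NULL`
#'   (everything `Unknown`).
#' @return character vector, `"Known"` or `"Unknown"`.
#' @export
mitomapStatus <- function(position, ref, alt, catalog) {
  if (is.null(catalog) || !nrow(catalog))
    return(rep("Unknown", length(position)))
  .assertCols(catalog, c("position", "ref", "alt"), "catalog")
  key <- paste(position, toupper(ref), toupper(alt), sep = ":")
  known <- paste(catalog$position, toupper(catalog$ref),
                 toupper(catalog$alt), sep = ":")
  ifelse(key %in% known, "Known", "Unknown")
}

#' Translate a codon
#'
#' @param codon 3-letter nucleotide string(s) over A/C/G/T (case ignored).
#' @param code `"vertebrate_mitochondrial"` (NCBI translation table 2:
#'   ATA>Met, TGA>Trp, AGA/AGG>stop) or `"standard"` (table 1).
#' @return one-letter amino-acid code(s); `*` for stop.
#' @examples
#' translateCodon(c("ATA", "TGA", "AGA"))   # "M" "W" "*"
#' @export
translateCodon <- function(codon, code = c("vertebrate_mitochondrial",
                                           "standard")) {
  code <- match.arg(code)
  codon <- toupper(as.character(codon))
  if (any(nchar(codon) != 3L) || any(grepl("[^ACGT]", codon)))
    stop("codons must be 3 unambiguous bases (A/C/G/T)", call. = FALSE)
  tbl <- Biostrings::getGeneticCode(if (code == "standard") "1" else "2")
  unname(tbl[codon])
}

#' Codon and amino-acid change of a coding substitution
#'
#' Extracts the codon containing the variant on the gene's coding strand
#' (reverse-complementing heavy-strand bases for strand `-` genes),
#' substitutes the alternate base, and translates both codons under the
#' vertebrate mitochondrial code. Codons are rendered lowercase with the
#' altered base uppercase in both (`"Cta/Ata"` style). The reading frame is
#' anchored at the gene's coding-strand start; for genes spanning the
#' circular origin the frame wraps with the genome.
#'
#' @param position heavy-strand 1-based position of the substitution.
#' @param ref,alt single-base heavy-strand alleles.
#' @param geneSymbol symbol of the protein-coding gene to annotate against.
#' @param model [MitoGeneModel-class] whose genome carries a sequence.
#' @return list with `codon_change`, `aa_change` (`"X/Y"`), and `effect`
#'   (`synonymous`/`missense`/`nonsense`/`stop_loss`).
#' @export
codonContext <- function(position, ref, alt, geneSymbol, model) {
  stopifnot(is(model, "MitoGeneModel"))
  genome <- modelGenome(model)
  if (!hasSequence(genome))
    stop("genome carries no sequence; codon context unavailable",
         call. = FALSE)
  ref <- toupper(ref); alt <- toupper(alt)
  .checkAlleles(ref, alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop("codon context is defined for substitutions only", call. = FALSE)
  genes <- geneTable(model)
  gi <- match(geneSymbol, genes$symbol)
  if (is.na(gi))
    stop("unknown gene symbol: ", geneSymbol, call. = FALSE)
  if (genes$biotype[gi] != "protein_coding")
    stop(geneSymbol, " is not protein-coding", call. = FALSE)
  if (!.geneCovers(genes[gi, , drop = FALSE], position))
    stop(sprintf("position %d is outside %s", position, geneSymbol),
         call. = FALSE)
  L <- genomeLength(genome)
  s <- genes$start[gi]; e <- genes$end[gi]; strand <- genes$strand[gi]

  obs <- .basesAt(genome, position)
  if (obs != ref)
    stop(sprintf(
      "reference allele %s at %d does not match genome base %s",
      ref, position, obs), call. = FALSE)

  if (strand == "+") {
    off <- (position - s) %% L          # 0-based offset into the CDS
    wi <- off %% 3L
    codon_pos <- position - wi + 0:2    # heavy-strand, may wrap
    ref_codon <- toupper(paste(.basesAt(genome, codon_pos), collapse = ""))
    alt_codon <- ref_codon
    substr(alt_codon, wi + 1L, wi + 1L) <- alt
  } else {
    off <- (e - position) %% L
    wi <- off %% 3L
    codon_pos <- position + wi - 0:2    # heavy-strand, coding order
    heavy <- toupper(paste(.basesAt(genome, codon_pos), collapse = ""))
    ref_codon <- .complement(heavy)
    alt_codon <- ref_codon
    substr(alt_codon, wi + 1L, wi + 1L) <- .complement(alt)
  }
  aa_ref <- translateCodon(ref_codon)
  aa_alt <- translateCodon(alt_codon)
  effect <- if (aa_ref == aa_alt) "synonymous"
            else if (aa_alt == "*") "nonsense"
            else if (aa_ref == "*") "stop_loss"
            else "missense"
  render <- function(codon) {
    x <- tolower(codon)
    substr(x, wi + 1L, wi + 1L) <- toupper(substr(codon, wi + 1L, wi + 1L))
    x
  }
  list(codon_change = paste(render(ref_codon), render(alt_codon), sep = "/"),
       aa_change = paste(aa_ref, aa_alt, sep = "/"),
       effect = effect)
}

#' Conservation flag
#'
#' @param position position(s) to test.
#' @param conserved integer vector of conserved positions (possibly empty or
#'   `NULL`).
#' @return logical vector.
#' @export
conservationFlag <- function(position, conserved) {
  if (is.null(conserved)) conserved <- integer()
  as.integer(position) %in% as.integer(conserved)
}

#' Predictor-concordance filter
#'
#' Keeps variants called damaging by both predictors: SIFT `deleterious`
#' AND PolyPhen `probably_damaging`. `NA` in either field excludes.
#'
#' @param annotated data.frame with `sift` and `polyphen` columns.
#' @return the concordant subset (same columns).
#' @export
concordanceFilter <- function(annotated) {
  .assertCols(annotated, c("sift", "polyphen"), "annotated variants")
  keep <- !is.na(annotated$sift) & annotated$sift == "deleterious" &
          !is.na(annotated$polyphen) & annotated$polyphen == "probably_damaging"
  out <- annotated[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# logical per-position homopolymer mask over the whole genome:
# TRUE inside or immediately adjacent to a run of >= minRun identical bases
.homopolymerMask <- function(genome, minRun = 4L) {
  stopifnot(hasSequence(genome))
  L <- genomeLength(genome)
  chars <- strsplit(genomeSequence(genome), "")[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  len <- r$lengths
  # a circular genome may carry one run across the origin
  joined <- genomeCircular(genome) && length(r$lengths) > 1L &&
    r$values[1L] == r$values[length(r$values)]
  mask <- logical(L)
  for (k in seq_along(len)) {
    lk <- len[k]
    if (joined && k == 1L) next                     # handled with last run
    if (joined && k == length(len)) lk <- lk + len[1L]
    if (lk < minRun) next
    span <- if (joined && k == length(len))
      c(seq.int(starts[k], L), seq_len(len[1L])) else seq.int(starts[k], ends[k])
    span <- c(span, span[1L] - 1L, span[length(span)] + 1L)   # adjacency
    span <- if (genomeCircular(genome)) .wrapPos(span, L)
            else span[span >= 1L & span <= L]
    mask[span] <- TRUE
  }
  mask
}

#' Homopolymer-context flag
#'
#' Semiconductor sequencing is indel-error-prone in homopolymeric tracts.
#' A position is flagged when it lies within, or immediately adjacent to, a
#' run of at least `minRun` identical bases (runs may span the circular
#' origin).
#'
#' @param position position(s) to test.
#' @param genome [MitoGenome-class] with sequence.
#' @param minRun minimum run length (default 4, i.e. tracts longer than 3).
#' @return logical vector.
#' @export
homopolymerFlag <- function(position, genome, minRun = 4L) {
  mask <- .homopolymerMask(genome, minRun)
  position <- as.integer(position)
  if (any(position < 1L | position > genomeLength(genome)))
    stop("position outside the genome", call. = FALSE)
  mask[position]
}

#' Annotate aggregated variants
#'
#' Fills the full annotation bundle for each study-wide variant: overlapping
#' gene symbols (all of them; mtDNA ORFs overlap), region class
#' (`coding_exon` for protein-coding genes, `non_coding_exon` for
#' rRNA/tRNA, `intergenic` otherwise), variant type, catalog status, rsID,
#' conservation, codon/amino-acid change and effect for coding
#' substitutions (computed when the genome carries a sequence; against the
#' first overlapping protein-coding gene in model order), SIFT/PolyPhen
#' categories from the predictions table, and homopolymer context.
#'
#' @param variants data.frame from [aggregateCalls()] (`position`, `ref`,
#'   `alt`, `carrier_count`; `carriers` optional).
#' @param model [MitoGeneModel-class].
#' @param catalog optional data.frame from [readCatalog()].
#' @param conserved optional integer vector from [readConservedPositions()].
#' @param predictions optional data.frame from [readPredictions()].
#' @param rsids optional data.frame from [readRsids()].
#' @return the input data.frame with annotation columns `genes`
#'   (comma-separated symbols, `""` if intergenic), `region_class`,
#'   `variant_type`, `mitomap_status`, `rsid`, `conserved`, `codon_change`,
#'   `aa_change`, `effect`, `sift`, `polyphen`, `homopolymer`.
#' @export
annotateVariants <- function(variants, model, catalog = NULL,
                             conserved = NULL, predictions = NULL,
                             rsids = NULL) {
  stopifnot(is(model, "MitoGeneModel"))
  .assertCols(variants, c("position", "ref", "alt", "carrier_count"),
              "variants")
  out <- variants
  n <- nrow(out)
  if (!n) {
    for (col in c("genes", "region_class", "variant_type", "mitomap_status",
                  "rsid", "codon_change", "aa_change", "effect", "sift",
                  "polyphen"))
      out[[col]] <- character()
    out$conserved <- logical(); out$homopolymer <- logical()
    return(out)
  }
  .checkAlleles(out$ref, out$alt)
  genes <- geneTable(model)
  glist <- .genesAtPositions(model, out$position)
  out$genes <- vapply(glist, paste, "", collapse = ",")
  biolist <- lapply(glist, function(g) genes$biotype[match(g, genes$symbol)])
  out$region_class <- vapply(biolist, function(b) {
    if (!length(b)) "intergenic"
    else if (any(b == "protein_coding")) "coding_exon"
    else "non_coding_exon"
  }, "")
  out$variant_type <- classifyVariantType(out$ref, out$alt)
  out$mitomap_status <- mitomapStatus(out$position, out$ref, out$alt, catalog)
  key <- paste(out$position, out$ref, out$alt, sep = ":")
  out$rsid <- if (!is.null(rsids) && nrow(rsids)) {
    rk <- paste(rsids$position, rsids$ref, rsids$alt, sep = ":")
    as.character(rsids$rsid[match(key, rk)])
  } else rep(NA_character_, n)
  out$conserved <- conservationFlag(out$position, conserved)

  out$codon_change <- rep(NA_character_, n)
  out$aa_change <- rep(NA_character_, n)
  out$effect <- rep(NA_character_, n)
  coding <- out$region_class == "coding_exon"
  out$effect[out$region_class == "intergenic"] <- "intergenic"
  out$effect[out$region_class == "non_coding_exon"] <- "non_coding"
  is_sub <- out$variant_type == "substitution"
  out$effect[coding & !is_sub &
             out$variant_type %in% c("insertion", "deletion")] <-
    "frameshift_candidate"
  if (hasSequence(model)) {
    for (i in which(coding & is_sub)) {
      cg <- glist[[i]][biolist[[i]] == "protein_coding"][1L]
      ctx <- codonContext(out$position[i], out$ref[i], out$alt[i], cg, model)
      out$codon_change[i] <- ctx$codon_change
      out$aa_change[i] <- ctx$aa_change
      out$effect[i] <- ctx$effect
    }
    out$homopolymer <- homopolymerFlag(out$position, modelGenome(model))
  } else {
    out$homopolymer <- rep(NA, n)
  }
  if (!is.null(predictions) && nrow(predictions)) {
    pk <- paste(predictions$position, predictions$ref, predictions$alt,
                sep = ":")
    m <- match(key, pk)
    out$sift <- as.character(predictions$sift[m])
    out$polyphen <- as.character(predictions$polyphen[m])
  } else {
    out$sift <- rep(NA_character_, n)
    out$polyphen <- rep(NA_character_, n)
  }
  out
}
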