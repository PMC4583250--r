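# internal helpers

# run expr under a fixed RNG seed, restoring caller RNG state afterwards
.withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.assertCols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s lacks required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

.checkAlleles <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("alleles must be non-empty", call. = FALSE)
  if (any(grepl("[^ACGT]", ref)) || any(grepl("[^ACGT]", alt)))
    stop("alleles may only contain A/C/G/T", call. = FALSE)
  bad <- ref == alt
  if (any(bad))
    stop("ref and alt alleles must differ", call. = FALSE)
  invisible(NULL)
}

.readTsv <- function(path, what = "table") {
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# 1-based circular position normalisation
.wrapPos <- function(pos, L) ((pos - 1L) %% L) + 1L

# bases of a genome at (possibly wrapped) positions, as characters
.basesAt <- function(genome, pos) {
  L <- genomeLength(genome)
  if (!hasSequence(genome))
    stop("genome carries no sequence", call. = FALSE)
  if (!length(pos)) return(character())
  p <- if (genomeCircular(genome)) .wrapPos(pos, L) else pos
  if (any(p < 1L | p > L))
    stop("position outside the genome", call. = FALSE)
  substring(genomeSequence(genome), p, p)
}

.complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

.revComp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(.complement(s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

.emptyCallFrame <- function() {
  data.frame(sample_id = character(), position = integer(),
             ref = character(), alt = character(),
             genotype_class = character(), alt_fwd = integer(),
             alt_rev = integer(), depth = integer(),
             stringsAsFactors = FALSE)
}

.emptyDecisionFrame <- function() {
  data.frame(sample_id = character(), position = integer(),
             ref = character(), alt = character(),
             passed = logical(), reason = character(),
             stringsAsFactors = FALSE)
}

.validateCalls <- function(calls, what = "calls") {
  .assertCols(calls, .CALL_COLS, what)
  if (!nrow(calls)) return(invisible(calls))
  if (any(calls$alt_fwd < 0L) || any(calls$alt_rev < 0L) ||
      any(calls$depth < 0L))
    stop("read counts must be non-negative", call. = FALSE)
  if (any(calls$alt_fwd + calls$alt_rev > calls$depth))
    stop("alt_fwd + alt_rev must not exceed depth", call. = FALSE)
  if (!all(calls$genotype_class %in% .GENOTYPE_CLASSES))
    stop("unknown genotype_class value", call. = FALSE)
  invisible(calls)
}
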