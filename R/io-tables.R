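#' Read a known-variant catalog (MITOMAP-style)
#'
#' @param path TSV with header columns `position`, `ref`, `alt`. Lines
#'   starting with `#` are ignored; duplicate keys collapse to one.
#' @return data.frame of unique variant keys (`position`, `ref`, `alt`).
#' @export
readCatalog <- function(path) {
  tab <- .readTsv(path, "catalog")
  .assertCols(tab, c("position", "ref", "alt"), sprintf("catalog '%s'", path))
  p <- suppressWarnings(as.integer(tab$position))
  if (anyNA(p))
    stop(sprintf("catalog '%s': non-integer position on data line %d",
                 path, which(is.na(p))[1]), call. = FALSE)
  out <- data.frame(position = p, ref = toupper(as.character(tab$ref)),
                    alt = toupper(as.character(tab$alt)),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Read a conserved-positions file
#'
#' Accepts either a plain list of 1-based positions (one per line) or
#' 3-column BED (0-based half-open intervals, converted to 1-based positions
#' on read). Lines starting with `#` are ignored.
#'
#' @param path input file.
#' @return sorted integer vector of conserved 1-based positions.
#' @export
readConservedPositions <- function(path) {
  if (!file.exists(path))
    stop("conserved-positions file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(integer())
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (all(nf >= 3L)) {                      # BED: chrom start end
    s <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
    e <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
    if (anyNA(s) || anyNA(e))
      stop(sprintf("conserved file '%s': non-integer BED coordinate on line %d",
                   path, which(is.na(s) | is.na(e))[1]), call. = FALSE)
    pos <- unlist(mapply(function(a, b) seq.int(a + 1L, b), s, e,
                         SIMPLIFY = FALSE))
  } else if (all(nf == 1L)) {
    pos <- suppressWarnings(as.integer(vapply(fields, `[`, "", 1L)))
    if (anyNA(pos))
      stop(sprintf("conserved file '%s': non-integer position on line %d",
                   path, which(is.na(pos))[1]), call. = FALSE)
  } else {
    stop(sprintf("conserved file '%s': mixed 1-column and BED lines", path),
         call. = FALSE)
  }
  sort(unique(as.integer(pos)))
}

#' Read a SIFT/PolyPhen prediction table
#'
#' @param path TSV with columns `position`, `ref`, `alt`, `sift`
#'   (`deleterious`/`tolerated`/`NA`), `polyphen`
#'   (`probably_damaging`/`possibly_damaging`/`benign`/`NA`).
#' @return data.frame mapping variant keys to prediction categories.
#' @export
readPredictions <- function(path) {
  tab <- .readTsv(path, "predictions")
  .assertCols(tab, c("position", "ref", "alt", "sift", "polyphen"),
              sprintf("predictions '%s'", path))
  tab$position <- as.integer(tab$position)
  tab$sift <- as.character(tab$sift)
  tab$polyphen <- as.character(tab$polyphen)
  badS <- !is.na(tab$sift) & !tab$sift %in% .SIFT_LEVELS
  badP <- !is.na(tab$polyphen) & !tab$polyphen %in% .POLYPHEN_LEVELS
  if (any(badS))
    stop(sprintf("predictions '%s': unknown SIFT category '%s'",
                 path, tab$sift[badS][1]), call. = FALSE)
  if (any(badP))
    stop(sprintf("predictions '%s': unknown PolyPhen category '%s'",
                 path, tab$polyphen[badP][1]), call. = FALSE)
  tab[, c("position", "ref", "alt", "sift", "polyphen")]
}

#' Read an rsID table
#'
#' @param path TSV with columns `position`, `ref`, `alt`, `rsid`.
#' @return data.frame mapping variant keys to rsIDs.
#' @export
readRsids <- function(path) {
  tab <- .readTsv(path, "rsID table")
  .assertCols(tab, c("position", "ref", "alt", "rsid"),
              sprintf("rsID table '%s'", path))
  tab$position <- as.integer(tab$position)
  tab[, c("position", "ref", "alt", "rsid")]
}

.VT_DISPLAY <- c(Position = "position", Ref = "ref", Alt = "alt",
                 rsID = "rsid", MITOMAP = "mitomap_status",
                 Counts = "carrier_count", Conserved = "conserved",
                 Gene = "genes", CodonChange = "codon_change",
                 AAChange = "aa_change", Effect = "effect", SIFT = "sift",
                 PolyPhen = "polyphen")

#' Write an annotated variant table
#'
#' Writes one row per variant with the canonical display columns
#' `Position Ref Alt rsID MITOMAP Counts Conserved Gene CodonChange AAChange
#' Effect SIFT PolyPhen` (tab-separated, `-` for empty fields).
#'
#' @param annotated data.frame from [annotateVariants()].
#' @param path output path.
#' @return The path, invisibly.
#' @seealso [readVariantTable()] for the inverse.
#' @export
writeVariantTable <- function(annotated, path) {
  n <- nrow(annotated)
  grab <- function(col, default = NA) {
    if (col %in% names(annotated)) annotated[[col]] else rep(default, n)
  }
  out <- data.frame(matrix(nrow = n, ncol = 0))
  for (disp in names(.VT_DISPLAY)) {
    v <- grab(.VT_DISPLAY[[disp]])
    if (disp == "Conserved")
      v <- ifelse(is.na(v), "-", ifelse(as.logical(v), "Yes", "No"))
    v <- as.character(v)
    v[is.na(v) | !nzchar(v)] <- "-"
    out[[disp]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotated variant table written by [writeVariantTable()]
#'
#' @param path input path.
#' @return data.frame with the internal column names (`position`, `ref`,
#'   `alt`, `rsid`, `mitomap_status`, `carrier_count`, `conserved`, `genes`,
#'   `codon_change`, `aa_change`, `effect`, `sift`, `polyphen`); `-` becomes
#'   `NA` (empty string for `genes`).
#' @export
readVariantTable <- function(path) {
  tab <- .readTsv(path, "variant table")
  .assertCols(tab, names(.VT_DISPLAY), sprintf("variant table '%s'", path))
  out <- list()
  for (disp in names(.VT_DISPLAY)) {
    v <- as.character(tab[[disp]])
    v[v == "-"] <- NA_character_
    out[[.VT_DISPLAY[[disp]]]] <- v
  }
  out <- data.frame(out, stringsAsFactors = FALSE)
  out$position <- as.integer(out$position)
  out$carrier_count <- as.integer(out$carrier_count)
  out$conserved <- ifelse(is.na(out$conserved), NA, out$conserved == "Yes")
  out$genes[is.na(out$genes)] <- ""
  out
}
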