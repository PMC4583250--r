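#' Read per-sample variant calls from a VCF file
#'
#' Reads a VCF v4.x whose FORMAT carries `GT` plus the strand-split
#' alternate-allele depths `SAF` (forward) and `SAR` (reverse), one integer
#' per ALT allele (`Number=A`), and optionally `DP` (total depth at the
#' site). Multi-allelic records are decomposed into one call per sample and
#' ALT allele. Haploid (`1`) and diploid-style (`1/1`) genotypes both map to
#' `hom_alt`; mixed genotypes such as `0/1` map to `het`; `./.` maps to
#' `missing` (one call per ALT allele of the record). Samples whose genotype
#' is homozygous reference at a record yield no call.
#'
#' @param path path to a VCF file.
#' @return data.frame of calls with columns `sample_id`, `position`, `ref`,
#'   `alt`, `genotype_class`, `alt_fwd`, `alt_rev`, `depth`.
#' @seealso [writeVcfCalls()] for the inverse; the pair round-trips
#'   field-for-field.
#' @export
readVcfCalls <- function(path) {
  if (!file.exists(path))
    stop("VCF file not found: ", path, call. = FALSE)
  v <- VariantAnnotation::readVcf(path)
  hdr <- rownames(VariantAnnotation::geno(VariantAnnotation::header(v)))
  if (!"GT" %in% hdr)
    stop("VCF lacks the GT FORMAT field: ", path, call. = FALSE)
  if (!all(c("SAF", "SAR") %in% hdr))
    stop("VCF lacks the strand-split alt depth FORMAT fields SAF/SAR: ",
         path, call. = FALSE)
  if (nrow(v) == 0L) return(.emptyCallFrame())

  gt <- VariantAnnotation::geno(v)$GT
  saf <- VariantAnnotation::geno(v)$SAF
  sar <- VariantAnnotation::geno(v)$SAR
  dp <- if ("DP" %in% names(VariantAnnotation::geno(v)))
    VariantAnnotation::geno(v)$DP else NULL
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(v))
  refs <- as.character(VariantAnnotation::ref(v))
  altl <- VariantAnnotation::alt(v)
  alts <- lapply(seq_len(nrow(v)), function(i) as.character(altl[[i]]))
  samples <- colnames(gt)

  # per-ALT FORMAT value (matrix may hold lists when records are multiallelic)
  fmtA <- function(m, i, j, k) {
    x <- if (is.list(m)) m[[i, j]] else m[i, j]
    if (length(x) < k || is.na(x[k]))
      stop(sprintf("record %s:%d lacks a strand depth for ALT allele %d",
                   refs[i], pos[i], k), call. = FALSE)
    as.integer(x[k])
  }

  keep <- !(gt %in% c("0", "0/0", "0|0"))
  dim(keep) <- dim(gt)
  idx <- which(keep, arr.ind = TRUE)
  n_max <- 2L * nrow(idx) + 2L
  o_sample <- character(n_max); o_pos <- integer(n_max)
  o_ref <- character(n_max); o_alt <- character(n_max)
  o_class <- character(n_max); o_fwd <- integer(n_max)
  o_rev <- integer(n_max); o_dp <- integer(n_max)
  n <- 0L
  emit <- function(i, j, k, class) {
    n <<- n + 1L
    if (n > length(o_sample)) {   # grow (rare)
      grow <- function(x) c(x, x)
      o_sample <<- grow(o_sample); o_pos <<- grow(o_pos)
      o_ref <<- grow(o_ref); o_alt <<- grow(o_alt); o_class <<- grow(o_class)
      o_fwd <<- grow(o_fwd); o_rev <<- grow(o_rev); o_dp <<- grow(o_dp)
    }
    fwd <- fmtA(saf, i, j, k); rev <- fmtA(sar, i, j, k)
    d <- if (!is.null(dp) && !is.na(dp[i, j])) as.integer(dp[i, j])
         else fwd + rev
    o_sample[n] <<- samples[j]; o_pos[n] <<- pos[i]
    o_ref[n] <<- refs[i]; o_alt[n] <<- alts[[i]][k]
    o_class[n] <<- class; o_fwd[n] <<- fwd; o_rev[n] <<- rev; o_dp[n] <<- d
  }

  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    gtstr <- gt[i, j]
    al <- if (is.na(gtstr)) "." else strsplit(gtstr, "[/|]")[[1]]
    al <- al[nzchar(al)]
    if (!length(al) || all(al == ".")) {
      for (k in seq_along(alts[[i]])) emit(i, j, k, "missing")
      next
    }
    al <- al[al != "."]
    nz <- unique(al[al != "0"])
    if (!length(nz)) next       # hom_ref written with separators
    all_same <- length(unique(al)) == 1L
    for (a in nz) {
      k <- suppressWarnings(as.integer(a))
      if (is.na(k) || k > length(alts[[i]]))
        stop(sprintf("record %s:%d: GT allele '%s' has no matching ALT",
                     refs[i], pos[i], a), call. = FALSE)
      emit(i, j, k, if (all_same) "hom_alt" else "het")
    }
  }
  out <- data.frame(sample_id = o_sample[seq_len(n)],
                    position = o_pos[seq_len(n)], ref = o_ref[seq_len(n)],
                    alt = o_alt[seq_len(n)],
                    genotype_class = o_class[seq_len(n)],
                    alt_fwd = o_fwd[seq_len(n)], alt_rev = o_rev[seq_len(n)],
                    depth = o_dp[seq_len(n)], stringsAsFactors = FALSE)
  .validateCalls(out, sprintf("VCF '%s'", path))
  out
}

# VCF header of the package dialect: GT/DP plus per-ALT strand depths
.vcfDialectHeader <- function(samples) {
  hdr <- VariantAnnotation::VCFHeader(samples = samples)
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                      row.names = "fileformat"))
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
    Number = c("1", "1", "A", "A"),
    Type = c("String", "Integer", "Integer", "Integer"),
    Description = c("Genotype (haploid; diploid-style accepted on read)",
                    "Total read depth at the site",
                    "Reads supporting the ALT allele on the forward strand",
                    "Reads supporting the ALT allele on the reverse strand"),
    row.names = c("GT", "DP", "SAF", "SAR"))
  hdr
}

#' Write per-sample variant calls to a VCF file
#'
#' Writes the call table produced by [readVcfCalls()] (or by the simulator)
#' as a VCF v4.2 with per-sample FORMAT fields `GT`, `DP`, `SAF`, `SAR`
#' (`SAF`/`SAR` declared `Number=A`, one integer per ALT allele). Haploid
#' genotypes are written as single-allele GT (`1`); `het` calls as `0/i`;
#' `missing` as `.`; samples without a call at a record as `0`.
#' `readVcfCalls(writeVcfCalls(x))` reproduces `x` field-for-field.
#'
#' @param calls data.frame of calls (see [readVcfCalls()] for the schema).
#' @param path output path.
#' @param genome optional [MitoGenome-class]; provides the contig name and
#'   length written to the header.
#' @param contig contig name used when `genome` is absent.
#' @return The output path, invisibly.
#' @export
writeVcfCalls <- function(calls, path, genome = NULL, contig = "MT") {
  .validateCalls(calls)
  if (nrow(calls)) .checkAlleles(calls$ref, calls$alt)
  if (!is.null(genome)) contig <- genomeName(genome)
  sl <- if (!is.null(genome)) genomeLength(genome) else NA_integer_
  if (!nrow(calls)) {          # header-only VCF
    vcf <- VariantAnnotation::VCF(
      rowRanges = GenomicRanges::GRanges(
        seqinfo = GenomeInfoDb::Seqinfo(contig, sl)),
      colData = S4Vectors::DataFrame(Samples = integer()),
      exptData = list(header = .vcfDialectHeader(character())),
      fixed = S4Vectors::DataFrame(
        REF = Biostrings::DNAStringSet(),
        ALT = Biostrings::DNAStringSetList(), QUAL = numeric(),
        FILTER = character()),
      geno = S4Vectors::SimpleList())
    VariantAnnotation::writeVcf(vcf, path)
    return(invisible(path))
  }
  samples <- sort(unique(calls$sample_id))
  ord <- order(calls$position, calls$ref, calls$sample_id)
  calls <- calls[ord, , drop = FALSE]
  reckey <- paste(calls$position, calls$ref, sep = ":")
  recs <- unique(reckey)
  nrec <- length(recs)
  rec_pos <- calls$position[match(recs, reckey)]
  rec_ref <- calls$ref[match(recs, reckey)]
  alts <- lapply(recs, function(k) unique(calls$alt[reckey == k]))

  gt <- matrix("0", nrec, length(samples), dimnames = list(NULL, samples))
  dpm <- matrix(0L, nrec, length(samples), dimnames = list(NULL, samples))
  zero <- lapply(alts, function(a) integer(length(a)))
  safm <- matrix(rep(zero, length(samples)), nrec, length(samples),
                 dimnames = list(NULL, samples))
  sarm <- safm
  cell_idx <- vector("list", nrec * max(1L, length(samples)))
  dim(cell_idx) <- c(nrec, max(1L, length(samples)))
  cell_cls <- cell_idx

  ri <- match(reckey, recs)
  sj <- match(calls$sample_id, samples)
  for (r in seq_len(nrow(calls))) {
    i <- ri[r]; j <- sj[r]
    k <- match(calls$alt[r], alts[[i]])
    x <- safm[[i, j]]; x[k] <- calls$alt_fwd[r]; safm[[i, j]] <- x
    x <- sarm[[i, j]]; x[k] <- calls$alt_rev[r]; sarm[[i, j]] <- x
    dpm[i, j] <- max(dpm[i, j], calls$depth[r])
    cell_idx[[i, j]] <- c(cell_idx[[i, j]], k)
    cell_cls[[i, j]] <- c(cell_cls[[i, j]], calls$genotype_class[r])
  }
  for (i in seq_len(nrec)) for (j in seq_along(samples)) {
    ks <- cell_idx[[i, j]]
    if (is.null(ks)) next
    cls <- cell_cls[[i, j]]
    if (any(cls == "missing")) {
      if (length(ks) > 1L && !all(cls == "missing"))
        stop(sprintf("sample %s at %d: missing call mixed with others",
                     samples[j], rec_pos[i]), call. = FALSE)
      gt[i, j] <- "."
    } else if (all(cls == "hom_alt")) {
      if (length(unique(ks)) > 1L)
        stop(sprintf("sample %s at %d: conflicting haploid genotypes",
                     samples[j], rec_pos[i]), call. = FALSE)
      gt[i, j] <- as.character(ks[1L])
    } else if (all(cls == "het")) {
      u <- sort(unique(ks))
      gt[i, j] <- if (length(u) == 1L) paste0("0/", u)
                  else paste(u, collapse = "/")
    } else {
      stop(sprintf("sample %s at %d: hom_alt mixed with het",
                   samples[j], rec_pos[i]), call. = FALSE)
    }
  }

  hdr <- .vcfDialectHeader(samples)
  gr <- GenomicRanges::GRanges(
    contig, IRanges::IRanges(start = rec_pos, width = nchar(rec_ref)),
    seqlengths = stats::setNames(sl, contig))
  vcf <- VariantAnnotation::VCF(
    rowRanges = gr,
    colData = S4Vectors::DataFrame(Samples = seq_along(samples),
                                   row.names = samples),
    exptData = list(header = hdr),
    fixed = S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(rec_ref),
      ALT = Biostrings::DNAStringSetList(alts),
      QUAL = rep(NA_real_, nrec), FILTER = rep(".", nrec)),
    geno = S4Vectors::SimpleList(GT = gt, DP = dpm, SAF = safm, SAR = sarm))
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}
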