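#' Global variant enrichment rate
#'
#' \eqn{r_g = N_x / l_x \times 1000} variants per Mb, where \eqn{N_x} is the
#' number of distinct variants observed in gene \eqn{x} and \eqn{l_x} its
#' reported length in bp. Returned at full precision; display convention is
#' one decimal.
#'
#' @param nVariants distinct-variant count(s) \eqn{N_x}.
#' @param lengthBp reported gene length(s) in bp.
#' @return numeric, variants/Mb.
#' @examples
#' round(globalEnrichment(59, 682), 1)   # 86.5
#' @export
globalEnrichment <- function(nVariants, lengthBp) {
  if (any(is.na(lengthBp)) || any(lengthBp <= 0))
    stop("gene length must be positive", call. = FALSE)
  if (any(nVariants < 0))
    stop("variant count must be non-negative", call. = FALSE)
  nVariants / lengthBp * 1000
}

#' Weighted variant enrichment rate
#'
#' \eqn{r_w = \sum_{i=1}^{N_x} n_i / l_x}, where \eqn{n_i} is the number of
#' individuals carrying variant \eqn{i} of gene \eqn{x}. The default scale
#' `per_bp` divides the carrier sum by the gene length in bp; `per_Mb`
#' multiplies by 1000. Display convention is two decimals.
#'
#' @param carrierCounts integer vector of per-variant carrier counts
#'   (each >= 1); may be empty for a gene with no variants.
#' @param lengthBp reported gene length in bp.
#' @param scale `"per_bp"` (default) or `"per_Mb"`.
#' @return numeric(1).
#' @examples
#' weightedEnrichment(c(600, 27), 682)              # 0.9193548
#' weightedEnrichment(c(600, 27), 682, "per_Mb")    # 919.3548
#' @export
weightedEnrichment <- function(carrierCounts, lengthBp,
                               scale = c("per_bp", "per_Mb")) {
  scale <- match.arg(scale)
  if (length(lengthBp) != 1L || is.na(lengthBp) || lengthBp <= 0)
    stop("gene length must be a single positive value", call. = FALSE)
  if (length(carrierCounts) && any(carrierCounts < 1))
    stop("carrier counts must be >= 1", call. = FALSE)
  r <- sum(carrierCounts) / lengthBp
  if (scale == "per_Mb") r * 1000 else r
}

#' Shapiro-Wilk normality test
#'
#' @param values numeric vector (>= 3 values, not all equal).
#' @return list with `W` (statistic) and `p` (p-value).
#' @export
normalityTest <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L)
    stop("normality test needs at least 3 values", call. = FALSE)
  if (length(unique(values)) == 1L)
    stop("normality test undefined for constant input", call. = FALSE)
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Percentile placement of a value in a distribution
#'
#' Four conventions: `normal_model` (default) fits a normal by the sample
#' mean and sd (denominator \eqn{n-1}) and returns
#' \eqn{100\,\Phi((v-\bar x)/s)}; `empirical_strict` returns 100 times the
#' fraction of values strictly below; `hazen` returns
#' \eqn{100 (r - 0.5)/n} and `weibull` \eqn{100\, r/(n+1)} for the
#' (mean-tie) rank \eqn{r} of the value among `values`.
#'
#' @param value value to place.
#' @param values reference distribution (>= 2 values).
#' @param method percentile convention.
#' @return percentile on the 0-100 scale.
#' @examples
#' percentilePosition(5, 1:5, "weibull")   # 83.3
#' @export
percentilePosition <- function(value, values,
                               method = c("normal_model", "empirical_strict",
                                          "hazen", "weibull")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L)
    stop("need at least 2 reference values", call. = FALSE)
  if (method == "normal_model") {
    s <- stats::sd(values)
    if (is.na(s) || s == 0)
      stop("normal_model percentile undefined: zero standard deviation",
           call. = FALSE)
    return(100 * stats::pnorm((value - mean(values)) / s))
  }
  below <- sum(values < value)
  ties <- sum(values == value)
  if (method == "empirical_strict") return(100 * below / n)
  r <- below + if (ties) (ties + 1) / 2 else 0.5
  if (method == "hazen") 100 * (r - 0.5) / n else 100 * r / (n + 1)
}

#' Per-gene enrichment table
#'
#' Builds one row per non-excluded gene of the model: the distinct-variant
#' count \eqn{N_x} (a variant overlapping several genes contributes once to
#' each), the carrier sum \eqn{\sum n_i}, \eqn{r_g}, \eqn{r_w}, and the
#' percentile placement of each gene's \eqn{r_g} within the included genes.
#' Genes with zero observed variants are retained with zeros so the
#' denominators of the means are explicit. Mt-tRNA genes are excluded by
#' default: their very small lengths would bias the rates.
#'
#' @param annotated data.frame from [annotateVariants()] (needs `genes` and
#'   `carrier_count`).
#' @param model [MitoGeneModel-class].
#' @param excludeBiotypes biotypes to drop (default `"Mt_tRNA"`).
#' @param rwScale scale of \eqn{r_w}, see [weightedEnrichment()].
#' @param percentileMethod convention for [percentilePosition()].
#' @return An [EnrichmentReport-class].
#' @export
enrichmentTable <- function(annotated, model, excludeBiotypes = "Mt_tRNA",
                            rwScale = c("per_bp", "per_Mb"),
                            percentileMethod = "normal_model") {
  stopifnot(is(model, "MitoGeneModel"))
  rwScale <- match.arg(rwScale)
  .assertCols(annotated, c("genes", "carrier_count"), "annotated variants")
  genes <- geneTable(model)
  vgenes <- strsplit(annotated$genes, ",", fixed = TRUE)
  unknown <- setdiff(unlist(vgenes), genes$symbol)
  unknown <- unknown[nzchar(unknown)]
  if (length(unknown))
    stop("variant annotated against gene(s) absent from the model: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  keep <- !genes$biotype %in% excludeBiotypes
  inc <- genes[keep, , drop = FALSE]
  nx <- integer(nrow(inc)); csum <- integer(nrow(inc))
  for (k in seq_len(nrow(inc))) {
    hit <- vapply(vgenes, function(g) inc$symbol[k] %in% g, NA)
    nx[k] <- sum(hit)
    csum[k] <- sum(annotated$carrier_count[hit])
  }
  rg <- globalEnrichment(nx, inc$length)
  rw <- vapply(seq_len(nrow(inc)), function(k)
    weightedEnrichment(annotated$carrier_count[
      vapply(vgenes, function(g) inc$symbol[k] %in% g, NA)],
      inc$length[k], rwScale), numeric(1))
  pct <- rep(NA_real_, nrow(inc))
  if (nrow(inc) >= 2L && stats::sd(rg) > 0)
    pct <- vapply(rg, percentilePosition, numeric(1), values = rg,
                  method = percentileMethod)
  sw <- sp <- NA_real_
  if (nrow(inc) >= 3L && length(unique(rg)) > 1L) {
    nt <- normalityTest(rg)
    sw <- nt$W; sp <- nt$p
  }
  rows <- data.frame(gene = inc$symbol, biotype = inc$biotype,
                     length = inc$length, n_variants = nx,
                     carrier_sum = csum, r_g = rg, r_w = rw,
                     percentile = pct, stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  new("EnrichmentReport", rows = rows,
      meanRg = if (nrow(rows)) mean(rg) else NA_real_,
      meanRw = if (nrow(rows)) mean(rw) else NA_real_,
      shapiroW = sw, shapiroP = sp,
      excludedBiotypes = as.character(excludeBiotypes), rwScale = rwScale,
      percentileMethod = as.character(percentileMethod))
}

#' Rank genes by global enrichment
#'
#' @param report an [EnrichmentReport-class] (or its rows data.frame).
#' @return the rows ordered by `r_g` descending, ties broken by gene symbol
#'   (lexicographic).
#' @export
rankGenes <- function(report) {
  rows <- if (is(report, "EnrichmentReport")) enrichmentRows(report)
          else report
  out <- rows[order(-rows$r_g, rows$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment report as TSV
#'
#' Columns mirror the per-gene summary table (symbol, biotype, length,
#' variant count, carrier sum, `r_g` to 1 decimal, `r_w` to 2 decimals,
#' percentile to 1 decimal).
#'
#' @param report an [EnrichmentReport-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEnrichmentTable <- function(report, path) {
  stopifnot(is(report, "EnrichmentReport"))
  rows <- enrichmentRows(report)
  rows$r_g <- round(rows$r_g, 1L)
  rows$r_w <- round(rows$r_w, 2L)
  rows$percentile <- round(rows$percentile, 1L)
  .writeTsv(rows, path)
}
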