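#' Pipeline run configuration
#'
#' Collects input paths and parameters for [runPipeline()]. Either build it
#' programmatically or load it from a flat YAML file whose keys match the
#' arguments (CLI/function arguments override file values).
#'
#' @param vcf input VCF of per-sample calls (required).
#' @param genes gene-model TSV (required; see [loadGeneModel()]).
#' @param ref optional reference FASTA (enables codon and homopolymer
#'   annotation).
#' @param catalog,conserved,predictions,rsids optional annotation inputs.
#' @param genome_length genome length in bp, needed when `ref` is absent.
#' @param min_strand_fraction strand-balance threshold (default 0.10).
#' @param exclude_biotypes biotypes excluded from enrichment.
#' @param rw_scale `"per_bp"` or `"per_Mb"`.
#' @param percentile_method see [percentilePosition()].
#' @param outdir output directory.
#' @param verbose logical; progress messages to standard error.
#' @return a validated list of class `RunConfig`.
#' @export
runConfig <- function(vcf, genes, ref = NULL, catalog = NULL,
                      conserved = NULL, predictions = NULL, rsids = NULL,
                      genome_length = 16569L, min_strand_fraction = 0.10,
                      exclude_biotypes = "Mt_tRNA",
                      rw_scale = c("per_bp", "per_Mb"),
                      percentile_method = "normal_model",
                      outdir = ".", verbose = TRUE) {
  cfg <- list(vcf = vcf, genes = genes, ref = ref, catalog = catalog,
              conserved = conserved, predictions = predictions,
              rsids = rsids, genome_length = as.integer(genome_length),
              min_strand_fraction = as.numeric(min_strand_fraction),
              exclude_biotypes = exclude_biotypes,
              rw_scale = match.arg(rw_scale),
              percentile_method = percentile_method,
              outdir = outdir, verbose = isTRUE(verbose))
  for (f in c("vcf", "genes", "ref", "catalog", "conserved", "predictions",
              "rsids")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("input file for '%s' not found: %s", f, p), call. = FALSE)
  }
  if (cfg$min_strand_fraction < 0 || cfg$min_strand_fraction > 0.5)
    stop("min_strand_fraction must lie in [0, 0.5]", call. = FALSE)
  class(cfg) <- "RunConfig"
  cfg
}

#' Load a [runConfig()] from a flat YAML file
#'
#' @param path YAML file with keys matching the [runConfig()] arguments.
#' @param ... overrides passed on to [runConfig()].
#' @return a `RunConfig`.
#' @export
runConfigFromYaml <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(runConfig, vals)
}

.pmsg <- function(cfg, ...) if (cfg$verbose) message("[mitovar] ", ...)

#' Run the full post-processing pipeline
#'
#' Stages, in order: read calls; haploid-genotype and strand-balance
#' filtering; aggregation into study-wide variants with carrier counts;
#' annotation; per-gene enrichment. Writes `filtered.vcf`, `discards.tsv`,
#' `annotated.tsv`, `enrichment.tsv`, a human-readable `report.md` and a
#' machine-readable `manifest.json` (input checksums, parameters, per-stage
#' counts) into `outdir`. Re-running on identical inputs yields identical
#' outputs.
#'
#' @param config a [runConfig()] (or path to a YAML file for
#'   [runConfigFromYaml()]).
#' @return list with the in-memory stage results (`calls`, `filtered`,
#'   `log`, `aggregated`, `annotated`, `report`, `summary`, `paths`),
#'   invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- runConfigFromYaml(config)
  stopifnot(inherits(config, "RunConfig"))
  if (!dir.exists(config$outdir))
    dir.create(config$outdir, recursive = TRUE)

  genome <- if (!is.null(config$ref)) readFastaGenome(config$ref)
            else mitoGenome("MT", length = config$genome_length)
  model <- loadGeneModel(config$genes, genome)
  catalog <- if (!is.null(config$catalog)) readCatalog(config$catalog)
  conserved <- if (!is.null(config$conserved))
    readConservedPositions(config$conserved)
  predictions <- if (!is.null(config$predictions))
    readPredictions(config$predictions)
  rsids <- if (!is.null(config$rsids)) readRsids(config$rsids)

  .pmsg(config, "reading calls from ", config$vcf)
  calls <- readVcfCalls(config$vcf)
  .pmsg(config, nrow(calls), " calls read")
  flt <- filterCalls(calls, config$min_strand_fraction)
  .pmsg(config, nrow(flt$passed), " calls pass filters, ",
        sum(!flt$log$passed), " discarded")
  aggregated <- aggregateCalls(flt$passed)
  .pmsg(config, nrow(aggregated), " distinct variants")
  annotated <- annotateVariants(aggregated, model, catalog = catalog,
                                conserved = conserved,
                                predictions = predictions, rsids = rsids)
  report <- enrichmentTable(annotated, model,
                            excludeBiotypes = config$exclude_biotypes,
                            rwScale = config$rw_scale,
                            percentileMethod = config$percentile_method)
  summary <- summarizeVariants(annotated)

  paths <- list(filtered_vcf = file.path(config$outdir, "filtered.vcf"),
                discards = file.path(config$outdir, "discards.tsv"),
                annotated = file.path(config$outdir, "annotated.tsv"),
                enrichment = file.path(config$outdir, "enrichment.tsv"),
                report = file.path(config$outdir, "report.md"),
                manifest = file.path(config$outdir, "manifest.json"))
  writeVcfCalls(flt$passed, paths$filtered_vcf, genome = genome)
  .writeTsv(flt$log[!flt$log$passed, , drop = FALSE], paths$discards)
  writeVariantTable(annotated, paths$annotated)
  writeEnrichmentTable(report, paths$enrichment)
  writeLines(.renderReport(report, summary, config), paths$report)

  inputs <- Filter(Negate(is.null),
                   config[c("vcf", "genes", "ref", "catalog", "conserved",
                            "predictions", "rsids")])
  manifest <- list(
    package = "mitovar",
    version = as.character(utils::packageVersion("mitovar")),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    parameters = config[c("min_strand_fraction", "exclude_biotypes",
                          "rw_scale", "percentile_method")],
    counts = list(calls_in = nrow(calls),
                  calls_passed = nrow(flt$passed),
                  calls_discarded = sum(!flt$log$passed),
                  distinct_variants = nrow(aggregated)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(calls = calls, filtered = flt$passed, log = flt$log,
                 aggregated = aggregated, annotated = annotated,
                 report = report, summary = summary, paths = paths))
}

.renderReport <- function(report, summary, config) {
  rows <- rankGenes(report)
  top <- utils::head(rows, 2L)
  c("# mtDNA variant post-processing report", "",
    sprintf("- distinct variants: %d", summary$n_variants),
    sprintf("- substitutions: %.1f%%", summary$pct_substitutions),
    sprintf("- in coding sequence: %.1f%%", summary$pct_coding),
    sprintf("- unknown in catalog: %d", summary$n_unknown),
    sprintf("- concordant-deleterious (SIFT & PolyPhen): %d",
            summary$n_concordant), "",
    sprintf("Mean r_g = %.1f variants/Mb; mean r_w = %.2f (%s).",
            report@meanRg, report@meanRw, rwScale(report)),
    if (!is.na(report@shapiroP))
      sprintf("Shapiro-Wilk on r_g: W = %.3f, p = %.3f.",
              report@shapiroW, report@shapiroP) else character(),
    if (nrow(top))
      sprintf("Top genes by r_g: %s.",
              paste(sprintf("%s (%.1f)", top$gene, top$r_g),
                    collapse = ", ")) else character())
}

#' Summary statistics over an annotated variant table
#'
#' @param annotated data.frame from [annotateVariants()].
#' @return list with `n_variants`, `pct_substitutions`, `pct_coding`
#'   (percentages on 0-100), `effect_counts` (named integer vector),
#'   `n_unknown` (absent from the catalog) and `n_concordant`
#'   (SIFT-deleterious and PolyPhen-probably-damaging).
#' @export
summarizeVariants <- function(annotated) {
  n <- nrow(annotated)
  if (!n)
    return(list(n_variants = 0L, pct_substitutions = 0, pct_coding = 0,
                effect_counts = integer(), n_unknown = 0L,
                n_concordant = 0L))
  eff <- annotated$effect[!is.na(annotated$effect)]
  vt <- if ("variant_type" %in% names(annotated)) annotated$variant_type
        else classifyVariantType(annotated$ref, annotated$alt)
  coding_eff <- c("synonymous", "missense", "nonsense", "stop_loss",
                  "frameshift_candidate")
  rc <- if ("region_class" %in% names(annotated)) annotated$region_class
        else ifelse(is.na(annotated$effect), NA_character_,
                    ifelse(annotated$effect %in% coding_eff, "coding_exon",
                           ifelse(annotated$effect == "intergenic",
                                  "intergenic", "non_coding_exon")))
  list(n_variants = n,
       pct_substitutions = 100 * mean(vt == "substitution"),
       pct_coding = 100 * mean(rc == "coding_exon", na.rm = TRUE),
       effect_counts = if (length(eff)) table(eff) else integer(),
       n_unknown = sum(annotated$mitomap_status == "Unknown", na.rm = TRUE),
       n_concordant = nrow(concordanceFilter(annotated)))
}
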