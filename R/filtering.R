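#' Haploid genotype filter
#'
#' The mitochondrial genome is haploid, so calls genotyped as heterozygous
#' reflect heteroplasmy or sequencing noise and are treated as unreliable:
#' only `hom_alt` calls pass. `het` calls fail with reason `het_genotype`,
#' `missing` calls with `missing_genotype`; `hom_ref` calls are dropped
#' silently (they are not variant calls and are not logged).
#'
#' @param calls data.frame of calls (schema of [readVcfCalls()]).
#' @return list with `passed` (calls that survive) and `log` (one decision
#'   row per non-`hom_ref` call: `sample_id`, `position`, `ref`, `alt`,
#'   `passed`, `reason`).
#' @export
genotypeFilter <- function(calls) {
  .validateCalls(calls)
  if (!nrow(calls))
    return(list(passed = .emptyCallFrame(), log = .emptyDecisionFrame()))
  calls <- calls[calls$genotype_class != "hom_ref", , drop = FALSE]
  reason <- c(hom_alt = "pass", het = "het_genotype",
              missing = "missing_genotype")[calls$genotype_class]
  log <- data.frame(sample_id = calls$sample_id, position = calls$position,
                    ref = calls$ref, alt = calls$alt,
                    passed = unname(reason == "pass"),
                    reason = unname(reason), stringsAsFactors = FALSE)
  passed <- calls[log$passed, , drop = FALSE]
  rownames(passed) <- NULL; rownames(log) <- NULL
  list(passed = passed, log = log)
}

#' Strand-balance filter
#'
#' A genuine variant is supported by reads on both sequencing strands. With
#' \eqn{f = \min(\mathrm{alt\_fwd}, \mathrm{alt\_rev}) /
#' (\mathrm{alt\_fwd} + \mathrm{alt\_rev})}, a call fails with reason
#' `strand_imbalance` iff `f < minFraction` (strict: a call sitting exactly
#' at the threshold passes). The denominator is alt-supporting reads only,
#' not total depth, so a reference-heavy site cannot mask alt imbalance.
#' Calls with no alt-supporting reads fail with the distinct reason
#' `no_alt_support`.
#'
#' @param calls data.frame of calls.
#' @param minFraction minimum fraction of alt reads on the weaker strand,
#'   in `[0, 0.5]`; default 0.10.
#' @return list with `passed` and `log` (as in [genotypeFilter()]).
#' @examples
#' calls <- data.frame(sample_id = "S1", position = 100L, ref = "A",
#'                     alt = "G", genotype_class = "hom_alt",
#'                     alt_fwd = 50L, alt_rev = 4L, depth = 60L)
#' strandBalanceFilter(calls)$log   # 4/54 < 0.10 -> strand_imbalance
#' @export
strandBalanceFilter <- function(calls, minFraction = 0.10) {
  .validateCalls(calls)
  if (length(minFraction) != 1L || is.na(minFraction) ||
      minFraction < 0 || minFraction > 0.5)
    stop("'minFraction' must be a single value in [0, 0.5]", call. = FALSE)
  if (!nrow(calls))
    return(list(passed = .emptyCallFrame(), log = .emptyDecisionFrame()))
  tot <- calls$alt_fwd + calls$alt_rev
  f <- ifelse(tot > 0L, pmin(calls$alt_fwd, calls$alt_rev) / tot, NA_real_)
  reason <- ifelse(tot == 0L, "no_alt_support",
                   ifelse(f < minFraction, "strand_imbalance", "pass"))
  log <- data.frame(sample_id = calls$sample_id, position = calls$position,
                    ref = calls$ref, alt = calls$alt,
                    passed = reason == "pass", reason = reason,
                    stringsAsFactors = FALSE)
  passed <- calls[log$passed, , drop = FALSE]
  rownames(passed) <- NULL; rownames(log) <- NULL
  list(passed = passed, log = log)
}

#' Apply the genotype and strand-balance filters in sequence
#'
#' The two filters are order-independent; this convenience runs
#' [genotypeFilter()] then [strandBalanceFilter()] and concatenates the
#' decision logs (failed calls are logged once, by the filter that removed
#' them).
#'
#' @inheritParams strandBalanceFilter
#' @return list with `passed` and `log`.
#' @export
filterCalls <- function(calls, minFraction = 0.10) {
  g <- genotypeFilter(calls)
  s <- strandBalanceFilter(g$passed, minFraction)
  list(passed = s$passed,
       log = rbind(g$log[!g$log$passed, , drop = FALSE], s$log))
}

#' Aggregate passing calls into study-wide variants
#'
#' Groups calls by variant key (`position`, `ref`, `alt`) and counts, for
#' each key, the number of distinct samples carrying it (the carrier count
#' \eqn{n_i}). A sample with duplicate calls for the same key counts once.
#'
#' @param calls data.frame of (already filtered) calls.
#' @return data.frame with one row per variant: `position`, `ref`, `alt`,
#'   `carrier_count`, and `carriers` (comma-separated sorted sample ids).
#' @export
aggregateCalls <- function(calls) {
  .validateCalls(calls)
  if (!nrow(calls))
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), carrier_count = integer(),
                      carriers = character(), stringsAsFactors = FALSE))
  key <- paste(calls$position, calls$ref, calls$alt, sep = ":")
  grp <- split(calls$sample_id, key)
  samples <- lapply(grp, function(s) sort(unique(s)))
  first <- match(names(grp), key)
  out <- data.frame(position = calls$position[first],
                    ref = calls$ref[first], alt = calls$alt[first],
                    carrier_count = lengths(samples),
                    carriers = vapply(samples, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[order(out$position, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage breadth and mean depth
#'
#' @param depths non-negative integer vector of per-position read depths.
#' @param threshold depth threshold (default 50).
#' @return list with `breadth` (fraction of positions with depth >=
#'   `threshold`), `mean_depth`, and `n` (number of positions).
#' @examples
#' coverageBreadth(c(50, 50, 10, 60, 70, 80, 90, 100, 40, 55))$breadth  # 0.8
#' @export
coverageBreadth <- function(depths, threshold = 50L) {
  if (!length(depths))
    stop("'depths' must be non-empty", call. = FALSE)
  if (any(is.na(depths)) || any(depths < 0))
    stop("'depths' must be non-negative", call. = FALSE)
  list(breadth = mean(depths >= threshold), mean_depth = mean(depths),
       n = length(depths))
}
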