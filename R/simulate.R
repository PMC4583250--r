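#' Simulation configuration
#'
#' Parameters of the synthetic mtDNA study generator. The defaults emulate
#' the conditions of a targeted mtDNA resequencing study: 436 haploid
#' samples, roughly 1150 distinct variants (common haplogroup-style
#' polymorphisms at population frequency 0.05-0.5, rare/private variants in
#' 1-3 carriers, and a couple of sites where the reference itself carries
#' the minor allele so nearly every sample is called non-reference), mean
#' depth 198x, plus per-call sequencing artifacts: heterozygous-looking
#' heteroplasmy-like calls, single-strand false calls, and
#' homopolymer-associated indels.
#'
#' @param genome_length genome length in bp (>= 2000).
#' @param n_genes number of genes in the toy gene model (6-30).
#' @param n_samples number of haploid samples.
#' @param n_common_variants number of common variants.
#' @param common_freq_range population-frequency range of common variants.
#' @param n_rare_variants number of rare variants (1-3 carriers each).
#' @param rare_carrier_range carrier-count range for rare variants.
#' @param n_ref_minor_sites sites where the reference carries the minor
#'   allele (population alt frequency >= `ref_minor_freq`).
#' @param ref_minor_freq lower bound of the alt frequency at those sites.
#' @param het_artifact_rate expected number of injected heterozygous
#'   artifact calls per true call.
#' @param strand_artifact_rate expected number of injected single-strand
#'   false calls per true call.
#' @param homopolymer_indel_rate expected number of injected
#'   homopolymer-indel artifact calls per true call.
#' @param mean_depth Poisson mean of the per-call read depth.
#' @param seed integer seed; a fixed config (including seed) reproduces
#'   byte-identical outputs.
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(genome_length = 16569L, n_genes = 15L,
                      n_samples = 436L, n_common_variants = 400L,
                      common_freq_range = c(0.05, 0.5),
                      n_rare_variants = 750L, rare_carrier_range = c(1L, 3L),
                      n_ref_minor_sites = 2L, ref_minor_freq = 0.95,
                      het_artifact_rate = 0.05, strand_artifact_rate = 0.05,
                      homopolymer_indel_rate = 0.02, mean_depth = 198,
                      seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              n_samples = as.integer(n_samples),
              n_common_variants = as.integer(n_common_variants),
              common_freq_range = as.numeric(common_freq_range),
              n_rare_variants = as.integer(n_rare_variants),
              rare_carrier_range = as.integer(rare_carrier_range),
              n_ref_minor_sites = as.integer(n_ref_minor_sites),
              ref_minor_freq = as.numeric(ref_minor_freq),
              het_artifact_rate = as.numeric(het_artifact_rate),
              strand_artifact_rate = as.numeric(strand_artifact_rate),
              homopolymer_indel_rate = as.numeric(homopolymer_indel_rate),
              mean_depth = as.numeric(mean_depth), seed = as.integer(seed))
  if (cfg$genome_length < 2000L)
    stop("genome_length must be >= 2000", call. = FALSE)
  if (cfg$n_genes < 6L || cfg$n_genes > 30L)
    stop("n_genes must be between 6 and 30", call. = FALSE)
  rates <- c(cfg$het_artifact_rate, cfg$strand_artifact_rate,
             cfg$homopolymer_indel_rate)
  if (any(rates < 0 | rates > 1))
    stop("artifact rates must lie in [0, 1]", call. = FALSE)
  if (cfg$ref_minor_freq < 0.95)
    stop("ref_minor_freq must be >= 0.95", call. = FALSE)
  class(cfg) <- "SimConfig"
  cfg
}

#' Generate a toy circular genome and gene model
#'
#' Builds a random circular genome of `genome_length` bp with an
#' mtDNA-like gene layout: two rRNA-like genes, two short tRNA-like genes,
#' the remainder protein-coding (lengths divisible by 3), one gene on the
#' minus strand, one overlapping protein-coding pair, and at least three
#' planted homopolymer runs of length >= 4 in intergenic sequence. The
#' control-region analogue (intergenic) spans the circular origin.
#' Deterministic under `config$seed`.
#'
#' @param config a [simConfig()].
#' @return list with `genome` ([MitoGenome-class]) and `model`
#'   ([MitoGeneModel-class]).
#' @export
makeToyGenome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  L <- config$genome_length
  .withSeed(config$seed, {
    seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # gene layout: fractions of a control-region-free span
    ng <- config$n_genes
    n_pc <- ng - 4L
    biotypes <- c("Mt_rRNA", "Mt_rRNA", "Mt_tRNA",
                  rep("protein_coding", n_pc), "Mt_tRNA")
    cursor <- max(80L, round(0.04 * L))        # origin-spanning intergenic
    usable <- round(0.82 * L)
    trna_len <- 69L
    rrna_len <- round(c(0.06, 0.10) * usable)
    pc_len <- round(seq(0.045, 0.11, length.out = n_pc) * usable)
    pc_len <- pc_len - pc_len %% 3L
    budget <- usable - sum(rrna_len) - 2L * trna_len
    pc_len <- pmax(30L, round(pc_len * budget / sum(pc_len)))
    pc_len <- pc_len - pc_len %% 3L
    lens <- c(rrna_len, trna_len, pc_len, trna_len)
    gaps <- pmax(2L, round(stats::runif(ng, 2, 0.004 * L)))
    overlap_at <- 4L + max(2L, n_pc %/% 2L)    # a mid protein-coding gene
    minus_at <- 3L + n_pc                      # last protein-coding gene
    starts <- integer(ng); ends <- integer(ng)
    for (k in seq_len(ng)) {
      start <- cursor + gaps[k]
      if (k == overlap_at)                     # start inside previous gene
        start <- ends[k - 1L] - 45L + 1L
      ends[k] <- start + lens[k] - 1L
      starts[k] <- start
      cursor <- ends[k]
    }
    if (cursor > L - 50L)
      stop("infeasible gene packing for this genome_length", call. = FALSE)
    genes <- data.frame(
      symbol = sprintf("TG%02d", seq_len(ng)),
      biotype = biotypes,
      start = starts, end = ends,
      strand = ifelse(seq_len(ng) == minus_at, "-", "+"),
      length = ends - starts + 1L,
      stringsAsFactors = FALSE)
    # plant homopolymer runs in the intergenic tail after the last gene
    tail_space <- seq.int(cursor + 10L, L - 10L)
    run_starts <- sort(sample(tail_space[tail_space %% 29L == 0L], 4L))
    for (rs in run_starts) {
      rl <- sample(4:7, 1L)
      seq_chars[rs:(rs + rl - 1L)] <- sample(c("A", "C", "G", "T"), 1L)
      # break up accidental extensions at the run borders
      seq_chars[rs - 1L] <- setdiff(c("A", "C", "G", "T"),
                                    seq_chars[rs])[1L]
      seq_chars[rs + rl] <- setdiff(c("A", "C", "G", "T"),
                                    seq_chars[rs])[1L]
    }
    genome <- mitoGenome("toy_mt", sequence = paste(seq_chars, collapse = ""))
    list(genome = genome, model = geneModel(genes, genome))
  })
}

#' Simulate a haploid population of variant carriers
#'
#' Draws common variants (per-sample carriage Bernoulli at a frequency
#' uniform in `common_freq_range`), rare variants (1-3 carriers sampled
#' directly), and reference-minor sites (alt frequency >=
#' `ref_minor_freq`), all single-base substitutions at distinct positions.
#' Deterministic under `config$seed`.
#'
#' @param config a [simConfig()].
#' @param genome a [MitoGenome-class] with sequence.
#' @return list with `variants` (data.frame `position`, `ref`, `alt`,
#'   `class`, `target_freq`, `carrier_count`) and `carriers` (long
#'   data.frame `sample_id`, `position`, `ref`, `alt`). Variants that drew
#'   zero carriers are dropped from both.
#' @export
simulatePopulation <- function(config, genome) {
  stopifnot(inherits(config, "SimConfig"), is(genome, "MitoGenome"))
  L <- genomeLength(genome)
  n_var <- config$n_common_variants + config$n_rare_variants +
    config$n_ref_minor_sites
  if (n_var > L)
    stop("more variants requested than genome positions", call. = FALSE)
  samples <- sprintf("S%04d", seq_len(config$n_samples))
  .withSeed(config$seed + 1L, {
    pos <- sort(sample.int(L, n_var))
    ref <- toupper(.basesAt(genome, pos))
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), "", USE.NAMES = FALSE)
    cls <- c(rep("common", config$n_common_variants),
             rep("rare", config$n_rare_variants),
             rep("ref_minor", config$n_ref_minor_sites))
    cls <- sample(cls)                        # classes spread over positions
    freq <- rep(NA_real_, n_var)
    freq[cls == "common"] <- stats::runif(sum(cls == "common"),
                                          config$common_freq_range[1],
                                          config$common_freq_range[2])
    freq[cls == "ref_minor"] <- stats::runif(sum(cls == "ref_minor"),
                                             config$ref_minor_freq, 0.999)
    carrier_list <- vector("list", n_var)
    for (i in seq_len(n_var)) {
      carrier_list[[i]] <- if (cls[i] == "rare") {
        k <- sample(seq.int(config$rare_carrier_range[1],
                            config$rare_carrier_range[2]), 1L)
        sort(sample(samples, min(k, length(samples))))
      } else {
        samples[stats::runif(length(samples)) < freq[i]]
      }
    }
    nc <- lengths(carrier_list)
    keep <- nc > 0L
    variants <- data.frame(position = pos, ref = ref, alt = alt, class = cls,
                           target_freq = freq, carrier_count = nc,
                           stringsAsFactors = FALSE)[keep, , drop = FALSE]
    rownames(variants) <- NULL
    carriers <- data.frame(
      sample_id = unlist(carrier_list[keep]),
      position = rep(pos[keep], nc[keep]),
      ref = rep(ref[keep], nc[keep]), alt = rep(alt[keep], nc[keep]),
      stringsAsFactors = FALSE)
    list(variants = variants, carriers = carriers)
  })
}

#' Simulate per-sample calls with injected artifacts
#'
#' True carrier calls get a `hom_alt` genotype, Poisson(`mean_depth`) total
#' depth fully supporting the alt allele, split over strands as
#' Binomial(depth, 0.5). Artifact calls are injected at positions free of
#' true variants, in numbers Binomial(n_true, rate) per class:
#' heterozygous-looking calls (`het` genotype, balanced strands,
#' heteroplasmy-like 30% alt fraction), single-strand false calls
#' (`hom_alt` with all alt reads on one strand), and homopolymer indel
#' artifacts (1-bp insertions/deletions inside planted runs, strand-skewed
#' with a weak-strand fraction uniform in [0, 0.08]). Every call carries
#' exactly one ground-truth label.
#'
#' @param population output of [simulatePopulation()].
#' @param config a [simConfig()].
#' @param model [MitoGeneModel-class] whose genome carries the sequence.
#' @return list with `calls` (the call data.frame, schema of
#'   [readVcfCalls()]) and `truth` (`sample_id`, `position`, `ref`, `alt`,
#'   `label` in true_variant/het_artifact/strand_artifact/
#'   homopolymer_artifact).
#' @export
simulateCalls <- function(population, config, model) {
  stopifnot(inherits(config, "SimConfig"), is(model, "MitoGeneModel"))
  genome <- modelGenome(model)
  carriers <- population$carriers
  samples <- sprintf("S%04d", seq_len(config$n_samples))
  .withSeed(config$seed + 2L, {
    n_true <- nrow(carriers)
    depth <- stats::rpois(n_true, config$mean_depth)
    fwd <- stats::rbinom(n_true, depth, 0.5)
    true_calls <- data.frame(
      sample_id = carriers$sample_id, position = carriers$position,
      ref = carriers$ref, alt = carriers$alt,
      genotype_class = "hom_alt", alt_fwd = fwd, alt_rev = depth - fwd,
      depth = depth, stringsAsFactors = FALSE)
    truth <- data.frame(sample_id = carriers$sample_id,
                        position = carriers$position, ref = carriers$ref,
                        alt = carriers$alt, label = "true_variant",
                        stringsAsFactors = FALSE)

    used <- unique(population$variants$position)
    free <- setdiff(seq_len(genomeLength(genome)), used)
    newSub <- function(n) {
      p <- sample(free, n, replace = TRUE)
      r <- toupper(.basesAt(genome, p))
      a <- vapply(r, function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1L), "", USE.NAMES = FALSE)
      data.frame(sample_id = sample(samples, n, replace = TRUE),
                 position = p, ref = r, alt = a, stringsAsFactors = FALSE)
    }
    addArtifact <- function(calls, truth, n, label, maker) {
      if (n == 0L) return(list(calls = calls, truth = truth))
      art <- maker(n)
      list(calls = rbind(calls, art),
           truth = rbind(truth, data.frame(
             sample_id = art$sample_id, position = art$position,
             ref = art$ref, alt = art$alt, label = label,
             stringsAsFactors = FALSE)))
    }

    n_het <- stats::rbinom(1L, n_true, config$het_artifact_rate)
    n_str <- stats::rbinom(1L, n_true, config$strand_artifact_rate)
    n_hp <- stats::rbinom(1L, n_true, config$homopolymer_indel_rate)

    state <- list(calls = true_calls, truth = truth)
    state <- addArtifact(state$calls, state$truth, n_het, "het_artifact",
      function(n) {
        base <- newSub(n)
        d <- stats::rpois(n, config$mean_depth)
        at <- stats::rbinom(n, d, 0.3)        # heteroplasmy-like fraction
        f <- stats::rbinom(n, at, 0.5)
        cbind(base, data.frame(genotype_class = "het", alt_fwd = f,
                               alt_rev = at - f, depth = d))[
          , .CALL_COLS, drop = FALSE]
      })
    state <- addArtifact(state$calls, state$truth, n_str, "strand_artifact",
      function(n) {
        base <- newSub(n)
        d <- stats::rpois(n, config$mean_depth)
        side <- stats::runif(n) < 0.5
        cbind(base, data.frame(genotype_class = "hom_alt",
                               alt_fwd = ifelse(side, d, 0L),
                               alt_rev = ifelse(side, 0L, d), depth = d))[
          , .CALL_COLS, drop = FALSE]
      })
    hp_pos <- intersect(free, which(.homopolymerMask(genome, 4L)))
    hp_pos <- hp_pos[hp_pos < genomeLength(genome) - 1L]
    state <- addArtifact(state$calls, state$truth,
                         if (length(hp_pos)) n_hp else 0L,
                         "homopolymer_artifact",
      function(n) {
        p <- sample(hp_pos, n, replace = TRUE)
        b <- toupper(.basesAt(genome, p))
        nxt <- toupper(.basesAt(genome, p + 1L))
        ins <- stats::runif(n) < 0.5
        r <- ifelse(ins, b, paste0(b, nxt))
        a <- ifelse(ins, paste0(b, b), b)
        d <- stats::rpois(n, config$mean_depth)
        wf <- stats::runif(n, 0, 0.08)        # weak-strand fraction
        weak <- round(wf * d)
        side <- stats::runif(n) < 0.5
        data.frame(sample_id = sample(samples, n, replace = TRUE),
                   position = p, ref = r, alt = a,
                   genotype_class = "hom_alt",
                   alt_fwd = as.integer(ifelse(side, d - weak, weak)),
                   alt_rev = as.integer(ifelse(side, weak, d - weak)),
                   depth = d, stringsAsFactors = FALSE)
      })
    calls <- state$calls
    truth <- state$truth
    ord <- order(calls$position, calls$ref, calls$alt, calls$sample_id)
    calls <- calls[ord, , drop = FALSE]
    truth <- truth[ord, , drop = FALSE]
    rownames(calls) <- NULL; rownames(truth) <- NULL
    # duplicate (sample, position, ref) pairs would collide in a VCF record
    dup <- duplicated(calls[, c("sample_id", "position", "ref")])
    keep <- !dup
    list(calls = calls[keep, , drop = FALSE],
         truth = truth[keep, , drop = FALSE])
  })
}

#' Write a complete synthetic input bundle
#'
#' Runs [makeToyGenome()], [simulatePopulation()] and [simulateCalls()] and
#' writes `ref.fa`, `genes.tsv`, `calls.vcf`, `truth.tsv` into a directory.
#'
#' @param config a [simConfig()].
#' @param dir output directory (created if needed).
#' @return list with the simulated objects and file paths, invisibly.
#' @export
simulateBundle <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  toy <- makeToyGenome(config)
  pop <- simulatePopulation(config, toy$genome)
  sim <- simulateCalls(pop, config, toy$model)
  paths <- list(ref = file.path(dir, "ref.fa"),
                genes = file.path(dir, "genes.tsv"),
                vcf = file.path(dir, "calls.vcf"),
                truth = file.path(dir, "truth.tsv"))
  writeFastaGenome(toy$genome, paths$ref)
  .writeTsv(geneTable(toy$model), paths$genes)
  writeVcfCalls(sim$calls, paths$vcf, genome = toy$genome)
  .writeTsv(sim$truth, paths$truth)
  invisible(list(genome = toy$genome, model = toy$model, population = pop,
                 calls = sim$calls, truth = sim$truth, paths = paths))
}

#' Read a genome from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @param circular logical (default TRUE).
#' @return a [MitoGenome-class] with sequence.
#' @export
readFastaGenome <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (!length(ss))
    stop("no sequence in FASTA: ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(ss)[1])
  mitoGenome(nm, circular = circular, sequence = as.character(ss[[1]]))
}

#' Write a genome to FASTA
#'
#' @param genome a [MitoGenome-class] with sequence.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFastaGenome <- function(genome, path) {
  stopifnot(is(genome, "MitoGenome"), hasSequence(genome))
  ss <- Biostrings::DNAStringSet(genomeSequence(genome))
  names(ss) <- genomeName(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
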