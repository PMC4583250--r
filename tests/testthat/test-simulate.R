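smallCfg <- function(seed = 5L, ...) {
  simConfig(genome_length = 4000L, n_samples = 40L, n_common_variants = 25L,
            n_rare_variants = 40L, n_ref_minor_sites = 2L,
            mean_depth = 150, seed = seed, ...)
}

test_that("toy genomes satisfy the structural contract", {
  cfg <- smallCfg()
  toy <- makeToyGenome(cfg)
  expect_true(validObject(toy$model))
  g <- geneTable(toy$model)
  expect_equal(nrow(g), cfg$n_genes)
  expect_gte(sum(g$strand == "-"), 1L)
  expect_gte(sum(g$biotype == "Mt_rRNA"), 1L)
  expect_gte(sum(g$biotype == "Mt_tRNA"), 1L)
  # at least one overlapping pair
  overlaps <- sum(vapply(2:nrow(g), function(i)
    g$start[i] <= g$end[i - 1L], NA))
  expect_gte(overlaps, 1L)
  # protein-coding spans divisible by 3
  pc <- g$biotype == "protein_coding"
  expect_true(all((g$end[pc] - g$start[pc] + 1L) %% 3L == 0L))
  # at least 3 homopolymer runs of length >= 4 (independent rle count)
  chars <- strsplit(genomeSequence(toy$genome), "")[[1]]
  r <- rle(chars)
  expect_gte(sum(r$lengths >= 4L), 3L)
  expect_error(makeToyGenome(simConfig(genome_length = 1500L)), ">= 2000")
})

test_that("generation is byte-deterministic under a fixed seed", {
  cfg <- smallCfg()
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  b1 <- simulateBundle(cfg, d1)
  b2 <- simulateBundle(cfg, d2)
  for (f in c("ref", "genes", "vcf", "truth"))
    expect_identical(readLines(b1$paths[[f]]), readLines(b2$paths[[f]]),
                     label = f)
  # a different seed changes the genome
  b3 <- makeToyGenome(smallCfg(seed = 6L))
  expect_false(identical(genomeSequence(b3$genome),
                         genomeSequence(b1$genome)))
})

test_that("population structure matches the configured variant classes", {
  cfg <- simConfig(genome_length = 16569L, n_samples = 436L,
                   n_common_variants = 50L, n_rare_variants = 10L,
                   n_ref_minor_sites = 2L, seed = 3L)
  toy <- makeToyGenome(cfg)
  pop <- simulatePopulation(cfg, toy$genome)
  v <- pop$variants
  rare <- v[v$class == "rare", ]
  expect_equal(nrow(rare), 10L)
  expect_true(all(rare$carrier_count >= 1L & rare$carrier_count <= 3L))
  refmin <- v[v$class == "ref_minor", ]
  expect_equal(nrow(refmin), 2L)
  # alt frequency >= 0.95 of 436 samples: carrier counts near 414
  expect_true(all(refmin$carrier_count >= 400L))
  common <- v[v$class == "common", ]
  expect_true(all(common$carrier_count >= 1L))
  # carrier rows agree with the per-variant counts
  expect_equal(nrow(pop$carriers), sum(v$carrier_count))
  # no duplicated keys
  expect_false(anyDuplicated(paste(v$position, v$ref, v$alt)) > 0)
  # zero variants -> empty population
  none <- simConfig(genome_length = 4000L, n_samples = 10L,
                    n_common_variants = 0L, n_rare_variants = 0L,
                    n_ref_minor_sites = 0L, seed = 1L)
  toy0 <- makeToyGenome(none)
  pop0 <- simulatePopulation(none, toy0$genome)
  expect_equal(nrow(pop0$carriers), 0L)
})

test_that("artifact injection follows the configured rates and labels", {
  cfg <- smallCfg(het_artifact_rate = 0.1, strand_artifact_rate = 0.05,
                  homopolymer_indel_rate = 0.02)
  toy <- makeToyGenome(cfg)
  pop <- simulatePopulation(cfg, toy$genome)
  sim <- simulateCalls(pop, cfg, toy$model)
  expect_equal(nrow(sim$calls), nrow(sim$truth))
  expect_true(all(sim$truth$label %in%
                  c("true_variant", "het_artifact", "strand_artifact",
                    "homopolymer_artifact")))
  n_true <- sum(sim$truth$label == "true_variant")
  n_het <- sum(sim$truth$label == "het_artifact")
  # injected het count lies in the 99% binomial band of its rate
  expect_gte(n_het, qbinom(0.005, n_true, 0.1))
  expect_lte(n_het, qbinom(0.995, n_true, 0.1))
  # het labels carry het genotypes; strand artifacts are one-sided
  merged <- merge(sim$calls, sim$truth,
                  by = c("sample_id", "position", "ref", "alt"))
  expect_true(all(merged$genotype_class[merged$label == "het_artifact"] ==
                  "het"))
  sa <- merged[merged$label == "strand_artifact", ]
  expect_true(all(pmin(sa$alt_fwd, sa$alt_rev) == 0L))
  hp <- merged[merged$label == "homopolymer_artifact", ]
  expect_true(all(nchar(hp$ref) != nchar(hp$alt)))
  # rate zero means no labels of that class
  cfg0 <- smallCfg(strand_artifact_rate = 0)
  sim0 <- simulateCalls(simulatePopulation(cfg0, toy$genome), cfg0,
                        toy$model)
  expect_equal(sum(sim0$truth$label == "strand_artifact"), 0L)
})

test_that("filters recover the simulated truth end-to-end", {
  cfg <- smallCfg(het_artifact_rate = 0.08, strand_artifact_rate = 0.08,
                  homopolymer_indel_rate = 0.03)
  toy <- makeToyGenome(cfg)
  pop <- simulatePopulation(cfg, toy$genome)
  sim <- simulateCalls(pop, cfg, toy$model)
  flt <- filterCalls(sim$calls)
  merged <- merge(flt$passed, sim$truth,
                  by = c("sample_id", "position", "ref", "alt"))
  # every injected heterozygous and single-strand artifact is removed
  expect_equal(sum(merged$label %in% c("het_artifact", "strand_artifact")),
               0L)
  # every true call with balanced support at >= 10% survives
  tr <- merge(sim$calls, sim$truth,
              by = c("sample_id", "position", "ref", "alt"))
  tr <- tr[tr$label == "true_variant", ]
  frac <- pmin(tr$alt_fwd, tr$alt_rev) / (tr$alt_fwd + tr$alt_rev)
  balanced <- tr[frac >= 0.10, ]
  key <- function(d) paste(d$sample_id, d$position, d$ref, d$alt)
  expect_true(all(key(balanced) %in% key(flt$passed)))
  # carrier counts of fully retained variants equal the truth counts
  agg <- aggregateCalls(flt$passed)
  truth_counts <- table(paste(tr$position, tr$ref, tr$alt))
  retained <- paste(agg$position, agg$ref, agg$alt)
  full <- retained[retained %in% names(truth_counts)]
  expect_equal(agg$carrier_count[match(full, retained)],
               as.integer(truth_counts[full]))
})
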