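test_that("global enrichment rate follows N/l x 1000", {
  expect_equal(round(globalEnrichment(59, 682), 1), 86.5)
  expect_equal(round(globalEnrichment(96, 1142), 1), 84.1)
  expect_equal(globalEnrichment(0, 1000), 0)
  expect_error(globalEnrichment(10, 0), "positive")
  expect_error(globalEnrichment(-1, 100), "non-negative")
  # scale invariance: r_g(kN, kl) = r_g(N, l)
  for (k in c(2, 5, 10))
    expect_equal(globalEnrichment(k * 59, k * 682),
                 globalEnrichment(59, 682))
})

test_that("weighted enrichment sums carriers over the gene length", {
  # carrier counts summing to 627 over 682 bp reproduce the reported 0.92
  counts <- c(rep(10, 60), rep(1, 27))
  expect_equal(sum(counts), 627)
  expect_equal(round(weightedEnrichment(counts, 682), 2), 0.92)
  expect_equal(weightedEnrichment(counts, 682, "per_Mb"),
               1000 * weightedEnrichment(counts, 682))
  expect_equal(weightedEnrichment(integer(), 682), 0)
  expect_error(weightedEnrichment(c(1, 0), 682), ">= 1")
  expect_error(weightedEnrichment(5, 0), "positive")
})

test_that("reported per-gene rates recompute from counts and lengths", {
  e <- studyEnrichmentInputs()
  rg <- round(globalEnrichment(e$n_variants, e$length), 1)
  agree <- rg == e$rg
  expect_equal(sum(agree), 14L)
  # the single inconsistent row is the large rRNA gene
  expect_equal(e$symbol[!agree], "MT-RNR2")
  expect_equal(rg[e$symbol == "MT-RNR2"], 36.5)   # vs reported 37.2
  # means over the reported columns
  expect_equal(round(mean(e$rg), 1), 64.2)
  expect_equal(mean(e$rw), 0.445, tolerance = 0.01)
})

test_that("normality test wraps Shapiro-Wilk with input validation", {
  e <- studyEnrichmentInputs()
  nt <- normalityTest(e$rg)
  expect_equal(nt$p, 0.34, tolerance = 0.02)
  expect_true(nt$W > 0.9 && nt$W < 1)
  expect_error(normalityTest(c(1, 2)), "at least 3")
  expect_error(normalityTest(rep(5, 10)), "constant")
  # gross violation detected: heavy-tailed sample at fixed seed
  set.seed(17)
  heavy <- rcauchy(15)
  expect_lt(normalityTest(heavy)$p, 0.05)
  expect_equal(normalityTest(heavy)$p, shapiro.test(heavy)$p.value)
})

test_that("percentile conventions agree with closed forms", {
  e <- studyEnrichmentInputs()
  rg <- e$rg
  # strict empirical: 14 of 15 values below the maximum
  expect_equal(percentilePosition(86.5, rg, "empirical_strict"),
               100 * 14 / 15)
  expect_equal(percentilePosition(max(rg), rg, "weibull"), 100 * 15 / 16)
  expect_equal(percentilePosition(84.1, rg, "hazen"), 90)
  expect_equal(percentilePosition(86.5, rg, "normal_model"),
               100 * pnorm((86.5 - mean(rg)) / sd(rg)))
  sym <- c(1, 2, 3, 4, 5)
  expect_equal(percentilePosition(3, sym, "normal_model"), 50)
  expect_error(percentilePosition(1, rep(2, 5), "normal_model"), "zero")
  expect_error(percentilePosition(1, 2), "at least 2")
})

test_that("enrichment table counts overlap variants once per gene", {
  toy <- toyModel()
  agg <- data.frame(
    position = c(165L, 150L, 31L, 75L),
    ref = c("A", "C", "C", "G"), alt = c("G", "A", "A", "A"),
    carrier_count = c(4L, 2L, 1L, 7L), stringsAsFactors = FALSE)
  ann <- annotateVariants(agg, toy$model)
  rep <- enrichmentTable(ann, toy$model)
  rows <- enrichmentRows(rep)
  # tRNA-like gene excluded, all others retained (zeros included)
  expect_false("TRN" %in% rows$gene)
  expect_true(all(c("POS", "RNR", "NEG", "OVA", "OVB", "ORI", "WRP") %in%
                  rows$gene))
  # the 165 variant lies in the OVA/OVB overlap: counted in both
  expect_equal(rows$n_variants[rows$gene == "OVA"], 2L)
  expect_equal(rows$n_variants[rows$gene == "OVB"], 1L)
  expect_equal(rows$carrier_sum[rows$gene == "OVA"], 6L)
  expect_equal(rows$n_variants[rows$gene == "NEG"], 0L)
  expect_equal(rows$r_g[rows$gene == "NEG"], 0)
  # r_g arithmetic on a simple row
  expect_equal(rows$r_g[rows$gene == "POS"],
               globalEnrichment(1, 30))
  # r_w >= r_g on the same per-Mb scale whenever a gene has variants
  repMb <- enrichmentTable(ann, toy$model, rwScale = "per_Mb")
  rMb <- enrichmentRows(repMb)
  has <- rMb$n_variants >= 1L
  expect_true(all(rMb$r_w[has] >= rMb$r_g[has]))
  # unknown gene symbol in the variant table is rejected
  bad <- ann; bad$genes[1] <- "GHOST"
  expect_error(enrichmentTable(bad, toy$model), "GHOST")
})

test_that("single-gene single-variant table gives r_g 1.0 per Mb of 1kb", {
  g <- mitoGenome("g", 1000)
  m <- geneModel(data.frame(symbol = "ONE", biotype = "protein_coding",
                            start = 1L, end = 999L, strand = "+",
                            length = 1000L), g)
  ann <- annotateVariants(
    data.frame(position = 500L, ref = "A", alt = "G", carrier_count = 1L),
    m)
  rows <- enrichmentRows(enrichmentTable(ann, m))
  expect_equal(rows$n_variants, 1L)
  expect_equal(rows$r_g, 1.0)
  expect_equal(rows$carrier_sum, 1L)
})

test_that("gene ranking orders by r_g with lexicographic tie-break", {
  e <- studyEnrichmentInputs()
  rows <- data.frame(gene = e$symbol, biotype = e$biotype,
                     length = e$length, n_variants = e$n_variants,
                     carrier_sum = NA_integer_, r_g = e$rg, r_w = e$rw,
                     percentile = NA_real_, stringsAsFactors = FALSE)
  ranked <- rankGenes(rows)
  expect_equal(ranked$gene[1:2], c("MT-ATP6", "MT-CYB"))
  expect_equal(ranked$r_g[1:2], c(86.5, 84.1))
  # the same two genes top the weighted rate among protein-coding genes
  # (the small-subunit rRNA gene's r_w is inflated by reference-minor sites)
  pc <- rows[rows$biotype == "protein_coding", ]
  expect_equal(pc$gene[order(-pc$r_w)][1:2], c("MT-ATP6", "MT-CYB"))
  ties <- data.frame(gene = c("ZZ", "AA"), r_g = c(5, 5))
  expect_equal(rankGenes(ties)$gene, c("AA", "ZZ"))
  expect_equal(nrow(rankGenes(rows[0, ])), 0L)
})

test_that("enrichment ranks recover simulated per-base density order", {
  # two genes with 5x different variant densities; the denser gene's r_g
  # must come out on top in at least 95 of 100 seeded replicates
  g <- mitoGenome("sim", 3000)
  m <- geneModel(data.frame(
    symbol = c("DENSE", "SPARSE"), biotype = "protein_coding",
    start = c(1L, 1501L), end = c(600L, 2100L), strand = "+",
    length = c(600L, 600L)), g)
  wins <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    nd <- rbinom(1, 600, 0.025)          # dense: 2.5% of positions
    ns <- rbinom(1, 600, 0.005)          # sparse: 0.5%
    pos <- c(sample(1:600, nd), sample(1501:2100, ns))
    if (!length(pos)) next
    ann <- annotateVariants(
      data.frame(position = pos, ref = "A", alt = "G",
                 carrier_count = 1L, stringsAsFactors = FALSE), m)
    rows <- enrichmentRows(enrichmentTable(ann, m))
    if (rows$r_g[rows$gene == "DENSE"] > rows$r_g[rows$gene == "SPARSE"])
      wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})
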