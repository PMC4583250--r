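test_that("variant types classify by allele shape", {
  expect_equal(classifyVariantType("C", "A"), "substitution")
  expect_equal(classifyVariantType("T", "TA"), "insertion")
  expect_equal(classifyVariantType("GA", "G"), "deletion")
  expect_equal(classifyVariantType("AT", "GC"), "complex")
  expect_error(classifyVariantType("", "A"), "non-empty")
  expect_error(classifyVariantType("A", "A"), "differ")
})

test_that("the unknown-variant fixture classifies into 32 substitutions and 3 indels", {
  u <- studyUnknownVariants()
  ty <- classifyVariantType(u$ref, u$alt)
  expect_equal(nrow(u), 35L)
  expect_equal(sum(ty == "substitution"), 32L)
  expect_equal(sum(ty %in% c("insertion", "deletion")), 3L)
})

test_that("codon translation follows the vertebrate mitochondrial code", {
  expect_equal(translateCodon(c("ATA", "TGA", "AGA", "AGG")),
               c("M", "W", "*", "*"))
  expect_equal(translateCodon("ATA", code = "standard"), "I")
  expect_equal(translateCodon("tga"), "W")       # case-insensitive
  expect_error(translateCodon("ATN"), "unambiguous")
  expect_error(translateCodon("AT"), "unambiguous")
  # every printed codon/amino-acid pair of the deleterious-variant fixture
  d <- studyDeleteriousVariants()
  codons <- strsplit(d$codon_change, "/", fixed = TRUE)
  aas <- strsplit(d$aa_change, "/", fixed = TRUE)
  for (i in seq_len(nrow(d))) {
    expect_equal(translateCodon(toupper(codons[[i]][1])), aas[[i]][1],
                 label = d$codon_change[i])
    expect_equal(translateCodon(toupper(codons[[i]][2])), aas[[i]][2],
                 label = d$codon_change[i])
  }
})

test_that("codon context extracts, substitutes and renders codons", {
  toy <- toyModel()
  # plus strand, first codon position: CTA -> ATA gives L -> M
  ctx <- codonContext(31, "C", "A", "POS", toy$model)
  expect_equal(ctx$codon_change, "Cta/Ata")
  expect_equal(ctx$aa_change, "L/M")
  expect_equal(ctx$effect, "missense")
  # third position, synonymous
  ctx2 <- codonContext(36, "T", "C", "POS", toy$model)
  expect_equal(ctx2$codon_change, "caT/caC")
  expect_equal(ctx2$effect, "synonymous")
  # stop gain
  ctx3 <- codonContext(41, "G", "A", "POS", toy$model)
  expect_equal(ctx3$aa_change, "W/*")
  expect_equal(ctx3$effect, "nonsense")
  # minus strand: heavy T>C reads as coding ATG -> GTG (M -> V)
  ctx4 <- codonContext(130, "T", "C", "NEG", toy$model)
  expect_equal(ctx4$codon_change, "Atg/Gtg")
  expect_equal(ctx4$aa_change, "M/V")
  expect_equal(ctx4$effect, "missense")
  # reading frame wraps the circular origin with the gene
  ctx5 <- codonContext(2, "T", "C", "WRP", toy$model)
  expect_equal(ctx5$codon_change, "Tga/Cga")
  expect_equal(ctx5$aa_change, "W/R")
  # errors
  expect_error(codonContext(31, "G", "A", "POS", toy$model),
               "does not match")
  expect_error(codonContext(75, "A", "G", "RNR", toy$model),
               "not protein-coding")
  expect_error(codonContext(31, "C", "A", "NOPE", toy$model), "unknown")
})

test_that("rendered codon pairs uppercase the same position on both sides", {
  toy <- toyModel()
  cases <- list(c(31, "C", "A", "POS"), c(36, "T", "C", "POS"),
                c(130, "T", "C", "NEG"), c(2, "T", "C", "WRP"))
  for (cs in cases) {
    ctx <- codonContext(as.integer(cs[1]), cs[2], cs[3], cs[4], toy$model)
    parts <- strsplit(ctx$codon_change, "/", fixed = TRUE)[[1]]
    up <- lapply(parts, function(p) which(strsplit(p, "")[[1]] %in% LETTERS))
    expect_length(up[[1]], 1L)
    expect_equal(up[[1]], up[[2]])
    # translations match the reported amino-acid letters
    aa <- strsplit(ctx$aa_change, "/", fixed = TRUE)[[1]]
    expect_equal(translateCodon(toupper(parts[1])), aa[1])
    expect_equal(translateCodon(toupper(parts[2])), aa[2])
  }
})

test_that("minus-strand annotation equals plus-strand on the mirrored genome", {
  toy <- toyModel()
  L <- genomeLength(toy$genome)
  seq <- genomeSequence(toy$genome)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
              collapse = "")
  g <- geneTable(toy$model)[geneTable(toy$model)$symbol == "NEG", ]
  mirror <- geneModel(
    data.frame(symbol = "NEGRC", biotype = "protein_coding",
               start = L - g$end + 1L, end = L - g$start + 1L,
               strand = "+", length = g$length),
    mitoGenome("rc", sequence = rc))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (pos in c(101L, 107L, 115L, 128L, 130L)) {
    ref <- substr(seq, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    a <- codonContext(pos, ref, alt, "NEG", toy$model)
    b <- codonContext(L - pos + 1L, comp[[ref]], comp[[alt]], "NEGRC",
                      mirror)
    expect_equal(a, b, label = paste("pos", pos))
  }
})

test_that("conservation and concordance behave as set operations", {
  expect_true(conservationFlag(6489, studyConserved()))
  expect_false(conservationFlag(100, studyConserved()))
  expect_false(conservationFlag(6489, integer()))
  df <- data.frame(
    sift = c("deleterious", "deleterious", NA, "tolerated"),
    polyphen = c("probably_damaging", "possibly_damaging", NA,
                 "probably_damaging"), stringsAsFactors = FALSE)
  kept <- concordanceFilter(df)
  expect_equal(nrow(kept), 1L)
  expect_equal(concordanceFilter(kept), kept)    # idempotent
})

test_that("homopolymer context flags runs, adjacency and circular wrap", {
  g <- mitoGenome("h", sequence = "CGACAAAAGT")   # AAAA at 5..8
  expect_true(all(homopolymerFlag(5:8, g)))
  expect_true(homopolymerFlag(4, g))              # adjacent before
  expect_true(homopolymerFlag(9, g))              # adjacent after
  expect_false(homopolymerFlag(2, g))
  g2 <- mitoGenome("h2", sequence = "ACGTACGTACGT")
  expect_false(any(homopolymerFlag(1:12, g2)))
  # run of 5 split by the origin: TTT...TT
  g3 <- mitoGenome("h3", sequence = "TTTACGCGCGTT")
  expect_true(all(homopolymerFlag(c(11, 12, 1, 2, 3), g3)))
  expect_true(homopolymerFlag(4, g3))             # adjacency
  expect_false(homopolymerFlag(6, g3))
  # linear genome must not join across the ends
  g4 <- mitoGenome("h4", circular = FALSE, sequence = "TTTACGCGCGTT")
  expect_false(any(homopolymerFlag(c(1, 12), g4)))
})

test_that("annotateVariants fills the full bundle per region class", {
  toy <- toyModel()
  # ref alleles match the toy genome bases at each position
  agg <- data.frame(
    position = c(20L, 75L, 31L, 165L, 45L, 12L),
    ref = c("T", "G", "C", "A", "A", "A"),
    alt = c("A", "A", "A", "G", "AA", "G"),
    carrier_count = c(1L, 2L, 3L, 1L, 1L, 1L), stringsAsFactors = FALSE)
  expect_equal(vapply(seq_len(6), function(i)
    substr(genomeSequence(toy$genome), agg$position[i], agg$position[i]),
    ""), substr(agg$ref, 1, 1))
  ann <- annotateVariants(agg, toy$model, catalog = NULL,
                          conserved = c(75L), predictions = NULL)
  expect_equal(ann$region_class,
               c("intergenic", "non_coding_exon", "coding_exon",
                 "coding_exon", "coding_exon", "intergenic"))
  expect_equal(ann$effect[1], "intergenic")
  expect_equal(ann$effect[2], "non_coding")
  expect_equal(ann$effect[5], "frameshift_candidate")
  expect_equal(ann$genes[4], "OVA,OVB")   # overlap keeps both genes
  expect_true(ann$conserved[2])
  expect_false(ann$conserved[1])
  # coding substitution gets codon fields; translation consistency
  expect_false(is.na(ann$codon_change[3]))
  aa <- strsplit(ann$aa_change[3], "/")[[1]]
  cods <- strsplit(ann$codon_change[3], "/")[[1]]
  expect_equal(translateCodon(toupper(cods[1])), aa[1])
  expect_equal(translateCodon(toupper(cods[2])), aa[2])
  # homopolymer flag from the planted AAAA run
  expect_true(ann$homopolymer[6])
  expect_false(ann$homopolymer[1])
  # without genome sequence the codon fields stay NA
  bare <- geneModel(geneTable(toy$model), mitoGenome("b", 200))
  ann2 <- annotateVariants(agg, bare)
  expect_true(all(is.na(ann2$codon_change)))
  expect_true(all(is.na(ann2$homopolymer)))
})

test_that("annotation against the study tables reproduces printed fields", {
  m <- studyGeneModel()
  u <- studyVariantUnion()
  ann <- annotateVariants(u, m, catalog = studyCatalog(),
                          conserved = studyConserved(),
                          predictions = studyPredictions(),
                          rsids = studyRsids())
  expect_equal(nrow(ann), 57L)
  byPos <- function(p) ann[ann$position == p, ]
  expect_equal(byPos(393)$region_class, "intergenic")
  expect_equal(byPos(1713)$genes, "MT-RNR2")
  expect_equal(byPos(1713)$region_class, "non_coding_exon")
  expect_true(grepl("MT-ATP6", byPos(8563)$genes))
  expect_equal(byPos(15218)$rsid, "rs2853506")
  expect_equal(byPos(15218)$mitomap_status, "Known")
  expect_equal(byPos(9500)$mitomap_status, "Unknown")
  expect_equal(sum(ann$mitomap_status == "Unknown"), 35L)
  cc <- concordanceFilter(ann)
  expect_equal(nrow(cc), 24L)
  expect_equal(max(cc$carrier_count), 10L)
  expect_equal(cc$position[which.max(cc$carrier_count)], 15218L)
})
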