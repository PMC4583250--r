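# Hand-built 200 bp circular toy genome with planted codons, an overlap
# pair, a minus-strand gene, origin-spanning features and a homopolymer run.
#
# layout (1-based, heavy strand):
#   POS  protein_coding  +   31..60   codons CTA CAT GCT TGG CCA AGA TAA TGG CAG TAA
#   RNR  Mt_rRNA         +   70..95
#   TRN  Mt_tRNA         +   97..99
#   NEG  protein_coding  -  101..130  heavy 128..130 = CAT -> coding codon 1 ATG
#   OVA  protein_coding  +  140..169
#   OVB  protein_coding  +  160..189  overlaps OVA on 160..169
#   ORI  other           +  191..10   spans the circular origin
#   WRP  protein_coding  +  196..4    9 bp CDS wrapping the origin: ATG AAA TGA
#   homopolymer AAAA at 11..14 (neighbours C at 10, G at 15)
toyModel <- function() {
  s <- rep(c("A", "C", "G", "T"), 50)
  s[31:60] <- strsplit("CTACATGCTTGGCCAAGATAATGGCAGTAA", "")[[1]]
  s[128:130] <- c("C", "A", "T")
  s[196:200] <- c("A", "T", "G", "A", "A")
  s[1:4] <- c("A", "T", "G", "A")
  s[11:14] <- "A"
  genome <- mitoGenome("toy", sequence = paste(s, collapse = ""))
  genes <- data.frame(
    symbol = c("POS", "RNR", "TRN", "NEG", "OVA", "OVB", "ORI", "WRP"),
    biotype = c("protein_coding", "Mt_rRNA", "Mt_tRNA", "protein_coding",
                "protein_coding", "protein_coding", "other",
                "protein_coding"),
    start = c(31L, 70L, 97L, 101L, 140L, 160L, 191L, 196L),
    end = c(60L, 95L, 99L, 130L, 169L, 189L, 10L, 4L),
    strand = c("+", "+", "+", "-", "+", "+", "+", "+"),
    length = c(30L, 26L, 3L, 30L, 30L, 30L, 20L, 9L),
    stringsAsFactors = FALSE)
  list(genome = genome, model = geneModel(genes, genome))
}

# valid random call frames for filter property tests
randomCalls <- function(n, seed) {
  set.seed(seed)
  depth <- rpois(n, 80) + 1L
  alt_tot <- rbinom(n, depth, 0.9)
  fwd <- rbinom(n, alt_tot, runif(n))   # arbitrary strand skew
  data.frame(
    sample_id = sprintf("S%02d", sample.int(20, n, replace = TRUE)),
    position = sample.int(500, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = "N_FIXED",   # placeholder, fixed below
    genotype_class = sample(c("hom_alt", "het", "missing", "hom_ref"), n,
                            replace = TRUE, prob = c(0.7, 0.15, 0.05, 0.1)),
    alt_fwd = fwd, alt_rev = alt_tot - fwd, depth = depth,
    stringsAsFactors = FALSE) -> df
  df$alt <- vapply(df$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), "", USE.NAMES = FALSE)
  df
}

# call-frame sorter for order-insensitive comparisons
sortCalls <- function(d)
  `rownames<-`(d[order(d$position, d$ref, d$alt, d$sample_id), ], NULL)
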