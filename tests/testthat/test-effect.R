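# Effect classification against hand-built CDS fixtures.

plusCds <- function(seq, contig = "chr") {
  GenomicRanges::GRanges(contig, IRanges::IRanges(1, nchar(seq)),
                         strand = "+", type = "CDS", ID = "g1", phase = 0L)
}

test_that("indels are frameshift or in-frame by length modulo 3", {
  refseq <- Biostrings::DNAStringSet(c(chr = "ATGAAACGTTAA"))
  cds <- plusCds("ATGAAACGTTAA")
  expect_equal(classifyEffect(4, "A", "+T", cds, refseq, "chr")$effect,
               "frameshift")
  expect_equal(classifyEffect(4, "A", "+TGA", cds, refseq, "chr")$effect,
               "inframe_indel")
  expect_equal(classifyEffect(4, "A", "-AC", cds, refseq, "chr")$effect,
               "frameshift")
  expect_equal(classifyEffect(4, "A", "-ACG", cds, refseq, "chr")$effect,
               "inframe_indel")
})

test_that("substitutions are translated through their codon", {
  refseq <- Biostrings::DNAStringSet(c(chr = "ATGTACCGTTAA"))
  cds <- plusCds("ATGTACCGTTAA")
  # codon 2 TAC (Y): first base T>G gives GAC (D)
  expect_equal(classifyEffect(3, "T", "G", cds, refseq, "chr"),
               list(effect = "missense", detail = "Y2D"))
  # third base C>T gives TAT, still Y
  expect_equal(classifyEffect(5, "C", "T", cds, refseq, "chr")$effect,
               "synonymous")
  # C>A gives TAA: stop gained
  expect_equal(classifyEffect(5, "C", "A", cds, refseq, "chr"),
               list(effect = "nonsense", detail = "Y2*"))
  # outside the CDS
  refseq2 <- Biostrings::DNAStringSet(c(chr = paste0("ATGTACCGTTAA",
                                                     "GGGG")))
  expect_equal(classifyEffect(14, "G", "A", cds, refseq2, "chr")$effect,
               "intergenic")
})

test_that("an arginine-to-cysteine change at codon 276 is labelled R276C", {
  body <- paste(rep("GCT", 273), collapse = "")      # codons 2..274: Ala
  orf <- paste0("ATG", body, "GCA",                  # codon 275
                "CGT",                               # codon 276: Arg
                "GCC", "TAA")
  pad <- paste(rep("T", 100), collapse = "")
  seq <- paste0(pad, orf, pad)
  refseq <- Biostrings::DNAStringSet(seq)
  names(refseq) <- "chr"
  cds <- GenomicRanges::GRanges("chr",
                                IRanges::IRanges(101, 100 + nchar(orf)),
                                strand = "+", type = "CDS", ID = "g1",
                                phase = 0L)
  pos <- 100 + 275 * 3   # 0-based first base of codon 276
  res <- classifyEffect(pos, "C", "T", cds, refseq, "chr")
  expect_equal(res$effect, "missense")
  expect_equal(res$detail, "R276C")
})

test_that("minus-strand CDS are translated in the coding orientation", {
  coding <- "ATGAAACGTTAA"
  genomic <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(coding)))
  refseq <- Biostrings::DNAStringSet(genomic)
  names(refseq) <- "chr"
  cds <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, nchar(genomic)),
                                strand = "-", type = "CDS", ID = "g1",
                                phase = 0L)
  # coding offset 3 (codon 2, AAA = K) maps to genomic 0-based pos 8,
  # genomic base T; T>C in genomic space is A>G in coding space: K2E
  expect_equal(classifyEffect(8, "T", "C", cds, refseq, "chr"),
               list(effect = "missense", detail = "K2E"))
})

test_that("a CDS whose length is not a multiple of three is flagged", {
  refseq <- Biostrings::DNAStringSet(c(chr = "ATGAAACGTTAAG"))
  cds <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 13),
                                strand = "+", type = "CDS", ID = "g1",
                                phase = 0L)
  expect_error(classifyEffect(3, "A", "G", cds, refseq, "chr"),
               "not a multiple of 3")
})

test_that("divergent-site tables are annotated in place", {
  refseq <- Biostrings::DNAStringSet(c(chr = "ATGTACCGTTAA"))
  cds <- plusCds("ATGTACCGTTAA")
  sites <- data.frame(contig = "chr", pos = c(3, 4), ref = c("T", "A"),
                      alt = c("G", "+T"), altCount = c(70, 70),
                      depth = c(150, 150), fraction = c(0.47, 0.47),
                      dupStart = 0, dupEnd = 12,
                      stringsAsFactors = FALSE)
  ann <- annotateDivergentSites(sites, cds, refseq)
  expect_equal(ann$effect, c("missense", "frameshift"))
  expect_equal(ann$effectDetail[1], "Y2D")
})
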