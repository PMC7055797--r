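# Synthetic sequencing signal: reference sequences, coverage tracks with
# embedded duplications, pileups with divergent sites, and the packaged
# worked-case fixture. All randomness is seed-controlled so fixtures are
# byte-reproducible.

#' Generate a random reference sequence with an optional embedded CDS
#'
#' Uniform-random A/C/G/T sequence of the requested length. When `cds` is
#' `TRUE`, an open reading frame (ATG, stop-free random codons, TAA) is
#' written into the sequence at `cdsStart` and returned as a CDS annotation,
#' for effect-classification work.
#'
#' @param length Contig length in bp; at least 1000.
#' @param seed Integer seed; the same seed gives the same bytes.
#' @param cds `TRUE` to embed a CDS.
#' @param cdsStart 0-based start of the embedded CDS. Default places it
#'   mid-contig.
#' @param cdsCodons Number of codons including start and stop. Default 300.
#' @param contig Contig name.
#' @return `list(seq = <DNAStringSet named by contig>,
#'   cds = <GRanges or NULL>)`.
#' @examples
#' ref <- makeReference(10000, seed = 1, cds = TRUE)
#' ref$cds
#' @export
makeReference <- function(length, seed = 1, cds = FALSE, cdsStart = NULL,
                          cdsCodons = 300L, contig = "contig_1") {
  length <- as.integer(length)
  if (length < 1000L)
    stop("reference length must be at least 1000 bp")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  seq <- sample(bases, length, replace = TRUE)

  cdsGr <- NULL
  if (isTRUE(cds)) {
    cdsCodons <- as.integer(cdsCodons)
    cdsLen <- 3L * cdsCodons
    if (is.null(cdsStart)) cdsStart <- (length - cdsLen) %/% 2L
    cdsStart <- as.integer(cdsStart)
    if (cdsStart < 0L || cdsStart + cdsLen > length)
      stop("embedded CDS does not fit in the contig")
    codons <- apply(expand.grid(bases, bases, bases), 1L, paste0,
                    collapse = "")
    sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
    body <- sample(sense, cdsCodons - 2L, replace = TRUE)
    orf <- strsplit(paste0("ATG", paste(body, collapse = ""), "TAA"),
                    "")[[1L]]
    seq[(cdsStart + 1L):(cdsStart + cdsLen)] <- orf
    cdsGr <- GenomicRanges::GRanges(
      seqnames = contig,
      ranges = IRanges::IRanges(start = cdsStart + 1L,
                                end = cdsStart + cdsLen),
      strand = "+")
    S4Vectors::mcols(cdsGr)$type <- "CDS"
    S4Vectors::mcols(cdsGr)$ID <- "gene_1"
    S4Vectors::mcols(cdsGr)$phase <- 0L
  }
  dna <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(dna) <- contig
  list(seq = dna, cds = cdsGr)
}

#' Simulate a coverage track with embedded duplications
#'
#' Per-base depth is drawn from a negative binomial with mean
#' `meanDepth * copy` at each position (copy number 1 outside the spec's
#' duplication intervals) and dispersion `dispersion`
#' (variance `mu + dispersion * mu^2`); dispersion 0 gives Poisson depth.
#' Each base is drawn independently -- read-length autocorrelation is not
#' emulated, which is sufficient for windowed statistics.
#'
#' @param spec A [syntheticSpec()].
#' @return `list(track = <CoverageTrack>, truth = <GRanges of the true
#'   duplication intervals, mcols copy>)`.
#' @examples
#' sp <- syntheticSpec(50000, 150, duplications = data.frame(
#'   start = 20000, end = 35000, copy = 2), seed = 3)
#' cov <- simulateCoverage(sp)
#' mean(cov$track@depth[20001:35000]) / mean(cov$track@depth[1:20000])
#' @export
simulateCoverage <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  set.seed(as.integer(spec@seed))
  L <- as.integer(spec@contigLength)
  copy <- rep(1, L)
  d <- spec@duplications
  for (i in seq_len(nrow(d)))
    copy[(d$start[i] + 1L):d$end[i]] <- d$copy[i]
  mu <- spec@meanDepth * copy
  depth <- if (spec@dispersion > 0)
    stats::rnbinom(L, mu = mu, size = 1 / spec@dispersion)
  else stats::rpois(L, mu)

  truth <- if (nrow(d))
    GenomicRanges::GRanges(spec@contig,
                           IRanges::IRanges(start = d$start + 1L,
                                            end = d$end),
                           copy = d$copy)
  else GenomicRanges::GRanges()
  list(track = coverageTrack(spec@contig, depth), truth = truth)
}

#' Simulate a pileup with divergent sites
#'
#' At each divergent site of the spec, the total depth is drawn exactly as
#' in [simulateCoverage()] (honoring the local copy number) and the
#' alternate-allele count binomially with the site's true fraction; the
#' remainder of the depth is reference reads. Additional `positions` are
#' emitted as reference-only sites. A distinct seed stream (`seed + 1`)
#' keeps the pileup independent of the coverage track of the same spec.
#'
#' @param spec A [syntheticSpec()].
#' @param reference Optional reference ([Biostrings::DNAStringSet]); when
#'   given, reference alleles are the actual bases, otherwise `"A"`.
#' @param positions Optional extra 0-based positions emitted as
#'   reference-only pileup sites.
#' @return `list(pileup = <data.frame contig/pos/ref/allele/count>,
#'   truth = <data.frame pos/alt/fraction/depth/altCount>)`.
#' @examples
#' sp <- syntheticSpec(50000, 150,
#'   duplications = data.frame(start = 20000, end = 35000, copy = 2),
#'   divergentSites = data.frame(pos = 25000, alt = "+T", fraction = 0.49),
#'   seed = 3)
#' simulatePileup(sp)$pileup
#' @export
simulatePileup <- function(spec, reference = NULL, positions = NULL) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  set.seed(as.integer(spec@seed) + 1L)
  d <- spec@duplications
  localCopy <- function(pos) {
    for (i in seq_len(nrow(d)))
      if (pos >= d$start[i] && pos < d$end[i]) return(d$copy[i])
    1
  }
  refBase <- function(pos) {
    if (is.null(reference)) return("A")
    substr(.contigSeq(reference, spec@contig), pos + 1L, pos + 1L)
  }
  sites <- spec@divergentSites
  pile <- list()
  truth <- list()
  for (i in seq_len(nrow(sites))) {
    pos <- sites$pos[i]
    mu <- spec@meanDepth * localCopy(pos)
    depth <- if (spec@dispersion > 0)
      stats::rnbinom(1L, mu = mu, size = 1 / spec@dispersion)
    else stats::rpois(1L, mu)
    depth <- max(depth, 1L)
    altCount <- stats::rbinom(1L, depth, sites$fraction[i])
    ref <- refBase(pos)
    pile[[length(pile) + 1L]] <- data.frame(
      contig = spec@contig, pos = pos, ref = ref,
      allele = c(ref, sites$alt[i]),
      count = c(depth - altCount, altCount), stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      pos = pos, alt = sites$alt[i], fraction = sites$fraction[i],
      depth = depth, altCount = altCount, stringsAsFactors = FALSE)
  }
  for (pos in setdiff(as.integer(positions), sites$pos)) {
    mu <- spec@meanDepth * localCopy(pos)
    depth <- if (spec@dispersion > 0)
      stats::rnbinom(1L, mu = mu, size = 1 / spec@dispersion)
    else stats::rpois(1L, mu)
    ref <- refBase(pos)
    pile[[length(pile) + 1L]] <- data.frame(
      contig = spec@contig, pos = pos, ref = ref, allele = ref,
      count = max(depth, 0L), stringsAsFactors = FALSE)
  }
  pileup <- if (length(pile)) do.call(rbind, pile)
  else data.frame(contig = character(), pos = integer(), ref = character(),
                  allele = character(), count = numeric())
  pileup <- pileup[order(pileup$pos), , drop = FALSE]
  rownames(pileup) <- NULL
  truthDf <- if (length(truth)) do.call(rbind, truth)
  else data.frame(pos = integer(), alt = character(), fraction = numeric(),
                  depth = integer(), altCount = integer())
  list(pileup = pileup, truth = truthDf)
}

#' The packaged worked-case fixture
#'
#' A deterministic bundle mirroring the single fully printed real case the
#' scanner targets: a 21 kb duplication at copy number 2 inside a 200 kb
#' contig, with one 1-bp thymine insertion present on one of the two copies
#' (true alternate fraction 0.49) inside an annotated CDS, and the
#' background depth calibrated (77.5x at single copy) so the divergent
#' site's expected depth is about 155x. Truth objects for the duplication
#' and the site are included.
#'
#' @param seed Integer seed; the default is the packaged fixture. The same
#'   seed reproduces the bundle byte for byte.
#' @return `list(spec, reference, cds, track, truthDups, pileup,
#'   truthSites)`.
#' @examples
#' fx <- fig4cFixture()
#' fx$truthSites
#' @export
fig4cFixture <- function(seed = 1) {
  contig <- "synthetic_contig"
  dupStart <- 50000L
  dupEnd <- 71000L       # 21 kb duplication
  sitePos <- 60000L
  spec <- syntheticSpec(
    contigLength = 200000L, meanDepth = 77.5, dispersion = 0.05,
    duplications = data.frame(start = dupStart, end = dupEnd, copy = 2),
    divergentSites = data.frame(pos = sitePos, alt = "+T",
                                fraction = 0.49,
                                stringsAsFactors = FALSE),
    seed = seed, contig = contig)
  ref <- makeReference(200000L, seed = seed + 2L, cds = TRUE,
                       cdsStart = 59400L, cdsCodons = 300L,
                       contig = contig)
  cov <- simulateCoverage(spec)
  pu <- simulatePileup(spec, reference = ref$seq)
  list(spec = spec, reference = ref$seq, cds = ref$cds,
       track = cov$track, truthDups = cov$truth,
       pileup = pu$pileup, truthSites = pu$truth)
}

#' Write a synthetic bundle to disk
#'
#' Writes the fixture/bundle files in the plain-text formats the scanner
#' reads back: reference FASTA, coverage bedGraph, pileup TSV, CDS GFF3,
#' and truth BED/TSV.
#'
#' @param bundle A list as returned by [fig4cFixture()] (or assembled from
#'   [simulateCoverage()] / [simulatePileup()] output).
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix. Default `"synthetic"`.
#' @return Invisibly, the named vector of written paths.
#' @export
writeSyntheticBundle <- function(bundle, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  if (!is.null(bundle$reference)) {
    Biostrings::writeXStringSet(bundle$reference, p(".fasta"))
    paths["fasta"] <- p(".fasta")
  }
  if (!is.null(bundle$track)) {
    writeCoverageBedGraph(bundle$track, p(".bedgraph"))
    paths["bedgraph"] <- p(".bedgraph")
  }
  if (!is.null(bundle$pileup)) {
    writePileup(bundle$pileup, p(".pileup.tsv"))
    paths["pileup"] <- p(".pileup.tsv")
  }
  if (!is.null(bundle$cds)) {
    writeAnnotationGFF3(bundle$cds, p(".gff3"))
    paths["gff3"] <- p(".gff3")
  }
  if (!is.null(bundle$truthDups) && length(bundle$truthDups)) {
    gr <- bundle$truthDups
    lines <- sprintf("%s\t%d\t%d\tdup_%d\t%d\t.",
                     as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr) - 1L,
                     GenomicRanges::end(gr),
                     seq_along(gr),
                     as.integer(S4Vectors::mcols(gr)$copy) * 1000L)
    writeLines(lines, p(".truth.bed"))
    paths["truth_bed"] <- p(".truth.bed")
  }
  if (!is.null(bundle$truthSites)) {
    utils::write.table(bundle$truthSites, p(".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths["truth_tsv"] <- p(".truth.tsv")
  }
  invisible(paths)
}
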