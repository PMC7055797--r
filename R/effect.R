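# Minimal variant-effect classification of divergent sites against a CDS
# annotation: indels are frameshift/in-frame by length modulo 3;
# substitutions are translated through the codon they hit, honoring strand
# and phase.

#' Classify the coding effect of a divergent site
#'
#' An insertion or deletion allele whose length is not a multiple of 3
#' inside a CDS is a `frameshift`; a multiple of 3 is an `inframe_indel`.
#' A substitution inside a CDS is translated through its codon and labelled
#' `synonymous`, `missense` (with the amino-acid change, e.g. `"R276C"`) or
#' `nonsense`. Sites outside every CDS are `intergenic`.
#'
#' @param pos 0-based genomic position of the site.
#' @param ref Reference base at the site.
#' @param allele Alternate allele: a base, or `"+SEQ"` / `"-SEQ"` for an
#'   insertion/deletion of SEQ.
#' @param cds A [GenomicRanges::GRanges] of CDS intervals (1-based, as
#'   imported from GFF3); multi-interval genes are spliced in genomic
#'   order. Strand and `phase` metadata are honored. A CDS whose spliced
#'   length (after phase trimming) is not a multiple of 3 is an error.
#' @param reference A [Biostrings::DNAStringSet] holding the contig
#'   sequence (named by contig), or a single `DNAString`.
#' @param contig Contig of the site (used to match `cds` and `reference`).
#' @return `list(effect = <label>, detail = <amino-acid change or NA>)`.
#' @examples
#' # a CDS 1..9 on the forward strand of a toy contig
#' refseq <- Biostrings::DNAStringSet(c(chr = "ATGCGTTAA"))
#' cds <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 9),
#'                               strand = "+", phase = 0L)
#' classifyEffect(4, "C", "T", cds, refseq, "chr")   # R2C missense
#' @export
classifyEffect <- function(pos, ref, allele, cds, reference,
                           contig = NULL) {
  pos <- as.integer(pos)
  mc <- S4Vectors::mcols(cds)
  cdsRows <- if ("type" %in% names(mc))
    cds[as.character(mc$type) == "CDS"] else cds
  if (!is.null(contig))
    cdsRows <- cdsRows[as.character(GenomicRanges::seqnames(cdsRows)) == contig]
  hitIdx <- which(GenomicRanges::start(cdsRows) - 1L <= pos &
                    GenomicRanges::end(cdsRows) > pos)
  if (!length(hitIdx))
    return(list(effect = "intergenic", detail = NA_character_))

  first <- substr(allele, 1L, 1L)
  if (first %in% c("+", "-")) {
    len <- nchar(allele) - 1L
    if (len < 1L) stop("malformed indel allele: ", allele)
    eff <- if (len %% 3L == 0L) "inframe_indel" else "frameshift"
    return(list(effect = eff, detail = sprintf("%s%dbp", first, len)))
  }

  # substitution: splice the hit gene's CDS intervals and translate the codon
  mcR <- S4Vectors::mcols(cdsRows)
  idCol <- intersect(c("ID", "gene", "Name"), names(mcR))[1L]
  if (!is.na(idCol)) {
    ids <- as.character(mcR[[idCol]])
    cdsRows <- cdsRows[!is.na(ids) & ids == ids[hitIdx[1L]]]
  }
  exons <- sort(cdsRows)
  strand <- as.character(GenomicRanges::strand(exons))[1L]
  seq <- .contigSeq(reference, if (is.null(contig))
    as.character(GenomicRanges::seqnames(exons))[1L] else contig)
  parts <- vapply(seq_along(exons), function(i)
    substr(seq, GenomicRanges::start(exons)[i],
           GenomicRanges::end(exons)[i]), character(1L))
  spliced <- paste(parts, collapse = "")

  widths <- GenomicRanges::width(exons)
  hit <- which(GenomicRanges::start(exons) - 1L <= pos &
                 GenomicRanges::end(exons) > pos)[1L]
  offLeft <- (if (hit > 1L) sum(widths[seq_len(hit - 1L)]) else 0L) +
    (pos - (GenomicRanges::start(exons)[hit] - 1L))

  phases <- S4Vectors::mcols(exons)$phase
  if (is.null(phases)) phases <- rep(0L, length(exons))
  phases[is.na(phases)] <- 0L

  if (strand == "-") {
    coding <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(spliced)))
    offset <- nchar(spliced) - 1L - offLeft
    phase <- phases[length(exons)]
  } else {
    coding <- spliced
    offset <- offLeft
    phase <- phases[1L]
  }
  coding <- substr(coding, phase + 1L, nchar(coding))
  offset <- offset - phase
  if (offset < 0L)
    return(list(effect = "intergenic", detail = NA_character_))
  if (nchar(coding) %% 3L != 0L)
    stop(sprintf("malformed annotation: spliced CDS length %d is not a multiple of 3",
                 nchar(coding)))

  codonIdx <- offset %/% 3L
  posInCodon <- offset %% 3L
  codon <- substr(coding, codonIdx * 3L + 1L, codonIdx * 3L + 3L)
  refC <- if (strand == "-") .complementBase(ref) else toupper(ref)
  altC <- if (strand == "-") .complementBase(allele) else toupper(allele)
  if (substr(codon, posInCodon + 1L, posInCodon + 1L) != refC)
    warning(sprintf("reference allele '%s' does not match the annotated sequence at position %d",
                    ref, pos))
  newCodon <- codon
  substr(newCodon, posInCodon + 1L, posInCodon + 1L) <- altC

  code <- Biostrings::GENETIC_CODE
  aaRef <- unname(code[codon])
  aaAlt <- unname(code[newCodon])
  if (is.na(aaRef) || is.na(aaAlt))
    stop("codon contains non-ACGT characters: ", codon, "/", newCodon)
  if (aaRef == aaAlt)
    list(effect = "synonymous",
         detail = sprintf("%s%d%s", aaRef, codonIdx + 1L, aaAlt))
  else if (aaAlt == "*")
    list(effect = "nonsense",
         detail = sprintf("%s%d*", aaRef, codonIdx + 1L))
  else
    list(effect = "missense",
         detail = sprintf("%s%d%s", aaRef, codonIdx + 1L, aaAlt))
}

.contigSeq <- function(reference, contig) {
  if (is(reference, "DNAStringSet")) {
    if (!is.null(names(reference)) && contig %in% names(reference))
      return(as.character(reference[[contig]]))
    return(as.character(reference[[1L]]))
  }
  as.character(reference)
}

.complementBase <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[[toupper(b)]]
}

#' Annotate divergent-site calls with coding effects
#'
#' Applies [classifyEffect()] to every row of a [callDivergentSites()]
#' result.
#'
#' @param sites Divergent-site data.frame.
#' @param cds CDS annotation ([GenomicRanges::GRanges]).
#' @param reference Contig sequence(s) ([Biostrings::DNAStringSet]).
#' @return `sites` with added `effect` and `effectDetail` columns.
#' @export
annotateDivergentSites <- function(sites, cds, reference) {
  if (!nrow(sites)) {
    sites$effect <- character()
    sites$effectDetail <- character()
    return(sites)
  }
  res <- lapply(seq_len(nrow(sites)), function(i)
    classifyEffect(sites$pos[i], sites$ref[i], sites$alt[i], cds,
                   reference, contig = sites$contig[i]))
  sites$effect <- vapply(res, `[[`, character(1L), "effect")
  sites$effectDetail <- vapply(res, function(r)
    as.character(r$detail), character(1L))
  sites
}
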