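# Read-depth scanner: sliding-window statistics, median normalization,
# duplication calling, and divergent-site detection inside called regions.
# Duplicated chromosomal segments show up as blocks of ~2x depth; a
# diverging duplication additionally carries a variant at ~50% of the reads
# because only one of the two copies holds it.

#' Sliding-window depth statistics
#'
#' Minimum, mean and maximum depth in windows of `window` bp placed every
#' `step` bp along the contig (0-based half-open coordinates). The trailing
#' partial window is dropped.
#'
#' @param track A [coverageTrack()].
#' @param window Window size in bp. Default 1000.
#' @param step Step between window starts in bp. Default 100.
#' @return data.frame with columns `start`, `end`, `min`, `mean`, `max`,
#'   one row per window.
#' @examples
#' tr <- coverageTrack("chr", rep(150, 5000))
#' head(slidingWindowStats(tr))
#' @export
slidingWindowStats <- function(track, window = 1000L, step = 100L) {
  stopifnot(is(track, "CoverageTrack"))
  window <- as.integer(window); step <- as.integer(step)
  L <- length(track@depth)
  if (window > L)
    stop(sprintf("window (%d bp) exceeds contig length (%d bp)", window, L))
  if (window < 1L || step < 1L) stop("window and step must be positive")
  starts <- seq.int(0L, L - window, by = step)
  d <- track@depth

  if (window %% step == 0L) {
    # chunked computation: per-step-chunk stats, then aggregate the
    # window/step chunks covering each window (exact for equal chunks)
    nChunk <- L %/% step
    M <- matrix(d[seq_len(nChunk * step)], nrow = step)
    rows <- asplit(M, 1L)
    cMin <- do.call(pmin, rows)
    cMax <- do.call(pmax, rows)
    cSum <- colSums(M)
    m <- window %/% step
    nW <- length(starts)
    idx <- outer(seq_len(nW) - 1L, seq_len(m) - 1L, `+`) + 1L
    wMin <- do.call(pmin, lapply(seq_len(m), function(j) cMin[idx[, j]]))
    wMax <- do.call(pmax, lapply(seq_len(m), function(j) cMax[idx[, j]]))
    wSum <- rowSums(matrix(cSum[idx], nrow = nW))
    res <- data.frame(start = starts, end = starts + window,
                      min = wMin, mean = wSum / window, max = wMax)
  } else {
    stats <- vapply(starts, function(s) {
      w <- d[(s + 1L):(s + window)]
      c(min(w), mean(w), max(w))
    }, numeric(3L))
    res <- data.frame(start = starts, end = starts + window,
                      min = stats[1L, ], mean = stats[2L, ],
                      max = stats[3L, ])
  }
  res
}

#' Normalize window means to the genome-wide baseline
#'
#' Divides each window's mean depth by the median of all window means. The
#' median is a robust single-copy baseline as long as duplicated windows
#' are a minority of the contig, so single-copy windows sit near ratio 1
#' and two-copy windows near ratio 2.
#'
#' @param stats Window statistics from [slidingWindowStats()].
#' @return The input data.frame with an added `ratio` column.
#' @examples
#' tr <- coverageTrack("chr", rep(150, 5000))
#' head(normalizeCoverage(slidingWindowStats(tr)))
#' @export
normalizeCoverage <- function(stats) {
  stopifnot(is.data.frame(stats), nrow(stats) > 0L, "mean" %in% names(stats))
  baseline <- stats::median(stats$mean)
  if (baseline <= 0)
    stop("cannot normalize an all-zero coverage track (median window mean is 0)")
  stats$ratio <- stats$mean / baseline
  stats
}

#' Call duplicated regions from normalized window ratios
#'
#' Maximal runs of consecutive windows with normalized ratio at least
#' `minRatio` become candidate calls; candidates separated by at most
#' `mergeGap` bp are merged; merged calls shorter than `minLength` bp are
#' discarded. Call boundaries start at the midpoints of the outermost
#' qualifying windows and are then refined by interpolating where the
#' window-ratio ramp crosses half-way between the background (ratio 1) and
#' the call's interior ratio; on a clean 2x block this recovers the true
#' edges exactly, and under depth noise to well within one window step.
#'
#' @param stats Normalized window statistics ([normalizeCoverage()]).
#' @param contig Contig name for the calls.
#' @param minRatio Minimum normalized ratio. Default 1.5.
#' @param minLength Minimum call length in bp. Default 5000.
#' @param mergeGap Maximum gap merged between runs, bp. Default 2000.
#' @return A [GenomicRanges::GRanges] (0-based starts stored in
#'   `mcols()$start0`; the GRanges itself is 1-based per Bioconductor
#'   convention) with metadata columns `meanRatio` and `lengthBp`.
#' @examples
#' d <- rep(150, 50000); d[20001:35000] <- 300
#' st <- normalizeCoverage(slidingWindowStats(coverageTrack("chr", d)))
#' callDuplications(st, "chr")
#' @export
callDuplications <- function(stats, contig = "contig_1", minRatio = 1.5,
                             minLength = 5000, mergeGap = 2000) {
  stopifnot("ratio" %in% names(stats))
  step <- if (nrow(stats) > 1L) stats$start[2L] - stats$start[1L]
          else stats$end[1L] - stats$start[1L]
  window <- stats$end[1L] - stats$start[1L]
  half <- window %/% 2L

  qual <- which(stats$ratio >= minRatio)
  if (!length(qual)) return(.emptyCalls(contig))

  runBreak <- c(TRUE, diff(qual) != 1L)
  runId <- cumsum(runBreak)
  starts <- ends <- numeric(max(runId))
  for (r in seq_len(max(runId))) {
    w <- qual[runId == r]
    starts[r] <- stats$start[w[1L]] + half
    ends[r] <- stats$start[w[length(w)]] + half
  }
  ends <- pmax(ends, starts + step)

  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends),
                        min.gapwidth = mergeGap + 1L)
  ir <- ir[IRanges::width(ir) >= minLength]
  if (!length(ir)) return(.emptyCalls(contig))

  centers <- stats$start + half
  refined <- vapply(seq_along(ir), function(i) {
    .refineCallEdges(IRanges::start(ir)[i] - 1L, IRanges::end(ir)[i],
                     stats, centers, half, step)
  }, numeric(2L))
  ir <- IRanges::IRanges(start = refined[1L, ] + 1L, end = refined[2L, ])
  ir <- ir[IRanges::width(ir) >= minLength]
  if (!length(ir)) return(.emptyCalls(contig))

  meanRatio <- vapply(seq_along(ir), function(i) {
    s0 <- IRanges::start(ir)[i] - 1L
    e0 <- IRanges::end(ir)[i]
    mean(stats$ratio[centers >= s0 & centers < e0])
  }, numeric(1L))

  gr <- GenomicRanges::GRanges(seqnames = contig, ranges = ir)
  S4Vectors::mcols(gr)$start0 <- IRanges::start(ir) - 1L
  S4Vectors::mcols(gr)$meanRatio <- meanRatio
  S4Vectors::mcols(gr)$lengthBp <- IRanges::width(ir)
  gr
}

# Refine one call's edges by locating where the window-ratio ramp crosses
# the midpoint between background (1) and the call's interior ratio. A
# window overlapping a copy-number edge has an expected ratio that ramps
# linearly across one window width, so the midpoint crossing, linearly
# interpolated between adjacent windows, estimates the true edge without
# the half-window quantization (and threshold-miss asymmetry) of raw
# qualifying-window edges. Returns c(start0, end0).
.refineCallEdges <- function(s0, e0, stats, centers, half, step) {
  inside <- which(centers > s0 + half / 2 & centers < e0 - half / 2)
  if (!length(inside)) inside <- which(centers > s0 & centers < e0)
  if (!length(inside)) return(c(s0, e0))
  rIn <- mean(stats$ratio[inside])
  t <- (1 + rIn) / 2
  r <- stats$ratio
  n <- length(r)
  if (n < 2L) return(c(s0, e0))
  m <- max(1L, (2L * half) %/% step)

  jLead <- inside[1L]
  lo <- max(1L, jLead - m - 1L)
  hi <- min(n - 1L, jLead + m)
  newS <- s0
  for (i in seq(hi, lo)) {
    if (r[i] < t && r[i + 1L] >= t) {
      sx <- stats$start[i] + step * (t - r[i]) / (r[i + 1L] - r[i])
      newS <- round(sx) + half
      break
    }
  }

  jTrail <- inside[length(inside)]
  lo <- max(1L, jTrail - m)
  hi <- min(n - 1L, jTrail + m + 1L)
  newE <- e0
  for (i in seq(lo, hi)) {
    if (r[i] >= t && r[i + 1L] < t) {
      sx <- stats$start[i] + step * (r[i] - t) / (r[i] - r[i + 1L])
      newE <- round(sx) + half
      break
    }
  }
  if (newE <= newS) return(c(s0, e0))
  c(newS, newE)
}

.emptyCalls <- function(contig) {
  gr <- GenomicRanges::GRanges(seqnames = character(),
                               ranges = IRanges::IRanges())
  S4Vectors::mcols(gr)$start0 <- integer()
  S4Vectors::mcols(gr)$meanRatio <- numeric()
  S4Vectors::mcols(gr)$lengthBp <- integer()
  gr
}

#' Call divergent sites inside duplicated regions
#'
#' A diverging duplication carries a variant on one of its two copies, seen
#' as an alternate allele at an intermediate fraction of the reads
#' (~50% for a balanced two-copy duplication). For every pileup site that
#' falls inside a duplication call and has total depth of at least
#' `minDepth`, the non-reference allele with the highest count (ties broken
#' by lexicographic allele order) is reported when its fraction of the
#' total depth lies within `band`. Fractions near 0 (sequencing noise) and
#' near 1 (fixed differences from the reference) are thereby excluded.
#'
#' @param pileup data.frame with columns `contig`, `pos` (0-based), `ref`,
#'   `allele`, `count`; one row per observed allele per site, reference
#'   rows carry `allele == ref`. Insertion/deletion alleles are written
#'   `"+SEQ"` / `"-SEQ"`.
#' @param calls Duplication calls from [callDuplications()].
#' @param minDepth Minimum site depth. Default 30.
#' @param band Inclusive alternate-fraction window. Default `c(0.3, 0.7)`.
#' @return data.frame with one row per reported site: `contig`, `pos`,
#'   `ref`, `alt`, `altCount`, `depth`, `fraction`, `dupStart`, `dupEnd`
#'   (0-based half-open span of the enclosing call).
#' @examples
#' pu <- data.frame(contig = "chr", pos = 25000, ref = "A",
#'                  allele = c("A", "+T"), count = c(79, 76))
#' d <- rep(150, 50000); d[20001:35000] <- 300
#' st <- normalizeCoverage(slidingWindowStats(coverageTrack("chr", d)))
#' callDivergentSites(pu, callDuplications(st, "chr"))
#' @export
callDivergentSites <- function(pileup, calls, minDepth = 30,
                               band = c(0.3, 0.7)) {
  need <- c("contig", "pos", "ref", "allele", "count")
  stopifnot(all(need %in% names(pileup)))
  empty <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      altCount = numeric(), depth = numeric(),
                      fraction = numeric(), dupStart = integer(),
                      dupEnd = integer(), stringsAsFactors = FALSE)
  if (!nrow(pileup) || !length(calls)) return(empty)
  if (is.unsorted(pileup$pos[pileup$contig == pileup$contig[1L]]))
    pileup <- pileup[order(pileup$contig, pileup$pos), ]

  callDf <- data.frame(
    contig = as.character(GenomicRanges::seqnames(calls)),
    start0 = GenomicRanges::start(calls) - 1L,
    end0 = GenomicRanges::end(calls))

  out <- list()
  keys <- unique(pileup[c("contig", "pos")])
  for (i in seq_len(nrow(keys))) {
    ctg <- keys$contig[i]; pos <- keys$pos[i]
    enclosing <- callDf[callDf$contig == ctg & callDf$start0 <= pos &
                          callDf$end0 > pos, , drop = FALSE]
    if (!nrow(enclosing)) next
    rows <- pileup[pileup$contig == ctg & pileup$pos == pos, , drop = FALSE]
    depth <- sum(rows$count)
    if (depth < minDepth) next
    ref <- rows$ref[1L]
    altRows <- rows[rows$allele != ref, , drop = FALSE]
    if (!nrow(altRows)) next
    altRows <- altRows[order(-altRows$count, altRows$allele), , drop = FALSE]
    fraction <- altRows$count[1L] / depth
    if (fraction < band[1L] || fraction > band[2L]) next
    out[[length(out) + 1L]] <- data.frame(
      contig = ctg, pos = pos, ref = ref, alt = altRows$allele[1L],
      altCount = altRows$count[1L], depth = depth, fraction = fraction,
      dupStart = enclosing$start0[1L], dupEnd = enclosing$end0[1L],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}
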