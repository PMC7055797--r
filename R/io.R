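# Readers and writers for the plain-text formats shared by the modules:
# bedGraph / two-column TSV coverage, pileup TSV, BED duplication calls,
# GFF3 annotation, trajectory TSV + JSON run summaries. Coverage and pileup
# parsing is validated line by line (overlap, ordering, malformed fields)
# because silent coordinate errors are the classic failure mode of
# depth-based CNV scans.

#' Read a per-base coverage track
#'
#' Reconstructs the contiguous per-base depth array of one contig from a
#' bedGraph (`chrom start end depth`, 0-based half-open) or a two-column
#' TSV (`pos depth`, 0-based). Positions absent from the file get depth 0.
#' Overlapping intervals, unsorted records and malformed lines are errors
#' reported with their line number.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"bedgraph"`, or `"tsv"`.
#' @return A [coverageTrack()].
#' @export
readCoverage <- function(path, format = c("auto", "bedgraph", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(bedgraph|bdg|bg)$", path, ignore.case = TRUE))
      "bedgraph" else "tsv"
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no data lines in ", path)
  fields <- strsplit(lines, "\t| +")

  if (format == "bedgraph") {
    ok <- lengths(fields) >= 4L
    if (any(!ok))
      stop("malformed bedGraph line ", lineNo[which(!ok)[1L]], " in ", path)
    contig <- vapply(fields, `[`, "", 1L)
    if (length(unique(contig)) > 1L)
      stop("multiple contigs in ", path, " (",
           paste(unique(contig), collapse = ", "),
           "); one contig per track is supported")
    start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    depth <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
    bad <- which(is.na(start) | is.na(end) | is.na(depth) | end <= start |
                   start < 0)
    if (length(bad))
      stop("malformed bedGraph line ", lineNo[bad[1L]], " in ", path)
    if (is.unsorted(start, strictly = FALSE)) {
      i <- which(diff(start) < 0)[1L] + 1L
      stop("unsorted bedGraph at line ", lineNo[i], " in ", path)
    }
    if (length(start) > 1L) {
      ov <- which(start[-1L] < end[-length(end)])
      if (length(ov))
        stop("overlapping bedGraph intervals at line ", lineNo[ov[1L] + 1L],
             " in ", path)
    }
    d <- numeric(max(end))
    for (i in seq_along(start))
      d[(start[i] + 1L):end[i]] <- depth[i]
    return(coverageTrack(contig[1L], d))
  }

  ok <- lengths(fields) >= 2L
  if (any(!ok))
    stop("malformed coverage TSV line ", lineNo[which(!ok)[1L]], " in ", path)
  # optional header
  first <- suppressWarnings(as.numeric(fields[[1L]][1L]))
  if (is.na(first)) {
    fields <- fields[-1L]; lineNo <- lineNo[-1L]
  }
  pos <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  depth <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  bad <- which(is.na(pos) | is.na(depth) | pos < 0)
  if (length(bad))
    stop("malformed coverage TSV line ", lineNo[bad[1L]], " in ", path)
  if (is.unsorted(pos, strictly = FALSE)) {
    i <- which(diff(pos) < 0)[1L] + 1L
    stop("unsorted positions at line ", lineNo[i], " in ", path)
  }
  dup <- which(duplicated(pos))
  if (length(dup))
    stop("duplicate position at line ", lineNo[dup[1L]], " in ", path)
  d <- numeric(max(pos) + 1L)
  d[pos + 1L] <- depth
  coverageTrack(sub("\\.(bedgraph|bdg|bg|tsv|txt)$", "", basename(path)), d)
}

#' Write a coverage track as bedGraph
#'
#' Runs of constant depth are collapsed into single 0-based half-open
#' intervals, the standard bedGraph encoding. [readCoverage()] restores the
#' identical per-base array.
#'
#' @param track A [coverageTrack()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeCoverageBedGraph <- function(track, path) {
  stopifnot(is(track, "CoverageTrack"))
  r <- rle(track@depth)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  writeLines(sprintf("%s\t%d\t%d\t%s", track@contig, start, end,
                     format(r$values, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Read a pileup allele-count table
#'
#' TSV with header columns `contig pos ref allele count` (0-based
#' positions), one row per observed allele per site. Malformed lines are
#' errors with line numbers.
#'
#' @param path Input file.
#' @return data.frame suitable for [callDivergentSites()].
#' @export
readPileup <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "character",
                                         "character", "numeric"),
                          stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref", "allele", "count")
  if (!all(need %in% names(df)))
    stop("pileup file must have header columns: ",
         paste(need, collapse = ", "))
  bad <- which(is.na(df$pos) | is.na(df$count) | df$count < 0)
  if (length(bad))
    stop("malformed pileup record at data line ", bad[1L], " in ", path)
  df
}

#' @rdname readPileup
#' @param pileup Pileup data.frame.
#' @export
writePileup <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a CDS annotation from GFF3
#'
#' Thin wrapper over [rtracklayer::import()] keeping `CDS` records (all
#' records if the file has no typed features). GFF3 1-based coordinates are
#' preserved in the returned GRanges; the scanner converts at the boundary.
#'
#' @param path GFF3 file.
#' @return [GenomicRanges::GRanges] of CDS intervals.
#' @export
readAnnotationGFF3 <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc) && any(as.character(mc$type) == "CDS"))
    gr <- gr[as.character(mc$type) == "CDS"]
  gr
}

#' @rdname readAnnotationGFF3
#' @param cds CDS annotation ([GenomicRanges::GRanges]) with optional
#'   `ID`/`phase` metadata.
#' @export
writeAnnotationGFF3 <- function(cds, path) {
  mc <- S4Vectors::mcols(cds)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID)
         else sprintf("cds_%d", seq_along(cds))
  phase <- if ("phase" %in% names(mc)) as.integer(mc$phase)
           else rep(0L, length(cds))
  phase[is.na(phase)] <- 0L
  strand <- as.character(GenomicRanges::strand(cds))
  strand[strand == "*"] <- "+"
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s",
                     as.character(GenomicRanges::seqnames(cds)),
                     "snapdup",
                     GenomicRanges::start(cds), GenomicRanges::end(cds),
                     strand, phase, ids))
  writeLines(lines, path)
  invisible(path)
}

#' Write duplication calls as BED
#'
#' One 0-based half-open BED line per call, sorted by contig then start,
#' with the score column holding the mean normalized ratio times 1000,
#' truncated to an integer (a 2x call scores 2000). An empty call set
#' writes only the header comment.
#'
#' @param calls Calls from [callDuplications()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeCalls <- function(calls, path) {
  header <- "#chrom\tstart\tend\tname\tscore\tstrand"
  if (!length(calls)) {
    writeLines(header, path)
    return(invisible(path))
  }
  ord <- order(as.character(GenomicRanges::seqnames(calls)),
               GenomicRanges::start(calls))
  calls <- calls[ord]
  lines <- sprintf("%s\t%d\t%d\tdup_%d\t%d\t.",
                   as.character(GenomicRanges::seqnames(calls)),
                   GenomicRanges::start(calls) - 1L,
                   GenomicRanges::end(calls),
                   seq_along(calls),
                   as.integer(trunc(S4Vectors::mcols(calls)$meanRatio * 1000)))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read duplication calls from BED
#'
#' @param path BED file written by [writeCalls()].
#' @return [GenomicRanges::GRanges] with `meanRatio` restored from the
#'   score column.
#' @export
readCalls <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(.emptyCalls("none"))
  f <- strsplit(lines, "\t")
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(f, `[`, "", 1L),
    ranges = IRanges::IRanges(
      start = as.integer(vapply(f, `[`, "", 2L)) + 1L,
      end = as.integer(vapply(f, `[`, "", 3L))))
  S4Vectors::mcols(gr)$start0 <- GenomicRanges::start(gr) - 1L
  S4Vectors::mcols(gr)$meanRatio <-
    as.numeric(vapply(f, `[`, "", 5L)) / 1000
  S4Vectors::mcols(gr)$lengthBp <- GenomicRanges::width(gr)
  gr
}

# scenario -> plain list, for parameter-echo JSON
.scenarioEcho <- function(scenario) {
  list(fitness = as.list(scenario@fitness),
       rates = as.list(scenario@rates),
       growth = list(r0 = scenario@growth@r0, k = scenario@growth@k,
                     e = scenario@growth@e,
                     exhaustionFraction = scenario@growth@exhaustionFraction,
                     maxTime = scenario@growth@maxTime),
       protocol = list(
         dilutionFactor = scenario@protocol@dilutionFactor,
         bottleneckSize = scenario@protocol@bottleneckSize,
         initialPopulation = scenario@protocol@initialPopulation,
         targetGenerations = scenario@protocol@targetGenerations,
         bottleneckMode = scenario@protocol@bottleneckMode),
       replicates = scenario@replicates,
       seed = scenario@seed,
       mutationMode = scenario@mutationMode)
}

#' Write a trajectory as TSV plus a JSON run summary
#'
#' The TSV holds one row per passage with columns `passage`, `generations`,
#' `wt`, `dup`, `d1`, `d2`; counts are written with 6 significant digits in
#' scientific notation (fractional cells exist in continuous bottleneck
#' mode). The JSON summary records the outcome, fixation generation, seed,
#' seeded mutation events and, when a scenario is supplied, the full
#' parameter echo, which suffices to re-run the result.
#'
#' @param trajectory A `Trajectory` from [runSerialPassages()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @param scenario Optional [newScenario()] echoed into the JSON.
#' @return Invisibly, the two paths.
#' @export
writeTrajectory <- function(trajectory, prefix, scenario = NULL) {
  stopifnot(is(trajectory, "Trajectory"))
  rec <- trajectory@records
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  fmt <- function(x) formatC(x, format = "e", digits = 5L)
  out <- data.frame(passage = as.integer(rec$passage),
                    generations = formatC(rec$generations, format = "f",
                                          digits = 4L),
                    wt = fmt(rec$WT), dup = fmt(rec$DUP),
                    d1 = fmt(rec$D1), d2 = fmt(rec$D2))
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    outcome = trajectory@outcome,
    fixationGeneration = if (is.na(trajectory@fixationGeneration)) NULL
                         else trajectory@fixationGeneration,
    passages = nrow(rec),
    generations = rec$generations[nrow(rec)],
    seed = trajectory@seed,
    events = trajectory@events,
    parameters = if (is.null(scenario)) NULL else .scenarioEcho(scenario))
  jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(tsv = tsv, json = json))
}

#' Read back a trajectory TSV
#'
#' @param path TSV written by [writeTrajectory()].
#' @return data.frame with the written columns, counts as numerics.
#' @export
readTrajectoryTSV <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
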