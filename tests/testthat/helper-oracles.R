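# Independent oracles and small builders shared across the suite.

# Two-state per-generation Markov chain for the neutral WT<->DUP balance:
# each generation a WT cell becomes DUP with probability muD and a DUP cell
# segregates back with probability muS. Iterated directly, independent of
# the ODE/serial-passage machinery.
markovDupFraction <- function(muD, muS, generations) {
  f <- 0
  for (g in seq_len(generations)) f <- f + (1 - f) * muD - f * muS
  f
}

# Build a trajectory-records data.frame from per-passage count rows.
makeRecords <- function(counts, gensPerPassage = 6.64) {
  counts <- as.data.frame(counts)
  names(counts) <- strainTypes()
  cbind(passage = seq_len(nrow(counts)),
        generations = gensPerPassage * seq_len(nrow(counts)),
        counts)
}

# Noise-free coverage track with 2x blocks at the given 0-based intervals.
blockTrack <- function(length, blocks = NULL, base = 150, contig = "chr") {
  d <- rep(base, length)
  if (!is.null(blocks))
    for (i in seq_len(nrow(blocks)))
      d[(blocks$start[i] + 1):blocks$end[i]] <- base * blocks$copy[i]
  coverageTrack(contig, d)
}

# Scan a track with default parameters in one call.
scanTrack <- function(track, ...) {
  callDuplications(normalizeCoverage(slidingWindowStats(track)),
                   contig = track@contig, ...)
}
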