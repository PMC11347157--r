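# Shared fixtures, built in code.

# Small transcriptome with equal abundances (clean dwell-recovery conditions).
smallTx <- function(n = 20, seed = 101, ...) {
  generateTranscriptome(n, meanCdsCodons = 100, abundance = rep(1, n),
                        seed = seed, ...)
}

# Alignments straight from a dwell simulation (error-free reads).
simAln <- function(ts, dwell = dwellModel(), depth = 5e4, seed = 1, ...) {
  alignmentsFromReads(simulateFootprints(ts, dwell, depth = depth,
                                         emitSequences = FALSE, seed = seed,
                                         ...))
}

# Hand-built single-transcript annotation for coordinate arithmetic tests:
# CDS [100, 400) on a 500 nt transcript.
toyAnno <- function() {
  data.frame(transcript_id = "t1", feature = "CDS", start = 100L,
             end = 400L)
}

toyAlign <- function(pos, length = 29L, ref = "t1", multiplicity = 1L) {
  data.frame(read_id = as.character(seq_along(pos)), ref = ref,
             pos = as.integer(pos), length = as.integer(length),
             mismatches = 0L, multiplicity = as.integer(multiplicity))
}

# Exact A-site sampling distribution over codon identities, by enumeration
# of every sense-codon position of every transcript (independent of the
# simulator's internal position table).
expectedCodonFractions <- function(ts, dwell = dwellModel(),
                                   initiationPause = 1) {
  anno <- featureTable(ts)
  seqs <- as.character(txSeqs(ts))
  ab <- abundances(ts)
  cds <- anno[anno$feature == "CDS", ]
  w <- setNames(numeric(61), names(dwell))
  for (i in seq_len(nrow(cds))) {
    tx <- cds$transcript_id[i]
    s <- seqs[[tx]]
    nc <- (cds$end[i] - cds$start[i]) %/% 3L
    cods <- substring(s, cds$start[i] + 1L + 3L * (seq_len(nc - 1L) - 1L),
                      cds$start[i] + 3L * seq_len(nc - 1L))  # sense only
    wi <- ab[[tx]] * dwell[cods]
    if (initiationPause != 1 && length(wi) >= 2L)
      wi[2L] <- wi[2L] * initiationPause
    add <- tapply(wi, cods, sum)
    w[names(add)] <- w[names(add)] + add
  }
  w / sum(w)
}
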