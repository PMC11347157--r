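#' Codon dwell-time model
#'
#' Ground-truth relative ribosome dwell weights per sense codon
#' (dimensionless; 1 = baseline). Under the steady-state, traffic-free
#' elongation model used throughout the package, footprint density on a codon
#' is proportional to its dwell weight, so these weights are exactly what the
#' occupancy estimator targets. A slow-decoded codon (e.g. CAG when its
#' cognate tRNA is depleted) gets a weight above 1.
#'
#' @param ... Named weight overrides, e.g. \code{CAG = 2}.
#' @param baseline Baseline weight for unlisted codons.
#' @return Named positive numeric vector over the 61 sense codons.
#' @examples
#' dw <- dwellModel(CAG = 2)
#' dw[["CAG"]]
#' @export
dwellModel <- function(..., baseline = 1) {
  w <- setNames(rep(baseline, 61L), senseCodons())
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(w))
    if (length(bad)) stop("not sense codons: ", paste(bad, collapse = ", "))
    w[names(over)] <- unlist(over)
  }
  if (any(w <= 0)) stop("dwell weights must be positive")
  w
}

#' Default footprint length distribution and A-site offsets
#'
#' Standard mammalian monosome values: lengths 28-31 nt with a mode at 29,
#' A-site offset 15 nt (5' end to the first nucleotide of the A-site codon)
#' for 28-30-mers and 16 nt for 31-mers. Override per experiment.
#'
#' @return Named numeric (probabilities) / named integer (offsets) keyed by
#'   read length.
#' @export
defaultLengthDist <- function() c(`28` = 0.2, `29` = 0.4, `30` = 0.3,
                                  `31` = 0.1)

#' @rdname defaultLengthDist
#' @export
defaultOffsets <- function() c(`28` = 15L, `29` = 15L, `30` = 15L, `31` = 16L)

newReadSet <- function(id, seq, tx, pos, length, tag) {
  new("ReadSet",
      reads = data.frame(id = id, seq = seq, tx = tx, pos = as.integer(pos),
                         length = as.integer(length)),
      tag = tag)
}

emptyReadSet <- function(tag) {
  newReadSet(character(), character(), character(), integer(), integer(), tag)
}

## Position table of candidate A-sites: one row per (tx, site) with sampling
## weight abundance * dwell(codon) [* initiation pause at codon index 1].
## Sense codons only: a stop codon in the A site is a terminating, not an
## elongating, ribosome.
asitePositionTable <- function(ts, dwell, initiationPause = 1) {
  anno <- featureTable(ts)
  seqs <- as.character(txSeqs(ts))
  ab <- abundances(ts)
  cds <- anno[anno$feature == "CDS", , drop = FALSE]
  out <- vector("list", nrow(cds))
  for (i in seq_len(nrow(cds))) {
    tx <- cds$transcript_id[i]
    codons <- codonsOfRegion(seqs[[tx]], cds$start[i], cds$end[i])
    nSense <- length(codons) - 1L        # drop terminal stop
    if (nSense < 1L) next
    idx <- seq_len(nSense) - 1L
    w <- ab[[tx]] * dwell[codons[seq_len(nSense)]]
    if (initiationPause != 1 && nSense >= 2L)
      w[2L] <- w[2L] * initiationPause   # codon index 1: first elongation cycle
    out[[i]] <- data.table(tx = tx, site = cds$start[i] + 3L * idx,
                           codon = codons[seq_len(nSense)], w = unname(w))
  }
  rbindlist(out)
}

## Draw footprints given a position table; resamples draws whose footprint
## would run past a transcript end.
drawFootprints <- function(posTab, txLens, depth, lengthDist, offsets,
                           emitSequences, seqs, tag) {
  if (depth == 0L) return(emptyReadSet(tag))
  lens <- as.integer(names(lengthDist))
  if (!all(as.character(lens) %in% names(offsets)))
    stop("offsets must be defined for every length in lengthDist")
  off <- as.integer(offsets[as.character(lens)])
  posLen <- txLens[posTab$tx]            # per-position transcript length
  idx <- sample.int(nrow(posTab), depth, replace = TRUE, prob = posTab$w)
  li <- sample.int(length(lens), depth, replace = TRUE, prob = lengthDist)
  repeat {
    p5 <- posTab$site[idx] - off[li]
    bad <- which(p5 < 0L | p5 + lens[li] > posLen[idx])
    if (!length(bad)) break
    idx[bad] <- sample.int(nrow(posTab), length(bad), replace = TRUE,
                           prob = posTab$w)
    li[bad] <- sample.int(length(lens), length(bad), replace = TRUE,
                          prob = lengthDist)
  }
  tx <- posTab$tx[idx]
  sq <- if (emitSequences) substring(seqs[tx], p5 + 1L, p5 + lens[li])
        else NA_character_
  newReadSet(as.character(seq_len(depth)), sq, tx, p5, lens[li], tag)
}

#' Simulate ribosome footprints under a codon dwell model
#'
#' Forward model of elongation at steady state without ribosome traffic: the
#' A-site codon of each footprint is drawn over all sense CDS codons of all
#' transcripts with probability proportional to
#' \code{abundance * dwellWeight(codon)}. The 5' end is the A-site first
#' nucleotide minus the length-specific offset; draws whose footprint would
#' extend past a transcript end are resampled. An optional multiplicative
#' pause at codon index 1 (the first elongation cycle, A-site on the codon
#' after the initiator) reproduces the start-codon metagene peak that offset
#' calibration relies on; it is off (1) by default so density is exactly
#' proportional to dwell weight.
#'
#' @param ts A \linkS4class{TranscriptSet}.
#' @param dwell Dwell weights from \code{\link{dwellModel}}.
#' @param depth Total number of footprints (>= 0).
#' @param lengthDist Named probabilities by read length.
#' @param offsets Named A-site offsets by read length (5' end to A-site first
#'   nt).
#' @param initiationPause Multiplier on the codon-index-1 position weight.
#' @param emitSequences If \code{FALSE}, skip sequence extraction (origin
#'   coordinates only); much faster for large simulations feeding coordinate
#'   analyses.
#' @param seed Integer seed for reproducibility.
#' @return A \linkS4class{ReadSet} tagged \code{"footprint"}.
#' @export
simulateFootprints <- function(ts, dwell = dwellModel(), depth,
                               lengthDist = defaultLengthDist(),
                               offsets = defaultOffsets(),
                               initiationPause = 1, emitSequences = TRUE,
                               seed = NULL) {
  if (depth < 0L) stop("depth must be >= 0")
  if (length(ts) == 0L && depth > 0L)
    stop("cannot simulate footprints from an empty transcript set")
  if (depth == 0L) return(emptyReadSet("footprint"))
  posTab <- asitePositionTable(ts, dwell, initiationPause)
  seqs <- as.character(txSeqs(ts))
  txLens <- setNames(width(txSeqs(ts)), names(ts))
  withSeedIf(seed,
    drawFootprints(posTab, txLens, as.integer(depth), lengthDist, offsets,
                   emitSequences, seqs, "footprint"))
}

#' Simulate RNA-seq reads
#'
#' Uniform fragmentation model: a transcript is chosen with probability
#' proportional to \code{abundance * (length - readLength + 1)} (its number of
#' valid 5' start positions) and the read 5' position is uniform over those
#' starts.
#'
#' @param ts A \linkS4class{TranscriptSet}.
#' @param depth Number of reads (>= 0).
#' @param readLength Read length in nt.
#' @param emitSequences As in \code{\link{simulateFootprints}}.
#' @param seed Integer seed.
#' @return A \linkS4class{ReadSet} tagged \code{"rna"}.
#' @export
simulateRnaSeq <- function(ts, depth, readLength = 50L, emitSequences = TRUE,
                           seed = NULL) {
  if (depth < 0L) stop("depth must be >= 0")
  if (depth == 0L) return(emptyReadSet("rna"))
  lens <- setNames(width(txSeqs(ts)), names(ts))
  short <- names(lens)[lens < readLength]
  if (length(short))
    stop("read length ", readLength, " exceeds transcript length of: ",
         paste(short, collapse = ", "))
  nStart <- lens - readLength + 1L
  w <- abundances(ts)[names(lens)] * nStart
  seqs <- as.character(txSeqs(ts))
  withSeedIf(seed, {
    ti <- sample.int(length(lens), depth, replace = TRUE, prob = w)
    p5 <- as.integer(floor(stats::runif(depth) * nStart[ti]))
    tx <- names(lens)[ti]
    sq <- if (emitSequences) substring(seqs[tx], p5 + 1L, p5 + readLength)
          else NA_character_
    newReadSet(as.character(seq_len(depth)), sq, tx, p5, readLength,
               "rna")
  })
}

#' Ground-truth alignments from a simulated ReadSet
#'
#' Converts the origin records of error-free simulated reads directly into
#' the alignment table that \code{\link{mapReads}} would produce (position =
#' recorded origin, zero mismatches, multiplicity 1). This is the fast path
#' for large coordinate-level simulations; the mapper itself is validated
#' against a brute-force oracle on small inputs.
#'
#' @param rs A \linkS4class{ReadSet} with origin records.
#' @return Alignment \code{data.frame} with columns \code{read_id},
#'   \code{ref}, \code{pos}, \code{length}, \code{mismatches},
#'   \code{multiplicity}.
#' @export
alignmentsFromReads <- function(rs) {
  r <- readTable(rs)
  data.frame(read_id = r$id, ref = r$tx, pos = r$pos, length = r$length,
             mismatches = 0L, multiplicity = 1L)
}

#' Write reads as FASTQ
#'
#' Constant quality ("I"); requires sequences to be present.
#'
#' @param rs A \linkS4class{ReadSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeReadsFastq <- function(rs, path) {
  r <- readTable(rs)
  if (nrow(r) && anyNA(r$seq))
    stop("ReadSet was simulated without sequences (emitSequences = FALSE)")
  x <- DNAStringSet(setNames(r$seq, r$id))
  q <- Biostrings::BStringSet(vapply(r$length,
        function(l) strrep("I", l), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read FASTQ/FASTA into a ReadSet
#'
#' Origin fields are \code{NA} for externally produced reads.
#'
#' @param path Input path.
#' @param format \code{"fastq"} or \code{"fasta"}.
#' @return A \linkS4class{ReadSet}.
#' @export
readReads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  x <- Biostrings::readDNAStringSet(path, format = format)
  newReadSet(names(x), as.character(x), NA_character_, NA_integer_,
             width(x), format)
}
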