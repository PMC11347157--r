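#' Calibrate A-site offsets from the start-codon metagene peak
#'
#' For each footprint length with at least \code{minReadsPerLength} reads,
#' the offset is the candidate value maximising the number of footprints
#' whose inferred A-site lands on CDS codon index 1 -- the codon after the
#' initiator, where the first elongation cycle pauses and the start-codon
#' metagene peak sits. Lengths below the read floor are omitted.
#'
#' @param aln Alignment \code{data.frame} (columns \code{ref}, \code{pos},
#'   \code{length}).
#' @param anno Annotation \code{data.frame} with CDS rows.
#' @param minReadsPerLength Read floor per length class.
#' @param candidates Candidate offsets (nt from the 5' end to the A-site
#'   first nucleotide).
#' @return Named integer vector of offsets keyed by length, with the
#'   per-length candidate score matrix in \code{attr(, "diagnostics")}.
#' @export
calibrateOffsets <- function(aln, anno, minReadsPerLength = 100L,
                             candidates = 10:20) {
  cds <- anno[anno$feature == "CDS", , drop = FALSE]
  cdsStart <- setNames(cds$start, cds$transcript_id)
  a <- as.data.table(aln)
  a <- a[ref %in% names(cdsStart)]
  nPerLen <- a[, .N, by = length]
  use <- nPerLen[N >= minReadsPerLength]
  if (!nrow(use))
    stop("no footprint length class reaches ", minReadsPerLength,
         " reads; supply offsets manually (named vector length -> offset)")
  diag <- matrix(0L, nrow(use), length(candidates),
                 dimnames = list(as.character(use$length), candidates))
  offsets <- integer(nrow(use))
  for (i in seq_len(nrow(use))) {
    L <- use$length[i]
    rel <- a[length == L, pos - cdsStart[ref]]   # 5' end relative to CDS start
    score <- vapply(candidates,
                    function(o) sum(rel + o == 3L), integer(1))
    diag[i, ] <- score
    offsets[i] <- candidates[which.max(score)]
  }
  out <- setNames(offsets, as.character(use$length))
  attr(out, "diagnostics") <- diag
  out
}

#' Assign footprints to A-site codons
#'
#' The A-site first nucleotide is the 5' position plus the length-specific
#' offset; the codon index is \code{floor((site - cds.start) / 3)}, so an
#' off-frame A-site is assigned to its containing codon. Footprints whose
#' length has no calibrated offset are dropped (tallied); multimapped
#' footprints (multiplicity > 1) are dropped by default because their codon
#' assignment is ambiguous. A-sites outside the CDS are kept in the
#' per-position table (for uORF/leader quantification) and tallied as
#' upstream/downstream of the CDS.
#'
#' @param aln Alignment \code{data.frame}.
#' @param offsets Named offsets by length (e.g. from
#'   \code{\link{calibrateOffsets}} or \code{\link{defaultOffsets}}).
#' @param anno Annotation \code{data.frame} with CDS rows.
#' @param sample Sample identifier.
#' @param dropMultimapped Drop alignments with multiplicity > 1 (default
#'   \code{TRUE}); if \code{FALSE} they contribute fractionally
#'   (1/multiplicity).
#' @return An \linkS4class{ASiteCounts}; the tallies satisfy
#'   in_cds + upstream + downstream + dropped_length + dropped_multimap ==
#'   total alignments.
#' @export
assignASites <- function(aln, offsets, anno, sample = "sample1",
                         dropMultimapped = TRUE) {
  ref <- aln$ref; pos <- aln$pos; len <- aln$length
  mult <- if ("multiplicity" %in% names(aln)) aln$multiplicity
          else rep(1L, length(ref))
  uniform <- !any(mult > 1L)
  droppedMulti <- 0L
  if (dropMultimapped) {
    if (!uniform) {
      keep <- mult == 1L
      droppedMulti <- sum(!keep)
      ref <- ref[keep]; pos <- pos[keep]; len <- len[keep]
    }
    wt <- NULL                       # all weights 1: count rows instead
  } else if (uniform) wt <- NULL else wt <- 1 / mult
  off <- as.integer(offsets)[match(len, as.integer(names(offsets)))]
  droppedLen <- sum(is.na(off))
  if (droppedLen > 0L) {
    ok <- !is.na(off)
    ref <- ref[ok]; pos <- pos[ok]; off <- off[ok]
    if (!is.null(wt)) wt <- wt[ok]
  }
  # aggregate to unique (tx, site) once; all region logic runs on the
  # aggregate, which is orders of magnitude smaller than the alignment list
  posTab <- if (is.null(wt))
    data.table::setDT(list(tx = ref, site = pos + off))[
      , list(n = as.numeric(.N)), by = list(tx, site)]
  else
    data.table::setDT(list(tx = ref, site = pos + off, wt = wt))[
      , list(n = sum(wt)), by = list(tx, site)]
  cds <- anno[anno$feature == "CDS", , drop = FALSE]
  ci <- match(posTab$tx, cds$transcript_id)
  cs <- cds$start[ci]; ce <- cds$end[ci]
  inCds <- !is.na(cs) & posTab$site >= cs & posTab$site < ce
  upstream <- sum(posTab$n[!is.na(cs) & posTab$site < cs]) +
    sum(posTab$n[is.na(cs)])  # incl. alignments to unannotated references
  downstream <- sum(posTab$n[!is.na(cs) & posTab$site >= ce])
  codTab <- data.table(tx = posTab$tx[inCds],
                       codon_idx = (posTab$site[inCds] - cs[inCds]) %/% 3L,
                       n = posTab$n[inCds])[
    , list(n = sum(n)), by = list(tx, codon_idx)]
  new("ASiteCounts", sample = sample,
      pos = setDF(setorder(posTab, tx, site)),
      codon = setDF(setorder(codTab, tx, codon_idx)),
      tallies = c(in_cds = as.integer(round(sum(posTab$n[inCds]))),
                  upstream = as.integer(round(upstream)),
                  downstream = as.integer(round(downstream)),
                  dropped_length = as.integer(droppedLen),
                  dropped_multimap = as.integer(droppedMulti)))
}

#' Per-codon relative A-site occupancy for one sample
#'
#' Pooled-ratio estimator of relative dwell. For each transcript whose
#' windowed CDS counts reach \code{minReadsPerTranscript}, positions within
#' \code{trimCodons} of either CDS end (and the stop codon) are excluded to
#' remove initiation/termination structure. For codon identity \eqn{c},
#' \deqn{O_c = \frac{\sum_{(t,i):\ codon=c} n_{t,i}}
#'                  {\sum_{(t,i):\ codon=c} \bar n_t}}
#' where \eqn{\bar n_t} is the transcript's mean windowed count (the expected
#' count under uniform dwell); the profile is finally rescaled so the mean
#' over observed codons is 1. Summing counts before dividing (rather than
#' averaging per-transcript ratios) keeps low-count transcripts from
#' dominating the estimate.
#'
#' @param asite An \linkS4class{ASiteCounts}.
#' @param ts The \linkS4class{TranscriptSet} (codon identities).
#' @param minReadsPerTranscript Windowed read floor per transcript
#'   (default 64).
#' @param trimCodons Codons trimmed from each CDS end (default 5).
#' @return A \linkS4class{CodonOccupancyProfile}.
#' @export
codonOccupancy <- function(asite, ts, minReadsPerTranscript = 64L,
                           trimCodons = 5L) {
  anno <- featureTable(ts)
  seqs <- as.character(txSeqs(ts))
  cds <- anno[anno$feature == "CDS", , drop = FALSE]
  cnt <- as.data.table(asite@codon)
  num <- setNames(numeric(61L), senseCodons())
  den <- setNames(numeric(61L), senseCodons())
  used <- 0L
  for (i in seq_len(nrow(cds))) {
    txid <- cds$transcript_id[i]
    codons <- codonsOfRegion(seqs[[txid]], cds$start[i], cds$end[i])
    Lc <- length(codons)
    lo <- trimCodons; hi <- Lc - trimCodons - 1L   # window, 0-based indices
    hi <- min(hi, Lc - 2L)                          # never the stop codon
    if (hi - lo + 1L < 3L) next
    winIdx <- lo:hi
    n <- numeric(length(winIdx))
    obs <- cnt[tx == txid & codon_idx %in% winIdx]
    if (nrow(obs)) n[match(obs$codon_idx, winIdx)] <- obs$n
    if (sum(n) < minReadsPerTranscript) next
    used <- used + 1L
    nbar <- mean(n)
    cc <- codons[winIdx + 1L]
    add <- tapply(n, cc, sum)
    num[names(add)] <- num[names(add)] + add
    den[names(add)] <- den[names(add)] + table(cc)[names(add)] * nbar
  }
  if (used == 0L)
    stop("no transcript reaches ", minReadsPerTranscript,
         " windowed A-site reads")
  occ <- ifelse(den > 0, num / den, NA_real_)
  occ <- occ / mean(occ, na.rm = TRUE)
  new("CodonOccupancyProfile", sample = asite@sample,
      occupancy = occ, transcriptsUsed = used)
}

#' Compare per-codon occupancy between genotype groups
#'
#' Per sense codon: group means and s.e.m. of the replicate occupancies, the
#' null/WT ratio of means, Welch's two-sided t-test across replicates, and a
#' significance tier (\code{*} p<0.05 through \code{****} p<0.0001). Codons
#' with zero variance in both groups are flagged degenerate with p = 1.
#'
#' @param wtProfiles,nullProfiles Lists (>= 2 each) of
#'   \linkS4class{CodonOccupancyProfile} replicates.
#' @return \code{data.frame} with columns \code{codon}, \code{aa},
#'   \code{mean_WT}, \code{sem_WT}, \code{mean_null}, \code{sem_null},
#'   \code{ratio}, \code{t}, \code{p}, \code{tier}, \code{degenerate}.
#' @export
compareOccupancy <- function(wtProfiles, nullProfiles) {
  if (length(wtProfiles) < 2L || length(nullProfiles) < 2L)
    stop("at least 2 replicate profiles per group are required")
  W <- vapply(wtProfiles, occupancy, numeric(61L))
  N <- vapply(nullProfiles, occupancy, numeric(61L))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(senseCodons(), function(cod) {
    w <- W[cod, ]; n <- N[cod, ]
    if (anyNA(w) || anyNA(n))
      return(data.frame(codon = cod, aa = GENETIC_CODE[[cod]],
                        mean_WT = mean(w), sem_WT = NA_real_,
                        mean_null = mean(n), sem_null = NA_real_,
                        ratio = NA_real_, t = NA_real_, p = NA_real_,
                        tier = NA_character_, degenerate = NA))
    wt <- welchTest(n, w)
    data.frame(codon = cod, aa = GENETIC_CODE[[cod]],
               mean_WT = mean(w), sem_WT = sem(w),
               mean_null = mean(n), sem_null = sem(n),
               ratio = mean(n) / mean(w), t = wt$t, p = wt$p,
               tier = pTier(wt$p), degenerate = wt$degenerate)
  })
  do.call(rbind, rows)
}
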