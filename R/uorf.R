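#' Quantify footprints over uORF1 / uORF2 / CDS regions
#'
#' Counts A-site positions falling in each annotated region of one
#' transcript and converts to densities (reads per kilobase of region per
#' million mapped reads). An A-site inside the uORF2/CDS overlap counts
#' toward uORF2 only, because a ribosome that initiated at uORF2 reads
#' through the CDS start out of frame; set
#' \code{overlapTo = "both"} to credit both regions.
#'
#' @param asite An \linkS4class{ASiteCounts} (its per-position table includes
#'   A-sites outside the CDS).
#' @param anno Annotation \code{data.frame}; must contain rows for the
#'   transcript's CDS and any uORFs.
#' @param tx Transcript id to quantify.
#' @param librarySize Total mapped reads of the sample (for the per-million
#'   term).
#' @param overlapTo Attribution of the uORF2-CDS overlap
#'   (\code{"uORF2"} or \code{"both"}).
#' @return \code{data.frame}: \code{tx}, \code{region}, \code{count},
#'   \code{length}, \code{density}.
#' @export
quantifyRegions <- function(asite, anno, tx, librarySize,
                            overlapTo = c("uORF2", "both")) {
  overlapTo <- match.arg(overlapTo)
  reg <- anno[anno$transcript_id == tx, , drop = FALSE]
  if (!nrow(reg)) stop("no annotation for transcript '", tx, "'")
  pos <- asite@pos
  pos <- pos[pos$tx == tx, , drop = FALSE]
  u2 <- reg[reg$feature == "uORF2", , drop = FALSE]
  out <- lapply(seq_len(nrow(reg)), function(i) {
    s <- reg$start[i]; e <- reg$end[i]
    inReg <- pos$site >= s & pos$site < e
    if (reg$feature[i] == "CDS" && overlapTo == "uORF2" && nrow(u2) == 1L)
      inReg <- inReg & !(pos$site >= u2$start & pos$site < u2$end)
    cnt <- sum(pos$n[inReg])
    data.frame(tx = tx, region = reg$feature[i], count = cnt,
               length = e - s,
               density = cnt / ((e - s) / 1000) / (librarySize / 1e6))
  })
  do.call(rbind, out)
}

#' Translational release of the main CDS relative to uORF1
#'
#' The release statistic is the null/WT ratio of the per-genotype
#' (geometric mean) CDS-to-uORF1 density ratios: values above 1 mean the
#' main CDS gained footprints relative to the scanning-normalising uORF1
#' signal, the signature of reinitiation shifting past uORF2. When both
#' groups have >= 2 replicates, a Welch t-test on the per-replicate log2
#' ratios gives a p-value. Replicates with zero uORF1 density make the ratio
#' undefined and are flagged.
#'
#' @param wtQuants,nullQuants Lists of \code{\link{quantifyRegions}} outputs
#'   (one per replicate).
#' @return List: \code{release}, \code{p} (NA with < 2 replicates a group),
#'   \code{logRatios} (per-replicate log2 CDS/uORF1 by group),
#'   \code{undefined} (flag).
#' @export
cdsRelease <- function(wtQuants, nullQuants) {
  ratio1 <- function(q) {
    cds <- q$density[q$region == "CDS"]
    u1 <- q$density[q$region == "uORF1"]
    if (!length(cds) || !length(u1)) stop("quantification lacks CDS/uORF1")
    if (u1 == 0) return(NA_real_)
    log2(cds / u1)
  }
  lw <- vapply(wtQuants, ratio1, numeric(1))
  ln <- vapply(nullQuants, ratio1, numeric(1))
  undefined <- anyNA(lw) || anyNA(ln)
  if (undefined)
    return(list(release = NA_real_, p = NA_real_,
                logRatios = list(WT = lw, null = ln), undefined = TRUE))
  release <- 2^(mean(ln) - mean(lw))
  p <- if (length(lw) >= 2L && length(ln) >= 2L) welchTest(ln, lw)$p
       else NA_real_
  list(release = release, p = p,
       logRatios = list(WT = lw, null = ln), undefined = FALSE)
}

#' Simulate footprints over an Atf4-like uORF transcript
#'
#' Couples the delayed-reinitiation scanning model to footprint generation:
#' every ribosome translates uORF1, a fraction
#' \code{p_uORF2} of scanning ribosomes reinitiates at uORF2 and a fraction
#' \code{p_CDS} at the main CDS (from \code{\link{reinitProbabilities}}).
#' Within each translated region, A-site positions are drawn over the
#' region's in-frame codons weighted by the dwell model, and region totals
#' are proportional to the scanning outcome probabilities (uORF1 weight 1).
#'
#' @param ts A \linkS4class{TranscriptSet} containing the uORF transcript.
#' @param tx Transcript id with uORF1/uORF2/CDS annotation.
#' @param params A \linkS4class{ScanningParams}.
#' @param depth Number of footprints on this transcript.
#' @param dwell Dwell weights.
#' @param lengthDist,offsets Footprint length/offset configuration.
#' @param uorf1Leak Fraction of scanning ribosomes that skip uORF1
#'   entirely (leaky scanning); they retain the ternary complex and
#'   initiate at uORF2. Default 0: uORF1 initiation is obligatory.
#' @param emitSequences,seed As in \code{\link{simulateFootprints}}.
#' @return A \linkS4class{ReadSet} tagged \code{"footprint"}.
#' @export
simulateUorfFootprints <- function(ts, tx, params, depth,
                                   dwell = dwellModel(),
                                   lengthDist = defaultLengthDist(),
                                   offsets = defaultOffsets(),
                                   uorf1Leak = 0,
                                   emitSequences = TRUE, seed = NULL) {
  stopifnot(is(params, "ScanningParams"))
  if (uorf1Leak < 0 || uorf1Leak > 1)
    stop("uorf1Leak must be a probability")
  if (depth == 0L) return(emptyReadSet("footprint"))
  anno <- featureTable(ts)
  reg <- anno[anno$transcript_id == tx, , drop = FALSE]
  need <- c("uORF1", "uORF2", "CDS")
  if (!all(need %in% reg$feature))
    stop("transcript '", tx, "' lacks uORF1/uORF2/CDS annotation")
  pr <- reinitProbabilities(params)
  regionW <- c(uORF1 = 1 - uorf1Leak,
               uORF2 = (1 - uorf1Leak) * unname(pr["p_uORF2"]) + uorf1Leak,
               CDS = (1 - uorf1Leak) * unname(pr["p_CDS"]))
  seq <- as.character(txSeqs(ts))[[tx]]
  tabs <- lapply(need, function(f) {
    r <- reg[reg$feature == f, ]
    codons <- codonsOfRegion(seq, r$start, r$end)
    nSense <- length(codons) - as.integer(f != "uORF2")  # uORF2 end need not be a stop
    if (nSense < 1L) return(NULL)
    idx <- seq_len(nSense) - 1L
    cod <- codons[seq_len(nSense)]
    w <- dwell[cod]
    w[is.na(w)] <- 1   # out-of-frame stop triplets inside uORF2: baseline
    data.table(tx = tx, site = r$start + 3L * idx, codon = cod,
               w = regionW[[f]] * unname(w) / nSense)
  })
  posTab <- rbindlist(tabs)
  txLens <- setNames(width(txSeqs(ts)), names(ts))
  withSeedIf(seed,
    drawFootprints(posTab, txLens, as.integer(depth), lengthDist, offsets,
                   emitSequences, setNames(seq, tx), "footprint"))
}
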