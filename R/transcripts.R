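#' @importFrom Biostrings width
NULL

#' Construct a TranscriptSet
#'
#' @param seqs Named character vector or \link[Biostrings]{DNAStringSet}.
#' @param anno Annotation \code{data.frame} (\code{transcript_id},
#'   \code{feature}, \code{start}, \code{end}; 0-based, half-open).
#' @param abundance Optional named relative expression weights (default 1).
#' @return A \linkS4class{TranscriptSet}.
#' @export
TranscriptSet <- function(seqs, anno, abundance = NULL) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  if (is.null(abundance))
    abundance <- setNames(rep(1, length(seqs)), names(seqs))
  anno <- as.data.frame(anno)
  anno$start <- as.integer(anno$start)
  anno$end <- as.integer(anno$end)
  new("TranscriptSet", seqs = seqs, anno = anno, abundance = abundance)
}

## Draw n CDS codon counts (incl. stop) from a log-normal length model.
drawCdsCodons <- function(n, meanCodons, sdlog = 0.25, minCodons = 30L) {
  pmax(minCodons, as.integer(round(stats::rlnorm(n, log(meanCodons), sdlog))))
}

randomNt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Sample m sense codons from a 61-weight usage table.
sampleCodons <- function(m, usage) {
  if (m == 0L) return(character())
  sample(names(usage), m, replace = TRUE, prob = usage)
}

#' Default Atf4-like uORF architecture
#'
#' Two upstream ORFs in the 5' leader: a short uORF1, a spacer of \code{d1}
#' nucleotides, then uORF2 whose reading frame overlaps the main CDS start
#' out of frame -- the architecture through which delayed reinitiation
#' represses the main CDS under normal ternary-complex availability.
#'
#' @param uorf1Len uORF1 length in nt (multiple of 3, >= 6).
#' @param d1 Spacer from the uORF1 stop to the uORF2 start (nt).
#' @param uorf2Len uORF2 length in nt (multiple of 3).
#' @param d2 Distance from the uORF2 start to the main CDS start (nt); must be
#'   smaller than \code{uorf2Len} (overlap) and not a multiple of 3 (out of
#'   frame).
#' @param transcripts How many transcripts carry the architecture.
#' @return A list understood by \code{\link{generateTranscriptome}}.
#' @export
uorfSpec <- function(uorf1Len = 9L, d1 = 87L, uorf2Len = 180L, d2 = 100L,
                     transcripts = 1L) {
  if (uorf1Len %% 3L != 0L || uorf1Len < 6L)
    stop("uorf1Len must be a multiple of 3 and >= 6")
  if (uorf2Len %% 3L != 0L) stop("uorf2Len must be a multiple of 3")
  if (d2 >= uorf2Len)
    stop("uORF2 must overlap the CDS: d2 (", d2,
         ") must be smaller than uorf2Len (", uorf2Len, ")")
  if (d2 %% 3L == 0L)
    stop("uORF2 must overlap the CDS out of frame: d2 must not be a ",
         "multiple of 3")
  if (d1 < 1L || d2 < 1L) stop("d1 and d2 must be >= 1")
  list(uorf1Len = as.integer(uorf1Len), d1 = as.integer(d1),
       uorf2Len = as.integer(uorf2Len), d2 = as.integer(d2),
       transcripts = as.integer(transcripts))
}

#' Generate a synthetic transcriptome with known architecture
#'
#' Builds \code{nGenes} single-isoform transcripts: a random 5' leader, a CDS
#' drawn codon-by-codon from a 61-codon usage table (ATG start, random stop),
#' and a random 3' trailer. Optionally the first \code{uorfSpec$transcripts}
#' transcripts carry an Atf4-like two-uORF leader (uORF1, spacer \code{d1},
#' uORF2 overlapping the CDS start out of frame).
#'
#' @param nGenes Number of transcripts (>= 1).
#' @param meanCdsCodons Mean CDS length in codons (incl. stop) of the
#'   log-normal length model; or supply \code{cdsCodons} directly.
#' @param cdsCodons Optional integer vector of CDS codon counts (recycled).
#' @param codonUsage Named positive weights over the 61 sense codons
#'   (default uniform).
#' @param utr5,utr3 UTR lengths in nt (uORF-bearing leaders are laid out from
#'   the architecture instead).
#' @param abundance Optional relative expression weights; default log-normal
#'   (meanlog 0, sdlog 1), the standard heavy-tailed expression model.
#' @param uorfSpec Optional architecture from \code{\link{uorfSpec}}.
#' @param seed Integer seed; the same configuration and seed give a
#'   byte-identical result.
#' @return A \linkS4class{TranscriptSet}.
#' @export
generateTranscriptome <- function(nGenes, meanCdsCodons = 150, cdsCodons = NULL,
                                  codonUsage = NULL, utr5 = 60L, utr3 = 60L,
                                  abundance = NULL, uorfSpec = NULL,
                                  seed = NULL) {
  if (nGenes < 1L) stop("nGenes must be >= 1")
  if (is.null(codonUsage))
    codonUsage <- setNames(rep(1, 61L), senseCodons())
  if (any(codonUsage < 0) || all(codonUsage == 0))
    stop("codon usage weights must be non-negative and not all zero")
  withSeedIf(seed, {
    if (is.null(cdsCodons)) cdsCodons <- drawCdsCodons(nGenes, meanCdsCodons)
    cdsCodons <- as.integer(rep_len(cdsCodons, nGenes))
    if (is.null(abundance)) abundance <- stats::rlnorm(nGenes, 0, 1)
    ids <- sprintf("tx%04d", seq_len(nGenes))
    nUorf <- if (is.null(uorfSpec)) 0L else uorfSpec$transcripts
    if (nUorf > nGenes) stop("uorfSpec$transcripts exceeds nGenes")
    seqs <- character(nGenes)
    annoList <- vector("list", nGenes)
    for (i in seq_len(nGenes)) {
      nc <- cdsCodons[i]
      cds <- paste0("ATG",
                    paste(sampleCodons(nc - 2L, codonUsage), collapse = ""),
                    sample(stopCodons(), 1L))
      if (i <= nUorf) {
        sp <- uorfSpec
        # leader: pad | uORF1 | d1 spacer | uORF2 head (d2 nt) | CDS ...
        pad <- 25L
        uorf1 <- paste0("ATG",
                        paste(sampleCodons(sp$uorf1Len %/% 3L - 2L,
                                           codonUsage), collapse = ""),
                        sample(stopCodons(), 1L))
        if (3L * nc < sp$uorf2Len - sp$d2)
          stop("uORF2 overlap requested but CDS too short: CDS has ",
               3L * nc, " nt, overlap needs ", sp$uorf2Len - sp$d2)
        uorf2Head <- paste0("ATG", randomNt(sp$d2 - 3L))
        leader <- paste0(randomNt(pad), uorf1, randomNt(sp$d1), uorf2Head)
        u1s <- pad
        u2s <- pad + sp$uorf1Len + sp$d1
        cs <- u2s + sp$d2
        seqs[i] <- paste0(leader, cds, randomNt(utr3))
        annoList[[i]] <- data.frame(
          transcript_id = ids[i],
          feature = c("uORF1", "uORF2", "CDS"),
          start = c(u1s, u2s, cs),
          end = c(u1s + sp$uorf1Len, u2s + sp$uorf2Len, cs + 3L * nc))
      } else {
        seqs[i] <- paste0(randomNt(utr5), cds, randomNt(utr3))
        annoList[[i]] <- data.frame(
          transcript_id = ids[i], feature = "CDS",
          start = utr5, end = utr5 + 3L * nc)
      }
    }
    TranscriptSet(setNames(seqs, ids), do.call(rbind, annoList),
                  setNames(abundance, ids))
  })
}

#' Read / write the plain-text annotation format
#'
#' Tab-separated, columns \code{transcript_id}, \code{feature} (CDS, uORF1,
#' uORF2), \code{start}, \code{end}; coordinates 0-based, half-open, in
#' transcript space.
#'
#' @param anno Annotation \code{data.frame}.
#' @param path File path.
#' @return \code{readAnnotation} returns the annotation \code{data.frame};
#'   \code{writeAnnotation} returns \code{path} invisibly.
#' @export
writeAnnotation <- function(anno, path) {
  data.table::fwrite(anno[, c("transcript_id", "feature", "start", "end")],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname writeAnnotation
#' @export
readAnnotation <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t",
                                  colClasses = list(character = 1:2,
                                                    integer = 3:4)))
}

#' Write transcript sequences as FASTA
#'
#' @param x A \linkS4class{TranscriptSet} or \linkS4class{TRNAReference}.
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path) {
  Biostrings::writeXStringSet(txSeqs(x), path)
  invisible(path)
}
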