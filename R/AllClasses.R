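#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet GENETIC_CODE
#' @importFrom S4Vectors metadata
#' @importFrom data.table data.table as.data.table setkeyv := .N setnames rbindlist fwrite fread setDF setorder
NULL

## The 61 sense codons / 3 stop codons, in Biostrings' GENETIC_CODE order.
senseCodons <- function() names(GENETIC_CODE)[GENETIC_CODE != "*"]
stopCodons  <- function() names(GENETIC_CODE)[GENETIC_CODE == "*"]

#' TranscriptSet: transcript sequences with CDS/uORF annotation
#'
#' Container for a set of transcripts: the nucleotide sequences, a feature
#' annotation table (0-based, half-open transcript coordinates) and a relative
#' expression weight per transcript. All footprint coordinate arithmetic in the
#' package is performed against this object.
#'
#' @slot seqs A \link[Biostrings]{DNAStringSet} of transcript sequences.
#' @slot anno \code{data.frame} with columns \code{transcript_id},
#'   \code{feature} (one of \code{"CDS"}, \code{"uORF1"}, \code{"uORF2"}),
#'   \code{start}, \code{end} (0-based, half-open).
#' @slot abundance Named non-negative numeric vector of relative expression
#'   weights, one per transcript.
#'
#' @details Validity requires: every CDS length divisible by 3, starting with
#'   ATG and ending with a stop codon; every uORF starting with ATG with length
#'   divisible by 3; all intervals within transcript bounds.
#' @export
setClass("TranscriptSet",
  representation(seqs = "DNAStringSet", anno = "data.frame",
                 abundance = "numeric"))

setValidity("TranscriptSet", function(object) {
  msg <- character()
  ids <- names(object@seqs)
  if (is.null(ids) || anyDuplicated(ids))
    return("transcript sequences must have unique names")
  need <- c("transcript_id", "feature", "start", "end")
  if (!all(need %in% colnames(object@anno)))
    return(paste("annotation must have columns:", paste(need, collapse = ", ")))
  if (!all(object@anno$transcript_id %in% ids))
    msg <- c(msg, "annotation refers to unknown transcripts")
  if (!identical(sort(names(object@abundance)), sort(ids)))
    msg <- c(msg, "abundance must be named by transcript id")
  if (any(object@abundance < 0)) msg <- c(msg, "abundances must be non-negative")
  lens <- setNames(width(object@seqs), ids)
  a <- object@anno
  bad <- a$start < 0 | a$end > lens[a$transcript_id] | a$start >= a$end
  if (any(bad)) msg <- c(msg, "annotation interval outside transcript bounds")
  cds <- a[a$feature == "CDS", , drop = FALSE]
  for (i in seq_len(nrow(cds))) {
    s <- as.character(object@seqs[[cds$transcript_id[i]]])
    len <- cds$end[i] - cds$start[i]
    if (len %% 3L != 0L) { msg <- c(msg, "CDS length not divisible by 3"); next }
    if (substr(s, cds$start[i] + 1L, cds$start[i] + 3L) != "ATG")
      msg <- c(msg, "CDS does not start with ATG")
    if (!substr(s, cds$end[i] - 2L, cds$end[i]) %in% stopCodons())
      msg <- c(msg, "CDS does not end with a stop codon")
  }
  uo <- a[a$feature %in% c("uORF1", "uORF2"), , drop = FALSE]
  for (i in seq_len(nrow(uo))) {
    s <- as.character(object@seqs[[uo$transcript_id[i]]])
    if ((uo$end[i] - uo$start[i]) %% 3L != 0L)
      msg <- c(msg, "uORF length not divisible by 3")
    if (substr(s, uo$start[i] + 1L, uo$start[i] + 3L) != "ATG")
      msg <- c(msg, "uORF does not start with ATG")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' ReadSet: simulated or loaded sequencing reads with origin records
#'
#' Reads plus, for simulated data, the ground-truth origin of each read
#' (transcript/reference id, 0-based 5' position, length). Sequences may be
#' omitted (\code{NA}) when only coordinates are needed, which keeps large
#' simulations cheap.
#'
#' @slot reads \code{data.frame} with columns \code{id}, \code{seq} (character
#'   or \code{NA}), \code{tx}, \code{pos} (0-based 5' position on origin),
#'   \code{length}.
#' @slot tag Single character format/provenance tag (e.g. \code{"footprint"}).
#' @export
setClass("ReadSet", representation(reads = "data.frame", tag = "character"))

setValidity("ReadSet", function(object) {
  need <- c("id", "seq", "tx", "pos", "length")
  if (!all(need %in% colnames(object@reads)))
    return(paste("reads must have columns:", paste(need, collapse = ", ")))
  if (length(object@tag) != 1L) return("tag must be a single string")
  if (nrow(object@reads) && any(object@reads$pos < 0, na.rm = TRUE))
    return("read origin positions must be >= 0")
  TRUE
})

#' KmerIndex: exact k-mer lookup index over a reference set
#'
#' @slot k k-mer size (>= 8).
#' @slot table \code{data.table} keyed by \code{kmer} with columns
#'   \code{kmer}, \code{ref}, \code{pos} (0-based).
#' @slot refs Named character vector of reference sequences.
#' @export
setClass("KmerIndex",
  representation(k = "integer", table = "data.table", refs = "character"))

setValidity("KmerIndex", function(object) {
  if (object@k < 8L) return("k must be >= 8")
  if (is.null(names(object@refs))) return("references must be named")
  TRUE
})

#' ASiteCounts: per-position and per-codon A-site footprint counts
#'
#' One sample's footprint A-site assignments: counts at every transcript
#' nucleotide position where an A-site landed (including positions outside the
#' CDS, used for uORF quantification), the per-CDS-codon count matrix, and
#' bookkeeping tallies proving read conservation.
#'
#' @slot sample Sample identifier.
#' @slot pos \code{data.frame} with columns \code{tx}, \code{site}
#'   (0-based transcript nt of the A-site first nucleotide), \code{n}.
#' @slot codon \code{data.frame} with columns \code{tx}, \code{codon_idx}
#'   (0-based from CDS start), \code{n}; only in-CDS A-sites.
#' @slot tallies Named integer vector:
#'   \code{in_cds}, \code{upstream}, \code{downstream}, \code{dropped_length},
#'   \code{dropped_multimap}.
#' @export
setClass("ASiteCounts",
  representation(sample = "character", pos = "data.frame",
                 codon = "data.frame", tallies = "integer"))

setValidity("ASiteCounts", function(object) {
  if (nrow(object@codon) && any(object@codon$n < 0))
    return("counts must be non-negative")
  need <- c("in_cds", "upstream", "downstream", "dropped_length",
            "dropped_multimap")
  if (!all(need %in% names(object@tallies)))
    return(paste("tallies must contain:", paste(need, collapse = ", ")))
  TRUE
})

#' CodonOccupancyProfile: relative A-site occupancy per sense codon
#'
#' @slot sample Sample identifier.
#' @slot occupancy Named numeric vector over the 61 sense codons (codons never
#'   observed are \code{NA}); mean over observed codons equals 1.
#' @slot transcriptsUsed Number of transcripts passing the read floor.
#' @export
setClass("CodonOccupancyProfile",
  representation(sample = "character", occupancy = "numeric",
                 transcriptsUsed = "integer"))

setValidity("CodonOccupancyProfile", function(object) {
  occ <- object@occupancy[!is.na(object@occupancy)]
  if (!length(occ)) return("profile has no observed codons")
  if (any(occ < 0)) return("occupancy must be non-negative")
  if (abs(mean(occ) - 1) > 1e-9)
    return("mean occupancy over observed codons must equal 1")
  TRUE
})

#' TRNAReference: mature tRNA isodecoder reference
#'
#' @slot seqs \link[Biostrings]{DNAStringSet} of mature sequences (introns
#'   removed, 3' CCA present).
#' @slot info \code{data.frame} with columns \code{id}, \code{aa},
#'   \code{anticodon}, \code{family} (isoacceptor family), \code{copies}.
#' @export
setClass("TRNAReference",
  representation(seqs = "DNAStringSet", info = "data.frame"))

setValidity("TRNAReference", function(object) {
  if (!length(object@seqs)) return("reference is empty")
  if (anyDuplicated(names(object@seqs))) return("isodecoder ids must be unique")
  tails <- substring(as.character(object@seqs), width(object@seqs) - 2L)
  if (!all(tails == "CCA")) return("every mature sequence must end in CCA")
  if (!identical(object@info$id, names(object@seqs)))
    return("info$id must match sequence names")
  TRUE
})

#' ScanningParams: delayed-reinitiation scanning model parameters
#'
#' The quantitative form of post-uORF1 reinitiation: a 40S subunit scanning
#' downstream of uORF1 reacquires the eIF2-GTP-tRNAiMet ternary complex at
#' each nucleotide with probability \code{q}, and initiates at the next start
#' codon it reaches after reacquisition: the uORF2 start (within \code{d1} nt)
#' or the main CDS start (within the following \code{d2} nt), else neither.
#'
#' @slot q Per-nucleotide ternary-complex reacquisition probability in [0, 1].
#' @slot d1 Nucleotides from the uORF1 stop to the uORF2 start (>= 1).
#' @slot d2 Nucleotides from the uORF2 start to the main CDS start (>= 1).
#' @export
setClass("ScanningParams",
  representation(q = "numeric", d1 = "integer", d2 = "integer"))

setValidity("ScanningParams", function(object) {
  if (length(object@q) != 1L || object@q < 0 || object@q > 1)
    return("q must be a single probability in [0, 1]")
  if (object@d1 < 1L || object@d2 < 1L) return("d1 and d2 must be >= 1")
  TRUE
})

#' IsodecoderTable: per-sample fractional tRNA isodecoder counts
#'
#' @slot counts Numeric matrix (isodecoder x sample) of fractional
#'   multimap-resolved read counts.
#' @slot genotype Named character vector mapping sample to genotype.
#' @slot mode Multimap resolution mode used (\code{"uniform"} or \code{"em"}).
#' @export
setClass("IsodecoderTable",
  representation(counts = "matrix", genotype = "character", mode = "character"))

setValidity("IsodecoderTable", function(object) {
  if (!identical(sort(names(object@genotype)), sort(colnames(object@counts))))
    return("genotype must be named by sample (matrix columns)")
  if (any(object@counts < 0)) return("fractional counts must be non-negative")
  TRUE
})
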