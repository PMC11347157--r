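#' Accessors for riboDwell classes
#'
#' Small accessor generics: \code{txSeqs} (transcript or reference sequences),
#' \code{featureTable} (the CDS/uORF annotation), \code{abundances},
#' \code{readTable} (read records of a \linkS4class{ReadSet}),
#' \code{asiteTallies} (read-conservation tallies of an
#' \linkS4class{ASiteCounts}), \code{occupancy} (the named per-codon vector of
#' a \linkS4class{CodonOccupancyProfile}), and \code{relAbundance}
#' (per-sample relative abundances of an \linkS4class{IsodecoderTable}).
#'
#' @param x An object of the documented class.
#' @return The slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("txSeqs", function(x) standardGeneric("txSeqs"))
#' @rdname accessors
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))
#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setGeneric("readTable", function(x) standardGeneric("readTable"))
#' @rdname accessors
#' @export
setGeneric("asiteTallies", function(x) standardGeneric("asiteTallies"))
#' @rdname accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))
#' @rdname accessors
#' @export
setGeneric("relAbundance", function(x) standardGeneric("relAbundance"))

#' @rdname accessors
#' @export
setMethod("txSeqs", "TranscriptSet", function(x) x@seqs)
#' @rdname accessors
#' @export
setMethod("txSeqs", "TRNAReference", function(x) x@seqs)
#' @rdname accessors
#' @export
setMethod("featureTable", "TranscriptSet", function(x) x@anno)
#' @rdname accessors
#' @export
setMethod("abundances", "TranscriptSet", function(x) x@abundance)
#' @rdname accessors
#' @export
setMethod("readTable", "ReadSet", function(x) x@reads)
#' @rdname accessors
#' @export
setMethod("asiteTallies", "ASiteCounts", function(x) x@tallies)
#' @rdname accessors
#' @export
setMethod("occupancy", "CodonOccupancyProfile", function(x) x@occupancy)
#' @rdname accessors
#' @export
setMethod("relAbundance", "IsodecoderTable", function(x) {
  sweep(x@counts, 2L, colSums(x@counts), "/")
})

#' @describeIn accessors Number of transcripts.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@seqs))
#' @describeIn accessors Number of reads.
#' @export
setMethod("length", "ReadSet", function(x) nrow(x@reads))
#' @describeIn accessors Transcript ids.
#' @export
setMethod("names", "TranscriptSet", function(x) names(x@seqs))

setMethod("show", "TranscriptSet", function(object) {
  n_uorf <- length(unique(object@anno$transcript_id[
    object@anno$feature != "CDS"]))
  cat("TranscriptSet with", length(object@seqs), "transcripts (",
      n_uorf, "uORF-bearing )\n")
  cat("  width:", min(width(object@seqs)), "-", max(width(object@seqs)),
      "nt\n")
})

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet [", object@tag, "] with ", nrow(object@reads), " reads\n",
      sep = "")
  if (nrow(object@reads))
    cat("  lengths:", paste(sort(unique(object@reads$length)),
                            collapse = ", "), "nt\n")
})

setMethod("show", "KmerIndex", function(object) {
  cat("KmerIndex: k =", object@k, "over", length(object@refs),
      "references (", nrow(object@table), "k-mer positions )\n")
})

setMethod("show", "ASiteCounts", function(object) {
  cat("ASiteCounts for sample", object@sample, "\n")
  print(object@tallies)
})

setMethod("show", "CodonOccupancyProfile", function(object) {
  occ <- object@occupancy[!is.na(object@occupancy)]
  top <- head(sort(occ, decreasing = TRUE), 3L)
  cat("CodonOccupancyProfile [", object@sample, "]:",
      length(occ), "codons,", object@transcriptsUsed, "transcripts\n")
  cat("  highest:", paste(sprintf("%s=%.3f", names(top), top),
                          collapse = ", "), "\n")
})

setMethod("show", "TRNAReference", function(object) {
  cat("TRNAReference with", length(object@seqs), "isodecoders in",
      length(unique(object@info$family)), "isoacceptor families\n")
})

setMethod("show", "ScanningParams", function(object) {
  cat(sprintf("ScanningParams: q = %g, d1 = %d, d2 = %d\n",
              object@q, object@d1, object@d2))
})

setMethod("show", "IsodecoderTable", function(object) {
  cat("IsodecoderTable [", object@mode, "]: ", nrow(object@counts),
      " isodecoders x ", ncol(object@counts), " samples\n", sep = "")
})
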