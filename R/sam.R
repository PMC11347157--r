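#' Ingest ungapped alignments from a SAM file
#'
#' Minimal coordinate-level ingestion for externally aligned reads: only the
#' mandatory fields plus the \code{NH} tag (multiplicity) are used. Records
#' must be ungapped -- a CIGAR other than pure \code{<n>M} (insertions,
#' deletions, clipping, splicing) is rejected with an explicit message,
#' because all downstream coordinate arithmetic assumes ungapped transcript
#' alignments. Unmapped records (flag 0x4) are skipped.
#'
#' @param path Path to a SAM file.
#' @return Alignment \code{data.frame} with columns \code{read_id},
#'   \code{ref}, \code{pos} (0-based), \code{length}, \code{mismatches}
#'   (\code{NM} tag, else 0), \code{multiplicity} (\code{NH} tag, else 1).
#' @export
readSamAlignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(read_id = character(), ref = character(),
                      pos = integer(), length = integer(),
                      mismatches = integer(), multiplicity = integer()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  getTag <- function(x, tag) {
    hit <- grep(paste0("^", tag, ":i:"), x[-(1:11)], value = TRUE)
    if (length(hit)) as.integer(sub(".*:", "", hit[1])) else NA_integer_
  }
  rows <- lapply(f, function(x) {
    if (length(x) < 11L) stop("malformed SAM record: fewer than 11 fields")
    flag <- as.integer(x[2])
    if (bitwAnd(flag, 4L) > 0L) return(NULL)
    cigar <- x[6]
    if (!grepl("^[0-9]+M$", cigar))
      stop("unsupported CIGAR '", cigar, "' for read '", x[1],
           "': only ungapped (pure M) alignments are accepted; realign ",
           "or filter indel/clipped records first")
    len <- as.integer(sub("M", "", cigar, fixed = TRUE))
    nh <- getTag(x, "NH"); nm <- getTag(x, "NM")
    data.frame(read_id = x[1], ref = x[3], pos = as.integer(x[4]) - 1L,
               length = len,
               mismatches = if (is.na(nm)) 0L else nm,
               multiplicity = if (is.na(nh)) 1L else nh)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(read_id = character(), ref = character(),
                      pos = integer(), length = integer(),
                      mismatches = integer(), multiplicity = integer())
  out
}

#' Write alignments as minimal SAM
#'
#' @param aln Alignment \code{data.frame} (as from \code{\link{mapReads}}).
#' @param refLengths Named integer vector of reference lengths (for
#'   \code{@SQ} headers).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSamAlignments <- function(aln, refLengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(refLengths),
                       as.integer(refLengths))), con)
  if (nrow(aln))
    writeLines(sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tNH:i:%d\tNM:i:%d",
                       aln$read_id, aln$ref, aln$pos + 1L, aln$length,
                       aln$multiplicity, aln$mismatches), con)
  invisible(path)
}

#' Read / write alignments as TSV
#'
#' @param aln Alignment \code{data.frame}.
#' @param path File path.
#' @return \code{readAlignmentsTsv} returns the alignment \code{data.frame}.
#' @export
writeAlignmentsTsv <- function(aln, path) {
  data.table::fwrite(aln, path, sep = "\t")
  invisible(path)
}

#' @rdname writeAlignmentsTsv
#' @export
readAlignmentsTsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
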