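#' Build an exact k-mer index over reference sequences
#'
#' Indexes every k-mer occurrence of every reference (k-mers containing N are
#' skipped). Duplicate reference names are made unique so identical sequences
#' remain distinguishable.
#'
#' @param refs Named character vector, \link[Biostrings]{DNAStringSet}, or
#'   path to a FASTA file.
#' @param k k-mer size (>= 8; must not exceed the shortest reference).
#' @return A \linkS4class{KmerIndex}.
#' @export
buildKmerIndex <- function(refs, k = 12L) {
  if (is.character(refs) && length(refs) == 1L && file.exists(refs) &&
      is.null(names(refs)))
    refs <- Biostrings::readDNAStringSet(refs)
  if (is(refs, "DNAStringSet")) refs <- setNames(as.character(refs),
                                                 names(refs))
  if (!length(refs)) stop("reference set is empty")
  if (is.null(names(refs)) || any(names(refs) == ""))
    stop("references must be named")
  names(refs) <- make.unique(names(refs))
  k <- as.integer(k)
  if (k < 8L) stop("k must be >= 8")
  if (k > min(nchar(refs)))
    stop("k (", k, ") exceeds the shortest reference (",
         min(nchar(refs)), " nt)")
  tabs <- lapply(names(refs), function(id) {
    s <- refs[[id]]
    n <- nchar(s) - k + 1L
    km <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    keep <- !grepl("N", km, fixed = TRUE)
    data.table(kmer = km[keep], ref = id, pos = (seq_len(n) - 1L)[keep])
  })
  tab <- rbindlist(tabs)
  data.table::setkeyv(tab, "kmer")
  new("KmerIndex", k = k, table = tab, refs = refs)
}

## Seed offsets for a read of length len: pigeonhole segmentation into
## (maxMismatches + 1) blocks guarantees an exact seed for any alignment with
## <= maxMismatches substitutions when len >= k * (maxMismatches + 1);
## shorter reads fall back to every k-mer offset.
seedOffsets <- function(len, k, maxMismatches) {
  nSeg <- maxMismatches + 1L
  if (len >= k * nSeg) {
    starts <- floor(len * (seq_len(nSeg) - 1L) / nSeg)
    pmin(as.integer(starts), len - k)
  } else if (len >= k) {
    0:(len - k)
  } else {
    integer()
  }
}

#' Map reads to an indexed reference (seed-and-verify, ungapped)
#'
#' Exact/near-exact ungapped mapping: k-mer seeds are looked up in the index
#' and every candidate placement is verified by full-length mismatch
#' counting. All placements achieving the minimal mismatch count (at most
#' \code{maxMismatches}) are reported, with \code{multiplicity} set to the
#' number of tied best hits. Seeding is pigeonhole-complete: any alignment
#' with at most \code{maxMismatches} substitutions is found whenever the read
#' is at least \code{k * (maxMismatches + 1)} nt long.
#'
#' Reads are assumed sense-strand (stranded library protocols);
#' \code{bothStrands = TRUE} additionally tries the reverse complement and
#' reports a \code{strand} column.
#'
#' @param reads A \linkS4class{ReadSet} or named character vector of read
#'   sequences.
#' @param index A \linkS4class{KmerIndex}.
#' @param maxMismatches Maximum substitutions allowed (default 0).
#' @param bothStrands Also match the reverse complement (default
#'   \code{FALSE}).
#' @return \code{data.frame} with columns \code{read_id}, \code{ref},
#'   \code{pos} (0-based), \code{length}, \code{mismatches},
#'   \code{multiplicity} (and \code{strand} if \code{bothStrands}); ids of
#'   unmapped reads in \code{attr(, "unmapped")}.
#' @export
mapReads <- function(reads, index, maxMismatches = 0L, bothStrands = FALSE) {
  if (is(reads, "ReadSet")) {
    r <- readTable(reads)
    seqs <- setNames(r$seq, r$id)
  } else seqs <- reads
  if (anyNA(seqs)) stop("reads have no sequences")
  aln <- mapSeqs(seqs, index, as.integer(maxMismatches))
  if (bothStrands) {
    rc <- as.character(Biostrings::reverseComplement(DNAStringSet(seqs)))
    alnRC <- mapSeqs(setNames(rc, names(seqs)), index,
                     as.integer(maxMismatches))
    aln$strand <- if (nrow(aln)) "+" else character()
    alnRC$strand <- if (nrow(alnRC)) "-" else character()
    both <- rbind(aln, alnRC)
    # re-resolve ties across strands
    bt <- as.data.table(both)
    bt[, best := min(mismatches), by = read_id]
    bt <- bt[mismatches == best][, best := NULL]
    bt[, multiplicity := .N, by = read_id]
    aln <- setDF(bt)
  }
  attr(aln, "unmapped") <- setdiff(names(seqs), aln$read_id)
  aln
}

mapSeqs <- function(seqs, index, maxMismatches) {
  empty <- data.frame(read_id = character(), ref = character(),
                      pos = integer(), length = integer(),
                      mismatches = integer(), multiplicity = integer())
  if (!length(seqs)) return(empty)
  if (is.null(names(seqs))) names(seqs) <- sprintf("read%06d",
                                                   seq_along(seqs))
  k <- index@k
  lens <- nchar(seqs)
  # seed table: (read, seed offset, kmer)
  sl <- lapply(sort(unique(lens)), function(L) {
    offs <- seedOffsets(L, k, maxMismatches)
    if (!length(offs)) return(NULL)
    ids <- names(seqs)[lens == L]
    # column-major: all reads at the first offset, then the second, ...
    data.table(read_id = rep(ids, length(offs)),
               soff = rep(offs, each = length(ids)),
               kmer = as.vector(vapply(offs, function(o)
                 substring(seqs[lens == L], o + 1L, o + k),
                 character(length(ids)))))
  })
  seeds <- rbindlist(sl)
  if (!nrow(seeds)) return(empty)
  hits <- index@table[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(hits)) return(empty)
  hits[, pos0 := pos - soff]
  cand <- unique(hits[, .(read_id, ref, pos0)])
  rl <- lens[cand$read_id]
  refLen <- nchar(index@refs)[cand$ref]
  keep <- cand$pos0 >= 0L & cand$pos0 + rl <= refLen
  cand <- cand[keep]; rl <- rl[keep]
  if (!nrow(cand)) return(empty)
  sub <- substr(index@refs[cand$ref], cand$pos0 + 1L, cand$pos0 + rl)
  rd <- unname(seqs[cand$read_id])
  mm <- integer(nrow(cand))
  ne <- which(sub != rd)
  if (length(ne)) {
    if (maxMismatches == 0L) {
      cand <- cand[-ne]; rl <- rl[-ne]; mm <- mm[seq_len(nrow(cand))]
    } else {
      mm[ne] <- hammingDist(rd[ne], sub[ne])
      ok <- mm <= maxMismatches
      cand <- cand[ok]; rl <- rl[ok]; mm <- mm[ok]
    }
  }
  if (!nrow(cand)) return(empty)
  cand[, `:=`(length = rl, mismatches = mm)]
  cand[, best := min(mismatches), by = read_id]
  cand <- cand[mismatches == best][, best := NULL]
  cand[, multiplicity := .N, by = read_id]
  setnames(cand, "pos0", "pos")
  setorder(cand, read_id, ref, pos)
  setDF(cand[, .(read_id, ref, pos, length, mismatches, multiplicity)])
}

#' Remove reads matching a contaminant reference
#'
#' Reads mapping to the contaminant index (e.g. rRNA) at up to
#' \code{maxMismatches} substitutions are removed; survivors keep their
#' original order. The removed reads are attached as
#' \code{attr(, "removed")}, so no read is lost or duplicated.
#'
#' @param reads A \linkS4class{ReadSet}.
#' @param contaminantIndex A \linkS4class{KmerIndex} of contaminant
#'   sequences.
#' @param maxMismatches Maximum substitutions for a contaminant call.
#' @return The filtered \linkS4class{ReadSet}.
#' @export
filterContaminants <- function(reads, contaminantIndex, maxMismatches = 0L) {
  r <- readTable(reads)
  if (!nrow(r)) {
    out <- reads
    attr(out, "removed") <- reads
    return(out)
  }
  aln <- mapSeqs(setNames(r$seq, r$id), contaminantIndex,
                 as.integer(maxMismatches))
  hit <- r$id %in% aln$read_id
  kept <- new("ReadSet", reads = r[!hit, , drop = FALSE], tag = reads@tag)
  attr(kept, "removed") <- new("ReadSet", reads = r[hit, , drop = FALSE],
                               tag = reads@tag)
  kept
}

#' Brute-force reference scan (oracle)
#'
#' Exhaustive ungapped alignment of one read over every (reference, offset)
#' pair; used as the independent correctness oracle for
#' \code{\link{mapReads}} on small inputs.
#'
#' @param read Single read sequence.
#' @param refs Named character vector of references.
#' @param maxMismatches Maximum substitutions.
#' @return Alignment \code{data.frame} as in \code{\link{mapReads}} (one
#'   read), or zero rows if unmapped.
#' @export
bruteForceMap <- function(read, refs, maxMismatches = 0L) {
  len <- nchar(read)
  out <- list()
  for (id in names(refs)) {
    L <- nchar(refs[[id]])
    if (L < len) next
    starts <- 0:(L - len)
    subs <- substring(refs[[id]], starts + 1L, starts + len)
    mm <- hammingDist(rep(read, length(subs)), subs)
    ok <- mm <= maxMismatches
    if (any(ok))
      out[[id]] <- data.frame(ref = id, pos = starts[ok],
                              mismatches = mm[ok])
  }
  if (!length(out))
    return(data.frame(read_id = character(), ref = character(),
                      pos = integer(), length = integer(),
                      mismatches = integer(), multiplicity = integer()))
  d <- do.call(rbind, out)
  d <- d[d$mismatches == min(d$mismatches), , drop = FALSE]
  d <- data.frame(read_id = "read", ref = d$ref, pos = d$pos, length = len,
                  mismatches = d$mismatches, multiplicity = nrow(d))
  d[order(d$ref, d$pos), , drop = FALSE]
}
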