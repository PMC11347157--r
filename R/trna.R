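#' Construct a TRNAReference
#'
#' @param seqs Named character vector or DNAStringSet of mature sequences
#'   (must end in CCA).
#' @param info Optional \code{data.frame} (\code{id}, \code{aa},
#'   \code{anticodon}, \code{family}, \code{copies}); derived from ids of the
#'   form \code{"Aa-ANT-1"} when omitted.
#' @return A \linkS4class{TRNAReference}.
#' @export
TRNAReference <- function(seqs, info = NULL) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  if (is.null(info)) {
    parts <- strsplit(names(seqs), "-", fixed = TRUE)
    info <- data.frame(id = names(seqs),
                       aa = vapply(parts, `[`, "", 1L),
                       anticodon = vapply(parts, `[`, "", 2L),
                       copies = 1L)
    info$family <- paste(info$aa, info$anticodon, sep = "-")
    info <- info[, c("id", "aa", "anticodon", "family", "copies")]
  }
  new("TRNAReference", seqs = seqs, info = info)
}

#' Build a mature tRNA reference from raw gene sequences
#'
#' Splices out annotated introns, appends the 3' CCA when absent, prepends
#' the 5' G-1 carried by histidine tRNAs when absent, and collapses genes
#' with identical mature sequences into one record with a copy count.
#'
#' @param raw Named character vector, DNAStringSet, or FASTA path of raw
#'   tRNA gene sequences; ids of the form \code{"Aa-ANT-..."} (amino acid,
#'   anticodon).
#' @param introns Optional \code{data.frame} (\code{id}, \code{start},
#'   \code{end}; 0-based, half-open) of intron intervals to remove.
#' @return A \linkS4class{TRNAReference}.
#' @export
buildMatureReference <- function(raw, introns = NULL) {
  if (is.character(raw) && length(raw) == 1L && file.exists(raw) &&
      is.null(names(raw)))
    raw <- Biostrings::readDNAStringSet(raw)
  if (is(raw, "DNAStringSet")) raw <- setNames(as.character(raw), names(raw))
  if (!length(raw)) stop("no tRNA sequences supplied")
  if (!is.null(introns)) {
    for (i in seq_len(nrow(introns))) {
      id <- introns$id[i]
      s <- raw[[id]]
      raw[[id]] <- paste0(substr(s, 1L, introns$start[i]),
                          substring(s, introns$end[i] + 1L))
    }
  }
  aa <- vapply(strsplit(names(raw), "-", fixed = TRUE), `[`, "", 1L)
  his <- aa == "His" & !startsWith(raw, "G")
  raw[his] <- paste0("G", raw[his])
  noCCA <- !endsWith(raw, "CCA")
  raw[noCCA] <- paste0(raw[noCCA], "CCA")
  # collapse identical mature sequences
  first <- !duplicated(raw)
  copies <- as.integer(table(factor(raw, levels = raw[first]))[raw[first]])
  mature <- raw[first]
  parts <- strsplit(names(mature), "-", fixed = TRUE)
  info <- data.frame(id = names(mature),
                     aa = vapply(parts, `[`, "", 1L),
                     anticodon = vapply(parts, `[`, "", 2L),
                     copies = copies)
  info$family <- paste(info$aa, info$anticodon, sep = "-")
  TRNAReference(mature, info[, c("id", "aa", "anticodon", "family",
                                 "copies")])
}

#' Synthetic mature tRNA reference
#'
#' Random-body isodecoder set for simulation and testing: \code{n}
#' isodecoders spread over common amino-acid/anticodon families, always
#' including the initiator \code{iMet-CAT-1} and the glutamine isodecoders
#' \code{Gln-CTG-1} and \code{Gln-TTG-1} (the species depleted when m1G9 is
#' lost). Bodies are random (72-76 nt) and end in CCA, so reads are
#' unique-mappable except where tests construct sharing on purpose.
#'
#' @param n Number of isodecoders (>= 3).
#' @param seed Integer seed.
#' @return A \linkS4class{TRNAReference}.
#' @export
syntheticTrnaReference <- function(n = 40L, seed = NULL) {
  if (n < 3L) stop("need at least 3 isodecoders")
  aas <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Glu", "Gly", "His", "Ile",
           "Leu", "Lys", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")
  withSeedIf(seed, {
    ids <- c("iMet-CAT-1", "Gln-CTG-1", "Gln-TTG-1")
    extra <- n - 3L
    if (extra > 0L) {
      fam <- rep_len(aas, extra)
      anticodon <- vapply(seq_len(extra), function(i)
        paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
              collapse = ""), "")
      copy <- stats::ave(seq_len(extra), fam, FUN = seq_along)
      ids <- c(ids, paste(fam, anticodon, copy, sep = "-"))
    }
    lens <- sample(72:76, n, replace = TRUE)
    seqs <- vapply(lens, function(L) paste0(randomNt(L - 3L), "CCA"), "")
    TRNAReference(setNames(seqs, ids))
  })
}

#' Simulate tRNA-seq reads with end variation
#'
#' Reads are full-length mature tRNA sequences, with the isodecoder drawn
#' proportionally to its abundance. The end model applies two independent
#' edits: with probability \code{p_extra5} one non-templated random
#' nucleotide is prepended to the 5' end (the reverse-transcriptase terminal
#' transferase artefact), and with probability \code{p_trunc3} the terminal
#' A of the CCA tail is missing. Origin records describe the pre-edit slice.
#'
#' @param reference A \linkS4class{TRNAReference}.
#' @param abundance Named non-negative weights per isodecoder (default
#'   equal).
#' @param endModel List with \code{p_extra5} and \code{p_trunc3} in [0, 1].
#' @param depth Number of reads (>= 0).
#' @param seed Integer seed.
#' @return A \linkS4class{ReadSet} tagged \code{"trna"}.
#' @export
simulateTrnaReads <- function(reference, abundance = NULL,
                              endModel = list(p_extra5 = 0, p_trunc3 = 0),
                              depth, seed = NULL) {
  if (!length(txSeqs(reference))) stop("tRNA reference is empty")
  ids <- names(txSeqs(reference))
  if (is.null(abundance)) abundance <- setNames(rep(1, length(ids)), ids)
  if (any(abundance < 0)) stop("abundances must be non-negative")
  p5 <- endModel$p_extra5; p3 <- endModel$p_trunc3
  if (p5 < 0 || p5 > 1 || p3 < 0 || p3 > 1)
    stop("end-model probabilities must lie in [0, 1]")
  if (depth == 0L) return(emptyReadSet("trna"))
  seqs <- setNames(as.character(txSeqs(reference)), ids)
  lens <- nchar(seqs)
  withSeedIf(seed, {
    ti <- sample(ids, depth, replace = TRUE, prob = abundance[ids])
    rdLen <- lens[ti]
    sq <- seqs[ti]
    trunc <- stats::runif(depth) < p3
    sq[trunc] <- substr(sq[trunc], 1L, rdLen[trunc] - 1L)
    rdLen[trunc] <- rdLen[trunc] - 1L
    extra <- stats::runif(depth) < p5
    nt <- sample(c("A", "C", "G", "T"), depth, replace = TRUE)
    sq[extra] <- paste0(nt[extra], sq[extra])
    # origin length is the templated slice (the non-templated 5' nt excluded),
    # so slicing the reference at the origin always reproduces the pre-edit read
    newReadSet(as.character(seq_len(depth)), unname(sq), ti,
               0L, unname(rdLen), "trna")
  })
}

#' Map tRNA reads allowing one non-templated 5' nucleotide
#'
#' Full-length reads are mapped exactly; a read that fails to map is retried
#' with its first nucleotide removed (the single allowed non-templated 5'
#' base), and successes are flagged \code{soft5 = 1}. The read length column
#' always refers to the aligned portion.
#'
#' @param reads A \linkS4class{ReadSet} of tRNA reads.
#' @param reference A \linkS4class{TRNAReference}.
#' @param k Index k-mer size.
#' @param maxMismatches Substitutions allowed in the aligned portion.
#' @return Alignment \code{data.frame} with the extra column \code{soft5};
#'   unmapped ids in \code{attr(, "unmapped")}.
#' @export
mapTrnaReads <- function(reads, reference, k = 12L, maxMismatches = 0L) {
  idx <- buildKmerIndex(txSeqs(reference), k = k)
  r <- readTable(reads)
  seqs <- setNames(r$seq, r$id)
  aln <- mapSeqs(seqs, idx, as.integer(maxMismatches))
  aln$soft5 <- if (nrow(aln)) 0L else integer()
  left <- setdiff(names(seqs), aln$read_id)
  if (length(left)) {
    trimmed <- substring(seqs[left], 2L)
    keep <- nchar(trimmed) >= k
    aln2 <- mapSeqs(trimmed[keep], idx, as.integer(maxMismatches))
    if (nrow(aln2)) {
      aln2$soft5 <- 1L
      aln <- rbind(aln, aln2)
    }
  }
  attr(aln, "unmapped") <- setdiff(names(seqs), aln$read_id)
  aln
}

#' Quantify isodecoder abundances with multimap resolution
#'
#' \code{uniform} mode splits each read equally over its tied best hits
#' (1/multiplicity each). \code{em} mode resolves shared reads by
#' expectation--maximisation: reads are fractionally assigned in proportion
#' to current isodecoder abundances among their hits and abundances
#' re-estimated, iterating until the maximum relative-abundance change is
#' below \code{tol} (or 100 iterations). Both modes conserve the total
#' mapped read count exactly.
#'
#' @param aln Alignment \code{data.frame} (one sample) against the tRNA
#'   reference.
#' @param reference A \linkS4class{TRNAReference}.
#' @param mode \code{"uniform"} or \code{"em"}.
#' @param tol EM convergence tolerance (default 1e-8).
#' @return Named numeric vector of fractional counts over all isodecoders.
#' @export
quantifyIsodecoders <- function(aln, reference, mode = c("uniform", "em"),
                                tol = 1e-8) {
  mode <- match.arg(mode)
  ids <- names(txSeqs(reference))
  if (!nrow(aln)) stop("zero mapped reads")
  a <- as.data.table(aln)
  if (mode == "uniform") {
    tot <- a[, sum(1 / multiplicity), by = ref]
    out <- setNames(numeric(length(ids)), ids)
    out[tot$ref] <- tot$V1
    return(out)
  }
  # EM over hit-set equivalence classes
  hitSets <- a[, list(key = paste(sort(unique(ref)), collapse = "\r")),
               by = read_id]
  classes <- hitSets[, .N, by = key]
  members <- strsplit(classes$key, "\r", fixed = TRUE)
  total <- sum(classes$N)
  alpha <- setNames(rep(1 / length(ids), length(ids)), ids)
  for (it in seq_len(100L)) {
    cnt <- setNames(numeric(length(ids)), ids)
    for (j in seq_along(members)) {
      h <- members[[j]]
      w <- alpha[h]
      if (sum(w) == 0) w <- rep(1, length(h))
      cnt[h] <- cnt[h] + classes$N[j] * w / sum(w)
    }
    alphaNew <- cnt / total
    if (max(abs(alphaNew - alpha)) < tol) { alpha <- alphaNew; break }
    alpha <- alphaNew
  }
  alpha * total
}

#' Assemble an IsodecoderTable across samples
#'
#' @param quantList Named list of per-sample fractional count vectors from
#'   \code{\link{quantifyIsodecoders}}.
#' @param genotype Character vector of genotypes, one per sample.
#' @param mode Multimap mode used (metadata).
#' @return An \linkS4class{IsodecoderTable}.
#' @export
isodecoderTable <- function(quantList, genotype, mode = "uniform") {
  m <- do.call(cbind, quantList)
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("s%d", seq_along(quantList))
  new("IsodecoderTable", counts = m,
      genotype = setNames(genotype, colnames(m)), mode = mode)
}

#' Compare isodecoder abundances between genotypes
#'
#' Per isodecoder: Welch's t-test on the per-sample relative abundances
#' (fraction of the sample's mapped tRNA reads), the null/WT ratio of mean
#' relative abundances, and Sidak family-wise adjustment
#' \eqn{p_{adj} = 1-(1-p)^m} over the \code{m} isodecoders tested. A two-way
#' ANOVA omnibus (genotype x isodecoder interaction on relative abundances)
#' is attached as \code{attr(, "anova")}. Isodecoders whose mature sequences
#' are within one edit of another get a similarity note, since short-read
#' (or probe) assignment between such species is unreliable.
#'
#' @param tab An \linkS4class{IsodecoderTable} with >= 2 replicates per
#'   genotype.
#' @return \code{data.frame}: \code{isodecoder}, \code{mean_WT},
#'   \code{mean_null}, \code{ratio}, \code{t}, \code{p}, \code{p_adj},
#'   \code{tier}, \code{degenerate}, \code{similar_to}.
#' @param reference Optional \linkS4class{TRNAReference} for the similarity
#'   check.
#' @export
compareAbundance <- function(tab, reference = NULL) {
  rel <- relAbundance(tab)
  gt <- tab@genotype[colnames(rel)]
  if (sum(gt == "WT") < 2L || sum(gt == "null") < 2L)
    stop("need >= 2 replicates per genotype")
  iso <- rownames(rel)
  res <- lapply(iso, function(i) {
    w <- rel[i, gt == "WT"]; n <- rel[i, gt == "null"]
    wt <- welchTest(n, w)
    data.frame(isodecoder = i, mean_WT = mean(w), mean_null = mean(n),
               ratio = if (mean(w) > 0) mean(n) / mean(w) else NA_real_,
               t = wt$t, p = wt$p, degenerate = wt$degenerate)
  })
  res <- do.call(rbind, res)
  res$p_adj <- sidakAdjust(res$p, m = nrow(res))
  res$tier <- pTier(res$p_adj)
  res$similar_to <- ""
  if (!is.null(reference)) {
    seqs <- as.character(txSeqs(reference))[iso]
    d <- utils::adist(seqs)
    for (i in seq_along(iso)) {
      close <- iso[d[i, ] <= 1L & seq_along(iso) != i]
      if (length(close)) res$similar_to[i] <- paste(close, collapse = ",")
    }
  }
  long <- data.frame(rel = as.vector(rel),
                     isodecoder = rep(iso, ncol(rel)),
                     genotype = rep(gt, each = nrow(rel)))
  res <- res[order(res$p_adj), ]
  rownames(res) <- NULL
  attr(res, "anova") <- summary(stats::aov(rel ~ genotype * isodecoder,
                                           data = long))
  res
}

#' 5'/3' read end profiles per isodecoder
#'
#' Tallies, for each isodecoder, the distribution of read 5' start offsets
#' relative to the mature 5' end (-1 = one extra non-templated nucleotide,
#' 0 = mature start, +k = truncated by k) and of 3' end offsets relative to
#' the CCA terminus (0 = full CCA, -1 = missing the terminal A, ...). Both
#' distributions are normalised to 1, and the -1 (extra nucleotide) 5' row
#' is always reported even at zero mass.
#'
#' @param aln Alignments from \code{\link{mapTrnaReads}} (needs the
#'   \code{soft5} column).
#' @param reference A \linkS4class{TRNAReference}.
#' @return \code{data.frame}: \code{isodecoder}, \code{end}
#'   (\code{"five"}/\code{"three"}), \code{offset}, \code{fraction}.
#' @export
endProfiles <- function(aln, reference) {
  refLen <- setNames(nchar(as.character(txSeqs(reference))),
                     names(txSeqs(reference)))
  a <- as.data.table(aln)
  a[, wt := 1 / multiplicity]
  a[, five := ifelse(soft5 == 1L, -1L, pos)]
  a[, three := (pos + length) - refLen[ref]]
  out <- list()
  for (id in sort(unique(a$ref))) {
    s <- a[ref == id]
    tot <- sum(s$wt)
    f5 <- s[, sum(wt), by = five]
    if (!(-1L) %in% f5$five)
      f5 <- rbind(f5, data.table(five = -1L, V1 = 0))
    setorder(f5, five)
    f3 <- s[, sum(wt), by = three]
    setorder(f3, three)
    out[[id]] <- rbind(
      data.frame(isodecoder = id, end = "five", offset = f5$five,
                 fraction = f5$V1 / tot),
      data.frame(isodecoder = id, end = "three", offset = f3$three,
                 fraction = f3$V1 / tot))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
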