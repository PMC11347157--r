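#' Per-gene codon fraction of the coding sequence
#'
#' For each CDS, the percentage of in-frame codons equal to \code{codon}.
#' The terminal stop codon is excluded from the denominator by default
#' (\code{includeStop = TRUE} keeps it); \code{ofGln = TRUE} instead
#' expresses CAG (or CAA) as a percentage of glutamine codons only,
#' \eqn{100 \cdot CAG / (CAG + CAA)}. Input case is ignored.
#'
#' @param cds Named character vector or \link[Biostrings]{DNAStringSet} of
#'   CDS sequences (length divisible by 3).
#' @param codon Target 3-mer (default \code{"CAG"}).
#' @param includeStop Count the final codon in the denominator.
#' @param ofGln Use glutamine codons as the denominator.
#' @return Named numeric vector of percentages in [0, 100].
#' @examples
#' codonFraction(c(g1 = "ATGCAGCAGTAA"))  # 2 of 3 non-stop codons
#' @export
codonFraction <- function(cds, codon = "CAG", includeStop = FALSE,
                          ofGln = FALSE) {
  if (is(cds, "DNAStringSet")) cds <- setNames(as.character(cds), names(cds))
  cds <- toupper(cds)
  codon <- toupper(codon)
  if (nchar(codon) != 3L) stop("codon must be a 3-mer")
  bad <- names(cds)[nchar(cds) %% 3L != 0L]
  if (length(bad))
    stop("CDS length not divisible by 3 for: ", paste(bad, collapse = ", "))
  vapply(names(cds), function(g) {
    s <- cds[[g]]
    nc <- nchar(s) %/% 3L
    cods <- substring(s, 3L * (seq_len(nc) - 1L) + 1L, 3L * seq_len(nc))
    if (!includeStop) cods <- cods[-nc]
    if (ofGln) {
      gln <- sum(cods %in% c("CAG", "CAA"))
      if (gln == 0L) return(NA_real_)
      return(100 * sum(cods == codon) / gln)
    }
    if (!length(cods)) return(NA_real_)
    100 * sum(cods == codon) / length(cods)
  }, numeric(1))
}

#' Compare codon fractions between two gene groups
#'
#' Two-sided Mann--Whitney (Wilcoxon rank-sum) test of the per-gene codon
#' fractions of two disjoint gene groups -- e.g. the TE-down versus TE-up
#' classes. The exact null distribution (full enumeration) is used when the
#' smaller group has at most 8 genes and there are no ties; otherwise the
#' normal approximation with tie correction.
#'
#' @param fractions Named numeric vector from \code{\link{codonFraction}}.
#' @param groupA,groupB Character vectors of gene ids (non-empty, disjoint).
#' @return List: \code{medianA}, \code{medianB}, \code{U} (for group A),
#'   \code{p}, \code{method} (\code{"exact"} or \code{"approx"}).
#' @export
compareCodonGroups <- function(fractions, groupA, groupB) {
  if (!length(groupA) || !length(groupB)) stop("groups must be non-empty")
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  missing <- setdiff(c(groupA, groupB), names(fractions))
  if (length(missing))
    stop("genes missing from the fraction table: ",
         paste(missing, collapse = ", "))
  a <- fractions[groupA]; b <- fractions[groupB]
  ties <- any(duplicated(c(a, b)))
  exact <- min(length(a), length(b)) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(medianA = stats::median(a), medianB = stats::median(b),
       U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "approx")
}
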