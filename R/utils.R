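#' @importFrom withr with_seed
#' @importFrom stats rnbinom rgeom rlnorm runif median optimize uniroot
#'   p.adjust pt qchisq t.test wilcox.test aov var setNames rmultinom pchisq
#' @importFrom utils head adist
NULL

## Run expr under a fixed seed without disturbing the caller's RNG stream;
## seed = NULL uses the current stream.
withSeedIf <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

## Welch two-sample t on numeric vectors, tolerating degenerate variance.
## Returns list(t, df, p, degenerate). Both groups constant -> p = 1, flag.
welchTest <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if ((is.na(vx) || vx == 0) && (is.na(vy) || vy == 0))
    return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
  se2 <- vx / length(x) + vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1L) +
                 (vy / length(y))^2 / (length(y) - 1L))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

## Significance tiers as in standard figure legends.
pTier <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Sidak family-wise adjustment
#'
#' \eqn{p_{adj} = 1 - (1 - p)^m} over \code{m} tests (defaults to the number
#' of p-values supplied).
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size.
#' @return Adjusted p-values, capped at 1.
#' @export
sidakAdjust <- function(p, m = length(p)) {
  pmin(1, 1 - (1 - p)^m)
}

## Hamming distance between equal-length strings (vectorised over pairs).
hammingDist <- function(a, b) {
  stopifnot(length(a) == length(b))
  vapply(seq_along(a),
         function(i) sum(charToRaw(a[[i]]) != charToRaw(b[[i]])),
         integer(1))
}

## In-frame codons of a subsequence [start, end) of a transcript sequence.
codonsOfRegion <- function(seq, start, end) {
  len <- end - start
  stopifnot(len %% 3L == 0L)
  n <- len %/% 3L
  if (n == 0L) return(character())
  substring(seq, start + 1L + 3L * (seq_len(n) - 1L),
            start + 3L * seq_len(n))
}

## CDS interval [start, end) for one transcript from an annotation table.
cdsOf <- function(anno, tx) {
  row <- anno[anno$transcript_id == tx & anno$feature == "CDS", , drop = FALSE]
  if (nrow(row) != 1L)
    stop("transcript '", tx, "' must have exactly one CDS annotation")
  c(start = row$start, end = row$end)
}
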