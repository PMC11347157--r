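#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @importFrom limma squeezeVar
NULL

#' Count reads per gene for one sample
#'
#' A footprint counts toward a gene iff its A-site nucleotide (5' position +
#' length offset) lies within the CDS; an RNA-seq read counts iff its 5' end
#' lies within the transcript. Multimapped reads contribute fractionally
#' (1/multiplicity); the per-gene totals are rounded to integers at matrix
#' level. Genes are the transcripts of the single-isoform annotation.
#'
#' @param aln Alignment \code{data.frame}.
#' @param anno Annotation \code{data.frame} with CDS rows.
#' @param assay \code{"footprint"} or \code{"rna"}.
#' @param offsets A-site offsets by length (footprint assay only).
#' @return Named integer vector of counts over all annotated genes.
#' @export
countCds <- function(aln, anno, assay = c("footprint", "rna"),
                     offsets = defaultOffsets()) {
  assay <- match.arg(assay)
  cds <- anno[anno$feature == "CDS", , drop = FALSE]
  genes <- cds$transcript_id
  a <- as.data.table(aln)
  if (!nrow(a)) return(setNames(integer(length(genes)), genes))
  if (!"multiplicity" %in% names(a)) a[, multiplicity := 1L]
  a[, wt := 1 / multiplicity]
  if (assay == "footprint") {
    a <- a[as.character(length) %in% names(offsets)]
    a[, site := pos + offsets[as.character(length)]]
    cs <- setNames(cds$start, genes); ce <- setNames(cds$end, genes)
    a <- a[ref %in% genes & site >= cs[ref] & site < ce[ref]]
  } else {
    a <- a[ref %in% genes & pos >= 0L]
  }
  tot <- a[, sum(wt), by = ref]
  out <- setNames(numeric(length(genes)), genes)
  out[tot$ref] <- tot$V1
  setNames(as.integer(round(out)), genes)
}

#' Build a genotype-labelled count matrix
#'
#' @param alnList Named list of alignment \code{data.frame}s, one per sample.
#' @param anno Annotation \code{data.frame}.
#' @param genotype Character vector of genotypes (\code{"WT"} /
#'   \code{"null"}), one per sample.
#' @param assay \code{"footprint"} or \code{"rna"}.
#' @param offsets A-site offsets (footprint assay).
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with one
#'   \code{counts} assay and \code{colData} column \code{genotype}.
#' @export
countMatrix <- function(alnList, anno, genotype,
                        assay = c("footprint", "rna"),
                        offsets = defaultOffsets()) {
  assay <- match.arg(assay)
  m <- vapply(alnList, countCds, anno = anno, assay = assay,
              offsets = offsets,
              FUN.VALUE = integer(sum(anno$feature == "CDS")))
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("%s_%d", assay, seq_along(alnList))
  SummarizedExperiment(assays = list(counts = m),
                       colData = DataFrame(genotype = genotype,
                                           row.names = colnames(m)))
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (restricted to genes with nonzero
#' counts in every sample) of the ratio of the sample's count to the gene's
#' geometric mean across samples. A single-sample matrix gets factor 1. If no
#' gene is nonzero in all samples, falls back to total-count scaling
#' (normalised to mean 1) with a warning.
#'
#' @param counts Integer matrix, genes x samples (or a SummarizedExperiment).
#' @return Named numeric vector of per-sample size factors.
#' @export
computeSizeFactors <- function(counts) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts)
  ok <- rowSums(counts == 0) == 0
  if (!any(ok)) {
    warning("no gene has nonzero counts in all samples; ",
            "falling back to total-count scaling")
    tc <- colSums(counts)
    return(tc / mean(tc))
  }
  m <- counts[ok, , drop = FALSE]
  geo <- exp(rowMeans(log(m)))
  apply(m, 2, function(col) stats::median(col / geo))
}

#' Translational efficiency table (null vs WT)
#'
#' Per gene, counts are size-factor normalised, shifted by a pseudocount and
#' log2-transformed; the TE log2 fold change is the difference-of-differences
#' contrast
#' \deqn{\Delta = (\bar x^{fp}_{null} - \bar x^{fp}_{WT}) -
#'                (\bar x^{rna}_{null} - \bar x^{rna}_{WT})}
#' with standard error from the four group variance-of-mean terms and
#' Welch--Satterthwaite degrees of freedom. The footprint and RNA assays may
#' have different replicate numbers; replicates are not paired across assays.
#' By default the four group variances are moderated across genes by
#' empirical Bayes (\code{limma::squeezeVar}), which restores calibrated
#' power at the 3-replicate scale; \code{moderate = FALSE} gives the plain
#' per-gene Welch contrast. Benjamini--Hochberg q-values are included for the
#' record; classification (\code{\link{classifyTE}}) uses raw p.
#'
#' @param fp,rna \link[SummarizedExperiment]{SummarizedExperiment} count
#'   matrices with \code{colData$genotype} in \{"WT", "null"\} (>= 2
#'   replicates per genotype per assay).
#' @param pseudocount Added to normalised counts before log2 (default 0.5).
#' @param moderate Moderate group variances across genes (default
#'   \code{TRUE}).
#' @return \code{data.frame}: \code{gene}, \code{log2FC_TE} (null/WT),
#'   \code{se}, \code{t}, \code{df}, \code{p}, \code{q}, \code{flag}
#'   (\code{TRUE} when some group is all-zero; p forced to 1).
#' @export
teTable <- function(fp, rna, pseudocount = 0.5, moderate = TRUE) {
  genes <- intersect(rownames(fp), rownames(rna))
  if (!length(genes)) stop("no shared genes between assays")
  fp <- fp[genes, ]; rna <- rna[genes, ]
  groups <- list(
    fpN  = assay(fp)[, colData(fp)$genotype == "null", drop = FALSE],
    fpW  = assay(fp)[, colData(fp)$genotype == "WT", drop = FALSE],
    rnaN = assay(rna)[, colData(rna)$genotype == "null", drop = FALSE],
    rnaW = assay(rna)[, colData(rna)$genotype == "WT", drop = FALSE])
  n <- vapply(groups, ncol, integer(1))
  if (any(n < 2L)) stop("need >= 2 replicates per genotype per assay")
  sfFp <- computeSizeFactors(assay(fp))
  sfRna <- computeSizeFactors(assay(rna))
  sf <- list(fpN = sfFp[colData(fp)$genotype == "null"],
             fpW = sfFp[colData(fp)$genotype == "WT"],
             rnaN = sfRna[colData(rna)$genotype == "null"],
             rnaW = sfRna[colData(rna)$genotype == "WT"])
  x <- Map(function(cnt, s) log2(sweep(cnt, 2, s, "/") + pseudocount),
           groups, sf)
  m <- vapply(x, rowMeans, numeric(length(genes)))
  v <- vapply(x, function(z) apply(z, 1, stats::var), numeric(length(genes)))
  dfg <- matrix(rep(n - 1L, each = length(genes)), ncol = 4L)
  if (moderate && length(genes) >= 10L) {
    for (j in 1:4) {
      # suppressed: limma offsets exact-zero variances away from zero itself
      sq <- suppressWarnings(limma::squeezeVar(v[, j], df = n[j] - 1L))
      v[, j] <- sq$var.post
      dfg[, j] <- dfg[, j] + min(sq$df.prior, 1e6)
    }
  }
  lfc <- (m[, "fpN"] - m[, "fpW"]) - (m[, "rnaN"] - m[, "rnaW"])
  vterm <- sweep(v, 2, n, "/")
  se2 <- rowSums(vterm)
  t <- lfc / sqrt(se2)
  df <- se2^2 / rowSums(vterm^2 / dfg)
  p <- 2 * stats::pt(-abs(t), df)
  allZero <- vapply(groups, function(g) rowSums(g) == 0,
                    logical(length(genes)))
  flag <- rowSums(allZero) > 0
  p[flag] <- 1
  t[flag] <- 0
  data.frame(gene = genes, log2FC_TE = unname(lfc), se = unname(sqrt(se2)),
             t = unname(t), df = unname(df), p = unname(p),
             q = stats::p.adjust(p, "BH"), flag = unname(flag))
}

#' Classify TE changes at fixed thresholds
#'
#' \code{up} iff p < \code{pThreshold} and log2FC > \code{lfcThreshold};
#' \code{down} iff p < \code{pThreshold} and log2FC < -\code{lfcThreshold};
#' otherwise \code{unchanged}. Inequalities are strict, so a gene at exactly
#' the fold-change threshold is unchanged.
#'
#' @param results \code{data.frame} from \code{\link{teTable}}.
#' @param pThreshold Raw p cutoff (default 0.05).
#' @param lfcThreshold log2 fold-change cutoff (default 0.5).
#' @return The input with a \code{label} column added.
#' @export
classifyTE <- function(results, pThreshold = 0.05, lfcThreshold = 0.5) {
  lab <- rep("unchanged", nrow(results))
  lab[results$p < pThreshold & results$log2FC_TE > lfcThreshold] <- "up"
  lab[results$p < pThreshold & results$log2FC_TE < -lfcThreshold] <- "down"
  results$label <- lab
  results
}

#' Write / read TE class gene lists
#'
#' One gene id per line, one file per class (\code{up.txt},
#' \code{down.txt}); the hand-off format feeding codon-composition
#' comparisons and external enrichment tools.
#'
#' @param results Classified table from \code{\link{classifyTE}}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
writeGeneLists <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(up = file.path(dir, "up.txt"),
             down = file.path(dir, "down.txt"))
  for (cls in names(paths))
    writeLines(results$gene[results$label == cls], paths[[cls]])
  invisible(paths)
}

#' @rdname writeGeneLists
#' @param path A gene-list file.
#' @export
readGeneList <- function(path) readLines(path)

#' Simulate negative binomial footprint/RNA count matrices
#'
#' Replicate counts per gene are negative binomial with common dispersion
#' (variance \eqn{\mu + \alpha\mu^2}); a chosen subset of genes carries a
#' footprint-only fold change in the null genotype, i.e. a pure TE effect.
#'
#' @param nGenes Total genes.
#' @param effectGenes Number of genes (the first ones) given the TE effect.
#' @param lfc True log2 TE fold change (null/WT) for effect genes.
#' @param mu Mean count.
#' @param dispersion NB dispersion \eqn{\alpha} (default 0.05).
#' @param nFpRep,nRnaRep Replicates per genotype for footprint / RNA assays
#'   (defaults 3 and 5).
#' @param seed Integer seed.
#' @return List with elements \code{fp}, \code{rna} (SummarizedExperiments)
#'   and \code{truth} (logical vector marking effect genes).
#' @export
simulateTECounts <- function(nGenes = 2000L, effectGenes = 0L, lfc = 1,
                             mu = 500, dispersion = 0.05, nFpRep = 3L,
                             nRnaRep = 5L, seed = NULL) {
  size <- 1 / dispersion
  genes <- sprintf("g%04d", seq_len(nGenes))
  muFpNull <- rep(mu, nGenes)
  truth <- rep(FALSE, nGenes)
  if (effectGenes > 0L) {
    truth[seq_len(effectGenes)] <- TRUE
    muFpNull[truth] <- mu * 2^lfc
  }
  withSeedIf(seed, {
    draw <- function(muVec, nrep) matrix(stats::rnbinom(nGenes * nrep,
      mu = rep(muVec, nrep), size = size), nrow = nGenes)
    fpW <- draw(rep(mu, nGenes), nFpRep); fpN <- draw(muFpNull, nFpRep)
    rnW <- draw(rep(mu, nGenes), nRnaRep); rnN <- draw(rep(mu, nGenes),
                                                       nRnaRep)
    mkSE <- function(w, nn, tag) {
      m <- cbind(w, nn)
      rownames(m) <- genes
      colnames(m) <- c(sprintf("%s_WT_%d", tag, seq_len(ncol(w))),
                       sprintf("%s_null_%d", tag, seq_len(ncol(nn))))
      SummarizedExperiment(assays = list(counts = m),
        colData = DataFrame(genotype = rep(c("WT", "null"),
                                           c(ncol(w), ncol(nn))),
                            row.names = colnames(m)))
    }
    list(fp = mkSE(fpW, fpN, "fp"), rna = mkSE(rnW, rnN, "rna"),
         truth = setNames(truth, genes))
  })
}
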