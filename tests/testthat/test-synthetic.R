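# Synthetic-data generators: construction invariants, determinism, and
# agreement of every simulator with its exact sampling distribution.

test_that("generated transcripts satisfy the coding-sequence invariants", {
  ts <- generateTranscriptome(10, meanCdsCodons = 100, seed = 1)
  expect_true(validObject(ts))
  anno <- featureTable(ts)
  cds <- anno[anno$feature == "CDS", ]
  expect_equal(nrow(cds), 10)
  seqs <- as.character(txSeqs(ts))
  for (i in seq_len(nrow(cds))) {
    s <- seqs[[cds$transcript_id[i]]]
    len <- cds$end[i] - cds$start[i]
    expect_equal(len %% 3, 0)
    expect_equal(substr(s, cds$start[i] + 1, cds$start[i] + 3), "ATG")
    expect_true(substr(s, cds$end[i] - 2, cds$end[i]) %in%
                  c("TAA", "TAG", "TGA"))
  }
})

test_that("Atf4-like architecture places uORF2 across the CDS start", {
  sp <- uorfSpec(uorf1Len = 9, d1 = 87, uorf2Len = 180, d2 = 100)
  ts <- generateTranscriptome(5, meanCdsCodons = 120, uorfSpec = sp,
                              seed = 2)
  anno <- featureTable(ts)
  u <- anno[anno$transcript_id == "tx0001", ]
  expect_setequal(u$feature, c("uORF1", "uORF2", "CDS"))
  u1 <- u[u$feature == "uORF1", ]; u2 <- u[u$feature == "uORF2", ]
  cds <- u[u$feature == "CDS", ]
  expect_equal(u2$start - u1$end, 87)            # spacer d1
  expect_equal(cds$start - u2$start, 100)        # d2
  expect_gt(u2$end, cds$start)                   # overlap
  expect_true((cds$start - u2$start) %% 3 != 0)  # out of frame
})

test_that("impossible uORF architectures are rejected by name", {
  expect_error(uorfSpec(d2 = 200, uorf2Len = 180), "overlap")
  expect_error(uorfSpec(d2 = 99), "out of frame")
  # CDS shorter than the requested overlap
  expect_error(
    generateTranscriptome(1, cdsCodons = 20,
                          uorfSpec = uorfSpec(uorf2Len = 300, d2 = 100),
                          seed = 1),
    "too short")
})

test_that("generators are byte-identical under a repeated seed", {
  ts1 <- generateTranscriptome(8, uorfSpec = uorfSpec(), seed = 7)
  ts2 <- generateTranscriptome(8, uorfSpec = uorfSpec(), seed = 7)
  expect_identical(as.character(txSeqs(ts1)), as.character(txSeqs(ts2)))
  expect_identical(featureTable(ts1), featureTable(ts2))
  f1 <- simulateFootprints(ts1, depth = 1000, seed = 9)
  f2 <- simulateFootprints(ts2, depth = 1000, seed = 9)
  expect_identical(readTable(f1), readTable(f2))
  r1 <- simulateRnaSeq(ts1, depth = 500, seed = 9)
  r2 <- simulateRnaSeq(ts2, depth = 500, seed = 9)
  expect_identical(readTable(r1), readTable(r2))
})

test_that("FASTA and annotation files are byte-identical under a seed", {
  d1 <- withr::local_tempdir()
  ts1 <- generateTranscriptome(5, seed = 3)
  ts2 <- generateTranscriptome(5, seed = 3)
  fa1 <- writeFasta(ts1, file.path(d1, "a.fa"))
  fa2 <- writeFasta(ts2, file.path(d1, "b.fa"))
  an1 <- writeAnnotation(featureTable(ts1), file.path(d1, "a.tsv"))
  an2 <- writeAnnotation(featureTable(ts2), file.path(d1, "b.tsv"))
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(readLines(an1), readLines(an2))
  expect_identical(readAnnotation(an1), featureTable(ts1))
})

test_that("every simulated read slices back out of its origin transcript", {
  ts <- smallTx()
  seqs <- as.character(txSeqs(ts))
  for (rs in list(simulateFootprints(ts, depth = 500, seed = 11),
                  simulateRnaSeq(ts, depth = 500, seed = 12))) {
    r <- readTable(rs)
    expect_identical(r$seq,
                     unname(substring(seqs[r$tx], r$pos + 1,
                                      r$pos + r$length)))
  }
  ref <- syntheticTrnaReference(10, seed = 13)
  tr <- simulateTrnaReads(ref, endModel = list(p_extra5 = 0.4,
                                               p_trunc3 = 0.3),
                          depth = 500, seed = 14)
  r <- readTable(tr)
  pre <- substring(as.character(txSeqs(ref))[r$tx], r$pos + 1,
                   r$pos + r$length)
  # pre-edit slice: the read equals the slice after undoing the 5' addition
  stripped <- ifelse(nchar(r$seq) > r$length, substring(r$seq, 2), r$seq)
  expect_identical(unname(stripped), unname(pre))
})

test_that("uniform dwell yields codon-frequency A-site fractions", {
  ts <- smallTx()
  depth <- 5e4
  exp <- expectedCodonFractions(ts)
  aln <- simAln(ts, depth = depth, seed = 21)
  as1 <- assignASites(aln, defaultOffsets(), featureTable(ts))
  # observed codon-identity fractions from the codon-index counts
  seqs <- as.character(txSeqs(ts))
  anno <- featureTable(ts)
  cds <- anno[anno$feature == "CDS", ]
  cod <- as1@codon
  starts <- setNames(cds$start, cds$transcript_id)
  ident <- substring(seqs[cod$tx], starts[cod$tx] + 3 * cod$codon_idx + 1,
                     starts[cod$tx] + 3 * cod$codon_idx + 3)
  obs <- tapply(cod$n, ident, sum) / sum(cod$n)
  for (c in names(exp)[exp > 0]) {
    se <- sqrt(exp[[c]] * (1 - exp[[c]]) / depth)
    expect_lt(abs(obs[[c]] - exp[[c]]), 3.5 * se + 1e-12)
  }
})

test_that("an injected slow codon shifts A-site mass to its exact expectation", {
  ts <- smallTx()
  dw <- dwellModel(CAG = 2)
  exp <- expectedCodonFractions(ts, dw)
  depth <- 1e5
  rs <- simulateFootprints(ts, dw, depth = depth, emitSequences = FALSE,
                           seed = 22)
  r <- readTable(rs)
  # recover each footprint's A-site codon identity from its origin record
  seqs <- as.character(txSeqs(ts))
  site <- r$pos + defaultOffsets()[as.character(r$length)]
  ident <- substring(seqs[r$tx], site + 1, site + 3)
  obsCAG <- mean(ident == "CAG")
  se <- sqrt(exp[["CAG"]] * (1 - exp[["CAG"]]) / depth)
  expect_lt(abs(obsCAG - exp[["CAG"]]), 3 * se)
})

test_that("chi-square of A-site counts is calibrated under the uniform null", {
  ts <- smallTx()
  exp <- expectedCodonFractions(ts)
  depth <- 2e4
  fails <- 0
  for (s in 1:100) {
    rs <- simulateFootprints(ts, depth = depth, emitSequences = FALSE,
                             seed = 3000 + s)
    r <- readTable(rs)
    seqs <- as.character(txSeqs(ts))
    site <- r$pos + defaultOffsets()[as.character(r$length)]
    ident <- substring(seqs[r$tx], site + 1, site + 3)
    obs <- table(factor(ident, levels = names(exp)[exp > 0]))
    e <- exp[exp > 0] * depth
    stat <- sum((obs - e)^2 / e)
    p <- stats::pchisq(stat, df = length(e) - 1, lower.tail = FALSE)
    if (p < 0.01) fails <- fails + 1
  }
  expect_lte(fails, 5)
})

test_that("zero-depth simulations return empty read sets", {
  ts <- smallTx(5)
  expect_equal(length(simulateFootprints(ts, depth = 0)), 0)
  expect_equal(length(simulateRnaSeq(ts, depth = 0)), 0)
  ref <- syntheticTrnaReference(5, seed = 1)
  expect_equal(length(simulateTrnaReads(ref, depth = 0)), 0)
  expect_error(simulateFootprints(TranscriptSet(
    setNames(character(), character()),
    data.frame(transcript_id = character(), feature = character(),
               start = integer(), end = integer())), depth = 10),
    "empty")
})

test_that("RNA-seq respects abundance weights and rejects short transcripts", {
  seqs <- c(a = paste0("ATG", strrep("GCT", 65), "TAA"),
            b = paste0("ATG", strrep("GAA", 65), "TAA"))
  anno <- data.frame(transcript_id = c("a", "b"), feature = "CDS",
                     start = 0L, end = 201L)
  ts <- TranscriptSet(seqs, anno, abundance = c(a = 1, b = 3))
  rs <- simulateRnaSeq(ts, depth = 1e5, readLength = 50, seed = 31)
  fb <- mean(readTable(rs)$tx == "b")
  se <- sqrt(0.75 * 0.25 / 1e5)
  expect_lt(abs(fb - 0.75), 3 * se)
  expect_error(simulateRnaSeq(ts, depth = 10, readLength = 300), "b")
})

test_that("tRNA end-variation probabilities are respected", {
  ref <- syntheticTrnaReference(10, seed = 41)
  depth <- 2e4
  tr <- simulateTrnaReads(ref, endModel = list(p_extra5 = 0.3,
                                               p_trunc3 = 0),
                          depth = depth, seed = 42)
  r <- readTable(tr)
  fr <- mean(nchar(r$seq) > r$length)
  expect_lt(abs(fr - 0.3), 3 * sqrt(0.3 * 0.7 / depth))
  # no edits: reads equal their mature reference exactly
  tr0 <- simulateTrnaReads(ref, depth = 1000, seed = 43)
  r0 <- readTable(tr0)
  expect_identical(unname(r0$seq),
                   unname(as.character(txSeqs(ref))[r0$tx]))
  # zero abundance excludes an isodecoder entirely
  ab <- setNames(rep(1, 10), names(txSeqs(ref)))
  ab["iMet-CAT-1"] <- 0
  tri <- simulateTrnaReads(ref, abundance = ab, depth = 5000, seed = 44)
  expect_false("iMet-CAT-1" %in% readTable(tri)$tx)
})

test_that("scanning cohort outcomes match the closed form across a grid", {
  for (q in c(0.002, 0.01, 0.05, 0.2, 0.8)) {
    for (d1 in c(10, 50, 100, 200, 400)) {
      for (d2 in c(10, 50, 100, 200, 400)) {
        pars <- scanningParams(q, d1, d2)
        n <- 1e5
        cnt <- simulateScanningCohort(pars, n, seed = round(1e4 * q) + d1 + d2)
        p <- reinitProbabilities(pars)
        expect_equal(sum(cnt), n)
        for (i in 1:3) {
          se <- sqrt(p[i] * (1 - p[i]) / n)
          # + 2/n: discreteness allowance for cells expecting < 1 count
          expect_lt(abs(cnt[i] / n - p[i]), 4 * se + 2 / n)
        }
      }
    }
  }
})

test_that("degenerate reacquisition probabilities hit single outcomes", {
  expect_equal(simulateScanningCohort(scanningParams(1, 50, 50), 1000,
                                      seed = 1),
               c(uORF2 = 1000L, CDS = 0L, none = 0L))
  expect_equal(simulateScanningCohort(scanningParams(0, 50, 50), 1000,
                                      seed = 1),
               c(uORF2 = 0L, CDS = 0L, none = 1000L))
})
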