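# Mature reference construction, isodecoder quantification (uniform and EM),
# genotype comparison with Sidak adjustment, and end profiles.

test_that("mature reference construction applies CCA, His G-1 and collapsing", {
  raw <- c("Ala-AGC-1" = "GGGCCCGTACGTACGTACGTAAACCA",
           "Gly-GCC-1" = "GGGTTTGTACGTACGTACGTAAA",
           "His-GTG-1" = "ATGCCCGTACGTACGTACGTAAA",
           "Ala-AGC-2" = "GGGCCCGTACGTACGTACGTAAACCA")
  ref <- buildMatureReference(raw)
  seqs <- as.character(txSeqs(ref))
  expect_true(all(endsWith(seqs, "CCA")))
  # already-CCA input unchanged; CCA appended otherwise
  expect_equal(seqs[["Ala-AGC-1"]], raw[["Ala-AGC-1"]])
  expect_equal(nchar(seqs[["Gly-GCC-1"]]), nchar(raw[["Gly-GCC-1"]]) + 3)
  # His gains the 5' G-1
  expect_true(startsWith(seqs[["His-GTG-1"]], "GATG"))
  # identical mature sequences collapse with a copy count
  expect_false("Ala-AGC-2" %in% names(seqs))
  expect_equal(ref@info$copies[ref@info$id == "Ala-AGC-1"], 2)
  # intron splicing
  ref2 <- buildMatureReference(c("Tyr-GTA-1" = "AAACCCGGGTTTCCA"),
                               introns = data.frame(id = "Tyr-GTA-1",
                                                    start = 3L, end = 6L))
  expect_equal(as.character(txSeqs(ref2))[[1]], "AAAGGGTTTCCA")
  expect_error(buildMatureReference(character()), "no tRNA")
})

test_that("unique reads give raw counts; shared reads split uniformly", {
  ref <- syntheticTrnaReference(8, seed = 301)
  tr <- simulateTrnaReads(ref, depth = 4000, seed = 302)
  aln <- mapTrnaReads(tr, ref)
  q <- quantifyIsodecoders(aln, ref)
  expect_equal(sum(q), 4000)
  truth <- table(readTable(tr)$tx)
  expect_equal(q[names(truth)], unclass(truth)[names(truth)],
               ignore_attr = TRUE)
  # a read hitting two isodecoders contributes 1/2 to each
  shared <- data.frame(read_id = "r1", ref = c("A", "B"), pos = 0L,
                       length = 70L, mismatches = 0L, multiplicity = 2L)
  refAB <- TRNAReference(c(A = paste0(strrep("ACGT", 17), "CCA"),
                           B = paste0(strrep("TGCA", 17), "CCA")))
  qs <- quantifyIsodecoders(shared, refAB)
  expect_equal(unname(qs[c("A", "B")]), c(0.5, 0.5))
  expect_equal(sum(qs), 1)
  expect_error(quantifyIsodecoders(shared[0, ], refAB), "zero")
})

test_that("EM allocation matches an independent fixed-point oracle", {
  refAB <- TRNAReference(c(A = paste0(strrep("ACGT", 17), "CCA"),
                           B = paste0(strrep("TGCA", 17), "CCA")))
  # 90 reads unique to A, 10 unique to B, 100 shared
  aln <- rbind(
    data.frame(read_id = sprintf("a%03d", 1:90), ref = "A", pos = 0L,
               length = 70L, mismatches = 0L, multiplicity = 1L),
    data.frame(read_id = sprintf("b%03d", 1:10), ref = "B", pos = 0L,
               length = 70L, mismatches = 0L, multiplicity = 1L),
    data.frame(read_id = rep(sprintf("s%03d", 1:100), each = 2),
               ref = rep(c("A", "B"), 100), pos = 0L, length = 70L,
               mismatches = 0L, multiplicity = 2L))
  got <- quantifyIsodecoders(aln, refAB, mode = "em")
  # oracle: iterate the fixed point a <- 90 + 100 a/(a+b); b <- 10 + ...
  a <- b <- 100
  for (i in 1:10000) {
    aNew <- 90 + 100 * a / (a + b)
    bNew <- 10 + 100 * b / (a + b)
    if (max(abs(c(aNew - a, bNew - b))) < 1e-12) break
    a <- aNew; b <- bNew
  }
  expect_equal(unname(got[c("A", "B")]), c(a, b), tolerance = 1e-6)
  expect_equal(sum(got), 200, tolerance = 1e-6)
})

test_that("EM never decreases the multimap log-likelihood", {
  set.seed(311)
  for (case in 1:20) {
    nIso <- 4
    ids <- LETTERS[1:nIso]
    ref <- TRNAReference(setNames(vapply(1:nIso, function(i)
      paste0(paste(sample(c("A", "C", "G", "T"), 69, TRUE), collapse = ""),
             "CCA"), ""), ids))
    # random hit sets
    nr <- 200
    rows <- lapply(1:nr, function(r) {
      hits <- sample(ids, sample(1:3, 1))
      data.frame(read_id = sprintf("r%03d", r), ref = hits, pos = 0L,
                 length = 72L, mismatches = 0L,
                 multiplicity = length(hits))
    })
    aln <- do.call(rbind, rows)
    hitSets <- split(aln$ref, aln$read_id)
    ll <- function(alpha) {
      alpha <- alpha / sum(alpha)
      sum(vapply(hitSets, function(h) log(sum(alpha[h])), numeric(1)))
    }
    # trace the EM by hand with the package's update rule
    alpha <- setNames(rep(1 / nIso, nIso), ids)
    prev <- ll(alpha)
    for (it in 1:25) {
      cnt <- setNames(numeric(nIso), ids)
      for (h in hitSets) {
        w <- alpha[h]
        cnt[h] <- cnt[h] + w / sum(w)
      }
      alpha <- cnt / sum(cnt)
      cur <- ll(alpha)
      expect_gte(cur, prev - 1e-10)
      prev <- cur
    }
    # and the packaged EM lands at (or above) the same likelihood
    em <- quantifyIsodecoders(aln, ref, mode = "em")
    expect_gte(ll(em), prev - 1e-6)
  }
})

test_that("Sidak adjustment matches its closed form", {
  expect_equal(sidakAdjust(0.001, m = 40), 1 - 0.999^40, tolerance = 1e-12)
  expect_equal(round(sidakAdjust(0.001, m = 40), 4), 0.0392)
  expect_equal(sidakAdjust(c(0.5, 1)), c(1 - 0.5^2, 1))
})

test_that("depleted isodecoders are detected with correct ratios", {
  ref <- syntheticTrnaReference(20, seed = 321)
  ids <- names(txSeqs(ref))
  abWT <- setNames(rep(1, 20), ids)
  abNull <- abWT
  abNull[c("iMet-CAT-1", "Gln-CTG-1")] <- 0.5
  quantOne <- function(ab, seed) {
    tr <- simulateTrnaReads(ref, abundance = ab, depth = 3e4, seed = seed)
    quantifyIsodecoders(mapTrnaReads(tr, ref), ref)
  }
  qs <- c(lapply(1:3, function(i) quantOne(abWT, 400 + i)),
          lapply(1:3, function(i) quantOne(abNull, 450 + i)))
  tab <- isodecoderTable(qs, rep(c("WT", "null"), each = 3))
  res <- compareAbundance(tab, ref)
  top2 <- res$isodecoder[order(res$p_adj)][1:2]
  expect_setequal(top2, c("iMet-CAT-1", "Gln-CTG-1"))
  r <- res$ratio[match(top2, res$isodecoder)]
  expect_true(all(r > 0.4 & r < 0.6))
  expect_true(!is.null(attr(res, "anova")))
})

test_that("identical groups give unit ratios and similarity notes appear", {
  seqA <- paste0(strrep("ACGT", 17), "CCA")
  seqB <- sub("^A", "C", seqA)   # one edit away
  ref <- TRNAReference(c(`Gln-CTG-1` = seqA, `Gln-TTG-1` = seqB))
  cnt <- matrix(c(60, 40, 60, 40, 60, 40, 60, 40), nrow = 2,
                dimnames = list(c("Gln-CTG-1", "Gln-TTG-1"),
                                sprintf("s%d", 1:4)))
  tab <- new("IsodecoderTable", counts = cnt,
             genotype = setNames(rep(c("WT", "null"), each = 2),
                                 colnames(cnt)),
             mode = "uniform")
  res <- compareAbundance(tab, ref)
  expect_true(all(res$ratio == 1))
  expect_true(all(res$degenerate))
  expect_equal(res$similar_to[res$isodecoder == "Gln-CTG-1"], "Gln-TTG-1")
})

test_that("end profiles recover the extra-nucleotide rate and report -1", {
  ref <- syntheticTrnaReference(6, seed = 331)
  depth <- 2e4
  tr <- simulateTrnaReads(ref, endModel = list(p_extra5 = 0.3,
                                               p_trunc3 = 0.2),
                          depth = depth, seed = 332)
  aln <- mapTrnaReads(tr, ref)
  expect_equal(length(attr(aln, "unmapped")), 0)
  ep <- endProfiles(aln, ref)
  tot <- table(readTable(tr)$tx)
  f5 <- ep[ep$end == "five" & ep$offset == -1, ]
  pooled5 <- sum(f5$fraction * tot[f5$isodecoder]) / sum(tot)
  expect_lt(abs(pooled5 - 0.3), 3 * sqrt(0.3 * 0.7 / depth))
  f3 <- ep[ep$end == "three" & ep$offset == -1, ]
  pooled3 <- sum(f3$fraction * tot[f3$isodecoder]) / sum(tot)
  expect_lt(abs(pooled3 - 0.2), 3 * sqrt(0.2 * 0.8 / depth))
  # no end variation: all mass at (0, 0), and the -1 row is still present
  tr0 <- simulateTrnaReads(ref, depth = 2000, seed = 333)
  ep0 <- endProfiles(mapTrnaReads(tr0, ref), ref)
  for (id in unique(ep0$isodecoder)) {
    e <- ep0[ep0$isodecoder == id, ]
    expect_true(any(e$end == "five" & e$offset == -1))
    expect_equal(e$fraction[e$end == "five" & e$offset == 0], 1)
    expect_equal(e$fraction[e$end == "three" & e$offset == 0], 1)
  }
})
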