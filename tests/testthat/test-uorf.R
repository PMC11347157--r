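# uORF region quantification, the CDS release statistic, and the
# reinitiation model (closed form, simulator agreement, MLE).

# A hand-built ASiteCounts over a transcript with uORF1 [10,19),
# uORF2 [40,100), CDS [70,160): uORF2 overlaps the CDS head.
uorfAnno <- function() {
  data.frame(transcript_id = "u1",
             feature = c("uORF1", "uORF2", "CDS"),
             start = c(10L, 40L, 70L), end = c(19L, 100L, 160L))
}

mkAsite <- function(sites, n = 1) {
  new("ASiteCounts", sample = "s",
      pos = data.frame(tx = "u1", site = as.integer(sites),
                       n = rep(n, length(sites))),
      codon = data.frame(tx = character(), codon_idx = integer(),
                         n = numeric()),
      tallies = c(in_cds = 0L, upstream = 0L, downstream = 0L,
                  dropped_length = 0L, dropped_multimap = 0L))
}

test_that("uniform per-nucleotide coverage gives equal region densities", {
  asite <- mkAsite(0:199)   # one count at every position
  q <- quantifyRegions(asite, uorfAnno(), "u1", librarySize = 200)
  # overlap positions counted toward uORF2 only -> CDS density drops
  qb <- quantifyRegions(asite, uorfAnno(), "u1", librarySize = 200,
                        overlapTo = "both")
  dens <- setNames(qb$density, qb$region)
  expect_equal(dens[["uORF1"]], dens[["uORF2"]], tolerance = 1e-9)
  expect_equal(dens[["uORF1"]], dens[["CDS"]], tolerance = 1e-9)
  dens1 <- setNames(q$density, q$region)
  expect_lt(dens1[["CDS"]], dens1[["uORF2"]])
})

test_that("overlap attribution and empty regions follow the stated rules", {
  # all footprints in uORF1 -> zero CDS count
  q1 <- quantifyRegions(mkAsite(c(10, 13, 16)), uorfAnno(), "u1", 3)
  expect_equal(q1$count[q1$region == "CDS"], 0)
  expect_equal(q1$count[q1$region == "uORF1"], 3)
  # a footprint inside the uORF2/CDS overlap increments uORF2, not CDS
  q2 <- quantifyRegions(mkAsite(85), uorfAnno(), "u1", 1)
  expect_equal(q2$count[q2$region == "uORF2"], 1)
  expect_equal(q2$count[q2$region == "CDS"], 0)
  q2b <- quantifyRegions(mkAsite(85), uorfAnno(), "u1", 1,
                         overlapTo = "both")
  expect_equal(q2b$count[q2b$region == "CDS"], 1)
})

test_that("identical groups give release 1 and zero uORF1 is flagged", {
  q <- quantifyRegions(mkAsite(c(12, 50, 120, 130)), uorfAnno(), "u1", 4)
  rel <- cdsRelease(list(q, q), list(q, q))
  expect_equal(rel$release, 1)
  expect_false(rel$undefined)
  q0 <- quantifyRegions(mkAsite(c(50, 120)), uorfAnno(), "u1", 2)
  rel0 <- cdsRelease(list(q0, q0), list(q, q))
  expect_true(rel0$undefined)
  expect_true(is.na(rel0$release))
})

test_that("lower reacquisition in the null releases CDS footprints", {
  ts <- generateTranscriptome(4, meanCdsCodons = 120,
                              uorfSpec = uorfSpec(transcripts = 1),
                              abundance = rep(1, 4), seed = 201)
  anno <- featureTable(ts)
  quantOne <- function(q, seed) {
    rs <- simulateUorfFootprints(ts, "tx0001", scanningParams(q, 87, 100),
                                 depth = 2e4, emitSequences = FALSE,
                                 seed = seed)
    as1 <- assignASites(alignmentsFromReads(rs), defaultOffsets(), anno)
    quantifyRegions(as1, anno, "tx0001", librarySize = 2e4)
  }
  hits <- 0
  for (s in 1:20) {
    wt <- lapply(1:3, function(i) quantOne(0.02, 3000 + 10 * s + i))
    nul <- lapply(1:3, function(i) quantOne(0.005, 6000 + 10 * s + i))
    rel <- cdsRelease(wt, nul)
    if (!rel$undefined && rel$release > 1) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("closed-form probabilities are exact and sum to one", {
  expect_equal(unname(reinitProbabilities(scanningParams(1, 10, 10))),
               c(1, 0, 0))
  expect_equal(unname(reinitProbabilities(scanningParams(0, 10, 10))),
               c(0, 0, 1))
  # independent evaluation of the geometric tail masses
  q <- 0.01; d1 <- 100; d2 <- 200
  want <- c((1 - 0.99^100), 0.99^100 * (1 - 0.99^200), 0.99^300)
  got <- reinitProbabilities(scanningParams(q, d1, d2))
  expect_equal(unname(got), want, tolerance = 1e-12)
  expect_equal(round(unname(got), 4), c(0.6340, 0.3170, 0.0490))
  for (qq in seq(0, 1, length.out = 101)) {
    p <- reinitProbabilities(scanningParams(qq, 37, 91))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
})

test_that("CDS probability is unimodal in q: rises from 0 and returns to 0", {
  grid <- seq(0, 1, length.out = 101)
  pcds <- vapply(grid, function(q)
    reinitProbabilities(scanningParams(q, 87, 100))[["p_CDS"]], numeric(1))
  expect_equal(pcds[1], 0)
  expect_equal(pcds[101], 0)
  peak <- which.max(pcds)
  expect_true(all(diff(pcds[1:peak]) >= 0))
  expect_true(all(diff(pcds[peak:101]) <= 0))
})

test_that("the MLE matches a fine grid search and recovers boundaries", {
  set.seed(211)
  for (i in 1:50) {
    q <- runif(1, 0.001, 0.5)
    d1 <- sample(20:200, 1); d2 <- sample(20:200, 1)
    n <- sample(c(1e3, 1e4), 1)
    cnt <- as.vector(rmultinom(1, n,
      reinitProbabilities(scanningParams(q, d1, d2))))
    if (cnt[2] == 0 && cnt[3] == 0) next
    if (cnt[1] == 0 && cnt[2] == 0) next
    fit <- fitReacquisition(cnt, d1, d2)
    grid <- seq(1e-5, 1 - 1e-5, by = 1e-5)
    r <- 1 - grid
    p1 <- 1 - r^d1; p3 <- r^(d1 + d2); p2 <- 1 - p1 - p3
    ll <- suppressWarnings(cnt[1] * log(p1) + cnt[2] * log(p2) +
                             cnt[3] * log(p3))
    ll[!is.finite(ll)] <- -Inf
    expect_lt(abs(fit$q_hat - grid[which.max(ll)]), 2e-5)
    expect_true(fit$ci[1] <= fit$q_hat && fit$q_hat <= fit$ci[2])
  }
  expect_identical(fitReacquisition(c(100, 0, 0), 50, 50)[c("q_hat",
                                                            "boundary")],
                   list(q_hat = 1, boundary = TRUE))
  expect_identical(fitReacquisition(c(0, 0, 100), 50, 50)[c("q_hat",
                                                            "boundary")],
                   list(q_hat = 0, boundary = TRUE))
  expect_error(fitReacquisition(c(0, 0, 0), 50, 50), "zero")
})

test_that("profile-likelihood intervals cover the true q", {
  covered <- 0
  for (s in 1:100) {
    cnt <- simulateScanningCohort(scanningParams(0.01, 100, 200), 1e4,
                                  seed = 500 + s)
    fit <- fitReacquisition(cnt, 100, 200)
    if (fit$ci[1] <= 0.01 && 0.01 <= fit$ci[2]) covered <- covered + 1
  }
  expect_gte(covered, 90)
})
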