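# Pairwise likelihood engine: transmission model, phases, estimation.

test_that("two-locus gamete distribution equals brute-force enumeration", {
  for (ploidy in c(4L, 6L)) {
    for (dA in 1:(ploidy - 1)) for (dB in dA:(ploidy - 1)) {
      for (s in max(0, dA + dB - ploidy):min(dA, dB)) {
        for (r in c(0, 0.12)) {
          expect_equal(twoLocusGameteDistribution(ploidy, dA, dB, s, r),
                       oracleTwoLocus(ploidy, dA, dB, s, r),
                       tolerance = 1e-12,
                       info = sprintf("ploidy %d, %dx%d s=%d r=%g",
                                      ploidy, dA, dB, s, r))
        }
        # marginal conservation at several r
        for (r in c(0, 0.12, 0.37)) {
          G <- twoLocusGameteDistribution(ploidy, dA, dB, s, r)
          expect_equal(unname(rowSums(G)),
                       unname(gameteDosageDistribution(ploidy, dA)),
                       tolerance = 1e-12)
          expect_equal(unname(colSums(G)),
                       unname(gameteDosageDistribution(ploidy, dB)),
                       tolerance = 1e-12)
        }
        # r = 0.5 is the independence null, hence phase-free
        G5 <- twoLocusGameteDistribution(ploidy, dA, dB, s, 0.5)
        expect_equal(G5, outer(gameteDosageDistribution(ploidy, dA),
                               gameteDosageDistribution(ploidy, dB)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("simplex coupling and repulsion probabilities match closed forms", {
  for (r in c(0, 0.1, 0.25, 0.4)) {
    cpl <- twoLocusGameteDistribution(6, 1, 1, 1, r)
    expect_equal(cpl[2, 2], (1 - r) / 2, tolerance = 1e-12)
    rep_ <- twoLocusGameteDistribution(6, 1, 1, 0, r)
    expect_equal(rep_[2, 2], 1 / 5 + r / 10, tolerance = 1e-12)
  }
})

test_that("pair likelihood is maximal at the generating r and phase", {
  ploidy <- 6L
  for (cfg in list(c(1, 1, 1, 1, 0, 0), c(2, 1, 1, 0, 0, 0),
                   c(1, 2, 1, 1, 1, 1))) {
    rTrue <- 0.15
    P <- HexaMapQTL:::.offspringJoint(ploidy, cfg[1], cfg[2], cfg[3],
                                      cfg[4], cfg[5], cfg[6], rTrue)
    counts <- P * 4000                        # counts exactly at expectation
    grid <- seq(0, 0.5, by = 0.01)
    ll <- vapply(grid, function(r)
      pairLikelihood(counts, ploidy, cfg[1], cfg[2], cfg[3],
                     cfg[4], cfg[5], cfg[6], r), 0)
    expect_equal(grid[which.max(ll)], rTrue, tolerance = 1e-9)
  }
})

test_that("impossible observed cells give -Inf likelihood", {
  counts <- matrix(0, 7, 7)
  counts[3, 1] <- 5                      # dosage 2 impossible for 1x0 cross
  expect_identical(pairLikelihood(counts, 6, 1, 1, 1, 0, 0, 0, 0.1), -Inf)
})

test_that("at r = 0.5 all phases give identical likelihood", {
  set.seed(31)
  counts <- matrix(0, 7, 7)
  counts[1:3, 1:3] <- rpois(9, 40)   # feasible offspring cells of a 1x1 pair
  lls <- sapply(0:1, function(s1) sapply(0:1, function(s2)
    pairLikelihood(counts, 6, 1, 1, s1, 1, 1, s2, 0.5)))
  expect_lt(max(lls) - min(lls), 1e-9)
})

test_that("estimatePair recovers coupling pairs and is symmetric", {
  des <- twoMarkerDesign(haldaneInverse(0.1))
  sim <- simulateF1(des, nInd = 400L, seed = 21L)
  ab <- estimatePair(sim$dosage, "mA", "mB")
  ba <- estimatePair(sim$dosage, "mB", "mA")
  expect_equal(ab$r, ba$r, tolerance = 1e-9)
  expect_equal(ab$LOD, ba$LOD, tolerance = 1e-9)
  expect_identical(c(ab$phase1, ab$phase2), c(ba$phase1, ba$phase2))
  expect_lt(abs(ab$r - 0.1), 0.05)
  expect_identical(ab$phase1, 1L)       # coupling recovered
  expect_gt(ab$LOD, 10)
})

test_that("a marker paired with its duplicate gives r = 0 in full coupling", {
  d <- rbind(a = rep(c(0L, 1L), 50), b = rep(c(0L, 1L), 50))
  colnames(d) <- paste0("i", 1:100)
  dm <- DosageMatrix(d, p1 = c(1L, 1L), p2 = c(0L, 0L))
  est <- estimatePair(dm, "a", "b")
  expect_equal(est$r, 0, tolerance = 1e-6)
  expect_identical(est$phase1, 1L)
})

test_that("coupling 1x0 pair with no recombinants estimates r = 0", {
  des <- twoMarkerDesign(0.001)
  sim <- simulateF1(des, nInd = 400L, seed = 22L)
  est <- estimatePair(sim$dosage, "mA", "mB")
  expect_lt(est$r, 0.01)
})

test_that("unlinked markers pile near r = 0.5 with LOD near 0", {
  set.seed(23)
  lods <- numeric(30); rs <- numeric(30)
  for (k in seq_len(30)) {
    # independent simplex markers: dosage = independent fair coin per ind
    d <- rbind(a = rbinom(400, 1, 0.5), b = rbinom(400, 1, 0.5))
    storage.mode(d) <- "integer"
    colnames(d) <- paste0("i", 1:400)
    dm <- DosageMatrix(d, p1 = c(1L, 1L), p2 = c(0L, 0L))
    est <- estimatePair(dm, "a", "b")
    lods[k] <- est$LOD; rs[k] <- est$r
  }
  expect_lt(median(lods), 0.5)
  expect_gt(median(rs), 0.4)
})

test_that("repulsion estimates are far noisier than coupling (hexaploid weakness)", {
  nrep <- 30L
  rC <- rR <- numeric(nrep)
  for (k in seq_len(nrep)) {
    simC <- simulateF1(twoMarkerDesign(haldaneInverse(0.1), coupling = TRUE),
                       nInd = 400L, seed = 100L + k)
    simR <- simulateF1(twoMarkerDesign(haldaneInverse(0.1), coupling = FALSE),
                       nInd = 400L, seed = 200L + k)
    rC[k] <- estimatePair(simC$dosage, "mA", "mB")$r
    rR[k] <- estimatePair(simR$dosage, "mA", "mB")$r
  }
  expect_gt(var(rR) / var(rC), 2)
})

test_that("batched all-pairs estimation agrees with the single-pair path", {
  sim <- smallMapSim()
  dm <- sim$dosage
  mk <- rownames(dm)[c(1, 2, 3, 10, 25, 60)]
  lk <- pairwiseLinkage(dm, mk, rStep = 0.005)
  lk <- lk[lk$LOD >= 3, ]           # flat likelihoods make phase arbitrary
  set.seed(41)
  for (row in sample(nrow(lk), min(5, nrow(lk)))) {
    single <- estimatePair(dm, lk$marker1[row], lk$marker2[row])
    expect_lt(abs(single$r - lk$r[row]), 0.006)
    expect_lt(abs(single$LOD - lk$LOD[row]), 0.2)
    expect_identical(c(single$phase1, single$phase2),
                     c(lk$phase1[row], lk$phase2[row]))
  }
  expect_error(estimatePair(dm[, 1:10], rownames(dm)[1], rownames(dm)[2]),
               "jointly non-missing")
})
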