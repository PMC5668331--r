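# IBD probability reconstruction: informative calls, nearest-informative
# fill, normalization, spline gridding and GIC.

test_that("informative calls follow the dosage rules", {
  ph <- integer(12); ph[c(2, 8)] <- 1L           # 1x1 marker on h2 and h8
  out <- informativeCalls(ph, 1, 1, c(0L, 1L, 2L, NA))
  expect_equal(out[2, ], c(0, NA, 1, NA))
  expect_equal(out[8, ], c(0, NA, 1, NA))
  expect_true(all(is.na(out[-c(2, 8), ])))       # non-carriers: no call
  # 2x0 marker, dosage 0 pins both carriers to 0
  ph2 <- integer(12); ph2[c(1, 2)] <- 1L
  out2 <- informativeCalls(ph2, 2, 0, c(0L, 1L, 2L))
  expect_equal(out2[1, ], c(0, NA, 1))
  expect_equal(out2[2, ], c(0, NA, 1))
  # dosage above d1 + d2 is inconsistent and treated as missing
  out3 <- informativeCalls(ph, 1, 1, c(3L, 2L))
  expect_identical(attr(out3, "inconsistent"), 1L)
  expect_true(is.na(out3[2, 1]))
})

test_that("nearest-informative fill uses Haldane's function and averages ties", {
  # partially informative trace: h1 pinned to 1 at locus 1 only. The raw
  # fill gives 1 - r at locus 2, then normalization rescales towards the
  # per-parent sum of 3; order relations survive the rescale.
  calls <- array(NA_real_, c(2, 1, 12))
  calls[1, 1, 1] <- 1
  A <- interpolateIBD(calls, positions = c(0, 5), ploidy = 6)
  expect_gt(A[1, 1, 1], A[2, 1, 1])              # information decays with distance
  expect_gt(A[2, 1, 1], A[2, 1, 2])
  expect_equal(rowSums(A[, 1, 1:6]), c(3, 3))    # conservation
  expect_equal(rowSums(A[, 1, 7:12]), c(3, 3))

  # with all six homologues informative the sums are already 3, so calls
  # and Haldane fills are kept exactly
  calls2 <- array(NA_real_, c(2, 1, 12))
  calls2[1, 1, 1:6] <- c(1, 1, 1, 0, 0, 0)
  calls2[, 1, 7:12] <- rbind(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 0))
  A2 <- interpolateIBD(calls2, positions = c(0, 5), ploidy = 6)
  expect_equal(A2[1, 1, 1], 1, tolerance = 1e-9) # call at 0 cM kept exactly
  expect_equal(A2[2, 1, 1], 1 - haldane(5), tolerance = 1e-6)
  expect_equal(A2[2, 1, 4], haldane(5), tolerance = 1e-6)

  # equidistant conflicting informative markers average to 0.5: make every
  # parent-1 homologue a symmetric conflict so normalization is neutral
  calls3 <- array(NA_real_, c(3, 1, 12))
  calls3[1, 1, 1:6] <- c(1, 0, 1, 0, 1, 0)
  calls3[3, 1, 1:6] <- c(0, 1, 0, 1, 0, 1)
  calls3[1, 1, 7:12] <- c(1, 1, 1, 0, 0, 0)
  calls3[3, 1, 7:12] <- c(1, 1, 1, 0, 0, 0)
  A3 <- interpolateIBD(calls3, positions = c(0, 5, 10), ploidy = 6)
  expect_equal(A3[2, 1, 1], 0.5, tolerance = 1e-9)
})

test_that("gridding keeps constant traces and stays within [0, 1]", {
  calls <- array(NA_real_, c(5, 2, 12))
  calls[, , 1:3] <- 1; calls[, , 4:6] <- 0       # fully informative parent 1
  calls[, , 7:9] <- 1; calls[, , 10:12] <- 0
  pos <- c(0, 3, 7, 12, 20)
  ib <- new("IBDResult", arrays = list("1" = interpolateIBD(calls, pos, 6)),
            positions = list("1" = pos), gic = list(), ploidy = 6L)
  gr <- gridIBD(ib)
  expect_equal(gr@positions[["1"]], 0:20)
  expect_true(all(gr@arrays[["1"]][, , 1] == 1))
  expect_true(all(gr@arrays[["1"]][, , 4] == 0))
  expect_true(all(gr@arrays[["1"]] >= 0 & gr@arrays[["1"]] <= 1))
  # conservation after clamping and re-normalization
  s1 <- apply(gr@arrays[["1"]][, , 1:6], c(1, 2), sum)
  expect_true(all(abs(s1 - 3) < 1e-6))
})

test_that("GIC formula reproduces its closed-form examples", {
  mk <- function(p) {
    a <- array(p, c(1, length(p), 12))
    new("IBDResult", arrays = list("1" = a), positions = list("1" = 0),
        gic = list(), ploidy = 6L)
  }
  expect_equal(unname(gicProfile(mk(c(0, 1, 1, 0)))@gic[["1"]][1, 1]), 1)
  expect_equal(unname(gicProfile(mk(rep(0.5, 4)))@gic[["1"]][1, 1]), 0)
  expect_equal(unname(gicProfile(mk(c(0.75, 1)))@gic[["1"]][1, 1]), 0.75)
  # 0.5 rounds down to 0 (boundary convention)
  expect_equal(unname(gicProfile(mk(c(0.5, 0.5)))@gic[["1"]][1, 1]), 0)
})

test_that("reconstructed IBD matches simulated inheritance truth", {
  sim <- smallMapSim()
  bb <- buildBackbone(sim$dosage)
  clgRes <- identifyCLG(sim$dosage, bb)
  pm <- assignAndPhase(sim$dosage, bb, clgRes$clg)
  # use true positions: this isolates the IBD step from ordering noise
  mt <- sim$design$markerTable
  pm@map$position <- mt$pos[match(pm@map$marker, mt$marker)]
  ibd <- estimateIBD(sim$dosage, pm)
  # score predicted probabilities against truth for one CLG / parent 1,
  # mapping homologue slots back to true homologues via the clusters
  H <- do.call(rbind, lapply(sim$design$chromosomes, `[[`, "H"))
  truthHom <- clusterTruth(bb[bb$used, ], sim$design)
  clg <- clgRes$clg
  g <- clg$clg[1]
  chrom <- unique(mt$chrom[mt$marker %in%
                             bb$marker[bb$cluster %in%
                                         clg$cluster[clg$clg == g]]])[1]
  A <- ibd@arrays[[as.character(g)]]
  tm <- sim$truth[[chrom]]
  mk <- dimnames(A)[[1]]
  cl <- sort(clg$cluster[clg$clg == g & clg$parent == 1])
  acc <- NULL
  for (s in seq_along(cl)) {
    hTrue <- truthHom[cl[s]]
    pred <- A[, , s]
    truth <- tm[mk, , hTrue] * 1
    conf <- abs(pred - 0.5) > 0.3          # only confident predictions
    acc <- c(acc, mean((pred > 0.5)[conf] == (truth == 1)[conf]))
  }
  expect_gt(mean(acc), 0.95)
})
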