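# Backbone clustering, CLG identification and phasing on a simulated
# two-chromosome hexaploid population with known truth.

test_that("backbone clustering recovers one cluster per homologue", {
  sim <- smallMapSim()
  bb <- buildBackbone(sim$dosage)
  for (par in 1:2) {
    used <- bb[bb$parent == par & bb$used, ]
    expect_identical(length(unique(used$cluster)), 12L,   # 2 chrom x 6 hom
                     info = sprintf("parent %d", par))
  }
  # clusters are pure: members share one true homologue
  H <- do.call(rbind, lapply(sim$design$chromosomes, `[[`, "H"))
  chrom <- rep(seq_along(sim$design$chromosomes),
               vapply(sim$design$chromosomes, function(ch) length(ch$pos), 0L))
  names(chrom) <- rownames(H)
  for (cl in unique(bb$cluster[bb$used])) {
    mk <- bb$marker[bb$cluster == cl]
    key <- paste(chrom[mk], apply(H[mk, , drop = FALSE], 1, which.max))
    expect_identical(length(unique(key)), 1L, info = cl)
  }
})

test_that("empty input and missing homologues are handled", {
  expect_identical(nrow(clusterBackbone(
    data.frame(marker1 = character(0), marker2 = character(0),
               r = numeric(0), LOD = numeric(0), phase1 = integer(0),
               phase2 = integer(0)), character(0))), 0L)
  # removing all simplex markers of one P2 homologue loses that cluster
  sim <- smallMapSim()
  H <- do.call(rbind, lapply(sim$design$chromosomes, `[[`, "H"))
  types <- sim$design$markerTable$type
  names(types) <- sim$design$markerTable$marker
  drop <- rownames(H)[H[, 7] == 1 & types[rownames(H)] == "0x1" &
                        sim$design$markerTable$chrom == 1]
  dm <- sim$dosage[setdiff(rownames(sim$dosage), drop), ]
  bb <- buildBackbone(dm)
  expect_identical(length(unique(bb$cluster[bb$parent == 2 & bb$used])), 11L)
})

test_that("1x1 bridge markers identify the chromosomal linkage groups", {
  sim <- smallMapSim()
  bb <- buildBackbone(sim$dosage)
  clgRes <- identifyCLG(sim$dosage, bb)
  clg <- clgRes$clg
  expect_identical(length(unique(clg$clg)), 2L)
  for (g in unique(clg$clg)) {
    expect_identical(sum(clg$clg == g & clg$parent == 1), 6L)
    expect_identical(sum(clg$clg == g & clg$parent == 2), 6L)
  }
  # CLG must match the true chromosome partition of the clusters
  H <- do.call(rbind, lapply(sim$design$chromosomes, `[[`, "H"))
  chrom <- rep(seq_along(sim$design$chromosomes),
               vapply(sim$design$chromosomes, function(ch) length(ch$pos), 0L))
  names(chrom) <- rownames(H)
  for (g in unique(clg$clg)) {
    mk <- bb$marker[bb$cluster %in% clg$cluster[clg$clg == g]]
    expect_identical(length(unique(chrom[mk])), 1L)
  }
})

test_that("assignment and phasing recover the simulated truth", {
  sim <- smallMapSim()
  bb <- buildBackbone(sim$dosage)
  clgRes <- identifyCLG(sim$dosage, bb)
  pm <- assignAndPhase(sim$dosage, bb, clgRes$clg)
  m <- pm@map
  expect_gt(mean(m$assigned), 0.9)
  # backbone markers trivially phased to their own homologue
  bmk <- bb$marker[bb$used][1]
  expect_true(m$phased[m$marker == bmk])
  expect_identical(sum(unlist(m[m$marker == bmk, paste0("h", 1:12)])), 1L)

  # phasing accuracy vs truth, up to the cluster -> homologue relabelling
  H <- do.call(rbind, lapply(sim$design$chromosomes, `[[`, "H"))
  truthHom <- clusterTruth(bb[bb$used, ], sim$design)
  clg <- clgRes$clg
  slot <- integer(0)
  for (g in unique(clg$clg)) for (par in 1:2) {
    cl <- sort(clg$cluster[clg$clg == g & clg$parent == par])
    slot[cl] <- seq_along(cl) + (par - 1L) * 6L
  }
  phased <- m[m$phased, ]
  hcols <- paste0("h", 1:12)
  correct <- 0L
  for (i in seq_len(nrow(phased))) {
    g <- phased$CLG[i]
    cl <- clg$cluster[clg$clg == g]
    predHom <- truthHom[cl[match(which(unlist(phased[i, hcols]) == 1),
                                 slot[cl])]]
    trueHom <- which(H[phased$marker[i], ] == 1)
    if (setequal(predHom, trueHom)) correct <- correct + 1L
  }
  expect_gt(correct / nrow(phased), 0.98)

  # phased fraction is monotone non-increasing in the LOD threshold
  pmStrict <- assignAndPhase(sim$dosage, bb, clgRes$clg, lodThreshold = 12)
  expect_lte(sum(pmStrict@map$phased), sum(m$phased))
  expect_lte(sum(pmStrict@map$assigned), sum(m$assigned))
})
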