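## Simulation studies that validate the toolkit against the meiosis
## simulator's known truth: pairwise-estimate recovery, full-pipeline
## recovery, and QTL-scan calibration. These run the package end to end
## under chrysanthemum-like study conditions (hexaploid, F1 of 400).

#' Recombination-recovery study for coupling simplex pairs
#'
#' Simulates replicate F1 populations of two 1x0 markers in coupling at a
#' given true recombination fraction and re-estimates r and phase with
#' [estimatePair()].
#'
#' @param nRep Number of replicate populations (default 200).
#' @param nInd Individuals per population (default 400).
#' @param rTrue True recombination fraction (default 0.1).
#' @param seed Integer seed.
#' @return List with `rHat` (vector), `meanR`, `phaseRecovery` (fraction
#'   of replicates recovering the coupling phase), `lod` (vector).
#' @export
pairRecoveryStudy <- function(nRep = 200L, nInd = 400L, rTrue = 0.1,
                              seed = 1L) {
  set.seed(seed)
  dcm <- haldaneInverse(rTrue)
  rHat <- lod <- numeric(nRep)
  coupling <- logical(nRep)
  for (k in seq_len(nRep)) {
    des <- .twoSimplexDesign(dcm)
    sim <- simulateF1(des, nInd = nInd, seed = sample.int(2^31 - 1, 1L))
    est <- estimatePair(sim$dosage, "mA", "mB")
    rHat[k] <- est$r; lod[k] <- est$LOD
    coupling[k] <- est$phase1 == 1L
  }
  list(rHat = rHat, meanR = mean(rHat), phaseRecovery = mean(coupling),
       lod = lod)
}

## minimal design: two coupled 1x0 markers dcm apart on homologue 1
.twoSimplexDesign <- function(dcm, ploidy = 6L) {
  des <- designCross(ploidy = ploidy, nChrom = 1L,
                     chromLength = max(dcm, 1), simplexPerHomologue = 0L,
                     duplexPerChrom = 0L, simplexSimplexPerChrom = 0L)
  H <- matrix(0L, 2L, 2L * ploidy, dimnames = list(c("mA", "mB"), NULL))
  H[, 1L] <- 1L
  des$chromosomes[[1L]] <- list(pos = c(0, dcm), lengthCM = max(dcm, 1),
                                marker = c("mA", "mB"),
                                type = c("1x0", "1x0"),
                                contig = c(NA_character_, NA_character_),
                                H = H)
  des$markerTable <- data.frame(marker = c("mA", "mB"), chrom = 1L,
                                pos = c(0, dcm), type = "1x0",
                                contig = NA_character_,
                                stringsAsFactors = FALSE)
  des
}

## majority-vote true homologue of each backbone cluster
.clusterTruthHomologue <- function(backbone, design) {
  H <- do.call(rbind, lapply(design$chromosomes, `[[`, "H"))
  vapply(split(backbone$marker, backbone$cluster), function(mk) {
    hs <- apply(H[mk, , drop = FALSE], 1L, which.max)
    as.integer(names(sort(table(hs), decreasing = TRUE))[1L])
  }, 0L)
}

#' Full-pipeline recovery study on a simulated hexaploid population
#'
#' Simulates a bi-parental hexaploid F1 population over `nChrom`
#' chromosomes with abundant simplex markers plus duplex and 1x1 markers,
#' runs the complete mapping pipeline (filtering through gridded IBD) and
#' scores each stage against the simulator's truth.
#'
#' @param seed Integer seed.
#' @param nInd Individuals (default 400).
#' @param nChrom Chromosomes (default 2).
#' @param chromLength Chromosome length in cM (default 90).
#' @param simplexPerHomologue 1x0 (and 0x1) markers per homologue
#'   (default 60).
#' @param duplexPerChrom,simplexSimplexPerChrom,contigPairsPerChrom As in
#'   [designCross()].
#' @return List of metrics: `clustersPerParent`, `nCLG`, `kendallTau`
#'   (per CLG, vs true order), `mapLength` and `trueLength`,
#'   `phasingAccuracy`, `calibration` (`data.frame` bin, n, predicted,
#'   observed), `rConcordance` (median |r_pairwise - r_map| at LOD >= 20),
#'   `contigRMSE` (same/different homologue), `gicMidVsEnd`, and the
#'   pipeline `result`.
#' @export
pipelineRecoveryStudy <- function(seed = 1L, nInd = 400L, nChrom = 2L,
                                  chromLength = 90,
                                  simplexPerHomologue = 60L,
                                  duplexPerChrom = 60L,
                                  simplexSimplexPerChrom = 40L,
                                  contigPairsPerChrom = 15L) {
  set.seed(seed)
  des <- designCross(nChrom = nChrom, chromLength = chromLength,
                     simplexPerHomologue = simplexPerHomologue,
                     duplexPerChrom = duplexPerChrom,
                     simplexSimplexPerChrom = simplexSimplexPerChrom,
                     contigPairsPerChrom = contigPairsPerChrom)
  sim <- simulateF1(des, nInd = nInd, seed = seed)
  res <- suppressMessages(
    runPipeline(dosage = sim$dosage, config = runConfig(seed = seed)))

  bb <- res$backbone
  clg <- res$clg$clg
  clustersPerParent <- vapply(1:2, function(par)
    length(unique(bb$cluster[bb$parent == par & bb$used])), 0L)
  nCLG <- length(unique(clg$clg))

  mt <- des$markerTable
  truthPos <- setNames(mt$pos, mt$marker)
  truthChrom <- setNames(mt$chrom, mt$marker)

  # ordering concordance and length per CLG
  pm <- res$phasedMap@map
  kendallTau <- numeric(0); mapLength <- numeric(0)
  for (g in sort(unique(pm$CLG[!is.na(pm$CLG)]))) {
    mg <- pm[!is.na(pm$CLG) & pm$CLG == g & !is.na(pm$position), ]
    tau <- abs(stats::cor(mg$position, truthPos[mg$marker], method = "kendall"))
    kendallTau[as.character(g)] <- tau
    mapLength[as.character(g)] <- max(mg$position)
  }

  # phasing accuracy against truth (cluster -> homologue relabelling)
  H <- do.call(rbind, lapply(des$chromosomes, `[[`, "H"))
  truthHom <- .clusterTruthHomologue(bb[bb$used, ], des)
  slot <- integer(0)
  ploidy <- ploidy(sim$dosage)
  for (g in unique(clg$clg)) for (par in 1:2) {
    cl <- sort(clg$cluster[clg$clg == g & clg$parent == par])
    slot[cl] <- seq_along(cl) + (par - 1L) * ploidy
  }
  hcols <- paste0("h", seq_len(2L * ploidy))
  phased <- pm[pm$phased, ]
  Hm <- as.matrix(phased[, hcols])
  correct <- logical(nrow(phased))
  for (i in seq_len(nrow(phased))) {
    g <- phased$CLG[i]
    cl <- clg$cluster[clg$clg == g]
    predHom <- truthHom[cl[match(which(Hm[i, ] == 1), slot[cl])]]
    correct[i] <- setequal(predHom, which(H[phased$marker[i], ] == 1))
  }
  phasingAccuracy <- mean(correct)

  # IBD calibration on the cM grid, aligned to truth through marker positions
  calib <- list(); gicMid <- gicEnd <- numeric(0)
  ibdG <- res$ibdGrid
  for (g in names(ibdG@arrays)) {
    gi <- as.integer(g)
    mg <- pm[!is.na(pm$CLG) & pm$CLG == gi & !is.na(pm$position), ]
    chrom <- as.integer(names(sort(table(truthChrom[mg$marker]),
                                   decreasing = TRUE))[1L])
    fit <- approx(mg$position, truthPos[mg$marker],
                  xout = ibdG@positions[[g]], rule = 2L, ties = mean)
    tIdx <- pmin(pmax(round(fit$y) + 1L, 1L),
                 dim(sim$gridTruth[[chrom]])[1L])
    A <- ibdG@arrays[[g]]
    cl1 <- sort(clg$cluster[clg$clg == gi])
    for (s in which(!is.na(slot[cl1]))) {
      hTrue <- truthHom[cl1[s]]
      pred <- as.vector(A[, , slot[cl1[s]]])
      tr <- as.vector(sim$gridTruth[[chrom]][tIdx, , hTrue]) * 1
      calib[[paste(g, s)]] <- data.frame(pred = pred, truth = tr)
    }
    gic <- ibdG@gic[[g]]
    nloc <- nrow(gic)
    mid <- seq.int(floor(nloc * 0.4), ceiling(nloc * 0.6))
    ends <- c(seq_len(ceiling(nloc * 0.07)),
              seq.int(floor(nloc * 0.93), nloc))
    gicMid <- c(gicMid, mean(gic[mid, ]))
    gicEnd <- c(gicEnd, mean(gic[ends, ]))
  }
  cal <- do.call(rbind, calib)
  bins <- cut(cal$pred, breaks = seq(0, 1, by = 0.1), include.lowest = TRUE)
  calibration <- data.frame(
    bin = levels(bins),
    n = as.vector(table(bins)),
    predicted = tapply(cal$pred, bins, mean),
    observed = tapply(cal$truth, bins, mean))
  rownames(calibration) <- NULL

  # pairwise r vs map r concordance at high LOD within each CLG
  devs <- numeric(0)
  for (g in sort(unique(pm$CLG[!is.na(pm$CLG)]))) {
    mg <- pm[!is.na(pm$CLG) & pm$CLG == g & !is.na(pm$position), ]
    mk <- mg$marker
    lk <- pairwiseLinkage(res$filtered, mk, minLOD = 20)
    pos <- setNames(mg$position, mg$marker)
    dmap <- abs(pos[lk$marker1] - pos[lk$marker2])
    devs <- c(devs, abs(lk$r - haldane(dmap)))
  }

  ctg <- setNames(rowData(sim$dosage)$contig, rownames(sim$dosage))
  types <- setNames(segType(sim$dosage), rownames(sim$dosage))
  rmse <- sameContigRMSE(pm, ctg, types)

  list(clustersPerParent = clustersPerParent, nCLG = nCLG,
       kendallTau = kendallTau, mapLength = mapLength,
       trueLength = chromLength, phasingAccuracy = phasingAccuracy,
       calibration = calibration, rConcordance = median(devs),
       contigRMSE = rmse[rmse$CLG == "all", ],
       gicMidVsEnd = c(mid = mean(gicMid), end = mean(gicEnd)),
       result = res)
}

#' QTL-scan calibration and power study
#'
#' Uses exact (truth-based) IBD probabilities from the meiosis simulator.
#' Type-I error: `nNull` null traits are each tested against their own
#' permutation threshold (`nPermEach` permutations, 5th percentile of
#' minimum p-values); the genome-wide rejection rate should be close to
#' 5%. Power: for `nPower` fresh populations, a QTL explaining `h2qtl` of
#' the variance is planted on homologue 2 at `qtlPos` and the scan peak
#' position is compared with the truth.
#'
#' @param seed Integer seed.
#' @param nInd Individuals (default 400).
#' @param lengthCM Chromosome length (default 90).
#' @param nNull Null replicates (default 200).
#' @param nPermEach Permutations per null replicate (default 200).
#' @param nPower Power replicates (default 50).
#' @param h2qtl Variance fraction of the planted QTL (default 0.2).
#' @param qtlPos True QTL position in cM (default 45).
#' @return List with `typeIRate`, `powerWithin5cM`, `peakErrors`.
#' @export
qtlCalibrationStudy <- function(seed = 1L, nInd = 400L, lengthCM = 90,
                                nNull = 200L, nPermEach = 200L,
                                nPower = 50L, h2qtl = 0.2, qtlPos = 45) {
  set.seed(seed)
  base <- simulateInheritanceGrid(6, nInd, lengthCM,
                                  seed = sample.int(2^31 - 1, 1L))
  dimnames(base$ibd) <- list(NULL, sprintf("F1_%04d", seq_len(nInd)),
                             paste0("h", 1:12))
  ib <- new("IBDResult", arrays = list("1" = base$ibd),
            positions = list("1" = base$pos), gic = list(), ploidy = 6L)
  inds <- dimnames(base$ibd)[[2L]]

  reject <- logical(nNull)
  for (k in seq_len(nNull)) {
    y <- setNames(rnorm(nInd), inds)
    thr <- suppressWarnings(
      permutationThreshold(ib, y, nPerm = nPermEach,
                           seed = sample.int(2^31 - 1, 1L)))
    sc <- qtlScan(ib, y, threshold = thr)
    reject[k] <- any(sc@scan$significant, na.rm = TRUE)
  }

  peakErr <- numeric(nPower)
  beta <- sqrt(h2qtl / (1 - h2qtl) / 0.25)   # X is Bernoulli(1/2)
  for (k in seq_len(nPower)) {
    pop <- simulateInheritanceGrid(6, nInd, lengthCM,
                                   seed = sample.int(2^31 - 1, 1L))
    dimnames(pop$ibd) <- dimnames(base$ibd)
    ibk <- new("IBDResult", arrays = list("1" = pop$ibd),
               positions = list("1" = pop$pos), gic = list(), ploidy = 6L)
    X <- pop$ibd[which.min(abs(pop$pos - qtlPos)), , 2]
    y <- setNames(beta * X + rnorm(nInd), inds)
    sc <- qtlScan(ibk, y)
    peak <- sc@scan$position[which.max(sc@scan$neg_log10_p)]
    peakErr[k] <- abs(peak - qtlPos)
  }
  list(typeIRate = mean(reject), powerWithin5cM = mean(peakErr <= 5),
       peakErrors = peakErr)
}
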