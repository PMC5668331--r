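# Independent brute-force oracles, deliberately implemented by exhaustive
# enumeration (no reuse of the package's convolution/DP code paths).

# single-locus gamete distribution by enumerating all transmitted subsets
oracleGameteDist <- function(ploidy, d) {
  g <- ploidy / 2
  subsets <- combn(ploidy, g)
  counts <- numeric(g + 1)
  for (k in seq_len(ncol(subsets))) {
    dose <- sum(subsets[, k] <= d)          # homologues 1..d carry the allele
    counts[dose + 1] <- counts[dose + 1] + 1
  }
  setNames(counts / ncol(subsets), 0:g)
}

# two-locus gamete distribution by explicit enumeration over all pairings
# and all 4^(ploidy/2) per-bivalent transmission outcomes
oracleTwoLocus <- function(ploidy, dA, dB, shared, r) {
  g <- ploidy / 2
  labA <- labB <- integer(ploidy)
  labA[seq_len(dA)] <- 1L
  labB[seq_len(shared)] <- 1L
  if (dB > shared) labB[dA + seq_len(dB - shared)] <- 1L
  pairings <- enumerateBivalentPairings(ploidy)
  acc <- matrix(0, g + 1, g + 1)
  outcomes <- expand.grid(rep(list(1:4), g))   # per-bivalent transmission
  for (m in pairings) {
    for (o in seq_len(nrow(outcomes))) {
      p <- 1
      dosA <- 0L; dosB <- 0L
      for (b in seq_len(g)) {
        i <- m[b, 1]; j <- m[b, 2]
        oc <- outcomes[o, b]
        if (oc == 1) { dosA <- dosA + labA[i]; dosB <- dosB + labB[i]; p <- p * (1 - r) / 2 }
        if (oc == 2) { dosA <- dosA + labA[i]; dosB <- dosB + labB[j]; p <- p * r / 2 }
        if (oc == 3) { dosA <- dosA + labA[j]; dosB <- dosB + labB[j]; p <- p * (1 - r) / 2 }
        if (oc == 4) { dosA <- dosA + labA[j]; dosB <- dosB + labB[i]; p <- p * r / 2 }
      }
      acc[dosA + 1, dosB + 1] <- acc[dosA + 1, dosB + 1] + p
    }
  }
  acc / length(pairings)
}

# deterministic toy dosage matrix for container/filtering tests
tinyDosage <- function() {
  d <- rbind(
    m1 = c(0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L),       # 1x0
    m2 = c(0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L),       # duplicate of m1
    m3 = c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L),       # 1x0, other homologue
    m4 = c(3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L),       # 6x0 non-segregating
    m5 = c(1L, 2L, 0L, 1L, 1L, 2L, 0L, 1L)        # 1x1
  )
  colnames(d) <- paste0("i", 1:8)
  DosageMatrix(d, p1 = c(1L, 1L, 1L, 6L, 1L), p2 = c(0L, 0L, 0L, 0L, 1L),
               ploidy = 6L)
}

# design with exactly two 1x0 markers on homologue h at given positions
twoMarkerDesign <- function(dCM, hom = 1L, coupling = TRUE, ploidy = 6L) {
  des <- designCross(ploidy = ploidy, nChrom = 1L, chromLength = max(dCM, 1),
                     simplexPerHomologue = 0L, duplexPerChrom = 0L,
                     simplexSimplexPerChrom = 0L)
  nh <- 2L * ploidy
  hom2 <- if (coupling) hom else hom %% ploidy + 1L
  H <- matrix(0L, 2L, nh)
  H[1L, hom] <- 1L
  H[2L, hom2] <- 1L
  rownames(H) <- c("mA", "mB")
  des$chromosomes[[1L]] <- list(pos = c(0, dCM), lengthCM = max(dCM, 1),
                                marker = c("mA", "mB"),
                                type = c("1x0", "1x0"),
                                contig = c(NA_character_, NA_character_),
                                H = H)
  des$markerTable <- data.frame(marker = c("mA", "mB"), chrom = 1L,
                                pos = c(0, dCM), type = "1x0",
                                contig = NA_character_,
                                stringsAsFactors = FALSE)
  des
}

# small mappable population shared by map-construction tests (built once)
smallMapSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(2024)
      des <- designCross(nChrom = 2L, chromLength = 80,
                         simplexPerHomologue = 10L, duplexPerChrom = 10L,
                         simplexSimplexPerChrom = 24L)
      cache <<- simulateF1(des, nInd = 250L, seed = 11L)
    }
    cache
  }
})

# map a backbone cluster id to the true homologue of its member markers
clusterTruth <- function(backbone, design) {
  H <- do.call(rbind, lapply(design$chromosomes, `[[`, "H"))
  vapply(split(backbone$marker, backbone$cluster), function(mk) {
    hs <- apply(H[mk, , drop = FALSE], 1L, which.max)
    as.integer(names(sort(table(hs), decreasing = TRUE))[1L])
  }, 0L)
}
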