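## Ploidy-general simulator of random-bivalent-pairing meiosis. Serves as
## fixture generator with known truth (allele-to-homologue phase and
## per-individual inheritance vectors) and as a brute-force check on the
## analytic segregation and linkage models. Crossovers follow a Poisson
## process on genetic length (Haldane model: no interference), bivalent
## partners are drawn uniformly from all perfect matchings, and double
## reduction is absent (no multivalents).

#' Enumerate bivalent pairing scenarios
#'
#' All perfect matchings of the `ploidy` homologues into bivalents. A
#' hexaploid has 15 such pairings, a tetraploid 3, a diploid 1
#' (double factorial `(ploidy - 1)!!`).
#'
#' @param ploidy Even integer ploidy.
#' @return List of matchings; each matching is a 2-column integer matrix
#'   with one row per bivalent.
#' @examples
#' length(enumerateBivalentPairings(6))  # 15
#' @export
enumerateBivalentPairings <- function(ploidy) {
  ploidy <- .checkPloidy(ploidy)
  rec <- function(items) {
    if (length(items) == 0L) return(list(matrix(integer(0), 0L, 2L)))
    first <- items[1L]
    rest <- items[-1L]
    out <- list()
    for (k in seq_along(rest)) {
      sub <- rec(rest[-k])
      pair <- c(first, rest[k])
      out <- c(out, lapply(sub, function(m) rbind(pair, m)))
    }
    out
  }
  lapply(rec(seq_len(ploidy)), function(m) {
    dimnames(m) <- NULL
    m
  })
}

## One transmitted product of one bivalent (i, j): start homologue chosen
## uniformly, alternate partners at Poisson(length/100) crossover points.
## Returns the founder homologue present at each query position.
.bivalentProduct <- function(i, j, lengthCM, at) {
  start <- if (runif(1L) < 0.5) c(i, j) else c(j, i)
  nco <- rpois(1L, lengthCM / 100)
  if (nco == 0L) return(rep(start[1L], length(at)))
  pts <- sort(runif(nco, 0, lengthCM))
  parity <- findInterval(at, pts) %% 2L
  ifelse(parity == 0L, start[1L], start[2L])
}

#' Simulate one gamete of a polysomic parent
#'
#' Draws a bivalent pairing uniformly from
#' [enumerateBivalentPairings()], transmits one recombinant product per
#' bivalent (crossovers as a Poisson process on genetic length, Haldane
#' model), and reports the founder homologue present at each query
#' position for each of the `ploidy/2` transmitted chromosomes.
#'
#' @param ploidy Even integer ploidy.
#' @param lengthCM Chromosome length in centiMorgan.
#' @param at Numeric vector of query positions (cM).
#' @param pairings Optional pre-enumerated pairing list (for speed).
#' @return Integer matrix `(ploidy/2) x length(at)`: founder homologue
#'   indices (1..ploidy) carried by the gamete at each position.
#' @export
simulateGamete <- function(ploidy, lengthCM, at,
                           pairings = enumerateBivalentPairings(ploidy)) {
  m <- pairings[[sample.int(length(pairings), 1L)]]
  out <- matrix(0L, nrow(m), length(at))
  for (b in seq_len(nrow(m)))
    out[b, ] <- .bivalentProduct(m[b, 1L], m[b, 2L], lengthCM, at)
  out
}

## ---------------------------------------------------------------------------
## Cross designs: marker layout + parental phases with known truth.

#' Design a simulated bi-parental cross
#'
#' Lays out markers on `nChrom` chromosomes and assigns their alleles to
#' parental homologues, producing the ground-truth phase against which
#' mapping results can be scored. Defaults reflect a chrysanthemum-like
#' hexaploid F1 study: ploidy 6, 9 chromosomes of ~84 cM and an abundance
#' of simplex (1x0 / 0x1) markers complemented by duplex and
#' simplex-x-simplex markers.
#'
#' @param ploidy Even integer ploidy.
#' @param nChrom Number of chromosomes.
#' @param chromLength Length (cM) of each chromosome (recycled).
#' @param simplexPerHomologue Number of 1x0 markers per parent-1 homologue
#'   (and 0x1 per parent-2 homologue).
#' @param duplexPerChrom Number of duplex markers per chromosome, split
#'   evenly between 2x0 and 0x2.
#' @param simplexSimplexPerChrom Number of 1x1 markers per chromosome.
#' @param contigPairsPerChrom Number of co-located 1x0 marker pairs per
#'   chromosome sharing a transcript-contig label (for map diagnostics).
#' @return A `crossDesign` list: `ploidy`, `chromosomes` (each with `pos`,
#'   `lengthCM`, `marker`, `type`, and the truth phase matrix `H`
#'   (loci x 2*ploidy 0/1)), and a flat `markerTable`.
#' @seealso [simulateF1()]
#' @export
designCross <- function(ploidy = 6L, nChrom = 9L, chromLength = 84,
                        simplexPerHomologue = 60L, duplexPerChrom = 60L,
                        simplexSimplexPerChrom = 40L,
                        contigPairsPerChrom = 0L) {
  ploidy <- .checkPloidy(ploidy)
  chromLength <- rep_len(chromLength, nChrom)
  nh <- 2L * ploidy
  chroms <- vector("list", nChrom)
  for (cc in seq_len(nChrom)) {
    len <- chromLength[cc]
    pos <- numeric(0); type <- character(0); contig <- character(0)
    H <- matrix(0L, 0L, nh)
    addMarker <- function(p, ty, homs, ctg = NA_character_) {
      pos <<- c(pos, p); type <<- c(type, ty); contig <<- c(contig, ctg)
      h <- integer(nh); h[homs] <- 1L
      H <<- rbind(H, h)
    }
    for (par in 1:2) {
      off <- if (par == 1L) 0L else ploidy
      ty <- if (par == 1L) "1x0" else "0x1"
      for (h in seq_len(ploidy))
        for (k in seq_len(simplexPerHomologue))
          addMarker(runif(1, 0, len), ty, off + h)
    }
    for (par in 1:2) {
      off <- if (par == 1L) 0L else ploidy
      ty <- if (par == 1L) "2x0" else "0x2"
      for (k in seq_len(duplexPerChrom %/% 2L))
        addMarker(runif(1, 0, len), ty, off + sample.int(ploidy, 2L))
    }
    for (k in seq_len(simplexSimplexPerChrom))
      addMarker(runif(1, 0, len), "1x1",
                c(sample.int(ploidy, 1L), ploidy + sample.int(ploidy, 1L)))
    if (contigPairsPerChrom > 0L) {
      for (k in seq_len(contigPairsPerChrom)) {
        # a small within-contig offset keeps same-homologue twins from
        # being exact duplicates in a noise-free simulation
        p <- runif(1, 0, len - 0.5)
        h1 <- sample.int(ploidy, 1L)
        h2 <- if (runif(1) < 0.5) h1 else sample(setdiff(seq_len(ploidy), h1), 1L)
        ctg <- sprintf("ctg%02d_%03d", cc, k)
        addMarker(p, "1x0", h1, ctg)
        addMarker(p + 0.5, "1x0", h2, ctg)
      }
    }
    ord <- order(pos)
    pos <- pos[ord]; type <- type[ord]; contig <- contig[ord]
    H <- H[ord, , drop = FALSE]
    marker <- sprintf("c%02d_%05d_%s", cc, seq_along(pos), type[])
    rownames(H) <- marker
    chroms[[cc]] <- list(pos = pos, lengthCM = len, marker = marker,
                         type = type, contig = contig, H = H)
  }
  markerTable <- do.call(rbind, lapply(seq_len(nChrom), function(cc) {
    ch <- chroms[[cc]]
    if (!length(ch$marker)) return(NULL)
    data.frame(marker = ch$marker, chrom = cc, pos = ch$pos,
               type = ch$type, contig = ch$contig,
               stringsAsFactors = FALSE)
  }))
  structure(list(ploidy = ploidy, chromosomes = chroms,
                 markerTable = markerTable),
            class = "crossDesign")
}

#' Simulate an F1 population with known inheritance truth
#'
#' Simulates `nInd` F1 individuals from a [designCross()] design: each
#' individual is the union of one gamete from each parent, simulated by
#' [simulateGamete()]. Returns the dosage matrix together with the full
#' inheritance truth (which founder homologues each individual carries at
#' every marker locus and on a regular cM grid), enabling truth-based
#' scoring of clustering, phasing, ordering, IBD and QTL steps.
#'
#' @param design A `crossDesign`.
#' @param nInd Number of F1 individuals (default 400).
#' @param seed Integer seed; the simulation is reproducible given the seed.
#' @param missingRate Per-call probability of a missing dosage.
#' @param errorRate Per-call probability that the dosage is replaced by a
#'   random draw from the marker's offspring distribution.
#' @param gridStep Spacing (cM) of the truth grid (default 1).
#' @return List with `dosage` (a [DosageMatrix-class]), `truth` (per
#'   chromosome, logical array loci x individuals x 2*ploidy), `gridTruth`
#'   (same on the cM grid) and `gridPos`, plus the `design` and `seed`.
#' @export
simulateF1 <- function(design, nInd = 400L, seed = NULL,
                       missingRate = 0, errorRate = 0, gridStep = 1) {
  if (!inherits(design, "crossDesign")) stop("design must come from designCross()")
  if (!is.null(seed)) set.seed(seed)
  ploidy <- design$ploidy
  g <- ploidy %/% 2L
  pairings <- enumerateBivalentPairings(ploidy)
  nChrom <- length(design$chromosomes)

  truth <- vector("list", nChrom)
  gridTruth <- vector("list", nChrom)
  gridPos <- vector("list", nChrom)
  dosageBlocks <- vector("list", nChrom)

  for (cc in seq_len(nChrom)) {
    ch <- design$chromosomes[[cc]]
    nm <- length(ch$pos)
    gp <- seq(0, ceiling(ch$lengthCM), by = gridStep)
    at <- c(ch$pos, gp)
    Tm <- array(FALSE, c(nm, nInd, 2L * ploidy))
    Tg <- array(FALSE, c(length(gp), nInd, 2L * ploidy))
    D <- matrix(0L, nm, nInd)
    alleleP1 <- ch$H[, seq_len(ploidy), drop = FALSE]
    alleleP2 <- ch$H[, ploidy + seq_len(ploidy), drop = FALSE]
    ng <- length(gp)
    im <- seq_len(nm); ig <- seq_len(ng)
    nh <- 2L * ploidy
    for (ind in seq_len(nInd)) {
      for (par in 1:2) {
        gm <- simulateGamete(ploidy, ch$lengthCM, at, pairings)
        alleles <- if (par == 1L) alleleP1 else alleleP2
        off <- if (par == 1L) 0L else ploidy
        for (b in seq_len(g)) {
          hm <- gm[b, im]; hg <- gm[b, nm + ig]
          D[, ind] <- D[, ind] + alleles[im + (hm - 1L) * nm]
          Tm[im + (ind - 1L) * nm + (off + hm - 1L) * (nm * nInd)] <- TRUE
          Tg[ig + (ind - 1L) * ng + (off + hg - 1L) * (ng * nInd)] <- TRUE
        }
      }
    }
    rownames(D) <- ch$marker
    dimnames(Tm) <- list(ch$marker, NULL, paste0("h", seq_len(2L * ploidy)))
    dosageBlocks[[cc]] <- D
    truth[[cc]] <- Tm
    gridTruth[[cc]] <- Tg
    gridPos[[cc]] <- gp
  }

  D <- do.call(rbind, dosageBlocks)
  colnames(D) <- sprintf("F1_%04d", seq_len(nInd))
  mt <- design$markerTable
  pd <- .typeToDosages(mt$type)
  if (errorRate > 0) {
    err <- which(matrix(runif(length(D)) < errorRate, nrow(D)))
    for (i in err) {
      r <- (i - 1L) %% nrow(D) + 1L
      pr <- offspringDosageDistribution(ploidy, pd[r, 1L], pd[r, 2L])
      D[i] <- sample(0:ploidy, 1L, prob = pr)
    }
  }
  if (missingRate > 0)
    D[matrix(runif(length(D)) < missingRate, nrow(D))] <- NA_integer_

  dm <- DosageMatrix(D, p1 = pd[, 1L], p2 = pd[, 2L], ploidy = ploidy,
                     contig = mt$contig)
  list(dosage = dm, truth = truth, gridTruth = gridTruth, gridPos = gridPos,
       design = design, seed = seed)
}

.typeToDosages <- function(type) {
  parts <- strsplit(type, "x", fixed = TRUE)
  cbind(P1 = as.integer(vapply(parts, `[`, "", 1L)),
        P2 = as.integer(vapply(parts, `[`, "", 2L)))
}

#' Simulate inheritance truth on a cM grid only
#'
#' Lightweight variant of [simulateF1()] for power/calibration studies
#' that need exact identity-by-descent indicators but no markers: per
#' individual, the founder homologues carried along one chromosome.
#'
#' @param ploidy Even integer ploidy.
#' @param nInd Number of individuals.
#' @param lengthCM Chromosome length (cM).
#' @param gridStep Grid spacing (cM).
#' @param seed Optional integer seed.
#' @return List with `ibd` (array loci x individuals x 2*ploidy, 0/1) and
#'   `pos` (grid positions).
#' @export
simulateInheritanceGrid <- function(ploidy = 6L, nInd = 400L, lengthCM = 90,
                                    gridStep = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ploidy <- .checkPloidy(ploidy)
  g <- ploidy %/% 2L
  pairings <- enumerateBivalentPairings(ploidy)
  gp <- seq(0, ceiling(lengthCM), by = gridStep)
  ng <- length(gp); ig <- seq_len(ng)
  A <- array(0, c(ng, nInd, 2L * ploidy))
  for (ind in seq_len(nInd)) {
    for (par in 1:2) {
      gm <- simulateGamete(ploidy, lengthCM, gp, pairings)
      off <- if (par == 1L) 0L else ploidy
      for (b in seq_len(g))
        A[ig + (ind - 1L) * ng + (off + gm[b, ] - 1L) * (ng * nInd)] <- 1
    }
  }
  list(ibd = A, pos = gp)
}
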