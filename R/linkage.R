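## Generic maximum-likelihood engine for pairwise linkage under completely
## random bivalent pairing. Instead of a catalogue of closed-form likelihood
## functions per segregation-type/phase combination, the joint two-locus
## transmission distribution is built numerically from the pairing model for
## any dosage pair and phase class, at any even ploidy.
##
## Phase classes: within one parent, the phase of a marker pair is fully
## characterized (up to homologue relabelling) by the number of homologues
## carrying BOTH marker alleles ("shared count" s). s ranges over
## max(0, dA + dB - ploidy) .. min(dA, dB); s > 0 is coupling.

.phaseRange <- function(ploidy, dA, dB) {
  seq.int(max(0L, dA + dB - ploidy), min(dA, dB))
}

## memoization: bivalent pairings per ploidy and gamete distributions per
## (ploidy, dA, dB, shared, r) are identical across calls and cached.
.linkCache <- new.env(parent = emptyenv())
.cachedPairings <- function(ploidy) {
  key <- paste0("pair", ploidy)
  if (is.null(.linkCache[[key]]))
    .linkCache[[key]] <- enumerateBivalentPairings(ploidy)
  .linkCache[[key]]
}

#' Joint two-locus gamete distribution of one parent
#'
#' Distribution of the dosages transmitted at two linked loci A and B by a
#' parent with dosages `dA`, `dB`, phase class `shared` (number of
#' homologues carrying both alleles) and recombination fraction `r`,
#' under uniformly random bivalent pairing. Within each bivalent the
#' transmitted product carries homologue i at both loci with probability
#' `(1-r)/2` and homologue i at A with its partner j at B with
#' probability `r/2`.
#'
#' Both marginals equal [gameteDosageDistribution()] for every phase and
#' `r` (conservation), and at `r = 0.5` the two loci are independent.
#'
#' @param ploidy Even integer ploidy.
#' @param dA,dB Parental dosages at the two loci.
#' @param shared Phase class: homologues carrying both alleles.
#' @param r Recombination fraction in `[0, 0.5]`.
#' @return Numeric matrix `(ploidy/2 + 1) x (ploidy/2 + 1)`; entry
#'   `[a+1, b+1]` is the probability the gamete carries `a` copies at A
#'   and `b` at B.
#' @export
twoLocusGameteDistribution <- function(ploidy, dA, dB, shared, r) {
  ploidy <- .checkPloidy(ploidy)
  if (r < 0 || r > 0.5) stop("r must be in [0, 0.5]")
  if (!shared %in% .phaseRange(ploidy, dA, dB))
    stop("shared count out of range for these dosages")
  key <- sprintf("g%d_%d_%d_%d_%.10g", ploidy, dA, dB, shared, r)
  hit <- .linkCache[[key]]
  if (!is.null(hit)) return(hit)
  g <- ploidy %/% 2L
  if (r == 0.5) {
    # null convention: r = 0.5 means unlinked, i.e. independent loci.
    # (For loci far apart on one chromosome the bivalent constraint keeps
    # a small dependence between dosages when both exceed 1; the LOD null
    # must be true independence, which also makes it phase-free.)
    out <- outer(gameteDosageDistribution(ploidy, dA),
                 gameteDosageDistribution(ploidy, dB))
    .linkCache[[key]] <- out
    return(out)
  }
  labA <- labB <- integer(ploidy)
  labA[seq_len(dA)] <- 1L                          # homologues 1..dA carry A
  labB[seq_len(shared)] <- 1L                      # 1..s carry both
  if (dB > shared) labB[dA + seq_len(dB - shared)] <- 1L
  pairings <- .cachedPairings(ploidy)
  acc <- matrix(0, g + 1L, g + 1L)
  for (m in pairings) {
    J <- matrix(0, g + 1L, g + 1L); J[1L, 1L] <- 1
    for (b in seq_len(nrow(m))) {
      i <- m[b, 1L]; j <- m[b, 2L]
      # contribution (carry at A, carry at B) of this bivalent's product
      ca <- c(labA[i], labA[i], labA[j], labA[j])
      cb <- c(labB[i], labB[j], labB[j], labB[i])
      pw <- c((1 - r) / 2, r / 2, (1 - r) / 2, r / 2)
      Jn <- matrix(0, g + 1L, g + 1L)
      for (k in 1:4) {
        p <- pw[k]
        if (p == 0) next
        da <- ca[k]; db <- cb[k]
        src <- J[seq_len(g + 1L - da), seq_len(g + 1L - db), drop = FALSE]
        Jn[da + seq_len(nrow(src)), db + seq_len(ncol(src))] <-
          Jn[da + seq_len(nrow(src)), db + seq_len(ncol(src))] + p * src
      }
      J <- Jn
    }
    acc <- acc + J
  }
  out <- acc / length(pairings)
  .linkCache[[key]] <- out
  out
}

## Offspring joint distribution over (dosage at A, dosage at B): 2-D
## convolution of the two parental gamete distributions.
.offspringJoint <- function(ploidy, dA1, dB1, s1, dA2, dB2, s2, r) {
  key <- sprintf("o%d_%d_%d_%d_%d_%d_%d_%.10g", ploidy, dA1, dB1, s1,
                 dA2, dB2, s2, r)
  hit <- .linkCache[[key]]
  if (!is.null(hit)) return(hit)
  G1 <- twoLocusGameteDistribution(ploidy, dA1, dB1, s1, r)
  G2 <- twoLocusGameteDistribution(ploidy, dA2, dB2, s2, r)
  g <- ploidy %/% 2L
  P <- matrix(0, ploidy + 1L, ploidy + 1L)
  for (a1 in 0:g) for (b1 in 0:g) {
    p1 <- G1[a1 + 1L, b1 + 1L]
    if (p1 == 0) next
    P[a1 + (0:g) + 1L, b1 + (0:g) + 1L] <-
      P[a1 + (0:g) + 1L, b1 + (0:g) + 1L] + p1 * G2
  }
  dimnames(P) <- list(0:ploidy, 0:ploidy)
  .linkCache[[key]] <- P
  P
}

#' Multinomial log-likelihood of joint dosage counts for a phase and r
#'
#' @param counts Matrix `(ploidy+1) x (ploidy+1)` of observed joint
#'   progeny dosage counts (marker A in rows, B in columns), from progeny
#'   with both dosages non-missing.
#' @param ploidy Even integer ploidy.
#' @param dA1,dB1 Parent-1 dosages of markers A and B; `s1` its phase
#'   class (shared-homologue count).
#' @param dA2,dB2,s2 Same for parent 2.
#' @param r Recombination fraction.
#' @return Log-likelihood; `-Inf` when an observed cell has probability
#'   zero (impossible phase or data error).
#' @export
pairLikelihood <- function(counts, ploidy, dA1, dB1, s1, dA2, dB2, s2, r) {
  P <- .offspringJoint(ploidy, dA1, dB1, s1, dA2, dB2, s2, r)
  use <- counts > 0
  if (any(P[use] == 0)) return(-Inf)
  sum(counts[use] * log(P[use]))
}

## log-probabilities for the support cells, floored so that matrix products
## with zero counts stay finite while any observed impossible cell sinks
## the phase.
.logFloor <- -1e12
.logP <- function(p) {
  lp <- log(p)
  lp[p <= 0] <- .logFloor
  lp
}

#' All-pairs recombination, LOD and phase estimation
#'
#' Batched maximum-likelihood estimation of recombination fraction, LOD
#' and phase class for marker pairs, maximizing the multinomial
#' log-likelihood of the joint progeny dosage counts over all phase-class
#' combinations and an r grid. The LOD is
#' `log10 L(r_hat, best phase) - log10 L(0.5)`; at `r = 0.5` all phases
#' coincide. Pairs are handled with pairwise-complete observations.
#'
#' @param x A [DosageMatrix-class].
#' @param markers1 Character vector of marker ids (rows of `x`).
#' @param markers2 Optional second set; `NULL` (default) estimates all
#'   pairs within `markers1`.
#' @param rStep Grid step for r in `[0, 0.5]` (default 0.005).
#' @param minShared Minimum jointly non-missing progeny per pair
#'   (default 20); pairs below it are dropped.
#' @param minLOD Only pairs with LOD >= `minLOD` are returned (default 0,
#'   keep all).
#' @param chunkSize Internal block size for memory control.
#' @return `data.frame` with columns `marker1`, `marker2`, `r`, `LOD`,
#'   `phase1`, `phase2` (shared-homologue counts per parent), `loglik`,
#'   `n`.
#' @seealso [estimatePair()] for a single pair with r refinement.
#' @export
pairwiseLinkage <- function(x, markers1, markers2 = NULL, rStep = 0.005,
                            minShared = 20L, minLOD = 0, chunkSize = 40000L) {
  ploidy <- ploidy(x)
  D <- t(dosages(x))                       # individuals x markers
  pd <- parentalDosages(x)
  rownames(pd) <- rownames(x)
  rGrid <- seq(0, 0.5, by = rStep)
  if (rGrid[length(rGrid)] < 0.5) rGrid <- c(rGrid, 0.5)
  i05 <- length(rGrid)
  within <- is.null(markers2)
  if (within) markers2 <- markers1

  t1 <- paste0(pd[markers1, 1L], "x", pd[markers1, 2L])
  t2 <- paste0(pd[markers2, 1L], "x", pd[markers2, 2L])
  res <- list()

  typePairs <- unique(rbind(
    do.call(rbind, lapply(unique(t1), function(a)
      cbind(a, unique(t2))))))
  if (within) {
    keepTP <- typePairs[, 1L] <= typePairs[, 2L]
    typePairs <- typePairs[keepTP, , drop = FALSE]
  }

  for (tp in seq_len(nrow(typePairs))) {
    tyA <- typePairs[tp, 1L]; tyB <- typePairs[tp, 2L]
    mA <- markers1[t1 == tyA]
    mB <- markers2[t2 == tyB]
    if (!length(mA) || !length(mB)) next
    dA <- .typeToDosages(tyA)[1L, ]; dB <- .typeToDosages(tyB)[1L, ]
    cellsA <- which(offspringDosageDistribution(ploidy, dA[1L], dA[2L]) > 0) - 1L
    cellsB <- which(offspringDosageDistribution(ploidy, dB[1L], dB[2L]) > 0) - 1L

    # joint counts for every pair: crossprod of dosage-indicator matrices
    IA <- lapply(cellsA, function(a) {
      M <- D[, mA, drop = FALSE] == a; M[is.na(M)] <- FALSE; M * 1
    })
    IB <- lapply(cellsB, function(b) {
      M <- D[, mB, drop = FALSE] == b; M[is.na(M)] <- FALSE; M * 1
    })
    nc <- length(cellsA) * length(cellsB)
    pA <- length(mA); pB <- length(mB)
    C <- matrix(0, pA * pB, nc)
    k <- 0L
    for (b in seq_along(cellsB)) for (a in seq_along(cellsA)) {
      k <- k + 1L
      C[, k] <- as.vector(crossprod(IA[[a]], IB[[b]]))
    }

    # pair bookkeeping (upper triangle when within one set of same type)
    pairIdx <- if (within && tyA == tyB) {
      ut <- which(upper.tri(matrix(0, pA, pB)))
      cbind((ut - 1L) %% pA + 1L, (ut - 1L) %/% pA + 1L)
    } else {
      as.matrix(expand.grid(seq_len(pA), seq_len(pB)))
    }
    rows <- (pairIdx[, 2L] - 1L) * pA + pairIdx[, 1L]
    C <- C[rows, , drop = FALSE]
    nPer <- rowSums(C)
    okN <- nPer >= minShared
    if (!any(okN)) next
    C <- C[okN, , drop = FALSE]
    pairIdx <- pairIdx[okN, , drop = FALSE]
    nPer <- nPer[okN]

    phases <- expand.grid(s1 = .phaseRange(ploidy, dA[1L], dB[1L]),
                          s2 = .phaseRange(ploidy, dA[2L], dB[2L]))
    # log-prob tables [cells x grid] per phase
    logTabs <- lapply(seq_len(nrow(phases)), function(ph) {
      sapply(rGrid, function(r) {
        P <- .offspringJoint(ploidy, dA[1L], dB[1L], phases$s1[ph],
                             dA[2L], dB[2L], phases$s2[ph], r)
        .logP(as.vector(P[cellsA + 1L, cellsB + 1L]))
      })
    })

    np <- nrow(C)
    bestLL <- rep(-Inf, np); bestR <- rep(NA_real_, np)
    bestP1 <- integer(np); bestP2 <- integer(np); ll05 <- rep(NA_real_, np)
    rSub <- seq_len(i05 - 1L)              # r < 0.5 for the estimate
    for (start in seq(1L, np, by = chunkSize)) {
      sel <- start:min(np, start + chunkSize - 1L)
      for (ph in seq_len(nrow(phases))) {
        M <- C[sel, , drop = FALSE] %*% logTabs[[ph]]
        if (ph == 1L) ll05[sel] <- M[, i05]
        mx <- max.col(M[, rSub, drop = FALSE], ties.method = "first")
        v <- M[cbind(seq_along(sel), mx)]
        upd <- v > bestLL[sel] + 1e-9
        tie <- abs(v - bestLL[sel]) <= 1e-9 &
          (phases$s1[ph] + phases$s2[ph] > bestP1[sel] + bestP2[sel])
        take <- upd | tie
        if (any(take)) {
          tsel <- sel[take]
          bestLL[tsel] <- v[take]
          bestR[tsel] <- rGrid[rSub][mx[take]]
          bestP1[tsel] <- phases$s1[ph]
          bestP2[tsel] <- phases$s2[ph]
        }
      }
    }
    lod <- pmax(0, (bestLL - ll05) / log(10))
    keep <- lod >= minLOD
    if (!any(keep)) next
    res[[length(res) + 1L]] <- data.frame(
      marker1 = mA[pairIdx[keep, 1L]],
      marker2 = mB[pairIdx[keep, 2L]],
      r = bestR[keep], LOD = lod[keep],
      phase1 = bestP1[keep], phase2 = bestP2[keep],
      loglik = bestLL[keep], n = nPer[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(marker1 = character(0), marker2 = character(0),
                      r = numeric(0), LOD = numeric(0),
                      phase1 = integer(0), phase2 = integer(0),
                      loglik = numeric(0), n = integer(0)))
  out <- do.call(rbind, res)
  out <- out[out$marker1 != out$marker2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate recombination, LOD and phase for one marker pair
#'
#' Maximizes the multinomial log-likelihood over phase classes and r,
#' evaluating r on a grid (step `rStep`) and refining the best grid point
#' by golden-section search ([stats::optimize()]); deterministic given the
#' inputs, and symmetric in the two markers.
#'
#' @param x A [DosageMatrix-class].
#' @param markerA,markerB Marker ids.
#' @param rStep Grid step (default 0.005).
#' @param minShared Minimum jointly non-missing progeny (default 20).
#' @return List with `r`, `LOD`, `phase1`, `phase2`, `loglik`, `n`.
#' @export
estimatePair <- function(x, markerA, markerB, rStep = 0.005, minShared = 20L) {
  ploidy <- ploidy(x)
  d <- dosages(x)[c(markerA, markerB), , drop = FALSE]
  pd <- parentalDosages(x)[match(c(markerA, markerB), rownames(x)), ,
                           drop = FALSE]
  both <- !is.na(d[1L, ]) & !is.na(d[2L, ])
  n <- sum(both)
  if (n < minShared)
    stop(sprintf("only %d jointly non-missing progeny (need >= %d): linkage undefined",
                 n, minShared))
  counts <- matrix(0, ploidy + 1L, ploidy + 1L)
  tab <- table(factor(d[1L, both], levels = 0:ploidy),
               factor(d[2L, both], levels = 0:ploidy))
  counts[] <- as.numeric(tab)
  phases <- expand.grid(s1 = .phaseRange(ploidy, pd[1L, 1L], pd[2L, 1L]),
                        s2 = .phaseRange(ploidy, pd[1L, 2L], pd[2L, 2L]))
  rGrid <- seq(0, 0.5 - rStep, by = rStep)
  best <- list(ll = -Inf, r = NA_real_, s1 = 0L, s2 = 0L)
  for (ph in seq_len(nrow(phases))) {
    s1 <- phases$s1[ph]; s2 <- phases$s2[ph]
    f <- function(r) pairLikelihood(counts, ploidy, pd[1L, 1L], pd[2L, 1L],
                                    s1, pd[1L, 2L], pd[2L, 2L], s2, r)
    ll <- vapply(rGrid, f, 0)
    i <- which.max(ll)
    lo <- max(0, rGrid[i] - rStep); hi <- min(0.5 - 1e-6, rGrid[i] + rStep)
    opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-6)
    cand <- if (opt$objective >= ll[i]) {
      list(r = opt$maximum, ll = opt$objective)
    } else list(r = rGrid[i], ll = ll[i])
    if (cand$ll > best$ll + 1e-9 ||
        (abs(cand$ll - best$ll) <= 1e-9 && s1 + s2 > best$s1 + best$s2)) {
      best <- list(ll = cand$ll, r = cand$r, s1 = s1, s2 = s2)
    }
  }
  ll05 <- pairLikelihood(counts, ploidy, pd[1L, 1L], pd[2L, 1L],
                         phases$s1[1L], pd[1L, 2L], pd[2L, 2L],
                         phases$s2[1L], 0.5)
  list(r = best$r, LOD = max(0, (best$ll - ll05) / log(10)),
       phase1 = best$s1, phase2 = best$s2, loglik = best$ll, n = n)
}
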