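## Identity-by-descent (IBD) probability reconstruction along the
## integrated map. Only fully informative dosage scores seed the array
## (progeny dosage 0, or equal to the summed parental dosage, pins every
## carrier homologue to 0 or 1); remaining entries are filled from the
## nearest informative marker on the same homologue via Haldane's mapping
## function (P = 1 - r if the informative call is 1, P = r if it is 0),
## normalized so each parent's homologues sum to ploidy/2, splined onto a
## 1 cM grid, and summarized as genotype information content (GIC).

#' Fully informative IBD calls of one marker
#'
#' A progeny dosage of 0 means none of the marker's carrier homologues
#' was inherited (probability 0 for each); a dosage equal to the summed
#' parental dosage means all of them were (probability 1). Intermediate
#' dosages are non-informative: for a 1x1 marker, progeny dosages 0 and 2
#' are informative, dosage 1 is not. Non-carrier homologues receive no
#' call from the marker.
#'
#' @param phase 0/1 vector over the `2 * ploidy` homologues (1 = this
#'   marker has an allele on that homologue).
#' @param d1,d2 Parental dosages.
#' @param progeny Integer vector of progeny dosages (`NA` = missing).
#' @return Numeric matrix homologues x individuals: 0 or 1 where the
#'   marker is informative for a carrier homologue, `NA` elsewhere.
#'   Dosages exceeding `d1 + d2` are flagged via attribute
#'   `"inconsistent"` (individual indices) and treated as missing.
#' @export
informativeCalls <- function(phase, d1, d2, progeny) {
  total <- d1 + d2
  out <- matrix(NA_real_, length(phase), length(progeny))
  carriers <- which(phase == 1L)
  bad <- which(!is.na(progeny) & progeny > total)
  if (length(bad)) progeny[bad] <- NA_integer_
  out[carriers, which(!is.na(progeny) & progeny == 0L)] <- 0
  out[carriers, which(!is.na(progeny) & progeny == total)] <- 1
  attr(out, "inconsistent") <- bad
  out
}

## nearest-informative fill for one homologue/individual trace:
## implied probability 1 - r (call 1) or r (call 0). Flanking informative
## markers that are equidistant within `tieTol` cM (the map's effective
## resolution) count as tied and their implied probabilities are averaged;
## strictly one-sided choice there would be overconfident whenever map
## positions carry small errors.
.fillTrace <- function(queryPos, infPos, infVal, tieTol = 1) {
  if (!length(infPos)) return(rep(0.5, length(queryPos)))
  j <- findInterval(queryPos, infPos)
  dl <- ifelse(j >= 1L, queryPos - infPos[pmax(j, 1L)], Inf)
  dr <- ifelse(j < length(infPos), infPos[pmin(j + 1L, length(infPos))] -
                 queryPos, Inf)
  pl <- ifelse(j >= 1L & infVal[pmax(j, 1L)] == 1,
               1 - haldane(pmax(dl, 0)), haldane(pmax(dl, 0)))
  pr <- ifelse(j < length(infPos) &
                 infVal[pmin(j + 1L, length(infPos))] == 1,
               1 - haldane(pmax(dr, 0)), haldane(pmax(dr, 0)))
  tie <- is.finite(dl) & is.finite(dr) & abs(dl - dr) <= tieTol
  out <- ifelse(tie, (pl + pr) / 2, ifelse(dl < dr, pl, pr))
  out[is.infinite(dl) & is.infinite(dr)] <- 0.5
  out
}

## Per-parent normalization to ploidy/2 by a common additive shift on the
## log-odds scale (vectorized bisection per locus/individual cell).
## Unlike multiplicative scaling, this keeps fully informative values
## pinned at 0/1 and spreads the residual probability mass over the
## uncertain homologues only — e.g. two homologues pinned at 1 plus four
## at the 0.5 prior yield 0.25 each, the actual carrier rate.
.normalizeParent <- function(M, target) {
  # M: (locus*individual) x homologues-of-one-parent matrix
  eps <- 1e-9
  L <- log(pmin(pmax(M, eps), 1 - eps) /
             (1 - pmin(pmax(M, eps), 1 - eps)))
  lo <- rep(-40, nrow(M)); hi <- rep(40, nrow(M))
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    s <- rowSums(1 / (1 + exp(-(L + mid))))
    up <- s < target
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  out <- 1 / (1 + exp(-(L + (lo + hi) / 2)))
  # snap values that were exactly pinned back to 0/1
  out[M <= eps & out < 2 * eps] <- 0
  out[M >= 1 - eps & out > 1 - 2 * eps] <- 1
  out
}

#' Fill an IBD call array by nearest-informative interpolation
#'
#' @param calls Numeric array loci x individuals x homologues with
#'   informative calls (0/1) and `NA` elsewhere, e.g. stacked
#'   [informativeCalls()] output.
#' @param positions Locus positions (cM), nondecreasing, matching dim 1.
#' @param ploidy Even integer ploidy.
#' @return Numeric array of the same shape with every entry in `[0, 1]`
#'   and each parent's homologues summing to `ploidy/2` per locus and
#'   individual.
#' @export
interpolateIBD <- function(calls, positions, ploidy = 6L) {
  ploidy <- .checkPloidy(ploidy)
  dm <- dim(calls)
  nh <- dm[3L]
  if (nh != 2L * ploidy) stop("homologue dimension must be 2 * ploidy")
  A <- array(0.5, dm, dimnames = dimnames(calls))
  for (h in seq_len(nh)) {
    Ch <- calls[, , h, drop = FALSE]
    dim(Ch) <- dm[1:2]
    hasInfo <- which(colSums(!is.na(Ch)) > 0L)
    for (ind in hasInfo) {
      inf <- which(!is.na(Ch[, ind]))
      A[, ind, h] <- .fillTrace(positions, positions[inf], Ch[inf, ind])
    }
  }
  .renormalizeArray(A, ploidy)
}

.renormalizeArray <- function(A, ploidy) {
  dm <- dim(A)
  for (par in 1:2) {
    slots <- (par - 1L) * ploidy + seq_len(ploidy)
    M <- A[, , slots]
    dim(M) <- c(dm[1L] * dm[2L], ploidy)
    M <- .normalizeParent(M, ploidy / 2)
    dim(M) <- c(dm[1L], dm[2L], ploidy)
    A[, , slots] <- M
  }
  A
}

#' Estimate IBD probabilities from a phased, ordered map
#'
#' Runs [informativeCalls()] for every phased mapped marker, fills each
#' homologue/individual trace from the nearest informative marker
#' ([interpolateIBD()]), and normalizes. Homologues without any marker
#' are recovered through normalization from the other homologues of the
#' same parent.
#'
#' @param x A [DosageMatrix-class].
#' @param phasedMap A [PhasedMap-class] with positions filled.
#' @return An [IBDResult-class] at marker loci.
#' @export
estimateIBD <- function(x, phasedMap) {
  ploidy <- ploidy(x)
  nh <- 2L * ploidy
  m <- phasedMap@map
  m <- m[m$phased & !is.na(m$position) & !is.na(m$CLG), , drop = FALSE]
  hcols <- paste0("h", seq_len(nh))
  d <- dosages(x)
  pd <- parentalDosages(x)
  arrays <- list(); positions <- list()
  for (g in sort(unique(m$CLG))) {
    mg <- m[m$CLG == g, , drop = FALSE]
    mg <- mg[order(mg$position), , drop = FALSE]
    idx <- match(mg$marker, rownames(x))
    calls <- array(NA_real_, c(nrow(mg), ncol(d), nh),
                   dimnames = list(mg$marker, colnames(d), hcols))
    for (i in seq_len(nrow(mg))) {
      calls[i, , ] <- t(informativeCalls(as.integer(unlist(mg[i, hcols])),
                                         pd[idx[i], 1L], pd[idx[i], 2L],
                                         d[idx[i], ]))
    }
    arrays[[as.character(g)]] <- interpolateIBD(calls, mg$position, ploidy)
    positions[[as.character(g)]] <- mg$position
  }
  new("IBDResult", arrays = arrays, positions = positions, gic = list(),
      ploidy = as.integer(ploidy))
}

#' Interpolate IBD probabilities onto a regular cM grid
#'
#' Fits a natural cubic spline per homologue and individual over IBD
#' probability versus position and evaluates it at `gridStep` intervals
#' from 0 to the rounded-up map length; traces with fewer than 4 loci
#' fall back to linear interpolation. Values are clamped to `[0, 1]` and
#' re-normalized per parent.
#'
#' @param ibd An [IBDResult-class] at marker loci.
#' @param gridStep Grid spacing in cM (default 1).
#' @return An [IBDResult-class] on the grid.
#' @export
gridIBD <- function(ibd, gridStep = 1) {
  ploidy <- ibd@ploidy
  arrays <- list(); positions <- list()
  for (g in names(ibd@arrays)) {
    A <- ibd@arrays[[g]]
    pos <- ibd@positions[[g]]
    gp <- seq(0, ceiling(max(pos)), by = gridStep)
    dm <- dim(A)
    G <- array(0.5, c(length(gp), dm[2L], dm[3L]),
               dimnames = list(NULL, dimnames(A)[[2L]], dimnames(A)[[3L]]))
    dup <- !duplicated(pos)
    for (h in seq_len(dm[3L])) {
      for (ind in seq_len(dm[2L])) {
        y <- A[dup, ind, h]
        p <- pos[dup]
        G[, ind, h] <- if (length(p) >= 4L) {
          splinefun(p, y, method = "natural")(gp)
        } else if (length(p) >= 2L) {
          approx(p, y, xout = gp, rule = 2L)$y
        } else rep(y[1L], length(gp))
      }
    }
    G[G < 0] <- 0; G[G > 1] <- 1
    arrays[[g]] <- .renormalizeArray(G, ploidy)
    positions[[g]] <- gp
  }
  new("IBDResult", arrays = arrays, positions = positions, gic = list(),
      ploidy = ploidy)
}

#' Genotype information content
#'
#' `GIC_hk = 1 - (2/n) * sum_i |P_i - round(P_i)|` per homologue `h` and
#' locus `k` over the `n` individuals, where probabilities up to and
#' including 0.5 round to 0 and above 0.5 to 1. GIC is 1 at a fully
#' informative locus (all probabilities 0 or 1) and 0 when all
#' probabilities equal 0.5.
#'
#' @param ibd An [IBDResult-class] (typically gridded).
#' @return The input with its `gic` slot filled: per CLG a matrix
#'   loci x homologues in `[0, 1]`.
#' @export
gicProfile <- function(ibd) {
  gic <- list()
  for (g in names(ibd@arrays)) {
    A <- ibd@arrays[[g]]
    R <- ifelse(A > 0.5, 1, 0)
    gic[[g]] <- apply(1 - 2 * abs(A - R), c(1L, 3L), mean)
  }
  ibd@gic <- gic
  ibd
}
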