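## Integrated-map ordering: pairwise recombination fractions are converted
## to distances with Haldane's mapping function and embedded in two
## dimensions by weighted multidimensional scaling (stress majorization,
## LOD^2 weights), a principal curve is fitted through the embedding by
## iterated local averaging, and marker positions are arc lengths along the
## curve. Problematic markers are removed iteratively on a
## nearest-neighbour fit criterion.

#' Haldane mapping function and its inverse
#'
#' `haldane()` converts map distance (cM) to recombination fraction,
#' `r = (1 - exp(-2 d)) / 2` with `d` in Morgan; `haldaneInverse()`
#' converts back, `d = -50 ln(1 - 2 r)` cM. A distance of 5 cM corresponds
#' to r = 0.047.
#'
#' @param distanceCM Nonnegative distance(s) in centiMorgan.
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Numeric vector.
#' @examples
#' round(haldane(5), 3)        # 0.047
#' haldaneInverse(haldane(25)) # 25
#' @export
haldane <- function(distanceCM) {
  if (any(distanceCM < 0)) stop("distance must be >= 0")
  (1 - exp(-2 * distanceCM / 100)) / 2
}

#' @rdname haldane
#' @export
haldaneInverse <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must be in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

## distance/weight matrices from a pairwise linkage table
.distanceInput <- function(linkage, markers, rCap = 0.49) {
  n <- length(markers)
  D <- matrix(NA_real_, n, n, dimnames = list(markers, markers))
  W <- matrix(0, n, n, dimnames = list(markers, markers))
  i <- match(linkage$marker1, markers)
  j <- match(linkage$marker2, markers)
  ok <- !is.na(i) & !is.na(j)
  i <- i[ok]; j <- j[ok]
  d <- haldaneInverse(pmin(linkage$r[ok], rCap))
  w <- linkage$LOD[ok]^2
  D[cbind(i, j)] <- D[cbind(j, i)] <- d
  W[cbind(i, j)] <- W[cbind(j, i)] <- w
  diag(D) <- 0
  list(D = D, W = W)
}

## weighted SMACOF with deterministic classical-scaling start
.wmds <- function(D, W, ndim = 2L, nIter = 100L, tol = 1e-6) {
  n <- nrow(D)
  D0 <- D
  D0[is.na(D0)] <- mean(D0, na.rm = TRUE)
  X <- cmdscale(as.dist(D0), k = ndim)
  if (ncol(X) < ndim) X <- cbind(X, matrix(0, n, ndim - ncol(X)))
  W2 <- W
  W2[is.na(D)] <- 0
  V <- -W2
  diag(V) <- rowSums(W2)
  Vinv <- solve(V + 1 / n) - 1 / n
  Dt <- D
  Dt[is.na(Dt)] <- 0
  stress <- Inf
  for (it in seq_len(nIter)) {
    E <- as.matrix(dist(X))
    Bm <- -W2 * Dt / pmax(E, 1e-9)
    diag(Bm) <- 0
    diag(Bm) <- -rowSums(Bm)
    X <- Vinv %*% (Bm %*% X)
    newStress <- sum(W2 * (Dt - E)^2) / 2
    if (is.finite(stress) && abs(stress - newStress) < tol * stress) break
    stress <- newStress
  }
  list(X = X, stress = stress)
}

## Guttman-transform iterations in one dimension, warm-started from the
## principal-curve arc lengths
.wmds1d <- function(lambda, D, W, nIter = 50L, tol = 1e-7) {
  n <- length(lambda)
  W2 <- W
  W2[is.na(D)] <- 0
  Dt <- D
  Dt[is.na(Dt)] <- 0
  V <- -W2
  diag(V) <- rowSums(W2)
  Vinv <- solve(V + 1 / n) - 1 / n
  X <- matrix(lambda - mean(lambda))
  stress <- Inf
  for (it in seq_len(nIter)) {
    E <- abs(outer(X[, 1L], X[, 1L], "-"))
    Bm <- -W2 * Dt / pmax(E, 1e-9)
    diag(Bm) <- 0
    diag(Bm) <- -rowSums(Bm)
    X <- Vinv %*% (Bm %*% X)
    newStress <- sum(W2 * (Dt - E)^2) / 2
    if (is.finite(stress) && abs(stress - newStress) < tol * stress) break
    stress <- newStress
  }
  X[, 1L]
}

## Positions given a fixed marker order: weighted least-squares estimate of
## the adjacent gaps g_k, minimizing sum_ij w_ij (d_ij - sum_{k in (i,j)} g_k)^2
## over pairs within `window` cM of map distance. The normal equations have
## M[k, l] = sum of w over pairs spanning both gaps, computed with 2-D
## cumulative sums; small negative gaps are clipped to zero.
.gapPositions <- function(ord, D, W, window = 20) {
  n <- length(ord)
  Do <- D[ord, ord]
  Wo <- W[ord, ord]
  Wo[is.na(Do)] <- 0
  Do[is.na(Do)] <- 0
  Wo[Do > window] <- 0
  Wo[lower.tri(Wo, diag = TRUE)] <- 0       # pairs i < j in map order
  WD <- Wo * Do
  # F[a, b] = sum_{i <= a, j >= b} w_ij ; same for G on w * d
  revCum <- function(M) {
    M <- apply(M, 2L, cumsum)               # over i <= a
    t(apply(t(M)[n:1, , drop = FALSE], 2L, cumsum))[, n:1, drop = FALSE]
  }
  Fw <- revCum(Wo)
  Gw <- revCum(WD)
  k <- seq_len(n - 1L)
  M <- matrix(0, n - 1L, n - 1L)
  for (a in k) M[a, a:(n - 1L)] <- Fw[a, (a:(n - 1L)) + 1L]
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  b <- Gw[cbind(k, k + 1L)]
  diag(M) <- diag(M) + 1e-6 * mean(diag(M))
  g <- tryCatch(solve(M, b), error = function(e) rep(mean(b) / n, n - 1L))
  # the unconstrained solution can oscillate slightly around co-located
  # clusters; project onto monotone positions (cumulative max) rather than
  # clipping gaps, which would inflate the map length
  p <- cummax(c(0, cumsum(g)))
  pos <- numeric(n)
  pos[ord] <- p
  pos
}

## principal curve by iterated local averaging: parameterize by the first
## principal component, smooth each coordinate against the parameter
## (lowess, fixed span), project points onto the smoothed polyline, use
## arc length as the new parameter.
.principalCurve <- function(X, span = 0.25, nIter = 10L) {
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  lambda <- pc$x[, 1L]
  for (it in seq_len(nIter)) {
    ord <- order(lambda)
    lam <- lambda[ord]
    curve <- sapply(seq_len(ncol(X)), function(k)
      lowess(lam, X[ord, k], f = span)$y)
    newLam <- .projectOnPolyline(X, curve)
    if (all(order(newLam) == ord)) { lambda <- newLam; break }
    lambda <- newLam
  }
  lambda
}

## orthogonal projection of points on the polyline through `curve` rows;
## returns arc length at the projection foot.
.projectOnPolyline <- function(X, curve) {
  nseg <- nrow(curve) - 1L
  segStart <- curve[-nrow(curve), , drop = FALSE]
  segVec <- curve[-1L, , drop = FALSE] - segStart
  segLen2 <- rowSums(segVec^2)
  segLen <- sqrt(segLen2)
  cumLen <- c(0, cumsum(segLen))
  out <- numeric(nrow(X))
  for (p in seq_len(nrow(X))) {
    dx <- sweep(segStart, 2L, X[p, ], "-")
    tt <- pmin(1, pmax(0, -rowSums(dx * segVec) / pmax(segLen2, 1e-12)))
    foot <- segStart + segVec * tt
    d2 <- rowSums((foot - matrix(X[p, ], nseg, ncol(X), byrow = TRUE))^2)
    s <- which.min(d2)
    out[p] <- cumLen[s] + tt[s] * segLen[s]
  }
  out
}

#' Order the markers of one chromosomal linkage group
#'
#' Weighted multidimensional scaling (stress majorization, LOD^2 weights)
#' of Haldane-transformed recombination fractions into two dimensions,
#' principal-curve fit, and projection: marker positions are arc lengths
#' along the curve, rescaled so that local pairwise distances are
#' reproduced in weighted least squares. Deterministic: initialization is
#' classical scaling, and orientation puts the alphabetically first
#' marker in the left map half with the leftmost marker at 0 cM.
#'
#' @param linkage Pairwise linkage `data.frame` ([pairwiseLinkage()]) for
#'   the CLG's markers.
#' @param markers Character vector of marker ids to order.
#' @param rCap Recombination fractions are capped here before the Haldane
#'   transform (default 0.49).
#' @param span Lowess span of the principal-curve smoother (default 0.25).
#' @param ndim Embedding dimension (default 2).
#' @return List with `map` (`data.frame` marker, position — input order
#'   preserved), `order` (permutation), `stress`, and `X` (embedding).
#' @export
orderCLG <- function(linkage, markers, rCap = 0.49, span = 0.25, ndim = 2L) {
  di <- .distanceInput(linkage, markers, rCap)
  conn <- igraph::graph_from_adjacency_matrix(di$W > 0, mode = "undirected")
  if (igraph::components(conn)$no > 1L)
    stop("pairwise linkage within this group is disconnected; re-cluster before ordering")
  if (length(markers) == 2L) {
    pos <- c(0, di$D[1L, 2L])
    return(list(map = data.frame(marker = markers, position = pos,
                                 stringsAsFactors = FALSE),
                order = 1:2, stress = 0, X = NULL))
  }
  emb <- .wmds(di$D, di$W, ndim = ndim)
  lambda <- if (length(markers) < 8L) {
    prcomp(emb$X)$x[, 1L]        # too few points to smooth a curve
  } else .principalCurve(emb$X, span = span)
  # 1-D weighted stress polish: refines local order and gap sizes around
  # the curve solution
  lambda <- .wmds1d(lambda, di$D, di$W)
  # deterministic orientation: alphabetically first marker in left half
  ref <- which.min(rank(markers, ties.method = "first"))
  if (lambda[ref] > (max(lambda) + min(lambda)) / 2) lambda <- -lambda
  # the embedding fixes the order; positions come from weighted
  # least-squares gap estimation on the pairwise distances
  pos <- .gapPositions(order(lambda), di$D, di$W)
  list(map = data.frame(marker = markers, position = pos,
                        stringsAsFactors = FALSE),
       order = order(pos), stress = emb$stress, X = emb$X)
}

#' Nearest-neighbour fit of an ordered map
#'
#' Per-marker discrepancy between map distance and pairwise
#' (Haldane-transformed) distance over its `k` nearest map neighbours,
#' summarized as the LOD^2-weighted mean absolute difference (cM); a
#' perfectly additive map scores 0 everywhere. The total fit is the sum
#' over markers.
#'
#' @param positions Named numeric vector of map positions (cM).
#' @param linkage Pairwise linkage `data.frame` for these markers.
#' @param k Number of nearest neighbours (default 10).
#' @param rCap As in [orderCLG()].
#' @return List with `fits` (`data.frame` marker, fit) and `total`.
#' @export
nnFit <- function(positions, linkage, k = 10L, rCap = 0.49) {
  markers <- names(positions)
  di <- .distanceInput(linkage, markers, rCap)
  n <- length(positions)
  fit <- numeric(n)
  for (i in seq_len(n)) {
    dm <- abs(positions - positions[i])
    nb <- order(dm)[-1L]
    # k nearest map neighbours that carry linkage information
    nb <- nb[di$W[i, nb] > 0 & !is.na(di$D[i, nb])]
    nb <- nb[seq_len(min(k, length(nb)))]
    w <- di$W[i, nb]
    dp <- di$D[i, nb]
    fit[i] <- if (length(nb))
      sum(w * abs(dm[nb] - dp)) / sum(w) else 0
  }
  list(fits = data.frame(marker = markers, fit = fit,
                         stringsAsFactors = FALSE),
       total = sum(fit))
}

#' Iterative ordering with removal of problematic markers
#'
#' Orders a group ([orderCLG()]), computes the nearest-neighbour fit,
#' removes markers whose fit exceeds `fitThreshold`, re-orders, and
#' repeats while the total fit keeps decreasing. Removed markers are
#' logged with their removal round.
#'
#' @inheritParams orderCLG
#' @param fitThreshold Per-marker fit above which a marker counts as
#'   problematic (default 4 cM).
#' @param k Neighbourhood size for [nnFit()].
#' @param maxRounds Safety bound on re-ordering rounds.
#' @return List with `map` (`data.frame` marker, position, nnfit),
#'   `removed` (`data.frame` marker, round), `rounds`, `totalFit`.
#' @export
iterateOrdering <- function(linkage, markers, fitThreshold = 4, k = 10L,
                            rCap = 0.49, span = 0.25, maxRounds = 10L) {
  removed <- data.frame(marker = character(0), round = integer(0),
                        stringsAsFactors = FALSE)
  current <- markers
  best <- NULL
  lastTotal <- Inf
  round <- 0L
  repeat {
    round <- round + 1L
    om <- orderCLG(linkage, current, rCap = rCap, span = span)
    pos <- setNames(om$map$position, om$map$marker)
    nf <- nnFit(pos, linkage, k = k, rCap = rCap)
    result <- list(map = data.frame(om$map, nnfit = nf$fits$fit),
                   removed = removed, rounds = round, totalFit = nf$total)
    if (nf$total >= lastTotal && round > 1L) {
      # no improvement: keep the previous round's map
      best$rounds <- round - 1L
      return(best)
    }
    best <- result
    lastTotal <- nf$total
    bad <- nf$fits$marker[nf$fits$fit > fitThreshold]
    if (!length(bad) || round >= maxRounds ||
        length(current) - length(bad) < 3L)
      return(best)
    removed <- rbind(removed,
                     data.frame(marker = bad, round = round,
                                stringsAsFactors = FALSE))
    current <- setdiff(current, bad)
  }
}

#' Same-contig marker distance diagnostic (RMSE)
#'
#' Markers derived from the same transcript contig should map to (nearly)
#' the same position. For all pairs of mapped simplex (1x0 / 0x1) markers
#' sharing a contig, computes the RMSE of their position differences per
#' CLG, split into pairs phased to the same homologue versus different
#' homologues — the latter measures the quality of homologue integration.
#'
#' @param map `data.frame` with columns `marker`, `CLG`, `position` and
#'   homologue indicator columns `h1`, `h2`, ... (as in a
#'   [PhasedMap-class] after ordering).
#' @param contigs Named character vector: contig id per marker (NA = no
#'   contig annotation).
#' @param types Named character vector of segregation types per marker;
#'   only `"1x0"` and `"0x1"` markers enter the diagnostic.
#' @return `data.frame` per CLG (plus row `all`): `n_same`, `rmse_same`,
#'   `n_diff`, `rmse_diff`. Empty (0-row) if there are no same-contig
#'   pairs.
#' @export
sameContigRMSE <- function(map, contigs, types) {
  hcols <- grep("^h[0-9]+$", colnames(map), value = TRUE)
  simplex <- map$marker[types[map$marker] %in% c("1x0", "0x1") &
                          !is.na(map$position)]
  ctg <- contigs[simplex]
  simplex <- simplex[!is.na(ctg)]
  ctg <- ctg[!is.na(ctg)]
  pairs <- list()
  for (ct in unique(ctg[duplicated(ctg)])) {
    mk <- simplex[ctg == ct]
    if (length(mk) < 2L) next
    cmb <- combn(mk, 2L)
    pairs[[ct]] <- data.frame(m1 = cmb[1L, ], m2 = cmb[2L, ],
                              stringsAsFactors = FALSE)
  }
  if (!length(pairs))
    return(data.frame(CLG = character(0), n_same = integer(0),
                      rmse_same = numeric(0), n_diff = integer(0),
                      rmse_diff = numeric(0)))
  pp <- do.call(rbind, pairs)
  i1 <- match(pp$m1, map$marker); i2 <- match(pp$m2, map$marker)
  sameCLG <- map$CLG[i1] == map$CLG[i2]
  pp <- pp[sameCLG & !is.na(sameCLG), ]; i1 <- i1[sameCLG]; i2 <- i2[sameCLG]
  dd <- abs(map$position[i1] - map$position[i2])
  H <- as.matrix(map[, hcols])
  sameHom <- rowSums(H[i1, , drop = FALSE] * H[i2, , drop = FALSE]) > 0
  clg <- map$CLG[i1]
  rmse <- function(v) if (length(v)) sqrt(mean(v^2)) else NA_real_
  groups <- c(sort(unique(clg)), "all")
  out <- do.call(rbind, lapply(groups, function(g) {
    sel <- if (g == "all") rep(TRUE, length(dd)) else clg == g
    data.frame(CLG = as.character(g),
               n_same = sum(sel & sameHom),
               rmse_same = rmse(dd[sel & sameHom]),
               n_diff = sum(sel & !sameHom),
               rmse_diff = rmse(dd[sel & !sameHom]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
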