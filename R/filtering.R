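## Marker and individual quality control for the F1 dosage matrix.

#' Chi-square test of segregation against polysomic expectation
#'
#' Tests observed progeny dosage counts of one marker against the expected
#' offspring distribution under polysomic inheritance
#' ([offspringDosageDistribution()]). Degrees of freedom equal the number
#' of dosage classes with nonzero expectation minus one. Observations in a
#' zero-expectation class make the statistic infinite (p = 0), flagging
#' dosages impossible under the cross.
#'
#' @param dosageRow Integer vector of progeny dosages (`NA` = missing).
#' @param ploidy Even integer ploidy.
#' @param d1,d2 Parental dosages.
#' @return List with `statistic`, `df`, `p.value`, `n`.
#' @export
segregationTest <- function(dosageRow, ploidy, d1, d2) {
  obs <- dosageRow[!is.na(dosageRow)]
  n <- length(obs)
  if (n == 0L)
    stop("segregation test undefined: all progeny dosages missing")
  expP <- offspringDosageDistribution(ploidy, d1, d2)
  counts <- tabulate(obs + 1L, nbins = ploidy + 1L)
  nz <- expP > 0
  df <- sum(nz) - 1L
  if (any(counts[!nz] > 0L)) {
    return(list(statistic = Inf, df = df, p.value = 0, n = n))
  }
  if (df == 0L)  # non-segregating: single expected class, nothing to test
    return(list(statistic = 0, df = 0L, p.value = 1, n = n))
  e <- n * expP[nz]
  stat <- sum((counts[nz] - e)^2 / e)
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE), n = n)
}

#' Filter markers on segregation, missingness and skewness
#'
#' Removes, in this order of precedence: non-segregating markers (expected
#' offspring distribution with a single class), markers whose progeny
#' dosage is impossible under the cross, markers with more than
#' `maxMissing` missing calls, and skewed markers whose segregation
#' chi-square p-value falls below `skewAlpha`.
#'
#' @param x A [DosageMatrix-class].
#' @param maxMissing Maximum tolerated missing fraction per marker
#'   (default 0.05).
#' @param skewAlpha Significance level below which a marker counts as
#'   skewed (default 0.001).
#' @return List with `matrix` (the filtered [DosageMatrix-class]) and
#'   `report`, a `data.frame` of dropped markers with columns `marker`,
#'   `reason` (`"non_segregating"`, `"impossible_dosage"`, `"missing"`,
#'   `"skewed"`) and `detail`.
#' @export
filterMarkers <- function(x, maxMissing = 0.05, skewAlpha = 0.001) {
  d <- dosages(x)
  pd <- parentalDosages(x)
  p <- ploidy(x)
  reason <- rep(NA_character_, nrow(d))
  detail <- rep(NA_character_, nrow(d))

  seg <- isSegregating(p, pd[, 1L], pd[, 2L])
  reason[!seg] <- "non_segregating"

  missFrac <- rowMeans(is.na(d))
  idx <- which(is.na(reason))
  for (i in idx) {
    if (all(is.na(d[i, ]))) {
      reason[i] <- "missing"; detail[i] <- "all calls missing"; next
    }
    st <- segregationTest(d[i, ], p, pd[i, 1L], pd[i, 2L])
    if (is.infinite(st$statistic)) {
      reason[i] <- "impossible_dosage"
      detail[i] <- "observed dosage with zero expected frequency"
    } else if (missFrac[i] > maxMissing) {
      reason[i] <- "missing"
      detail[i] <- sprintf("%.1f%% missing", 100 * missFrac[i])
    } else if (st$p.value < skewAlpha) {
      reason[i] <- "skewed"
      detail[i] <- sprintf("chi2 = %.2f, p = %.3g", st$statistic, st$p.value)
    }
  }
  keep <- is.na(reason)
  if (!any(keep))
    warning("no markers retained after filtering")
  report <- data.frame(marker = rownames(d)[!keep],
                       reason = reason[!keep],
                       detail = detail[!keep],
                       stringsAsFactors = FALSE)
  list(matrix = x[keep, ], report = report)
}

#' Filter individuals on missingness and cross-compatibility
#'
#' Removes individuals with more than `maxMissing` missing calls and flags
#' putative selfings/outliers: individuals whose dosage has probability
#' zero under the cross ([offspringDosageDistribution()]) at more than
#' `maxImpossible` of their non-missing markers. Selfings of parent 1
#' violate `0 x k` markers systematically, which this rate detects.
#'
#' @param x A [DosageMatrix-class].
#' @param maxMissing Maximum missing fraction per individual (default 0.10).
#' @param maxImpossible Maximum tolerated rate of cross-impossible dosages
#'   (default 0.02).
#' @return List with `matrix` (filtered), and `report` with columns
#'   `individual`, `reason` (`"missing"` or `"incompatible"`), `detail`.
#' @export
filterIndividuals <- function(x, maxMissing = 0.10, maxImpossible = 0.02) {
  d <- dosages(x)
  pd <- parentalDosages(x)
  p <- ploidy(x)

  # possible offspring dosages per marker under the cross
  ok <- matrix(FALSE, nrow(d), p + 1L)
  types <- paste0(pd[, 1L], "x", pd[, 2L])
  for (tt in unique(types)) {
    i <- which(types == tt)[1L]
    pr <- offspringDosageDistribution(p, pd[i, 1L], pd[i, 2L])
    ok[types == tt, ] <- matrix(pr > 0, sum(types == tt), p + 1L, byrow = TRUE)
  }
  impossible <- !is.na(d) & !ok[cbind(rep(seq_len(nrow(d)), ncol(d)),
                                      as.vector(d) + 1L)]
  dim(impossible) <- dim(d)

  missFrac <- colMeans(is.na(d))
  impRate <- colSums(impossible) / pmax(1L, colSums(!is.na(d)))
  reason <- ifelse(missFrac > maxMissing, "missing",
                   ifelse(impRate > maxImpossible, "incompatible",
                          NA_character_))
  keep <- is.na(reason)
  report <- data.frame(
    individual = colnames(d)[!keep],
    reason = reason[!keep],
    detail = sprintf("missing %.1f%%, impossible %.1f%%",
                     100 * missFrac[!keep], 100 * impRate[!keep]),
    stringsAsFactors = FALSE)
  list(matrix = x[, keep], report = report)
}

#' Bin duplicate markers
#'
#' Groups markers whose non-missing dosage scores are identical on every
#' individual where both are scored (and whose parental dosages agree).
#' Bins are formed greedily in marker-input order against existing bin
#' representatives, which resolves the intransitivity that missing values
#' can create; after binning, each bin's representative is the member with
#' the fewest missing values. Only the representatives need to be carried
#' through linkage analysis and ordering; members are re-attached at the
#' representative's position afterwards.
#'
#' @param x A [DosageMatrix-class] (typically already filtered).
#' @return A `data.frame` with columns `marker`, `bin` (integer id) and
#'   `representative` (logical).
#' @export
binDuplicates <- function(x) {
  d <- dosages(x)
  types <- segType(x)
  nMiss <- rowSums(is.na(d))
  # complete rows can be compared by hash in O(1)
  hash <- apply(d, 1L, paste, collapse = ",")
  bin <- integer(nrow(d))
  repIdx <- integer(0)          # row index of each bin's current anchor
  for (i in seq_len(nrow(d))) {
    assigned <- FALSE
    for (b in seq_along(repIdx)) {
      j <- repIdx[b]
      if (types[i] != types[j]) next
      if (nMiss[i] == 0L && nMiss[j] == 0L) {
        same <- hash[i] == hash[j]
      } else {
        both <- !is.na(d[i, ]) & !is.na(d[j, ])
        same <- !any(both) || !any(d[i, both] != d[j, both])
      }
      if (same) { bin[i] <- b; assigned <- TRUE; break }
    }
    if (!assigned) {
      repIdx <- c(repIdx, i)
      bin[i] <- length(repIdx)
    }
  }
  out <- data.frame(marker = rownames(d), bin = bin,
                    representative = FALSE, stringsAsFactors = FALSE)
  for (b in unique(bin)) {
    members <- which(bin == b)
    out$representative[members[which.min(nMiss[members])]] <- TRUE
  }
  out
}
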