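## Single-locus segregation under polysomic inheritance (random bivalent
## pairing, no double reduction): a parent of dosage d transmits k copies in
## a gamete of size ploidy/2 with hypergeometric probability.

.checkPloidy <- function(ploidy) {
  if (length(ploidy) != 1L || is.na(ploidy) || ploidy < 2L || ploidy %% 2L != 0L)
    stop("ploidy must be a single even integer >= 2")
  as.integer(ploidy)
}

#' Gamete dosage distribution of a polysomic parent
#'
#' Probability distribution of the number of alternative-allele copies
#' transmitted in a gamete by a parent with a given dosage, assuming
#' polysomic inheritance with random bivalent pairing and no double
#' reduction. The distribution is hypergeometric: the gamete receives
#' `ploidy/2` of the `ploidy` homologues, drawn without replacement.
#'
#' @param ploidy Even integer ploidy of the parent.
#' @param parentDosage Integer dosage in `0:ploidy`.
#' @return Named numeric vector over gamete dosages `0:(ploidy/2)`,
#'   summing to 1.
#' @examples
#' gameteDosageDistribution(6, 3)  # 0.05 0.45 0.45 0.05
#' @export
gameteDosageDistribution <- function(ploidy, parentDosage) {
  ploidy <- .checkPloidy(ploidy)
  d <- parentDosage
  if (length(d) != 1L || is.na(d) || d < 0L || d > ploidy)
    stop("parentDosage must be in 0..ploidy")
  g <- ploidy %/% 2L
  k <- 0:g
  p <- choose(d, k) * choose(ploidy - d, g - k) / choose(ploidy, g)
  names(p) <- k
  p
}

#' Offspring dosage distribution for a bi-parental cross
#'
#' Convolution of the two parental gamete-dosage distributions; gives the
#' expected segregation ratio of a marker with parental dosages `d1 x d2`.
#'
#' @param ploidy Even integer ploidy.
#' @param d1,d2 Parental dosages in `0:ploidy`.
#' @return Named numeric vector over offspring dosages `0:ploidy`, summing
#'   to 1 with mean `(d1 + d2) / 2`.
#' @examples
#' offspringDosageDistribution(6, 1, 1)  # 1:2:1 on dosages 0,1,2
#' @export
offspringDosageDistribution <- function(ploidy, d1, d2) {
  g1 <- gameteDosageDistribution(ploidy, d1)
  g2 <- gameteDosageDistribution(ploidy, d2)
  p <- rep(0, ploidy + 1L)
  for (a in seq_along(g1)) {
    if (g1[a] == 0) next
    idx <- (a - 1L) + seq_along(g2)       # offspring dosage + 1
    p[idx] <- p[idx] + g1[a] * g2
  }
  names(p) <- 0:ploidy
  p
}

#' Is a parental dosage pair segregating?
#'
#' A marker segregates in the F1 when its expected offspring distribution
#' has at least two dosage classes, i.e. at least one parent is
#' heterozygous (dosage in `1:(ploidy-1)`).
#'
#' @inheritParams offspringDosageDistribution
#' @return Logical.
#' @export
isSegregating <- function(ploidy, d1, d2) {
  ploidy <- .checkPloidy(ploidy)
  (d1 %% ploidy != 0) | (d2 %% ploidy != 0)
}

#' Fundamental form of a marker segregation type
#'
#' Canonicalizes a parental dosage pair under the joint allele-label swap
#' `(d1, d2) -> (ploidy - d1, ploidy - d2)`, which leaves segregation
#' untouched. The representative with `d1 + d2 <= ploidy` is chosen
#' (ties broken by the smaller `d1`), so e.g. `5x6` maps to `1x0`.
#'
#' @inheritParams offspringDosageDistribution
#' @return Integer vector `c(d1, d2)` of the canonical pair. Vectorized
#'   over `d1`, `d2`.
#' @examples
#' fundamentalForm(6, 5, 6)  # 1 0
#' fundamentalForm(6, 3, 3)  # 3 3 (self-conjugate)
#' @export
fundamentalForm <- function(ploidy, d1, d2) {
  ploidy <- .checkPloidy(ploidy)
  if (any(d1 < 0 | d1 > ploidy | d2 < 0 | d2 > ploidy, na.rm = TRUE))
    stop("dosages must be in 0..ploidy")
  swap <- (d1 + d2 > ploidy) |
    (d1 + d2 == ploidy & (ploidy - d1) < d1)
  out <- cbind(d1 = ifelse(swap, ploidy - d1, d1),
               d2 = ifelse(swap, ploidy - d2, d2))
  if (length(d1) == 1L) out[1L, ] else out
}

#' Counting facts for polysomic loci
#'
#' `nDosageClasses()` returns the number of distinct dosage scores at a
#' bi-allelic locus (`ploidy + 1`; 7 for a hexaploid). `nGenotypeClasses()`
#' returns the number of distinct fully multi-allelic two-parent genotype
#' classes, `choose(ploidy, ploidy/2)^2` (36 for a tetraploid, 400 for a
#' hexaploid) — the reason full genotype-class QTL models over-fit at
#' higher ploidies.
#'
#' @param ploidy Even integer ploidy.
#' @return A single number.
#' @export
nDosageClasses <- function(ploidy) {
  .checkPloidy(ploidy) + 1L
}

#' @rdname nDosageClasses
#' @export
nGenotypeClasses <- function(ploidy) {
  ploidy <- .checkPloidy(ploidy)
  choose(ploidy, ploidy %/% 2L)^2
}
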