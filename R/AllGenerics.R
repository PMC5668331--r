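#' @import methods
#' @importFrom stats pchisq dpois rpois runif rnorm rbinom pf lm anova aov
#'   optimize splinefun approx quantile median setNames
#'   lowess prcomp cmdscale
#' @importFrom utils read.delim write.table combn
NULL

#' Ploidy of an object
#'
#' Accessor for the (even) ploidy level carried by HexaMapQTL objects.
#'
#' @param x An object with a ploidy, e.g. a [DosageMatrix-class].
#' @return A single even integer (6 for a hexaploid).
#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))

#' Marker-by-individual dosage calls
#'
#' @param x A [DosageMatrix-class].
#' @return Integer matrix (markers x individuals) with values in
#'   `0:ploidy(x)` and `NA` for missing calls.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Parental dosages
#'
#' @param x A [DosageMatrix-class].
#' @return Integer matrix with one row per marker and columns `P1`, `P2`.
#' @export
setGeneric("parentalDosages", function(x) standardGeneric("parentalDosages"))

#' Marker segregation type labels
#'
#' @param x A [DosageMatrix-class].
#' @return Character vector like `"1x0"`, `"2x1"` per marker
#'   (parent-1 dosage x parent-2 dosage).
#' @export
setGeneric("segType", function(x) standardGeneric("segType"))
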