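#' @import SummarizedExperiment
#' @import S4Vectors
NULL

#' DosageMatrix: SNP dosage calls for a bi-parental F1 population
#'
#' An S4 container for integer allele-dosage calls (0..ploidy) of markers
#' scored on the two parents and the F1 progeny of a polyploid cross. It
#' extends [SummarizedExperiment::SummarizedExperiment] with one assay,
#' `"dosage"` (markers x individuals); parental dosages live in
#' `rowData(x)$P1` and `rowData(x)$P2`, an optional marker-to-contig
#' annotation in `rowData(x)$contig`, and the ploidy in
#' `metadata(x)$ploidy`.
#'
#' Validity requires an even ploidy, unique marker identifiers, parental
#' dosages present (never missing) and in `0:ploidy`, and all non-missing
#' progeny dosages in `0:ploidy`.
#'
#' @seealso [DosageMatrix()] for construction, [readDosageMatrix()] for the
#'   delimited-text format, [filterMarkers()] and [filterIndividuals()] for
#'   quality control.
#' @aliases DosageMatrix-class
#' @exportClass DosageMatrix
setClass("DosageMatrix", contains = "SummarizedExperiment")

.validDosageMatrix <- function(object) {
  msg <- NULL
  if (!"dosage" %in% assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  p <- metadata(object)$ploidy
  if (is.null(p) || length(p) != 1L || is.na(p) || p < 2L || p %% 2L != 0L)
    msg <- c(msg, "metadata(x)$ploidy must be a single even integer >= 2")
  rd <- rowData(object)
  if (!all(c("P1", "P2") %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain parental dosage columns 'P1' and 'P2'")
  } else if (is.null(msg)) {
    pd <- cbind(rd$P1, rd$P2)
    if (anyNA(pd))
      msg <- c(msg, "parental dosages must not be missing")
    else if (any(pd < 0L | pd > p))
      msg <- c(msg, sprintf("parental dosages must be in 0..%d", p))
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "marker identifiers (rownames) must be unique")
  if (is.null(msg)) {
    d <- assay(object, "dosage")
    bad <- !is.na(d) & (d < 0L | d > p)
    if (any(bad))
      msg <- c(msg, sprintf("progeny dosages must be in 0..%d or NA", p))
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("DosageMatrix", .validDosageMatrix)

#' Construct a DosageMatrix
#'
#' @param dosage Integer matrix, markers x individuals; `NA` = missing.
#'   Rownames are marker ids, colnames individual ids.
#' @param p1,p2 Integer vectors of parental dosages, one entry per marker.
#' @param ploidy Even integer ploidy (default 6, hexaploid).
#' @param contig Optional character vector mapping markers to transcript
#'   contigs (used by [sameContigRMSE()]).
#' @return A [DosageMatrix-class].
#' @examples
#' dm <- DosageMatrix(matrix(c(0L, 1L, 1L, 0L), 2,
#'                           dimnames = list(c("m1", "m2"), c("i1", "i2"))),
#'                    p1 = c(1L, 1L), p2 = c(0L, 0L))
#' segType(dm)
#' @export
DosageMatrix <- function(dosage, p1, p2, ploidy = 6L, contig = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("M%04d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("F1_%04d", seq_len(ncol(dosage)))
  rd <- DataFrame(P1 = as.integer(p1), P2 = as.integer(p2))
  if (!is.null(contig)) rd$contig <- as.character(contig)
  se <- SummarizedExperiment(
    assays = list(dosage = dosage),
    rowData = rd,
    metadata = list(ploidy = as.integer(ploidy))
  )
  new("DosageMatrix", se)
}

#' @rdname ploidy
#' @export
setMethod("ploidy", "DosageMatrix", function(x) metadata(x)$ploidy)

#' @rdname dosages
#' @export
setMethod("dosages", "DosageMatrix", function(x) assay(x, "dosage"))

#' @rdname parentalDosages
#' @export
setMethod("parentalDosages", "DosageMatrix", function(x) {
  cbind(P1 = rowData(x)$P1, P2 = rowData(x)$P2)
})

#' @rdname segType
#' @export
setMethod("segType", "DosageMatrix", function(x) {
  paste0(rowData(x)$P1, "x", rowData(x)$P2)
})

setMethod("show", "DosageMatrix", function(object) {
  cat(sprintf("DosageMatrix (ploidy %d): %d markers x %d individuals\n",
              ploidy(object), nrow(object), ncol(object)))
  tt <- sort(table(segType(object)), decreasing = TRUE)
  cat("  marker types:",
      paste(sprintf("%s (%d)", names(tt), tt), collapse = ", "), "\n")
  miss <- mean(is.na(assay(object, "dosage")))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
})

#' PhasedMap: an integrated, phased linkage map
#'
#' Holds per-marker chromosomal linkage group (CLG), map position (cM) and
#' the allele-to-homologue assignment over the `2 * ploidy` parental
#' homologues (h1..h6 = parent 1, h7..h12 = parent 2 for a hexaploid). A 1
#' in a homologue column means one allele of the marker resides on that
#' homologue; the number of 1s per parent equals that parent's dosage for
#' phased markers.
#'
#' @slot map `data.frame` with columns `marker`, `CLG`, `position`, then
#'   `h1`..`h<2*ploidy>` (0/1; all-zero rows are assigned-but-unphased
#'   markers), and `phased` (logical).
#' @slot ploidy Even integer.
#' @aliases PhasedMap-class
#' @exportClass PhasedMap
setClass("PhasedMap",
         representation(map = "data.frame", ploidy = "integer"))

setValidity("PhasedMap", function(object) {
  m <- object@map
  need <- c("marker", "CLG", "position",
            paste0("h", seq_len(2L * object@ploidy)))
  if (!all(need %in% colnames(m)))
    return(paste("map must contain columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(m$marker)) return("marker ids must be unique")
  if (any(m$position < 0, na.rm = TRUE)) return("positions must be >= 0")
  TRUE
})

setMethod("show", "PhasedMap", function(object) {
  m <- object@map
  cat(sprintf("PhasedMap: %d markers in %d CLG; %d phased\n",
              nrow(m), length(unique(m$CLG)), sum(m$phased)))
  for (g in sort(unique(m$CLG))) {
    mg <- m[m$CLG == g, ]
    cat(sprintf("  CLG%s: %d markers, %.1f cM\n", g, nrow(mg),
                max(mg$position, na.rm = TRUE)))
  }
})

#' IBDResult: identity-by-descent probabilities along the map
#'
#' Per chromosomal linkage group, a 3-D array of IBD probabilities with
#' dimensions locus x individual x homologue (2 * ploidy homologues). After
#' normalization the probabilities of each parent's homologues sum to
#' ploidy/2 at every locus for every individual.
#'
#' @slot arrays Named list (one per CLG) of 3-D numeric arrays.
#' @slot positions Named list of locus positions (cM) matching dim 1.
#' @slot gic Named list of matrices (locus x homologue) of genotype
#'   information content, filled by [gicProfile()]; may be empty.
#' @slot ploidy Even integer.
#' @aliases IBDResult-class
#' @exportClass IBDResult
setClass("IBDResult",
         representation(arrays = "list", positions = "list",
                        gic = "list", ploidy = "integer"))

setValidity("IBDResult", function(object) {
  for (g in names(object@arrays)) {
    a <- object@arrays[[g]]
    if (length(dim(a)) != 3L) return("each IBD array must be 3-dimensional")
    if (dim(a)[3] != 2L * object@ploidy)
      return("homologue dimension must equal 2 * ploidy")
    if (length(object@positions[[g]]) != dim(a)[1])
      return("positions must match the locus dimension")
    if (any(a < -1e-8 | a > 1 + 1e-8, na.rm = TRUE))
      return("IBD probabilities must lie in [0, 1]")
  }
  TRUE
})

setMethod("show", "IBDResult", function(object) {
  cat(sprintf("IBDResult (ploidy %d): %d linkage groups\n",
              object@ploidy, length(object@arrays)))
  for (g in names(object@arrays)) {
    d <- dim(object@arrays[[g]])
    cat(sprintf("  %s: %d loci x %d individuals x %d homologues\n",
                g, d[1], d[2], d[3]))
  }
})

#' QTLScan: genome-scan result for one trait
#'
#' @slot scan `data.frame` with columns `CLG`, `position`, `neg_log10_p`,
#'   `df_model`, `significant`.
#' @slot threshold Genome-wide p-value threshold from permutations
#'   (`NA` if not computed).
#' @slot alleleEffects `data.frame` of per-allele effects at the scan peak
#'   (may be empty): columns `CLG`, `position`, `homologue`, `effect`, `p`.
#' @slot trait Trait name.
#' @aliases QTLScan-class
#' @exportClass QTLScan
setClass("QTLScan",
         representation(scan = "data.frame", threshold = "numeric",
                        alleleEffects = "data.frame", trait = "character"))

setMethod("show", "QTLScan", function(object) {
  s <- object@scan
  cat(sprintf("QTLScan for '%s': %d loci over %d CLG\n",
              object@trait, nrow(s), length(unique(s$CLG))))
  if (!is.na(object@threshold))
    cat(sprintf("  permutation threshold: p <= %.3g (-log10 = %.2f)\n",
                object@threshold, -log10(object@threshold)))
  top <- s[which.max(s$neg_log10_p), , drop = FALSE]
  if (nrow(top))
    cat(sprintf("  peak: CLG%s @ %.0f cM, -log10(p) = %.2f\n",
                top$CLG, top$position, top$neg_log10_p))
})
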