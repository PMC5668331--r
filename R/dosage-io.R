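## Delimited-text interchange formats. The dosage file has a header row and
## columns marker_id, P1, P2, then one column per F1 individual; missing
## calls are "NA". Comma- or tab-delimited, auto-detected on read.

#' Read a dosage matrix from delimited text
#'
#' @param file Path to a comma- or tab-delimited file with header
#'   `marker_id, P1, P2, <individual ids...>`; missing calls `NA`.
#' @param ploidy Even integer ploidy of the population (default 6).
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A [DosageMatrix-class].
#' @seealso [writeDosageMatrix()]
#' @export
readDosageMatrix <- function(file, ploidy = 6L, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(file, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  tab <- read.delim(file, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 4L)
    stop("dosage file needs columns marker_id, P1, P2 and >= 1 individual")
  d <- as.matrix(tab[, -(1:3), drop = FALSE])
  storage.mode(d) <- "integer"
  rownames(d) <- as.character(tab[[1L]])
  DosageMatrix(d, p1 = tab[[2L]], p2 = tab[[3L]], ploidy = ploidy)
}

#' Write a dosage matrix to delimited text
#'
#' @param x A [DosageMatrix-class].
#' @param file Output path.
#' @param sep Field separator (default tab).
#' @return Invisibly, `file`.
#' @export
writeDosageMatrix <- function(x, file, sep = "\t") {
  tab <- data.frame(marker_id = rownames(x),
                    P1 = rowData(x)$P1, P2 = rowData(x)$P2,
                    dosages(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a marker/individual filter report
#'
#' @param report `data.frame` as produced by [filterMarkers()] or
#'   [filterIndividuals()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeFilterReport <- function(report, file) {
  write.table(report, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a phased map to delimited text
#'
#' One row per marker with its CLG, position (cM) and homologue indicator
#' columns h1..h12 (for a hexaploid); a 1 in a homologue column means the
#' marker has an allele on that homologue.
#'
#' @param x A [PhasedMap-class].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writePhasedMap <- function(x, file) {
  write.table(x@map, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a phased map written by [writePhasedMap()]
#'
#' @param file Path.
#' @param ploidy Even integer ploidy.
#' @return A [PhasedMap-class].
#' @export
readPhasedMap <- function(file, ploidy = 6L) {
  m <- read.delim(file, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  m$phased <- as.logical(m$phased)
  if ("assigned" %in% colnames(m)) m$assigned <- as.logical(m$assigned)
  new("PhasedMap", map = m, ploidy = as.integer(ploidy))
}

#' Read IBD probabilities written by [writeIBDLong()]
#'
#' @param file Path.
#' @param ploidy Even integer ploidy.
#' @return An [IBDResult-class].
#' @export
readIBDLong <- function(file, ploidy = 6L) {
  tab <- read.delim(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  arrays <- list(); positions <- list()
  for (g in unique(tab$CLG)) {
    tg <- tab[tab$CLG == g, ]
    pos <- sort(unique(tg$position_cM))
    inds <- unique(tg$individual)
    nh <- 2L * ploidy
    a <- array(NA_real_, c(length(pos), length(inds), nh),
               dimnames = list(NULL, inds, paste0("h", seq_len(nh))))
    a[cbind(match(tg$position_cM, pos), match(tg$individual, inds),
            as.integer(sub("^h", "", tg$homologue)))] <- tg$probability
    arrays[[as.character(g)]] <- a
    positions[[as.character(g)]] <- pos
  }
  new("IBDResult", arrays = arrays, positions = positions, gic = list(),
      ploidy = as.integer(ploidy))
}

#' Write IBD probabilities in long format
#'
#' One table over all linkage groups: columns `CLG`, `individual`,
#' `homologue`, `position_cM`, `probability`.
#'
#' @param x An [IBDResult-class].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeIBDLong <- function(x, file) {
  out <- vector("list", length(x@arrays))
  for (k in seq_along(x@arrays)) {
    g <- names(x@arrays)[k]
    a <- x@arrays[[g]]
    dn <- dimnames(a)
    grid <- expand.grid(locus = seq_len(dim(a)[1]),
                        individual = seq_len(dim(a)[2]),
                        homologue = seq_len(dim(a)[3]))
    out[[k]] <- data.frame(
      CLG = g,
      individual = dn[[2]][grid$individual],
      homologue = paste0("h", grid$homologue),
      position_cM = x@positions[[g]][grid$locus],
      probability = as.vector(a),
      stringsAsFactors = FALSE)
  }
  write.table(do.call(rbind, out), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
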