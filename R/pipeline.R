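## End-to-end orchestration: filter -> bin -> backbone -> CLG -> assign/
## phase -> order -> IBD -> (optional) QTL, with per-stage logging of
## marker/individual counts and delimited-text artifacts.

#' Default run configuration
#'
#' All thresholds of the pipeline with their default values: marker
#' missingness 5%, segregation-skew alpha 0.001, individual missingness
#' 10%, backbone clustering LOD 10 with minimum cluster size 5,
#' assignment/phasing LOD 5 with at least 5 coupling linkages,
#' nearest-neighbour fit threshold 4, r grid step 0.005, IBD grid step
#' 1 cM, 1000 permutations with the 5th percentile for the QTL threshold.
#'
#' @param ... Named overrides of any default.
#' @return Named list.
#' @export
runConfig <- function(...) {
  cfg <- list(ploidy = 6L, maxMissingMarker = 0.05, skewAlpha = 0.001,
              maxMissingInd = 0.10, maxImpossible = 0.02,
              clusterLOD = 10, minClusterSize = 5L,
              assignLOD = 5, minLinks = 5L,
              fitThreshold = 4, nnK = 10L, rStep = 0.005,
              gridStep = 1, nPerm = 1000L, percentile = 5, seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a flat key=value configuration file
#'
#' @param file Path to a text file with `key = value` lines (`#` starts a
#'   comment). Values are coerced to numeric where possible.
#' @param ... Overrides applied after the file (e.g. from CLI flags).
#' @return Named list as [runConfig()].
#' @export
readRunConfig <- function(file, ...) {
  lines <- readLines(file)
  lines <- sub("#.*", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- trimws(paste(x[-1L], collapse = "="))
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  })
  names(vals) <- trimws(vapply(kv, `[`, "", 1L))
  do.call(runConfig, c(vals, list(...)))
}

#' Run the full mapping pipeline
#'
#' Executes marker/individual filtering, duplicate binning, backbone
#' clustering, CLG identification, assignment and phasing, per-CLG
#' ordering with iterative removal of problematic markers, duplicate
#' re-attachment at the representative's position, IBD estimation and
#' gridding with GIC, and (when phenotypes are supplied) a QTL scan per
#' trait with a permutation threshold. Per-stage counts are logged via
#' `message()`; artifacts are written to `outDir` as delimited text when
#' given.
#'
#' @param dosage A [DosageMatrix-class] (or use `dosageFile`).
#' @param dosageFile Path to a dosage file for [readDosageMatrix()].
#' @param phenotypes Optional `data.frame` of traits (rownames =
#'   individual ids) or named numeric vector for a single trait.
#' @param config List from [runConfig()].
#' @param outDir Optional output directory for artifacts.
#' @return List with elements `filtered` (DosageMatrix), `reports`,
#'   `bins`, `backbone`, `clg`, `phasedMap` (a [PhasedMap-class] with
#'   positions), `integratedMap` (`data.frame`), `orderingInfo`, `ibd`
#'   and `ibdGrid` ([IBDResult-class]), and `qtl` (list of
#'   [QTLScan-class]).
#' @export
runPipeline <- function(dosage = NULL, dosageFile = NULL, phenotypes = NULL,
                        config = runConfig(), outDir = NULL) {
  stopifnot(!is.null(dosage) || !is.null(dosageFile))
  set.seed(config$seed)
  if (is.null(dosage))
    dosage <- readDosageMatrix(dosageFile, ploidy = config$ploidy)
  message(sprintf("input: %d markers x %d individuals", nrow(dosage),
                  ncol(dosage)))

  fm <- filterMarkers(dosage, config$maxMissingMarker, config$skewAlpha)
  fi <- filterIndividuals(fm$matrix, config$maxMissingInd,
                          config$maxImpossible)
  x <- fi$matrix
  message(sprintf("after filtering: %d markers, %d individuals (removed %d markers, %d individuals)",
                  nrow(x), ncol(x), nrow(fm$report), nrow(fi$report)))

  bins <- binDuplicates(x)
  reps <- bins$marker[bins$representative]
  xr <- x[reps, ]
  message(sprintf("duplicate binning: %d unique of %d markers",
                  length(reps), nrow(x)))

  backbone <- buildBackbone(xr, config$clusterLOD, config$minClusterSize,
                            config$rStep)
  nUsed <- tapply(backbone$used, backbone$parent, sum)
  nCl <- sapply(split(backbone[backbone$used, ], backbone$parent[backbone$used]),
                function(b) length(unique(b$cluster)))
  message(sprintf("backbone: %s clusters (P1, P2) from %s used simplex markers",
                  paste(nCl, collapse = "/"), paste(nUsed, collapse = "/")))

  clgRes <- identifyCLG(xr, backbone, config$assignLOD, config$rStep)
  message(sprintf("CLG: %d groups; %d ambiguous bridge markers",
                  length(unique(clgRes$clg$clg)), length(clgRes$ambiguous)))

  pm <- assignAndPhase(xr, backbone, clgRes$clg, config$assignLOD,
                       config$minLinks, config$rStep)
  message(sprintf("assigned %d / %d unique markers; %d phased",
                  sum(pm@map$assigned), nrow(pm@map), sum(pm@map$phased)))

  # per-CLG ordering
  orderingInfo <- list()
  for (g in sort(unique(pm@map$CLG[!is.na(pm@map$CLG)]))) {
    mg <- pm@map$marker[pm@map$CLG == g & !is.na(pm@map$CLG)]
    if (length(mg) < 3L) next
    lk <- pairwiseLinkage(xr, mg, rStep = config$rStep)
    io <- iterateOrdering(lk, mg, fitThreshold = config$fitThreshold,
                          k = config$nnK)
    idx <- match(io$map$marker, pm@map$marker)
    pm@map$position[idx] <- io$map$position
    orderingInfo[[as.character(g)]] <- io
    message(sprintf("CLG %s: %d markers ordered over %.1f cM (%d rounds, %d removed)",
                    g, nrow(io$map), max(io$map$position), io$rounds,
                    nrow(io$removed)))
  }

  # integrated map incl. duplicate re-attachment at representative position
  repOf <- bins$marker[bins$representative][bins$bin]
  names(repOf) <- bins$marker
  integrated <- pm@map[, c("marker", "CLG", "position", "phased")]
  dup <- bins$marker[!bins$representative]
  di <- match(repOf[dup], integrated$marker)
  add <- integrated[di[!is.na(di)], ]
  add$marker <- dup[!is.na(di)]
  add$phased <- FALSE
  integrated <- rbind(integrated, add)
  integrated <- integrated[!is.na(integrated$position), ]
  integrated <- integrated[order(integrated$CLG, integrated$position), ]
  rownames(integrated) <- NULL
  message(sprintf("integrated map: %d markers (%d unique) on %d CLG",
                  nrow(integrated), sum(!is.na(pm@map$position)),
                  length(unique(integrated$CLG))))

  ibd <- estimateIBD(xr, pm)
  ibdGrid <- gicProfile(gridIBD(ibd, config$gridStep))

  qtl <- list()
  if (!is.null(phenotypes)) {
    if (is.numeric(phenotypes) && !is.null(names(phenotypes)))
      phenotypes <- data.frame(trait = phenotypes)
    for (tr in colnames(phenotypes)) {
      ph <- setNames(phenotypes[[tr]], rownames(phenotypes))
      thr <- permutationThreshold(ibdGrid, ph, config$nPerm,
                                  config$percentile, seed = config$seed)
      qtl[[tr]] <- qtlScan(ibdGrid, ph, threshold = thr, trait = tr)
      message(sprintf("QTL scan '%s': threshold p <= %.3g, %d significant loci",
                      tr, thr, sum(qtl[[tr]]@scan$significant)))
    }
  }

  out <- list(filtered = x, reports = list(markers = fm$report,
                                           individuals = fi$report),
              bins = bins, backbone = backbone, clg = clgRes,
              phasedMap = pm, integratedMap = integrated,
              orderingInfo = orderingInfo, ibd = ibd, ibdGrid = ibdGrid,
              qtl = qtl, config = config)
  if (!is.null(outDir)) .writeArtifacts(out, outDir)
  out
}

.writeArtifacts <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outDir, f)
  writeFilterReport(res$reports$markers, fp("filter_markers.tsv"))
  writeFilterReport(res$reports$individuals, fp("filter_individuals.tsv"))
  write.table(res$bins, fp("marker_bins.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(res$backbone, fp("backbone_clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$clg$clg, fp("clg.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writePhasedMap(res$phasedMap, fp("phased_map.tsv"))
  write.table(res$integratedMap, fp("integrated_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeIBDLong(res$ibdGrid, fp("ibd_grid.tsv"))
  if (length(res$ibdGrid@gic)) {
    gic <- do.call(rbind, lapply(names(res$ibdGrid@gic), function(g) {
      m <- res$ibdGrid@gic[[g]]
      data.frame(CLG = g,
                 position_cM = res$ibdGrid@positions[[g]],
                 m, check.names = FALSE)
    }))
    colnames(gic)[-(1:2)] <- paste0("h", seq_len(ncol(gic) - 2L))
    write.table(gic, fp("gic.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  for (tr in names(res$qtl)) {
    write.table(res$qtl[[tr]]@scan, fp(sprintf("qtl_scan_%s.tsv", tr)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- res$config
  writeLines(paste(names(cfg), unlist(cfg), sep = " = "),
             fp("config.txt"))
  invisible(outDir)
}
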