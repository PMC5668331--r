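## Homologue backbone clustering, chromosomal linkage group (CLG)
## identification and allele-to-homologue phasing.
##
## Simplex x nulliplex (1x0 / 0x1) markers linked in coupling identify one
## physical homologue of one parent; clustering them at a high LOD gives
## "backbone" clusters. Bi-parental 1x1 markers bridge clusters of the two
## parents into CLG. All remaining markers are then assigned and phased via
## their coupling linkages with backbone markers.

#' Cluster simplex markers into homologue backbone clusters
#'
#' Builds the graph on one parent's simplex (1x0 or 0x1) markers with an
#' edge wherever the pairwise LOD is at least `lodThreshold` and the best
#' phase is coupling (shared-homologue count > 0); connected components
#' are the homologue clusters. Components smaller than `minSize` are
#' flagged as unused for mapping. Repulsion linkages are ignored: in a
#' hexaploid they carry almost no information at realistic population
#' sizes.
#'
#' @param linkage `data.frame` from [pairwiseLinkage()] over one parent's
#'   simplex markers.
#' @param markers Character vector of that parent's simplex marker ids
#'   (singletons with no qualifying edge still get a cluster).
#' @param lodThreshold Minimum LOD for an edge (default 10).
#' @param minSize Minimum cluster size to be used in mapping (default 5).
#' @return `data.frame` with columns `marker`, `cluster` (integer within
#'   this call), `size`, `used`.
#' @export
clusterBackbone <- function(linkage, markers, lodThreshold = 10, minSize = 5L) {
  if (length(markers) == 0L)
    return(data.frame(marker = character(0), cluster = integer(0),
                      size = integer(0), used = logical(0)))
  keep <- linkage$LOD >= lodThreshold & (linkage$phase1 + linkage$phase2) > 0 &
    linkage$marker1 %in% markers & linkage$marker2 %in% markers
  g <- igraph::graph_from_data_frame(
    linkage[keep, c("marker1", "marker2"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = markers, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  cl <- comp$membership[markers]
  size <- as.integer(comp$csize[cl])
  data.frame(marker = markers, cluster = as.integer(cl), size = size,
             used = size >= minSize, stringsAsFactors = FALSE)
}

#' Build the full two-parent backbone
#'
#' Convenience wrapper: computes pairwise linkage within each parent's
#' simplex markers and clusters them with [clusterBackbone()].
#'
#' @param x A [DosageMatrix-class] (filtered, unique markers).
#' @param lodThreshold Minimum LOD for a coupling edge (default 10).
#' @param minSize Minimum cluster size (default 5).
#' @param rStep Grid step passed to [pairwiseLinkage()].
#' @return `data.frame` with columns `marker`, `parent` (1 or 2),
#'   `cluster` (character id like `"P1_03"`), `size`, `used`.
#' @export
buildBackbone <- function(x, lodThreshold = 10, minSize = 5L, rStep = 0.005) {
  pd <- parentalDosages(x)
  out <- list()
  for (par in 1:2) {
    simplex <- rownames(x)[pd[, par] == 1L & pd[, 3L - par] == 0L]
    if (!length(simplex)) next
    lk <- pairwiseLinkage(x, simplex, rStep = rStep, minLOD = lodThreshold)
    cb <- clusterBackbone(lk, simplex, lodThreshold, minSize)
    out[[par]] <- data.frame(marker = cb$marker, parent = par,
                             cluster = sprintf("P%d_%02d", par, cb$cluster),
                             size = cb$size, used = cb$used,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## qualifying coupling links of target markers to backbone markers:
## LOD above threshold and coupling phase in the backbone marker's parent.
.qualifyingLinks <- function(linkage, backbone, lodThreshold) {
  bb <- backbone[backbone$used, , drop = FALSE]
  m <- match(linkage$marker2, bb$marker)
  ok <- !is.na(m) & linkage$LOD > lodThreshold
  par2 <- bb$parent[m]
  coup <- ifelse(par2 == 1L, linkage$phase1, linkage$phase2) > 0
  ok <- ok & !is.na(coup) & coup
  data.frame(marker = linkage$marker1[ok],
             cluster = bb$cluster[m[ok]],
             parent = par2[ok],
             LOD = linkage$LOD[ok],
             stringsAsFactors = FALSE)
}

#' Identify chromosomal linkage groups via 1x1 bridge markers
#'
#' Each simplex x simplex (1x1) marker has one allele in each parent; its
#' strongest coupling-linked backbone cluster per parent (most qualifying
#' links) therefore associates a parent-1 cluster with a parent-2 cluster.
#' Clusters connected through shared bridge markers are merged
#' transitively; the resulting components are the CLG, numbered by
#' descending backbone marker count. Bridge markers whose per-parent best
#' cluster is tied are logged as ambiguous and skipped.
#'
#' @param x A [DosageMatrix-class].
#' @param backbone Output of [buildBackbone()].
#' @param lodThreshold Minimum LOD for a qualifying bridge link (default 5).
#' @param rStep Grid step for the internal [pairwiseLinkage()] call.
#' @param linkage Optional precomputed linkage of the 1x1 markers (rows
#'   `marker1` = bridge, `marker2` = backbone marker).
#' @return List: `clg` (`data.frame` cluster, parent, clg), `bridges`
#'   (per 1x1 marker, its per-parent best clusters), `ambiguous`
#'   (skipped bridge marker ids).
#' @export
identifyCLG <- function(x, backbone, lodThreshold = 5, rStep = 0.005,
                        linkage = NULL) {
  pd <- parentalDosages(x)
  ss <- rownames(x)[pd[, 1L] == 1L & pd[, 2L] == 1L]
  bbm <- backbone$marker[backbone$used]
  if (is.null(linkage) && length(ss))
    linkage <- pairwiseLinkage(x, ss, bbm, rStep = rStep,
                               minLOD = lodThreshold)
  clusters <- unique(backbone[backbone$used, c("cluster", "parent")])
  edges <- NULL; ambiguous <- character(0)
  if (length(ss) && nrow(linkage)) {
    q <- .qualifyingLinks(linkage, backbone, lodThreshold)
    for (mk in unique(q$marker)) {
      qi <- q[q$marker == mk, ]
      best <- character(2L)
      for (par in 1:2) {
        qp <- qi[qi$parent == par, ]
        if (!nrow(qp)) break
        cnt <- sort(table(qp$cluster), decreasing = TRUE)
        if (length(cnt) > 1L && cnt[1L] == cnt[2L]) {
          ambiguous <- c(ambiguous, mk); break
        }
        best[par] <- names(cnt)[1L]
      }
      if (all(nzchar(best)))
        edges <- rbind(edges, data.frame(marker = mk, c1 = best[1L],
                                         c2 = best[2L],
                                         stringsAsFactors = FALSE))
    }
  }
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(0), to = character(0))
    else edges[, c("c1", "c2")],
    directed = FALSE,
    vertices = data.frame(name = clusters$cluster))
  comp <- igraph::components(g)
  member <- comp$membership[clusters$cluster]
  # number CLG by descending backbone marker count
  nmk <- vapply(split(clusters$cluster, member), function(cl)
    sum(backbone$used & backbone$cluster %in% cl), 0L)
  rank <- match(member, as.integer(names(sort(nmk, decreasing = TRUE))))
  clg <- data.frame(cluster = clusters$cluster, parent = clusters$parent,
                    clg = rank, stringsAsFactors = FALSE)
  list(clg = clg, bridges = edges, ambiguous = ambiguous)
}

#' Assign markers to CLG and phase alleles to homologues
#'
#' Every marker is assigned to the CLG holding the most qualifying
#' coupling linkages (LOD > `lodThreshold`) with used backbone markers;
#' each of its alleles is placed on the homologue (backbone cluster)
#' showing at least `minLinks` such linkages. Markers whose number of
#' placed alleles differs from the parental dosage in either parent are
#' kept in the map but flagged unphased. Backbone markers are phased
#' directly to their own cluster's homologue. Ties in CLG support leave
#' the marker unassigned.
#'
#' @param x A [DosageMatrix-class] of the markers to place (typically all
#'   unique filtered markers).
#' @param backbone From [buildBackbone()].
#' @param clgMap From [identifyCLG()] (its `clg` element).
#' @param lodThreshold Minimum LOD for a qualifying linkage (default 5).
#' @param minLinks Minimum coupling linkages per homologue (default 5).
#' @param rStep Grid step for internal [pairwiseLinkage()].
#' @param linkage Optional precomputed linkage (`marker1` = target,
#'   `marker2` = backbone marker) to avoid recomputation.
#' @return A [PhasedMap-class] with positions `NA` (fill by
#'   [orderCLG()]/[iterateOrdering()]); its `map` also has columns
#'   `assigned` and `phased`. Homologue slots h1..h6 are parent-1 clusters
#'   of the CLG in cluster-id order, h7..h12 parent-2.
#' @export
assignAndPhase <- function(x, backbone, clgMap, lodThreshold = 5,
                           minLinks = 5L, rStep = 0.005, linkage = NULL) {
  ploidy <- ploidy(x)
  nh <- 2L * ploidy
  markers <- rownames(x)
  bb <- backbone[backbone$used, , drop = FALSE]
  targets <- setdiff(markers, bb$marker)
  if (is.null(linkage) && length(targets))
    linkage <- pairwiseLinkage(x, targets, bb$marker, rStep = rStep,
                               minLOD = lodThreshold)

  # homologue slot of each used cluster within its CLG
  slotOf <- integer(0)
  for (g in unique(clgMap$clg)) {
    for (par in 1:2) {
      cl <- sort(clgMap$cluster[clgMap$clg == g & clgMap$parent == par])
      if (length(cl) > ploidy)
        warning(sprintf("CLG %s has %d parent-%d clusters (> ploidy/parent)",
                        g, length(cl), par))
      s <- seq_along(cl) + (par - 1L) * ploidy
      slotOf[cl] <- s
    }
  }

  nm <- length(markers)
  H <- matrix(0L, nm, nh, dimnames = list(markers, paste0("h", seq_len(nh))))
  CLG <- rep(NA_integer_, nm)
  assigned <- phased <- rep(FALSE, nm)
  pd <- parentalDosages(x)

  # backbone markers: own cluster's homologue
  bidx <- match(bb$marker, markers)
  CLG[bidx] <- clgMap$clg[match(bb$cluster, clgMap$cluster)]
  assigned[bidx] <- TRUE
  phased[bidx] <- TRUE
  H[cbind(bidx, slotOf[bb$cluster])] <- 1L

  if (length(targets) && nrow(linkage)) {
    q <- .qualifyingLinks(linkage, backbone, lodThreshold)
    q$clg <- clgMap$clg[match(q$cluster, clgMap$cluster)]
    counts <- table(factor(q$marker, levels = targets), q$cluster)
    clgSupport <- table(factor(q$marker, levels = targets), factor(q$clg))
    clgLevels <- as.integer(colnames(clgSupport))
    for (i in seq_along(targets)) {
      sup <- clgSupport[i, ]
      if (!any(sup > 0)) next
      top <- which(sup == max(sup))
      if (length(top) > 1L) next               # conflicting CLG evidence
      g <- clgLevels[top]
      mi <- match(targets[i], markers)
      CLG[mi] <- g
      assigned[mi] <- TRUE
      cl <- clgMap$cluster[clgMap$clg == g]
      cl <- cl[cl %in% colnames(counts)]
      hits <- cl[counts[i, cl] >= minLinks]
      if (length(hits)) {
        H[mi, slotOf[hits]] <- 1L
        nP1 <- sum(H[mi, seq_len(ploidy)])
        nP2 <- sum(H[mi, ploidy + seq_len(ploidy)])
        if (nP1 == pd[mi, 1L] && nP2 == pd[mi, 2L]) {
          phased[mi] <- TRUE
        } else {
          H[mi, ] <- 0L                        # keep assigned, not phased
        }
      }
    }
  }
  map <- data.frame(marker = markers, CLG = CLG, position = NA_real_,
                    H, assigned = assigned, phased = phased,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(map) <- NULL
  new("PhasedMap", map = map, ploidy = as.integer(ploidy))
}
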