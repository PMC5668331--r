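## Multi-allelic QTL analysis on IBD probabilities. At every grid locus the
## phenotype is regressed on the IBD probabilities of the parental
## homologues in an additive fixed-effects model; one homologue per parent
## (the first) is the reference class and is omitted, since each parent
## always transmits ploidy/2 homologues. Significance is assessed with an
## overall model-vs-intercept F test and a permutation-based genome-wide
## threshold. Genotype-class interaction models are deliberately out of
## scope: at ploidy 6 they would need choose(6,3)^2 = 400 parameters.

## residual sums of squares of Ymat's columns after projecting on X
## (with intercept); returns list(rss, df1, df2, flagged)
.rssProjection <- function(X, Ymat) {
  n <- nrow(Ymat)
  Xd <- cbind(1, X)
  qrX <- qr(Xd)
  rank <- qrX$rank
  Q <- qr.Q(qrX)[, seq_len(rank), drop = FALSE]
  rss <- colSums(Ymat^2) - colSums(crossprod(Q, Ymat)^2)
  list(rss = rss, df1 = rank - 1L, df2 = n - rank,
       flagged = rank < ncol(Xd))
}

.scanDesign <- function(A, ploidy) {
  keep <- setdiff(seq_len(2L * ploidy), c(1L, ploidy + 1L))
  A[, , keep, drop = FALSE]
}

#' Multi-allelic QTL genome scan
#'
#' At each grid locus of each CLG, fits the additive model
#' `Y = mu + sum_i alpha_i X_i` where `X_i` is the IBD probability of
#' homologue i and the first homologue of each parent is the reference
#' class (10 allele parameters for a hexaploid), and reports the p-value
#' of the overall model-vs-intercept F test. Missing phenotypes are
#' handled complete-case; rank-deficient designs are fitted on the
#' reduced column space and flagged.
#'
#' @param ibd A gridded [IBDResult-class].
#' @param phenotype Named numeric vector (names = individual ids matching
#'   the IBD arrays; `NA` allowed).
#' @param threshold Optional genome-wide p-value threshold (e.g. from
#'   [permutationThreshold()]) used to set the `significant` flag.
#' @param trait Trait name for display.
#' @return A [QTLScan-class].
#' @export
qtlScan <- function(ibd, phenotype, threshold = NA_real_, trait = "trait") {
  ploidy <- ibd@ploidy
  inds <- dimnames(ibd@arrays[[1L]])[[2L]]
  if (is.null(inds)) inds <- as.character(seq_len(dim(ibd@arrays[[1L]])[2L]))
  common <- intersect(inds, names(phenotype)[!is.na(phenotype)])
  if (length(common) < 30L)
    stop("need at least 30 individuals with both IBD and phenotype data")
  Y <- phenotype[common]
  if (stats::sd(Y) == 0)
    stop("constant phenotype: F statistic undefined")
  Ym <- matrix(Y - mean(Y))
  tss <- sum(Ym^2)
  rows <- list()
  for (g in names(ibd@arrays)) {
    A <- .scanDesign(ibd@arrays[[g]], ploidy)[, match(common, inds), ,
                                              drop = FALSE]
    pos <- ibd@positions[[g]]
    pv <- numeric(length(pos)); fl <- logical(length(pos))
    for (k in seq_along(pos)) {
      X <- A[k, , ]
      pr <- .rssProjection(X, Ym)
      fl[k] <- pr$flagged
      if (pr$df1 < 1L || pr$df2 < 1L || pr$rss < 1e-12 * tss) {
        pv[k] <- NA_real_; fl[k] <- TRUE; next
      }
      Fstat <- ((tss - pr$rss) / pr$df1) / (pr$rss / pr$df2)
      pv[k] <- pf(Fstat, pr$df1, pr$df2, lower.tail = FALSE)
    }
    rows[[g]] <- data.frame(CLG = g, position = pos,
                            neg_log10_p = -log10(pv),
                            df_model = NA_integer_, flagged = fl,
                            p = pv, stringsAsFactors = FALSE)
  }
  scan <- do.call(rbind, rows)
  scan$significant <- !is.na(threshold) & !is.na(scan$p) & scan$p <= threshold
  rownames(scan) <- NULL
  new("QTLScan",
      scan = scan[, c("CLG", "position", "neg_log10_p", "p", "flagged",
                      "significant")],
      threshold = as.numeric(threshold),
      alleleEffects = data.frame(), trait = trait)
}

#' Permutation-based genome-wide significance threshold
#'
#' Shuffles the phenotype across individuals `nPerm` times, runs the full
#' genome scan for each permutation, records the minimum p-value, and
#' returns the `percentile`-th percentile of those minima as the
#' genome-wide p-value threshold. Reproducible given `seed`.
#'
#' @inheritParams qtlScan
#' @param nPerm Number of permutations (default 1000; fewer than 100
#'   triggers a warning about percentile stability).
#' @param percentile Percentile of the ordered minima (default 5).
#' @param seed Integer seed for the permutations.
#' @return Numeric p-value threshold, with attribute `"minima"`.
#' @export
permutationThreshold <- function(ibd, phenotype, nPerm = 1000L,
                                 percentile = 5, seed = NULL) {
  if (nPerm < 100L)
    warning("fewer than 100 permutations: threshold percentile is unstable")
  if (!is.null(seed)) set.seed(seed)
  ploidy <- ibd@ploidy
  inds <- dimnames(ibd@arrays[[1L]])[[2L]]
  if (is.null(inds)) inds <- as.character(seq_len(dim(ibd@arrays[[1L]])[2L]))
  common <- intersect(inds, names(phenotype)[!is.na(phenotype)])
  Y <- phenotype[common]
  n <- length(Y)
  Yperm <- vapply(seq_len(nPerm), function(i) Y[sample.int(n)],
                  numeric(n))
  Yperm <- sweep(Yperm, 2L, colMeans(Yperm))
  tss <- colSums(Yperm^2)
  minp <- rep(1, nPerm)
  for (g in names(ibd@arrays)) {
    A <- .scanDesign(ibd@arrays[[g]], ploidy)[, match(common, inds), ,
                                              drop = FALSE]
    for (k in seq_len(dim(A)[1L])) {
      pr <- .rssProjection(A[k, , ], Yperm)
      if (pr$df1 < 1L || pr$df2 < 1L) next
      Fstat <- ((tss - pr$rss) / pr$df1) / (pr$rss / pr$df2)
      pv <- pf(Fstat, pr$df1, pr$df2, lower.tail = FALSE)
      minp <- pmin(minp, pv)
    }
  }
  out <- unname(quantile(minp, percentile / 100))
  attr(out, "minima") <- minp
  out
}

#' Per-allele effects at one locus
#'
#' For each of the `2 * ploidy` homologues separately, fits the simple
#' linear model `Y = mu + alpha_i X_i` and reports the estimated effect
#' of full presence versus full absence of the allele, with its p-value.
#' Homologues with (near-)constant IBD probabilities are flagged with
#' `NA` effects.
#'
#' @param ibd A gridded [IBDResult-class].
#' @param clg CLG name (as in `names(ibd@arrays)`).
#' @param position Grid position (cM); the closest grid locus is used.
#' @param phenotype Named numeric vector.
#' @return `data.frame` with columns `homologue`, `effect`, `se`, `p`.
#' @export
perAlleleEffects <- function(ibd, clg, position, phenotype) {
  clg <- as.character(clg)
  A <- ibd@arrays[[clg]]
  inds <- dimnames(A)[[2L]]
  if (is.null(inds)) inds <- as.character(seq_len(dim(A)[2L]))
  common <- intersect(inds, names(phenotype)[!is.na(phenotype)])
  Y <- phenotype[common]
  k <- which.min(abs(ibd@positions[[clg]] - position))
  nh <- dim(A)[3L]
  out <- data.frame(homologue = paste0("h", seq_len(nh)),
                    effect = NA_real_, se = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (h in seq_len(nh)) {
    X <- A[k, match(common, inds), h]
    if (stats::sd(X) < 1e-8) next                      # no variance: flagged NA
    fit <- summary(lm(Y ~ X))
    out$effect[h] <- fit$coefficients["X", "Estimate"]
    out$se[h] <- fit$coefficients["X", "Std. Error"]
    out$p[h] <- fit$coefficients["X", "Pr(>|t|)"]
  }
  out
}

#' Proportion of phenotypic variance explained by selected predictors
#'
#' Coefficient of determination (R^2) of the least-squares fit of the
#' phenotype on the given predictor columns (e.g. the dosages of the
#' markers closest to detected QTL, or IBD probability columns).
#'
#' @param predictors Numeric matrix or data.frame, individuals x
#'   predictors.
#' @param phenotype Numeric vector (NA allowed; complete cases used).
#' @return R^2 in `[0, 1]`.
#' @export
varianceExplained <- function(predictors, phenotype) {
  df <- data.frame(y = phenotype, as.data.frame(predictors))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  summary(lm(y ~ ., data = df))$r.squared
}

#' Broad-sense heritability from a trial-replicated design
#'
#' Two-factor fixed-effects ANOVA with trial and genotype
#' (`aov(value ~ trial + genotype)`); the genotypic variance component is
#' `(MS_genotype - MS_residual) / r` with `r` the (mean) number of
#' replicates per genotype, and `H^2 = sigma2_g / (sigma2_g + sigma2_e)`
#' where `sigma2_e` is the residual variance — the genotypic share of the
#' phenotypic variance after removing the fixed trial effect.
#'
#' @param data `data.frame` with columns `genotype`, `trial`, `value`.
#' @return List with `H2`, `sigma2_g`, `sigma2_e`, `MS` (the ANOVA mean
#'   squares).
#' @export
heritability <- function(data) {
  data$genotype <- factor(data$genotype)
  data$trial <- factor(data$trial)
  reps <- table(data$genotype[!is.na(data$value)])
  if (max(reps) < 2L)
    stop("heritability undefined with a single replicate per genotype")
  fit <- aov(value ~ trial + genotype, data = data)
  ms <- anova(fit)[, "Mean Sq"]
  names(ms) <- rownames(anova(fit))
  r <- mean(reps)
  sg <- max(0, (ms[["genotype"]] - ms[["Residuals"]]) / r)
  se <- ms[["Residuals"]]
  list(H2 = sg / (sg + se), sigma2_g = sg, sigma2_e = se, MS = ms)
}

#' Two-locus allele interaction test
#'
#' ANOVA of the interaction between two bi-allelic predictors (e.g. the
#' simplex markers closest to two detected QTL): fits
#' `Y ~ x1 * x2` and reports the interaction term's p-value — the test
#' used to establish that two complementary alleles must both be present
#' for a phenotype.
#'
#' @param x1,x2 Numeric vectors (marker dosages or IBD columns).
#' @param phenotype Numeric vector.
#' @return List with `p_interaction` and the `anova` table.
#' @export
interactionTest <- function(x1, x2, phenotype) {
  df <- data.frame(y = phenotype, x1 = x1, x2 = x2)
  df <- df[stats::complete.cases(df), ]
  a <- anova(lm(y ~ x1 * x2, data = df))
  list(p_interaction = a["x1:x2", "Pr(>F)"], anova = a)
}
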