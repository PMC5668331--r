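# Multi-allelic QTL scan, permutation threshold, per-allele effects,
# variance explained and heritability.

# truth-based IBD grid for one chromosome (exact 0/1 probabilities)
truthIBD <- function(nInd = 200L, lengthCM = 90, seed = 1L) {
  g <- simulateInheritanceGrid(6, nInd, lengthCM, seed = seed)
  dimnames(g$ibd) <- list(NULL, sprintf("F1_%03d", seq_len(nInd)),
                          paste0("h", 1:12))
  new("IBDResult", arrays = list("1" = g$ibd),
      positions = list("1" = g$pos), gic = list(), ploidy = 6L)
}

test_that("the scan peaks at a simulated additive QTL", {
  ib <- truthIBD(nInd = 300L, seed = 51L)
  qpos <- 45L
  X <- ib@arrays[["1"]][qpos + 1L, , 2]          # presence of h2
  set.seed(52)
  y <- setNames(5 * X + rnorm(300), dimnames(ib@arrays[["1"]])[[2]])
  sc <- qtlScan(ib, y)
  peak <- sc@scan$position[which.max(sc@scan$neg_log10_p)]
  expect_lt(abs(peak - qpos), 5)
  expect_gt(max(sc@scan$neg_log10_p), 10)
})

test_that("null phenotypes give approximately uniform p-values", {
  ib <- truthIBD(nInd = 200L, seed = 53L)
  set.seed(54)
  pv <- replicate(40, {
    y <- setNames(rnorm(200), dimnames(ib@arrays[["1"]])[[2]])
    sc <- qtlScan(ib, y)
    sc@scan$neg_log10_p[sample(nrow(sc@scan), 1)]
  })
  expect_gt(ks.test(10^(-pv), "punif")$p.value, 0.01)
})

test_that("constant phenotypes and tiny overlaps are rejected", {
  ib <- truthIBD(nInd = 40L, seed = 55L)
  inds <- dimnames(ib@arrays[["1"]])[[2]]
  expect_error(qtlScan(ib, setNames(rep(1, 40), inds)), "constant")
  expect_error(qtlScan(ib, setNames(rnorm(10), inds[1:10])), "at least 30")
})

test_that("permutation threshold is reproducible and respects its definition", {
  ib <- truthIBD(nInd = 120L, seed = 56L)
  set.seed(57)
  y <- setNames(rnorm(120), dimnames(ib@arrays[["1"]])[[2]])
  t1 <- permutationThreshold(ib, y, nPerm = 120L, seed = 7L)
  t2 <- permutationThreshold(ib, y, nPerm = 120L, seed = 7L)
  expect_identical(as.numeric(t1), as.numeric(t2))
  expect_warning(permutationThreshold(ib, y, nPerm = 50L, seed = 7L),
                 "permutations")
  tAll <- permutationThreshold(ib, y, nPerm = 120L, percentile = 100,
                               seed = 7L)
  expect_equal(as.numeric(tAll), max(attr(tAll, "minima")))
  expect_gte(as.numeric(tAll), as.numeric(t1))
})

test_that("per-allele effects recover simulated effects and signs", {
  ib <- truthIBD(nInd = 300L, seed = 58L)
  inds <- dimnames(ib@arrays[["1"]])[[2]]
  X2 <- ib@arrays[["1"]][46, , 2]
  X3 <- ib@arrays[["1"]][46, , 3]
  set.seed(59)
  y <- setNames(2 * X2 - 2 * X3 + rnorm(300), inds)
  eff <- perAlleleEffects(ib, "1", 45, y)
  expect_lt(abs(eff$effect[2] - 2), 2 * eff$se[2])
  expect_lt(abs(eff$effect[3] + 2), 2 * eff$se[3])
  expect_lt(eff$p[2], 1e-6)
  expect_gt(min(eff$p[7:12]), 1e-4)       # other parent: no signal
  # constant predictor flagged NA
  ib2 <- ib
  ib2@arrays[["1"]][46, , 5] <- 0.5
  expect_true(is.na(perAlleleEffects(ib2, "1", 45, y)$effect[5]))
})

test_that("variance explained behaves like R^2", {
  set.seed(60)
  x <- rbinom(200, 1, 0.5)
  expect_equal(suppressWarnings(varianceExplained(cbind(x), as.numeric(x))), 1)
  expect_lt(varianceExplained(cbind(x), rnorm(200)), 0.05)
  # AND epistasis: two-marker additive fit explains much but not all
  x2 <- rbinom(200, 1, 0.5)
  y <- as.numeric(x & x2) + rnorm(200, sd = 0.1)
  r2 <- varianceExplained(cbind(x, x2), y)
  expect_gt(r2, 0.4)
  expect_lt(r2, 0.9)
  expect_lt(interactionTest(x, x2, y)$p_interaction, 1e-10)
})

test_that("heritability recovers the simulated value", {
  # exact case: no residual variance
  d0 <- data.frame(genotype = rep(1:20, each = 2), trial = rep(1:2, 20),
                   value = rep(rnorm(20), each = 2))
  expect_equal(suppressWarnings(heritability(d0))$H2, 1, tolerance = 1e-9)
  expect_error(heritability(d0[!duplicated(d0$genotype), ]), "replicate")
  # H2 = 0.7 at 400 genotypes x 3 trials
  set.seed(61)
  ng <- 400L
  gvals <- rnorm(ng, sd = sqrt(0.7))
  d <- expand.grid(genotype = seq_len(ng), trial = 1:3)
  d$value <- gvals[d$genotype] + c(0, 1, -1)[d$trial] +
    rnorm(nrow(d), sd = sqrt(0.3))
  expect_lt(abs(heritability(d)$H2 - 0.7), 0.05)
  # pure noise
  set.seed(62)
  d$value <- rnorm(nrow(d))
  expect_lt(heritability(d)$H2, 0.1)
})
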