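# Haldane transforms, weighted-MDS ordering, nearest-neighbour fit,
# iterative marker removal and the same-contig diagnostic.

# exact pairwise linkage table for markers at given true positions
chainLinkage <- function(pos, lod = 50) {
  cmb <- combn(seq_along(pos), 2)
  data.frame(marker1 = names(pos)[cmb[1, ]], marker2 = names(pos)[cmb[2, ]],
             r = haldane(abs(pos[cmb[1, ]] - pos[cmb[2, ]])),
             LOD = lod, phase1 = 1L, phase2 = 0L,
             stringsAsFactors = FALSE)
}

test_that("Haldane function matches its closed form and round-trips", {
  expect_lt(abs(haldane(5) - 0.047), 1e-3)   # printed value is truncated
  expect_equal(haldane(0), 0)
  expect_equal(haldaneInverse(0.25), -50 * log(0.5))
  expect_equal(haldane(haldaneInverse(0.25)), 0.25, tolerance = 1e-12)
  expect_lt(haldane(500), 0.5)
  expect_lte(haldane(1e6), 0.5)
  expect_error(haldaneInverse(0.5), "r must be")
  expect_error(haldane(-1), ">= 0")
})

test_that("a three-marker additive chain orders correctly", {
  pos <- c(a = 0, b = 5, c = 10)
  om <- orderCLG(chainLinkage(pos), names(pos))
  est <- setNames(om$map$position, om$map$marker)
  if (est["a"] > est["c"]) est <- max(est) - est   # orientation-free
  expect_equal(unname(est[c("a", "b", "c")]), c(0, 5, 10), tolerance = 0.5)
})

test_that("a dense additive chain is recovered with tau = 1 and zero nn-fit", {
  pos <- setNames(seq(0, 78, by = 2), sprintf("m%02d", 1:40))
  om <- orderCLG(chainLinkage(pos), names(pos))
  est <- setNames(om$map$position, om$map$marker)
  expect_equal(abs(cor(est, pos, method = "kendall")), 1)
  expect_lt(abs(max(est) - 78), 4)
  nf <- nnFit(est, chainLinkage(pos))
  expect_lt(max(nf$fits$fit), 0.7)
  expect_equal(nf$total, sum(nf$fits$fit))
})

test_that("reversing marker input yields the same map up to reversal", {
  pos <- setNames(seq(0, 58, by = 2), sprintf("m%02d", 1:30))
  lk <- chainLinkage(pos)
  f <- orderCLG(lk, names(pos))
  r <- orderCLG(lk, rev(names(pos)))
  pf <- setNames(f$map$position, f$map$marker)[names(pos)]
  pr <- setNames(r$map$position, r$map$marker)[names(pos)]
  if (cor(pf, pr) < 0) pr <- max(pr) - pr
  expect_equal(abs(cor(pf, pr, method = "kendall")), 1)
  expect_lt(max(abs(pf - pr)), 3)
})

test_that("a displaced marker gets the highest nn-fit and is removed", {
  pos <- setNames(seq(0, 78, by = 2), sprintf("m%02d", 1:40))
  lk <- chainLinkage(pos)
  # marker m20 pretends to sit 12 cM away from its neighbours
  bad <- lk$marker1 == "m20" | lk$marker2 == "m20"
  lk$r[bad] <- haldane(pmin(
    abs(pos[lk$marker1[bad]] + 12 - pos[lk$marker2[bad]]), 150))
  om <- orderCLG(lk, names(pos))
  nf <- nnFit(setNames(om$map$position, om$map$marker), lk)
  expect_identical(nf$fits$marker[which.max(nf$fits$fit)], "m20")
  it <- iterateOrdering(lk, names(pos))
  expect_true("m20" %in% it$removed$marker)
  expect_lte(max(it$removed$round), 2L)
  expect_false("m20" %in% it$map$marker)
})

test_that("iterative ordering terminates on a clean chain without removals", {
  pos <- setNames(seq(0, 38, by = 2), sprintf("m%02d", 1:20))
  it <- iterateOrdering(chainLinkage(pos), names(pos))
  expect_identical(it$rounds, 1L)
  expect_identical(nrow(it$removed), 0L)
})

test_that("disconnected linkage input is rejected with advice", {
  pos1 <- c(a = 0, b = 2, c = 4); pos2 <- c(x = 0, y = 2, z = 4)
  lk <- rbind(chainLinkage(pos1), chainLinkage(pos2))
  expect_error(orderCLG(lk, c(names(pos1), names(pos2))), "re-cluster")
})

test_that("same-contig RMSE splits by homologue and matches closed forms", {
  map <- data.frame(
    marker = c("a1", "a2", "b1", "b2", "c1", "c2"),
    CLG = 1L, position = c(10, 10, 20, 23, 30, 30),
    h1 = c(1L, 1L, 1L, 0L, 1L, 0L),
    h2 = c(0L, 0L, 0L, 1L, 0L, 1L),
    stringsAsFactors = FALSE)
  contigs <- setNames(c("c01", "c01", "c02", "c02", "c03", "c03"), map$marker)
  types <- setNames(rep("1x0", 6), map$marker)
  out <- sameContigRMSE(map, contigs, types)
  all <- out[out$CLG == "all", ]
  expect_equal(all$rmse_same, 0)                  # co-located, same homologue
  expect_equal(all$rmse_diff, sqrt(mean(c(3, 0)^2)))  # 3 cM and 0 cM pairs
  expect_identical(all$n_same, 1L)
  expect_identical(all$n_diff, 2L)
  # no same-contig pairs -> empty diagnostic, not an error
  empty <- sameContigRMSE(map, setNames(as.character(1:6), map$marker), types)
  expect_identical(nrow(empty), 0L)
})

test_that("ordering a simulated CLG reaches high rank concordance", {
  sim <- smallMapSim()
  # markers of chromosome 1 with their true phase known
  mt <- sim$design$markerTable
  mk <- mt$marker[mt$chrom == 1]
  lk <- pairwiseLinkage(sim$dosage, mk)
  it <- iterateOrdering(lk, mk)
  est <- setNames(it$map$position, it$map$marker)
  truth <- setNames(mt$pos, mt$marker)[names(est)]
  expect_gt(abs(cor(est, truth, method = "kendall")), 0.9)
  # map length within 25% on this small population
  expect_lt(abs(max(est) - 80) / 80, 0.25)
})
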