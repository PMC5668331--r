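# Marker/individual quality filters and duplicate binning.

test_that("segregation chi-square test matches hand calculation", {
  # 1x0 marker, 180/220 of n = 400 against the 200/200 expectation
  row <- c(rep(0L, 180), rep(1L, 220))
  st <- segregationTest(row, 6, 1, 0)
  expect_equal(st$statistic, 4)
  expect_equal(st$df, 1L)
  expect_equal(st$p.value, pchisq(4, 1, lower.tail = FALSE))
  expect_gt(st$p.value, 0.001)   # retained at the skew threshold

  # exact expectation -> statistic 0, p 1
  st0 <- segregationTest(c(rep(0L, 200), rep(1L, 200)), 6, 1, 0)
  expect_equal(st0$statistic, 0)
  expect_equal(st0$p.value, 1)

  # fully one-sided segregation is skewed beyond any threshold
  st1 <- segregationTest(rep(0L, 400), 6, 1, 0)
  expect_equal(st1$statistic, 400)
  expect_lt(st1$p.value, 1e-10)

  # impossible dosage class -> infinite statistic
  expect_equal(segregationTest(c(0L, 1L, 5L), 6, 1, 0)$p.value, 0)
  expect_error(segregationTest(c(NA_integer_, NA_integer_), 6, 1, 0),
               "missing")
})

test_that("marker filter removes non-segregating, missing and skewed markers", {
  n <- 400L
  d <- rbind(
    good   = rep(c(0L, 1L), n / 2),
    miss   = c(rep(NA_integer_, 24), rep(c(0L, 1L), (n - 24) / 2)),  # 6%
    fixed  = rep(3L, n),
    skewed = rep(0L, n)
  )
  colnames(d) <- paste0("i", seq_len(n))
  dm <- DosageMatrix(d, p1 = c(1L, 1L, 6L, 1L), p2 = c(0L, 0L, 0L, 0L))
  fm <- filterMarkers(dm)
  expect_identical(rownames(fm$matrix), "good")
  expect_identical(fm$report$reason[fm$report$marker == "miss"], "missing")
  expect_identical(fm$report$reason[fm$report$marker == "fixed"],
                   "non_segregating")
  expect_identical(fm$report$reason[fm$report$marker == "skewed"], "skewed")
  # idempotent
  fm2 <- filterMarkers(fm$matrix)
  expect_identical(dosages(fm2$matrix), dosages(fm$matrix))
  expect_identical(nrow(fm2$report), 0L)
})

test_that("individual filter flags missingness and cross-incompatible dosages", {
  set.seed(1)
  nm <- 60L
  d <- matrix(rbinom(nm * 10L, 1L, 0.5), nm, 10L,
              dimnames = list(sprintf("m%02d", 1:nm), sprintf("i%02d", 1:10)))
  storage.mode(d) <- "integer"
  d[seq_len(ceiling(0.12 * nm)), 2L] <- NA            # 12% missing
  d[seq_len(20L), 3L] <- 2L                           # dosage 2 at 1x0 markers
  dm <- DosageMatrix(d, p1 = rep(1L, nm), p2 = rep(0L, nm))
  fi <- filterIndividuals(dm)
  expect_setequal(fi$report$individual, c("i02", "i03"))
  expect_identical(fi$report$reason[fi$report$individual == "i02"], "missing")
  expect_identical(fi$report$reason[fi$report$individual == "i03"],
                   "incompatible")
  expect_true("i01" %in% colnames(fi$matrix))
})

test_that("duplicate binning partitions markers and picks least-missing representatives", {
  d <- rbind(
    a = c(0L, 1L, 0L, 1L),
    b = c(0L, 1L, 0L, 1L),          # identical to a
    c = c(0L, 1L, 1L, 1L),          # differs at one individual
    d = c(NA, 1L, 0L, 1L)           # identical to a on shared entries
  )
  colnames(d) <- paste0("i", 1:4)
  dm <- DosageMatrix(d, p1 = rep(1L, 4), p2 = rep(0L, 4))
  bins <- binDuplicates(dm)
  expect_identical(bins$bin[bins$marker == "a"], bins$bin[bins$marker == "b"])
  expect_identical(bins$bin[bins$marker == "a"], bins$bin[bins$marker == "d"])
  expect_false(bins$bin[bins$marker == "c"] == bins$bin[bins$marker == "a"])
  # every marker in exactly one bin; representative has fewest NAs
  expect_identical(anyDuplicated(bins$marker), 0L)
  repA <- bins$marker[bins$representative & bins$bin == bins$bin[1]]
  expect_true(repA %in% c("a", "b"))
  # one representative per bin
  expect_true(all(tapply(bins$representative, bins$bin, sum) == 1L))
})

test_that("greedy binning with missing data follows the pairwise-compatibility graph", {
  # x ~ y and y ~ z on shared entries, but x and z differ: greedy order
  # puts x first, y joins x's bin, z starts a new bin
  d <- rbind(
    x = c(0L, 1L, NA, 1L),
    y = c(0L, 1L, 1L, 1L),
    z = c(NA, 1L, 1L, 0L)
  )
  colnames(d) <- paste0("i", 1:4)
  dm <- DosageMatrix(d, p1 = rep(1L, 3), p2 = rep(0L, 3))
  bins <- binDuplicates(dm)
  expect_identical(bins$bin[1], bins$bin[2])
  expect_false(bins$bin[3] == bins$bin[1])
})
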