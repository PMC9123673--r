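test_that("Haldane function matches closed forms and inverts exactly", {
  expect_equal(haldaneCM(0), 0)
  expect_equal(haldaneCM(0.25), -50 * log(0.5))
  expect_equal(haldaneCM(0.25), 34.657, tolerance = 1e-4)
  r <- seq(0.01, 0.45, by = 0.02)
  expect_equal(haldaneR(haldaneCM(r)), r, tolerance = 1e-12)
  # capping keeps distances finite
  expect_equal(haldaneCM(0.6), haldaneCM(0.49))
  expect_true(is.finite(haldaneCM(0.5)))
  # monotone
  expect_true(all(diff(haldaneCM(seq(0, 0.49, 0.01))) > 0))
})

test_that("two-point recombination estimates are direct ratios", {
  a <- c(1L, 1L, 2L, 2L, NA, 1L)
  b <- c(1L, 2L, 2L, NA, 1L, 1L)
  est <- estimateR(a, b)
  expect_equal(est$N, 4)
  expect_equal(est$R, 1)
  expect_equal(est$rHat, 0.25)
  expect_equal(estimateR(a, a)$rHat, 0)
  expect_true(is.na(estimateR(a, rep(NA_integer_, 6))$rHat))
})

test_that("two-point LOD closed forms set the linkage-group boundary", {
  expect_equal(twoPointLOD(5, 10), 0)        # rHat = 0.5
  expect_equal(twoPointLOD(0, 17), 17 * log10(2))
  expect_gte(twoPointLOD(0, 17), 5)
  expect_equal(twoPointLOD(0, 16), 16 * log10(2))
  expect_lt(twoPointLOD(0, 16), 5)
  expect_true(is.na(twoPointLOD(0, 0)))
})

test_that("LOD filter separates linked from unlinked markers", {
  # 200 gametes, 12 truly linked markers (r = 0.05 chain) plus one marker
  # recombining freely against all others
  set.seed(81)
  n <- 200
  S <- matrix(NA_integer_, n, 13)
  S[, 1] <- sample(1:2, n, replace = TRUE)
  for (j in 2:12)
    S[, j] <- ifelse(runif(n) < 0.05, 3L - S[, j - 1], S[, j - 1])
  S[, 13] <- sample(1:2, n, replace = TRUE)
  gs <- list(states = S,
             markers = data.frame(marker = paste0("m", 1:13), chrom = "1",
                                  bp = 1:13 * 1e6),
             gametes = data.frame(parentSex = rep(c("M", "F"), n / 2)))
  lf <- lodLinkageFilter(gs, lodMin = 5, window = 12)
  expect_true(all(lf$keep[1:12]))
  expect_false(lf$keep[13])
})

test_that("adjacent-interval estimates recover the Haldane fraction", {
  # one 100 cM chromosome, markers 1 cM apart, 1e4 gametes, no interference
  set.seed(82)
  nm <- 101
  chrom <- rep(1L, nm); cm <- 0:100
  h <- rep(0L, nm)
  S <- matrix(NA_integer_, 1e4, nm)
  for (i in seq_len(1e4)) {
    t <- rnorm(1, 1, sqrt(0.25))
    S[i, ] <- simulateMeiosis(h, h, chrom, cm, 100, targetAcc = t,
                              nu = 1)$origin
  }
  rhat <- vapply(seq_len(nm - 1), function(j) mean(S[, j] != S[, j + 1]),
                 0)
  target <- haldaneR(1)  # 0.00990
  se <- sqrt(target * (1 - target) / (1e4 * (nm - 1)))
  expect_lt(abs(mean(rhat) - target), 3 * se + 2e-4)
})

test_that("Haldane distances are additive without interference", {
  set.seed(83)
  nm <- 3
  chrom <- rep(1L, nm); cm <- c(0, 10, 20)
  h <- rep(0L, nm)
  S <- matrix(NA_integer_, 2e4, nm)
  for (i in seq_len(2e4)) {
    t <- rnorm(1, 2, sqrt(2))
    S[i, ] <- simulateMeiosis(h, h, chrom, cm, 100, targetAcc = t,
                              nu = 1)$origin
  }
  d12 <- haldaneCM(estimateR(S[, 1], S[, 2])$rHat)
  d23 <- haldaneCM(estimateR(S[, 2], S[, 3])$rHat)
  d13 <- haldaneCM(estimateR(S[, 1], S[, 3])$rHat)
  expect_equal(d13, d12 + d23, tolerance = 0.06)
})

test_that("map assembly closed forms hold", {
  # single interval with rHat 0.1 -> -50 log(0.8) = 11.157 cM
  mkGs <- function(S) list(
    states = S,
    markers = data.frame(marker = c("a", "b"), chrom = "1", bp = c(1, 2e6)),
    gametes = data.frame(parentSex = rep("F", nrow(S))))
  S <- cbind(rep(1L, 100), c(rep(2L, 10), rep(1L, 90)))
  m <- buildMaps(mkGs(S))
  expect_s4_class(m, "SexLinkageMap")
  expect_equal(mapTotals(m)[["female"]], -50 * log(0.8), tolerance = 1e-10)
  expect_equal(mapTotals(m)[["female"]], 11.157, tolerance = 1e-3)
  expect_equal(mapPositions(m)$cmFemale, c(0, -50 * log(0.8)))
  # all-identical states: zero-length map
  m0 <- buildMaps(mkGs(cbind(rep(1L, 50), rep(1L, 50))))
  expect_equal(mapTotals(m0)[["female"]], 0)
  # monotonicity: adding a recombinant gamete never shrinks the map
  S2 <- rbind(S, c(1L, 2L))
  m2 <- buildMaps(mkGs(S2))
  expect_gte(mapTotals(m2)[["female"]], mapTotals(m)[["female"]])
})

test_that("per-marker cM positions are zero-based and non-decreasing", {
  lmap <- buildMaps(stdGametes())
  mp <- mapPositions(lmap)
  for (c in unique(mp$chrom)) {
    sub <- mp[mp$chrom == c, ]
    expect_equal(sub$cmMale[1], 0)
    expect_equal(sub$cmFemale[1], 0)
    expect_true(all(diff(sub$cmMale) >= 0))
    expect_true(all(diff(sub$cmFemale) >= 0))
  }
  # chromosome totals = last marker's cumulative position
  ms <- mapSummary(lmap)
  last <- vapply(split(mp$cmFemale, mp$chrom), function(x) x[length(x)], 0)
  expect_equal(as.numeric(last[ms$chrom]), ms$cmFemale)
  # landscape mass equals chromosome totals
  ld <- mapLandscape(lmap)
  massF <- tapply(ld$cmPerMbFemale * (ld$windowEnd - ld$windowStart + 1) / 1e6,
                  ld$chrom, sum)
  expect_equal(as.numeric(massF[ms$chrom]), ms$cmFemale,
               tolerance = 1e-6)
})

test_that("interval recombinants are consistent with called crossovers", {
  gs <- stdGametes()
  S <- gs$states
  mk <- gs$markers
  # per gamete: number of state switches across informative neighbours
  # equals the called ACC (switch calling operates on the cleaned states)
  for (i in seq_len(25)) {
    sw <- 0
    for (c in unique(mk$chrom)) {
      v <- S[i, mk$chrom == c]
      v <- v[!is.na(v)]
      if (length(v) > 1) sw <- sw + sum(diff(v) != 0)
    }
    expect_gte(sw, gs$gametes$acc[i])
  }
})
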