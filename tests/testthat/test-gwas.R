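test_that("GRM entries follow pedigree expectations", {
  # identical genotype vectors: off-diagonal equals diagonal
  gd <- simulateFounderGenotypes(200, 2000, seed = 101)
  g <- genotypes(gd)
  g[2, ] <- g[1, ]
  gd2 <- GenotypeData(g, markerInfo(gd))
  G <- computeGRM(gd2)
  expect_equal(G[1, 2], G[1, 1], tolerance = 1e-12)
  # unrelated founders: mean off-diagonal near zero (sample-frequency
  # centring biases it by about -1/n), diagonal near one
  G0 <- computeGRM(gd)
  off <- G0[upper.tri(G0)]
  expect_lt(abs(mean(off)), 1 / 200 + 3 / sqrt(200 * 2000))
  expect_equal(mean(diag(G0)), 1, tolerance = 0.1)
  # parent-offspring pairs near 0.5 with base-population frequencies
  sim <- stdSim()
  fams <- buildFamilies(sim$pedigree, sampleIds(sim$genotypes))
  founders <- sim$pedigree$id[sim$pedigree$generation == 1]
  pf <- colMeans(genotypes(sim$genotypes)[founders, ], na.rm = TRUE) / 2
  Gp <- computeGRM(sim$genotypes, freqs = pf)
  po <- vapply(seq_len(40), function(i)
    Gp[fams$sire[i], fams$genotypedOffspring[[i]][1]], 0)
  expect_lt(abs(mean(po) - 0.5), 0.08)
})

test_that("sparsification zeroes strictly-below-threshold entries only", {
  set.seed(102)
  G <- matrix(runif(2500, -0.1, 0.2), 50, 50)
  G <- (G + t(G)) / 2; diag(G) <- 1
  G[1, 2] <- G[2, 1] <- 0.05    # exactly at the cut-off: kept
  G[1, 3] <- G[3, 1] <- 0.049   # below: zeroed
  Gs <- as.matrix(sparsifyGRM(G, cutoff = 0.05))
  expect_equal(Gs[1, 2], 0.05)
  expect_equal(Gs[1, 3], 0)
  expect_equal(diag(Gs), diag(G), ignore_attr = TRUE)
  # zeroed count agrees with brute-force enumeration
  expect_equal(sum(Gs == 0) - sum(G == 0),
               sum(G < 0.05 & row(G) != col(G) & G != 0))
  # identity stays identity
  expect_equal(as.matrix(sparsifyGRM(diag(10))), diag(10),
               ignore_attr = TRUE)
})

test_that("PVE formula matches its algebraic simplification and bounds", {
  set.seed(103)
  maf <- runif(200, 0.01, 0.5)
  beta <- rnorm(200); se <- runif(200, 0.01, 1); n <- 5000
  expect_equal(pve(maf, beta, se, n),
               100 * beta^2 / (beta^2 + n * se^2), tolerance = 1e-12)
  expect_true(all(pve(maf, beta, se, n) >= 0 &
                    pve(maf, beta, se, n) <= 100))
  expect_equal(pve(0.3, 0, 0.1, 1000), 0)
  # monotone: increasing |beta| raises PVE, increasing SE lowers it
  expect_true(all(diff(pve(0.2, seq(0, 2, 0.1), 0.1, 1000)) > 0 |
                    seq(0, 2, 0.1)[-1] == 0))
  expect_true(all(diff(pve(0.2, 1, seq(0.05, 1, 0.05), 1000)) < 0))
  expect_true(is.na(pve(0, 1, 0.1, 100)))
})

test_that("significance threshold is 0.05 over the marker count", {
  expect_equal(significanceThreshold(50000), 1e-6)
  expect_equal(significanceThreshold(1), 0.05)
  # flags agree with brute force on a toy table
  set.seed(104)
  gd <- simulateFounderGenotypes(150, 300, seed = 104)
  y <- setNames(rnorm(150), sampleIds(gd))
  res <- fastgwaFit(y, gd, nPcs = 2)
  expect_equal(res$SIGNIF, res$P < 0.05 / nrow(res))
})

test_that("diagonal GRM with no PCs reduces exactly to OLS", {
  gd <- simulateFounderGenotypes(120, 40, seed = 105)
  set.seed(105)
  y <- setNames(rnorm(120, 10, 2), sampleIds(gd))
  res <- fastgwaFit(y, gd, nPcs = 0, grm = diag(120))
  g <- genotypes(gd)
  for (k in c(1, 7, 20, 40)) {
    sm <- summary(lm(y ~ g[, res$SNP[k]]))$coefficients
    expect_equal(res$BETA[k], sm[2, 1], tolerance = 1e-8)
    expect_equal(res$SE[k], sm[2, 2], tolerance = 1e-8)
    expect_equal(res$P[k], sm[2, 4], tolerance = 1e-8)
  }
})

test_that("allele-label flipping only changes the sign of the effect", {
  gd <- simulateFounderGenotypes(150, 30, seed = 106)
  set.seed(106)
  y <- setNames(rnorm(150), sampleIds(gd))
  res1 <- fastgwaFit(y, gd, nPcs = 0)
  g2 <- genotypes(gd)
  g2[, 5] <- 2L - g2[, 5]
  res2 <- fastgwaFit(y, GenotypeData(g2, markerInfo(gd)), nPcs = 0)
  expect_equal(res2$BETA[5], -res1$BETA[5], tolerance = 1e-6)
  expect_equal(res2$SE[5], res1$SE[5], tolerance = 1e-6)
  expect_equal(res2$P[5], res1$P[5], tolerance = 1e-6)
  expect_equal(res2$PVE_PCT[5], res1$PVE_PCT[5], tolerance = 1e-6)
})

test_that("each FID contributes one response value regardless of gametes", {
  acc <- data.frame(
    fid = c("a", "a", "a", "b", "c", "c"),
    offspring = paste0("o", 1:6), parentSex = "F",
    acc = c(20, 22, 24, 30, 10, 50), qcPass = TRUE)
  y <- meanAccPerFid(acc)
  expect_equal(y, c(a = 22, b = 30, c = 30))
  # QC-failing gametes are excluded from the mean
  acc$qcPass[6] <- FALSE
  expect_equal(meanAccPerFid(acc)[["c"]], 10)
})
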