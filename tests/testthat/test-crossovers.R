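test_that("phasing is forced exactly where Mendelian rules decide it", {
  # FID het, father hom A, mother hom B: paternal allele is A (0)
  ph <- phaseFID(1L, 0L, 2L)
  expect_equal(ph$pat, 0L)
  # father hom B
  expect_equal(phaseFID(1L, 2L, 0L)$pat, 1L)
  # father het, mother hom: mother's contribution pins the other haplotype
  expect_equal(phaseFID(1L, 1L, 0L)$pat, 1L)
  # both parents het: unknown
  ph2 <- phaseFID(1L, 1L, 1L)
  expect_true(is.na(ph2$pat))
  expect_false(ph2$phased)
  # homozygous FID: phase-trivial, not usable for crossover detection
  expect_true(is.na(phaseFID(0L, 0L, 0L)$pat))
  # Mendelian inconsistency counted and left unphased
  ph3 <- phaseFID(1L, 0L, 0L)
  expect_equal(ph3$nMendel, 1)
  expect_true(is.na(ph3$pat))
})

test_that("transmission states are deduced with mate information", {
  ph <- phaseFID(1L, 0L, 2L)  # hap1 (grandpaternal) carries allele 0
  # offspring hom: direct
  expect_equal(inferTransmission(ph, 1L, 0L, 1L)[1], 1L)
  expect_equal(inferTransmission(ph, 1L, 2L, 1L)[1], 2L)
  # offspring het, mate hom B: FID sent 0 -> hap1
  expect_equal(inferTransmission(ph, 1L, 1L, 2L)[1], 1L)
  # offspring het, mate hom A: FID sent 1 -> hap2
  expect_equal(inferTransmission(ph, 1L, 1L, 0L)[1], 2L)
  # offspring het, mate het: ambiguous
  expect_true(is.na(inferTransmission(ph, 1L, 1L, 1L)[1]))
  # Mendelian-inconsistent offspring: unknown, counted
  st <- inferTransmission(ph, 1L, 2L, 0L)
  expect_true(is.na(st[1]))
  expect_gt(attr(st, "mendelRate"), 0)
})

test_that("switch calling localises crossovers and reverts singletons", {
  bp <- (1:5) * 100
  ch <- rep("1", 5)
  cc <- callCrossovers(c(1L, 1L, 1L, 2L, 2L), ch, bp)
  expect_equal(cc$acc, 1)
  expect_equal(cc$intervals$startBp, 300)
  expect_equal(cc$intervals$endBp, 400)
  # singleton flip reverted
  cc2 <- callCrossovers(c(1L, 1L, 2L, 1L, 1L), ch, bp, minSupport = 2)
  expect_equal(cc2$acc, 0)
  # with minSupport = 1 it would count two crossovers
  cc3 <- callCrossovers(c(1L, 1L, 2L, 1L, 1L), ch, bp, minSupport = 1)
  expect_equal(cc3$acc, 2)
  # unknowns are skipped, crossover spans the informative gap
  cc4 <- callCrossovers(c(1L, 1L, NA, 2L, 2L), ch, bp)
  expect_equal(cc4$acc, 1)
  expect_equal(cc4$intervals$startBp, 200)
  expect_equal(cc4$intervals$endBp, 400)
  # an unsupported leading run is reverted like any other short run
  cc4b <- callCrossovers(c(1L, NA, NA, 2L, 2L), ch, bp)
  expect_equal(cc4b$acc, 0)
  # chromosomes with < 2 informative markers contribute zero
  cc5 <- callCrossovers(c(1L, NA, NA, NA, NA), ch, bp)
  expect_equal(cc5$acc, 0)
})

test_that("error-free fully informative gametes are called exactly", {
  cfg <- simConfig(markersPerChrom = 100, seed = 71)
  oc <- accCallOracle(150, cfg)
  expect_true(all(oc$calledAcc == oc$trueAcc))
})

test_that("phased alleles equal the true transmitted grandparental alleles", {
  sim <- stdSim()
  ped <- sim$pedigree
  g <- genotypes(sim$genotypes)
  fids <- ped[ped$generation == 2, ][1:10, ]
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  for (i in seq_len(nrow(fids))) {
    fid <- fids$id[i]
    ph <- phaseFID(g[fid, ], g[fids$sire[i], ], g[fids$dam[i], ])
    expect_equal(ph$nMendel, 0)
    # hap1 is the paternal gamete = H1 row of the FID in the simulator
    trueH1 <- sim$haplotypes$H1[idx[fid], ]
    ok <- ph$phased
    expect_gt(mean(ok), 0.15)        # most het markers phase
    expect_gt(ph$fracPhased, 0.5)
    expect_equal(ph$pat[ok], trueH1[ok])
  }
})

test_that("called ACC never exceeds truth and matches it at high density", {
  sim <- stdSim()
  gs <- stdGametes()
  ta <- trueAccFor(sim, gs$gametes)
  expect_true(all(gs$gametes$acc <= ta))
  expect_gt(mean(gs$gametes$acc == ta), 0.85)
  # per-sex means within 2% of the configured 18 / 23
  for (sx in c("M", "F")) {
    mu <- if (sx == "M") 18 else 23
    expect_equal(mean(gs$gametes$acc[gs$gametes$parentSex == sx]), mu,
                 tolerance = 0.02)
  }
  # state sequences agree with true grandparental origin wherever informative
  expect_equal(nrow(gs$gametes), 2 * 150)
})

test_that("ACC phenotype filter applies the 6-50 boundary semantics", {
  tab <- data.frame(fid = "f", offspring = paste0("o", 1:5),
                    parentSex = "F", acc = c(5, 6, 20, 50, 51))
  out <- collectACC(tab)
  expect_equal(out$qcPass, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  summ <- attr(out, "summary")
  expect_equal(summ$n, 3)
  # empty input: empty table, no error
  e <- collectACC(tab[0, ])
  expect_equal(nrow(e), 0)
  expect_equal(nrow(attr(e, "summary")), 0)
})

test_that("almost no gametes are lost to the ACC filter at realistic settings", {
  # female-type gametes: mean 24.4, SD 4.6 -> P(acc < 6 or > 50) ~ 3e-5
  p <- pnorm(5.5, 24.4, 4.6) + pnorm(50.5, 24.4, 4.6, lower.tail = FALSE)
  expect_lt(p, 0.01)
  sim <- stdSim()
  out <- collectACC(stdGametes())
  expect_gt(mean(out$qcPass), 0.99)
})
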