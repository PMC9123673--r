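test_that("simulated pedigrees have the polygynous three-generation shape", {
  ped <- simulatePedigree(simConfig(nSires = 2, nDams = 10,
                                    offspringPerMating = 5, seed = 1))
  expect_gte(nrow(ped), 2 + 10 + 50)
  expect_equal(sum(ped$generation == 1), 12)
  # every non-founder's sire is male and dam is female
  nf <- ped[ped$sire != "0", ]
  sx <- setNames(ped$sex, ped$id)
  expect_true(all(sx[nf$sire] == "M"))
  expect_true(all(sx[nf$dam] == "F"))
  expect_true(all(ped$age[ped$generation > 1] %in% 1:4))
  # sires reused across many dams
  expect_gte(max(table(nf$sire)), 5 * 5)
  # at least 10 extractable full-sib families (all individuals "genotyped")
  fam <- buildFamilies(ped, ped$id)
  expect_gte(nrow(fam), 10)
  # acyclic: checkPedigree (via buildFamilies) did not error, and a
  # topological order exists
  expect_silent(pedigreeInbreeding(ped))
})

test_that("impossible pedigree shapes are rejected", {
  expect_error(simConfig(nSires = 0), "sire")
  expect_error(simConfig(founderMafRange = c(0, 0.5)), "founderMafRange")
  expect_error(simConfig(obligate = TRUE, muAccMale = 10), "obligate")
  expect_error(simConfig(interferenceNu = 0), "interferenceNu")
})

test_that("commercial-scale family sizes span the published 1-18 range", {
  # Duroc-like shape at reduced scale: few sires, many dams, variable litters
  ped <- simulatePedigree(simConfig(nSires = 19, nDams = 169,
                                    offspringPerMating = 4,
                                    litterRange = c(1, 18), seed = 3))
  fam <- buildFamilies(ped, ped$id)
  g3 <- fam$nOffspring[fam$sire %in% ped$id[ped$generation == 2]]
  expect_true(all(g3 >= 1 & g3 <= 18))
  expect_gt(length(unique(g3)), 5)  # genuinely variable litter sizes
})

test_that("breeding values follow the pedigree-Gaussian model", {
  # founder variance: 1e4 founders
  cfg <- simConfig(nSires = 5000, nDams = 5000, offspringPerMating = 1,
                   nGenerations = 2, varA = 2, varPe = 1, varE = 0.5,
                   seed = 4)
  ped <- simulatePedigree(cfg)
  bt <- simulateBvTargets(ped, cfg, setSeed = FALSE)
  aF <- bt$individuals$a[bt$individuals$id %in%
                           ped$id[ped$generation == 1]]
  expect_equal(var(aF), 2, tolerance = 0.05)

  # half-sib covariance ~ varA / 4 = 0.5; many sires keep the cluster
  # noise (shared sire breeding values) small
  cfg2 <- simConfig(nSires = 500, nDams = 5000, offspringPerMating = 1,
                    nGenerations = 2, varA = 2, seed = 5)
  ped2 <- simulatePedigree(cfg2)
  bt2 <- simulateBvTargets(ped2, cfg2, setSeed = FALSE)
  off <- merge(ped2[ped2$generation == 2, c("id", "sire")],
               bt2$individuals[, c("id", "a")])
  prods <- unlist(lapply(split(off$a, off$sire), function(a)
    utils::combn(a, 2, FUN = function(x) x[1] * x[2])))
  expect_gte(length(prods), 1e4)
  expect_lt(abs(mean(prods) - 0.5), 0.1)
})

test_that("degenerate variances make gamete targets deterministic", {
  cfg <- simConfig(nSires = 2, nDams = 6, offspringPerMating = 2,
                   varA = 0, varPe = 0, varE = 0, betaAge = 0.5,
                   muAccMale = 16, muAccFemale = 21, seed = 6)
  ped <- simulatePedigree(cfg)
  bt <- simulateBvTargets(ped, cfg, setSeed = FALSE)
  g <- bt$gametes
  mu <- ifelse(g$parentSex == "M", 16, 21)
  expect_equal(g$target, mu + 0.5 * g$age)
})

test_that("realized mean ACC matches the configured sex means", {
  sim <- stdSim()   # defaults: mu 18 male / 23 female, no age effect
  tg <- sim$truth$gametes
  expect_gt(nrow(tg), 500)
  expect_equal(mean(tg$acc[tg$parentSex == "M"]), 18, tolerance = 0.02)
  expect_equal(mean(tg$acc[tg$parentSex == "F"]), 23, tolerance = 0.02)
  # SD close to sqrt(varA + varPe + varE) = sqrt(20)
  expect_equal(sd(tg$acc), sqrt(20), tolerance = 0.15)
  # configured map-length ratio is 1.278 by construction
  cfg <- sim$config
  expect_equal(sum(cfg@mapLenFemale) / sum(cfg@mapLenMale), 2300 / 1800)
})
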