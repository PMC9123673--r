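test_that("relationship matrix identities hold on hand pedigrees", {
  ped <- tinyPedigree()
  A <- buildA(ped)
  # founders: identity block
  expect_equal(A[c("a", "b"), c("a", "b")], diag(2),
               ignore_attr = TRUE)
  # parent-offspring and full-sib relationship 0.5
  expect_equal(A["a", "x"], 0.5)
  expect_equal(A["x", "y"], 0.5)
  # offspring of full-sib mating: F = 0.25, diagonal 1.25
  expect_equal(A["z", "z"], 1.25)
  expect_equal(unname(pedigreeInbreeding(ped)["z"]), 0.25)
  # sparse inverse inverts the tabular matrix
  ab <- buildAInverse(ped)
  expect_equal(as.matrix(solve(ab$Ainv))[ab$ids, ab$ids],
               A[ab$ids, ab$ids], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(ab$logDetA, determinant(A)$modulus, ignore_attr = TRUE)
})

test_that("AI-REML matches a direct dense-matrix REML oracle", {
  set.seed(91)
  cfg <- simConfig(nSires = 3, nDams = 15, offspringPerMating = 3,
                   varA = 2, varPe = 1, varE = 4, seed = 91)
  ped <- simulatePedigree(cfg)
  bt <- simulateBvTargets(ped, cfg, setSeed = FALSE)
  g <- bt$gametes
  y <- g$target; id <- g$fid; X <- cbind(age = g$age)
  fit <- fitAIREML(y, id, X = X, pedigree = ped, tol = 1e-10)

  # oracle: brute-force REML on the explicit covariance matrix
  ids <- unique(id)
  A <- buildA(ped)[ids, ids]
  Z <- outer(id, ids, "==") + 0
  Xf <- cbind(1, X)
  n <- length(y)
  m2ll <- function(th) {
    V <- Z %*% (A * th[1]) %*% t(Z) + tcrossprod(Z) * th[2] + diag(n) * th[3]
    cV <- chol(V); Vi <- chol2inv(cV)
    XtVX <- crossprod(Xf, Vi %*% Xf)
    b <- solve(XtVX, crossprod(Xf, Vi %*% y))
    r <- y - Xf %*% b
    as.numeric(2 * sum(log(diag(cV))) + determinant(XtVX)$modulus +
                 crossprod(r, Vi %*% r))
  }
  op <- optim(c(1, 1, 1), m2ll, method = "L-BFGS-B", lower = 1e-6,
              control = list(factr = 1e3))
  expect_equal(unname(varComponents(fit)), op$par, tolerance = 1e-3)
  # engine's likelihood is the same function (same constant)
  expect_equal(m2ll(varComponents(fit)), -2 * fit@logLik, tolerance = 1e-6)
  # accepted iterations are monotone in the REML likelihood
  expect_true(all(diff(fit@trace$m2ll) <= 1e-10))
})

test_that("estimates are invariant to observation order and location shift", {
  set.seed(92)
  cfg <- simConfig(nSires = 3, nDams = 12, offspringPerMating = 3,
                   varA = 2, varPe = 1, varE = 4, seed = 92)
  ped <- simulatePedigree(cfg)
  bt <- simulateBvTargets(ped, cfg, setSeed = FALSE)
  g <- bt$gametes
  fit1 <- fitAIREML(g$target, g$fid, pedigree = ped, tol = 1e-10)
  pm <- sample(nrow(g))
  fit2 <- fitAIREML(g$target[pm], g$fid[pm], pedigree = ped, tol = 1e-10)
  fit3 <- fitAIREML(g$target + 100, g$fid, pedigree = ped, tol = 1e-10)
  expect_equal(varComponents(fit1), varComponents(fit2), tolerance = 1e-6)
  expect_equal(varComponents(fit1), varComponents(fit3), tolerance = 1e-6)
})

test_that("null additive variance is not declared heritable too often", {
  # varA = 0 truth: the h2 estimate should exceed twice its SE only rarely
  hits <- 0
  for (r in 1:25) {
    cfg <- simConfig(nSires = 4, nDams = 24, offspringPerMating = 3,
                     varA = 0, varPe = 1, varE = 4, seed = 900 + r)
    ped <- simulatePedigree(cfg)
    bt <- simulateBvTargets(ped, cfg, setSeed = FALSE)
    g <- bt$gametes
    fit <- suppressWarnings(fitAIREML(g$target, g$fid, pedigree = ped))
    if (fit@h2 > 2 * fit@se["h2"]) hits <- hits + 1
  }
  # one-sided 2-SE exceedance has rate ~2.5%; allow generous binomial slack
  expect_lte(hits, 4)
})

test_that("inbreeding covariate slope is recovered with correct sign", {
  set.seed(93)
  nid <- 150; k <- 4
  id <- rep(sprintf("f%03d", 1:nid), each = k)
  f <- rep(runif(nid, 0, 0.3), each = k)
  u <- rep(rnorm(nid, 0, 1), each = k)
  # masking: high-F individuals have fewer callable crossovers
  y <- 22 - 5 * f + u + rnorm(nid * k, 0, 2)
  fit <- fitAIREML(y, id, X = cbind(het = f))
  eff <- reportInbreedingEffect(fit)
  expect_true(eff$negative)
  expect_equal(eff$estimate, -5, tolerance = 2.5 * eff$se / 5 + 0.2)
  expect_lt(abs(eff$estimate + 5), 3 * eff$se)
  # null: no masking
  y0 <- 22 + u + rnorm(nid * k, 0, 2)
  fit0 <- fitAIREML(y0, id, X = cbind(het = f))
  eff0 <- reportInbreedingEffect(fit0)
  expect_lt(abs(eff0$estimate), 3 * eff0$se)
  # model without the covariate refuses to report it
  expect_error(reportInbreedingEffect(fitAIREML(y, id)), "het")
})

test_that("fitAccModel wires phenotypes, sexes and covariates together", {
  sim <- stdSim()
  acc <- collectACC(stdGametes())
  fit <- fitAccModel(acc, sim$pedigree, sex = "F")
  expect_s4_class(fit, "RemlFit")
  expect_true(fit@converged)
  expect_true(all(c("(Intercept)", "age") %in% fixedEffects(fit)$term))
  expect_gte(fit@h2, 0); expect_lte(fit@h2, 1)
  vc <- varComponents(fit)
  expect_equal(unname(sum(vc)), var(acc$acc[acc$qcPass &
                                              acc$parentSex == "F"]),
               tolerance = 0.3)
})
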