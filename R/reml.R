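## ancestral closure: rows of `pedigree` for `keep` plus all their ancestors
prunePedigree <- function(pedigree, keep) {
  p <- pedigree
  p$id <- as.character(p$id); p$sire <- as.character(p$sire)
  p$dam <- as.character(p$dam)
  want <- unique(as.character(keep))
  repeat {
    rows <- p[p$id %in% want, , drop = FALSE]
    parents <- setdiff(unique(c(rows$sire, rows$dam)), c("0", want))
    parents <- parents[parents %in% p$id]
    if (!length(parents)) break
    want <- c(want, parents)
  }
  p[p$id %in% want, , drop = FALSE]
}

#' Fit the ACC repeatability animal model by AI-REML
#'
#' Model: `y = X b + Z a + Z pe + e` with `a ~ N(0, A varA)` on the pedigree
#' relationship matrix, a permanent-environment effect `pe ~ N(0, I varPe)`
#' per focal individual capturing repeated gametes, and residual
#' `e ~ N(0, I varE)`. Estimation maximises the REML log-likelihood with
#' average-information updates (exact scores via mixed-model-equation trace
#' identities); steps that leave the parameter space or decrease the
#' likelihood fall back to step-halving and expectation-maximisation
#' updates, so accepted iterations are monotone. Convergence is declared
#' when the change in -2 log-likelihood falls below `tol`. Standard errors
#' come from the inverse average-information matrix; the heritability
#' `h2 = varA / (varA + varPe + varE)` gets a delta-method SE.
#'
#' @param y numeric response (one entry per gamete).
#' @param id character focal-individual of each observation.
#' @param X optional fixed-effect design matrix (columns named; an intercept
#'   is always prepended).
#' @param pedigree pedigree for the relationship matrix (pruned to the
#'   observed ids and their ancestors). If omitted (and no `Ainv`),
#'   individuals are treated as unrelated (`A = I`), in which case only
#'   `varA + varPe` is identifiable.
#' @param Ainv,logDetA,aIds optionally, a precomputed sparse inverse
#'   relationship matrix with its log-determinant and id order (as from
#'   [buildAInverse()]).
#' @param maxIter,tol iteration cap and -2logL convergence tolerance.
#' @param verbose print the iteration trace.
#' @return a [RemlFit-class].
#' @examples
#' set.seed(1)
#' id <- rep(sprintf("f%02d", 1:40), each = 4)
#' u <- rnorm(40, 0, sqrt(4))[match(id, unique(id))]
#' fit <- fitAIREML(10 + u + rnorm(160, 0, 2), id)
#' varComponents(fit)  # varA + varPe ~ 4, varE ~ 4
#' @export
fitAIREML <- function(y, id, X = NULL, pedigree = NULL,
                      Ainv = NULL, logDetA = NULL, aIds = NULL,
                      maxIter = 100, tol = 1e-8, verbose = FALSE) {
  id <- as.character(id)
  n <- length(y)
  stopifnot(length(id) == n)
  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    X <- cbind("(Intercept)" = 1, X)
  }
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design is rank deficient")

  if (is.null(Ainv)) {
    if (!is.null(pedigree)) {
      pp <- prunePedigree(pedigree, unique(id))
      ab <- buildAInverse(pp)
      Ainv <- ab$Ainv; logDetA <- ab$logDetA; aIds <- ab$ids
    } else {
      aIds <- unique(id)
      Ainv <- Diagonal(length(aIds))
      dimnames(Ainv) <- list(aIds, aIds)
      logDetA <- 0
    }
  } else {
    if (is.null(aIds)) aIds <- rownames(Ainv)
    if (is.null(logDetA))
      logDetA <- -as.numeric(determinant(Ainv, logarithm = TRUE)$modulus)
  }
  if (!all(id %in% aIds))
    stop("some observation ids are missing from the relationship matrix")
  Ainv <- Matrix::forceSymmetric(methods::as(Ainv, "CsparseMatrix"))
  q1 <- length(aIds)
  lev2 <- unique(id)
  q2 <- length(lev2)
  if (max(table(id)) < 2)
    warning("no individual has repeated gametes; varPe and varE are ",
            "poorly separable")

  Z1 <- sparseMatrix(i = seq_len(n), j = match(id, aIds), x = 1,
                     dims = c(n, q1))
  Z2 <- sparseMatrix(i = seq_len(n), j = match(id, lev2), x = 1,
                     dims = c(n, q2))
  W <- cbind(methods::as(X, "CsparseMatrix"), Z1, Z2)
  WtW <- crossprod(W)
  Wty <- as.numeric(crossprod(W, y))
  yty <- sum(y^2)
  i1 <- p + seq_len(q1)
  i2 <- p + q1 + seq_len(q2)
  AinvT <- methods::as(methods::as(Ainv, "generalMatrix"), "TsparseMatrix")
  AinvChol <- Cholesky(Matrix::forceSymmetric(
    methods::as(Ainv + Diagonal(q1, 1e-10), "CsparseMatrix")), LDL = FALSE)

  vy <- var(y)
  lb <- 1e-8 * vy
  theta <- c(0.4, 0.1, 0.5) * vy  # (varA, varPe, varE) start
  names(theta) <- c("varA", "varPe", "varE")

  mme <- function(th) {
    Gi <- Matrix::bdiag(Diagonal(p, 0), Ainv / th[1], Diagonal(q2) / th[2])
    C <- WtW / th[3] + Gi
    Ch <- Cholesky(methods::as(Matrix::forceSymmetric(C), "dsCMatrix"),
                   LDL = FALSE)
    sol <- as.numeric(solve(Ch, Wty / th[3]))
    yPy <- (yty - sum(sol * Wty)) / th[3]
    ldC <- 2 * as.numeric(determinant(Ch, logarithm = TRUE,
                                      sqrt = TRUE)$modulus)
    m2ll <- ldC + q1 * log(th[1]) + logDetA + q2 * log(th[2]) +
      n * log(th[3]) + yPy
    list(Ch = Ch, sol = sol, yPy = yPy, m2ll = m2ll)
  }

  derivs <- function(th, fit) {
    Cinv <- as.matrix(solve(fit$Ch, diag(p + q1 + q2)))
    tr11 <- sum(AinvT@x * Cinv[cbind(i1[AinvT@i + 1L], i1[AinvT@j + 1L])])
    tr22 <- sum(diag(Cinv)[i2])
    Py <- as.numeric(y - W %*% fit$sol) / th[3]
    f1 <- as.numeric(Z1 %*% solve(AinvChol, as.numeric(crossprod(Z1, Py))))
    f2 <- as.numeric(Z2 %*% as.numeric(crossprod(Z2, Py)))
    F3 <- cbind(f1, f2, Py)
    PF <- (F3 - as.matrix(W %*% solve(fit$Ch,
                                      crossprod(W, F3) / th[3]))) / th[3]
    AI <- 0.5 * crossprod(F3, PF)
    AI <- (AI + t(AI)) / 2
    trP1 <- q1 / th[1] - tr11 / th[1]^2
    trP2 <- q2 / th[2] - tr22 / th[2]^2
    trP <- (n - p - th[1] * trP1 - th[2] * trP2) / th[3]
    score <- -0.5 * c(trP1 - sum(Py * f1),
                      trP2 - sum(Py * f2),
                      trP - sum(Py * Py))
    u1 <- fit$sol[i1]; u2 <- fit$sol[i2]
    em <- c((sum(u1 * as.numeric(Ainv %*% u1)) + tr11) / q1,
            (sum(u2^2) + tr22) / q2,
            (yty - sum(fit$sol * Wty)) / (n - p))
    list(AI = AI, score = score, em = em, Cinv = Cinv)
  }

  fit <- mme(theta)
  trace <- data.frame(iter = 0, varA = theta[1], varPe = theta[2],
                      varE = theta[3], m2ll = fit$m2ll, step = "start")
  converged <- FALSE
  de <- NULL
  for (it in seq_len(maxIter)) {
    de <- derivs(theta, fit)
    step <- "AI"
    delta <- tryCatch(solve(de$AI + Diagonal(3, 1e-10 * max(abs(de$AI))),
                            de$score),
                      error = function(e) NULL)
    cand <- if (!is.null(delta)) pmax(theta + as.numeric(delta), lb) else NULL
    newFit <- NULL
    if (!is.null(cand)) {
      h <- 1
      for (ls in 1:12) {
        trial <- pmax(theta + h * as.numeric(delta), lb)
        tf <- mme(trial)
        if (tf$m2ll <= fit$m2ll + 1e-12) {
          cand <- trial; newFit <- tf
          if (ls > 1) step <- "AI-halved"
          break
        }
        h <- h / 2
      }
    }
    if (is.null(newFit)) {  # EM fallback
      step <- "EM"
      cand <- pmax(de$em, lb)
      newFit <- mme(cand)
    }
    dll <- fit$m2ll - newFit$m2ll
    theta <- cand; fit <- newFit
    trace <- rbind(trace, data.frame(iter = it, varA = theta[1],
                                     varPe = theta[2], varE = theta[3],
                                     m2ll = fit$m2ll, step = step))
    if (verbose)
      message(sprintf("it %d [%s]: varA=%.5g varPe=%.5g varE=%.5g -2ll=%.8f",
                      it, step, theta[1], theta[2], theta[3], fit$m2ll))
    if (abs(dll) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("AI-REML did not converge in ", maxIter, " iterations")

  de <- derivs(theta, fit)
  covTheta <- tryCatch(solve(de$AI), error = function(e)
    tryCatch(solve(de$AI + Diagonal(3, 1e-6 * max(abs(de$AI)))),
             error = function(e2) matrix(NA_real_, 3, 3)))
  covTheta <- as.matrix(covTheta)
  vp <- sum(theta)
  h2 <- theta[1] / vp
  gh <- c((vp - theta[1]) / vp^2, -theta[1] / vp^2, -theta[1] / vp^2)
  seH2 <- sqrt(max(0, as.numeric(gh %*% covTheta %*% gh)))
  ses <- sqrt(pmax(0, diag(covTheta)))
  fixef <- data.frame(term = colnames(X),
                      estimate = fit$sol[seq_len(p)],
                      se = sqrt(pmax(0, diag(de$Cinv)[seq_len(p)])),
                      stringsAsFactors = FALSE)
  new("RemlFit", varA = unname(theta[1]), varPe = unname(theta[2]),
      varE = unname(theta[3]), h2 = unname(h2),
      se = c(varA = ses[1], varPe = ses[2], varE = ses[3], h2 = seH2),
      fixef = fixef, logLik = unname(-fit$m2ll / 2), trace = trace,
      converged = converged, boundary = any(theta <= lb * (1 + 1e-9)))
}

#' Fit the ACC model from a gamete table
#'
#' Convenience wrapper: selects QC-passing gametes of one sex (or both with
#' a sex covariate), builds the fixed-effect design (age class, and the
#' genomic inbreeding coefficient when supplied) and calls [fitAIREML()]
#' with the pedigree relationship matrix.
#'
#' @param acc gamete table from [collectACC()] (needs fid, parentSex, acc,
#'   qcPass, and age for the age covariate).
#' @param pedigree pedigree data.frame.
#' @param sex \"F\", \"M\" or \"joint\" (sexes pooled with a sex fixed
#'   effect).
#' @param fCoef optional named vector of per-FID inbreeding coefficients
#'   (the `het` covariate).
#' @param ... passed to [fitAIREML()].
#' @return a [RemlFit-class].
#' @export
fitAccModel <- function(acc, pedigree, sex = c("F", "M", "joint"),
                        fCoef = NULL, ...) {
  sex <- match.arg(sex)
  tab <- acc[acc$qcPass, , drop = FALSE]
  if (sex != "joint") tab <- tab[tab$parentSex == sex, , drop = FALSE]
  if (!nrow(tab)) stop("no QC-passing gametes for sex ", sex)
  X <- NULL
  if ("age" %in% names(tab) && length(unique(tab$age)) > 1)
    X <- cbind(age = tab$age)
  if (sex == "joint" && length(unique(tab$parentSex)) > 1)
    X <- cbind(X, sexM = as.numeric(tab$parentSex == "M"))
  if (!is.null(fCoef)) {
    het <- unname(fCoef[tab$fid])
    if (length(unique(het[!is.na(het)])) > 1) X <- cbind(X, het = het)
  }
  fitAIREML(tab$acc, tab$fid, X = X, pedigree = pedigree, ...)
}

#' Slope of ACC on the inbreeding coefficient
#'
#' Extracts the fixed regression of ACC on the genomic inbreeding
#' coefficient (`het` term) from a fitted model: runs of homozygosity mask
#' double crossovers, so a negative slope is the expected signature.
#'
#' @param fit a [RemlFit-class] whose model included the `het` covariate.
#' @return list: `estimate`, `se`, `negative` (logical, estimate < 0).
#' @export
reportInbreedingEffect <- function(fit) {
  fe <- fixedEffects(fit)
  row <- fe[fe$term == "het", , drop = FALSE]
  if (!nrow(row))
    stop("model was fitted without the inbreeding (het) covariate")
  list(estimate = row$estimate, se = row$se, negative = row$estimate < 0)
}
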