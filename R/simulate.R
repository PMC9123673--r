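#' Simulate a multi-generation polygynous pedigree
#'
#' Generates a pedigree in which each generation is produced by `nSires`
#' breeding males each mated to several of `nDams` breeding females
#' (round-robin assignment), so that sires are reused across many dams as in
#' commercial livestock populations. With three or more generations the
#' pedigree contains three-generation full-sib families: generation-2 mating
#' pairs are focal individuals whose four parents (generation 1) and
#' offspring (generation 3) are all present.
#'
#' @param config a [SimConfig-class]; uses the pedigree-shape and seed fields.
#' @param setSeed set the RNG from `config@seed` (default TRUE). Internal
#'   callers that manage the stream themselves pass FALSE.
#' @return data.frame with columns `id`, `sire`, `dam` (\"0\" = unknown),
#'   `sex` (\"M\"/\"F\"), `age` (age class 1-4 of the parents at this
#'   individual's birth; 0 for founders) and `generation`.
#' @examples
#' ped <- simulatePedigree(simConfig(nSires = 2, nDams = 10,
#'                                   offspringPerMating = 5, seed = 42))
#' table(ped$generation)
#' @export
simulatePedigree <- function(config, setSeed = TRUE) {
  stopifnot(is(config, "SimConfig"))
  if (config@nGenerations < 2)
    stop("need at least 2 generations")
  if (setSeed) set.seed(config@seed)
  ns <- config@nSires; nd <- config@nDams; k <- config@offspringPerMating

  rows <- list()
  idc <- 0L
  newIds <- function(n) {
    out <- sprintf("I%06d", idc + seq_len(n)); idc <<- idc + n; out
  }
  ## generation 1: founders
  sires <- newIds(ns); dams <- newIds(nd)
  rows[[1]] <- data.frame(
    id = c(sires, dams), sire = "0", dam = "0",
    sex = rep(c("M", "F"), c(ns, nd)), age = 0L, generation = 1L,
    stringsAsFactors = FALSE)

  for (g in 2:config@nGenerations) {
    nMat <- length(dams)
    sireOf <- sires[(seq_len(nMat) - 1L) %% length(sires) + 1L]
    litters <- if (length(config@litterRange))
      sample(config@litterRange[1]:config@litterRange[2], nMat,
             replace = TRUE) else rep(k, nMat)
    off <- list()
    for (m in seq_len(nMat)) {
      ids <- newIds(litters[m])
      off[[m]] <- data.frame(
        id = ids, sire = sireOf[m], dam = dams[m],
        sex = rep_len(c("M", "F"), litters[m]),
        age = sample(1:4, litters[m], replace = TRUE),
        generation = g, stringsAsFactors = FALSE)
    }
    off <- do.call(rbind, off)
    rows[[g]] <- off
    if (g < config@nGenerations) {
      males <- off$id[off$sex == "M"]
      females <- off$id[off$sex == "F"]
      if (length(males) < 1L || length(females) < 1L)
        stop("generation ", g, " has no breeding individuals")
      sires <- head(males, ns)
      dams <- head(females, nd)
    }
  }
  do.call(rbind, rows)
}

## order check: every parent must precede its offspring (input pedigrees are
## generated in order; user pedigrees are sorted by checkPedigree)
checkPedigree <- function(pedigree) {
  p <- pedigree
  need <- c("id", "sire", "dam", "sex")
  if (!all(need %in% names(p)))
    stop("pedigree needs columns ", paste(need, collapse = ", "))
  p$id <- as.character(p$id); p$sire <- as.character(p$sire)
  p$dam <- as.character(p$dam)
  if (anyDuplicated(p$id)) stop("duplicated pedigree ids")
  ## topological sort (Kahn); detects cycles / self-ancestry
  idx <- setNames(seq_len(nrow(p)), p$id)
  si <- idx[p$sire]; di <- idx[p$dam]
  indeg <- integer(nrow(p))
  kids <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    for (pa in c(si[i], di[i])) {
      if (!is.na(pa)) {
        indeg[i] <- indeg[i] + 1L
        kids[[pa]] <- c(kids[[pa]], i)
      }
    }
  }
  queue <- which(indeg == 0L); ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; ord <- c(ord, v)
    for (w in kids[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(ord) != nrow(p))
    stop("pedigree contains a cycle (an individual is its own ancestor)")
  ## sex-role consistency
  sx <- setNames(p$sex, p$id)
  badS <- unique(p$sire[p$sire != "0" & !is.na(sx[p$sire]) &
                          sx[p$sire] != "M"])
  badD <- unique(p$dam[p$dam != "0" & !is.na(sx[p$dam]) & sx[p$dam] != "F"])
  if (length(badS) || length(badD))
    stop("sex-role conflicts for: ", paste(c(badS, badD), collapse = ", "))
  p[ord, , drop = FALSE]
}

#' Simulate breeding values and per-gamete crossover targets
#'
#' Founders draw additive values `a ~ N(0, varA)`; descendants receive the
#' parent average plus a Mendelian-sampling deviation
#' `N(0, varA/2 * (1 - (F_s + F_d)/2))` using pedigree inbreeding.
#' Permanent-environment values are `N(0, varPe)` per individual. Each gamete
#' (one per parent per offspring) gets a latent Gaussian target
#' `T = mu_sex + betaAge * age + betaHet * F + a + pe + e`, `e ~ N(0, varE)`.
#' Realized crossover counts in [simulateDataset()] are `round(T)` clamped at
#' the obligate floor, so `varE` is the gamete-level residual variance of the
#' repeatability model.
#'
#' @param pedigree as from [simulatePedigree()].
#' @param config a [SimConfig-class].
#' @param setSeed set RNG from `config@seed` (default TRUE).
#' @return list with `individuals` (id, a, pe, f) and `gametes`
#'   (fid, offspring, parentSex, age, target). QTL dosage effects are added
#'   by [simulateDataset()] where genotypes exist.
#' @export
simulateBvTargets <- function(pedigree, config, setSeed = TRUE) {
  if (setSeed) set.seed(config@seed)
  p <- checkPedigree(pedigree)
  f <- pedigreeInbreeding(p)
  n <- nrow(p)
  idx <- setNames(seq_len(n), p$id)
  a <- numeric(n); pe <- rnorm(n, 0, sqrt(config@varPe))
  for (i in seq_len(n)) {
    s <- idx[p$sire[i]]; d <- idx[p$dam[i]]
    if (is.na(s) && is.na(d)) {
      a[i] <- rnorm(1, 0, sqrt(config@varA))
    } else {
      pm <- mean(c(if (!is.na(s)) a[s] else 0, if (!is.na(d)) a[d] else 0))
      fs <- if (!is.na(s)) f[s] else 0
      fd <- if (!is.na(d)) f[d] else 0
      msv <- 0.5 * config@varA * (1 - (fs + fd) / 2)
      a[i] <- pm + rnorm(1, 0, sqrt(msv))
    }
  }
  ind <- data.frame(id = p$id, a = a, pe = pe, f = f,
                    stringsAsFactors = FALSE)
  off <- p[p$sire != "0" & p$dam != "0", , drop = FALSE]
  gam <- data.frame(
    fid = c(off$sire, off$dam),
    offspring = rep(off$id, 2),
    parentSex = rep(c("M", "F"), each = nrow(off)),
    age = rep(off$age, 2), stringsAsFactors = FALSE)
  mu <- ifelse(gam$parentSex == "M", config@muAccMale, config@muAccFemale)
  gi <- idx[gam$fid]
  gam$target <- mu + config@betaAge * gam$age + config@betaHet * f[gi] +
    a[gi] + pe[gi] + rnorm(nrow(gam), 0, sqrt(config@varE))
  list(individuals = ind, gametes = gam)
}

#' Simulate one meiosis with crossover interference
#'
#' Distributes a target number of crossovers over chromosomes with
#' probability proportional to the sex-specific chromosome map length
#' (optionally one obligate crossover per chromosome first), then places
#' positions on the cM axis by normalised gamma-renewal spacings with shape
#' `nu`: `nu = 1` reproduces uniform order statistics (no interference),
#' larger `nu` spaces crossovers more evenly.
#'
#' @param h1,h2 the parent's two haplotypes (0/1 allele vectors over all
#'   markers, chromosomes concatenated in map order).
#' @param markerChrom integer chromosome index per marker.
#' @param markerCm cM position of each marker on the parent-sex map.
#' @param chromLen per-chromosome map length in cM for the parent's sex.
#' @param targetAcc latent crossover target (rounded, floored at 0, or at the
#'   chromosome count in obligate mode; sub-floor targets are clamped).
#' @param nu gamma-renewal shape (interference strength).
#' @param obligate logical, force >= 1 crossover per chromosome.
#' @return list: `gamete` (0/1 alleles), `origin` (1/2 = which parental
#'   haplotype each marker came from), `xo` (data.frame chrom, cm), and
#'   `clamped` (TRUE if the target was raised to the obligate floor).
#' @examples
#' cm <- seq(0, 100, length.out = 11)
#' m <- simulateMeiosis(rep(0L, 11), rep(1L, 11), rep(1L, 11), cm, 100,
#'                      targetAcc = 0)
#' stopifnot(nrow(m$xo) == 0, length(unique(m$origin)) == 1)
#' @export
simulateMeiosis <- function(h1, h2, markerChrom, markerCm, chromLen,
                            targetAcc, nu = 1, obligate = FALSE) {
  nC <- length(chromLen)
  cnt <- as.integer(round(max(targetAcc, 0)))
  clamped <- FALSE
  if (obligate && cnt < nC) { cnt <- nC; clamped <- TRUE }
  if (obligate) {
    perChrom <- rep(1L, nC)
    if (cnt > nC)
      perChrom <- perChrom +
        as.integer(rmultinom(1, cnt - nC, prob = chromLen))
  } else {
    perChrom <- if (cnt > 0)
      as.integer(rmultinom(1, cnt, prob = chromLen)) else rep(0L, nC)
  }
  origin <- integer(length(h1))
  xo <- vector("list", nC)
  for (c in seq_len(nC)) {
    sel <- which(markerChrom == c)
    k <- perChrom[c]
    start <- sample.int(2L, 1L)
    if (k > 0) {
      g <- rgamma(k + 1L, shape = nu, rate = 1)
      pos <- (cumsum(g)[seq_len(k)] / sum(g)) * chromLen[c]
      nprior <- findInterval(markerCm[sel], pos)
      origin[sel] <- 1L + (start - 1L + nprior) %% 2L
      xo[[c]] <- data.frame(chrom = c, cm = pos)
    } else {
      origin[sel] <- start
    }
  }
  xo <- if (any(perChrom > 0)) do.call(rbind, xo[perChrom > 0]) else
    data.frame(chrom = integer(), cm = numeric())
  list(gamete = ifelse(origin == 1L, h1, h2), origin = origin,
       xo = xo, clamped = clamped)
}

#' Simulate unrelated genotypes in linkage equilibrium
#'
#' Convenience generator for founder-style panels (e.g. GWAS calibration):
#' each marker's counted-allele frequency is drawn uniformly from
#' `mafRange`, individuals are unrelated, markers independent.
#'
#' @param n individuals; @param markers data.frame as from marker table, or an
#'   integer number of markers (placed on one chromosome).
#' @param mafRange allele-frequency interval.
#' @param seed integer seed.
#' @return a [GenotypeData-class] object.
#' @export
simulateFounderGenotypes <- function(n, markers, mafRange = c(0.1, 0.5),
                                     seed = 1L) {
  set.seed(seed)
  if (is.numeric(markers) && length(markers) == 1L)
    markers <- data.frame(marker = sprintf("snp%05d", seq_len(markers)),
                          chrom = "1", bp = seq_len(markers) * 1000)
  m <- nrow(markers)
  p <- runif(m, mafRange[1], mafRange[2])
  g <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  rownames(g) <- sprintf("F%05d", seq_len(n))
  GenotypeData(g, markers)
}

#' Simulate a complete pedigreed SNP dataset with known crossover truth
#'
#' Runs the full generative model: pedigree, founder haplotypes in linkage
#' equilibrium, per-individual breeding values and permanent-environment
#' effects, gamete-by-gamete meiosis with interference (recording every
#' crossover position), optional planted QTLs that add dosage x effect to the
#' transmitting parent's additive value, and finally observed genotypes with
#' genotyping error (random allele swaps) and missingness applied after the
#' truth is recorded.
#'
#' @param config a [SimConfig-class].
#' @return list of class `xoversim`: `pedigree`, `genotypes` (observed
#'   [GenotypeData-class]), `trueGenotypes` (error-free matrix), `truth`
#'   (list: `gametes` per-meiosis table with true ACC and crossover
#'   positions, `xo` long table of crossover positions, `individuals` with
#'   a/pe/F, `qtl`), and `config`.
#' @examples
#' sim <- simulateDataset(simConfig(nSires = 2, nDams = 8,
#'   offspringPerMating = 2, markersPerChrom = 8, nChromosomes = 3,
#'   chromBp = c(1e8, 8e7, 6e7), seed = 7))
#' head(sim$truth$gametes)
#' @export
simulateDataset <- function(config) {
  set.seed(config@seed)
  ped <- simulatePedigree(config, setSeed = FALSE)
  f <- pedigreeInbreeding(ped)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)

  markers <- simMarkerTable(config)
  M <- nrow(markers)
  mChrom <- as.integer(markers$chrom)
  cmF <- simMarkerCm(config, "F")
  cmM <- simMarkerCm(config, "M")

  ## breeding values / permanent environment (same model as
  ## simulateBvTargets, drawn inside this stream)
  a <- numeric(n); pe <- rnorm(n, 0, sqrt(config@varPe))
  for (i in seq_len(n)) {
    s <- idx[ped$sire[i]]; d <- idx[ped$dam[i]]
    if (is.na(s) && is.na(d)) {
      a[i] <- rnorm(1, 0, sqrt(config@varA))
    } else {
      pm <- mean(c(if (!is.na(s)) a[s] else 0, if (!is.na(d)) a[d] else 0))
      fs <- if (!is.na(s)) f[s] else 0
      fd <- if (!is.na(d)) f[d] else 0
      a[i] <- pm + rnorm(1, 0, sqrt(0.5 * config@varA * (1 - (fs + fd) / 2)))
    }
  }

  maf <- runif(M, config@founderMafRange[1], config@founderMafRange[2])
  H1 <- matrix(0L, n, M); H2 <- matrix(0L, n, M)
  qtlIdx <- config@qtl$marker
  qtlEff <- config@qtl$effect
  aTotal <- function(i) {
    if (!length(qtlIdx)) return(a[i])
    dose <- H1[i, qtlIdx] + H2[i, qtlIdx]
    a[i] + sum(dose * qtlEff)
  }

  gamRows <- vector("list", 2L * n)
  xoRows <- vector("list", 2L * n)
  gk <- 0L
  meiose <- function(pIdx, childAge) {
    sex <- ped$sex[pIdx]
    mu <- if (sex == "M") config@muAccMale else config@muAccFemale
    target <- mu + config@betaAge * childAge + config@betaHet * f[pIdx] +
      aTotal(pIdx) + pe[pIdx] + rnorm(1, 0, sqrt(config@varE))
    cl <- if (sex == "M") config@mapLenMale else config@mapLenFemale
    cm <- if (sex == "M") cmM else cmF
    simulateMeiosis(H1[pIdx, ], H2[pIdx, ], mChrom, cm, cl,
                    targetAcc = target, nu = config@interferenceNu,
                    obligate = config@obligate)
  }

  for (i in seq_len(n)) {
    s <- idx[ped$sire[i]]; d <- idx[ped$dam[i]]
    if (is.na(s) && is.na(d)) {
      H1[i, ] <- rbinom(M, 1L, maf)
      H2[i, ] <- rbinom(M, 1L, maf)
      next
    }
    for (role in c("pat", "mat")) {
      pIdx <- if (role == "pat") s else d
      mz <- meiose(pIdx, ped$age[i])
      if (role == "pat") H1[i, ] <- mz$gamete else H2[i, ] <- mz$gamete
      gk <- gk + 1L
      nxo <- nrow(mz$xo)
      gamRows[[gk]] <- data.frame(
        fid = ped$id[pIdx], offspring = ped$id[i],
        parentSex = ped$sex[pIdx], age = ped$age[i],
        acc = nxo, clamped = mz$clamped, stringsAsFactors = FALSE)
      if (nxo) {
        L <- if (ped$sex[pIdx] == "M") config@mapLenMale else
          config@mapLenFemale
        bp <- 1 + mz$xo$cm / L[mz$xo$chrom] * (config@chromBp[mz$xo$chrom] - 1)
        xoRows[[gk]] <- data.frame(
          fid = ped$id[pIdx], offspring = ped$id[i],
          parentSex = ped$sex[pIdx], chrom = mz$xo$chrom,
          cm = mz$xo$cm, bp = round(bp), stringsAsFactors = FALSE)
      }
    }
  }
  gametes <- do.call(rbind, gamRows[seq_len(gk)])
  xo <- do.call(rbind, xoRows[!vapply(xoRows, is.null, TRUE)])
  if (is.null(xo))
    xo <- data.frame(fid = character(), offspring = character(),
                     parentSex = character(), chrom = integer(),
                     cm = numeric(), bp = numeric())

  trueG <- H1 + H2
  rownames(trueG) <- ped$id
  colnames(trueG) <- markers$marker
  obsG <- trueG
  ## genotyping error: random allele swap (one of the two alleles flips)
  if (config@genoErrorRate > 0) {
    hit <- which(runif(length(obsG)) < config@genoErrorRate)
    if (length(hit)) {
      cur <- obsG[hit]
      up <- rbinom(length(hit), 1L, 0.5) == 1L
      nw <- ifelse(cur == 0L, 1L,
            ifelse(cur == 2L, 1L, ifelse(up, 2L, 0L)))
      obsG[hit] <- nw
    }
  }
  if (config@missingRate > 0)
    obsG[runif(length(obsG)) < config@missingRate] <- NA_integer_

  structure(list(
    pedigree = ped,
    genotypes = GenotypeData(obsG, markers),
    trueGenotypes = trueG,
    haplotypes = list(H1 = H1, H2 = H2),
    truth = list(
      gametes = gametes, xo = xo,
      individuals = data.frame(id = ped$id, a = a, pe = pe, f = f,
                               stringsAsFactors = FALSE),
      qtl = if (nrow(config@qtl))
        cbind(config@qtl, markers[config@qtl$marker, c("marker", "chrom", "bp")])
      else data.frame()),
    config = config), class = "xoversim")
}

#' Write a simulated dataset to disk (PLINK text + truth tables)
#'
#' Emits `prefix.ped`/`prefix.map` (alleles A/B, missing \"0 0\"),
#' `pedigree.csv` (id,sire,dam,sex,age; unknown parent \"0\"), and truth TSVs
#' `gametes_truth.tsv` (one row per crossover-bearing meiosis with
#' comma-separated chrom:bp positions), `bv_truth.tsv` and `qtl_truth.tsv`.
#' Output is deterministic given the simulation seed.
#'
#' @param sim result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @param prefix PLINK file prefix (default \"sim\").
#' @return invisibly, the paths written.
#' @export
writeDataset <- function(sim, dir, prefix = "sim") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gd <- sim$genotypes
  paths <- c(
    ped = file.path(dir, paste0(prefix, ".ped")),
    map = file.path(dir, paste0(prefix, ".map")),
    pedigree = file.path(dir, "pedigree.csv"),
    gametes = file.path(dir, "gametes_truth.tsv"),
    bv = file.path(dir, "bv_truth.tsv"),
    qtl = file.path(dir, "qtl_truth.tsv"))
  writePlink(gd, file.path(dir, prefix), pedigree = sim$pedigree)
  data.table::fwrite(sim$pedigree[, c("id", "sire", "dam", "sex", "age")],
                     paths["pedigree"])
  tg <- sim$truth$gametes
  xo <- sim$truth$xo
  key <- paste(xo$fid, xo$offspring)
  posStr <- vapply(paste(tg$fid, tg$offspring), function(k) {
    sel <- key == k
    if (!any(sel)) return("")
    paste(sprintf("%d:%d", xo$chrom[sel], as.integer(xo$bp[sel])),
          collapse = ",")
  }, "")
  tg$positions <- unname(posStr)
  data.table::fwrite(tg, paths["gametes"], sep = "\t")
  data.table::fwrite(sim$truth$individuals, paths["bv"], sep = "\t")
  qt <- sim$truth$qtl
  if (!ncol(qt))
    qt <- data.frame(marker = character(), chrom = character(),
                     bp = numeric(), effect = numeric())
  data.table::fwrite(qt, paths["qtl"], sep = "\t")
  invisible(paths)
}

#' Fully informative gamete fixture for caller validation
#'
#' Constructs, for each simulated meiosis, a trio in which every marker is
#' informative: the focal parent is heterozygous at all markers with
#' grandparents homozygous for opposite alleles (so phase is forced
#' everywhere) and the mate is homozygous, so the transmitted focal allele
#' is always resolvable. Offspring genotypes can be corrupted with random
#' allele swaps at `genoErrorRate` before calling. This isolates the
#' crossover-calling rules from marker-informativeness effects: with no
#' genotyping error the called count must equal the simulated truth.
#'
#' @param n number of gametes.
#' @param config a [SimConfig-class] providing the genome, female map,
#'   crossover mean and interference shape.
#' @param genoErrorRate per-call allele-swap probability on the offspring.
#' @param minSupport passed to [callCrossovers()].
#' @return data.frame with one row per gamete: `trueAcc`, `calledAcc`.
#' @examples
#' oc <- accCallOracle(20, simConfig(nChromosomes = 2, chromBp = c(1e8, 8e7),
#'                                   muAccFemale = 3, seed = 3))
#' stopifnot(all(oc$calledAcc == oc$trueAcc))
#' @export
accCallOracle <- function(n, config, genoErrorRate = 0, minSupport = 2) {
  set.seed(config@seed)
  mk <- simMarkerTable(config)
  mChrom <- as.integer(mk$chrom)
  cm <- simMarkerCm(config, "F")
  M <- nrow(mk)
  h1 <- rep(0L, M); h2 <- rep(1L, M)
  fidG <- rep(1L, M); faG <- rep(0L, M); moG <- rep(2L, M)
  mateG <- rep(0L, M)
  ph <- phaseFID(fidG, faG, moG)
  out <- data.frame(trueAcc = integer(n), calledAcc = integer(n))
  for (i in seq_len(n)) {
    tgt <- config@muAccFemale + rnorm(1, 0, sqrt(config@varE))
    mz <- simulateMeiosis(h1, h2, mChrom, cm, config@mapLenFemale,
                          targetAcc = tgt, nu = config@interferenceNu,
                          obligate = config@obligate)
    offG <- mz$gamete  # + 0 copies from the homozygous mate
    if (genoErrorRate > 0) {
      hit <- which(runif(M) < genoErrorRate)
      if (length(hit)) {
        cur <- offG[hit]
        up <- rbinom(length(hit), 1L, 0.5) == 1L
        offG[hit] <- ifelse(cur == 0L, 1L,
                     ifelse(cur == 2L, 1L, ifelse(up, 2L, 0L)))
      }
    }
    st <- inferTransmission(ph, fidG, offG, mateG)
    cc <- callCrossovers(st, mk$chrom, mk$bp, minSupport = minSupport)
    out$trueAcc[i] <- nrow(mz$xo)
    out$calledAcc[i] <- cc$acc
  }
  out
}
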