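## Physical lengths (Mb) of the 18 pig autosomes (Sscrofa11.1 scale), used as
## the default simulated genome.
PIG_AUTOSOME_MB <- c(274.3, 151.9, 132.9, 130.9, 104.5, 170.8, 121.8, 139.0,
                     139.5, 69.4, 79.2, 61.6, 208.3, 141.8, 140.7, 79.9,
                     63.5, 56.0)

#' SimConfig: parameters of the pedigreed meiosis simulator
#'
#' See [simConfig()] for field semantics and defaults.
#'
#' @export
setClass("SimConfig",
  slots = c(nChrom = "integer", chromBp = "numeric",
            mapLenFemale = "numeric", mapLenMale = "numeric",
            markersPerChrom = "integer", founderMafRange = "numeric",
            nSires = "integer", nDams = "integer",
            offspringPerMating = "integer", litterRange = "numeric",
            nGenerations = "integer",
            muAccMale = "numeric", muAccFemale = "numeric",
            varA = "numeric", varPe = "numeric", varE = "numeric",
            betaAge = "numeric", betaHet = "numeric",
            qtl = "data.frame", interferenceNu = "numeric",
            obligate = "logical", genoErrorRate = "numeric",
            missingRate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSires < 1L || object@nDams < 1L)
    msg <- c(msg, "need at least one sire and one dam")
  if (any(c(object@varA, object@varPe, object@varE) < 0))
    msg <- c(msg, "variance components must be >= 0")
  r <- object@founderMafRange
  if (length(r) != 2 || r[1] <= 0 || r[2] > 0.5 || r[1] > r[2])
    msg <- c(msg, "founderMafRange must be within (0, 0.5]")
  if (any(object@mapLenFemale <= 0) || any(object@mapLenMale <= 0))
    msg <- c(msg, "map lengths must be > 0")
  if (length(object@chromBp) != object@nChrom ||
      length(object@mapLenFemale) != object@nChrom ||
      length(object@mapLenMale) != object@nChrom)
    msg <- c(msg, "chromBp and map lengths must have nChrom elements")
  if (object@obligate &&
      (object@muAccMale < object@nChrom || object@muAccFemale < object@nChrom))
    msg <- c(msg, "with obligate crossovers, mu ACC must be >= nChrom")
  if (object@interferenceNu <= 0)
    msg <- c(msg, "interferenceNu must be > 0")
  lr <- object@litterRange
  if (length(lr) && (length(lr) != 2 || lr[1] < 1 || lr[1] > lr[2]))
    msg <- c(msg, "litterRange must be c(lo, hi) with 1 <= lo <= hi")
  if (nrow(object@qtl) &&
      !all(c("marker", "effect") %in% names(object@qtl)))
    msg <- c(msg, "qtl must have columns marker (index) and effect")
  if (length(msg)) msg else TRUE
})

#' Configure the pedigreed recombination simulator
#'
#' Defaults emulate a commercial pig-style population: 18 autosomes with the
#' pig physical lengths, sex-specific genome map totals of 1800 cM (male) and
#' 2300 cM (female) (female:male ratio 1.278), mean crossovers per gamete
#' matching those totals (18 male / 23 female), a polygynous multi-generation
#' pedigree with few sires and many dams, and ACC variance components on the
#' observed scale (varA 2, varPe 1, varE 17: phenotypic variance 20,
#' h2 = 0.10, SD ~ 4.5 crossovers).
#'
#' @param nChromosomes number of autosomes.
#' @param chromBp physical chromosome lengths in bp.
#' @param mapLenFemale,mapLenMale per-chromosome map lengths in cM. Defaults
#'   scale `chromBp` so genome totals are 2300 (female) and 1800 (male) cM.
#' @param markersPerChrom markers simulated per chromosome (evenly spaced).
#'   The default of 200 (3600 genome-wide) behaves like a down-sampled
#'   medium-density SNP chip: informative-marker gaps are small enough that
#'   called crossover counts track the simulated truth closely. Much
#'   sparser panels progressively merge and lose crossovers.
#' @param founderMafRange interval in (0, 0.5]; founder minor allele
#'   frequencies are drawn uniformly from it (linkage equilibrium).
#' @param nSires,nDams breeding males/females used per generation.
#' @param offspringPerMating full sibs per mating.
#' @param litterRange optional integer range c(lo, hi): litter sizes are
#'   drawn uniformly from it per mating instead of the fixed
#'   `offspringPerMating` (commercial pig datasets show 1-27 genotyped
#'   offspring per family).
#' @param nGenerations number of generations (>= 3 gives three-generation
#'   full-sib families).
#' @param muAccMale,muAccFemale mean crossovers per transmitted gamete by sex
#'   of the transmitting parent.
#' @param varA,varPe,varE additive, permanent-environment and residual
#'   variance of the per-gamete crossover count.
#' @param betaAge fixed-effect slope of ACC on parent age class (1-4).
#' @param betaHet fixed-effect slope of ACC on pedigree inbreeding F.
#' @param qtl data.frame with columns `marker` (global marker index) and
#'   `effect` (additive effect on ACC in crossovers per allele).
#' @param interferenceNu gamma-renewal shape controlling crossover
#'   interference; 1 = none (uniform placement), larger values space
#'   crossovers more evenly. Default 8, a typical mammalian interference
#'   strength.
#' @param obligate logical; if TRUE every chromosome receives at least one
#'   crossover per meiosis and targets below the obligate minimum are clamped.
#' @param genoErrorRate per-call probability of a random allele swap in the
#'   observed genotypes.
#' @param missingRate per-call probability of a missing observed genotype.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nSires = 2, nDams = 10, offspringPerMating = 5, seed = 1)
#' cfg
#' @export
simConfig <- function(nChromosomes = 18,
                      chromBp = PIG_AUTOSOME_MB * 1e6,
                      mapLenFemale = NULL,
                      mapLenMale = NULL,
                      markersPerChrom = 200,
                      founderMafRange = c(0.1, 0.5),
                      nSires = 10, nDams = 100, offspringPerMating = 4,
                      litterRange = NULL, nGenerations = 3,
                      muAccMale = 18, muAccFemale = 23,
                      varA = 2, varPe = 1, varE = 17,
                      betaAge = 0, betaHet = 0,
                      qtl = data.frame(marker = integer(), effect = numeric()),
                      interferenceNu = 8,
                      obligate = FALSE,
                      genoErrorRate = 0, missingRate = 0,
                      seed = 1L) {
  chromBp <- chromBp[seq_len(nChromosomes)]
  if (is.null(mapLenFemale))
    mapLenFemale <- chromBp / sum(chromBp) * 2300
  if (is.null(mapLenMale))
    mapLenMale <- chromBp / sum(chromBp) * 1800
  new("SimConfig",
      nChrom = as.integer(nChromosomes), chromBp = as.numeric(chromBp),
      mapLenFemale = as.numeric(mapLenFemale),
      mapLenMale = as.numeric(mapLenMale),
      markersPerChrom = as.integer(markersPerChrom),
      founderMafRange = as.numeric(founderMafRange),
      nSires = as.integer(nSires), nDams = as.integer(nDams),
      offspringPerMating = as.integer(offspringPerMating),
      litterRange = if (is.null(litterRange)) numeric(0) else
        as.numeric(litterRange),
      nGenerations = as.integer(nGenerations),
      muAccMale = as.numeric(muAccMale), muAccFemale = as.numeric(muAccFemale),
      varA = as.numeric(varA), varPe = as.numeric(varPe),
      varE = as.numeric(varE),
      betaAge = as.numeric(betaAge), betaHet = as.numeric(betaHet),
      qtl = qtl, interferenceNu = as.numeric(interferenceNu),
      obligate = isTRUE(obligate),
      genoErrorRate = as.numeric(genoErrorRate),
      missingRate = as.numeric(missingRate),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nChrom, "chromosomes,",
      object@markersPerChrom, "markers/chrom\n")
  cat(sprintf("  map totals: male %.0f cM, female %.0f cM\n",
              sum(object@mapLenMale), sum(object@mapLenFemale)))
  cat(sprintf("  pedigree: %d sires x %d dams x %d offspring, %d generations\n",
              object@nSires, object@nDams, object@offspringPerMating,
              object@nGenerations))
  cat(sprintf("  ACC: mu M/F %.1f/%.1f, varA %.2f varPe %.2f varE %.2f\n",
              object@muAccMale, object@muAccFemale,
              object@varA, object@varPe, object@varE))
})

## marker table implied by a config: evenly spaced positions per chromosome
simMarkerTable <- function(config) {
  k <- config@markersPerChrom
  out <- lapply(seq_len(config@nChrom), function(c) {
    bp <- round(seq(1, config@chromBp[c], length.out = k))
    data.frame(marker = sprintf("snp%02d_%04d", c, seq_len(k)),
               chrom = as.character(c), bp = bp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## cM position of each marker on the (linear) true map of one sex
simMarkerCm <- function(config, sex) {
  len <- if (sex == "F") config@mapLenFemale else config@mapLenMale
  unlist(lapply(seq_len(config@nChrom), function(c) {
    bp <- round(seq(1, config@chromBp[c], length.out = config@markersPerChrom))
    (bp - 1) / (config@chromBp[c] - 1) * len[c]
  }))
}
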