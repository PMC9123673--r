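#' Marker and phenotype QC thresholds
#'
#' Boundary semantics are inclusive for retention: markers with MAF exactly
#' at `mafMin`, call rate exactly at `callRateMin` or HWE chi-square exactly
#' at `hweChi2Max` are kept; gametes with ACC exactly at `accMin` or `accMax`
#' are kept.
#'
#' @param mafMin minimum minor allele frequency (exclusion is MAF < mafMin).
#' @param callRateMin minimum genotype call rate.
#' @param hweChi2Max maximum Hardy-Weinberg goodness-of-fit chi-square.
#' @param segTolerance p-value cut for the segregation-distortion test.
#' @param lodMin minimum two-point LOD for linkage-group membership.
#' @param accMin,accMax retained range of autosomal crossover counts.
#' @return list of thresholds (class `qcThresholds`).
#' @export
qcThresholds <- function(mafMin = 0.01, callRateMin = 0.95,
                         hweChi2Max = 600, segTolerance = 0.01,
                         lodMin = 5, accMin = 6, accMax = 50) {
  structure(list(mafMin = mafMin, callRateMin = callRateMin,
                 hweChi2Max = hweChi2Max, segTolerance = segTolerance,
                 lodMin = lodMin, accMin = accMin, accMax = accMax),
            class = "qcThresholds")
}

#' Per-marker summary statistics
#'
#' Computes, over non-missing genotypes: the counted-allele frequency `p`,
#' minor allele frequency `maf = min(p, 1 - p)`, call rate, and the
#' Hardy-Weinberg goodness-of-fit chi-square over the three genotype classes
#' (expected counts from `p` and the non-missing sample size; classes with
#' zero expectation contribute zero). All-missing markers get `NA` stats and
#' call rate 0 so they fail the call-rate filter.
#'
#' @param gd a [GenotypeData-class].
#' @return data.frame: marker, chrom, bp, p, maf, callRate, hweChi2,
#'   counts n0/n1/n2.
#' @examples
#' gd <- simulateFounderGenotypes(100, 20, seed = 2)
#' head(markerStats(gd))
#' @export
markerStats <- function(gd) {
  g <- genotypes(gd)
  nm <- !is.na(g)
  nObs <- colSums(nm)
  n0 <- colSums(g == 0L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n2 <- colSums(g == 2L, na.rm = TRUE)
  p <- ifelse(nObs > 0, (n1 + 2 * n2) / (2 * nObs), NA_real_)
  e0 <- nObs * (1 - p)^2; e1 <- nObs * 2 * p * (1 - p); e2 <- nObs * p^2
  term <- function(o, e) ifelse(is.na(e) | e == 0, 0, (o - e)^2 / e)
  chi2 <- term(n0, e0) + term(n1, e1) + term(n2, e2)
  chi2[nObs == 0] <- NA_real_
  m <- markerInfo(gd)
  data.frame(marker = m$marker, chrom = m$chrom, bp = m$bp,
             p = p, maf = pmin(p, 1 - p),
             callRate = nObs / nrow(g), hweChi2 = chi2,
             n0 = n0, n1 = n1, n2 = n2, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Filter markers on MAF, call rate and HWE
#'
#' Keeps markers with `maf >= mafMin` AND `callRate >= callRateMin` AND
#' `hweChi2 <= hweChi2Max` (boundary values kept). The exclusion log records
#' one reason per dropped marker, the first failing rule in the order MAF,
#' call rate, HWE.
#'
#' @param stats output of [markerStats()].
#' @param thresholds a [qcThresholds()] list.
#' @return list: `keep` (character marker ids), `log` (data.frame marker,
#'   reason for the excluded ones).
#' @export
filterMarkers <- function(stats, thresholds = qcThresholds()) {
  failMaf <- is.na(stats$maf) | stats$maf < thresholds$mafMin
  failCall <- stats$callRate < thresholds$callRateMin
  failHwe <- !is.na(stats$hweChi2) & stats$hweChi2 > thresholds$hweChi2Max
  ## all-missing markers: stats undefined, fail on call rate
  failMaf[stats$callRate == 0] <- FALSE
  failCall[stats$callRate == 0] <- TRUE
  reason <- rep(NA_character_, nrow(stats))
  reason[failHwe] <- "hwe"
  reason[failCall] <- "call_rate"
  reason[failMaf] <- "maf"
  drop <- !is.na(reason)
  list(keep = stats$marker[!drop],
       log = data.frame(marker = stats$marker[drop],
                        reason = reason[drop], stringsAsFactors = FALSE))
}

## transmitted-allele resolution for one parent at one offspring, vectorised
## over markers: returns 0/1 (allele sent by `parent`) or NA when ambiguous.
## Counted-allele coding: genotype = copies of allele "B".
transmittedAllele <- function(parentG, mateG, offG) {
  out <- rep(NA_integer_, length(parentG))
  known <- !is.na(parentG) & !is.na(offG)
  out[known & offG == 0L] <- 0L
  out[known & offG == 2L] <- 1L
  hetOff <- known & offG == 1L & !is.na(mateG)
  out[hetOff & mateG == 0L] <- 1L  # mate must have sent A
  out[hetOff & mateG == 2L] <- 0L
  ## a homozygous parent can only send its own allele; keep consistency
  out[which(parentG == 0L & out == 1L)] <- NA_integer_
  out[which(parentG == 2L & out == 0L)] <- NA_integer_
  out
}

#' Segregation-distortion filter
#'
#' For each marker, pools transmissions from heterozygous parents across all
#' families (both focal parents of every genotyped offspring, where the
#' transmitted allele can be resolved) and tests 1:1 transmission with a
#' 1-df chi-square. Markers with p below `tolerance` are dropped; markers
#' with no informative transmission are kept and flagged untested.
#'
#' @param gd a [GenotypeData-class] (coded 0/1/2 counted-allele copies).
#' @param families output of [buildFamilies()].
#' @param tolerance p-value cut (default 0.01).
#' @return data.frame: marker, nB (transmissions of the counted allele), n,
#'   chi2, p, tested, keep.
#' @export
segDistortionFilter <- function(gd, families, tolerance = 0.01) {
  g <- genotypes(gd)
  M <- ncol(g)
  nB <- numeric(M); n <- numeric(M)
  for (r in seq_len(nrow(families))) {
    sire <- families$sire[r]; dam <- families$dam[r]
    offs <- families$genotypedOffspring[[r]]
    sg <- g[sire, ]; dg <- g[dam, ]
    for (o in offs) {
      og <- g[o, ]
      for (par in c("s", "d")) {
        pg <- if (par == "s") sg else dg
        mg <- if (par == "s") dg else sg
        ta <- transmittedAllele(pg, mg, og)
        ## mate genotype required: resolving via offspring homozygosity
        ## alone conditions on which allele the mate sent and would fake
        ## distortion at unbalanced allele frequencies
        inf <- !is.na(ta) & !is.na(pg) & pg == 1L & !is.na(mg)
        ## in a double-heterozygous trio the two parental transmissions are
        ## resolvable only together (homozygous offspring) and are then
        ## identical; counting both would double one Mendelian coin flip,
        ## so the dam's copy is dropped there
        if (par == "d") inf <- inf & mg != 1L
        nB[inf] <- nB[inf] + ta[inf]
        n[inf] <- n[inf] + 1
      }
    }
  }
  chi2 <- ifelse(n > 0, (2 * nB - n)^2 / n, NA_real_)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  tested <- n > 0
  data.frame(marker = markerInfo(gd)$marker, nB = nB, n = n,
             chi2 = chi2, p = p, tested = tested,
             keep = !tested | p >= tolerance,
             stringsAsFactors = FALSE)
}

#' Method-of-moments inbreeding coefficient from genotypes
#'
#' `F = (Ohom - Ehom) / (L - Ehom)` per individual over its L non-missing
#' polymorphic markers, with `Ehom = sum(1 - 2 p (1 - p))` by default; with
#' `smallSampleCorrection = TRUE` the expected heterozygosity term uses the
#' `2 p q * n/(n - 1)` small-sample correction applied per marker.
#'
#' @param gd a [GenotypeData-class].
#' @param freqs optional counted-allele frequencies (defaults to the sample
#'   frequencies of `gd`).
#' @param smallSampleCorrection logical, default FALSE.
#' @return named numeric vector of F per individual; `NA` (flagged via
#'   attribute `degenerate`) where `L == Ehom`.
#' @examples
#' g <- matrix(1L, 1, 4, dimnames = list("x", paste0("m", 1:4)))
#' gd <- GenotypeData(g, data.frame(marker = paste0("m", 1:4),
#'                                  chrom = "1", bp = 1:4))
#' hetCoefficient(gd, freqs = rep(0.5, 4))  # all-het at p = 0.5: F = -1
#' @export
hetCoefficient <- function(gd, freqs = NULL, smallSampleCorrection = FALSE) {
  g <- genotypes(gd)
  nm <- !is.na(g)
  if (is.null(freqs)) {
    nObs <- colSums(nm)
    freqs <- ifelse(nObs > 0, colSums(g, na.rm = TRUE) / (2 * nObs), NA_real_)
  }
  poly <- !is.na(freqs) & freqs > 0 & freqs < 1
  g <- g[, poly, drop = FALSE]; nm <- nm[, poly, drop = FALSE]
  p <- freqs[poly]
  hetExp <- 2 * p * (1 - p)
  if (smallSampleCorrection) {
    nk <- colSums(nm)
    hetExp <- hetExp * ifelse(nk > 1, nk / (nk - 1), 1)
  }
  eHomPer <- 1 - hetExp
  L <- rowSums(nm)
  oHom <- rowSums(g != 1L, na.rm = TRUE)
  eHom <- as.numeric(nm %*% eHomPer)
  denom <- L - eHom
  f <- ifelse(abs(denom) < 1e-12, NA_real_, (oHom - eHom) / denom)
  structure(setNames(f, rownames(g)), degenerate = abs(denom) < 1e-12)
}
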