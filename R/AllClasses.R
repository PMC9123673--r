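#' GenotypeData: SNP genotypes with marker metadata
#'
#' Container for an individuals-by-markers matrix of additive genotype codes
#' (0, 1, 2 copies of the counted allele; `NA` = missing) together with the
#' marker map (chromosome and 1-based physical bp position).
#'
#' @slot geno integer matrix, individuals in rows (rownames = sample ids),
#'   markers in columns (colnames = marker ids).
#' @slot markers data.frame with columns `marker`, `chrom`, `bp`, one row per
#'   column of `geno`, in the same order. Markers are expected sorted by
#'   (chrom, bp).
#' @export
setClass("GenotypeData",
  slots = c(geno = "matrix", markers = "data.frame"))

setValidity("GenotypeData", function(object) {
  g <- object@geno; m <- object@markers
  msg <- character()
  if (!all(c("marker", "chrom", "bp") %in% names(m)))
    msg <- c(msg, "markers must have columns marker, chrom, bp")
  if (nrow(m) != ncol(g))
    msg <- c(msg, "nrow(markers) must equal ncol(geno)")
  if (is.null(rownames(g)) || anyDuplicated(rownames(g)))
    msg <- c(msg, "geno must have unique rownames (sample ids)")
  bad <- g[!is.na(g)]
  if (length(bad) && !all(bad %in% 0:2))
    msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  if (nrow(m) && any(m$bp < 1, na.rm = TRUE))
    msg <- c(msg, "bp positions must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param geno numeric/integer matrix of 0/1/2/NA codes with sample ids as
#'   rownames.
#' @param markers data.frame with columns `marker`, `chrom`, `bp`.
#' @return A [GenotypeData-class] object.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 1L), 2, 2,
#'             dimnames = list(c("a", "b"), c("m1", "m2")))
#' gd <- GenotypeData(g, data.frame(marker = c("m1", "m2"),
#'                                  chrom = "1", bp = c(100, 200)))
#' nMarkers(gd)
#' @export
GenotypeData <- function(geno, markers) {
  storage.mode(geno) <- "integer"
  markers$marker <- as.character(markers$marker)
  markers$chrom <- as.character(markers$chrom)
  if (is.null(colnames(geno))) colnames(geno) <- markers$marker
  rownames(markers) <- NULL
  new("GenotypeData", geno = geno, markers = markers)
}

#' @describeIn GenotypeData-class genotype matrix accessor
#' @param x,object a `GenotypeData` object
#' @export
genotypes <- function(x) x@geno

#' @describeIn GenotypeData-class marker metadata accessor
#' @export
markerInfo <- function(x) x@markers

#' @describeIn GenotypeData-class sample id accessor
#' @export
sampleIds <- function(x) rownames(x@geno)

#' @describeIn GenotypeData-class number of markers
#' @export
nMarkers <- function(x) ncol(x@geno)

#' @describeIn GenotypeData-class number of samples
#' @export
nSamples <- function(x) nrow(x@geno)

#' @describeIn GenotypeData-class subset by samples (i) and/or markers (j);
#'   markers may be given as ids or indices
#' @param i,j,...,drop subsetting indices (samples, markers); `drop` ignored
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@geno))
  if (missing(j)) j <- seq_len(ncol(x@geno))
  if (is.character(j)) j <- match(j, x@markers$marker)
  GenotypeData(x@geno[i, j, drop = FALSE], x@markers[j, , drop = FALSE])
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@geno), "samples x",
      ncol(object@geno), "markers on",
      length(unique(object@markers$chrom)), "chromosome(s)\n")
  mr <- mean(is.na(object@geno))
  cat(sprintf("  missing rate: %.4f\n", mr))
})

#' SexLinkageMap: sex-specific linkage map with totals and landscape
#'
#' @slot map data.frame: `chrom`, `marker`, `bp`, `cmMale`, `cmFemale`
#'   (cumulative cM within chromosome, 0 at the first marker).
#' @slot summary data.frame: per-chromosome `mb`, `cmMale`, `cmFemale` plus
#'   genome totals as attributes `totalMale`, `totalFemale`.
#' @slot landscape data.frame: `chrom`, `windowStart`, `windowEnd`,
#'   `cmPerMbMale`, `cmPerMbFemale`.
#' @export
setClass("SexLinkageMap",
  slots = c(map = "data.frame", summary = "data.frame",
            landscape = "data.frame"))

#' @describeIn SexLinkageMap-class per-marker map accessor
#' @param x,object a `SexLinkageMap`
#' @export
mapPositions <- function(x) x@map

#' @describeIn SexLinkageMap-class per-chromosome summary accessor
#' @export
mapSummary <- function(x) x@summary

#' @describeIn SexLinkageMap-class cM/Mb landscape accessor
#' @export
mapLandscape <- function(x) x@landscape

#' @describeIn SexLinkageMap-class genome totals (cM) per sex
#' @export
mapTotals <- function(x) {
  c(male = sum(x@summary$cmMale, na.rm = TRUE),
    female = sum(x@summary$cmFemale, na.rm = TRUE))
}

setMethod("show", "SexLinkageMap", function(object) {
  tot <- mapTotals(object)
  cat("SexLinkageMap:", nrow(object@summary), "chromosomes,",
      nrow(object@map), "markers\n")
  cat(sprintf("  total map length: male %.1f cM, female %.1f cM (F:M %.3f)\n",
              tot["male"], tot["female"], tot["female"] / tot["male"]))
})

#' RemlFit: AI-REML variance component estimates for the ACC model
#'
#' @slot varA,varPe,varE numeric variance components (additive, permanent
#'   environment, residual).
#' @slot h2 narrow-sense heritability varA / (varA + varPe + varE).
#' @slot se named numeric: standard errors of `varA`, `varPe`, `varE`, `h2`
#'   (inverse average-information matrix; delta method for h2).
#' @slot fixef data.frame of fixed-effect solutions: `term`, `estimate`, `se`.
#' @slot logLik REML log-likelihood (up to a constant) at convergence.
#' @slot trace data.frame iteration trace.
#' @slot converged logical.
#' @slot boundary logical: any variance pinned at its lower bound.
#' @export
setClass("RemlFit",
  slots = c(varA = "numeric", varPe = "numeric", varE = "numeric",
            h2 = "numeric", se = "numeric", fixef = "data.frame",
            logLik = "numeric", trace = "data.frame",
            converged = "logical", boundary = "logical"))

#' @describeIn RemlFit-class variance components as a named vector
#' @param x,object a `RemlFit`
#' @export
varComponents <- function(x) {
  c(varA = x@varA, varPe = x@varPe, varE = x@varE)
}

#' @describeIn RemlFit-class heritability estimate with its SE
#' @export
heritability <- function(x) c(h2 = x@h2, se = unname(x@se["h2"]))

#' @describeIn RemlFit-class fixed-effect solutions
#' @export
fixedEffects <- function(x) x@fixef

setMethod("show", "RemlFit", function(object) {
  cat("RemlFit (repeatability animal model, AI-REML)\n")
  cat(sprintf("  varA = %.4f  varPe = %.4f  varE = %.4f\n",
              object@varA, object@varPe, object@varE))
  cat(sprintf("  h2 = %.4f (SE %.4f); converged: %s after %d iterations\n",
              object@h2, object@se["h2"], object@converged,
              nrow(object@trace)))
})
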