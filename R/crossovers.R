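## Mendelian-inconsistency indicator for a (child, father, mother) trio,
## vectorised over markers. Counts only combinations that are impossible
## under biparental inheritance.
mendelErrors <- function(childG, faG, moG) {
  e <- (childG == 0L & (faG %in% 2L | moG %in% 2L)) |
       (childG == 2L & (faG %in% 0L | moG %in% 0L)) |
       (childG == 1L & ((faG %in% 0L & moG %in% 0L) |
                        (faG %in% 2L & moG %in% 2L)))
  e & !is.na(childG)
}

#' Phase a focal individual against its parents
#'
#' At markers where the FID is heterozygous, Mendelian rules against the
#' parental genotypes determine which allele is paternal: a homozygous
#' father forces his allele onto the paternal haplotype; failing that, a
#' homozygous mother forces the maternal allele (so the paternal one is the
#' other). Markers where both parents are heterozygous (or missing) stay
#' unphased; Mendelian-inconsistent markers are set unknown and counted.
#' Homozygous FID markers are phase-trivial and uninformative for crossover
#' detection.
#'
#' @param fidG,faG,moG genotype vectors (0/1/2/NA counted-allele copies) of
#'   the focal individual and its father and mother, on the same marker
#'   panel.
#' @return list: `pat` (0/1 allele on the paternal haplotype at phased
#'   heterozygous markers, NA elsewhere), `het` (logical, FID heterozygous),
#'   `phased` (logical), `fracPhased` (share of het markers phased),
#'   `nMendel`, `mendelRate` (errors over markers with all three genotypes
#'   present).
#' @examples
#' phaseFID(c(1L, 1L), c(0L, 1L), c(2L, 1L))
#' @export
phaseFID <- function(fidG, faG, moG) {
  M <- length(fidG)
  stopifnot(length(faG) == M, length(moG) == M)
  err <- mendelErrors(fidG, faG, moG)
  het <- !is.na(fidG) & fidG == 1L
  pat <- rep(NA_integer_, M)
  use <- het & !err
  i <- which(use & faG %in% 0L); pat[i] <- 0L
  i <- which(use & faG %in% 2L); pat[i] <- 1L
  i <- which(use & is.na(pat) & moG %in% 0L); pat[i] <- 1L
  i <- which(use & is.na(pat) & moG %in% 2L); pat[i] <- 0L
  complete <- !is.na(fidG) & !is.na(faG) & !is.na(moG)
  list(pat = pat, het = het, phased = !is.na(pat),
       fracPhased = if (any(het)) mean(!is.na(pat[het])) else NA_real_,
       nMendel = sum(err),
       mendelRate = if (any(complete)) sum(err) / sum(complete) else 0)
}

#' Infer which focal haplotype each offspring received
#'
#' At phased heterozygous FID markers, deduces the allele the FID
#' transmitted to the offspring (directly when the offspring is homozygous;
#' via the mate's genotype when the offspring is heterozygous and the mate
#' is homozygous) and maps it to haplotype state 1 (grandpaternal) or 2
#' (grandmaternal). Unresolvable, missing or Mendelian-inconsistent markers
#' are unknown.
#'
#' @param phase output of [phaseFID()] for the focal individual.
#' @param fidG,offG,mateG genotypes of the FID, offspring and mate.
#' @return integer vector of states 1/2/NA with attribute `mendelRate`
#'   (offspring-vs-pair inconsistency rate over complete markers).
#' @export
inferTransmission <- function(phase, fidG, offG, mateG) {
  sent <- transmittedAllele(fidG, mateG, offG)
  err <- mendelErrors(offG, fidG, mateG)
  sent[err] <- NA_integer_
  state <- rep(NA_integer_, length(fidG))
  ok <- which(phase$phased & !is.na(sent))
  state[ok] <- ifelse(sent[ok] == phase$pat[ok], 1L, 2L)
  complete <- !is.na(offG) & !is.na(fidG) & !is.na(mateG)
  attr(state, "mendelRate") <-
    if (any(complete)) sum(err, na.rm = TRUE) / sum(complete) else 0
  state
}

## drop runs shorter than minSupport from an informative state sequence,
## iterating until all remaining runs are supported; returns indices kept
supportedRuns <- function(v, minSupport) {
  keep <- seq_along(v)
  repeat {
    if (!length(keep)) return(keep)
    r <- rle(v[keep])
    if (length(r$lengths) <= 1L || all(r$lengths >= minSupport)) return(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    short <- r$lengths < minSupport
    if (all(short)) {  # keep the single longest run
      j <- which.max(r$lengths)
      return(keep[starts[j]:ends[j]])
    }
    drop <- unlist(mapply(function(s, e) s:e, starts[short], ends[short],
                          SIMPLIFY = FALSE))
    keep <- keep[-drop]
  }
}

#' Call crossovers from a gamete state sequence
#'
#' Unknown states are skipped; a crossover is a switch between consecutive
#' informative states, localised to the half-open bp interval between the
#' flanking informative markers. Runs of fewer than `minSupport` consecutive
#' identical states are treated as genotyping error and reverted before
#' counting (singleton reversion with the default of 2). Chromosomes with
#' fewer than two informative markers contribute zero crossovers and are
#' flagged uninformative.
#'
#' @param states integer vector (1/2/NA) over all markers.
#' @param chrom chromosome of each marker.
#' @param bp physical position of each marker.
#' @param minSupport minimum run length accepted as a real phase (default 2).
#' @return list: `acc` (total crossovers), `intervals` (data.frame chrom,
#'   startBp, endBp), `cleaned` (states with reverted/uninformative markers
#'   set NA), `nInformative`, `uninformativeChrom`.
#' @examples
#' st <- c(1L, 1L, 1L, 2L, 2L)
#' callCrossovers(st, rep("1", 5), 1:5 * 100)$intervals
#' @export
callCrossovers <- function(states, chrom, bp, minSupport = 2) {
  acc <- 0L
  cleaned <- rep(NA_integer_, length(states))
  ivals <- list()
  uninf <- character(0)
  for (c in unique(chrom)) {
    sel <- which(chrom == c)
    inf <- sel[!is.na(states[sel])]
    if (length(inf) < 2L) {
      if (length(inf) < 1L) uninf <- c(uninf, c)
      cleaned[inf] <- states[inf]
      next
    }
    keep <- inf[supportedRuns(states[inf], minSupport)]
    cleaned[keep] <- states[keep]
    if (length(keep) < 2L) next
    r <- rle(states[keep])
    nxo <- length(r$lengths) - 1L
    acc <- acc + nxo
    if (nxo > 0L) {
      ends <- cumsum(r$lengths)
      left <- keep[ends[-length(ends)]]
      right <- keep[ends[-length(ends)] + 1L]
      ivals[[length(ivals) + 1L]] <-
        data.frame(chrom = c, startBp = bp[left], endBp = bp[right],
                   stringsAsFactors = FALSE)
    }
  }
  intervals <- if (length(ivals)) do.call(rbind, ivals) else
    data.frame(chrom = character(), startBp = numeric(), endBp = numeric())
  list(acc = acc, intervals = intervals, cleaned = cleaned,
       nInformative = sum(!is.na(states)), uninformativeChrom = uninf)
}

#' Phase families and call crossovers for every gamete
#'
#' The full caller: phases each focal parent against its own parents, infers
#' the transmitted haplotype state at every informative marker for each
#' genotyped offspring, and calls crossovers per gamete with singleton
#' reversion. Trios whose Mendelian-error rate exceeds `mendelCeiling` are
#' excluded (family level for FID phasing, gamete level for offspring).
#'
#' @param gd a [GenotypeData-class] on the QC-passed panel.
#' @param pedigree pedigree data.frame (id, sire, dam, sex, optionally age).
#' @param families output of [buildFamilies()]; defaults to building them
#'   from `pedigree` and the genotyped ids.
#' @param minSupport run-length threshold for [callCrossovers()].
#' @param mendelCeiling maximum tolerated trio Mendelian-error rate.
#' @return list of class `gameteSet`: `gametes` (data.frame fid, offspring,
#'   parentSex, age, acc, nInformative, fracPhased), `states` (gametes x
#'   markers integer matrix of cleaned states), `intervals` (long data.frame
#'   of crossover intervals), `markers`, `log` (excluded families/gametes).
#' @export
callGametes <- function(gd, pedigree, families = NULL, minSupport = 2,
                        mendelCeiling = 0.05) {
  if (is.null(families))
    families <- buildFamilies(pedigree, sampleIds(gd))
  g <- genotypes(gd)
  mk <- markerInfo(gd)
  ped <- pedigree
  ped$id <- as.character(ped$id)
  age <- if ("age" %in% names(ped)) setNames(ped$age, ped$id) else NULL
  logRows <- list()
  gamRows <- list()
  stRows <- list()
  ivRows <- list()
  seen <- character(0)
  for (r in seq_len(nrow(families))) {
    fam <- families[r, ]
    phS <- phaseFID(g[fam$sire, ], g[fam$sireSire, ], g[fam$sireDam, ])
    phD <- phaseFID(g[fam$dam, ], g[fam$damSire, ], g[fam$damDam, ])
    if (phS$mendelRate > mendelCeiling || phD$mendelRate > mendelCeiling) {
      logRows[[length(logRows) + 1L]] <- data.frame(
        unit = paste(fam$sire, fam$dam, sep = "x"), level = "family",
        reason = "fid_mendel_rate", stringsAsFactors = FALSE)
      next
    }
    for (o in fam$genotypedOffspring[[1]]) {
      for (side in c("M", "F")) {
        fid <- if (side == "M") fam$sire else fam$dam
        mate <- if (side == "M") fam$dam else fam$sire
        keyG <- paste(fid, o)
        if (keyG %in% seen) next
        seen <- c(seen, keyG)
        ph <- if (side == "M") phS else phD
        st <- inferTransmission(ph, g[fid, ], g[o, ], g[mate, ])
        if (attr(st, "mendelRate") > mendelCeiling) {
          logRows[[length(logRows) + 1L]] <- data.frame(
            unit = keyG, level = "gamete", reason = "offspring_mendel_rate",
            stringsAsFactors = FALSE)
          next
        }
        cc <- callCrossovers(st, mk$chrom, mk$bp, minSupport = minSupport)
        gamRows[[length(gamRows) + 1L]] <- data.frame(
          fid = fid, offspring = o, parentSex = side,
          age = if (!is.null(age)) unname(age[o]) else NA_integer_,
          acc = cc$acc, nInformative = cc$nInformative,
          fracPhased = ph$fracPhased, stringsAsFactors = FALSE)
        stRows[[length(stRows) + 1L]] <- cc$cleaned
        if (nrow(cc$intervals))
          ivRows[[length(ivRows) + 1L]] <-
            cbind(fid = fid, offspring = o, parentSex = side,
                  cc$intervals, stringsAsFactors = FALSE)
      }
    }
  }
  gametes <- if (length(gamRows)) do.call(rbind, gamRows) else
    data.frame(fid = character(), offspring = character(),
               parentSex = character(), age = integer(), acc = integer(),
               nInformative = integer(), fracPhased = numeric())
  states <- if (length(stRows)) do.call(rbind, stRows) else
    matrix(NA_integer_, 0, nrow(mk))
  colnames(states) <- mk$marker
  intervals <- if (length(ivRows)) do.call(rbind, ivRows) else
    data.frame(fid = character(), offspring = character(),
               parentSex = character(), chrom = character(),
               startBp = numeric(), endBp = numeric())
  structure(list(gametes = gametes, states = states, intervals = intervals,
                 markers = mk,
                 log = if (length(logRows)) do.call(rbind, logRows) else
                   data.frame(unit = character(), level = character(),
                              reason = character())),
            class = "gameteSet")
}

#' Collect the ACC phenotype table
#'
#' One record per gamete with the quality flag `qcPass` = ACC within
#' `[accMin, accMax]` (boundaries kept: \"less than\" `accMin` or \"more
#' than\" `accMax` excluded), plus per-sex summary statistics of the
#' retained gametes.
#'
#' @param gameteSet output of [callGametes()] (or any data.frame with fid,
#'   offspring, parentSex, acc).
#' @param thresholds a [qcThresholds()] list.
#' @return data.frame of gametes with `qcPass`; per-sex mean/SD/count of
#'   passing gametes in attribute `summary`.
#' @export
collectACC <- function(gameteSet, thresholds = qcThresholds()) {
  tab <- if (inherits(gameteSet, "gameteSet")) gameteSet$gametes else
    gameteSet
  tab$qcPass <- tab$acc >= thresholds$accMin & tab$acc <= thresholds$accMax
  keep <- tab[tab$qcPass, , drop = FALSE]
  summ <- if (nrow(keep)) {
    ag <- aggregate(keep$acc, by = list(parentSex = keep$parentSex),
                    FUN = function(x) c(mean = mean(x), sd = sd(x),
                                        n = length(x)))
    data.frame(parentSex = ag$parentSex, mean = ag$x[, "mean"],
               sd = ag$x[, "sd"], n = ag$x[, "n"],
               stringsAsFactors = FALSE)
  } else {
    data.frame(parentSex = character(), mean = numeric(), sd = numeric(),
               n = numeric())
  }
  attr(tab, "summary") <- summ
  tab
}
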