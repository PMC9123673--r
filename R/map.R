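#' Haldane mapping function and its inverse
#'
#' `haldaneCM(r) = -50 * log(1 - 2 r)` converts a recombination fraction to
#' map distance in cM assuming no interference; `haldaneR(cm)` is the
#' inverse `(1 - exp(-cm / 50)) / 2`. Fractions at or above `cap` are capped
#' before the transform so sampling noise near 0.5 never yields an infinite
#' distance.
#'
#' @param r recombination fraction(s) in `[0, 0.5]`.
#' @param cm map distance(s) in cM.
#' @param cap maximum fraction used in the transform (default 0.49).
#' @return numeric vector of cM (or fractions for `haldaneR`).
#' @examples
#' haldaneCM(0.25)            # -50 log(0.5) = 34.657
#' haldaneR(haldaneCM(0.37))  # 0.37
#' @export
haldaneCM <- function(r, cap = 0.49) {
  -50 * log(1 - 2 * pmin(r, cap))
}

#' @rdname haldaneCM
#' @export
haldaneR <- function(cm) {
  (1 - exp(-cm / 50)) / 2
}

#' Two-point recombination estimate between two markers
#'
#' `N` is the number of gametes with known phase state at both markers, `R`
#' the number whose state differs; the estimate is `r = R / N`.
#'
#' @param statesA,statesB integer state vectors (1/2/NA) over gametes.
#' @return list: `N`, `R`, `rHat` (NA when `N` is 0).
#' @export
estimateR <- function(statesA, statesB) {
  ok <- !is.na(statesA) & !is.na(statesB)
  N <- sum(ok)
  R <- sum(statesA[ok] != statesB[ok])
  list(N = N, R = R, rHat = if (N > 0) R / N else NA_real_)
}

#' Two-point LOD score against free recombination
#'
#' `LOD = log10( rHat^R (1 - rHat)^(N - R) / 0.5^N )` with
#' `rHat = min(R/N, 0.5)`; 17 non-recombinant gametes give LOD
#' `17 log10(2) = 5.12`, 16 give 4.82.
#'
#' @param R recombinant count; @param N informative gamete count.
#' @return LOD score (NA when `N` is 0).
#' @export
twoPointLOD <- function(R, N) {
  if (length(N) == 1L && N == 0) return(NA_real_)
  r <- pmin(R / N, 0.5)
  ll <- ifelse(R > 0, R * log10(r), 0) +
    ifelse(N - R > 0, (N - R) * log10(1 - r), 0)
  ll - N * log10(0.5)
}

#' Linkage-group membership filter by two-point LOD
#'
#' For each marker, the maximum two-point LOD against up to `window`
#' neighbouring markers on the same chromosome is computed from the pooled
#' gamete states; markers whose best LOD is below `lodMin` (or that have no
#' informative pairing) are excluded from the map.
#'
#' @param gameteSet output of [callGametes()].
#' @param lodMin minimum LOD (default 5).
#' @param window number of physical neighbours examined on each side.
#' @return data.frame: marker, chrom, maxLod, keep.
#' @export
lodLinkageFilter <- function(gameteSet, lodMin = 5, window = 10) {
  S <- gameteSet$states
  mk <- gameteSet$markers
  maxLod <- rep(NA_real_, nrow(mk))
  for (c in unique(mk$chrom)) {
    sel <- which(mk$chrom == c)
    sel <- sel[order(mk$bp[sel])]
    for (a in seq_along(sel)) {
      nb <- sel[setdiff(max(1, a - window):min(length(sel), a + window), a)]
      best <- NA_real_
      for (b in nb) {
        est <- estimateR(S[, sel[a]], S[, b])
        if (est$N > 0) {
          lod <- twoPointLOD(est$R, est$N)
          if (is.na(best) || lod > best) best <- lod
        }
      }
      maxLod[sel[a]] <- best
    }
  }
  data.frame(marker = mk$marker, chrom = mk$chrom, maxLod = maxLod,
             keep = !is.na(maxLod) & maxLod >= lodMin,
             stringsAsFactors = FALSE)
}

## sex-specific map for one chromosome estimated over gamete spans. Each
## gamete contributes one observation per pair of consecutive informative
## markers (a, b): whether its phase state switches across the span. Every
## switch is treated as one crossover (switch-calling has already merged
## unresolvable doubles) whose location within the span is latent; an EM
## allocates each switch over its intervals in proportion to the current
## interval rates and re-estimates each rate against the number of spans
## covering the interval. The per-interval crossover fraction is then
## converted to cM with the Haldane mapping function, so a single
## two-marker interval reduces exactly to the Haldane transform of the
## recombinant fraction. Spanning estimation side-steps the selection bias
## of naive adjacent-pair counting, where resolution through offspring
## homozygosity makes a gamete's informativeness at the flanking markers
## depend on whether it recombined between them, and it is robust to
## intervals with few doubly-informative gametes.
chromMapEM <- function(S, bp, rCap = 0.49, maxIter = 200, tol = 1e-10) {
  m <- ncol(S)
  nIv <- m - 1L
  empty <- list(cm = rep(0, m),
                intervals = data.frame(fromBp = numeric(), toBp = numeric(),
                                       N = integer(), R = numeric(),
                                       rHat = numeric(), cm = numeric()))
  if (m < 2L || !nrow(S)) return(empty)
  ## collect spans (a, b, switch) over all gametes
  aL <- list(); bL <- list(); sL <- list()
  for (i in seq_len(nrow(S))) {
    inf <- which(!is.na(S[i, ]))
    if (length(inf) < 2L) next
    aL[[length(aL) + 1L]] <- inf[-length(inf)]
    bL[[length(bL) + 1L]] <- inf[-1]
    sL[[length(sL) + 1L]] <- diff(S[i, inf]) != 0
  }
  if (!length(aL)) return(empty)
  a <- unlist(aL); b <- unlist(bL); sw <- unlist(sL)
  key <- a * (m + 1) + b
  grp <- match(key, unique(key))
  n_ab <- as.numeric(rowsum(rep(1, length(grp)), grp))
  k_ab <- as.numeric(rowsum(as.numeric(sw), grp))
  first <- !duplicated(grp)
  pa <- a[first][order(unique(grp))]; pb <- b[first][order(unique(grp))]
  ## scatter index: intervals covered by each unique span
  lens <- pb - pa
  idx <- unlist(mapply(function(x, y) x:(y - 1L), pa, pb,
                       SIMPLIFY = FALSE))
  pid <- rep(seq_along(pa), lens)
  expo <- as.numeric(rowsum(n_ab[pid], idx))
  covered <- sort(unique(idx))
  exposure <- rep(0, nIv); exposure[covered] <- expo

  d <- rep(sum(k_ab) / max(1, sum(n_ab)) / nIv, nIv)  # flat start
  Sj <- rep(0, nIv)
  for (it in seq_len(maxIter)) {
    cumd <- c(0, cumsum(d))
    L <- cumd[pb] - cumd[pa]
    w <- ifelse(L[pid] > 1e-12, d[idx] / L[pid], 1 / lens[pid])
    Sj <- rep(0, nIv)
    Sj[covered] <- as.numeric(rowsum(k_ab[pid] * w, idx))
    dNew <- ifelse(exposure > 0, Sj / pmax(exposure, 1), 0)
    delta <- max(abs(dNew - d))
    d <- dNew
    if (delta < tol) break
  }
  rHat <- pmin(d, rCap)
  dcm <- haldaneCM(rHat, cap = rCap)
  cm <- c(0, cumsum(dcm))
  iv <- data.frame(fromBp = bp[-m], toBp = bp[-1], N = exposure,
                   R = Sj, rHat = rHat, cm = dcm)
  list(cm = cm, intervals = iv)
}

#' Build sex-specific linkage maps from called gametes
#'
#' Estimates per-interval map distances separately for male and female
#' meioses (sex of the transmitting parent) by maximum likelihood over each
#' gamete's spans between consecutive informative markers, under the
#' Poisson-crossover model on which the Haldane mapping function is based
#' (a single two-marker interval reduces exactly to the Haldane transform
#' of the recombinant fraction). Distances accumulate along the physical
#' marker order; intervals no gamete's span covers contribute zero.
#' Chromosome totals, genome totals and a fixed-window cM/Mb landscape
#' (interval cM mass spread uniformly over its bp span) are derived from
#' the same estimates.
#'
#' @param gameteSet output of [callGametes()].
#' @param rCap cap on the recombination fraction before the Haldane
#'   transform (default 0.49).
#' @param windowMb landscape window width in Mb (default 1).
#' @return a [SexLinkageMap-class].
#' @export
buildMaps <- function(gameteSet, rCap = 0.49, windowMb = 1) {
  S <- gameteSet$states
  mk <- gameteSet$markers
  sexes <- gameteSet$gametes$parentSex
  chroms <- unique(mk$chrom)
  mapRows <- list(); sumRows <- list(); landRows <- list()
  for (c in chroms) {
    sel <- which(mk$chrom == c)
    sel <- sel[order(mk$bp[sel])]
    bp <- mk$bp[sel]
    res <- list()
    for (sx in c("M", "F")) {
      rows <- sexes == sx
      res[[sx]] <- if (any(rows))
        chromMapEM(S[rows, sel, drop = FALSE], bp, rCap = rCap)
      else list(cm = rep(NA_real_, length(sel)),
                intervals = data.frame())
    }
    mapRows[[c]] <- data.frame(
      chrom = c, marker = mk$marker[sel], bp = bp,
      cmMale = res$M$cm, cmFemale = res$F$cm, stringsAsFactors = FALSE)
    lenM <- if (all(is.na(res$M$cm))) NA_real_ else max(res$M$cm, na.rm = TRUE)
    lenF <- if (all(is.na(res$F$cm))) NA_real_ else max(res$F$cm, na.rm = TRUE)
    sumRows[[c]] <- data.frame(
      chrom = c, mb = max(bp) / 1e6, nMarkers = length(sel),
      cmMale = lenM, cmFemale = lenF, stringsAsFactors = FALSE)
    ## landscape: spread each interval's cM uniformly over its bp span
    wbp <- windowMb * 1e6
    breaks <- seq(0, max(bp) + wbp, by = wbp)
    accum <- function(ivs) {
      out <- numeric(length(breaks) - 1L)
      if (!nrow(ivs)) return(out)
      for (i in seq_len(nrow(ivs))) {
        a <- ivs$fromBp[i]; b <- ivs$toBp[i]
        if (b <= a) next
        dens <- ivs$cm[i] / (b - a)
        lo <- pmax(breaks[-length(breaks)], a)
        hi <- pmin(breaks[-1], b)
        out <- out + dens * pmax(hi - lo, 0)
      }
      out
    }
    cmM <- accum(res$M$intervals); cmF <- accum(res$F$intervals)
    landRows[[c]] <- data.frame(
      chrom = c, windowStart = breaks[-length(breaks)] + 1,
      windowEnd = breaks[-1],
      cmPerMbMale = cmM / windowMb, cmPerMbFemale = cmF / windowMb,
      stringsAsFactors = FALSE)
  }
  new("SexLinkageMap",
      map = do.call(rbind, c(mapRows, list(make.row.names = FALSE))),
      summary = do.call(rbind, c(sumRows, list(make.row.names = FALSE))),
      landscape = do.call(rbind, c(landRows, list(make.row.names = FALSE))))
}
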