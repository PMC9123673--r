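#' Write genotypes as PLINK text (.ped/.map)
#'
#' Genotype codes are written as allele pairs A/B (0 = \"A A\", 1 = \"A B\",
#' 2 = \"B B\", missing = \"0 0\"); the .map file has columns chromosome,
#' marker id, genetic position (0) and 1-based bp.
#'
#' @param gd a [GenotypeData-class].
#' @param prefix output path prefix (writes `prefix.ped`, `prefix.map`).
#' @param pedigree optional pedigree data.frame (id, sire, dam, sex) used to
#'   fill the parental and sex columns; otherwise zeros.
#' @return invisibly, the two file paths.
#' @export
writePlink <- function(gd, prefix, pedigree = NULL) {
  m <- markerInfo(gd)
  mapDt <- data.table::data.table(chrom = m$chrom, marker = m$marker,
                                  cm = 0, bp = as.integer(m$bp))
  data.table::fwrite(mapDt, paste0(prefix, ".map"), sep = "\t",
                     col.names = FALSE)
  g <- genotypes(gd)
  ids <- rownames(g)
  pat <- mat <- rep("0", length(ids)); sex <- rep(0L, length(ids))
  if (!is.null(pedigree)) {
    i <- match(ids, as.character(pedigree$id))
    ok <- !is.na(i)
    pat[ok] <- as.character(pedigree$sire[i[ok]])
    mat[ok] <- as.character(pedigree$dam[i[ok]])
    sex[ok] <- ifelse(pedigree$sex[i[ok]] == "M", 1L, 2L)
  }
  codes <- c("A A", "A B", "B B")
  al <- matrix("0 0", nrow(g), ncol(g))
  ok <- !is.na(g)
  al[ok] <- codes[g[ok] + 1L]
  lines <- paste("1", ids, pat, mat, sex, "-9",
                 apply(al, 1, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

#' Read PLINK text genotypes (.ped/.map)
#'
#' At markers whose observed alleles are within \{A, B\} the counted allele
#' is B (the convention [writePlink()] uses, so round-trips are exact even
#' at monomorphic markers); otherwise the lexicographically last observed
#' allele is counted. Monomorphic markers code as a constant either way and
#' are removed by the MAF filter downstream.
#'
#' @param prefix path prefix of the `.ped`/`.map` pair.
#' @return a [GenotypeData-class]; individual ids come from the IID column.
#' @export
readPlink <- function(prefix) {
  map <- data.table::fread(paste0(prefix, ".map"), header = FALSE,
                           colClasses = "character")
  markers <- data.frame(marker = map$V2, chrom = map$V1,
                        bp = as.numeric(map$V4), stringsAsFactors = FALSE)
  ped <- data.table::fread(paste0(prefix, ".ped"), header = FALSE,
                           colClasses = "character")
  ids <- ped[[2]]
  al <- as.matrix(ped[, -(1:6)])
  M <- nrow(markers)
  stopifnot(ncol(al) == 2L * M)
  a1 <- al[, seq(1L, 2L * M, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * M, by = 2L), drop = FALSE]
  g <- matrix(NA_integer_, length(ids), M)
  for (k in seq_len(M)) {
    obs <- sort(setdiff(unique(c(a1[, k], a2[, k])), "0"))
    if (!length(obs)) next
    counted <- if (all(obs %in% c("A", "B"))) "B" else obs[length(obs)]
    miss <- a1[, k] == "0" | a2[, k] == "0"
    g[, k] <- (a1[, k] == counted) + (a2[, k] == counted)
    g[miss, k] <- NA_integer_
  }
  rownames(g) <- ids
  colnames(g) <- markers$marker
  GenotypeData(g, markers)
}
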