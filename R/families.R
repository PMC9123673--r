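#' Build three-generation full-sib families
#'
#' Sub-divides a pedigree into families around unique (sire, dam) mating
#' pairs: the two focal individuals (FIDs), their four parents
#' (grandparents of the offspring) and all full-sib offspring of the pair. A
#' family is retained only if both FIDs, all four grandparents and at least
#' one offspring are genotyped. An FID may appear in several families (one
#' per mate); each (FID, offspring) gamete is counted once across families.
#'
#' @param pedigree data.frame with id, sire, dam (\"0\" unknown), sex.
#' @param genotypedIds character vector of ids with genotypes.
#' @return data.frame ordered by (sire, dam): sire, dam, the four
#'   grandparent ids (`sireSire`, `sireDam`, `damSire`, `damDam`),
#'   `nOffspring`, `nGenotyped`, and list-columns `offspring`,
#'   `genotypedOffspring`.
#' @export
buildFamilies <- function(pedigree, genotypedIds) {
  p <- checkPedigree(pedigree)
  genotypedIds <- as.character(genotypedIds)
  idx <- setNames(seq_len(nrow(p)), p$id)
  off <- p[p$sire != "0" & p$dam != "0", , drop = FALSE]
  if (!nrow(off))
    return(data.frame(sire = character(), dam = character()))
  key <- paste(off$sire, off$dam, sep = "\r")
  sp <- split(off$id, key)
  pairs <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
  par <- function(id, which) {
    i <- idx[id]
    ifelse(is.na(i), "0", p[[which]][i])
  }
  fam <- data.frame(sire = pairs[, 1], dam = pairs[, 2],
                    sireSire = par(pairs[, 1], "sire"),
                    sireDam = par(pairs[, 1], "dam"),
                    damSire = par(pairs[, 2], "sire"),
                    damDam = par(pairs[, 2], "dam"),
                    stringsAsFactors = FALSE)
  fam$offspring <- unname(sp)
  fam$genotypedOffspring <- lapply(sp, function(o) o[o %in% genotypedIds])
  fam$nOffspring <- lengths(fam$offspring)
  fam$nGenotyped <- lengths(fam$genotypedOffspring)
  gp <- as.matrix(fam[, c("sireSire", "sireDam", "damSire", "damDam")])
  ok <- fam$sire %in% genotypedIds & fam$dam %in% genotypedIds &
    fam$nGenotyped >= 1L &
    apply(gp != "0" & matrix(gp %in% genotypedIds, nrow(fam)), 1, all)
  fam <- fam[ok, , drop = FALSE]
  fam <- fam[order(fam$sire, fam$dam), , drop = FALSE]
  rownames(fam) <- NULL
  fam
}

#' Enumerate unique gametes to phenotype
#'
#' Two gametes per genotyped offspring: one from each focal parent, labelled
#' by the transmitting parent's sex. Duplicate (fid, offspring) pairs
#' arising from redundant family records collapse to one.
#'
#' @param families output of [buildFamilies()].
#' @return data.frame: fid, offspring, parentSex; unique rows.
#' @export
enumerateGametes <- function(families) {
  if (!nrow(families))
    return(data.frame(fid = character(), offspring = character(),
                      parentSex = character()))
  rows <- lapply(seq_len(nrow(families)), function(r) {
    offs <- families$genotypedOffspring[[r]]
    if (!length(offs)) return(NULL)
    data.frame(fid = rep(c(families$sire[r], families$dam[r]),
                         each = length(offs)),
               offspring = rep(offs, 2),
               parentSex = rep(c("M", "F"), each = length(offs)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[!duplicated(paste(out$fid, out$offspring)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
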