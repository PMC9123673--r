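## recursive kinship coefficient with memoisation; pedigree must be
## topologically sorted (checkPedigree) and passed as parent index vectors.
kinshipFun <- function(si, di) {
  memo <- new.env(hash = TRUE, parent = emptyenv())
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste0(i, ":", j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) {
      0.5 * (1 + phi(si[i], di[i]))
    } else {
      ## j is not an ancestor of i because i < j in topological order
      0.5 * (phi(i, si[j]) + phi(i, di[j]))
    }
    memo[[key]] <- v
    v
  }
  phi
}

#' Pedigree inbreeding coefficients
#'
#' F of each individual = kinship of its parents, computed recursively on the
#' (cycle-checked, topologically sorted) pedigree. Founders and individuals
#' with an unknown parent get F = 0.
#'
#' @param pedigree data.frame with id, sire, dam (\"0\" unknown), sex.
#' @return named numeric vector of F in the input row order.
#' @examples
#' ped <- data.frame(id = c("a", "b", "x", "y", "z"),
#'                   sire = c("0", "0", "a", "a", "x"),
#'                   dam  = c("0", "0", "b", "b", "y"),
#'                   sex  = c("M", "F", "M", "F", "M"))
#' pedigreeInbreeding(ped)["z"]  # offspring of full sibs: 0.25
#' @export
pedigreeInbreeding <- function(pedigree) {
  p <- checkPedigree(pedigree)
  idx <- setNames(seq_len(nrow(p)), p$id)
  si <- unname(idx[p$sire]); di <- unname(idx[p$dam])
  phi <- kinshipFun(si, di)
  f <- vapply(seq_len(nrow(p)), function(i) {
    if (is.na(si[i]) || is.na(di[i])) 0 else phi(si[i], di[i])
  }, 0)
  out <- setNames(f, p$id)
  out[as.character(pedigree$id)]
}

#' Pedigree additive relationship matrix (tabular method)
#'
#' Henderson's tabular method: `A[i, j] = (A[j, sire_i] + A[j, dam_i]) / 2`
#' and `A[i, i] = 1 + F_i` with F the kinship of the parents. Intended for
#' small-to-moderate pedigrees; the REML engine uses the sparse inverse from
#' [buildAInverse()] instead.
#'
#' @param pedigree data.frame with id, sire, dam, sex.
#' @return dense symmetric matrix with ids as dimnames, in pedigree order
#'   after topological sorting.
#' @export
buildA <- function(pedigree) {
  p <- checkPedigree(pedigree)
  n <- nrow(p)
  idx <- setNames(seq_len(n), p$id)
  si <- unname(idx[p$sire]); di <- unname(idx[p$dam])
  A <- matrix(0, n, n, dimnames = list(p$id, p$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      prev <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[s, prev]
      if (!is.na(d)) row <- row + 0.5 * A[d, prev]
      A[i, prev] <- row
      A[prev, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with inbreeding: each individual contributes
#' `1/d_i` to its diagonal, `-1/(2 d_i)` to individual-parent entries and
#' `1/(4 d_i)` among parents, where the Mendelian-sampling variance is
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (0.75 - F_known/4 with one unknown parent,
#' 1 with both unknown).
#'
#' @param pedigree data.frame with id, sire, dam, sex.
#' @return list: `Ainv` (sparse dsCMatrix with id dimnames), `logDetA`
#'   (log-determinant of A = sum of log d_i), `ids` (topological order),
#'   `f` (inbreeding coefficients in that order).
#' @export
buildAInverse <- function(pedigree) {
  p <- checkPedigree(pedigree)
  n <- nrow(p)
  idx <- setNames(seq_len(n), p$id)
  si <- unname(idx[p$sire]); di <- unname(idx[p$dam])
  f <- unname(pedigreeInbreeding(p))
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  add <- function(i, j, v) {
    k <<- k + 1L; ii[k] <<- i; jj[k] <<- j; xx[k] <<- v
  }
  d <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; dm <- di[i]
    d[i] <- 1 - 0.25 * ((!is.na(s)) * (1 + ifelse(is.na(s), 0, f[s])) +
                        (!is.na(dm)) * (1 + ifelse(is.na(dm), 0, f[dm])))
    m <- 1 / d[i]
    add(i, i, m)
    for (pa in c(s, dm)) if (!is.na(pa)) {
      add(i, pa, -m / 2); add(pa, i, -m / 2)
    }
    pars <- c(s, dm); pars <- pars[!is.na(pars)]
    if (length(pars))
      for (u in pars) for (v in pars) add(u, v, m / 4)
  }
  sel <- seq_len(k)
  Ainv <- Matrix::sparseMatrix(i = ii[sel], j = jj[sel], x = xx[sel],
                               dims = c(n, n),
                               dimnames = list(p$id, p$id))
  Ainv <- Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
  list(Ainv = Ainv, logDetA = sum(log(d)), ids = p$id, f = setNames(f, p$id))
}
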