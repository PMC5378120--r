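# Two-locus genetics of repeated selfing from an F1 double heterozygote.
#
# State space: the 10 unordered diplotypes over the 4 two-locus haplotypes
# AB, Ab, aB, ab (allele 1 = reference parent).  One selfing round maps a
# diplotype frequency vector through a 10x10 transition matrix whose
# entries are quadratic polynomials in the per-meiosis recombination
# fraction r; the polynomial coefficients are cached so repeated
# likelihood evaluations are cheap.

.haps <- rbind(AB = c(1, 1), Ab = c(1, 0), aB = c(0, 1), ab = c(0, 0))
.dips <- {
  idx <- which(upper.tri(diag(4), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]   # 10 rows: (h1, h2)
}

# gamete distribution over the 4 haplotypes for diplotype row i
.gametes <- function(i, r) {
  h1 <- .dips[i, 1]; h2 <- .dips[i, 2]
  g <- numeric(4)
  g[h1] <- g[h1] + (1 - r) / 2
  g[h2] <- g[h2] + (1 - r) / 2
  rec1 <- which(.haps[, 1] == .haps[h1, 1] & .haps[, 2] == .haps[h2, 2])
  rec2 <- which(.haps[, 1] == .haps[h2, 1] & .haps[, 2] == .haps[h1, 2])
  g[rec1] <- g[rec1] + r / 2
  g[rec2] <- g[rec2] + r / 2
  g
}

.dipIndex <- function(a, b) {
  h1 <- min(a, b); h2 <- max(a, b)
  which(.dips[, 1] == h1 & .dips[, 2] == h2)
}

.selfingTransition <- function(r) {
  T <- matrix(0, 10, 10)
  for (i in 1:10) {
    g <- .gametes(i, r)
    for (a in 1:4) for (b in a:4) {
      p <- if (a == b) g[a]^2 else 2 * g[a] * g[b]
      j <- .dipIndex(a, b)
      T[i, j] <- T[i, j] + p
    }
  }
  T
}

# diplotype -> joint genotype class (3x3, AA/AB/BB at each locus)
.collapseMatrix <- local({
  M <- matrix(0, 10, 9)
  for (i in 1:10) {
    h1 <- .dips[i, 1]; h2 <- .dips[i, 2]
    g1 <- 3L - (.haps[h1, 1] + .haps[h2, 1])   # 1=AA,2=AB,3=BB
    g2 <- 3L - (.haps[h1, 2] + .haps[h2, 2])
    M[i, (g2 - 1L) * 3L + g1] <- 1
  }
  M
})

.transCache <- new.env(parent = emptyenv())

# T(r) = T0 + T1 r + T2 r^2, coefficients fitted once
.transitionAt <- function(r) {
  if (is.null(.transCache$T0)) {
    T0 <- .selfingTransition(0)
    Tq <- .selfingTransition(0.25)
    Th <- .selfingTransition(0.5)
    T2 <- 8 * (Th - 2 * Tq + T0)
    T1 <- 4 * (Tq - T0) - 0.25 * T2
    .transCache$T0 <- T0; .transCache$T1 <- T1; .transCache$T2 <- T2
  }
  .transCache$T0 + r * .transCache$T1 + r * r * .transCache$T2
}

#' Joint two-locus genotype distribution after repeated selfing
#'
#' Computes the probability of each of the 9 two-locus genotype classes
#' (AA/AB/BB at each locus) in an F_k single-seed-descent line derived
#' from a fully heterozygous F1 in coupling phase, given a per-meiosis
#' recombination fraction `r`.  `k = Inf` returns the fully inbred
#' (Haldane-Waddington) limit, in which all mass sits on the four
#' double-homozygote classes.
#'
#' @param r per-meiosis recombination fraction, in `[0, 0.5]`.
#' @param k selfing generation (>= 2) or `Inf`.
#' @return list with elements `r`, `k`, `joint` (3x3 matrix, rows = locus 1,
#'   dimnames AA/AB/BB) and `marginals` (one-locus genotype frequencies).
#' @examples
#' m <- twoLocusSelfingDistribution(0, 4)
#' m$marginals        # 0.4375, 0.125, 0.4375
#' @export
twoLocusSelfingDistribution <- function(r, k) {
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r > 0.5)
    stop("r must be a single value in [0, 0.5]")
  if (!(is.infinite(k) || (k == round(k) && k >= 2)))
    stop("k must be an integer >= 2 or Inf")
  if (is.infinite(k)) {
    R <- haldaneWaddingtonLimit(r)
    joint <- matrix(0, 3, 3)
    joint[1, 1] <- joint[3, 3] <- (1 - R) / 2
    joint[1, 3] <- joint[3, 1] <- R / 2
  } else {
    f <- numeric(10)
    f[.dipIndex(1, 4)] <- 1           # F1 = AB/ab
    T <- .transitionAt(r)
    for (i in seq_len(k - 1)) f <- as.vector(f %*% T)
    joint <- matrix(as.vector(f %*% .collapseMatrix), 3, 3)
  }
  dimnames(joint) <- list(GENO_LEVELS, GENO_LEVELS)
  list(r = r, k = k, joint = joint, marginals = rowSums(joint))
}

#' One-locus genotype frequencies under selfing, exact
#'
#' Frequencies of AA, AB and BB at a neutral biallelic locus in an F_k
#' single-seed-descent line, computed by iterating the selfing recursion
#' on integer numerators over the denominator 4^(k-1).  All values are
#' dyadic rationals so the returned doubles are exact; at k = 4 the
#' homozygote classes are each 28/64 = 0.4375.
#'
#' @param k selfing generation (>= 2) or `Inf`.
#' @return named numeric vector (AA, AB, BB).
#' @export
selfingGenotypeFrequencies <- function(k) {
  if (is.infinite(k))
    return(c(AA = 0.5, AB = 0, BB = 0.5))
  if (!(k == round(k) && k >= 2)) stop("k must be an integer >= 2 or Inf")
  num <- c(0, 1, 0); den <- 1
  for (i in seq_len(k - 1)) {
    num <- c(4 * num[1] + num[2], 2 * num[2], 4 * num[3] + num[2])
    den <- 4 * den
  }
  stats::setNames(num / den, GENO_LEVELS)
}

#' Fully inbred recombinant-class frequency (Haldane-Waddington)
#'
#' The frequency of recombinant double homozygotes among fully inbred
#' selfed lines, `R = 2r / (1 + 2r)`; the k -> Inf limit of the selfing
#' recursion.
#'
#' @param r per-meiosis recombination fraction in `[0, 0.5]`.
#' @return R, in `[0, 0.5]`.
#' @export
haldaneWaddingtonLimit <- function(r) {
  stopifnot(all(r >= 0 & r <= 0.5))
  2 * r / (1 + 2 * r)
}

#' Kosambi map function and its inverse
#'
#' `kosambi()` converts a per-meiosis recombination fraction to map
#' distance, d = 25 ln((1 + 2r) / (1 - 2r)) centiMorgan; `kosambiInverse()`
#' converts back, r = tanh(d / 50) / 2.  They are mutual inverses.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM, >= 0.
#' @return numeric vector of distances (cM) or recombination fractions.
#' @examples
#' kosambi(0.1)                    # 10.137 cM
#' kosambiInverse(kosambi(0.23))   # 0.23
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambiInverse <- function(d) {
  if (any(d < 0)) stop("d must be non-negative")
  0.5 * tanh(d / 50)
}
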