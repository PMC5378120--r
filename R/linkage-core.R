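# Two-point linkage estimation, grouping, seriation ordering and map
# assembly for one selfed-RIL population.

.pairLoglik <- function(counts, r, k, collapse1 = FALSE, collapse2 = FALSE) {
  P <- twoLocusSelfingDistribution(r, k)$joint
  if (collapse1) {
    P <- rbind(P[1, ], P[2, ] + P[3, ])
    counts <- rbind(counts[1, ], counts[2, ] + counts[3, ])
  }
  if (collapse2) {
    P <- cbind(P[, 1], if (is.matrix(P)) P[, 2] + P[, 3] else P[2] + P[3])
    counts <- cbind(counts[, 1], counts[, 2] + counts[, 3])
  }
  n <- as.vector(counts); p <- as.vector(P)
  use <- n > 0
  if (any(use & p <= 0)) return(-Inf)
  sum(n[use] * log(p[use]))
}

#' Two-point recombination fraction MLE for a selfed-RIL marker pair
#'
#' Maximises the multinomial log-likelihood of a 3x3 two-locus genotype
#' contingency table under the selfing recursion
#' [twoLocusSelfingDistribution()] over the per-meiosis recombination
#' fraction r in `[0, 0.5]` (golden-section/Brent search, tolerance 1e-6),
#' and reports the linkage LOD, `log10 L(r.hat) - log10 L(0.5)`.
#'
#' Markers scored without any heterozygote calls (a common KASP scoring
#' failure) can be handled with a collapsed likelihood in which the AB and
#' BB classes of that marker are merged (AA vs non-AA).  For fully inbred
#' populations (`k = Inf`) heterozygote calls carry no model probability
#' and must be absent or will force `-Inf` likelihoods; drop them upstream.
#'
#' @param counts 3x3 matrix of joint genotype counts, rows = first marker
#'   (AA, AB, BB), columns = second marker.
#' @param k selfing generation (4, 5, 6, ...) or `Inf`.
#' @param collapse1,collapse2 collapse the AB/BB classes of marker 1 / 2.
#' @param tol search tolerance on r.
#' @return list with `rf`, `lod` and `n` (total pair count).
#' @export
estimateRf <- function(counts, k, collapse1 = FALSE, collapse2 = FALSE,
                       tol = 1e-6) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(3L, 3L)))
  n <- sum(counts)
  if (n < 1) stop("pair has no jointly observed individuals")
  f <- function(r) .pairLoglik(counts, r, k, collapse1, collapse2)
  opt <- stats::optimize(f, c(0, 0.5), maximum = TRUE, tol = tol)
  cand <- c(0, opt$maximum, 0.5)
  ll <- vapply(cand, f, numeric(1))
  best <- which.max(ll)
  rf <- cand[best]
  lod <- max(0, (ll[best] - f(0.5)) / log(10))
  list(rf = rf, lod = lod, n = n)
}

# log joint-class probabilities on an r grid: 9 x length(grid)
.gridLogP <- function(grid, k) {
  lp <- vapply(grid, function(r) {
    p <- as.vector(twoLocusSelfingDistribution(r, k)$joint)
    out <- log(p)
    out[p <= 0] <- -1e10        # count 0 contributes 0; count > 0 vetoes
    out
  }, numeric(9))
  lp
}

#' Pairwise recombination-fraction / LOD matrix for a population
#'
#' Estimates the per-meiosis recombination fraction and two-point LOD for
#' every marker pair by grid maximisation of the selfing-recursion
#' likelihood (grid step `gridStep` on `[0, 0.5]`), then refines pairs with
#' LOD at or above `refineLod` by Brent search to tolerance 1e-6.  Pairs
#' with no jointly observed individuals are `NA`.  Markers flagged
#' `noHet` in `rowData` (and every marker in a fully inbred population)
#' are estimated under the collapsed AA-vs-non-AA likelihood.
#'
#' @param x a [RilGenotypes-class].
#' @param gridStep spacing of the r grid.
#' @param refineLod minimum grid LOD for Brent refinement.
#' @return an [RfMatrix-class].
#' @export
estRfMatrix <- function(x, gridStep = 0.005, refineLod = 3) {
  calls <- genotypeCalls(x)
  k <- generation(x)
  M <- nrow(calls)
  if (M < 2) stop("need at least 2 markers")
  if (is.infinite(k)) calls[calls == 2L] <- NA   # hets uninformative when inbred
  ind <- lapply(1:3, function(g) {
    I <- calls == g
    I[is.na(I)] <- FALSE
    storage.mode(I) <- "double"
    I
  })
  # joint class counts per pair: C[[g + 3(h-1)]] = I_g %*% t(I_h)
  C <- vector("list", 9)
  for (h in 1:3) for (g in 1:3)
    C[[g + 3L * (h - 1L)]] <- tcrossprod(ind[[g]], ind[[h]])
  npair <- Reduce(`+`, C)

  grid <- seq(0, 0.5, by = gridStep)
  lp <- .gridLogP(grid, k)
  bestLL <- matrix(-Inf, M, M); bestR <- matrix(NA_real_, M, M)
  for (j in seq_along(grid)) {
    LL <- matrix(0, M, M)
    for (cl in 1:9) if (lp[cl, j] != 0) LL <- LL + C[[cl]] * lp[cl, j]
    upd <- LL > bestLL
    bestLL[upd] <- LL[upd]
    bestR[upd] <- grid[j]
  }
  LL05 <- matrix(0, M, M)
  for (cl in 1:9) LL05 <- LL05 + C[[cl]] * lp[cl, length(grid)]
  lod <- (bestLL - LL05) / log(10)
  lod[lod < 0] <- 0
  rf <- bestR

  noHet <- SummarizedExperiment::rowData(x)$noHet
  if (is.null(noHet)) noHet <- rep(FALSE, M)
  if (is.infinite(k)) noHet <- rep(TRUE, M)

  # refinement / collapsed re-estimation
  ut <- which(upper.tri(rf), arr.ind = TRUE)
  redo <- ut[(lod[ut] >= refineLod | noHet[ut[, 1]] | noHet[ut[, 2]]) &
               npair[ut] > 0, , drop = FALSE]
  if (nrow(redo)) {
    for (q in seq_len(nrow(redo))) {
      i <- redo[q, 1]; j <- redo[q, 2]
      cnt <- matrix(vapply(1:9, function(cl) C[[cl]][i, j], numeric(1)), 3, 3)
      est <- estimateRf(cnt, k, collapse1 = noHet[i], collapse2 = noHet[j])
      rf[i, j] <- rf[j, i] <- est$rf
      lod[i, j] <- lod[j, i] <- est$lod
    }
  }
  rf[npair == 0] <- NA
  lod[npair == 0] <- NA
  diag(rf) <- NA; diag(lod) <- 0
  dimnames(rf) <- dimnames(lod) <- list(rownames(calls), rownames(calls))
  methods::new("RfMatrix", rf = rf, lod = lod, generation = k)
}

#' Partition markers into linkage groups
#'
#' Single-linkage transitive closure: two markers belong to one group iff
#' a chain of marker pairs connects them in which every link has
#' `LOD >= lodMin` and `rf <= rfMax` (both constraints required per link).
#'
#' @param rfm an [RfMatrix-class].
#' @param lodMin minimum two-point LOD per link (default 3.0).
#' @param rfMax maximum recombination fraction per link (default 0.3).
#' @return list with `groups` (list of character vectors, size >= 2) and
#'   `singletons` (markers linked to nothing).
#' @export
formLinkageGroups <- function(rfm, lodMin = 3, rfMax = 0.3) {
  rf <- rfValues(rfm); lod <- lodValues(rfm)
  adj <- !is.na(rf) & !is.na(lod) & lod >= lodMin & rf <= rfMax
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  mem <- split(rownames(rf), comp$membership)
  sizes <- lengths(mem)
  groups <- unname(mem[sizes >= 2])
  groups <- groups[order(vapply(groups, min, character(1)))]
  list(groups = groups, singletons = sort(unlist(mem[sizes == 1], use.names = FALSE)))
}

.sarf <- function(ord, R) {
  if (length(ord) < 2) return(0)
  sum(R[cbind(ord[-length(ord)], ord[-1])])
}

#' Order the markers of one linkage group by seriation
#'
#' Greedy seriation under the minimum-SARF criterion (SARF = sum of
#' adjacent recombination fractions): seed with the pair of smallest rf,
#' then repeatedly insert the (marker, position) combination that yields
#' the smallest SARF, ties broken by marker name; followed by progressive
#' rippling, in which a window of `rippleWindow` markers slides along the
#' order and any within-window permutation that strictly lowers the SARF
#' is accepted, repeated to convergence.  Positions are cumulative Kosambi
#' distances of adjacent rf values, origin 0.
#'
#' @param markers character vector of marker names (>= 2).
#' @param rfm an [RfMatrix-class] covering them.
#' @param rippleWindow ripple window size (default 3).
#' @return data.frame (`marker`, `position`) with attribute `sarf`.
#' @export
orderLinkageGroup <- function(markers, rfm, rippleWindow = 3) {
  stopifnot(length(markers) >= 2)
  R <- rfValues(rfm)[markers, markers, drop = FALSE]
  R[is.na(R)] <- 0.5
  diag(R) <- 0
  m <- length(markers)
  if (m == 2) {
    ord <- sort(markers)
  } else {
    ut <- which(upper.tri(R), arr.ind = TRUE)
    pr <- order(R[ut], markers[ut[, 1]], markers[ut[, 2]])[1]
    ord <- sort(c(markers[ut[pr, 1]], markers[ut[pr, 2]]))
    left <- setdiff(markers, ord)
    while (length(left)) {
      best <- NULL
      for (mk in left[order(left)]) {
        for (pos in 0:length(ord)) {
          cand <- append(ord, mk, after = pos)
          s <- .sarf(cand, R)
          if (is.null(best) || s < best$s - 1e-15) best <- list(s = s, ord = cand, mk = mk)
        }
      }
      ord <- best$ord
      left <- setdiff(left, best$mk)
    }
    # progressive rippling
    w <- min(rippleWindow, m)
    perms <- .permutations(w)
    repeat {
      improved <- FALSE
      s0 <- .sarf(ord, R)
      for (start in 1:(m - w + 1)) {
        idx <- start:(start + w - 1)
        base <- ord
        for (p in seq_len(nrow(perms))) {
          cand <- base
          cand[idx] <- base[idx][perms[p, ]]
          s <- .sarf(cand, R)
          if (s < s0 - 1e-12) { ord <- cand; s0 <- s; improved <- TRUE }
        }
      }
      if (!improved) break
    }
  }
  if (ord[1] > ord[length(ord)]) ord <- rev(ord)   # deterministic orientation
  radj <- R[cbind(ord[-length(ord)], ord[-1])]
  pos <- cumsum(c(0, kosambi(pmin(radj, 0.49999))))
  out <- data.frame(marker = ord, position = pos, stringsAsFactors = FALSE)
  attr(out, "sarf") <- .sarf(ord, R)
  out
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(1:n, function(i)
    cbind(i, sub + (sub >= i))))
}

#' Split a linkage group at large gaps
#'
#' Cuts an ordered linkage group at every adjacent-marker distance greater
#' than or equal to `gapCm` (default 35 cM, inclusive), re-anchoring each
#' fragment at 0.
#'
#' @param lgTable data.frame (`marker`, `position`) ordered by position.
#' @param gapCm split threshold in cM.
#' @return list of data.frames, each re-anchored at 0.
#' @export
splitLinkageGroups <- function(lgTable, gapCm = 35) {
  pos <- lgTable$position
  if (length(pos) < 2) return(list(lgTable))
  cut <- which(diff(pos) >= gapCm)
  frag <- cumsum(c(1, seq_along(pos)[-1] %in% (cut + 1)))
  lapply(split(seq_along(pos), frag), function(i) {
    out <- lgTable[i, , drop = FALSE]
    out$position <- out$position - out$position[1]
    rownames(out) <- NULL
    out
  })
}

#' Build the genetic map of one population
#'
#' Full per-population mapping workflow: marker validation (missing-data
#' filter, no-heterozygote flagging), pairwise rf/LOD estimation, linkage
#' grouping at `LOD >= lodMin` and `rf <= rfMax`, seriation ordering with
#' rippling, Kosambi positions, and splitting at adjacent gaps
#' `>= gapCm`.  Linkage groups are labelled with the majority a-priori
#' chromosome assignment of their markers.
#'
#' @param x a [RilGenotypes-class].
#' @param lodMin,rfMax grouping constraints (defaults 3.0 and 0.3).
#' @param maxMissing per-marker missing-fraction threshold; markers
#'   strictly above it are dropped (default 0.10).
#' @param gapCm split threshold (default 35).
#' @param rippleWindow ripple window (default 3).
#' @param rfm optional precomputed [RfMatrix-class] on the validated
#'   markers (avoids recomputation in pipelines).
#' @return a [GeneticMap-class].  `@stats` holds Table-1-style summaries:
#'   `nLG`, `mapLength`, `linkedMarkers`, `cosegregatingMarkers`,
#'   `singletons`, `droppedMarkers`, `noHetMarkers`.
#' @export
buildGeneticMap <- function(x, lodMin = 3, rfMax = 0.3, maxMissing = 0.10,
                            gapCm = 35, rippleWindow = 3, rfm = NULL) {
  val <- validateGenotypes(x, maxMissing = maxMissing)
  xk <- val$kept
  if (is.null(rfm)) rfm <- estRfMatrix(xk)
  stopifnot(identical(rownames(rfValues(rfm)), rownames(xk)))
  grp <- formLinkageGroups(rfm, lodMin = lodMin, rfMax = rfMax)

  assigned <- SummarizedExperiment::rowData(xk)$assignedChromosome
  names(assigned) <- rownames(xk)

  rows <- list(); sarfs <- numeric(0); lgi <- 0L
  for (g in grp$groups) {
    ordered <- orderLinkageGroup(g, rfm, rippleWindow = rippleWindow)
    for (frag in splitLinkageGroups(ordered, gapCm = gapCm)) {
      lgi <- lgi + 1L
      chr <- .majorityChromosome(assigned[frag$marker])
      id <- sprintf("LG%02d", lgi)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = frag$marker, lg = id, chromosome = chr,
        position = frag$position, stringsAsFactors = FALSE)
      sarfs[id] <- attr(ordered, "sarf")
    }
  }
  tb <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker = character(), lg = character(),
               chromosome = character(), position = numeric())
  rownames(tb) <- NULL

  rf <- rfValues(rfm)
  coseg <- vapply(seq_len(nrow(tb)), function(i) {
    same <- tb$marker[tb$lg == tb$lg[i] & tb$marker != tb$marker[i]]
    length(same) > 0 && any(rf[tb$marker[i], same] == 0, na.rm = TRUE)
  }, logical(1))

  lgLen <- vapply(split(tb$position, tb$lg), max, numeric(1))
  stats <- list(
    nLG = length(unique(tb$lg)),
    mapLength = sum(lgLen),
    linkedMarkers = nrow(tb),
    cosegregatingMarkers = sum(coseg),
    singletons = grp$singletons,
    droppedMarkers = val$dropped,
    noHetMarkers = val$noHet)
  methods::new("GeneticMap", populationId = populationId(x) %||% NA_character_,
               table = tb, sarf = sarfs, stats = stats)
}

.majorityChromosome <- function(assigned) {
  a <- assigned[!is.na(assigned) & assigned != ""]
  if (!length(a)) return(NA_character_)
  tab <- sort(table(a), decreasing = TRUE)
  names(tab)[1]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
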