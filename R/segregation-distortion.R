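# Multipoint genotype imputation by forward-backward HMM along each
# linkage group, per-locus chi-square distortion tests with BH
# adjustment, population allele-ratio QC, and cross-population hotspots.

#' Impute genotypes by a max-marginal hidden Markov model
#'
#' Per individual and linkage group, runs forward-backward smoothing over
#' hidden genotype states {AA, AB, BB}: initial probabilities are the
#' generation-k one-locus selfing marginals, transitions between adjacent
#' markers are the conditionals of the two-locus selfing distribution at
#' r = kosambiInverse(adjacent distance), and emissions give the observed state
#' probability `1 - errorProb` (others `errorProb / 2`; uniform when
#' missing).  The hard call is the state of maximal posterior; calls
#' whose maximal posterior falls below `minProb` are left missing
#' (max-marginal behaviour).
#'
#' @param x a [RilGenotypes-class].
#' @param map a [GeneticMap-class]; every imputed marker must be on it.
#' @param errorProb genotyping error probability (default 1e-4).
#' @param minProb minimum posterior for a hard call (default 0.95).
#' @return an `imputedGenotypes` list: `calls` (hard-call matrix in map
#'   marker order), `posterior` (markers x individuals x 3 array),
#'   `generation`, `populationId`, `map` table, `errorProb`.
#' @export
imputeGenotypes <- function(x, map, errorProb = 1e-4, minProb = 0.95) {
  tb <- mapTable(map)
  calls <- genotypeCalls(x)
  off <- setdiff(tb$marker, rownames(calls))
  if (length(off))
    stop("markers on map but not in genotypes: ",
         paste(utils::head(off, 5), collapse = ", "))
  k <- generation(x)
  init <- selfingGenotypeFrequencies(k)
  N <- ncol(calls)
  post <- array(NA_real_, dim = c(nrow(tb), N, 3),
                dimnames = list(tb$marker, colnames(calls), GENO_LEVELS))
  hard <- matrix(NA_integer_, nrow(tb), N,
                 dimnames = list(tb$marker, colnames(calls)))

  for (g in unique(tb$lg)) {
    sub <- tb[tb$lg == g, , drop = FALSE]
    mk <- sub$marker
    M <- length(mk)
    Tm <- NULL
    if (M > 1) {
      radj <- kosambiInverse(diff(sub$position))
      Tm <- lapply(radj, function(r) {
        J <- twoLocusSelfingDistribution(r, k)$joint
        mar <- rowSums(J)
        Tr <- J / ifelse(mar > 0, mar, 1)
        Tr[mar == 0, ] <- init          # unreachable state: reset to prior
        Tr
      })
    }
    obs <- calls[mk, , drop = FALSE]
    for (i in seq_len(N)) {
      E <- matrix(1, M, 3)
      o <- obs[, i]
      seen <- which(!is.na(o))
      if (length(seen)) {
        E[seen, ] <- errorProb / 2
        E[cbind(seen, o[seen])] <- 1 - errorProb
      }
      fwd <- matrix(0, M, 3); sc <- numeric(M)
      f <- init * E[1, ]
      sc[1] <- sum(f); fwd[1, ] <- f / sc[1]
      if (M > 1) for (m in 2:M) {
        f <- as.vector(fwd[m - 1, ] %*% Tm[[m - 1]]) * E[m, ]
        sc[m] <- sum(f)
        fwd[m, ] <- f / sc[m]
      }
      bwd <- matrix(1, M, 3)
      if (M > 1) for (m in (M - 1):1) {
        b <- as.vector(Tm[[m]] %*% (bwd[m + 1, ] * E[m + 1, ]))
        bwd[m, ] <- b / sum(b)
      }
      p <- fwd * bwd
      p <- p / rowSums(p)
      post[mk, i, ] <- p
      top <- max.col(p, ties.method = "first")
      keep <- p[cbind(seq_len(M), top)] >= minProb
      hard[mk[keep], i] <- top[keep]
    }
  }
  structure(list(calls = hard, posterior = post, generation = k,
                 populationId = populationId(x), map = tb,
                 errorProb = errorProb),
            class = "imputedGenotypes")
}

#' Per-locus segregation-distortion scan
#'
#' Chi-square goodness-of-fit of the imputed hard-call genotype counts at
#' each marker against the generation-k selfing expectation (F4:
#' 0.4375 / 0.125 / 0.4375, df = 2; fully inbred: AA:BB = 1:1 on
#' homozygotes, df = 1), with Benjamini-Hochberg adjustment over all
#' tested markers of the population.  Markers flagged as having no
#' heterozygote calls are excluded (their het class is unscorable);
#' markers with fewer than 20 informative calls are flagged underpowered
#' but still tested.  Distortion direction is taken from the homozygote
#' counts (`Par_excess` when AA > BB).
#'
#' @param imputed an [imputeGenotypes()] result (or a call matrix plus
#'   `generation`).
#' @param noHet character vector of markers to exclude.
#' @param alpha significance level on adjusted p (default 0.05).
#' @return data.frame: `marker`, `nAA`, `nAB`, `nBB`, `chisq`, `p`,
#'   `pAdj`, `significant`, `direction`, `underpowered`; attribute
#'   `percentDistorted`.
#' @export
segregationScan <- function(imputed, noHet = character(0), alpha = 0.05) {
  calls <- imputed$calls
  k <- imputed$generation
  test <- setdiff(rownames(calls), noHet)
  exp0 <- selfingGenotypeFrequencies(k)
  rows <- lapply(test, function(mk) {
    o <- calls[mk, ]
    n <- tabulate(o[!is.na(o)], nbins = 3)
    if (is.infinite(k)) {
      obs <- n[c(1, 3)]; p0 <- c(0.5, 0.5); df <- 1
    } else {
      obs <- n; p0 <- exp0; df <- 2
    }
    tot <- sum(obs)
    if (tot == 0)
      return(data.frame(marker = mk, nAA = n[1], nAB = n[2], nBB = n[3],
                        chisq = NA_real_, p = NA_real_,
                        direction = NA_character_, underpowered = TRUE))
    e <- p0 * tot
    stat <- sum((obs - e)^2 / e)
    data.frame(marker = mk, nAA = n[1], nAB = n[2], nBB = n[3],
               chisq = stat,
               p = stats::pchisq(stat, df = df, lower.tail = FALSE),
               direction = if (n[1] >= n[3]) "Par_excess" else "other_excess",
               underpowered = tot < 20, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pAdj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$pAdj) & out$pAdj < alpha
  out <- out[, c("marker", "nAA", "nAB", "nBB", "chisq", "p", "pAdj",
                 "significant", "direction", "underpowered")]
  attr(out, "percentDistorted") <-
    100 * sum(out$significant) / sum(!is.na(out$p))
  out
}

#' Population-level allele-ratio quality control
#'
#' Mean per-locus homozygote frequencies for each parent, compared to the
#' generation expectation (0.4375 each at F4; 0.5 when fully inbred) by a
#' pooled chi-square, with the flag rule used to exclude populations with
#' aberrant allele distributions: reference-parent homozygote mean at or
#' above `flagPar` (default 0.54) or other-parent mean at or below
#' `flagOther` (default 0.37).
#'
#' @param x a [RilGenotypes-class].
#' @param flagPar,flagOther flag thresholds on the mean homozygote ratios.
#' @return list: `meanPar`, `meanOther`, `expected`, `chisq`, `p`, `flag`.
#' @export
qcAlleleRatio <- function(x, flagPar = 0.54, flagOther = 0.37) {
  calls <- genotypeCalls(x)
  k <- generation(x)
  nAA <- rowSums(calls == 1L, na.rm = TRUE)
  nAB <- rowSums(calls == 2L, na.rm = TRUE)
  nBB <- rowSums(calls == 3L, na.rm = TRUE)
  tot <- nAA + nAB + nBB
  ok <- tot > 0
  meanPar <- mean(nAA[ok] / tot[ok])
  meanOther <- mean(nBB[ok] / tot[ok])
  exp0 <- selfingGenotypeFrequencies(k)
  pooled <- c(sum(nAA), sum(nAB), sum(nBB))
  if (is.infinite(k)) {
    pooled <- pooled[c(1, 3)]; p0 <- c(0.5, 0.5); df <- 1
  } else { p0 <- exp0; df <- 2 }
  e <- p0 * sum(pooled)
  stat <- sum((pooled - e)^2 / e)
  list(populationId = populationId(x),
       meanPar = meanPar, meanOther = meanOther,
       expected = unname(exp0[1]),
       chisq = stat, p = stats::pchisq(stat, df, lower.tail = FALSE),
       flag = meanPar >= flagPar || meanOther <= flagOther)
}

#' Cross-population segregation-distortion hotspots
#'
#' Projects each population's significant distortion markers onto the
#' consensus map by name and counts, per consensus marker and per
#' consensus-position bin (default 10 cM), in how many populations the
#' locus is significantly distorted.  Positions reaching `minPops`
#' populations are hotspots; direction tallies are retained.
#'
#' @param scans named list (by population) of [segregationScan()] tables.
#' @param consensus a [ConsensusMap-class].
#' @param minPops hotspot threshold (default 3).
#' @param binWidth bin width in cM (default 10).
#' @return list: `byMarker` and `byBin` data.frames with `nPopulations`,
#'   direction counts and `hotspot`.
#' @export
sdlHotspots <- function(scans, consensus, minPops = 3, binWidth = 10) {
  ct <- mapTable(consensus)
  hits <- list()
  for (pop in names(scans)) {
    s <- scans[[pop]]
    sig <- s[s$significant, , drop = FALSE]
    if (!nrow(sig)) next
    at <- match(sig$marker, ct$marker)
    if (anyNA(at)) {
      warning(sum(is.na(at)), " significant markers of ", pop,
              " not on the consensus map; skipped")
      sig <- sig[!is.na(at), , drop = FALSE]
      at <- at[!is.na(at)]
    }
    if (nrow(sig))
      hits[[length(hits) + 1L]] <- data.frame(
        population = pop, marker = sig$marker,
        chromosome = ct$chromosome[at], position = ct$position[at],
        direction = sig$direction, stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    empty <- data.frame(nPopulations = integer(0))
    return(list(byMarker = empty, byBin = empty))
  }
  h <- do.call(rbind, hits)
  byMarker <- do.call(rbind, lapply(split(h, h$marker), function(d)
    data.frame(marker = d$marker[1], chromosome = d$chromosome[1],
               position = d$position[1],
               nPopulations = length(unique(d$population)),
               nParExcess = sum(d$direction == "Par_excess"),
               nOtherExcess = sum(d$direction == "other_excess"),
               stringsAsFactors = FALSE)))
  byMarker$hotspot <- byMarker$nPopulations >= minPops
  h$bin <- floor(h$position / binWidth) * binWidth
  key <- paste(h$chromosome, h$bin)
  byBin <- do.call(rbind, lapply(split(h, key), function(d)
    data.frame(chromosome = d$chromosome[1], binStart = d$bin[1],
               nPopulations = length(unique(d$population)),
               nParExcess = sum(d$direction == "Par_excess"),
               nOtherExcess = sum(d$direction == "other_excess"),
               stringsAsFactors = FALSE)))
  byBin$hotspot <- byBin$nPopulations >= minPops
  rownames(byMarker) <- rownames(byBin) <- NULL
  list(byMarker = byMarker, byBin = byBin)
}
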