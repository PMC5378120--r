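# Consensus mapping: orientation normalisation of component linkage
# groups, order-constrained L1 merging by linear programming, and
# selection of the maximum map interval K by RMSE diagnostics.  The L1
# objective is linearised in epigraph form and solved with the package's
# two-phase simplex (lp-simplex.R).

#' Orient component linkage groups for one chromosome
#'
#' Computes pairwise Spearman rank correlations of shared-marker orders
#' between all component linkage groups; any component whose mean
#' correlation against all others is negative has its order and positions
#' reversed.  Components sharing no markers with any other component are
#' discarded with a warning.
#'
#' @param lgs named list of data.frames (`marker`, `position`), one per
#'   component (population linkage group).
#' @return named list of oriented data.frames (possibly fewer).
#' @export
orientLinkageGroups <- function(lgs) {
  if (length(lgs) < 2) return(lgs)
  n <- length(lgs)
  shared <- matrix(0L, n, n)
  rho <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cm <- intersect(lgs[[i]]$marker, lgs[[j]]$marker)
    shared[i, j] <- shared[j, i] <- length(cm)
    if (length(cm) >= 2) {
      pi <- lgs[[i]]$position[match(cm, lgs[[i]]$marker)]
      pj <- lgs[[j]]$position[match(cm, lgs[[j]]$marker)]
      r <- suppressWarnings(stats::cor(pi, pj, method = "spearman"))
      rho[i, j] <- rho[j, i] <- r
    }
  }
  orphan <- rowSums(shared) == 0
  if (any(orphan)) {
    warning("discarding components with no shared markers: ",
            paste(names(lgs)[orphan], collapse = ", "))
    keep <- which(!orphan)
    return(orientLinkageGroups(lgs[keep]))
  }
  meanRho <- rowMeans(rho, na.rm = TRUE)
  for (i in which(!is.nan(meanRho) & meanRho < 0)) {
    lg <- lgs[[i]]
    lg$position <- max(lg$position) - lg$position
    lg <- lg[order(lg$position), , drop = FALSE]
    rownames(lg) <- NULL
    lgs[[i]] <- lg
  }
  lgs
}

#' Merge oriented linkage groups into a consensus order by LP
#'
#' Linear program over consensus positions `x_m`: every component
#' contributes order constraints `x_(i+q) - x_i >= 0` for all marker
#' pairs up to `K` apart in its order, and L1 objective terms
#' `|(x_j - x_i) - d_ij|` for its adjacent pairs, each component equally
#' weighted.  Conflicting order constraints (cycles in the union order
#' graph) are removed as a small feedback-arc set, greedily weighted by
#' the number of components supporting each constraint.  The L1 terms are
#' linearised with slack-variable pairs and solved with the simplex
#' method; the minimum position is anchored at 0.
#'
#' @param lgs named list of oriented data.frames (`marker`, `position`).
#' @param K maximum map interval for order constraints (1, 2 or 3).
#' @return list: `table` (data.frame `marker`, `position`, sorted),
#'   `removed` (data.frame of dropped constraints), `objective`.
#' @export
mergeLinkageGroups <- function(lgs, K = 2) {
  stopifnot(length(lgs) >= 1, K >= 1)
  markers <- unique(unlist(lapply(lgs, `[[`, "marker")))
  m <- length(markers)
  if (length(lgs) == 1L || m < 2) {
    tb <- do.call(rbind, lgs)[, c("marker", "position")]
    tb <- tb[!duplicated(tb$marker), , drop = FALSE]
    tb$position <- tb$position - min(tb$position)
    tb <- tb[order(tb$position, tb$marker), , drop = FALSE]
    rownames(tb) <- NULL
    return(list(table = tb, removed = data.frame(), objective = 0))
  }

  # order constraints (union, support-weighted) and L1 objective terms
  conKey <- character(0); conW <- numeric(0)
  terms <- list()
  for (li in seq_along(lgs)) {
    lg <- lgs[[li]]
    o <- match(lg$marker, markers)
    nl <- length(o)
    if (nl < 2) next
    for (q in seq_len(min(K, nl - 1)))
      for (i in seq_len(nl - q)) {
        key <- paste(o[i], o[i + q])
        at <- match(key, conKey)
        if (is.na(at)) { conKey <- c(conKey, key); conW <- c(conW, 1) }
        else conW[at] <- conW[at] + 1
      }
    w <- 1 / (nl - 1)
    for (i in seq_len(nl - 1))
      terms[[length(terms) + 1L]] <-
        list(i = o[i], j = o[i + 1], d = lg$position[i + 1] - lg$position[i],
             w = w)
  }
  # merge duplicate objective terms (identical pair and distance) so the
  # simplex never sees repeated rows
  tkey <- vapply(terms, function(t) paste(t$i, t$j, signif(t$d, 12)),
                 character(1))
  terms <- lapply(split(seq_along(terms), tkey), function(ix) {
    t0 <- terms[[ix[1]]]
    t0$w <- sum(vapply(terms[ix], `[[`, numeric(1), "w"))
    t0
  })
  conIJ <- do.call(rbind, lapply(strsplit(conKey, " "), as.integer))

  # break cycles: greedy minimal-support feedback arc set
  g <- igraph::graph_from_data_frame(
    data.frame(from = conIJ[, 1], to = conIJ[, 2]),
    vertices = data.frame(name = seq_len(m)))
  igraph::E(g)$weight <- conW
  removed <- data.frame()
  if (!igraph::is_dag(g)) {
    fas <- igraph::feedback_arc_set(g, weights = igraph::E(g)$weight)
    drop <- as.integer(fas)
    removed <- data.frame(from = markers[conIJ[drop, 1]],
                          to = markers[conIJ[drop, 2]],
                          support = conW[drop], stringsAsFactors = FALSE)
    conIJ <- conIJ[-drop, , drop = FALSE]
    conW <- conW[-drop]
    g2 <- igraph::delete_edges(g, fas)
    if (!igraph::is_dag(g2))
      stop("order conflicts remain after feedback-arc removal")
  }

  # epigraph form: e_t >= |(x_j - x_i) - d_t|, all-inequality system
  nt <- length(terms)
  nv <- m + nt
  obj <- c(rep(0, m), vapply(terms, `[[`, numeric(1), "w"))
  nc <- nrow(conIJ)
  Ale <- matrix(0, 2L * nt + nc, nv)
  ble <- numeric(2L * nt + nc)
  for (t in seq_len(nt)) {
    tt <- terms[[t]]
    r1 <- 2L * t - 1L                      # (x_j - x_i) - e_t <= d_t
    Ale[r1, tt$j] <- Ale[r1, tt$j] + 1
    Ale[r1, tt$i] <- Ale[r1, tt$i] - 1
    Ale[r1, m + t] <- -1
    ble[r1] <- tt$d
    r2 <- 2L * t                           # (x_i - x_j) - e_t <= -d_t
    Ale[r2, tt$i] <- Ale[r2, tt$i] + 1
    Ale[r2, tt$j] <- Ale[r2, tt$j] - 1
    Ale[r2, m + t] <- -1
    ble[r2] <- -tt$d
  }
  for (cc in seq_len(nc)) {                # x_u - x_v <= 0
    r <- 2L * nt + cc
    Ale[r, conIJ[cc, 1]] <- Ale[r, conIJ[cc, 1]] + 1
    Ale[r, conIJ[cc, 2]] <- Ale[r, conIJ[cc, 2]] - 1
  }
  sol <- .simplexLP(obj, Ale, ble)
  if (sol$status == 1L)
    stop("consensus LP infeasible; residual order conflicts")
  if (sol$status != 0L)
    stop("consensus LP failed to converge")
  x <- sol$x[seq_len(m)]
  x <- x - min(x)
  # stable order: position, then mean component rank, then name
  meanRank <- vapply(markers, function(mk) {
    r <- vapply(lgs, function(lg) {
      at <- match(mk, lg$marker)
      if (is.na(at)) NA_real_ else at / nrow(lg)
    }, numeric(1))
    mean(r, na.rm = TRUE)
  }, numeric(1))
  ord <- order(x, meanRank, markers)
  tb <- data.frame(marker = markers[ord], position = x[ord],
                   stringsAsFactors = FALSE)
  rownames(tb) <- NULL
  list(table = tb, removed = removed, objective = sol$fval)
}

.componentRmse <- function(consensus, lg) {
  cm <- intersect(consensus$marker, lg$marker)
  if (length(cm) < 2) return(NA_real_)
  y <- consensus$position[match(cm, consensus$marker)]
  p <- lg$position[match(cm, lg$marker)]
  if (stats::var(p) == 0) return(sqrt(mean((y - mean(y))^2)))
  fit <- stats::lm.fit(cbind(1, p), y)
  sqrt(mean(fit$residuals^2))
}

#' Build a consensus map across population maps
#'
#' For each chromosome, collects the linkage groups labelled to it from
#' every population map, orients them ([orientLinkageGroups()]), merges
#' them by LP ([mergeLinkageGroups()]) once per candidate `K`, and keeps
#' the candidate with the lowest mean component RMSE (ties: lower SD of
#' RMSE, then lower K).  RMSE per component is the root-mean-square
#' difference between consensus positions and the affinely rescaled
#' component positions over shared markers.
#'
#' @param maps list of [GeneticMap-class] objects.
#' @param K candidate maximum map intervals (default `1:3`).
#' @param chromosomes chromosomes to merge (default: all labelled).
#' @return a [ConsensusMap-class].
#' @export
buildConsensusMap <- function(maps, K = 1:3, chromosomes = NULL) {
  comp <- list()
  for (mp in maps) {
    tb <- mapTable(mp)
    for (g in unique(tb$lg)) {
      sub <- tb[tb$lg == g, , drop = FALSE]
      ch <- sub$chromosome[1]
      if (is.na(ch) || nrow(sub) < 2) next
      comp[[ch]] <- c(comp[[ch]], stats::setNames(
        list(sub[, c("marker", "position")]),
        paste(mp@populationId, g, sep = ":")))
    }
  }
  if (is.null(chromosomes)) chromosomes <- sort(names(comp))
  rows <- list(); Ksel <- numeric(0); diags <- list(); removed <- list()
  for (ch in chromosomes) {
    lgs <- orientLinkageGroups(comp[[ch]])
    if (!length(lgs)) next
    best <- NULL
    for (k in sort(K)) {
      mg <- mergeLinkageGroups(lgs, K = k)
      rmse <- vapply(lgs, .componentRmse, numeric(1),
                     consensus = mg$table)
      cand <- list(k = k, mg = mg, rmse = rmse,
                   mean = mean(rmse, na.rm = TRUE),
                   sd = stats::sd(rmse[!is.na(rmse)]))
      if (is.null(best) ||
          cand$mean < best$mean - 1e-9 ||
          (abs(cand$mean - best$mean) <= 1e-9 &&
           isTRUE(cand$sd < best$sd - 1e-9)))
        best <- cand
    }
    tb <- best$mg$table
    tb$chromosome <- ch
    rows[[ch]] <- tb[, c("marker", "chromosome", "position")]
    Ksel[ch] <- best$k
    diags[[ch]] <- data.frame(chromosome = ch,
                              component = names(best$rmse),
                              rmse = unname(best$rmse),
                              stringsAsFactors = FALSE)
    if (nrow(best$mg$removed)) {
      rm <- best$mg$removed; rm$chromosome <- ch
      removed[[ch]] <- rm
    }
  }
  methods::new("ConsensusMap",
               table = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
                       else data.frame(marker = character(),
                                       chromosome = character(),
                                       position = numeric()),
               K = Ksel,
               diagnostics = if (length(diags)) do.call(rbind, c(diags, make.row.names = FALSE))
                             else data.frame(),
               removed = if (length(removed)) do.call(rbind, c(removed, make.row.names = FALSE))
                         else data.frame())
}
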