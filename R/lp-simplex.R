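# Dense two-phase simplex for the consensus-merge linear programs.
#
# Solves  min c'x  s.t.  A x <= b, x >= 0  (b may be negative).  The
# instances here are small (tens of variables) but highly degenerate —
# many tied, duplicated and zero-distance constraints — so pivoting uses
# Bland's anti-cycling rule throughout, which guarantees termination.

.simplexLP <- function(cc, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  # slack form A x + s = b; flip rows with negative rhs and add artificials
  Afull <- cbind(A, diag(m))
  bfull <- b
  Afull[neg, ] <- -Afull[neg, , drop = FALSE]
  bfull[neg] <- -bfull[neg]
  nart <- sum(neg)
  artCols <- integer(0)
  if (nart) {
    art <- matrix(0, m, nart)
    art[cbind(which(neg), seq_len(nart))] <- 1
    Afull <- cbind(Afull, art)
    artCols <- n + m + seq_len(nart)
  }
  ntot <- ncol(Afull)
  basis <- n + seq_len(m)                 # slack basis ...
  if (nart) basis[neg] <- artCols         # ... artificials where flipped

  T <- cbind(Afull, bfull)                # m x (ntot + 1)

  pivot <- function(T, basis, pr, pc) {
    T[pr, ] <- T[pr, ] / T[pr, pc]
    for (r in seq_len(nrow(T))) if (r != pr && abs(T[r, pc]) > 0) {
      T[r, ] <- T[r, ] - T[r, pc] * T[pr, ]
    }
    basis[pr] <- pc
    list(T = T, basis = basis)
  }

  runPhase <- function(T, basis, cost, allowed) {
    repeat {
      cb <- cost[basis]
      red <- cost[seq_len(ntot)] - as.vector(cb %*% T[, seq_len(ntot), drop = FALSE])
      enter <- 0L
      for (j in allowed) {                 # Bland: first improving index
        if (red[j] < -tol && !(j %in% basis)) { enter <- j; break }
      }
      if (!enter) return(list(T = T, basis = basis, status = 0L))
      col <- T[, enter]
      ok <- which(col > tol)
      if (!length(ok)) return(list(T = T, basis = basis, status = 2L))  # unbounded
      ratio <- T[ok, ntot + 1L] / col[ok]
      best <- min(ratio)
      cand <- ok[ratio <= best + tol]
      pr <- cand[which.min(basis[cand])]   # Bland tie-break on leaving index
      st <- pivot(T, basis, pr, enter)
      T <- st$T; basis <- st$basis
    }
  }

  if (nart) {
    costP1 <- c(rep(0, n + m), rep(1, nart))
    ph1 <- runPhase(T, basis, costP1, seq_len(ntot))
    T <- ph1$T; basis <- ph1$basis
    val1 <- sum(costP1[basis] * T[, ntot + 1L])
    if (val1 > 1e-7) return(list(status = 1L))          # infeasible
    # pivot lingering artificials out of the basis where possible
    for (r in which(basis %in% artCols)) {
      sub <- which(abs(T[r, seq_len(n + m)]) > tol)
      if (length(sub)) {
        st <- pivot(T, basis, r, sub[1])
        T <- st$T; basis <- st$basis
      }
    }
  }
  costP2 <- c(cc, rep(0, m), rep(0, nart))
  allowed <- seq_len(n + m)               # artificials stay out
  ph2 <- runPhase(T, basis, costP2, allowed)
  if (ph2$status == 2L) return(list(status = 2L))
  T <- ph2$T; basis <- ph2$basis
  x <- numeric(ntot)
  x[basis] <- T[, ntot + 1L]
  list(status = 0L, x = x[seq_len(n)],
       fval = sum(cc * x[seq_len(n)]))
}
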