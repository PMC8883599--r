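# Dense two-phase primal simplex for the nutrient-replacement LP:
#
#   min c'x   s.t.  A x >= b,  0 <= x <= u   (b >= 0, u may be Inf)
#
# Problem sizes here are tiny (11 nutrient rows, <= ~150 columns), so a full
# tableau with Bland's anti-cycling rule is robust and fast; no factorisation
# updates needed. Upper bounds enter as explicit slack rows rather than a
# bounded-variable ratio test -- at most ~160 rows total.

simplex_lp <- function(cvec, A, b, upper, tol = 1e-9, max_iter = 20000L) {
  n <- length(cvec)
  stopifnot(is.matrix(A), ncol(A) == n, length(b) == nrow(A),
            length(upper) == n)
  if (any(b < 0))
    stop_validation("simplex_lp requires b >= 0 (nutrient targets)")
  m1 <- nrow(A)
  fin <- which(is.finite(upper))
  m2 <- length(fin)
  m <- m1 + m2

  # columns: x (n) | surplus (m1) | ub slack (m2) | artificial (m1)
  ncols <- n + m1 + m2 + m1
  Tm <- matrix(0, m, ncols + 1L)
  Tm[seq_len(m1), seq_len(n)] <- A
  Tm[cbind(seq_len(m1), n + seq_len(m1))] <- -1
  Tm[seq_len(m1), ncols + 1L] <- b
  if (m2) {
    Tm[cbind(m1 + seq_len(m2), fin)] <- 1
    Tm[cbind(m1 + seq_len(m2), n + m1 + seq_len(m2))] <- 1
    Tm[m1 + seq_len(m2), ncols + 1L] <- upper[fin]
  }
  art <- n + m1 + m2 + seq_len(m1)
  Tm[cbind(seq_len(m1), art)] <- 1
  basis <- c(art, if (m2) n + m1 + seq_len(m2))

  pivot <- function(Tm, r, j) {
    Tm[r, ] <- Tm[r, ] / Tm[r, j]
    other <- setdiff(seq_len(nrow(Tm)), r)
    Tm[other, ] <- Tm[other, ] - outer(Tm[other, j], Tm[r, ])
    Tm
  }

  run_phase <- function(Tm, basis, cost, allowed, tol, max_iter) {
    iters <- 0L
    repeat {
      iters <- iters + 1L
      if (iters > max_iter)
        return(list(Tm = Tm, basis = basis, status = "maxiter", iter = iters))
      y <- cost[basis]
      red <- cost - as.vector(y %*% Tm[, seq_along(cost), drop = FALSE])
      red[basis] <- 0
      cand <- which(allowed & red < -tol)
      if (!length(cand))
        return(list(Tm = Tm, basis = basis, status = "optimal", iter = iters))
      j <- cand[1L]                      # Bland: smallest index enters
      col <- Tm[, j]
      pos <- which(col > tol)
      if (!length(pos))
        return(list(Tm = Tm, basis = basis, status = "unbounded",
                    iter = iters, entering = j))
      ratio <- Tm[pos, ncol(Tm)] / col[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + tol * max(1, rmin)]
      r <- ties[which.min(basis[ties])]  # Bland: smallest basic leaves
      Tm <- pivot(Tm, r, j)
      basis[r] <- j
    }
  }

  # phase 1: drive artificials to zero
  c1 <- numeric(ncols); c1[art] <- 1
  allowed1 <- rep(TRUE, ncols)
  ph1 <- run_phase(Tm, basis, c1, allowed1, tol, max_iter)
  if (ph1$status == "maxiter")
    stop_state("simplex iteration limit reached in phase 1")
  Tm <- ph1$Tm; basis <- ph1$basis
  artvals <- numeric(m1)
  in_basis <- match(art, basis)
  has <- which(!is.na(in_basis))
  artvals[has] <- Tm[in_basis[has], ncols + 1L]
  phase1_obj <- sum(artvals)
  if (phase1_obj > 1e-7 * max(1, max(b)))
    return(list(status = "infeasible", x = NULL, value = NA_real_,
                residual_rows = artvals, iter = ph1$iter))

  # pivot any degenerate artificial out of the basis (or drop its row)
  keep_rows <- rep(TRUE, m)
  for (r in seq_len(m)) {
    if (basis[r] %in% art) {
      cand <- setdiff(which(abs(Tm[r, seq_len(n + m1 + m2)]) > tol),
                      basis)
      if (length(cand)) {
        j <- cand[1L]
        Tm <- pivot(Tm, r, j)
        basis[r] <- j
      } else {
        keep_rows[r] <- FALSE          # redundant row
      }
    }
  }
  if (!all(keep_rows)) {
    Tm <- Tm[keep_rows, , drop = FALSE]
    basis <- basis[keep_rows]
  }

  # phase 2 on the true objective; artificials barred from re-entering
  c2 <- numeric(ncols); c2[seq_len(n)] <- cvec
  allowed2 <- rep(TRUE, ncols); allowed2[art] <- FALSE
  ph2 <- run_phase(Tm, basis, c2, allowed2, tol, max_iter)
  if (ph2$status == "maxiter")
    stop_state("simplex iteration limit reached in phase 2")
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, value = -Inf,
                iter = ph1$iter + ph2$iter))
  Tm <- ph2$Tm; basis <- ph2$basis
  x <- numeric(n)
  bx <- which(basis <= n)
  x[basis[bx]] <- Tm[bx, ncols + 1L]
  x[x < 0 & x > -tol * 10] <- 0
  list(status = "optimal", x = x, value = sum(cvec * x),
       iter = ph1$iter + ph2$iter)
}
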