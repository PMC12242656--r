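#' @title Bounded-variable linear programming
#'
#' @description
#' Internal dense primal simplex for problems of the form
#' \deqn{\max\ c^T x \quad \mathrm{s.t.}\quad A x = b,\ l \le x \le u}
#' which is exactly the shape of the flux balance analysis (FBA) linear
#' program: equality mass balances plus box constraints on fluxes.
#'
#' The implementation is a textbook two-phase bounded-variable simplex with
#' Bland's anti-cycling rule.  FBA instances are highly degenerate (many
#' fluxes sit at zero bounds and stoichiometric matrices carry linearly
#' dependent rows from conserved moieties), so robustness, not speed, is the
#' design goal: the basic solution is recomputed from a fresh factorisation
#' at every iteration, redundant mass balances are absorbed by artificial
#' variables that stay basic at zero, and pivots are only accepted on
#' elements above a fixed tolerance.  Problem sizes in this package are tens
#' of columns, where this strategy is both exact enough and fast enough.
#'
#' @param obj objective coefficients (length n).
#' @param A constraint matrix (m x n), equality rows.
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds; each variable needs at least one finite
#'   bound.  `Inf`/`-Inf` are honoured in the ratio test so genuine
#'   unboundedness is detected, not masked by a big-M.
#' @param maximize direction; `FALSE` minimises.
#' @param warm optional warm-start state (the `state` element of a previous
#'   solution of a problem with the same columns); used heavily by the DFBA
#'   integrator where consecutive LPs differ only in one bound.
#' @param tol pivot/feasibility tolerance.
#'
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `value`, `x` (length n) and `state` (opaque warm-start data).
#' @keywords internal
#' @noRd
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, warm = NULL,
                     tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n,
            length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", value = NA_real_, x = rep(NA_real_, n),
                state = NULL))
  }
  if (any(!is.finite(lb) & !is.finite(ub))) {
    stop("lp_solve: free variables (both bounds infinite) are not supported")
  }
  sgn <- if (maximize) 1 else -1
  # Augment with one artificial column per row; artificials carry the
  # initial basis in phase 1 and are pinned to zero in phase 2 (a redundant
  # row simply keeps its artificial basic at zero).
  N <- n + m
  Aa <- cbind(A, diag(m))
  lo <- c(lb, rep(0, m))
  hi <- c(ub, rep(Inf, m))
  cc1 <- c(rep(0, n), rep(-1, m))       # phase 1: max -(sum artificials)
  cc2 <- c(sgn * obj, rep(0, m))        # phase 2

  start_at_upper <- function(lo, hi) {
    # nonbasic variables sit at the finite bound closest to zero
    au <- rep(FALSE, length(lo))
    au[!is.finite(lo)] <- TRUE
    both <- is.finite(lo) & is.finite(hi)
    au[both & (abs(hi) < abs(lo))] <- TRUE
    au
  }

  run <- function(cc, basis, at_upper, lo, hi, maxit = 500L + 50L * N) {
    for (it in seq_len(maxit)) {
      B <- Aa[, basis, drop = FALSE]
      nb <- setdiff(seq_len(N), basis)
      xN <- ifelse(at_upper[nb], hi[nb], lo[nb])
      xB <- tryCatch(
        solve(B, b - Aa[, nb, drop = FALSE] %*% xN),
        error = function(e) NULL)
      if (is.null(xB)) return(list(ok = FALSE))
      xB <- as.vector(xB)
      y <- as.vector(solve(t(B), cc[basis]))
      d <- cc[nb] - as.vector(crossprod(Aa[, nb, drop = FALSE], y))
      # entering candidates (maximisation)
      improving <- (!at_upper[nb] & d > tol) | (at_upper[nb] & d < -tol)
      improving <- improving & (hi[nb] > lo[nb] + tol)
      if (!any(improving)) {
        x <- numeric(N)
        x[nb] <- xN
        x[basis] <- xB
        return(list(ok = TRUE, status = "optimal", x = x, basis = basis,
                    at_upper = at_upper))
      }
      j <- min(nb[improving])            # Bland's rule
      dir <- if (at_upper[j]) -1 else 1
      w <- as.vector(solve(B, Aa[, j])) * dir
      # ratio test: how far can the entering variable move?
      t_enter <- hi[j] - lo[j]
      t_best <- t_enter
      leave <- 0L
      leave_upper <- FALSE
      for (i in seq_len(m)) {
        bi <- basis[i]
        if (w[i] > tol) {
          ti <- (xB[i] - lo[bi]) / w[i]
          hit_up <- FALSE
        } else if (w[i] < -tol) {
          ti <- (hi[bi] - xB[i]) / (-w[i])
          hit_up <- TRUE
        } else next
        if (!is.finite(ti)) next
        ti <- max(ti, 0)
        if (ti < t_best - tol ||
            (ti < t_best + tol && leave > 0L && bi < basis[leave])) {
          t_best <- ti
          leave <- i
          leave_upper <- hit_up
        }
      }
      if (!is.finite(t_best)) {
        return(list(ok = TRUE, status = "unbounded", x = rep(NA_real_, N),
                    basis = basis, at_upper = at_upper))
      }
      if (leave == 0L) {
        at_upper[j] <- !at_upper[j]      # bound flip, basis unchanged
      } else {
        old <- basis[leave]
        at_upper[old] <- leave_upper
        basis[leave] <- j
      }
    }
    list(ok = FALSE)                     # iteration limit: treat as failure
  }

  finish <- function(res) {
    x <- res$x[seq_len(n)]
    list(status = res$status,
         value = if (res$status == "optimal") sum(obj * x) else NA_real_,
         x = if (res$status == "optimal") x else rep(NA_real_, n),
         state = list(basis = res$basis, at_upper = res$at_upper))
  }

  # ---- warm start: previous basis, phase 2 only, if still primal feasible
  if (!is.null(warm) && length(warm$basis) == m &&
      all(warm$basis >= 1L) && all(warm$basis <= N)) {
    basis <- warm$basis
    at_upper <- warm$at_upper
    nb <- setdiff(seq_len(N), basis)
    # nonbasic variables snap to their (possibly moved) nearest bound
    snap <- start_at_upper(lo, hi)
    at_upper[nb] <- ifelse(is.finite(ifelse(at_upper[nb], hi[nb], lo[nb])),
                           at_upper[nb], snap[nb])
    xN <- ifelse(at_upper[nb], hi[nb], lo[nb])
    B <- Aa[, basis, drop = FALSE]
    xB <- tryCatch(as.vector(solve(B, b - Aa[, nb, drop = FALSE] %*% xN)),
                   error = function(e) NULL)
    if (!is.null(xB) &&
        all(xB >= lo[basis] - 1e-7) && all(xB <= hi[basis] + 1e-7)) {
      hi2 <- hi
      hi2[(n + 1L):N] <- 0               # artificials pinned
      if (all(xB[basis > n] <= 1e-7)) {
        res <- run(cc2, basis, at_upper, lo, hi2)
        if (isTRUE(res$ok)) return(finish(res))
      }
    }
  }

  # ---- phase 1 from scratch
  at_upper <- start_at_upper(lo, hi)
  x0 <- ifelse(at_upper[seq_len(n)], ub, lb)
  r <- b - as.vector(A %*% x0)
  # orient artificial columns so the starting artificial values are >= 0
  flip <- r < 0
  if (any(flip)) Aa[, n + which(flip)] <- -Aa[, n + which(flip), drop = FALSE]
  basis <- (n + 1L):N
  res1 <- run(cc1, basis, at_upper, lo, hi)
  if (!isTRUE(res1$ok)) stop("lp_solve: simplex failure in phase 1")
  if (res1$status != "optimal" || sum(res1$x[(n + 1L):N]) > 1e-7) {
    return(list(status = "infeasible", value = NA_real_,
                x = rep(NA_real_, n), state = NULL))
  }
  hi[(n + 1L):N] <- 0                    # pin artificials for phase 2
  res2 <- run(cc2, res1$basis, res1$at_upper, lo, hi)
  if (!isTRUE(res2$ok)) stop("lp_solve: simplex failure in phase 2")
  finish(res2)
}
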