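#' Solve a bounded-variable linear program
#'
#' Two-phase primal simplex for problems of the form
#' \deqn{\max\ c^\top v \quad \mathrm{s.t.}\quad A v = b,\ \ l \le v \le u,}
#' the shape taken by flux balance analysis (steady state \eqn{S v = 0}
#' with finite flux bounds). Variables rest on their bounds when nonbasic;
#' artificial variables give a trivially feasible starting basis, phase 1
#' drives them to zero, and Bland's smallest-index rule guarantees
#' termination under degeneracy (FBA problems are heavily degenerate).
#'
#' All structural bounds must be finite: genome-scale models in this
#' package use the conventional +/-1000 default bounds, so unbounded
#' directions can only arise through user-supplied infinite bounds, which
#' are rejected.
#'
#' @param obj objective coefficients (length n).
#' @param A constraint matrix (m x n), equality constraints `A v = b`.
#' @param b right-hand side (length m).
#' @param lb,ub finite lower / upper variable bounds (length n).
#' @param maximize maximize (default) or minimize the objective.
#' @param tol pivot / feasibility tolerance.
#' @param max_iter safety cap on simplex pivots.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective` and the solution vector `x` (NA unless optimal).
#' @export
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  obj <- as.numeric(obj); b <- as.numeric(b)
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  stopifnot(length(obj) == n, length(b) == m,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite variable bounds")
  failed <- list(status = "infeasible", objective = NA_real_,
                 x = rep(NA_real_, n))
  if (any(lb > ub + tol)) return(failed)

  # state over n structural + m artificial variables
  ntot <- n + m
  # nonbasic structural variables start at the bound nearest zero
  start_at_lb <- abs(lb) <= abs(ub)
  xval <- numeric(ntot)
  xval[seq_len(n)] <- ifelse(start_at_lb, lb, ub)
  vstat <- integer(ntot)                       # 0 basic, 1 at lb, 2 at ub
  vstat[seq_len(n)] <- ifelse(start_at_lb, 1L, 2L)

  resid <- drop(b - A %*% xval[seq_len(n)])
  art_sign <- ifelse(resid >= 0, 1, -1)
  Aext <- cbind(A, diag(art_sign, m, m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))
  xval[n + seq_len(m)] <- abs(resid)
  basis <- n + seq_len(m)
  vstat[basis] <- 0L
  Binv <- diag(1 / art_sign, m, m)             # inverse of artificial basis

  refactor <- function() {
    Bmat <- Aext[, basis, drop = FALSE]
    Binv <<- tryCatch(solve(Bmat), error = function(e) NULL)
    if (is.null(Binv)) stop("lp_solve: singular basis during refactor")
    nb <- setdiff(seq_len(ntot), basis)
    xval[basis] <<- drop(Binv %*% (b - Aext[, nb, drop = FALSE] %*% xval[nb]))
  }

  run_phase <- function(cost, allow_enter) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("lp_solve: iteration limit reached")
      if (it %% 60L == 0L) refactor()
      y <- drop(crossprod(Binv, cost[basis]))
      nb <- which(vstat != 0L & allow_enter)
      if (length(nb) == 0L) return("optimal")
      red <- cost[nb] - drop(crossprod(Aext[, nb, drop = FALSE], y))
      cand <- nb[(vstat[nb] == 1L & red < -tol) |
                 (vstat[nb] == 2L & red >  tol)]
      if (length(cand) == 0L) return("optimal")
      t <- min(cand)                            # Bland's rule
      s <- if (vstat[t] == 1L) 1 else -1        # direction of movement of x_t
      w <- drop(Binv %*% Aext[, t])
      # x_B moves by -s*delta*w; entering var can traverse its own range
      ratios <- rep(Inf, m)
      hit <- integer(m)                          # bound a basic var would hit
      for (i in seq_len(m)) {
        wi <- s * w[i]
        bi <- basis[i]
        if (wi > tol) {                          # basic value decreases
          ratios[i] <- (xval[bi] - lbe[bi]) / wi
          hit[i] <- 1L
        } else if (wi < -tol && is.finite(ube[bi])) {
          ratios[i] <- (ube[bi] - xval[bi]) / (-wi)
          hit[i] <- 2L
        }
      }
      rmin <- min(ratios)
      own_range <- ube[t] - lbe[t]
      delta_max <- min(rmin, own_range)
      if (!is.finite(delta_max)) return("unbounded")
      delta_max <- max(delta_max, 0)
      leave <- 0L; leave_to <- 0L
      if (rmin <= own_range + tol && is.finite(rmin)) {
        # Bland: among blocking basics, smallest variable index leaves
        blocking <- which(ratios <= rmin + tol)
        leave <- blocking[which.min(basis[blocking])]
        leave_to <- hit[leave]
        delta_max <- max(min(rmin, own_range), 0)
        if (own_range < rmin - tol) { leave <- 0L; leave_to <- 0L }
      }
      # apply step
      xval[basis] <<- xval[basis] - s * delta_max * w
      xval[t] <<- xval[t] + s * delta_max
      if (leave == 0L) {                         # bound flip, basis unchanged
        vstat[t] <<- if (vstat[t] == 1L) 2L else 1L
      } else {
        out <- basis[leave]
        vstat[out] <<- leave_to
        xval[out] <<- if (leave_to == 1L) lbe[out] else ube[out]
        vstat[t] <<- 0L
        basis[leave] <<- t
        # eta update of Binv
        wr <- w[leave]
        if (abs(wr) < 1e-11) { refactor() } else {
          Erow <- Binv[leave, ] / wr
          Binv <<- Binv - outer(w, Erow)
          Binv[leave, ] <<- Erow
        }
      }
    }
  }

  # phase 1: minimize sum of artificials
  cost1 <- c(rep(0, n), rep(1, m))
  st <- run_phase(cost1, allow_enter = c(rep(TRUE, n), rep(FALSE, m)))
  if (st != "optimal") return(failed)
  if (sum(xval[n + seq_len(m)]) > 1e-7) return(failed)
  # pin artificials to zero for phase 2
  ube[n + seq_len(m)] <- 0

  cost2 <- c(if (maximize) -obj else obj, rep(0, m))
  st <- run_phase(cost2, allow_enter = c(rep(TRUE, n), rep(FALSE, m)))
  if (st == "unbounded")
    return(list(status = "unbounded", objective = NA_real_,
                x = rep(NA_real_, n)))
  refactor()
  x <- xval[seq_len(n)]
  x <- pmin(pmax(x, lb), ub)                    # clip tiny bound violations
  list(status = "optimal", objective = sum(obj * x), x = x)
}
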