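# Dirichlet-multinomial mixture fitting for enterotype analysis.
#
# Gut communities cluster into a small number of compositional types
# (enterotypes). Genus-level counts are overdispersed relative to a
# multinomial, so each component is a Dirichlet-multinomial (DM); the
# mixture is fitted by EM with MM (Minka-type fixed-point) updates of the
# component alpha vectors, which keeps the observed-data log-likelihood
# non-decreasing at every step.

# log DM density per sample (rows of x), including the multinomial
# coefficient so traces are comparable across parameterizations
ldirmult <- function(x, alpha) {
  a0 <- sum(alpha)
  n <- rowSums(x)
  const <- lgamma(n + 1) - rowSums(lgamma(x + 1))
  const + lgamma(a0) - lgamma(a0 + n) +
    rowSums(lgamma(sweep(x, 2, alpha, "+"))) - sum(lgamma(alpha))
}

# one weighted MM fixed-point sweep of alpha for one component
dm_alpha_update <- function(x, w, alpha) {
  n <- rowSums(x)
  a0 <- sum(alpha)
  den <- sum(w * (digamma(n + a0) - digamma(a0)))
  if (den <= 0) return(alpha)
  num <- colSums(w * (digamma(sweep(x, 2, alpha, "+")) -
                        matrix(digamma(alpha), nrow(x), ncol(x), byrow = TRUE)))
  pmax(alpha * num / den, 1e-8)
}

#' Fit a Dirichlet-multinomial mixture to genus counts
#'
#' EM fit of a k-component Dirichlet-multinomial mixture (default k = 3,
#' the number of enterotype components used for gut communities): E-step
#' responsibilities from component DM log-likelihoods, M-step mixture
#' weights in closed form and component alphas by monotone fixed-point
#' (MM) sweeps. The best of `n_init` random restarts by final
#' log-likelihood is returned; an M-step that would numerically decrease
#' the log-likelihood is reverted and the fit declared converged, so the
#' reported trace is non-decreasing throughout. Components are labelled
#' by the genus with the largest fitted Dirichlet mean, which names the
#' enterotype (e.g. a Bacteroides-dominated component).
#'
#' @param genus_counts matrix of non-negative integer counts, either
#'   genera x samples (TSV orientation) or samples x genera; orientation
#'   is taken from `samples_in_rows`.
#' @param k number of mixture components (default 3).
#' @param seed RNG seed for the restarts.
#' @param n_init number of random restarts.
#' @param max_iter maximal EM iterations per restart.
#' @param tol convergence threshold on the log-likelihood increase.
#' @param samples_in_rows set TRUE when rows already are samples.
#' @return object of class `dmm_fit`: `k`, `alpha` (k x genera),
#'   `weights`, `responsibilities`, `assignment` (hard, named by sample),
#'   `labels` (component -> dominant genus), `loglik` (final),
#'   `loglik_trace` (of the winning restart).
#' @export
fit_dmm <- function(genus_counts, k = 3L, seed = 1L, n_init = 5L,
                    max_iter = 200L, tol = 1e-6, samples_in_rows = FALSE) {
  x <- as.matrix(genus_counts)
  if (!samples_in_rows) x <- t(x)
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  ns <- nrow(x); ng <- ncol(x)
  if (k < 1) stop("k must be >= 1")
  if (k > ns) stop("k (", k, ") exceeds the number of samples (", ns, ")")
  local_seed(seed)

  run_once <- function() {
    # moment-style init from k random samples, jittered
    pick <- sample(ns, k)
    alpha <- t(vapply(pick, function(i) {
      p <- (x[i, ] + 0.5) / sum(x[i, ] + 0.5)
      p * 10
    }, numeric(ng)))
    wts <- rep(1 / k, k)
    ll_old <- -Inf
    trace <- numeric(0)
    resp <- matrix(1 / k, ns, k)
    for (it in seq_len(max_iter)) {
      lmat <- vapply(seq_len(k), function(j)
        log(wts[j]) + ldirmult(x, alpha[j, ]), numeric(ns))
      mx <- apply(lmat, 1, max)
      lse <- mx + log(rowSums(exp(lmat - mx)))
      ll <- sum(lse)
      if (ll < ll_old - 1e-8) break           # numerical guard: keep old state
      resp <- exp(lmat - lse)
      trace <- c(trace, ll)
      converged <- is.finite(ll_old) && ll - ll_old < tol
      ll_old <- ll
      if (converged) break
      wts_new <- pmax(colMeans(resp), 1e-12)
      alpha_new <- alpha
      for (j in seq_len(k))
        for (sweep_i in 1:3)
          alpha_new[j, ] <- dm_alpha_update(x, resp[, j], alpha_new[j, ])
      # accept the M-step only if it does not decrease the likelihood
      lmat2 <- vapply(seq_len(k), function(j)
        log(wts_new[j]) + ldirmult(x, alpha_new[j, ]), numeric(ns))
      mx2 <- apply(lmat2, 1, max)
      ll2 <- sum(mx2 + log(rowSums(exp(lmat2 - mx2))))
      if (ll2 < ll - 1e-8) break
      wts <- wts_new; alpha <- alpha_new
    }
    list(alpha = alpha, weights = wts, resp = resp, ll = ll_old,
         trace = trace)
  }

  fits <- lapply(seq_len(n_init), function(i) run_once())
  best <- fits[[which.max(vapply(fits, `[[`, 0, "ll"))]]

  assign_idx <- apply(best$resp, 1, which.max)
  dmean <- sweep(best$alpha, 1, rowSums(best$alpha), "/")
  labels <- colnames(x)[apply(dmean, 1, which.max)]
  # degeneracy: a vanishing component, or two components whose mean
  # compositions are closer than any plausible enterotype contrast
  tiny <- any(best$weights < 1 / (10 * ns))
  tv_min <- Inf
  if (k > 1) {
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      tv_min <- min(tv_min, sum(abs(dmean[a, ] - dmean[b, ])) / 2)
  }
  degenerate <- tiny || (k > 1 && tv_min < 0.25)
  if (degenerate)
    warning("degenerate mixture fit (",
            if (tiny) "vanishing component weight"
            else sprintf("components nearly identical, min TV distance %.3f",
                         tv_min),
            "); consider a smaller k")
  structure(list(k = k,
                 alpha = best$alpha,
                 weights = best$weights,
                 responsibilities = best$resp,
                 assignment = stats::setNames(assign_idx, rownames(x)),
                 labels = labels,
                 loglik = best$ll,
                 loglik_trace = best$trace,
                 degenerate = degenerate,
                 genera = colnames(x)),
            class = "dmm_fit")
}

#' @export
print.dmm_fit <- function(x, ...) {
  cat("<dmm_fit> k =", x$k, "- logLik", format(x$loglik, digits = 8),
      "- components:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}
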