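# Toy models and independent oracles shared across the suite.

# linear chain: EX_A (uptake <= `uptake`) -> transport -> biomass
# consuming `yield_div` units of A[c] per unit growth; optimum is
# uptake / yield_div in closed form.
chain_gem <- function(yield_div = 1, uptake = 10) {
  mets <- data.frame(id = c("A[e]", "A[c]"), name = c("A", "A"),
                     compartment = c("e", "c"), stringsAsFactors = FALSE)
  rx <- list(
    "EX_A[e]" = list(id = "EX_A[e]", stoichiometry = c("A[e]" = -1),
                     lower_bound = -uptake, upper_bound = 1000,
                     kos = character(0), subsystem = ""),
    "T_A" = list(id = "T_A", stoichiometry = c("A[e]" = -1, "A[c]" = 1),
                 lower_bound = 0, upper_bound = 1000,
                 kos = character(0), subsystem = ""),
    "biomass" = list(id = "biomass",
                     stoichiometry = c("A[c]" = -yield_div),
                     lower_bound = 0, upper_bound = 1000,
                     kos = character(0), subsystem = ""))
  gem("chain", c("e", "c"), mets, rx, "biomass")
}

# chain with two redundant parallel transports: the optimum is unique in
# the exchange and biomass fluxes but the transport split is free
parallel_gem <- function(uptake = 10) {
  g <- chain_gem(uptake = uptake)
  g$reactions[["T_A2"]] <- list(id = "T_A2",
                                stoichiometry = c("A[e]" = -1, "A[c]" = 1),
                                lower_bound = 0, upper_bound = 1000,
                                kos = character(0), subsystem = "")
  gem(g$species_id, g$compartments, g$metabolites, g$reactions,
      g$biomass_reaction_id)
}

# chain whose biomass stoichiometrically co-produces a byproduct B that
# can only leave through its exchange: secretion is forced at optimum
byproduct_gem <- function(uptake = 10, bp_per_growth = 0.5) {
  g <- chain_gem(uptake = uptake)
  mets <- rbind(g$metabolites,
                data.frame(id = c("B[c]", "B[e]"), name = c("B", "B"),
                           compartment = c("c", "e"),
                           stringsAsFactors = FALSE))
  rx <- g$reactions
  rx[["biomass"]]$stoichiometry <- c("A[c]" = -1, "B[c]" = bp_per_growth)
  rx[["T_B"]] <- list(id = "T_B", stoichiometry = c("B[c]" = -1, "B[e]" = 1),
                      lower_bound = 0, upper_bound = 1000,
                      kos = character(0), subsystem = "")
  rx[["EX_B[e]"]] <- list(id = "EX_B[e]", stoichiometry = c("B[e]" = -1),
                          lower_bound = 0, upper_bound = 1000,
                          kos = character(0), subsystem = "")
  gem("byprod", c("e", "c"), mets, rx, "biomass")
}

# random small GEM with full-rank S and 3 degrees of freedom, so the
# vertex-enumeration oracle below stays cheap
random_small_gem <- function(n_rxn = 12, seed = 1) {
  set.seed(seed)
  repeat {
    m <- n_rxn - 3
    S <- matrix(0, m, n_rxn)
    for (j in seq_len(n_rxn)) {
      k <- sample(1:min(3, m), 1)
      S[sample(m, k), j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
    }
    if (qr(S)$rank < m) next
    lb <- ifelse(stats::runif(n_rxn) < 0.4, -stats::runif(n_rxn, 1, 10), 0)
    ub <- stats::runif(n_rxn, 1, 10)
    mets <- data.frame(id = sprintf("m%02d[c]", seq_len(m)),
                       name = sprintf("m%02d", seq_len(m)),
                       compartment = "c", stringsAsFactors = FALSE)
    rx <- lapply(seq_len(n_rxn), function(j) {
      nz <- which(S[, j] != 0)
      list(id = sprintf("r%02d", j),
           stoichiometry = stats::setNames(S[nz, j], mets$id[nz]),
           lower_bound = lb[j], upper_bound = ub[j],
           kos = character(0), subsystem = "")
    })
    names(rx) <- vapply(rx, `[[`, "", "id")
    bio <- sample(n_rxn, 1)
    return(gem(sprintf("rand%03d", seed), "c", mets, rx,
               sprintf("r%02d", bio)))
  }
}

# independent FBA oracle: enumerate all candidate vertices of
# {S v = 0, lb <= v <= ub} by fixing (n - rank) variables at bounds
vertex_fba_oracle <- function(g) {
  S <- stoichiometric_matrix(g)
  bd <- gem_bounds_for_test(g)
  lb <- bd$lb; ub <- bd$ub
  n <- ncol(S)
  obj <- as.numeric(colnames(S) == g$biomass_reaction_id)
  m0 <- qr(S)$rank
  free <- n - m0
  best <- -Inf; feasible <- FALSE
  combs <- utils::combn(n, free)
  for (ci in seq_len(ncol(combs))) {
    Fi <- combs[, ci]; Bi <- setdiff(seq_len(n), Fi)
    SB <- S[, Bi, drop = FALSE]
    if (qr(SB)$rank < m0) next
    for (mask in 0:(2^free - 1)) {
      vF <- ifelse(bitwAnd(mask, 2^(seq_len(free) - 1)) > 0, ub[Fi], lb[Fi])
      rhs <- -S[, Fi, drop = FALSE] %*% vF
      vB <- tryCatch(qr.solve(SB, rhs), error = function(e) NULL)
      if (is.null(vB)) next
      if (all(vB >= lb[Bi] - 1e-8) && all(vB <= ub[Bi] + 1e-8)) {
        feasible <- TRUE
        v <- numeric(n); v[Fi] <- vF; v[Bi] <- vB
        best <- max(best, sum(obj * v))
      }
    }
  }
  list(feasible = feasible, objective = best)
}

canonicalize_gem_for_test <- function(g) gutflux:::canonicalize_gem(g)

gem_bounds_for_test <- function(g) {
  list(lb = vapply(g$reactions, `[[`, 0, "lower_bound"),
       ub = vapply(g$reactions, `[[`, 0, "upper_bound"))
}

# steady-state residual and bound violation of a flux vector
conservation_violation <- function(g, flux) {
  S <- stoichiometric_matrix(g)
  bd <- gem_bounds_for_test(g)
  v <- flux$fluxes[colnames(S)]
  list(steady = max(abs(S %*% v)),
       bounds = max(c(bd$lb - v, v - bd$ub, 0)))
}

# exact Wilcoxon two-sided p by explicit enumeration of all 2^n sign
# assignments (the spec's oracle), usable up to n ~ 12
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    pos <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[pos])
  }, 0)
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# brute-force BH step-up q-values straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * p[o][i:m] / (i:m))), 0)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n)
# draws of the selected set (N <= 12)
hyper_enum_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  in_pathway <- seq_len(N) <= K
  overlaps <- apply(draws, 2, function(ix) sum(in_pathway[ix]))
  mean(overlaps >= k)
}
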