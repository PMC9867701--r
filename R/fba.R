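#' Define a diet
#'
#' A diet is a named set of maximal uptake fluxes over the shared
#' extracellular metabolite namespace, plus an anaerobic flag. Flux units
#' are mmol/gDW/h analogues on a fixed arbitrary scale (maximal bound 10
#' in the built-in diets); only the relative structure between diets
#' matters for the analyses here.
#'
#' @param name diet identifier.
#' @param uptake_bounds named numeric vector, metabolite base id ->
#'   maximal uptake flux (>= 0).
#' @param anaerobic if `TRUE` (the study condition for all six built-in
#'   diets), oxygen uptake is forced to zero regardless of the bounds.
#' @return object of class `diet`.
#' @export
diet <- function(name, uptake_bounds, anaerobic = TRUE) {
  ub <- unlist(uptake_bounds)
  if (any(ub < 0)) stop("uptake bounds must be >= 0")
  structure(list(name = name, uptake_bounds = ub, anaerobic = anaerobic),
            class = "diet")
}

#' @export
print.diet <- function(x, ...) {
  cat("<diet>", x$name, if (x$anaerobic) "(anaerobic)" else "(aerobic)",
      "-", length(x$uptake_bounds), "metabolites\n")
  invisible(x)
}

#' Write / read a diet as TSV
#'
#' Two-column TSV (`metabolite_id`, `max_uptake_flux`) with a header
#' comment line carrying the diet name and anaerobic flag.
#'
#' @param d a `diet`.
#' @param path file path.
#' @return `read_diet` returns a `diet`; `write_diet` its input, invisibly.
#' @export
write_diet <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# diet=%s anaerobic=%d", d$name, as.integer(d$anaerobic)), con)
  writeLines("metabolite_id\tmax_uptake_flux", con)
  writeLines(sprintf("%s\t%.10g", names(d$uptake_bounds), d$uptake_bounds), con)
  invisible(d)
}

#' @rdname write_diet
#' @export
read_diet <- function(path) {
  hdr <- readLines(path, n = 1)
  nm <- sub("^# diet=(\\S+).*$", "\\1", hdr)
  ana <- grepl("anaerobic=1", hdr)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                           stringsAsFactors = FALSE)
  diet(nm, stats::setNames(tab$max_uptake_flux, tab$metabolite_id),
       anaerobic = ana)
}

#' Constrain a model with a diet
#'
#' Returns a constrained copy of the model: for every exchange reaction in
#' the model's diet-facing compartment whose metabolite appears in the
#' diet, the lower bound is set to minus the diet's maximal uptake flux;
#' exchange reactions of metabolites absent from the diet get lower bound
#' 0 (nothing to take up). Exchange upper bounds are never touched, so
#' secretion stays free. Under an anaerobic diet the oxygen exchange lower
#' bound is 0 regardless of the diet table. Diet metabolites without a
#' matching exchange reaction are ignored with a warning. The operation is
#' idempotent and never modifies its input.
#'
#' @param g a valid `gem`.
#' @param d a `diet`.
#' @param oxygen_id base metabolite id for oxygen.
#' @return a constrained copy of `g`.
#' @export
apply_diet <- function(g, d, oxygen_id = "o2") {
  target_comp <- g$extracellular[1]
  ex_ids <- exchange_reactions(g, compartment = target_comp)
  ex_mets <- vapply(g$reactions[ex_ids],
                    function(r) met_base_id(names(r$stoichiometry)), "")
  for (i in seq_along(ex_ids)) {
    m <- ex_mets[i]
    rid <- ex_ids[i]
    g$reactions[[rid]]$lower_bound <-
      if (m %in% names(d$uptake_bounds)) -d$uptake_bounds[[m]] else 0
  }
  if (d$anaerobic) {
    o2 <- ex_ids[ex_mets == oxygen_id]
    for (rid in o2) g$reactions[[rid]]$lower_bound <- 0
  }
  missing <- setdiff(names(d$uptake_bounds), ex_mets)
  if (length(missing))
    warning("diet '", d$name, "' metabolites without exchange reaction ",
            "in model '", g$species_id, "' (ignored): ",
            paste(missing, collapse = ", "))
  g
}

#' Flux balance analysis
#'
#' Maximizes the flux of the objective reaction (biomass by default)
#' subject to the steady-state constraint `S v = 0` and the model's flux
#' bounds, via the package's bounded-variable simplex. With all-finite
#' bounds (the model convention) the LP cannot be unbounded; status is
#' reported faithfully.
#'
#' @param g a valid `gem` (normally diet-constrained, see [apply_diet()]).
#' @param objective_reaction reaction id to maximize; defaults to the
#'   model's biomass reaction.
#' @return a `flux_result`: list with `status`, `objective_value`, `fluxes`
#'   (named by reaction id).
#' @export
solve_fba <- function(g, objective_reaction = g$biomass_reaction_id) {
  rids <- vapply(g$reactions, `[[`, "", "id")
  if (!objective_reaction %in% rids)
    stop("objective reaction '", objective_reaction, "' not in model")
  S <- stoichiometric_matrix(g)
  bd <- gem_bounds(g)
  obj <- as.numeric(rids == objective_reaction)
  sol <- lp_solve(obj, S, rep(0, nrow(S)), bd$lb, bd$ub, maximize = TRUE)
  fluxes <- if (sol$status == "optimal") stats::setNames(sol$x, rids)
            else stats::setNames(rep(NA_real_, length(rids)), rids)
  structure(list(status = sol$status,
                 objective_value = if (sol$status == "optimal") sol$objective else NA_real_,
                 fluxes = fluxes),
            class = "flux_result")
}

#' Flux variability analysis
#'
#' For each requested reaction, the minimal and maximal flux compatible
#' with the steady state, the bounds, and an objective at or above
#' `objective_fraction` times the FBA optimum. At `objective_fraction = 1`
#' every interval contains the FBA flux (within solver tolerance); at 0
#' the objective constraint is vacuous.
#'
#' @param g a valid `gem`.
#' @param reactions reaction ids to scan (default all).
#' @param objective_fraction fraction of the optimum to retain, in [0, 1].
#' @param objective_reaction objective reaction id (default biomass).
#' @return data.frame with `reaction`, `min_flux`, `max_flux`.
#' @export
solve_fva <- function(g, reactions = NULL, objective_fraction = 1,
                      objective_reaction = g$biomass_reaction_id) {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1)
  base <- solve_fba(g, objective_reaction)
  if (base$status != "optimal")
    stop("FVA base problem is ", base$status)
  zstar <- base$objective_value
  # pin the objective with a tiny relief so the optimal face stays feasible
  g$reactions[[objective_reaction]]$lower_bound <-
    max(g$reactions[[objective_reaction]]$lower_bound,
        objective_fraction * zstar - 1e-9)
  rids <- vapply(g$reactions, `[[`, "", "id")
  if (is.null(reactions)) reactions <- rids
  S <- stoichiometric_matrix(g)
  bd <- gem_bounds(g)
  out <- data.frame(reaction = reactions,
                    min_flux = NA_real_, max_flux = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(reactions)) {
    obj <- as.numeric(rids == reactions[i])
    lo <- lp_solve(obj, S, rep(0, nrow(S)), bd$lb, bd$ub, maximize = FALSE)
    hi <- lp_solve(obj, S, rep(0, nrow(S)), bd$lb, bd$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem for ", reactions[i], " is ", lo$status)
    out$min_flux[i] <- lo$objective
    out$max_flux[i] <- hi$objective
  }
  out
}

#' Classify exchange metabolites from one flux solution
#'
#' A metabolite is `produced` when its exchange flux exceeds `eps`,
#' `consumed` below `-eps`, `inactive` otherwise. Because FBA flux vectors
#' are generally non-unique, group-level reporting
#' ([growth_matrix()], [community_secretions()]) instead classifies
#' through FVA intervals at the optimum ([exchange_profile_fva()]); this
#' function reads a single solution as-is.
#'
#' @param g a valid `gem`.
#' @param flux an optimal `flux_result` for `g`.
#' @param eps classification threshold.
#' @return data.frame `metabolite`, `flux`, `class`.
#' @export
exchange_profile <- function(g, flux, eps = 1e-6) {
  stopifnot(flux$status == "optimal")
  ex <- exchange_reactions(g)
  mets <- vapply(g$reactions[ex],
                 function(r) met_base_id(names(r$stoichiometry)), "")
  v <- flux$fluxes[ex]
  data.frame(metabolite = unname(mets), flux = unname(v),
             class = ifelse(v > eps, "produced",
                            ifelse(v < -eps, "consumed", "inactive")),
             stringsAsFactors = FALSE)
}

#' Deterministic exchange classification through FVA at the optimum
#'
#' Resolves alternate optima: a metabolite is `produced` when the minimal
#' exchange flux over the optimal face exceeds `eps` (production is
#' forced), `consumed` when the maximal flux is below `-eps`; otherwise
#' the single FBA solution decides and the row is flagged `ambiguous`.
#'
#' @inheritParams exchange_profile
#' @return data.frame `metabolite`, `flux`, `min_flux`, `max_flux`,
#'   `class`, `ambiguous`.
#' @export
exchange_profile_fva <- function(g, eps = 1e-6) {
  flux <- solve_fba(g)
  if (flux$status != "optimal")
    return(data.frame(metabolite = character(0), flux = numeric(0),
                      min_flux = numeric(0), max_flux = numeric(0),
                      class = character(0), ambiguous = logical(0)))
  ex <- exchange_reactions(g)
  fva <- solve_fva(g, reactions = ex, objective_fraction = 1)
  mets <- vapply(g$reactions[ex],
                 function(r) met_base_id(names(r$stoichiometry)), "")
  v <- unname(flux$fluxes[ex])
  cls <- ifelse(fva$min_flux > eps, "produced",
                ifelse(fva$max_flux < -eps, "consumed", NA))
  amb <- is.na(cls)
  cls[amb] <- ifelse(v[amb] > eps, "produced",
                     ifelse(v[amb] < -eps, "consumed", "inactive"))
  # inactive rows resolved by FVA agreeing with zero are not ambiguous
  amb <- amb & !(abs(fva$min_flux) <= eps & abs(fva$max_flux) <= eps)
  data.frame(metabolite = unname(mets), flux = v,
             min_flux = fva$min_flux, max_flux = fva$max_flux,
             class = cls, ambiguous = amb, stringsAsFactors = FALSE)
}

#' Growth matrix and pooled exchange profiles across diets
#'
#' Solves every (species, diet) pair: growth rates as a species x diet
#' table (infeasible pairs reported as growth 0 with a status flag, so
#' the table stays rectangular), and per-direction pooled counts of
#' producing/consuming species per metabolite and diet — the
#' individual-modelling summary of which guild contributes which
#' metabolite under which nutritional environment.
#'
#' @param gems list of `gem` objects.
#' @param diets list of `diet` objects.
#' @param directions optional named character vector `species_id ->`
#'   direction label (e.g. "increased"/"decreased") used for pooled
#'   summaries.
#' @param eps exchange classification threshold.
#' @return list with `growth` (matrix species x diet), `status`
#'   (same shape), `profiles` (long data.frame of per-species
#'   classifications) and `summary` (per direction x diet x metabolite
#'   producer/consumer counts; `NULL` when `directions` is missing).
#' @export
growth_matrix <- function(gems, diets, directions = NULL, eps = 1e-6) {
  sp <- vapply(gems, `[[`, "", "species_id")
  dn <- vapply(diets, `[[`, "", "name")
  growth <- matrix(0, length(sp), length(dn), dimnames = list(sp, dn))
  status <- matrix("optimal", length(sp), length(dn), dimnames = list(sp, dn))
  profs <- list()
  for (i in seq_along(gems)) for (j in seq_along(diets)) {
    gcon <- apply_diet(gems[[i]], diets[[j]])
    fr <- solve_fba(gcon)
    status[i, j] <- fr$status
    if (fr$status == "optimal") {
      growth[i, j] <- fr$objective_value
      pr <- exchange_profile_fva(gcon, eps = eps)
      if (nrow(pr)) {
        pr$species_id <- sp[i]; pr$diet <- dn[j]
        profs[[length(profs) + 1L]] <- pr
      }
    }
  }
  profiles <- if (length(profs)) do.call(rbind, profs) else NULL
  summary <- NULL
  if (!is.null(directions) && !is.null(profiles)) {
    profiles$direction <- unname(directions[profiles$species_id])
    act <- profiles[profiles$class != "inactive" & !is.na(profiles$direction), ]
    if (nrow(act)) {
      summary <- as.data.frame(
        table(direction = act$direction, diet = act$diet,
              metabolite = act$metabolite, class = act$class),
        responseName = "n_species", stringsAsFactors = FALSE)
      summary <- summary[summary$n_species > 0, ]
      rownames(summary) <- NULL
    }
  }
  list(growth = growth, status = status, profiles = profiles,
       summary = summary)
}
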