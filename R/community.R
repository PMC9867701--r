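#' Assemble a personalized multi-species community model
#'
#' Merges member stoichiometric models into one community GEM: each
#' member keeps its own cellular compartments (renamed `c_<species>`,
#' ...), every member's extracellular metabolite is remapped to a shared
#' intestinal-lumen compartment `lu`, and a secretion/fecal compartment
#' `fe` collects what the community does not consume. Member reaction ids
#' are prefixed `<species>__` so there are no collisions. Structure added
#' at assembly:
#'
#' * diet exchange reactions `EX_<m>[lu]` feeding the lumen (uptake only;
#'   bounds set later by [apply_diet()]);
#' * irreversible exports `UT_<m>` from `lu` to `fe` and free secretion
#'   exchanges `EX_<m>[fe]` — all material leaving the community exits
#'   through `fe`;
#' * each member's biomass reaction additionally produces one unit of a
#'   member-biomass metabolite `biomass_<species>[lu]`;
#' * a community biomass reaction consuming `a_i` units of each
#'   member-biomass metabolite (abundances renormalized to sum 1) and
#'   producing community biomass, which is exported.
#'
#' The abundance coupling is therefore hard (fixed stoichiometric
#' proportions): at any steady state routing all member biomass into
#' community biomass, member i grows at exactly `a_i` times the community
#' rate. A consequence worth knowing: if one member cannot grow on a
#' diet, the whole community objective is 0.
#'
#' @param gems list of member `gem` objects (1 to 10; the cap mirrors the
#'   community-size limit used when personalized communities are built
#'   per subject).
#' @param abundances numeric vector of member relative abundances
#'   (renormalized internally; total must be > 0).
#' @return a `gem` of subclass `community_gem`, with `members` and
#'   `abundances` fields.
#' @export
assemble_community <- function(gems, abundances) {
  n <- length(gems)
  if (n < 1) stop("a community needs at least one member")
  if (n > 10)
    stop("a maximum of 10 members per community is supported; got ", n)
  if (length(abundances) != n)
    stop("abundances must match the number of members")
  if (any(abundances < 0) || sum(abundances) <= 0)
    stop("abundances must be >= 0 with positive total")
  a <- abundances / sum(abundances)
  sp <- vapply(gems, `[[`, "", "species_id")
  if (anyDuplicated(sp)) stop("duplicate member species ids")

  mets <- list(); rxns <- list(); comps <- c("lu", "fe")
  lumen_mets <- character(0)
  remap_met <- function(mid, species) {
    comp <- met_compartment(mid)
    base <- met_base_id(mid)
    if (comp %in% c("e", "lu")) paste0(base, "[lu]")
    else paste0(base, "[", comp, "_", species, "]")
  }
  for (k in seq_len(n)) {
    g <- gems[[k]]; s <- sp[k]
    internal <- setdiff(g$compartments, g$extracellular)
    comps <- union(comps, paste0(internal, "_", s))
    for (i in seq_len(nrow(g$metabolites))) {
      mid <- remap_met(g$metabolites$id[i], s)
      if (met_compartment(mid) == "lu") lumen_mets <- union(lumen_mets, mid)
      mets[[mid]] <- data.frame(id = mid, name = g$metabolites$name[i],
                                compartment = met_compartment(mid),
                                stringsAsFactors = FALSE)
    }
    for (r in g$reactions) {
      if (is_exchange(g, r)) next                   # lumen plumbing replaces these
      st <- r$stoichiometry
      names(st) <- vapply(names(st), remap_met, "", species = s)
      rr <- r
      rr$id <- paste0(s, "__", r$id)
      rr$stoichiometry <- st
      if (r$id == g$biomass_reaction_id) {
        bm <- paste0("biomass_", s, "[lu]")
        mets[[bm]] <- data.frame(id = bm, name = paste0("biomass of ", s),
                                 compartment = "lu", stringsAsFactors = FALSE)
        rr$stoichiometry <- c(rr$stoichiometry, stats::setNames(1, bm))
      }
      rxns[[rr$id]] <- rr
    }
  }
  # lumen exchanges (uptake-only; diet opens them) and lu -> fe -> out routes
  for (mid in lumen_mets) {
    base <- met_base_id(mid)
    fe <- paste0(base, "[fe]")
    mets[[fe]] <- data.frame(id = fe, name = base, compartment = "fe",
                             stringsAsFactors = FALSE)
    rxns[[paste0("EX_", mid)]] <- list(
      id = paste0("EX_", mid), stoichiometry = stats::setNames(-1, mid),
      lower_bound = 0, upper_bound = 0, kos = character(0),
      subsystem = "lumen exchange")
    rxns[[paste0("UT_", base)]] <- list(
      id = paste0("UT_", base),
      stoichiometry = stats::setNames(c(-1, 1), c(mid, fe)),
      lower_bound = 0, upper_bound = 1000, kos = character(0),
      subsystem = "lumen-to-fecal transfer")
    rxns[[paste0("EX_", fe)]] <- list(
      id = paste0("EX_", fe), stoichiometry = stats::setNames(-1, fe),
      lower_bound = 0, upper_bound = 1000, kos = character(0),
      subsystem = "fecal exchange")
  }
  # community biomass: -a_i biomass_i[lu] ... -> +1 biomass_community[fe]
  cb <- "biomass_community[fe]"
  mets[[cb]] <- data.frame(id = cb, name = "community biomass",
                           compartment = "fe", stringsAsFactors = FALSE)
  st <- stats::setNames(c(-a, 1), c(paste0("biomass_", sp, "[lu]"), cb))
  rxns[["community_biomass"]] <- list(
    id = "community_biomass", stoichiometry = st,
    lower_bound = 0, upper_bound = 1000, kos = character(0),
    subsystem = "community biomass")
  rxns[[paste0("EX_", cb)]] <- list(
    id = paste0("EX_", cb), stoichiometry = stats::setNames(-1, cb),
    lower_bound = 0, upper_bound = 1000, kos = character(0),
    subsystem = "fecal exchange")

  cm <- gem(species_id = paste0("community(", paste(sp, collapse = ","), ")"),
            compartments = comps,
            metabolites = do.call(rbind, unname(mets)),
            reactions = rxns,
            biomass_reaction_id = "community_biomass",
            extracellular = c("lu", "fe"))
  class(cm) <- c("community_gem", class(cm))
  cm$members <- sp
  cm$abundances <- stats::setNames(a, sp)
  cm
}

#' Community flux balance analysis under a diet
#'
#' Applies the diet to the lumen exchange reactions (anaerobic enforced as
#' in [apply_diet()]) and maximizes community biomass.
#'
#' @param cm a `community_gem` from [assemble_community()].
#' @param d a `diet`.
#' @return a `flux_result` (see [solve_fba()]).
#' @export
community_fba <- function(cm, d) {
  solve_fba(apply_diet(cm, d))
}

#' Net and per-member secretion profile of a community
#'
#' Net community secretion of a metabolite is the flux of its fecal
#' exchange `EX_<m>[fe]`; production calls are made deterministic through
#' FVA at the community optimum (a metabolite counts as produced when its
#' minimal fecal exchange flux at the optimum exceeds `eps`, with the FBA
#' solution resolving ambiguous cases, as in [exchange_profile_fva()]).
#' Per-member contributions are each member's net lumen-directed flux of
#' the metabolite (sum of stoichiometry x flux over the member's
#' reactions touching `m[lu]`).
#'
#' @param cm a diet-constrained `community_gem`.
#' @param flux an optimal `flux_result` for `cm` (e.g. from
#'   [community_fba()] on the same constrained model).
#' @param eps classification threshold.
#' @param fva use FVA at the optimum to resolve alternate optima
#'   (default TRUE).
#' @return list with `net` (data.frame `metabolite`, `flux`, `produced`)
#'   and `members` (data.frame `member`, `metabolite`, `flux`).
#' @export
community_secretions <- function(cm, flux, eps = 1e-6, fva = TRUE) {
  stopifnot(inherits(cm, "community_gem"), flux$status == "optimal")
  fe_ex <- grep("^EX_.*\\[fe\\]$", names(cm$reactions), value = TRUE)
  fe_ex <- setdiff(fe_ex, "EX_biomass_community[fe]")
  mets <- vapply(cm$reactions[fe_ex],
                 function(r) met_base_id(names(r$stoichiometry)), "")
  v <- unname(flux$fluxes[fe_ex])
  if (fva) {
    # pin the optimum and take the guaranteed (minimal) secretion flux
    cm2 <- cm
    cm2$reactions[["community_biomass"]]$lower_bound <-
      max(0, flux$objective_value - 1e-9)
    fva_tab <- solve_fva(cm2, reactions = fe_ex, objective_fraction = 1)
    produced <- fva_tab$min_flux > eps
    produced[!produced & fva_tab$max_flux > eps] <- v[!produced & fva_tab$max_flux > eps] > eps
  } else {
    produced <- v > eps
  }
  net <- data.frame(metabolite = unname(mets), flux = v,
                    produced = produced, stringsAsFactors = FALSE)
  # per-member lumen-directed fluxes
  memb <- list()
  for (s in cm$members) {
    rids <- grep(paste0("^", s, "__"), names(cm$reactions), value = TRUE)
    contrib <- stats::setNames(numeric(length(mets)), mets)
    for (rid in rids) {
      st <- cm$reactions[[rid]]$stoichiometry
      lu <- names(st)[met_compartment(names(st)) == "lu"]
      lu <- lu[met_base_id(lu) %in% mets]
      if (length(lu))
        contrib[met_base_id(lu)] <- contrib[met_base_id(lu)] +
          st[lu] * flux$fluxes[[rid]]
    }
    memb[[s]] <- data.frame(member = s, metabolite = names(contrib),
                            flux = unname(contrib), stringsAsFactors = FALSE)
  }
  list(net = net, members = do.call(rbind, unname(memb)))
}

#' Count producing communities per metabolite
#'
#' Given secretion profiles of all communities in one group (one
#' timepoint), counts how many communities net-produce each metabolite.
#'
#' @param profiles named list of [community_secretions()] results.
#' @return data.frame `metabolite`, `n_producing`.
#' @export
producer_counts <- function(profiles) {
  if (length(profiles) == 0)
    return(data.frame(metabolite = character(0), n_producing = integer(0)))
  mets <- sort(unique(unlist(lapply(profiles, function(p) p$net$metabolite))))
  n <- vapply(mets, function(m) {
    sum(vapply(profiles, function(p) {
      i <- match(m, p$net$metabolite)
      !is.na(i) && p$net$produced[i]
    }, logical(1)))
  }, integer(1))
  data.frame(metabolite = mets, n_producing = unname(n),
             stringsAsFactors = FALSE)
}

#' Filter main contributor metabolites between two groups
#'
#' Keeps metabolites produced in at least `min_communities` communities in
#' at least one group AND with a strictly different producer count between
#' the groups ("similar" counts, read strictly as equal, are ignored).
#' The direction is the group with the larger count.
#'
#' @param counts_m0,counts_m4 [producer_counts()] tables for the two
#'   groups.
#' @param min_communities minimal producer count (default 3).
#' @return data.frame `metabolite`, `count_m0`, `count_m4`, `direction`.
#' @export
filter_contributors <- function(counts_m0, counts_m4, min_communities = 3) {
  mets <- sort(union(counts_m0$metabolite, counts_m4$metabolite))
  c0 <- counts_m0$n_producing[match(mets, counts_m0$metabolite)]
  c4 <- counts_m4$n_producing[match(mets, counts_m4$metabolite)]
  c0[is.na(c0)] <- 0L; c4[is.na(c4)] <- 0L
  keep <- (c0 >= min_communities | c4 >= min_communities) & c0 != c4
  data.frame(metabolite = mets[keep],
             count_m0 = c0[keep], count_m4 = c4[keep],
             direction = ifelse(c4[keep] > c0[keep], "M4", "M0"),
             stringsAsFactors = FALSE)
}
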