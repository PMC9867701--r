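#' Construct a genome-scale metabolic model (GEM)
#'
#' A GEM is the species-level stoichiometric reconstruction used throughout
#' the pipeline: metabolites with compartments, reactions with bounds and
#' optional KO/EC annotations, and a designated biomass reaction whose flux
#' is read as the growth rate. Serialized metabolite ids carry the
#' compartment as a suffix, `met[comp]` (e.g. `glc[e]`), which keeps ids
#' unambiguous when models are later merged into communities.
#'
#' Sign convention for exchange reactions (single metabolite in an
#' extracellular-class compartment, written `1 M[e] <-> 0`): negative flux
#' is uptake, positive flux is secretion.
#'
#' @param species_id model identifier.
#' @param compartments character vector of compartment ids; the first
#'   element of `extracellular` is where diet uptake applies.
#' @param metabolites data.frame with columns `id` (full `met[comp]` id),
#'   `name`, `compartment`.
#' @param reactions named list; each element a list with `id`,
#'   `stoichiometry` (named numeric, metabolite full ids), `lower_bound`,
#'   `upper_bound`, `kos` (character, possibly empty), `subsystem`.
#' @param biomass_reaction_id id of the biomass (objective) reaction.
#' @param extracellular compartments treated as boundary-facing.
#' @return object of class `gem`.
#' @export
gem <- function(species_id, compartments, metabolites, reactions,
                biomass_reaction_id, extracellular = "e") {
  g <- structure(
    list(species_id = species_id,
         compartments = as.character(compartments),
         metabolites = metabolites,
         reactions = reactions,
         biomass_reaction_id = biomass_reaction_id,
         extracellular = extracellular),
    class = "gem")
  errs <- validate_gem(g)
  if (length(errs)) stop("invalid GEM '", species_id, "':\n  ",
                         paste(errs, collapse = "\n  "))
  g
}

#' Validate a GEM, collecting all problems
#'
#' Validation is total: every structural defect found is reported together
#' (missing biomass reaction, dangling metabolite references, inverted
#' bounds, duplicate ids, undeclared compartments), never a partial model.
#'
#' @param g a `gem` (or gem-shaped list).
#' @return character vector of problems; `character(0)` if valid.
#' @export
validate_gem <- function(g) {
  errs <- character(0)
  mets <- g$metabolites
  if (anyDuplicated(mets$id))
    errs <- c(errs, paste0("duplicate metabolite id: ",
                           paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")))
  bad_comp <- setdiff(unique(mets$compartment), g$compartments)
  if (length(bad_comp))
    errs <- c(errs, paste0("undeclared compartment: ", paste(bad_comp, collapse = ", ")))
  rids <- vapply(g$reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    errs <- c(errs, paste0("duplicate reaction id: ",
                           paste(unique(rids[duplicated(rids)]), collapse = ", ")))
  for (r in g$reactions) {
    if (length(r$stoichiometry) == 0)
      errs <- c(errs, paste0("reaction ", r$id, ": empty stoichiometry"))
    if (r$lower_bound > r$upper_bound)
      errs <- c(errs, paste0("reaction ", r$id, ": lower_bound > upper_bound"))
    dangling <- setdiff(names(r$stoichiometry), mets$id)
    if (length(dangling))
      errs <- c(errs, paste0("reaction ", r$id, ": dangling metabolite ",
                             paste(dangling, collapse = ", ")))
  }
  if (!g$biomass_reaction_id %in% rids)
    errs <- c(errs, paste0("biomass_reaction_id '", g$biomass_reaction_id,
                           "' not among reactions"))
  errs
}

#' @export
print.gem <- function(x, ...) {
  cat("<gem>", x$species_id, "-", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions, biomass:", x$biomass_reaction_id, "\n")
  invisible(x)
}

met_compartment <- function(met_id) sub("^.*\\[(.*)\\]$", "\\1", met_id)
met_base_id <- function(met_id) sub("\\[.*\\]$", "", met_id)

#' Is a reaction an exchange reaction?
#'
#' An exchange reaction has exactly one metabolite, located in an
#' extracellular-class compartment of the model.
#'
#' @param g a `gem`.
#' @param r a reaction (list element of `g$reactions`).
#' @return logical.
#' @export
is_exchange <- function(g, r) {
  length(r$stoichiometry) == 1L &&
    met_compartment(names(r$stoichiometry)) %in% g$extracellular
}

#' Ids of all exchange reactions in a model
#' @param g a `gem`.
#' @param compartment optionally restrict to one extracellular compartment.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(g, compartment = NULL) {
  keep <- vapply(g$reactions, function(r) {
    if (!is_exchange(g, r)) return(FALSE)
    if (is.null(compartment)) return(TRUE)
    met_compartment(names(r$stoichiometry)) %in% compartment
  }, logical(1))
  vapply(g$reactions[keep], `[[`, "", "id")
}

#' Stoichiometric matrix of a GEM
#'
#' Builds the dense S matrix (metabolites x reactions): `S[i, j]` is the
#' signed coefficient of metabolite i in reaction j, 0 where absent.
#' Row/column names carry metabolite and reaction ids.
#'
#' @param g a valid `gem`.
#' @return numeric matrix with dimnames.
#' @export
stoichiometric_matrix <- function(g) {
  mids <- g$metabolites$id
  rids <- unname(vapply(g$reactions, `[[`, "", "id"))
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (j in seq_along(g$reactions)) {
    st <- g$reactions[[j]]$stoichiometry
    S[names(st), j] <- as.numeric(st)
  }
  S
}

gem_bounds <- function(g) {
  list(lb = vapply(g$reactions, `[[`, 0, "lower_bound"),
       ub = vapply(g$reactions, `[[`, 0, "upper_bound"))
}

canonicalize_gem <- function(g) {
  mo <- order(g$metabolites$id)
  g$metabolites <- g$metabolites[mo, c("id", "name", "compartment"),
                                 drop = FALSE]
  rownames(g$metabolites) <- NULL
  rids <- vapply(g$reactions, `[[`, "", "id")
  g$reactions <- g$reactions[order(rids)]
  names(g$reactions) <- sort(rids)
  g$compartments <- sort(unique(g$compartments))
  g
}

#' Load a GEM from JSON (or an SBML subset)
#'
#' The native format is a JSON document with top-level keys `species_id`,
#' `compartments`, `extracellular`, `metabolites`, `reactions`,
#' `biomass_reaction_id`. Reaction bounds default to (-1000, 1000) when a
#' reaction is flagged `reversible`, (0, 1000) otherwise, if bounds are
#' omitted. Files ending in `.xml` or `.sbml` are routed to the SBML
#' subset reader ([read_sbml_gem()]).
#'
#' Validation failures are collected and reported together.
#'
#' @param path_or_text path to a file, or a JSON string.
#' @return a validated `gem`.
#' @export
load_gem <- function(path_or_text) {
  is_file <- length(path_or_text) == 1L && !grepl("[{\n]", path_or_text) &&
    file.exists(path_or_text)
  if (is_file && grepl("\\.(xml|sbml)$", path_or_text, ignore.case = TRUE))
    return(read_sbml_gem(path_or_text))
  j <- jsonlite::fromJSON(path_or_text, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(j$metabolites, function(m)
    data.frame(id = m$id, name = if (is.null(m$name)) m$id else m$name,
               compartment = m$compartment, stringsAsFactors = FALSE)))
  rxns <- lapply(j$reactions, function(r) {
    rev <- isTRUE(r$reversible)
    list(id = r$id,
         stoichiometry = unlist(r$stoichiometry),
         lower_bound = if (is.null(r$lower_bound)) if (rev) -1000 else 0
                       else as.numeric(r$lower_bound),
         upper_bound = if (is.null(r$upper_bound)) 1000
                       else as.numeric(r$upper_bound),
         kos = as.character(unlist(r$kos)),
         subsystem = if (is.null(r$subsystem)) "" else r$subsystem)
  })
  names(rxns) <- vapply(rxns, `[[`, "", "id")
  gem(species_id = j$species_id,
      compartments = unlist(j$compartments),
      metabolites = mets,
      reactions = rxns,
      biomass_reaction_id = j$biomass_reaction_id,
      extracellular = if (is.null(j$extracellular)) "e"
                      else unlist(j$extracellular))
}

#' Serialize a GEM to canonical JSON
#'
#' Canonical form: metabolites and reactions sorted by id, fixed key
#' order, full numeric precision. `load_gem(save_gem(g))` is the identity
#' on canonical form, and re-saving a canonically saved model is
#' byte-identical.
#'
#' @param g a valid `gem`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
save_gem <- function(g, path = NULL) {
  errs <- validate_gem(g)
  if (length(errs)) stop("refusing to serialize invalid GEM:\n  ",
                         paste(errs, collapse = "\n  "))
  bounds <- unlist(lapply(g$reactions, function(r)
    c(r$lower_bound, r$upper_bound)))
  if (any(!is.finite(bounds)))
    stop("non-finite reaction bound; cannot serialize")
  g <- canonicalize_gem(g)
  obj <- list(
    species_id = g$species_id,
    compartments = as.list(g$compartments),
    extracellular = as.list(g$extracellular),
    biomass_reaction_id = g$biomass_reaction_id,
    metabolites = lapply(seq_len(nrow(g$metabolites)), function(i)
      list(id = g$metabolites$id[i], name = g$metabolites$name[i],
           compartment = g$metabolites$compartment[i])),
    reactions = lapply(g$reactions, function(r) {
      st <- r$stoichiometry[order(names(r$stoichiometry))]
      list(id = r$id,
           stoichiometry = as.list(st),
           lower_bound = r$lower_bound,
           upper_bound = r$upper_bound,
           kos = as.list(sort(as.character(r$kos))),
           subsystem = r$subsystem)
    }))
  names(obj$reactions) <- NULL
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = 2)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' Read a GEM from an SBML Level-3 subset
#'
#' Supports the subset needed to import simple constraint-based models:
#' compartments, species, reactions with `speciesReference` stoichiometry,
#' fbc-style bounds given as `fbc:lowerFluxBound`/`fbc:upperFluxBound`
#' parameter references (or numeric attributes), and the first fbc
#' objective as the biomass reaction. Anything beyond that subset is
#' ignored.
#'
#' @param path SBML file path.
#' @param extracellular compartment ids treated as extracellular.
#' @return a validated `gem`.
#' @export
read_sbml_gem <- function(path, extracellular = "e") {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  comps <- xml2::xml_attr(xml2::xml_find_all(model, ".//listOfCompartments/compartment"), "id")
  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  sbml_ids <- xml2::xml_attr(sp_nodes, "id")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  # strip the SBML "M_" prefix and build met[comp] ids
  base <- sub("^M_", "", sbml_ids)
  base <- unname(mapply(function(b, comp) sub(paste0("_", comp, "$"), "", b),
                        base, sp_comp))
  full <- paste0(base, "[", sp_comp, "]")
  names(full) <- sbml_ids
  mets <- data.frame(id = full,
                     name = ifelse(is.na(sp_name), base, sp_name),
                     compartment = sp_comp, stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(model, ".//listOfParameters/parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  rxns <- lapply(rx_nodes, function(nd) {
    rid <- sub("^R_", "", xml2::xml_attr(nd, "id"))
    get_side <- function(xp, sgn) {
      refs <- xml2::xml_find_all(nd, xp)
      if (length(refs) == 0) return(numeric(0))
      stats::setNames(
        sgn * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
        full[xml2::xml_attr(refs, "species")])
    }
    st <- c(get_side(".//listOfReactants/speciesReference", -1),
            get_side(".//listOfProducts/speciesReference", +1))
    lbr <- xml2::xml_attr(nd, "lowerFluxBound")
    ubr <- xml2::xml_attr(nd, "upperFluxBound")
    rev <- identical(xml2::xml_attr(nd, "reversible"), "true")
    lb <- if (!is.na(lbr)) unname(parval[lbr]) else if (rev) -1000 else 0
    ub <- if (!is.na(ubr)) unname(parval[ubr]) else 1000
    list(id = rid, stoichiometry = st, lower_bound = lb, upper_bound = ub,
         kos = character(0), subsystem = "")
  })
  names(rxns) <- vapply(rxns, `[[`, "", "id")
  obj_ref <- xml2::xml_find_first(model, ".//listOfObjectives//fluxObjective")
  biomass <- if (inherits(obj_ref, "xml_missing")) {
    bm <- grep("biomass", names(rxns), ignore.case = TRUE, value = TRUE)
    if (length(bm) == 0) stop("SBML model has no objective and no reaction named like 'biomass'")
    bm[1]
  } else sub("^R_", "", xml2::xml_attr(obj_ref, "reaction"))
  gem(species_id = xml2::xml_attr(model, "id"),
      compartments = comps, metabolites = mets, reactions = rxns,
      biomass_reaction_id = biomass,
      extracellular = intersect(extracellular, comps))
}
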