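# Synthetic study generator.
#
# Emulates the study conditions end-to-end with known ground truth: a
# paired cohort (M0 baseline, M4 after treatment) of ~22 subjects, a
# panel of species models with distinct uptake/secretion traits (butyrate
# producer, mucin degrader analogue, ...) and planted abundance effects,
# genus counts from a 3-component Dirichlet-multinomial mixture, six
# named anaerobic diets, and a KO pathway database with one
# enriched-by-construction pathway.

#' Shared extracellular metabolite namespace
#'
#' Base ids used by generated models and diets: carbon substrates (`glc`
#' glucose, `fib` fiber polysaccharide analogue, `pep` peptide/amino-acid
#' analogue, `mucin` host mucin analogue), short-chain fatty acids and
#' other secretions (`but` butyrate, `ppa` propionate, `ac` acetate,
#' `lac` lactate, `succ` succinate, `nh3`, `h2s`), plus `o2` and `h2o`.
#'
#' @return character vector of metabolite base ids.
#' @export
ex_namespace <- function() {
  c("glc", "fib", "pep", "mucin",
    "but", "ppa", "ac", "lac", "succ", "nh3", "h2s",
    "o2", "h2o")
}

#' Declare a species trait
#'
#' Ground truth attached to a generated species: the planted M0 -> M4
#' abundance effect and the metabolites its model can secrete / take up.
#'
#' @param species_id identifier.
#' @param direction "increased", "decreased" or "null".
#' @param log2_effect planted paired log2 fold change (must be 0 for
#'   direction "null").
#' @param secretors metabolite base ids the species secretes.
#' @param consumers metabolite base ids the species takes up (the four
#'   carbon substrates are always included so every species can grow,
#'   unless `exclusive_consumers` is set).
#' @param exclusive_consumers when TRUE the species can use *only* the
#'   metabolites in `consumers` (a specialist, e.g. a strict
#'   butyrate consumer for cross-feeding scenarios).
#' @return object of class `species_trait`.
#' @export
species_trait <- function(species_id, direction = "null", log2_effect = 0,
                          secretors = character(0),
                          consumers = character(0),
                          exclusive_consumers = FALSE) {
  direction <- match.arg(direction, c("null", "increased", "decreased"))
  if (direction == "null" && log2_effect != 0)
    stop("direction 'null' requires log2_effect = 0")
  if (exclusive_consumers && length(consumers) == 0)
    stop("exclusive_consumers requires a nonempty consumers set")
  structure(list(species_id = species_id, direction = direction,
                 log2_effect = log2_effect,
                 secretors = unique(secretors),
                 consumers = unique(consumers),
                 exclusive_consumers = exclusive_consumers),
            class = "species_trait")
}

default_trait_plan <- function(n_species) {
  stopifnot(n_species >= 2)
  dirs <- rep(c("increased", "decreased", "null"), length.out = n_species)
  secs <- rep(list("but", "ppa", c("ac", "h2s"), "lac", c("succ", "nh3")),
              length.out = n_species)
  cons <- rep(list(character(0), "mucin", "but", character(0)),
              length.out = n_species)
  lapply(seq_len(n_species), function(i)
    species_trait(sprintf("msp%02d", i),
                  direction = dirs[i],
                  log2_effect = switch(dirs[i], increased = 2.5,
                                       decreased = -2.5, 0),
                  secretors = secs[[i]],
                  consumers = cons[[i]]))
}

#' Generate a panel of species models with planted traits
#'
#' Each species gets a small but complete anaerobe model: exchange and
#' reversible transport reactions for every metabolite it touches,
#' shared-id catabolic reactions funnelling each consumed substrate into
#' a biomass precursor, and a biomass reaction consuming `1/yield`
#' precursor per unit growth while stoichiometrically co-producing the
#' species' secreted metabolites (so secretion is forced whenever the
#' species grows). All four carbon substrates are consumable by every
#' species, which makes growth on a diet `yield x total uptake`:
#' "increased" species receive systematically higher biomass yields than
#' "decreased" ones, planting the growth-rate contrast between the two
#' guilds. Every model is checked feasible (positive biomass) on at
#' least one built-in diet. Generation is deterministic for a fixed
#' seed.
#'
#' @param n_species number of species (>= 2); ignored when `trait_plan`
#'   is given.
#' @param trait_plan list of [species_trait()]; default plan cycles
#'   directions and secretion traits.
#' @param seed RNG seed.
#' @return list with `gems` (named list of `gem`) and `traits` (named
#'   list of `species_trait`).
#' @export
make_species_panel <- function(n_species = 8L, trait_plan = NULL, seed = 1L) {
  if (is.null(trait_plan)) trait_plan <- default_trait_plan(n_species)
  if (length(trait_plan) < 2) stop("need at least 2 species")
  ns <- ex_namespace()
  local_seed(seed)
  substrates <- c("glc", "fib", "pep", "mucin")
  gems <- list(); traits <- list()
  for (tr in trait_plan) {
    bad <- setdiff(c(tr$secretors, tr$consumers), ns)
    if (length(bad))
      stop("species '", tr$species_id, "': trait metabolite(s) outside the ",
           "extracellular namespace: ", paste(bad, collapse = ", "))
    consumed <- if (isTRUE(tr$exclusive_consumers)) tr$consumers
                else union(substrates, tr$consumers)
    yield <- switch(tr$direction,
                    increased = stats::runif(1, 0.80, 0.95),
                    decreased = stats::runif(1, 0.35, 0.50),
                    stats::runif(1, 0.55, 0.70))
    touched <- union(consumed, tr$secretors)
    mets <- rbind(
      data.frame(id = paste0(touched, "[e]"), name = touched,
                 compartment = "e", stringsAsFactors = FALSE),
      data.frame(id = paste0(touched, "[c]"), name = touched,
                 compartment = "c", stringsAsFactors = FALSE),
      data.frame(id = "prec[c]", name = "biomass precursor",
                 compartment = "c", stringsAsFactors = FALSE),
      data.frame(id = c("o2[e]", "h2o[e]"), name = c("oxygen", "water"),
                 compartment = "e", stringsAsFactors = FALSE))
    mets <- mets[!duplicated(mets$id), ]
    rxns <- list()
    for (m in touched) {
      rxns[[paste0("EX_", m, "[e]")]] <- list(
        id = paste0("EX_", m, "[e]"),
        stoichiometry = stats::setNames(-1, paste0(m, "[e]")),
        lower_bound = 0, upper_bound = 1000, kos = character(0),
        subsystem = "exchange")
      rxns[[paste0("T_", m)]] <- list(
        id = paste0("T_", m),
        stoichiometry = stats::setNames(c(-1, 1),
                                        paste0(m, c("[e]", "[c]"))),
        lower_bound = -1000, upper_bound = 1000,
        kos = paste0("K1", sprintf("%03d", match(m, ns))),
        subsystem = "transport")
    }
    for (m in c("o2", "h2o")) {
      rxns[[paste0("EX_", m, "[e]")]] <- list(
        id = paste0("EX_", m, "[e]"),
        stoichiometry = stats::setNames(-1, paste0(m, "[e]")),
        lower_bound = 0, upper_bound = 1000, kos = character(0),
        subsystem = "exchange")
    }
    for (s in consumed) {
      # mucin catabolism carries only an EC (tests the KO-absent path)
      kos <- if (s == "mucin") "3.2.1.18"
             else paste0("K2", sprintf("%03d", match(s, ns)))
      rxns[[paste0("CAT_", s)]] <- list(
        id = paste0("CAT_", s),
        stoichiometry = stats::setNames(c(-1, 1),
                                        c(paste0(s, "[c]"), "prec[c]")),
        lower_bound = 0, upper_bound = 1000, kos = kos,
        subsystem = paste0(s, " catabolism"))
    }
    bm_st <- stats::setNames(-1 / yield, "prec[c]")
    if (length(tr$secretors))
      bm_st <- c(bm_st, stats::setNames(rep(0.3, length(tr$secretors)),
                                        paste0(tr$secretors, "[c]")))
    rxns[["biomass"]] <- list(id = "biomass", stoichiometry = bm_st,
                              lower_bound = 0, upper_bound = 1000,
                              kos = character(0), subsystem = "biomass")
    g <- gem(species_id = tr$species_id,
             compartments = c("e", "c"), metabolites = mets,
             reactions = rxns, biomass_reaction_id = "biomass")
    gems[[tr$species_id]] <- g
    tr$yield <- yield
    traits[[tr$species_id]] <- tr
  }
  diets <- make_diets()
  for (sid in names(gems)) {
    # a specialist may live off cross-feeding only; check it grows when
    # its own substrates are supplied
    own <- diet("feasibility-check",
                stats::setNames(rep(10, length(traits[[sid]]$consumers) + 1),
                                c(traits[[sid]]$consumers, "h2o")))
    ok <- any(vapply(c(diets, list(own)), function(d)
      suppressWarnings(solve_fba(apply_diet(gems[[sid]], d)))$objective_value > 1e-6,
      logical(1)))
    if (!ok) stop("generated model for species '", sid,
                  "' cannot grow on any built-in diet")
  }
  list(gems = gems, traits = traits)
}

#' The six study diets
#'
#' Named anaerobic diets over the shared namespace: high protein
#' omnivorous (HPO), high protein plant based (HPP), high fiber plant
#' based (HFP), high fiber omnivorous (HFO), western (WESTERN) and
#' ketogenic (KETO). Uptake fluxes are on a fixed arbitrary scale
#' (maximal bound 10): fiber-rich diets give the largest bounds to the
#' polysaccharide analogue `fib`, protein-rich diets to the
#' peptide/amino-acid analogue `pep`; all include a small host-derived
#' mucin supply; oxygen uptake is 0 everywhere.
#'
#' @return named list of six [diet()] objects.
#' @export
make_diets <- function() {
  tab <- list(
    HPO     = c(glc = 3,   fib = 2,   pep = 10,  mucin = 1),
    HPP     = c(glc = 2.5, fib = 3,   pep = 9,   mucin = 1),
    HFP     = c(glc = 2,   fib = 10,  pep = 3,   mucin = 1),
    HFO     = c(glc = 3,   fib = 9,   pep = 4,   mucin = 1),
    WESTERN = c(glc = 10,  fib = 1,   pep = 5.5, mucin = 1),
    KETO    = c(glc = 0.5, fib = 0.5, pep = 8,   mucin = 1))
  lapply(names(tab), function(nm)
    diet(nm, c(tab[[nm]], h2o = 10), anaerobic = TRUE)) |>
    stats::setNames(names(tab))
}

#' Cohort generation parameters
#'
#' @param n_subjects paired subjects (default 22, the cohort size
#'   emulated).
#' @param depth reads per sample; default 100000, a desk-scale stand-in
#'   for the 4-million-read depth the full-size analysis rarefies to
#'   (the downsizing mechanics are depth-agnostic).
#' @param n_genes_per_msp genes per species pangenome.
#' @param n_marker_genes marker genes among them (must not exceed
#'   `n_genes_per_msp`).
#' @param dmm_components Dirichlet-multinomial mixture components for the
#'   genus table (default 3).
#' @param effect_sd per-subject log2 noise around the planted effect.
#' @param seed RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 22L, depth = 100000L,
                        n_genes_per_msp = 40L, n_marker_genes = 10L,
                        dmm_components = 3L, effect_sd = 0.25, seed = 1L) {
  if (n_marker_genes > n_genes_per_msp)
    stop("n_marker_genes must not exceed n_genes_per_msp")
  if (depth <= 0) stop("depth must be positive")
  structure(list(n_subjects = n_subjects, depth = depth,
                 n_genes_per_msp = n_genes_per_msp,
                 n_marker_genes = n_marker_genes,
                 dmm_components = dmm_components,
                 effect_sd = effect_sd, seed = seed),
            class = "cohort_spec")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Genus counts from a Dirichlet-multinomial mixture
#'
#' Draws samples from a k-component DM mixture over a fixed genus panel
#' (Bacteroides-, Prevotella- and Firmicutes-dominated components for
#' k = 3), with known component assignments returned as ground truth.
#'
#' @param n_samples samples to draw.
#' @param k mixture components.
#' @param seed RNG seed.
#' @param depth reads per sample.
#' @param separation Dirichlet mass placed on each component's dominant
#'   genera (larger = better separated components).
#' @param sample_names optional sample names.
#' @return list with `counts` (genera x samples), `components` (true
#'   assignment per sample) and `alpha` (k x genera matrix).
#' @export
make_genus_mixture <- function(n_samples, k = 3L, seed = 1L, depth = 5000L,
                               separation = 30, sample_names = NULL) {
  genera <- c("Bacteroides", "Prevotella", "Faecalibacterium", "Roseburia",
              "Blautia", "Ruminococcus", "Akkermansia", "Alistipes",
              "Escherichia", "Bifidobacterium", "Intestinibacter",
              "Subdoligranulum")
  dominant <- list(c("Bacteroides", "Alistipes"),
                   c("Prevotella"),
                   c("Faecalibacterium", "Roseburia", "Blautia",
                     "Ruminococcus"))
  local_seed(seed)
  alpha <- matrix(0.4, k, length(genera),
                  dimnames = list(NULL, genera))
  for (j in seq_len(k)) {
    dom <- dominant[[((j - 1) %% 3) + 1]]
    alpha[j, dom] <- alpha[j, dom] + separation / length(dom)
  }
  z <- sample.int(k, n_samples, replace = TRUE)
  counts <- vapply(seq_len(n_samples), function(i)
    as.integer(stats::rmultinom(1, depth, rdirichlet1(alpha[z[i], ]))),
    integer(length(genera)))
  rownames(counts) <- genera
  colnames(counts) <- if (is.null(sample_names))
    sprintf("sample%03d", seq_len(n_samples)) else sample_names
  list(counts = counts, components = stats::setNames(z, colnames(counts)),
       alpha = alpha)
}

#' Generate a paired two-timepoint cohort with planted effects
#'
#' Per subject, baseline species relative abundances are log-normal
#' around panel-level weights; at the second timepoint each species'
#' abundance is multiplied by `2^(log2_effect + noise)` and the
#' composition renormalized, so the planted `log2_effect` is the expected
#' paired log2 change of its (relative) abundance up to the mild
#' compositional distortion of renormalization. Gene counts are
#' multinomial draws at fixed depth from per-sample gene relative
#' abundance vectors (species weight x within-pangenome gene weight);
#' marker genes are the first `n_marker_genes` genes of each pangenome.
#' Genus counts come from [make_genus_mixture()] with
#' `dmm_components` components.
#'
#' @param spec a [cohort_spec()].
#' @param panel_traits named list of [species_trait()] (e.g. from
#'   [make_species_panel()]).
#' @return list with `counts_m0`, `counts_m4` (genes x samples integer
#'   matrices, sample names `<subject>_<M0|M4>`), `defs` (MSP definition
#'   data.frame), `genus_counts`, and `truth` (traits, true genus
#'   components, true abundance matrices).
#' @export
make_paired_cohort <- function(spec, panel_traits) {
  stopifnot(inherits(spec, "cohort_spec"), length(panel_traits) > 0)
  local_seed(spec$seed)
  sp <- vapply(panel_traits, `[[`, "", "species_id")
  eff <- vapply(panel_traits, `[[`, 0, "log2_effect")
  nsp <- length(sp)
  subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
  base_w <- exp(stats::rnorm(nsp, 0, 0.5))
  gene_ids <- unlist(lapply(unname(sp), function(s)
    paste0(s, "_g", sprintf("%03d", seq_len(spec$n_genes_per_msp)))),
    use.names = FALSE)
  defs <- data.frame(
    msp_id = rep(unname(sp), each = spec$n_genes_per_msp),
    gene_id = gene_ids,
    is_marker = rep(rep(c(1L, 0L),
                        c(spec$n_marker_genes,
                          spec$n_genes_per_msp - spec$n_marker_genes)),
                    nsp),
    stringsAsFactors = FALSE)
  gene_w <- lapply(sp, function(s) {
    w <- stats::runif(spec$n_genes_per_msp, 0.5, 1.5)
    w / sum(w)
  })
  draw_sample <- function(w_species) {
    p <- unlist(lapply(seq_len(nsp), function(i) w_species[i] * gene_w[[i]]))
    p <- p / sum(p)
    as.integer(stats::rmultinom(1, spec$depth, p))
  }
  counts_m0 <- matrix(0L, length(gene_ids), spec$n_subjects,
                      dimnames = list(gene_ids, paste0(subjects, "_M0")))
  counts_m4 <- matrix(0L, length(gene_ids), spec$n_subjects,
                      dimnames = list(gene_ids, paste0(subjects, "_M4")))
  ab0 <- matrix(0, spec$n_subjects, nsp,
                dimnames = list(paste0(subjects, "_M0"), sp))
  ab4 <- matrix(0, spec$n_subjects, nsp,
                dimnames = list(paste0(subjects, "_M4"), sp))
  for (i in seq_len(spec$n_subjects)) {
    w0 <- base_w * exp(stats::rnorm(nsp, 0, 0.3))
    w0 <- w0 / sum(w0)
    fac <- 2^(eff + stats::rnorm(nsp, 0, spec$effect_sd))
    w4 <- w0 * fac
    w4 <- w4 / sum(w4)
    ab0[i, ] <- w0; ab4[i, ] <- w4
    counts_m0[, i] <- draw_sample(w0)
    counts_m4[, i] <- draw_sample(w4)
  }
  planted <- eff != 0
  if (any(planted)) {
    smallest <- min(pmin(ab0[, planted, drop = FALSE],
                         ab4[, planted, drop = FALSE]))
    if (spec$depth * smallest < 5)
      warning("depth ", spec$depth, " is small for the least abundant ",
              "planted species (expected count < 5); effects may be lost")
  }
  gm <- make_genus_mixture(2L * spec$n_subjects, k = spec$dmm_components,
                           seed = spec$seed + 1L,
                           sample_names = c(colnames(counts_m0),
                                            colnames(counts_m4)))
  list(counts_m0 = counts_m0, counts_m4 = counts_m4, defs = defs,
       genus_counts = gm$counts,
       truth = list(traits = panel_traits,
                    genus_components = gm$components,
                    abundance_m0 = ab0, abundance_m4 = ab4))
}

#' Generate a KO pathway database with one planted enriched pathway
#'
#' Pathways are random KO subsets of the universe; when `planted_kos` is
#' given, the first pathway is built to cover them (plus a few random
#' fillers), making it enriched by construction for any selected set
#' that maps to those KOs. The planted pathway id and KO set are stored
#' as attributes `planted` and `planted_kos`.
#'
#' @param n_pathways number of pathways (>= 1).
#' @param ko_universe nonempty character vector of KO ids.
#' @param seed RNG seed.
#' @param planted_kos optional KO ids the first pathway must contain.
#' @param size_range pathway sizes drawn uniformly from this range.
#' @return named list pathway id -> KO character vector, with planted
#'   ground-truth attributes.
#' @export
make_pathway_db <- function(n_pathways, ko_universe, seed = 1L,
                            planted_kos = NULL, size_range = c(8L, 15L)) {
  if (n_pathways < 1) stop("n_pathways must be >= 1")
  if (length(ko_universe) == 0) stop("ko_universe must be nonempty")
  local_seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n_pathways,
                  replace = TRUE)
  db <- lapply(sizes, function(s)
    sample(ko_universe, min(s, length(ko_universe))))
  names(db) <- sprintf("PW%02d", seq_len(n_pathways))
  planted <- NULL
  if (!is.null(planted_kos)) {
    filler <- sample(setdiff(ko_universe, planted_kos),
                     min(3, length(setdiff(ko_universe, planted_kos))))
    db[[1]] <- unique(c(planted_kos, filler))
    planted <- names(db)[1]
  }
  attr(db, "planted") <- planted
  attr(db, "planted_kos") <- planted_kos
  db
}

#' Synthetic CAZyme annotation and substrate mapping tables
#'
#' Generates a gene -> CAZy-family annotation over the cohort's gene
#' universe in which "decreased" species are biased toward mucin- and
#' host-glycan-degrading families and "increased" species toward pectin
#' and mannose families, mirroring the kind of substrate contrast the
#' CAZyme summary is meant to surface. The companion family -> substrate
#' mapping is returned alongside.
#'
#' @param defs MSP definitions (`msp_id`, `gene_id`, `is_marker`).
#' @param traits named list of [species_trait()].
#' @param seed RNG seed.
#' @param annotate_fraction fraction of genes receiving an annotation.
#' @return list with `annotations` (`gene_id`, `family`) and
#'   `family_substrates` (`family`, `substrate`).
#' @export
make_cazyme_annotation <- function(defs, traits, seed = 1L,
                                   annotate_fraction = 0.6) {
  fam_map <- data.frame(
    family = c("GH_muc1", "GH_muc2", "GH_hg1", "GH_pec1", "GH_man1",
               "GH_fib1", "GH_fib2"),
    substrate = c("mucin", "mucin", "host glycan", "pectin", "mannose",
                  "fiber", "fiber"),
    stringsAsFactors = FALSE)
  pools <- list(
    decreased = c("GH_muc1", "GH_muc2", "GH_hg1", "GH_fib1"),
    increased = c("GH_pec1", "GH_man1", "GH_fib2"),
    null = c("GH_fib1", "GH_fib2", "GH_pec1", "GT_unk1"))
  local_seed(seed)
  rows <- lapply(names(traits), function(s) {
    genes <- defs$gene_id[defs$msp_id == s]
    genes <- sample(genes, round(annotate_fraction * length(genes)))
    pool <- pools[[traits[[s]]$direction]]
    data.frame(gene_id = genes,
               family = sample(pool, length(genes), replace = TRUE),
               stringsAsFactors = FALSE)
  })
  list(annotations = do.call(rbind, rows), family_substrates = fam_map)
}
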