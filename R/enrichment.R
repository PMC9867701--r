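#' Reaction-abundance matrix from MSP abundances and GEMs
#'
#' The abundance of a reaction in a sample is the summed relative
#' abundance of all MSPs whose model contains that reaction — the
#' "reactobiome" view of a community. The reaction -> KO map is unioned
#' over models; where a reaction carries no KO, its EC numbers are used
#' instead.
#'
#' @param table an `abundance_table` (samples x MSPs).
#' @param gems named list of `gem` objects, names = MSP ids. MSPs in the
#'   table without a model are excluded with a warning.
#' @return list with `abundance` (reactions x samples matrix), `kos`
#'   (named list reaction -> character vector of KO/EC ids) and `meta`
#'   (the table's sample metadata).
#' @export
reaction_abundance <- function(table, gems) {
  msps <- colnames(table$abundance)
  missing <- setdiff(msps, names(gems))
  if (length(missing)) {
    warning("MSP(s) without a GEM, excluded from reaction abundance: ",
            paste(missing, collapse = ", "))
    msps <- setdiff(msps, missing)
  }
  # membership matrix: reactions x MSPs (exchange plumbing excluded:
  # reaction content, not boundary bookkeeping, is what is annotated)
  rsets <- lapply(gems[msps], function(g)
    setdiff(names(g$reactions), exchange_reactions(g)))
  rids <- sort(unique(unlist(rsets)))
  memb <- vapply(rsets, function(rs) rids %in% rs,
                 logical(length(rids)))
  memb <- matrix(as.numeric(memb), nrow = length(rids),
                 dimnames = list(rids, msps))
  ab <- memb %*% t(table$abundance[, msps, drop = FALSE])
  kos <- stats::setNames(vector("list", length(rids)), rids)
  for (m in msps) {
    for (rid in rsets[[m]]) {
      k <- gems[[m]]$reactions[[rid]]$kos
      kos[[rid]] <- union(kos[[rid]], as.character(k))
    }
  }
  kos <- lapply(kos, function(k) {
    ko <- grep("^K\\d+", k, value = TRUE)
    if (length(ko)) ko else k                 # EC fallback when no KO
  })
  list(abundance = ab, kos = kos, meta = table$meta)
}

#' Binary reaction presence per sample
#'
#' A reaction is present in a sample when it is captured in at least one
#' MSP there, i.e. its reaction abundance is > 0.
#'
#' @param ram a [reaction_abundance()] result.
#' @return logical matrix reactions x samples.
#' @export
presence_vector <- function(ram) {
  ram$abundance > 0
}

#' Hypergeometric pathway enrichment
#'
#' Pathways are KO sets; each is mapped to the reaction universe through
#' the reaction -> KO/EC map (a reaction with several KOs belongs to
#' every pathway any of them belongs to). For a selected reaction set of
#' size n out of a universe of size N, a pathway covering K universe
#' reactions with overlap k gets the one-sided upper-tail p-value
#' \deqn{p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' Correction across pathways is Bonferroni by default (BH available).
#' Pathways mapping to zero universe reactions are skipped with a note.
#'
#' @param selected character vector of selected reaction ids (must be a
#'   subset of `universe`).
#' @param universe character vector of all candidate reaction ids.
#' @param pathways named list pathway -> character vector of KO/EC ids.
#' @param reaction_kos named list reaction -> KO/EC ids (e.g. `$kos` from
#'   [reaction_abundance()]).
#' @param correction "bonferroni" (default) or "bh".
#' @param alpha significance threshold on the adjusted p.
#' @return data.frame `pathway`, `k`, `K`, `n`, `N`, `p`, `p_adj`,
#'   `enriched`.
#' @export
pathway_enrichment <- function(selected, universe, pathways, reaction_kos,
                               correction = c("bonferroni", "bh"),
                               alpha = 0.05) {
  correction <- match.arg(correction)
  if (length(universe) == 0) stop("empty reaction universe")
  if (!all(selected %in% universe))
    stop("selected reactions must be a subset of the universe")
  N <- length(universe); n <- length(selected)
  rows <- lapply(names(pathways), function(pw) {
    pw_kos <- pathways[[pw]]
    pr <- universe[vapply(universe, function(r)
      any(reaction_kos[[r]] %in% pw_kos), logical(1))]
    if (length(pr) == 0) {
      message("pathway '", pw, "' maps to no universe reaction; skipped")
      return(NULL)
    }
    K <- length(pr)
    k <- length(intersect(selected, pr))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0)
    return(data.frame(pathway = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), enriched = logical(0)))
  out$p_adj <- if (correction == "bonferroni")
    pmin(1, out$p * nrow(out)) else bh_fdr(out$p)
  out$enriched <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Paired per-reaction abundance test
#'
#' Exact Wilcoxon signed-rank test of each reaction's paired M4 - M0
#' abundance across subjects, with Bonferroni correction (the convention
#' for reaction-level dysbiosis calls; BH available).
#'
#' @param ram_m0,ram_m4 [reaction_abundance()] results for the two
#'   timepoints over the same reaction universe, with paired samples
#'   named `<subject>_<M0|M4>`.
#' @param alpha significance threshold on the adjusted p.
#' @param correction "bonferroni" (default) or "bh".
#' @return data.frame `reaction`, `statistic`, `p`, `p_adj`, `direction`,
#'   `significant`.
#' @export
paired_reaction_test <- function(ram_m0, ram_m4, alpha = 0.05,
                                 correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  rx <- rownames(ram_m0$abundance)
  if (!identical(sort(rx), sort(rownames(ram_m4$abundance))))
    stop("reaction universes differ between timepoints")
  subj0 <- sub("_M0$", "", colnames(ram_m0$abundance))
  subj4 <- sub("_M4$", "", colnames(ram_m4$abundance))
  common <- intersect(subj0, subj4)
  if (length(common) == 0) stop("no paired subjects between the matrices")
  if (length(common) < length(union(subj0, subj4)))
    stop("mismatched pairing: unpaired subjects present")
  a0 <- ram_m0$abundance[rx, match(common, subj0), drop = FALSE]
  a4 <- ram_m4$abundance[rx, match(common, subj4), drop = FALSE]
  res <- lapply(rx, function(r) {
    wt <- wilcoxon_signed_rank(a4[r, ], a0[r, ])
    data.frame(reaction = r, statistic = wt$statistic, p = wt$p,
               direction = {
                 md <- stats::median(a4[r, ] - a0[r, ])
                 if (md > 0) "increased" else if (md < 0) "decreased" else "ns"
               }, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- if (correction == "bonferroni")
    pmin(1, out$p * nrow(out)) else bh_fdr(out$p)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' CAZyme substrate-class summary per species and direction group
#'
#' Counts annotated carbohydrate-active-enzyme genes per species and
#' substrate class (mucin, host glycan, pectin, ...): gene -> CAZy family
#' from the annotation table, family -> substrate class from the mapping
#' table (unmapped families fall into "other"), genes -> species through
#' the MSP definitions. Group-level sums aggregate species by direction
#' label.
#'
#' @param annotations data.frame `gene_id`, `family`.
#' @param family_substrates data.frame `family`, `substrate`.
#' @param defs MSP definitions (`msp_id`, `gene_id`, `is_marker`).
#' @param directions named character vector msp_id -> group label
#'   (species without a label are kept under their own species row but
#'   excluded from group sums).
#' @return list with `species` (data.frame msp_id x substrate counts,
#'   long form) and `groups` (direction x substrate sums).
#' @export
cazyme_summary <- function(annotations, family_substrates, defs,
                           directions = NULL) {
  if (nrow(annotations) == 0) {
    empty <- data.frame(msp_id = character(0), substrate = character(0),
                        n_genes = integer(0))
    return(list(species = empty,
                groups = data.frame(direction = character(0),
                                    substrate = character(0),
                                    n_genes = integer(0))))
  }
  subs <- family_substrates$substrate[match(annotations$family,
                                            family_substrates$family)]
  subs[is.na(subs)] <- "other"
  msp <- defs$msp_id[match(annotations$gene_id, defs$gene_id)]
  keep <- !is.na(msp)
  species <- as.data.frame(table(msp_id = msp[keep], substrate = subs[keep]),
                           responseName = "n_genes", stringsAsFactors = FALSE)
  species <- species[species$n_genes > 0, ]
  rownames(species) <- NULL
  groups <- NULL
  if (!is.null(directions)) {
    species$direction <- unname(directions[species$msp_id])
    gs <- species[!is.na(species$direction), ]
    groups <- stats::aggregate(n_genes ~ direction + substrate, gs, sum)
    species$direction <- NULL
  }
  list(species = species, groups = groups)
}
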