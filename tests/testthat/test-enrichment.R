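make_toy_ram_inputs <- function() {
  ab <- matrix(c(0.3, 0.7,
                 0.5, 0.5,
                 0.0, 1.0), 3, 2, byrow = TRUE,
               dimnames = list(c("S01_M0", "S02_M0", "S03_M0"),
                               c("mspA", "mspB")))
  mk_gem <- function(id, rxn_ids, kos) {
    mets <- data.frame(id = c("x[e]", "x[c]"), name = "x",
                       compartment = c("e", "c"), stringsAsFactors = FALSE)
    rx <- list("EX_x[e]" = list(id = "EX_x[e]", stoichiometry = c("x[e]" = -1),
                                lower_bound = -10, upper_bound = 1000,
                                kos = character(0), subsystem = ""))
    for (i in seq_along(rxn_ids))
      rx[[rxn_ids[i]]] <- list(id = rxn_ids[i],
                               stoichiometry = c("x[e]" = -1, "x[c]" = 1),
                               lower_bound = 0, upper_bound = 1000,
                               kos = kos[[i]], subsystem = "")
    rx[["biomass"]] <- list(id = "biomass", stoichiometry = c("x[c]" = -1),
                            lower_bound = 0, upper_bound = 1000,
                            kos = character(0), subsystem = "")
    gem(id, c("e", "c"), mets, rx, "biomass")
  }
  gems <- list(
    mspA = mk_gem("mspA", c("shared", "onlyA"), list("K00001", "K00002")),
    mspB = mk_gem("mspB", c("shared", "onlyB"), list("K00001", character(0))))
  list(table = abundance_table(ab), gems = gems)
}

test_that("reaction abundance is additive over MSP membership", {
  inp <- make_toy_ram_inputs()
  ram <- reaction_abundance(inp$table, inp$gems)
  expect_equal(unname(ram$abundance["shared", "S01_M0"]), 1.0)
  expect_equal(unname(ram$abundance["onlyA", "S01_M0"]), 0.3)
  expect_equal(unname(ram$abundance["onlyB", "S01_M0"]), 0.7)
  # zero-abundance MSP contributes nothing
  expect_equal(unname(ram$abundance["onlyA", "S03_M0"]), 0)
  # MSP without a model is excluded with a warning
  expect_warning(reaction_abundance(inp$table, inp$gems["mspA"]), "mspB")
})

test_that("presence is a strict positivity threshold", {
  inp <- make_toy_ram_inputs()
  ram <- reaction_abundance(inp$table, inp$gems)
  pv <- presence_vector(ram)
  expect_true(pv["shared", "S01_M0"])
  expect_false(pv["onlyA", "S03_M0"])
  # a tiny abundance still counts as present
  ram$abundance["onlyA", "S03_M0"] <- 1e-4
  expect_true(presence_vector(ram)["onlyA", "S03_M0"])
})

test_that("hypergeometric enrichment matches the closed form and enumeration", {
  kos <- stats::setNames(paste0("K", 1:10), paste0("R", 1:10))
  rk <- as.list(kos)
  pw <- list(P1 = kos[1:5])
  e <- pathway_enrichment(paste0("R", 1:4), paste0("R", 1:10), pw, rk)
  expect_equal(e$p, 5 / 210, tolerance = 1e-12)
  expect_equal(e$k, 4); expect_equal(e$K, 5)
  # exhaustive-enumeration oracle over several configurations
  set.seed(11)
  for (i in 1:8) {
    N <- sample(6:12, 1); K <- sample(2:(N - 1), 1); n <- sample(1:N, 1)
    univ <- paste0("R", seq_len(N))
    rk2 <- stats::setNames(as.list(paste0("K", seq_len(N))), univ)
    pw2 <- list(P = paste0("K", seq_len(K)))
    sel <- sample(univ, n)
    e2 <- pathway_enrichment(sel, univ, pw2, rk2)
    expect_equal(e2$p, hyper_enum_oracle(e2$k, K, n, N), tolerance = 1e-12)
  }
  # no overlap -> the whole upper tail, p = 1
  e3 <- pathway_enrichment(paste0("R", 6:10), paste0("R", 1:10), pw, rk)
  expect_equal(e3$p, 1)
  # saturation: selected = universe gives k = K and p = 1
  e4 <- pathway_enrichment(paste0("R", 1:10), paste0("R", 1:10), pw, rk)
  expect_equal(e4$p, 1)
  # a reaction with several KOs joins every matching pathway
  rk3 <- rk; rk3[["R1"]] <- c("K1", "K99")
  pw3 <- list(Pa = "K99", Pb = "K1")
  e5 <- pathway_enrichment("R1", paste0("R", 1:10), pw3, rk3)
  expect_equal(e5$k, c(1, 1))
  # unmappable pathway skipped with a message
  expect_message(
    pathway_enrichment("R1", paste0("R", 1:10), list(Px = "K77"), rk),
    "skipped")
  expect_error(pathway_enrichment("R1", character(0), pw, rk), "empty")
})

test_that("paired reaction tests propagate planted MSP effects", {
  panel <- make_species_panel(8, seed = 3)
  coh <- make_paired_cohort(cohort_spec(n_subjects = 20, seed = 31),
                            panel$traits)
  at0 <- msp_abundance(coh$counts_m0, coh$defs)
  at4 <- msp_abundance(coh$counts_m4, coh$defs)
  ram0 <- reaction_abundance(at0, panel$gems)
  ram4 <- reaction_abundance(at4, panel$gems)
  res <- paired_reaction_test(ram0, ram4)
  # biomass is carried by every MSP at total abundance 1: never significant
  expect_equal(res$p[res$reaction == "biomass"], 1)
  # Bonferroni is m * p capped at 1
  expect_equal(res$p_adj, pmin(1, res$p * nrow(res)), tolerance = 1e-12)
  # a reaction exclusive to planted increased species moves with them
  dirs <- vapply(panel$traits, function(t) t$direction, "")
  inc_only <- setdiff(
    unlist(lapply(panel$gems[dirs == "increased"], function(g) names(g$reactions))),
    unlist(lapply(panel$gems[dirs != "increased"], function(g) names(g$reactions))))
  inc_only <- intersect(inc_only, res$reaction)
  if (length(inc_only)) {
    sig_inc <- res$significant[res$reaction %in% inc_only] &
      res$direction[res$reaction %in% inc_only] == "increased"
    expect_true(any(sig_inc))
  }
  # mismatched pairing is an error
  expect_error(
    paired_reaction_test(
      list(abundance = ram0$abundance[, 1:5]), ram4), "unpaired")
})

test_that("CAZyme summaries count genes per substrate class and group", {
  defs <- data.frame(msp_id = rep(c("a", "b"), each = 3),
                     gene_id = paste0("g", 1:6), is_marker = 1)
  ann <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                    family = c("GH_muc1", "GH_muc2", "GH_pec1",
                               "GH_pec1", "GH_weird"))
  fam <- data.frame(family = c("GH_muc1", "GH_muc2", "GH_pec1"),
                    substrate = c("mucin", "mucin", "pectin"))
  out <- cazyme_summary(ann, fam, defs,
                        directions = c(a = "decreased", b = "increased"))
  sp <- out$species
  expect_equal(sp$n_genes[sp$msp_id == "a" & sp$substrate == "mucin"], 2)
  expect_equal(sp$n_genes[sp$msp_id == "a" & sp$substrate == "pectin"], 1)
  # unmapped family lands in "other"
  expect_equal(sp$n_genes[sp$msp_id == "b" & sp$substrate == "other"], 1)
  # group sums equal the sum over member species
  gr <- out$groups
  expect_equal(gr$n_genes[gr$direction == "decreased" & gr$substrate == "mucin"],
               sum(sp$n_genes[sp$msp_id == "a" & sp$substrate == "mucin"]))
  # empty annotation -> empty tables
  empty <- cazyme_summary(ann[0, ], fam, defs)
  expect_equal(nrow(empty$species), 0)
})
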