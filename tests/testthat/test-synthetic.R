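test_that("panel generation is deterministic and validated", {
  p1 <- make_species_panel(4, seed = 5)
  p2 <- make_species_panel(4, seed = 5)
  for (s in names(p1$gems))
    expect_identical(save_gem(p1$gems[[s]]), save_gem(p2$gems[[s]]))
  # every generated model validates and grows on at least one diet
  for (g in p1$gems) {
    expect_length(validate_gem(g), 0)
    growth <- vapply(make_diets(), function(d)
      solve_fba(apply_diet(g, d))$objective_value, 0)
    expect_gt(max(growth), 1e-6)
  }
})

test_that("planted secretion traits are realized in the flux solutions", {
  panel <- make_species_panel(trait_plan = list(
    species_trait("S1", secretors = "but"),
    species_trait("S2", consumers = "but")), seed = 6)
  d <- make_diets()$HFO
  fr1 <- solve_fba(apply_diet(panel$gems$S1, d))
  expect_gt(fr1$fluxes[["EX_but[e]"]], 1e-6)     # secretion forced
  # the consumer admits butyrate uptake
  g2 <- apply_diet(panel$gems$S2, diet("but_only", c(but = 10, h2o = 10)))
  fr2 <- solve_fba(g2)
  expect_gt(fr2$objective_value, 1e-6)
  expect_lt(fr2$fluxes[["EX_but[e]"]], -1e-6)
})

test_that("trait metabolites outside the namespace fail generation by name", {
  expect_error(
    make_species_panel(trait_plan = list(
      species_trait("S1", secretors = "unobtainium"),
      species_trait("S2"))),
    "S1.*unobtainium")
  expect_error(species_trait("x", direction = "null", log2_effect = 1),
               "log2_effect")
})

test_that("the six study diets have the stated structure", {
  diets <- make_diets()
  expect_setequal(names(diets),
                  c("HPO", "HPP", "HFP", "HFO", "WESTERN", "KETO"))
  ns <- ex_namespace()
  for (d in diets) {
    expect_true(d$anaerobic)
    expect_true(all(names(d$uptake_bounds) %in% ns))
    expect_true(all(d$uptake_bounds >= 0))
  }
  # anaerobic: oxygen uptake is shut on any model under any diet
  g <- make_species_panel(2, seed = 7)$gems[[1]]
  for (d in diets)
    expect_equal(apply_diet(g, d)$reactions[["EX_o2[e]"]]$lower_bound, 0)
  # fiber-rich diets out-supply the ketogenic diet in fiber analogue
  expect_gt(diets$HFO$uptake_bounds[["fib"]], diets$KETO$uptake_bounds[["fib"]])
  expect_gt(diets$HFP$uptake_bounds[["fib"]], diets$KETO$uptake_bounds[["fib"]])
  # protein-rich diets put their weight on the peptide analogue
  expect_gt(diets$HPO$uptake_bounds[["pep"]], diets$HPO$uptake_bounds[["fib"]])
  # round trip through the TSV format
  f <- withr::local_tempfile(fileext = ".tsv")
  write_diet(diets$KETO, f)
  d2 <- read_diet(f)
  expect_equal(d2$name, "KETO")
  expect_true(d2$anaerobic)
  expect_equal(sort(names(d2$uptake_bounds)),
               sort(names(diets$KETO$uptake_bounds)))
})

test_that("a single planted species shows its effect in marker abundance", {
  # one +2 species among 20 stable ones: the compositional distortion of
  # renormalization stays small and the paired log2 ratio lands near 2
  traits <- c(list(species_trait("planted", "increased", 2)),
              lapply(1:19, function(i) species_trait(sprintf("bg%02d", i))))
  names(traits) <- vapply(traits, `[[`, "", "species_id")
  lfcs <- vapply(1:3, function(seed) {
    coh <- make_paired_cohort(cohort_spec(n_subjects = 20, seed = seed),
                              traits)
    at <- msp_abundance(cbind(coh$counts_m0, coh$counts_m4), coh$defs)
    d <- paired_diff_abundance(at)
    d$log2fc[d$msp_id == "planted"]
  }, 0)
  expect_lt(abs(mean(lfcs) - 2), 0.3)
})

test_that("an all-null cohort yields no significant MSPs in most seeds", {
  traits <- lapply(1:8, function(i) species_trait(sprintf("n%02d", i)))
  names(traits) <- vapply(traits, `[[`, "", "species_id")
  n_sig <- vapply(1:10, function(seed) {
    coh <- make_paired_cohort(cohort_spec(n_subjects = 20, seed = seed),
                              traits)
    at <- msp_abundance(cbind(coh$counts_m0, coh$counts_m4), coh$defs)
    sum(paired_diff_abundance(at)$direction != "ns")
  }, 0)
  expect_gte(mean(n_sig == 0), 0.9)
})

test_that("cohort tables have paired structure and honest ground truth", {
  panel <- make_species_panel(6, seed = 8)
  spec <- cohort_spec(n_subjects = 10, seed = 9)
  coh <- make_paired_cohort(spec, panel$traits)
  expect_equal(colnames(coh$counts_m0), sprintf("S%02d_M0", 1:10))
  expect_equal(colnames(coh$counts_m4), sprintf("S%02d_M4", 1:10))
  expect_true(all(colSums(coh$counts_m0) == spec$depth))
  expect_equal(nrow(coh$defs), 6 * spec$n_genes_per_msp)
  expect_equal(sum(coh$defs$is_marker), 6 * spec$n_marker_genes)
  expect_equal(ncol(coh$genus_counts), 20)
  expect_length(coh$truth$genus_components, 20)
  # degenerate mixture: one component only
  coh1 <- make_paired_cohort(cohort_spec(n_subjects = 8, dmm_components = 1,
                                         seed = 10), panel$traits)
  expect_true(all(coh1$truth$genus_components == 1))
  # invalid spec caught at construction
  expect_error(cohort_spec(n_marker_genes = 50, n_genes_per_msp = 40),
               "exceed")
})

test_that("count tables and MSP definitions round trip through TSV", {
  panel <- make_species_panel(3, seed = 11)
  coh <- make_paired_cohort(cohort_spec(n_subjects = 6, seed = 12),
                            panel$traits)
  dirp <- withr::local_tempdir()
  f1 <- file.path(dirp, "counts.tsv")
  write_count_table(coh$counts_m0, f1)
  expect_identical(read_count_table(f1), coh$counts_m0)
  f2 <- file.path(dirp, "defs.tsv")
  write_msp_definition(coh$defs, f2)
  expect_identical(read_msp_definition(f2), coh$defs)
})

test_that("pathway databases plant exactly one enriched pathway", {
  kos <- paste0("K", sprintf("%05d", 1:100))
  db1 <- make_pathway_db(5, kos, seed = 13)
  db2 <- make_pathway_db(5, kos, seed = 13)
  expect_identical(db1, db2)
  expect_length(db1, 5)
  expect_error(make_pathway_db(0, kos), "n_pathways")
  expect_error(make_pathway_db(3, character(0)), "nonempty")
  planted_kos <- kos[1:10]
  db <- make_pathway_db(6, kos, seed = 14, planted_kos = planted_kos)
  expect_equal(attr(db, "planted"), "PW01")
  expect_true(all(planted_kos %in% db$PW01))
  # GMT round trip
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(db, f)
  back <- read_gmt(f)
  expect_equal(back$PW01, db$PW01)
  expect_equal(names(back), names(db))
})

test_that("synthetic CAZyme tables bias substrate classes by direction", {
  panel <- make_species_panel(6, seed = 15)
  coh <- make_paired_cohort(cohort_spec(n_subjects = 6, seed = 16),
                            panel$traits)
  caz <- make_cazyme_annotation(coh$defs, panel$traits, seed = 17)
  dirs <- vapply(panel$traits, function(t) t$direction, "")
  out <- cazyme_summary(caz$annotations, caz$family_substrates, coh$defs,
                        directions = dirs)
  gr <- out$groups
  muc_dec <- sum(gr$n_genes[gr$direction == "decreased" & gr$substrate == "mucin"])
  muc_inc <- sum(gr$n_genes[gr$direction == "increased" & gr$substrate == "mucin"])
  expect_gt(muc_dec, muc_inc)
})
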