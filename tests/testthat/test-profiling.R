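test_that("rarefaction hits the target depth exactly and is the identity at full depth", {
  set.seed(1)
  counts <- matrix(rpois(60, 50), 20, 3,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  dr <- downsize_counts(counts, depth = 200, n_draws = 3, seed = 2)
  for (d in dr) expect_true(all(colSums(d) == 200))
  # depth equal to the sample total leaves counts unchanged
  one <- counts[, 1, drop = FALSE]
  expect_identical(downsize_counts(one, depth = sum(one), seed = 3)[[1]], one)
  # shallow samples are dropped with a warning
  shallow <- counts; shallow[, 2] <- 0L
  expect_warning(downsize_counts(shallow, depth = 100, seed = 4), "dropping")
  expect_error(downsize_counts(counts, depth = 0), "positive")
})

test_that("rarefied counts have hypergeometric means", {
  set.seed(5)
  counts <- matrix(rpois(15, 100), 15, 1,
                   dimnames = list(paste0("g", 1:15), "s1"))
  depth <- 500
  draws <- downsize_counts(counts, depth, n_draws = 200, seed = 6)
  emp <- rowMeans(sapply(draws, function(d) d[, 1]))
  total <- sum(counts)
  expected <- depth * counts[, 1] / total
  # hypergeometric variance, SE of the mean over 200 draws
  vr <- depth * (counts[, 1] / total) * (1 - counts[, 1] / total) *
    (total - depth) / (total - 1)
  se <- sqrt(vr / 200)
  expect_true(all(abs(emp - expected) <= 3 * pmax(se, 1e-9)))
})

test_that("MSP abundance is marker-mean based and scale invariant", {
  counts <- matrix(c(10, 20, 30, 100,
                     60, 60, 60, 100), 4, 2,
                   dimnames = list(c("a_g1", "a_g2", "a_g3", "b_g1"),
                                   c("S01_M0", "S01_M4")))
  defs <- data.frame(msp_id = c("a", "a", "a", "b"),
                     gene_id = c("a_g1", "a_g2", "a_g3", "b_g1"),
                     is_marker = c(1, 1, 1, 1))
  at <- msp_abundance(counts, defs)
  # signals 20 and 100 -> abundances 1/6 and 5/6
  expect_equal(unname(at$abundance["S01_M0", ]), c(20, 100) / 120)
  # signals 60 and 100
  expect_equal(unname(at$abundance["S01_M4", ]), c(60, 100) / 160)
  # doubling all counts changes nothing
  at2 <- msp_abundance(counts * 2L, defs)
  expect_equal(at2$abundance, at$abundance)
  # sole-MSP case: relative abundance 1
  at3 <- msp_abundance(counts[1:3, , drop = FALSE], defs[1:3, ])
  expect_true(all(at3$abundance == 1))
  # MSP with no marker genes in the universe is excluded with a warning
  defs_bad <- rbind(defs, data.frame(msp_id = "ghost", gene_id = "nope",
                                     is_marker = 1))
  expect_warning(msp_abundance(counts, defs_bad), "ghost")
})

test_that("richness counts detected MSPs and grows with depth", {
  panel_defs <- data.frame(msp_id = rep(c("a", "b"), each = 2),
                           gene_id = c("a1", "a2", "b1", "b2"),
                           is_marker = 1)
  counts <- matrix(c(50L, 50L, 3L, 0L), 4, 1,
                   dimnames = list(c("a1", "a2", "b1", "b2"), "s1"))
  # full depth, one draw: both MSPs detected
  expect_equal(unname(msp_richness(counts, panel_defs, depth = sum(counts),
                                   n_draws = 1)), 2)
  # expected richness is non-decreasing in depth
  r_small <- mean(replicate(5, msp_richness(counts, panel_defs, depth = 5,
                                            n_draws = 10, seed = 7)))
  r_big <- mean(replicate(5, msp_richness(counts, panel_defs, depth = 80,
                                          n_draws = 10, seed = 8)))
  expect_gte(r_big, r_small)
})

test_that("the exact signed-rank test matches full sign enumeration", {
  # the textbook example first: all-positive n = 6
  wt <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))
  expect_equal(wt$statistic, 21)
  expect_equal(wt$p, 2 / 64)
  set.seed(9)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    d <- round(rnorm(n), sample(c(0, 1, 2), 1))   # coarse rounding makes ties
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxon_signed_rank(d)$p, wilcoxon_enum_oracle(d),
                 tolerance = 1e-12)
  }
  # and it agrees with the reference implementation on tie-free data
  for (i in 1:10) {
    d <- rnorm(sample(6:15, 1))
    expect_equal(wilcoxon_signed_rank(d)$p,
                 wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("signed-rank edge cases follow the stated conventions", {
  # all differences zero -> vacuous test, p = 1
  expect_equal(wilcoxon_signed_rank(rep(0, 8))$p, 1)
  # antisymmetric data sits at the centre of the null
  expect_equal(wilcoxon_signed_rank(c(3, -3, 2, -2, 1, -1))$p, 1)
  # zero differences are dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1, 2, 3))$n, 3)
  # large-n path returns a sane p
  p <- wilcoxon_signed_rank(rnorm(40) + 0.8)$p
  expect_true(p > 0 && p < 0.05)
})

test_that("BH q-values match the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    # order preserving
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("paired differential abundance recovers planted directions", {
  panel <- make_species_panel(8, seed = 3)
  coh <- make_paired_cohort(cohort_spec(n_subjects = 20, seed = 21),
                            panel$traits)
  at <- msp_abundance(cbind(coh$counts_m0, coh$counts_m4), coh$defs)
  diffr <- paired_diff_abundance(at)
  dirs <- vapply(panel$traits, function(t) t$direction, "")
  planted <- names(dirs)[dirs != "null"]
  hit <- diffr$msp_id[diffr$direction != "ns"]
  expect_true(all(planted %in% hit))
  for (s in planted)
    expect_equal(diffr$direction[diffr$msp_id == s], dirs[[s]])
  expect_error(paired_diff_abundance(
    abundance_table(at$abundance[1:4, ])), "at least 6")
})

test_that("top-MSP selection ranks by q, effect size, then id", {
  diffr <- data.frame(
    msp_id = c("m1", "m2", "m3", "m4", "m5"),
    statistic = 1, p = c(0.001, 0.001, 0.01, 0.2, 0.001),
    q = c(0.01, 0.01, 0.04, 0.3, 0.01),
    log2fc = c(1, 3, 2, 4, -2.5),
    direction = c("increased", "increased", "increased", "ns", "decreased"))
  sel <- select_top_msps(diffr, k = 2)
  # tie at q = 0.01 broken by |log2fc|: m2 before m1
  expect_equal(sel$increased, c("m2", "m1"))
  expect_equal(sel$decreased, "m5")
  # k larger than available returns everything significant
  sel_all <- select_top_msps(diffr, k = 10)
  expect_equal(length(sel_all$increased), 3)
})
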