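#' Exact paired Wilcoxon signed-rank test
#'
#' Signed-rank test on paired differences with the conventions needed for
#' compositional abundance data: zero differences are dropped before
#' ranking (Wilcoxon's original convention); with no non-zero difference
#' the test is vacuous and p = 1. For n <= `exact_max` non-zero pairs the
#' two-sided p-value comes from the exact sign-flip distribution of the
#' statistic conditional on the observed absolute ranks (computed by a
#' shift-algorithm convolution over doubled average ranks, so ties are
#' handled exactly); above that, a normal approximation with continuity
#' correction and tie-corrected variance is used.
#'
#' @param x,y paired measurement vectors (x - y is tested), or `x` alone
#'   as a vector of differences when `y` is NULL.
#' @param exact_max maximal n for the exact distribution (default 25).
#' @param zero_tol differences with absolute value at or below this are
#'   treated as zero (guards against floating-point residue in
#'   differences of quantities that are constant by construction).
#' @return list with `statistic` (W+, sum of positive signed ranks), `p`
#'   (two-sided), `n` (non-zero pairs) and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L,
                                 zero_tol = 1e-12) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[abs(d) > zero_tol]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p = 1, n = 0L, method = "degenerate"))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact distribution of 2*W+ over all 2^n sign assignments
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dp <- numeric(total + 1L)        # dp[k+1] = #assignments with 2W = k
    dp[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dp[seq_len(total + 1L - ri)])
      dp <- dp + shifted
    }
    dp <- dp / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(dp[seq_len(w2 + 1L)])
    p_ge <- sum(dp[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2)) / 2
    z <- (w - mu - sign(w - mu) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = w, p = p, n = n, method = method)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate control:
#' `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1 (delegates to
#' [stats::p.adjust()]).
#'
#' @param pvals p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Downsize (rarefy) a gene count table to fixed depth
#'
#' Sequencing-depth variation biases richness and abundance comparisons,
#' so samples are subsampled without replacement to a common depth: each
#' draw is an exact multivariate hypergeometric subsample per sample
#' (column sums equal `depth` exactly). Samples with fewer reads than
#' `depth` are dropped with a warning.
#'
#' @param counts integer matrix, genes x samples.
#' @param depth target reads per sample.
#' @param n_draws number of independent subsamples.
#' @param seed RNG seed.
#' @return list of `n_draws` downsized count matrices.
#' @export
downsize_counts <- function(counts, depth, n_draws = 1L, seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  totals <- colSums(counts)
  low <- totals < depth
  if (any(low)) {
    warning("dropping ", sum(low), " sample(s) below depth ", depth, ": ",
            paste(colnames(counts)[low], collapse = ", "))
    counts <- counts[, !low, drop = FALSE]
    totals <- totals[!low]
  }
  local_seed(seed)
  lapply(seq_len(n_draws), function(dr) {
    out <- counts
    for (s in seq_len(ncol(counts))) {
      if (totals[s] == depth) next
      remaining <- totals[s]
      left <- depth
      x <- counts[, s]
      y <- integer(length(x))
      for (gidx in seq_along(x)) {
        if (left == 0L) break
        if (remaining == x[gidx]) { y[gidx] <- left; left <- 0L; break }
        y[gidx] <- stats::rhyper(1, x[gidx], remaining - x[gidx], left)
        left <- left - y[gidx]
        remaining <- remaining - x[gidx]
      }
      out[, s] <- y
    }
    out
  })
}

#' MSP relative abundance from marker genes
#'
#' The MSP signal in a sample is the arithmetic mean of its marker-gene
#' counts; relative abundance is the signal divided by the summed signals
#' of all MSPs in that sample. MSPs with no marker gene in the count
#' table's gene universe are excluded with a warning.
#'
#' @param counts gene count matrix (genes x samples, rownames = gene ids).
#' @param defs MSP definition data.frame with columns `msp_id`, `gene_id`,
#'   `is_marker` (0/1).
#' @return an `abundance_table`: list with `abundance` (samples x MSPs
#'   matrix of relative abundances) and `meta` (data.frame `sample`,
#'   `subject`, `timepoint` parsed from `<subject>_<M0|M4>` names when
#'   possible).
#' @export
msp_abundance <- function(counts, defs) {
  msps <- unique(defs$msp_id)
  sig <- matrix(0, nrow = ncol(counts), ncol = length(msps),
                dimnames = list(colnames(counts), msps))
  drop <- character(0)
  for (m in msps) {
    mk <- defs$gene_id[defs$msp_id == m & defs$is_marker == 1]
    mk <- intersect(mk, rownames(counts))
    if (length(mk) == 0) { drop <- c(drop, m); next }
    sig[, m] <- colMeans(counts[mk, , drop = FALSE])
  }
  if (length(drop)) {
    warning("MSP(s) without marker genes in the count table, excluded: ",
            paste(drop, collapse = ", "))
    sig <- sig[, setdiff(msps, drop), drop = FALSE]
  }
  tot <- rowSums(sig)
  ab <- sweep(sig, 1, ifelse(tot > 0, tot, 1), "/")
  abundance_table(ab)
}

#' Build an abundance table with paired-sample metadata
#'
#' @param ab samples x MSPs matrix of relative abundances (rownames =
#'   sample ids, ideally `<subject>_<M0|M4>`).
#' @param meta optional data.frame `sample`, `subject`, `timepoint`.
#' @return object of class `abundance_table`.
#' @export
abundance_table <- function(ab, meta = NULL) {
  if (is.null(meta)) {
    sm <- rownames(ab)
    has <- grepl("_(M0|M4)$", sm)
    meta <- data.frame(sample = sm,
                       subject = ifelse(has, sub("_(M0|M4)$", "", sm), NA),
                       timepoint = ifelse(has, sub("^.*_(M0|M4)$", "\\1", sm), NA),
                       stringsAsFactors = FALSE)
  }
  structure(list(abundance = ab, meta = meta), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table>", nrow(x$abundance), "samples x",
      ncol(x$abundance), "MSPs\n")
  invisible(x)
}

#' MSP richness at fixed depth
#'
#' Richness (number of MSPs with positive marker signal) is sensitive to
#' sequencing depth, so it is computed on repeated fixed-depth subsamples
#' and averaged: per draw, richness = number of detected MSPs; reported
#' value = mean over draws.
#'
#' @inheritParams downsize_counts
#' @param defs MSP definitions (see [msp_abundance()]).
#' @return named numeric vector of per-sample mean richness.
#' @export
msp_richness <- function(counts, defs, depth, n_draws = 10L, seed = 1L) {
  draws <- downsize_counts(counts, depth, n_draws = n_draws, seed = seed)
  rich <- sapply(draws, function(cc) {
    at <- suppressWarnings(msp_abundance(cc, defs))
    rowSums(at$abundance > 0)
  })
  if (is.null(dim(rich))) rich <- matrix(rich, nrow = 1)
  rowMeans(rich)
}

#' Paired differential abundance of MSPs
#'
#' Per MSP: exact Wilcoxon signed-rank test of the paired M4 - M0
#' abundance differences across subjects, BH correction across MSPs,
#' direction from the sign of the median paired difference (`ns` when the
#' q-value misses the threshold). The mean paired log2 fold change uses a
#' pseudocount of half the smallest positive abundance for zero entries.
#'
#' @param table an `abundance_table` with paired M0/M4 samples per
#'   subject (at least 6 complete pairs).
#' @param fdr significance threshold on q.
#' @return data.frame `msp_id`, `statistic`, `p`, `q`, `log2fc`,
#'   `direction` ("increased"/"decreased"/"ns").
#' @export
paired_diff_abundance <- function(table, fdr = 0.05) {
  meta <- table$meta
  subj <- intersect(meta$subject[meta$timepoint == "M0"],
                    meta$subject[meta$timepoint == "M4"])
  if (length(subj) < 6) stop("need at least 6 complete M0/M4 pairs")
  s0 <- meta$sample[match(paste0(subj, "_M0"), meta$sample)]
  s4 <- meta$sample[match(paste0(subj, "_M4"), meta$sample)]
  a0 <- table$abundance[s0, , drop = FALSE]
  a4 <- table$abundance[s4, , drop = FALSE]
  pos <- table$abundance[table$abundance > 0]
  pc <- if (length(pos)) min(pos) / 2 else 1e-12
  res <- lapply(colnames(a0), function(m) {
    d <- a4[, m] - a0[, m]
    wt <- wilcoxon_signed_rank(d)
    lfc <- mean(log2(pmax(a4[, m], pc) / pmax(a0[, m], pc)))
    data.frame(msp_id = m, statistic = wt$statistic, p = wt$p,
               log2fc = lfc, med_diff = stats::median(d),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- bh_fdr(res$p)
  res$direction <- ifelse(res$q >= fdr, "ns",
                          ifelse(res$med_diff > 0, "increased", "decreased"))
  res[, c("msp_id", "statistic", "p", "q", "log2fc", "direction")]
}

#' Select the top MSPs per direction
#'
#' Ranks significant MSPs within each direction by q ascending, ties
#' broken by larger absolute mean paired log2 fold change, then lexical
#' id, and returns at most `k` per direction — the selection used for
#' individual and community metabolic modelling.
#'
#' @param diff a [paired_diff_abundance()] result.
#' @param k maximal MSPs per direction (default 10).
#' @return list with `increased` and `decreased` character vectors.
#' @export
select_top_msps <- function(diff, k = 10L) {
  pick <- function(dir) {
    d <- diff[diff$direction == dir, ]
    d <- d[order(d$q, -abs(d$log2fc), d$msp_id), ]
    utils::head(d$msp_id, k)
  }
  list(increased = pick("increased"), decreased = pick("decreased"))
}

# deterministic local RNG seeding that never clobbers the caller's stream
local_seed <- function(seed, envir = parent.frame()) {
  withr::local_seed(seed, .local_envir = envir)
}
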