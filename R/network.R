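# Compositionality-corrected co-occurrence networks.
#
# Relative abundances are compositional: closure alone induces spurious
# negative correlation. The significance machinery here compares, for
# every species pair, the bootstrap distribution of a checkerboard
# similarity score against a permutation null in which each species'
# values are shuffled independently and the rows renormalized — the
# renormalization restores compositional closure, so the null carries the
# same closure artefact as the data and the comparison cancels it.

quantile_bins <- function(x, n_bins) {
  r <- rank(x, ties.method = "average")
  if (max(r) == min(r)) return(rep(1L, length(x)))
  as.integer(cut(r, breaks = n_bins, include.lowest = TRUE))
}

#' Checkerboard similarity score between two abundance vectors
#'
#' Both vectors are discretized into `n_bins` quantile bins; over all
#' sample pairs, co-variation pairs (both bins move the same way) count
#' +1 and co-exclusion pairs (opposite ways) count -1, ties count 0, and
#' the sum is normalized by the maximum attainable given each vector's
#' marginal bin counts (the tie-aware Kendall normalization
#' \eqn{\sqrt{(P-T_x)(P-T_y)}}). The score lies in [-1, 1], is symmetric
#' in its arguments, and equals exactly +1 / -1 on monotone /
#' anti-monotone bin-aligned inputs. A constant vector yields 0 with
#' attribute `constant = TRUE`.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param n_bins number of quantile bins (default 4).
#' @return numeric score in [-1, 1].
#' @export
nc_score <- function(x, y, n_bins = 4L) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  bx <- quantile_bins(x, n_bins)
  by <- quantile_bins(y, n_bins)
  sx <- sign(outer(bx, bx, "-"))
  sy <- sign(outer(by, by, "-"))
  denom <- sqrt(sum(sx^2) * sum(sy^2))
  if (denom == 0) return(structure(0, constant = TRUE))
  sum(sx * sy) / denom
}

# all pairwise checkerboard scores of the columns of `ab` in one pass:
# flatten each column's pairwise sign matrix and take cross products
nc_score_matrix <- function(ab, n_bins = 4L) {
  n <- nrow(ab); p <- ncol(ab)
  M <- matrix(0, n * n, p)
  for (j in seq_len(p)) {
    b <- quantile_bins(ab[, j], n_bins)
    M[, j] <- as.numeric(sign(outer(b, b, "-")))
  }
  C <- crossprod(M)
  d <- sqrt(diag(C))
  d[d == 0] <- Inf                      # constant column -> score 0
  sc <- C / outer(d, d)
  diag(sc) <- 1
  dimnames(sc) <- list(colnames(ab), colnames(ab))
  sc
}

#' Bootstrap/permutation significance of pairwise co-occurrence
#'
#' For every pair of MSP columns: the checkerboard score is computed on
#' `n_boot` bootstrap resamples of the samples (rows resampled with
#' replacement, rows renormalized) and on `n_perm` permutation datasets
#' (each MSP's values permuted independently across samples, then rows
#' renormalized to restore compositional closure). The pooled-variance
#' z-statistic
#' \deqn{z = (\bar s_{boot} - \bar s_{perm}) / \sqrt{v_{boot} + v_{perm}}}
#' is referred to the standard normal, two-sided.
#'
#' @param table an `abundance_table` (or samples x MSPs matrix) with at
#'   least 8 samples.
#' @param n_boot,n_perm resample counts (>= 100 each).
#' @param seed RNG seed.
#' @param n_bins quantile bins for the score.
#' @return data.frame `msp_a`, `msp_b` (canonical order), `sim_score`
#'   (score on the observed data), `z`, `p`.
#' @export
reboot_significance <- function(table, n_boot = 1000L, n_perm = 1000L,
                                seed = 1L, n_bins = 4L) {
  ab <- if (inherits(table, "abundance_table")) table$abundance else table
  n <- nrow(ab); p <- ncol(ab)
  if (n < 8) stop("need at least 8 samples for resampling significance")
  if (n_boot < 100 || n_perm < 100) stop("n_boot and n_perm must be >= 100")
  renorm <- function(m) {
    rs <- rowSums(m)
    sweep(m, 1, ifelse(rs > 0, rs, 1), "/")
  }
  local_seed(seed)
  obs <- nc_score_matrix(renorm(ab), n_bins)
  np <- p * (p - 1) / 2
  up <- upper.tri(obs)
  sb <- matrix(0, n_boot, np); sp_ <- matrix(0, n_perm, np)
  for (b in seq_len(n_boot)) {
    m <- renorm(ab[sample.int(n, n, replace = TRUE), , drop = FALSE])
    sb[b, ] <- nc_score_matrix(m, n_bins)[up]
  }
  for (q in seq_len(n_perm)) {
    m <- apply(ab, 2, function(col) col[sample.int(n)])
    sp_[q, ] <- nc_score_matrix(renorm(m), n_bins)[up]
  }
  mb <- colMeans(sb); vb <- apply(sb, 2, stats::var)
  mp <- colMeans(sp_); vp <- apply(sp_, 2, stats::var)
  denom <- sqrt(vb + vp)
  z <- ifelse(denom > 1e-12, (mb - mp) / denom,
              ifelse(abs(mb - mp) < 1e-12, 0, sign(mb - mp) * Inf))
  idx <- which(up, arr.ind = TRUE)
  a <- colnames(ab)[idx[, 1]]; b2 <- colnames(ab)[idx[, 2]]
  swap <- a > b2
  data.frame(msp_a = ifelse(swap, b2, a), msp_b = ifelse(swap, a, b2),
             sim_score = obs[up], z = z, p = 2 * stats::pnorm(-abs(z)),
             stringsAsFactors = FALSE)
}

#' Build an integrative correlation network for one timepoint
#'
#' Nodes are the top MSPs per direction (via [select_top_msps()], or an
#' explicit `msps` vector); edges are pairs whose bootstrap/permutation
#' pooled-variance z-test passes BH FDR below `q_threshold`, signed by
#' the Spearman correlation of the pair.
#'
#' @param table an `abundance_table` restricted to one timepoint (or the
#'   full table plus `timepoint`).
#' @param diff a [paired_diff_abundance()] result used to select nodes
#'   (ignored when `msps` is given).
#' @param timepoint optional "M0"/"M4" filter applied to `table`.
#' @param msps optional explicit node set.
#' @param q_threshold BH FDR threshold for edges.
#' @param top_k MSPs per direction.
#' @param n_boot,n_perm,seed,n_bins passed to [reboot_significance()].
#' @param node_meta optional data.frame `msp_id`, `phylum` for node
#'   annotation.
#' @return object of class `icn_network`: list with `nodes` (msp_id,
#'   phylum, mean_abundance) and `edges` (msp_a, msp_b, sim_score,
#'   spearman_sign, p, q).
#' @export
build_icn <- function(table, diff = NULL, timepoint = NULL, msps = NULL,
                      q_threshold = 0.05, top_k = 10L,
                      n_boot = 1000L, n_perm = 1000L, seed = 1L,
                      n_bins = 4L, node_meta = NULL) {
  ab <- table$abundance
  meta <- table$meta
  if (!is.null(timepoint)) {
    keep <- meta$timepoint == timepoint
    ab <- ab[keep, , drop = FALSE]
  }
  if (is.null(msps)) {
    if (is.null(diff)) stop("either `diff` or `msps` must be given")
    sel <- select_top_msps(diff, k = top_k)
    msps <- c(sel$increased, sel$decreased)
  }
  msps <- intersect(msps, colnames(ab))
  ab <- ab[, msps, drop = FALSE]
  sig <- reboot_significance(ab, n_boot = n_boot, n_perm = n_perm,
                             seed = seed, n_bins = n_bins)
  sig$q <- bh_fdr(sig$p)
  edges <- sig[sig$q < q_threshold, , drop = FALSE]
  if (nrow(edges)) {
    edges$spearman_sign <- vapply(seq_len(nrow(edges)), function(i) {
      rho <- stats::cor(ab[, edges$msp_a[i]], ab[, edges$msp_b[i]],
                        method = "spearman")
      if (!is.na(rho) && rho < 0) "negative" else "positive"
    }, "")
  } else edges$spearman_sign <- character(0)
  rownames(edges) <- NULL
  nodes <- data.frame(msp_id = msps,
                      phylum = if (is.null(node_meta)) NA_character_
                               else node_meta$phylum[match(msps, node_meta$msp_id)],
                      mean_abundance = colMeans(ab),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes,
                 edges = edges[, c("msp_a", "msp_b", "sim_score",
                                   "spearman_sign", "p", "q")]),
            class = "icn_network")
}

#' @export
print.icn_network <- function(x, ...) {
  cat("<icn_network>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Compare two timepoint networks
#'
#' Edge sets are compared on canonical pair ids: `common` (both
#' networks), `lost` (first only), `gained` (second only), and
#' `sign_flipped` (common pairs whose Spearman sign differs).
#'
#' @param net_m0,net_m4 `icn_network` objects.
#' @return list of data.frames `common`, `lost`, `gained`, `sign_flipped`
#'   each with `msp_a`, `msp_b` (plus signs for `sign_flipped`).
#' @export
compare_networks <- function(net_m0, net_m4) {
  key <- function(e) paste(e$msp_a, e$msp_b, sep = "|")
  e0 <- net_m0$edges; e4 <- net_m4$edges
  k0 <- key(e0); k4 <- key(e4)
  pick <- function(e, keys) {
    out <- e[key(e) %in% keys, c("msp_a", "msp_b"), drop = FALSE]
    rownames(out) <- NULL
    out
  }
  common_keys <- intersect(k0, k4)
  common <- pick(e0, common_keys)
  flipped_keys <- common_keys[
    e0$spearman_sign[match(common_keys, k0)] !=
    e4$spearman_sign[match(common_keys, k4)]]
  sign_flipped <- pick(e0, flipped_keys)
  if (nrow(sign_flipped)) {
    sign_flipped$sign_m0 <- e0$spearman_sign[match(flipped_keys, k0)]
    sign_flipped$sign_m4 <- e4$spearman_sign[match(flipped_keys, k4)]
  }
  list(common = common,
       lost = pick(e0, setdiff(k0, k4)),
       gained = pick(e4, setdiff(k4, k0)),
       sign_flipped = sign_flipped)
}

#' Export a network as edge-list and node TSV files
#'
#' Writes `*_edges.tsv` (msp_a, msp_b, sim_score, spearman_sign, p, q)
#' and `*_nodes.tsv` (msp_id, phylum, mean_abundance) suitable for
#' external visualization tools.
#'
#' @param net an `icn_network`.
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_network <- function(net, prefix) {
  ef <- paste0(prefix, "_edges.tsv")
  nf <- paste0(prefix, "_nodes.tsv")
  utils::write.table(net$edges, ef, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$nodes, nf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(ef, nf))
}
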