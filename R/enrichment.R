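#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median, over features with
#' strictly positive counts in every sample, of the ratio of the sample's
#' count to the feature's geometric mean across samples. Features containing
#' any zero are excluded from the median (their geometric mean would vanish);
#' this is the usual median-of-ratios estimator for sequencing depth.
#'
#' @param counts Integer/numeric matrix (features x samples) or a
#'   `SummarizedExperiment` carrying a `counts` assay.
#' @return Named numeric vector of positive size factors, one per sample.
#' @examples
#' compute_size_factors(matrix(c(10, 10, 20, 20), ncol = 2))
#' @export
compute_size_factors <- function(counts) {
  counts <- .as_count_matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no feature has positive counts in all samples; ",
         "use coarser features or pseudo-features for normalization")
  logc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2L, function(x) exp(stats::median(x - loggeo)))
  stats::setNames(sf, colnames(counts))
}

.as_count_matrix <- function(counts) {
  if (methods::is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  as.matrix(counts)
}

#' Moderated per-window negative-binomial dispersions
#'
#' Method-of-moments dispersion per window from within-group residual
#' moments of normalized counts (`var = mu + alpha * mu^2`), moderated by
#' a mean-dispersion trend `alpha(mu) = a1/mu + a0` fitted across windows.
#' Within-group moments are used so a real between-group difference does
#' not inflate the dispersion of the very windows under test. The final
#' dispersion is the maximum of the window estimate and the trend value:
#' with two or three replicates per group the per-window moment estimate
#' has so few degrees of freedom that values far below the trend are
#' noise, and using them would anti-conservatively shrink standard errors
#' (the conservative "maximum" sharing rule of early NB count testing).
#' Estimates are floored at 1e-8.
#'
#' @param norm_counts Matrix of normalized counts (features x samples).
#' @param group Factor/character of length `ncol(norm_counts)` with two
#'   levels.
#' @return Numeric vector of final dispersions, with the raw (`raw`) and
#'   trend (`trend`) components as attributes.
#' @export
estimate_dispersions <- function(norm_counts, group) {
  group <- as.factor(group)
  idx <- split(seq_along(group), group)
  mu_g <- vapply(idx, function(j) rowMeans(norm_counts[, j, drop = FALSE]),
                 numeric(nrow(norm_counts)))
  mu_g <- matrix(mu_g, nrow = nrow(norm_counts))
  # pooled within-group excess variance relative to mu^2
  num <- 0; den <- 0
  for (g in seq_along(idx)) {
    j <- idx[[g]]
    if (length(j) < 2L) next
    resid2 <- (norm_counts[, j, drop = FALSE] - mu_g[, g])^2
    ss <- rowSums(resid2) / (length(j) - 1L)
    w <- length(j) - 1L
    num <- num + w * (ss - mu_g[, g]) / pmax(mu_g[, g], 1e-8)^2
    den <- den + w
  }
  if (den == 0) stop("need at least 2 replicates in some group")
  alpha_raw <- pmax(num / den, 1e-8)

  mu_bar <- rowMeans(norm_counts)
  alpha_trend <- .fit_dispersion_trend(alpha_raw, mu_bar)
  alpha <- pmax(alpha_raw, alpha_trend, 1e-8)
  attr(alpha, "raw") <- alpha_raw
  attr(alpha, "trend") <- alpha_trend
  alpha
}

# alpha(mu) = a1/mu + a0, least squares on informative windows, coefficients
# clamped nonnegative; falls back to the median raw dispersion when the fit
# is degenerate (e.g. all windows share one mean).
.fit_dispersion_trend <- function(alpha_raw, mu_bar) {
  use <- mu_bar > 1 & is.finite(alpha_raw)
  fallback <- stats::median(alpha_raw[use], na.rm = TRUE)
  if (!is.finite(fallback)) fallback <- 0.01
  if (sum(use) >= 10) {
    fit <- try(stats::lm.fit(cbind(1, 1 / mu_bar[use]), alpha_raw[use]),
               silent = TRUE)
    if (!inherits(fit, "try-error") && all(is.finite(fit$coefficients))) {
      a0 <- max(fit$coefficients[1L], 0)
      a1 <- max(fit$coefficients[2L], 0)
      if (a0 > 0 || a1 > 0)
        return(pmax(a0 + a1 / pmax(mu_bar, 1e-8), 1e-8))
    }
  }
  rep(fallback, length(mu_bar))
}

#' Two-group negative-binomial Wald test per window
#'
#' Fits, per window, an NB log-link model with a group coefficient (IP over
#' control) and log size factors as offsets, at a fixed moderated dispersion
#' from [estimate_dispersions()], and reports the Wald test of the group
#' coefficient. Windows with zero counts in every sample are excluded from
#' testing and flagged (`all_zero`), mirroring the rule that only windows
#' with at least one read in at least one replicate enter the analysis.
#'
#' @param counts Count matrix or `SummarizedExperiment` (`counts` assay).
#' @param groups Character/factor with entries `"IP"` and `"control"` (any
#'   two labels; `ref` names the reference/control level).
#' @param size_factors Optional; computed with [compute_size_factors()] when
#'   missing.
#' @param ref Reference group label (default `"control"`).
#' @param windows Optional `GRanges` describing the rows (taken from
#'   `rowRanges` when `counts` is a RangedSummarizedExperiment).
#' @return A `data.frame` with one row per window: `baseMean` (mean
#'   normalized count), `mean_control`, `mean_ip` (per-group means of
#'   normalized counts), `log2FoldChange` (fitted IP over control),
#'   `dispersion`, `stat`, `pvalue`, `padj` (Benjamini-Hochberg) and
#'   `all_zero`. All-zero windows carry `NA` statistics. When `windows` is
#'   available, `chrom`/`start`/`end` columns are prepended (1-based
#'   inclusive, as printed by `GRanges`).
#' @export
nb_two_group_test <- function(counts, groups, size_factors = NULL,
                              ref = "control", windows = NULL) {
  if (is.null(windows) && methods::is(counts, "RangedSummarizedExperiment"))
    windows <- SummarizedExperiment::rowRanges(counts)
  if (methods::is(counts, "SummarizedExperiment") && missing(groups) &&
      "group" %in% colnames(SummarizedExperiment::colData(counts)))
    groups <- SummarizedExperiment::colData(counts)$group
  counts <- .as_count_matrix(counts)
  groups <- as.character(groups)
  if (length(groups) != ncol(counts))
    stop("'groups' must have one label per sample")
  if (length(unique(groups)) != 2L)
    stop("exactly two groups are required")
  if (!ref %in% groups) stop("reference level '", ref, "' not in 'groups'")
  x <- as.numeric(groups != ref)            # 1 = IP, 0 = control
  if (min(table(groups)) < 2L)
    stop("need at least 2 replicates per group")

  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  if (any(size_factors <= 0)) stop("size factors must be positive")

  keep <- rowSums(counts) > 0
  norm <- sweep(counts, 2L, size_factors, "/")
  mean_ctrl <- rowMeans(norm[, x == 0, drop = FALSE])
  mean_ip <- rowMeans(norm[, x == 1, drop = FALSE])

  n <- nrow(counts)
  out <- data.frame(baseMean = rowMeans(norm), mean_control = mean_ctrl,
                    mean_ip = mean_ip, log2FoldChange = NA_real_,
                    dispersion = NA_real_, stat = NA_real_,
                    pvalue = NA_real_, padj = NA_real_,
                    all_zero = !keep)
  if (any(keep)) {
    alpha <- rep(NA_real_, n)
    alpha[keep] <- estimate_dispersions(norm[keep, , drop = FALSE],
                                        ifelse(x == 1, "IP", "control"))
    fit <- .nb_wald_fit(counts[keep, , drop = FALSE], size_factors, x,
                        alpha[keep])
    out$log2FoldChange[keep] <- fit$lfc
    out$dispersion[keep] <- alpha[keep]
    out$stat[keep] <- fit$stat
    out$pvalue[keep] <- fit$pvalue
    out$padj <- bh_adjust(out$pvalue)
  }
  if (!is.null(windows)) {
    out <- cbind(data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(windows)),
      start = BiocGenerics::start(windows),
      end = BiocGenerics::end(windows)), out)
  }
  out
}

# Vectorized IRLS across windows for the two-group NB GLM with log link,
# offsets log(size factor), fixed dispersion alpha per window. Returns the
# Wald statistic for the group coefficient.
.nb_wald_fit <- function(K, sf, x, alpha, max_iter = 50L, tol = 1e-8) {
  m <- nrow(K); n <- ncol(K)
  ip <- x == 1
  logsf <- log(sf)
  eps <- 0.125
  mc <- rowSums(sweep(K[, !ip, drop = FALSE], 2L, sf[!ip], "/")) / sum(!ip)
  mi <- rowSums(sweep(K[, ip, drop = FALSE], 2L, sf[ip], "/")) / sum(ip)
  b0 <- log(pmax(mc, eps))
  b1 <- log(pmax(mi, eps)) - b0
  for (it in seq_len(max_iter)) {
    eta <- outer(b0, rep(1, n)) + outer(b1, x) +
      matrix(logsf, m, n, byrow = TRUE)
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - matrix(logsf, m, n, byrow = TRUE)) + (K - mu) / mu
    sw <- rowSums(w)
    swx <- rowSums(w[, ip, drop = FALSE])
    swz <- rowSums(w * z)
    swxz <- rowSums((w * z)[, ip, drop = FALSE])
    det <- sw * swx - swx^2          # x binary: sum(w x^2) = sum(w x)
    det <- pmax(det, 1e-12)
    b0_new <- (swx * swz - swx * swxz) / det
    b1_new <- (sw * swxz - swx * swz) / det
    b0_new <- pmin(pmax(b0_new, -30), 30)
    b1_new <- pmin(pmax(b1_new, -30), 30)
    delta <- pmax(abs(b0_new - b0), abs(b1_new - b1))
    b0 <- b0_new; b1 <- b1_new
    if (max(delta) < tol) break
  }
  eta <- outer(b0, rep(1, n)) + outer(b1, x) + matrix(logsf, m, n, byrow = TRUE)
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  sw <- rowSums(w)
  swx <- rowSums(w[, ip, drop = FALSE])
  var_b1 <- sw / pmax(sw * swx - swx^2, 1e-12)
  stat <- b1 / sqrt(var_b1)
  list(lfc = b1 / log(2), stat = stat,
       pvalue = 2 * stats::pnorm(-abs(stat)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; `NA` entries (untested windows)
#' are passed through and do not count toward the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Select significantly IP-enriched windows
#'
#' Keeps windows with `padj < alpha`, a mean normalized IP count of at least
#' `min_ip_mean` (inclusive), and a positive log2 fold change (enrichment in
#' the IP direction only).
#'
#' @param results Data frame from [nb_two_group_test()].
#' @param alpha Adjusted-p-value cutoff (default 0.05, strict `<`).
#' @param min_ip_mean Minimum mean normalized IP count (default 50,
#'   inclusive `>=`).
#' @return The subset of `results` rows passing all three filters.
#' @export
call_significant_windows <- function(results, alpha = 0.05,
                                     min_ip_mean = 50) {
  keep <- !is.na(results$padj) & results$padj < alpha &
    results$mean_ip >= min_ip_mean &
    !is.na(results$log2FoldChange) & results$log2FoldChange > 0
  results[keep, , drop = FALSE]
}

#' Merge significant windows into binding sites
#'
#' Chains windows on the same chromosome whose gap is strictly less than
#' `max_gap` nt (overlapping or bookended windows always merge); each site
#' is the union hull of its chain, with per-site summary statistics over the
#' member windows.
#'
#' @param windows Data frame of significant windows (from
#'   [call_significant_windows()], with `chrom`/`start`/`end` columns) or a
#'   `GRanges` with `padj` and `mean_ip` metadata columns.
#' @param max_gap Exclusive gap threshold in nt (default 200: gaps of
#'   199 nt merge, 200 nt do not).
#' @return A `GRanges` of binding sites with metadata columns `n_windows`,
#'   `min_padj`, `mean_ip` (mean over member windows) and `width` available
#'   via `width()`.
#' @export
merge_windows_into_sites <- function(windows, max_gap = 200L) {
  if (is.data.frame(windows)) {
    if (nrow(windows) == 0L) return(GenomicRanges::GRanges())
    gr <- GenomicRanges::GRanges(windows$chrom,
                                 IRanges::IRanges(windows$start, windows$end))
    S4Vectors::mcols(gr)$padj <- windows$padj
    S4Vectors::mcols(gr)$mean_ip <- windows$mean_ip
  } else {
    gr <- windows
    if (length(gr) == 0L) return(GenomicRanges::GRanges())
  }
  red <- GenomicRanges::reduce(gr, min.gapwidth = as.integer(max_gap),
                               with.revmap = TRUE, ignore.strand = TRUE)
  rv <- S4Vectors::mcols(red)$revmap
  S4Vectors::mcols(red)$n_windows <- lengths(rv)
  S4Vectors::mcols(red)$min_padj <-
    vapply(rv, function(i) suppressWarnings(min(gr$padj[i])), numeric(1))
  S4Vectors::mcols(red)$mean_ip <-
    vapply(rv, function(i) mean(gr$mean_ip[i]), numeric(1))
  S4Vectors::mcols(red)$revmap <- NULL
  red
}
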