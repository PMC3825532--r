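#' Count tags per region
#'
#' Assigns a tag to a region when its shifted 5' position lies in
#' \code{[start, end)}. Regions must be disjoint (post-merge), otherwise the
#' assignment would be ambiguous.
#'
#' @param regions disjoint interval data.frame.
#' @param tags deduplicated multi-sample tag data.frame.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param shift tag shift in bp (same value as used in region calling).
#' @return integer matrix regions x samples; row names \code{chrom:start-end}.
#' @export
count_tags_per_region <- function(regions, tags, chrom_lengths, shift = 75) {
  validate_intervals(regions)
  gr <- as_granges0(regions)
  if (nrow(regions) > 1 && !GenomicRanges::isDisjoint(gr)) {
    stop("regions overlap: tag assignment would be ambiguous")
  }
  samples <- unique(tags$sample)
  ids <- paste0(regions$chrom, ":",
                format(regions$start, scientific = FALSE, trim = TRUE), "-",
                format(regions$end, scientific = FALSE, trim = TRUE))
  m <- matrix(0L, nrow(regions), length(samples), dimnames = list(ids, samples))
  pos <- shift_positions(tags, chrom_lengths, shift)
  tag_gr <- GenomicRanges::GRanges(tags$chrom, IRanges::IRanges(pos + 1, pos + 1))
  hits <- GenomicRanges::findOverlaps(tag_gr, gr)
  if (length(hits) > 0) {
    tab <- table(factor(S4Vectors::subjectHits(hits), levels = seq_len(nrow(regions))),
                 factor(tags$sample[S4Vectors::queryHits(hits)], levels = samples))
    m[] <- as.integer(tab)
  }
  grp <- attr(tags, "groups")
  if (!is.null(grp)) attr(m, "groups") <- grp[samples]
  m
}

#' Centile filter on row sums
#'
#' Removes rows whose count sum falls strictly below the empirical centile
#' (linear-interpolation definition, \code{quantile} type 7) of all row sums;
#' rows tied with the threshold are retained.
#'
#' @param m count matrix.
#' @param centile percentile in [0, 100].
#' @return filtered matrix (attributes preserved).
#' @export
centile_filter <- function(m, centile) {
  stopifnot(centile >= 0, centile <= 100)
  if (nrow(m) == 0) stop("empty count matrix")
  sums <- rowSums(m)
  thr <- stats::quantile(sums, centile / 100, type = 7, names = FALSE)
  keep <- sums >= thr
  out <- m[keep, , drop = FALSE]
  attr(out, "groups") <- attr(m, "groups")
  out
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample scaling factors by the TMM method: a reference sample
#' is chosen as the column whose upper quartile of scaled counts is closest to
#' the mean upper quartile; per-row log2 ratios (M) against the reference are
#' trimmed (30\% on M, 5\% on absolute intensity A by default), and the factor
#' is two to the precision-weighted trimmed mean of M. Rows with a zero in
#' either compared sample are excluded from the trimming set. Factors are
#' rescaled to multiply to one.
#'
#' @param m count matrix (>= 2 samples, no all-zero column).
#' @param logratio_trim,abs_trim two-sided trim fractions for M and A.
#' @return named numeric vector of normalization factors.
#' @export
tmm_factors <- function(m, logratio_trim = 0.30, abs_trim = 0.05) {
  if (ncol(m) < 2) stop("need >= 2 samples")
  lib <- colSums(m)
  if (any(lib == 0)) stop("sample with all-zero counts: ",
                          colnames(m)[which(lib == 0)[1]])
  uq <- apply(m, 2, function(x) stats::quantile(x / sum(x), 0.75, names = FALSE))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref) return(1)
    tmm_pair(m[, j], m[, ref], lib[j], lib[ref], logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(m))
}

# one column vs the reference; returns the unscaled factor
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0) return(1)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  # delta-method precision weights; floored so a row that is an entire
  # library (degenerate tiny matrices) cannot zero the weight
  w <- pmax((n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref), 1e-12)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

# conditional negative-binomial log likelihood of one group of counts given
# their sum, for iid NB with common mean and dispersion phi (size r = 1/phi);
# vectorised over a grid of phi values. y may be non-integer (pseudo-counts).
cond_nb_loglik <- function(y, phi_grid) {
  n <- length(y); z <- sum(y)
  vapply(phi_grid, function(phi) {
    r <- 1 / phi
    sum(lgamma(y + r)) - n * lgamma(r) - sum(lgamma(y + 1)) -
      (lgamma(z + n * r) - lgamma(n * r) - lgamma(z + 1))
  }, numeric(1))
}

#' Estimate common and shrunken tagwise dispersions
#'
#' The common dispersion maximizes the conditional negative-binomial
#' likelihood (counts scaled to a common library size, conditioned on the
#' per-group sums) pooled over all rows. Tagwise dispersions maximize the
#' per-row conditional likelihood plus \code{prior_df} residual-df-equivalents
#' of the pooled likelihood (weighted-likelihood shrinkage toward the common
#' value); \code{prior_df = Inf} forces all tagwise values to the common one.
#'
#' @param m count matrix.
#' @param groups factor or character vector of group labels per column.
#' @param norm_factors optional normalization factors (default TMM).
#' @param prior_df prior degrees of freedom for shrinkage (default 10).
#' @return list of class \code{dispersion_estimate}: \code{common},
#'   \code{tagwise}, \code{prior_df}.
#' @export
estimate_dispersions <- function(m, groups, norm_factors = NULL, prior_df = 10) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(m))
  df_res <- ncol(m) - nlevels(groups)
  if (df_res <= 0) {
    stop("no residual degrees of freedom; supply a fixed dispersion instead")
  }
  if (is.null(norm_factors)) norm_factors <- tmm_factors(m)
  eff <- colSums(m) * norm_factors
  common_lib <- stats::median(eff)
  pseudo <- sweep(m, 2, common_lib / eff, `*`)

  grid <- exp(seq(log(1e-4), log(4), length.out = 50))
  ll <- matrix(0, nrow(m), length(grid))
  for (g in levels(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2) next
    ll <- ll + t(apply(pseudo[, cols, drop = FALSE], 1, cond_nb_loglik, phi_grid = grid))
  }
  pooled <- colSums(ll)
  common <- grid_argmax(grid, pooled)

  if (is.infinite(prior_df)) {
    tagwise <- rep(common, nrow(m))
  } else {
    prior_n <- prior_df / df_res
    obj <- ll + matrix(prior_n * pooled / nrow(m), nrow(m), length(grid), byrow = TRUE)
    tagwise <- apply(obj, 1, function(v) grid_argmax(grid, v))
  }
  structure(list(common = common, tagwise = stats::setNames(tagwise, rownames(m)),
                 prior_df = prior_df),
            class = "dispersion_estimate")
}

# maximum of a smooth curve sampled on a log-spaced grid, refined by quadratic
# interpolation in log(x)
grid_argmax <- function(x, y) {
  i <- which.max(y)
  if (i == 1 || i == length(x)) return(x[i])
  lx <- log(x[(i - 1):(i + 1)]); ly <- y[(i - 1):(i + 1)]
  denom <- (lx[1] - lx[2]) * (lx[1] - lx[3]) * (lx[2] - lx[3])
  a <- (lx[3] * (ly[2] - ly[1]) + lx[2] * (ly[1] - ly[3]) + lx[1] * (ly[3] - ly[2])) / denom
  b <- (lx[3]^2 * (ly[1] - ly[2]) + lx[2]^2 * (ly[3] - ly[1]) + lx[1]^2 * (ly[2] - ly[3])) / denom
  if (!is.finite(a) || !is.finite(b) || a >= 0) return(x[i])  # flat or degenerate curve
  exp(-b / (2 * a))
}

#' Exact negative-binomial test for two groups
#'
#' Counts are scaled to a common effective library size; per row, the
#' two-sided p value comes from the conditional distribution of the case-group
#' pseudo-sum given the total under a negative binomial with the row's
#' dispersion (probability-mass summation, the same convention as Fisher's
#' exact test: all outcomes with probability not exceeding the observed one).
#' At dispersion zero the conditional law reduces to an exact binomial split
#' of the total. The log2 fold change is computed from normalized group means
#' with a proportional prior count of 0.125 per sample; its sign is positive
#' when the case group (second factor level) is higher.
#'
#' @param m count matrix.
#' @param groups two-level factor per column; first level = control,
#'   second = case.
#' @param dispersions \code{dispersion_estimate}, numeric vector, or scalar.
#' @param norm_factors optional normalization factors (default TMM).
#' @param prior_count proportional prior count per sample for the logFC.
#' @return data.frame: id, logFC, p, fdr (BH-adjusted).
#' @export
nb_exact_test <- function(m, groups, dispersions = NULL, norm_factors = NULL,
                          prior_count = 0.125) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) {
    stop("exactly 2 groups required; run case-vs-control pairs separately")
  }
  if (is.null(norm_factors)) norm_factors <- tmm_factors(m)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(m, groups, norm_factors)
  phi <- if (inherits(dispersions, "dispersion_estimate")) {
    dispersions$tagwise
  } else dispersions
  phi <- rep_len(phi, nrow(m))

  eff <- colSums(m) * norm_factors
  # the median effective library is the equalization target: it is invariant
  # to rescaling a single sample, which keeps the test's p values stable
  # under depth changes once normalization factors are applied
  common_lib <- stats::median(eff)
  pseudo <- sweep(m, 2, common_lib / eff, `*`)
  ctl <- groups == levels(groups)[1]
  n_ctl <- sum(ctl); n_case <- sum(!ctl)
  z_case <- rowSums(pseudo[, !ctl, drop = FALSE])
  z_ctl <- rowSums(pseudo[, ctl, drop = FALSE])

  logFC <- log2((z_case / n_case + prior_count) / (z_ctl / n_ctl + prior_count))
  p <- vapply(seq_len(nrow(m)), function(i) {
    exact_nb_split_p(round(z_case[i]), round(z_ctl[i]), n_case, n_ctl, phi[i])
  }, numeric(1))
  data.frame(id = rownames(m), logFC = logFC, p = p, fdr = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

# two-sided conditional p for observing group sums (za, zb) of na and nb
# samples sharing mean and dispersion phi: P(S = s | S + T = z) with
# S ~ NB(size na/phi), T ~ NB(size nb/phi) and equal per-sample means; the
# success probability cancels, leaving a generalized hypergeometric law.
exact_nb_split_p <- function(za, zb, na, nb, phi) {
  z <- za + zb
  if (z == 0) return(1)
  support <- 0:z
  if (z > 20000) {  # prune far tails; omitted mass is << 1e-12
    mu <- z * na / (na + nb)
    sd <- sqrt(z) * 4
    support <- max(0, floor(mu - 15 * sd)):min(z, ceiling(mu + 15 * sd))
    if (!(za %in% support)) support <- sort(unique(c(support, za)))
  }
  lp <- if (phi < 1e-8) {
    stats::dbinom(support, z, na / (na + nb), log = TRUE)
  } else {
    ra <- na / phi; rb <- nb / phi
    lgamma(support + ra) - lgamma(support + 1) +
      lgamma(z - support + rb) - lgamma(z - support + 1)
  }
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  obs <- pr[match(za, support)]
  min(1, sum(pr[pr <= obs * (1 + 1e-8)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR: sorted p values are scaled by n/rank, monotonicity is
#' enforced from the largest down, and values are capped at one.
#'
#' @param p vector of p values in [0, 1].
#' @return adjusted values in the original order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))
  adj[order(o)]
}

#' Z-score rows and cluster rows and columns
#'
#' Each row is centered and scaled to unit variance (rows with zero variance
#' are dropped with a warning), then rows and columns are clustered by
#' complete-linkage agglomeration on Euclidean distances. Columns are ordered
#' lexicographically by label before clustering so the tree is invariant to
#' input column order.
#'
#' @param m numeric matrix (typically normalized counts of significant rows).
#' @return list: \code{row_hclust}, \code{col_hclust}, \code{row_order},
#'   \code{col_order}, \code{zscores}.
#' @export
zscore_cluster <- function(m) {
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant row(s)")
    m <- m[sds > 0, , drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 variable rows and >= 2 columns")
  m <- m[, order(colnames(m)), drop = FALSE]
  z <- t(scale(t(m)))
  hr <- stats::hclust(stats::dist(z), method = "complete")
  hc <- stats::hclust(stats::dist(t(z)), method = "complete")
  list(row_hclust = hr, col_hclust = hc,
       row_order = rownames(z)[hr$order], col_order = colnames(z)[hc$order],
       zscores = z)
}
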