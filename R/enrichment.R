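#' Build the direction-by-overlap contingency table for one feature
#'
#' Rows are methylation direction (hyper / hypo at the chosen significance
#' cutoff), columns are overlap status against the feature's interval set
#' (>= 1 bp). Cell names follow the Up_OL / Up_NOL / Down_OL / Down_NOL
#' convention.
#'
#' @param hyper_regions,hypo_regions interval data.frames of regions already
#'   filtered at the region significance cutoff and split by logFC sign.
#' @param feature interval data.frame of the feature's instances.
#' @return named integer vector c(a, b, c, d) = (Up_OL, Up_NOL, Down_OL,
#'   Down_NOL).
#' @export
build_contingency <- function(hyper_regions, hypo_regions, feature) {
  if (nrow(hyper_regions) == 0 || nrow(hypo_regions) == 0) {
    stop("empty hyper or hypo region set")
  }
  up <- classify_overlap(hyper_regions, feature)$overlaps
  dn <- classify_overlap(hypo_regions, feature)$overlaps
  c(a = sum(up), b = sum(!up), c = sum(dn), d = sum(!dn))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric probabilities of
#' all tables at most as probable as the observed one (with a 1 + 1e-7
#' relative tolerance on the comparison). A zero margin gives p = 1 by
#' convention.
#'
#' @param tab numeric vector c(a, b, c, d), row-wise 2x2 counts.
#' @return two-sided p value.
#' @export
fisher_exact_two_sided <- function(tab) {
  stopifnot(length(tab) == 4, all(tab >= 0), all(tab == round(tab)))
  a <- tab[[1]]; b <- tab[[2]]; cc <- tab[[3]]; d <- tab[[4]]
  r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- stats::dhyper(support, c1, n - c1, r1)
  obs <- pr[match(a, support)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Fisher noncentral hypergeometric pmf over the support, log odds ratio lpsi
nchyper_pmf <- function(support, r1, c1, n, lpsi) {
  lw <- lchoose(r1, support) + lchoose(n - r1, c1 - support) + support * lpsi
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}

#' Log2 odds ratio with 95% confidence interval for a 2x2 table
#'
#' The point estimate is the conditional maximum-likelihood odds ratio (the
#' estimator of the exact conditional test, found by matching the conditional
#' expectation of the first cell to its observed value), and the interval is
#' the exact conditional one, both reported on the log2 scale. When a cell is
#' zero the conditional MLE degenerates to 0 or infinity, so the point
#' estimate falls back to the Haldane-Anscombe corrected sample odds ratio
#' (0.5 added to every cell). A Woolf normal-approximation interval is
#' available as an alternative.
#'
#' @param tab numeric vector c(a, b, c, d).
#' @param alpha 1 - confidence level.
#' @param method "conditional" (exact, default) or "woolf".
#' @return named vector c(log2_or, ci_low, ci_high).
#' @export
log2_odds_ratio_ci <- function(tab, alpha = 0.05, method = c("conditional", "woolf")) {
  method <- match.arg(method)
  stopifnot(length(tab) == 4, all(tab >= 0))
  a <- tab[[1]]; b <- tab[[2]]; cc <- tab[[3]]; d <- tab[[4]]
  if ((a == 0 && b == 0) || (cc == 0 && d == 0) ||
      (a == 0 && cc == 0) || (b == 0 && d == 0)) {
    stop("a zero margin leaves the odds ratio undefined")
  }
  if (method == "woolf") {
    if (any(tab == 0)) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
    lor <- log2(a * d / (b * cc))
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d) / log(2)
    zq <- stats::qnorm(1 - alpha / 2)
    return(c(log2_or = lor, ci_low = lor - zq * se, ci_high = lor + zq * se))
  }
  r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
  support <- max(0, r1 + c1 - n):min(r1, c1)

  solve_lpsi <- function(f, target) {
    # monotone in lpsi; bracket then uniroot
    g <- function(lp) f(lp) - target
    lo <- -1; hi <- 1
    while (g(lo) > 0 && lo > -50) lo <- lo * 2
    while (g(hi) < 0 && hi < 50) hi <- hi * 2
    if (g(lo) > 0 || g(hi) < 0) return(NA_real_)
    stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  }
  cond_mean <- function(lp) sum(support * nchyper_pmf(support, r1, c1, n, lp))
  p_le <- function(lp) sum(nchyper_pmf(support, r1, c1, n, lp)[support <= a])
  p_ge <- function(lp) sum(nchyper_pmf(support, r1, c1, n, lp)[support >= a])

  est <- if (any(tab == 0)) {
    log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (cc + 0.5)))
  } else {
    solve_lpsi(cond_mean, a)
  }
  # p_ge is increasing in lpsi, p_le decreasing; feed solve_lpsi increasing forms
  ci_low <- if (a == min(support)) -Inf else solve_lpsi(p_ge, alpha / 2)
  ci_high <- if (a == max(support)) Inf else solve_lpsi(function(lp) -p_le(lp), -alpha / 2)
  c(log2_or = est / log(2), ci_low = ci_low / log(2), ci_high = ci_high / log(2))
}

#' Feature-overlap enrichment of hyper- vs hypomethylated regions
#'
#' For each feature in the catalog, builds the Up/Down x OL/NOL contingency
#' table, the conditional-ML log2 odds ratio with its exact 95% interval, and
#' the two-sided Fisher exact p value.
#'
#' @param hyper_regions,hypo_regions significant regions split by direction.
#' @param features named list of interval data.frames (see
#'   \code{\link{feature_catalog}}).
#' @param method CI method passed to \code{\link{log2_odds_ratio_ci}}.
#' @return data.frame: feature, Up_OL, Up_NOL, Down_OL, Down_NOL, log2_or,
#'   ci_low, ci_high, p.
#' @export
feature_enrichment_table <- function(hyper_regions, hypo_regions, features,
                                     method = "conditional") {
  rows <- lapply(names(features), function(nm) {
    tab <- build_contingency(hyper_regions, hypo_regions, features[[nm]])
    or <- tryCatch(log2_odds_ratio_ci(tab, method = method),
                   error = function(e) c(log2_or = NA_real_, ci_low = NA_real_,
                                         ci_high = NA_real_))
    data.frame(feature = nm, Up_OL = tab[["a"]], Up_NOL = tab[["b"]],
               Down_OL = tab[["c"]], Down_NOL = tab[["d"]],
               log2_or = or[["log2_or"]], ci_low = or[["ci_low"]],
               ci_high = or[["ci_high"]], p = fisher_exact_two_sided(tab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enrichment of differential regions against a non-differential background
#'
#' Compares, separately for each direction, the feature-overlap frequency of
#' differential regions against non-differentially methylated regions (the
#' regions with -log10(p) below 0.25 from the differential stage), as a log2
#' odds ratio with 95% CI.
#'
#' @param hyper_regions,hypo_regions significant regions by direction.
#' @param nondiff_regions background regions (-log10 p < 0.25).
#' @param features named list of feature interval sets.
#' @param method CI method.
#' @return data.frame with one row per feature x direction.
#' @export
background_frequency_enrichment <- function(hyper_regions, hypo_regions,
                                            nondiff_regions, features,
                                            method = "conditional") {
  if (nrow(nondiff_regions) == 0) stop("empty non-differential background")
  one_dir <- function(regions, direction) {
    if (nrow(regions) == 0) stop("no regions in direction ", direction)
    lapply(names(features), function(nm) {
      fov <- classify_overlap(regions, features[[nm]])$overlaps
      bov <- classify_overlap(nondiff_regions, features[[nm]])$overlaps
      tab <- c(a = sum(fov), b = sum(!fov), c = sum(bov), d = sum(!bov))
      or <- log2_odds_ratio_ci(tab, method = method)
      data.frame(feature = nm, direction = direction,
                 diff_OL = tab[["a"]], diff_NOL = tab[["b"]],
                 bg_OL = tab[["c"]], bg_NOL = tab[["d"]],
                 log2_or = or[["log2_or"]], ci_low = or[["ci_low"]],
                 ci_high = or[["ci_high"]], p = fisher_exact_two_sided(tab),
                 stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, c(one_dir(hyper_regions, "hyper"),
                          one_dir(hypo_regions, "hypo")))
  rownames(out) <- NULL
  out
}
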