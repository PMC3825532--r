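#' Summarize a bisulfite clone matrix
#'
#' Per-clone methylation proportion (row mean) and per-CpG methylation
#' frequency (column mean). Fewer than six clones triggers a QC warning but
#' the summary is still returned.
#'
#' @param m binary matrix, clones x CpG sites.
#' @return list: \code{per_clone}, \code{per_cpg}, \code{qc_pass}.
#' @export
clone_methylation_summary <- function(m) {
  stopifnot(is.matrix(m), all(m %in% c(0, 1)))
  qc <- nrow(m) >= 6
  if (!qc) warning("fewer than six clones (", nrow(m), "); QC gate failed")
  list(per_clone = rowMeans(m), per_cpg = colMeans(m), qc_pass = qc)
}

#' Mann-Whitney U test (exact for small samples)
#'
#' Two-sided test of identical distributions. For combined n <= 20 the p
#' value is exact, by enumeration of all assignments of the pooled values to
#' the two groups (ties handled by mid-ranks); larger samples use the normal
#' approximation with tie correction. Completely tied data give p = 1.
#'
#' @param x,y numeric vectors (>= 1 value each).
#' @return list: \code{U} (statistic of the first group), \code{p}.
#' @export
mannwhitney_group_test <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    return(list(U = n1 * n2 / 2, p = 1))
  }
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= 20) {
    combs <- utils::combn(n1 + n2, n1)
    Us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    centre <- n1 * n2 / 2
    p <- mean(abs(Us - centre) >= abs(U - centre) - 1e-9)
  } else {
    ties <- table(r)
    mu <- n1 * n2 / 2
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, p = min(1, p))
}

#' Per-CpG Fisher's exact test between two clone matrices
#'
#' At each CpG site, tests independence of methylation status and group in
#' the 2x2 (group x methylated) table of clone calls.
#'
#' @param matA,matB binary clone matrices with identical CpG columns.
#' @param adjust apply BH adjustment across sites.
#' @return data.frame: cpg, meth_A, meth_B, p (and fdr when adjusted).
#' @export
percpg_fisher <- function(matA, matB, adjust = FALSE) {
  if (ncol(matA) != ncol(matB)) stop("CpG columns differ between groups")
  p <- vapply(seq_len(ncol(matA)), function(j) {
    a <- sum(matA[, j]); b <- nrow(matA) - a
    cc <- sum(matB[, j]); d <- nrow(matB) - cc
    fisher_exact_two_sided(c(a, b, cc, d))
  }, numeric(1))
  out <- data.frame(cpg = if (is.null(colnames(matA))) seq_len(ncol(matA)) else colnames(matA),
                    meth_A = colMeans(matA), meth_B = colMeans(matB), p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (adjust) out$fdr <- bh_adjust(out$p)
  out
}

#' Comparative delta-delta-Ct relative expression
#'
#' Per sample, delta-Ct is the mean target Ct minus the mean of the two
#' reference assays' mean Cts (arithmetic mean of Cts = geometric mean of
#' expression); delta-delta-Ct subtracts the control group's mean delta-Ct;
#' relative quantity is 2^(-ddCt). Invariant to adding a constant to every Ct.
#'
#' @param qpcr long data.frame: sample, group, assay, replicate, ct.
#' @param target target assay name.
#' @param references the two reference assay names.
#' @param control_group label of the calibrator group.
#' @return list: \code{per_sample} data.frame (sample, group, dct, ddct, rq)
#'   and \code{group_summary} (group, mean_rq, sd_rq, n).
#' @export
ddct_relative_expression <- function(qpcr, target = "target",
                                     references = c("Actb", "Gapdh"),
                                     control_group = "CTRL") {
  stopifnot(all(c("sample", "group", "assay", "ct") %in% names(qpcr)))
  missing_ref <- setdiff(references, unique(qpcr$assay))
  if (length(missing_ref)) stop("missing reference assay: ", missing_ref[1])
  if (!target %in% qpcr$assay) stop("missing target assay: ", target)
  mean_ct <- stats::aggregate(ct ~ sample + group + assay, qpcr, mean)
  samples <- unique(mean_ct$sample)
  per <- do.call(rbind, lapply(samples, function(s) {
    sub <- mean_ct[mean_ct$sample == s, ]
    ref_ct <- mean(vapply(references, function(a) sub$ct[sub$assay == a], numeric(1)))
    data.frame(sample = s, group = sub$group[1],
               dct = sub$ct[sub$assay == target] - ref_ct,
               stringsAsFactors = FALSE)
  }))
  if (!control_group %in% per$group) stop("no samples in control group ", control_group)
  cal <- mean(per$dct[per$group == control_group])
  per$ddct <- per$dct - cal
  per$rq <- 2^(-per$ddct)
  gs <- do.call(rbind, lapply(split(per, per$group), function(g) {
    data.frame(group = g$group[1], mean_rq = mean(g$rq),
               sd_rq = stats::sd(g$rq), n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(per) <- rownames(gs) <- NULL
  list(per_sample = per, group_summary = gs)
}

#' Group mean comparisons: t test or one-way ANOVA with Bonferroni post hoc
#'
#' The two-group design runs an unpaired two-tailed t test (pooled variance);
#' the multi-group design runs one-way ANOVA followed by all pairwise pooled-SD
#' t tests with Bonferroni multiplication (capped at 1).
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 values per group).
#' @param design "ttest" or "anova_bonferroni".
#' @return for "ttest", list(statistic, p); for "anova_bonferroni",
#'   list(statistic = F, p, pairwise = data.frame(group1, group2, p_adj)).
#' @export
group_mean_tests <- function(values, groups, design = c("ttest", "anova_bonferroni")) {
  design <- match.arg(design)
  groups <- as.factor(groups)
  if (any(table(groups) < 2)) stop("need >= 2 values per group")
  if (design == "ttest") {
    if (nlevels(groups) != 2) stop("t test design requires exactly 2 groups")
    tt <- stats::t.test(values ~ groups, var.equal = TRUE)
    return(list(statistic = unname(tt$statistic), p = tt$p.value))
  }
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  ncmp <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(ncmp), function(k) {
    sel <- groups %in% pairs[, k]
    tt <- stats::t.test(values[sel] ~ droplevels(groups[sel]), var.equal = TRUE)
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               p_adj = min(1, ncmp * tt$p.value), stringsAsFactors = FALSE)
  }))
  list(statistic = s[["F value"]][1], p = s[["Pr(>F)"]][1], pairwise = pw)
}

#' Lollipop-style text rendering of a clone matrix
#'
#' One line per clone; filled circles are methylated CpGs.
#' @param m binary clone matrix.
#' @return character vector of lines.
#' @export
lollipop_text <- function(m) {
  apply(m, 1, function(row) paste(ifelse(row == 1, "●", "○"), collapse = ""))
}
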