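#' Two-sample Kolmogorov-Smirnov comparison of cell-level distributions
#'
#' Feature distributions from imaging flow cytometry (circularity, pMLC,
#' similarity scores) are compared between groups with the two-sample KS
#' test.
#'
#' @param x,y Numeric samples.
#' @return A list with \code{statistic} (D) and \code{p.value}.
#' @export
compareDistributionsKS <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("both samples need at least 2 observations")
  ks <- suppressWarnings(stats::ks.test(x, y))
  list(statistic = unname(ks$statistic), p.value = ks$p.value)
}

#' Fisher least-significant-difference post hoc test
#'
#' Pairwise comparisons after a one-way ANOVA using the pooled residual
#' mean square: t = (mi - mj) / sqrt(MSE (1/ni + 1/nj)) on N - k degrees
#' of freedom, two-sided, with no family-wise correction (by design LSD
#' applies none).
#'
#' @param value Numeric response.
#' @param group Group factor.
#' @return A data.frame of pairwise comparisons: group1, group2,
#'   difference, t, df, p.value.
#' @export
fisherLSD <- function(value, group) {
  group <- factor(group)
  fit <- stats::aov(value ~ group)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  df <- stats::df.residual(fit)
  means <- tapply(value, group, mean)
  ns <- tapply(value, group, length)
  lv <- levels(group)
  combs <- utils::combn(lv, 2)
  do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    d <- means[[a]] - means[[b]]
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    tt <- d / se
    data.frame(group1 = a, group2 = b, difference = d, t = tt, df = df,
               p.value = 2 * stats::pt(-abs(tt), df))
  }))
}

#' Compare groups with t tests or ANOVA plus Fisher LSD
#'
#' Two groups are compared with a two-tailed Student t test (equal
#' variances by default, matching the study's analysis; Welch available);
#' three or more groups with a one-way ANOVA followed by Fisher LSD
#' pairwise comparisons.
#'
#' @param value Numeric response, one entry per cell.
#' @param group Group labels.
#' @param varEqual Use the pooled-variance t test (default TRUE).
#' @return For two groups, a list with \code{method}, \code{statistic},
#'   \code{p.value}; for more, a list with \code{method},
#'   \code{anova.F}, \code{anova.p} and a \code{pairwise} data.frame.
#' @export
compareGroups <- function(value, group, varEqual = TRUE) {
  group <- factor(group)
  ns <- table(group)
  if (any(ns < 2)) stop("every group needs at least 2 observations")
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (nlevels(group) == 2) {
    tt <- stats::t.test(value ~ group, var.equal = varEqual)
    return(list(method = "t", statistic = unname(tt$statistic),
                p.value = tt$p.value))
  }
  fit <- stats::aov(value ~ group)
  an <- summary(fit)[[1]]
  list(method = "anova_lsd", anova.F = an[["F value"]][1],
       anova.p = an[["Pr(>F)"]][1], pairwise = fisherLSD(value, group))
}

#' Cross-system normalization factor
#'
#' Measurements acquired on a second imaging system are scaled to the
#' reference system through the ratio of the two systems' untreated
#' control means; the factor multiplies the other system's measurements
#' so control means coincide exactly.
#'
#' @param referenceControlMean Control mean on the reference system.
#' @param otherControlMean Control mean on the other system.
#' @return The multiplicative normalization factor.
#' @examples
#' crossSystemScaling(10, 8)  # 1.25
#' @export
crossSystemScaling <- function(referenceControlMean, otherControlMean) {
  if (referenceControlMean <= 0 || otherControlMean <= 0)
    stop("control means must be positive")
  referenceControlMean / otherControlMean
}

#' Group-mean scaling regression
#'
#' Ordinary least squares across treatment-group means, used for the
#' cross-scale relationships between contractility (pMLC), circularity
#' and hyperosmotic hydraulic permeability. Group means, not per-cell
#' values, enter the regression.
#'
#' @param x,y Numeric vectors of group means (>= 3 groups).
#' @return A list with slope, intercept, r2, p.value and n.
#' @examples
#' scalingRelationship(c(1, 0.746, 0.839, 0.836, 1.167),
#'                     c(7.2, 10.5, 10.0, 8.3, 4.4))
#' @export
scalingRelationship <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 groups with both metrics")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = s$r.squared, p.value = s$coefficients[2, 4], n = length(x))
}

#' Per-group summary of a tidy metric table
#'
#' @param df Tidy data.frame with columns \code{group}, \code{value} (and
#'   optionally \code{metric}).
#' @param controlGroup Group whose mean defines the control-normalized
#'   column.
#' @return A data.frame with group, n, mean, sd, norm_mean.
#' @export
groupSummary <- function(df, controlGroup = "untreated") {
  split_by <- if ("metric" %in% names(df))
    interaction(df$metric, df$group, drop = TRUE) else df$group
  out <- do.call(rbind, lapply(split(df, split_by), function(d)
    data.frame(metric = if ("metric" %in% names(d)) d$metric[1] else NA,
               group = d$group[1], n = nrow(d), mean = mean(d$value),
               sd = stats::sd(d$value))))
  rownames(out) <- NULL
  ctrl <- out[out$group == controlGroup, ]
  out$norm_mean <- NA_real_
  for (i in seq_len(nrow(out))) {
    m <- ctrl[if ("metric" %in% names(df))
      which(ctrl$metric == out$metric[i]) else 1, "mean"]
    if (length(m) && is.finite(m) && m != 0)
      out$norm_mean[i] <- out$mean[i] / m
  }
  out
}
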