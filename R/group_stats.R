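#' Descriptive statistics
#'
#' Mean, SD (n-1 denominator), median, mode (smallest value on frequency
#' ties), min/max, quartiles by linear interpolation, IQR, and Tukey fences
#' at Q1 - 1.5 IQR and Q3 + 1.5 IQR.
#'
#' @param x numeric vector; non-finite values are dropped.
#' @return one-row data.frame.
#' @examples
#' describeValues(c(1, 2, 3, 4, 5))
#' @export
describeValues <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("empty input: no finite values to describe")
  tb <- table(x)
  mode <- as.numeric(names(tb)[tb == max(tb)][1])  # names sorted ascending
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  data.frame(n = length(x), mean = mean(x),
             sd = if (length(x) > 1) stats::sd(x) else 0,
             median = stats::median(x), mode = mode,
             min = min(x), max = max(x), q1 = q[1], q3 = q[2], iqr = iqr,
             fence_low = q[1] - 1.5 * iqr, fence_high = q[2] + 1.5 * iqr)
}

## ---- Kruskal-Wallis with optional exact permutation p ---------------------

kwStatistic <- function(values, g) {
  N <- length(values)
  r <- rank(values)
  Rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(n * Rbar^2) - 3 * (N + 1)
  ties <- table(values)
  tieCorr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tieCorr > 0) H <- H / tieCorr
  H
}

# exact permutation p: enumerate all partitions of the observations into
# groups of the observed sizes and count those with H >= observed
kwExactP <- function(values, g) {
  n <- tabulate(g); G <- length(n); N <- sum(n)
  r <- rank(values)
  ties <- table(values)
  tieCorr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  Hof <- function(gg) {
    Rbar2 <- vapply(seq_len(G), function(q) mean(r[gg == q]), numeric(1))^2
    H <- 12 / (N * (N + 1)) * sum(n * Rbar2) - 3 * (N + 1)
    if (tieCorr > 0) H / tieCorr else H
  }
  Hobs <- kwStatistic(values, g)
  cnt <- 0L; tot <- 0L
  gg <- integer(N)
  recurse <- function(remaining, gi) {
    if (gi == G) {
      gg[remaining] <<- G
      tot <<- tot + 1L
      if (Hof(gg) >= Hobs - 1e-9) cnt <<- cnt + 1L
      return(invisible())
    }
    for (cmb in utils::combn(remaining, n[gi], simplify = FALSE)) {
      gg[cmb] <<- gi
      recurse(setdiff(remaining, cmb), gi + 1L)
    }
  }
  recurse(seq_len(N), 1L)
  cnt / tot
}

#' Kruskal-Wallis rank-sum test with optional exact permutation p
#'
#' The omnibus H statistic with tie correction. For small samples the
#' p-value can be computed by exhaustive enumeration of every partition of
#' the observations into groups of the observed sizes; otherwise the
#' chi-square approximation is used.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param exact \code{"auto"} (exact when the enumeration is at most
#'   \code{maxEnum} partitions), \code{"always"}, or \code{"never"}.
#' @param maxEnum enumeration budget.
#' @return list: \code{statistic} (H), \code{p_value}, \code{exact},
#'   \code{df}.
#' @export
kruskalWallisTest <- function(values, groups, exact = c("auto", "never", "always"),
                              maxEnum = 300000) {
  exact <- match.arg(exact)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  g <- droplevels(as.factor(groups[keep]))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  n <- tabulate(g)
  H <- kwStatistic(values, g)
  nPart <- exp(lgamma(sum(n) + 1) - sum(lgamma(n + 1)))
  useExact <- exact == "always" || (exact == "auto" && nPart <= maxEnum)
  p <- if (useExact) kwExactP(values, g)
       else stats::pchisq(H, df = nlevels(g) - 1, lower.tail = FALSE)
  list(statistic = H, p_value = p, exact = useExact, df = nlevels(g) - 1)
}

#' Dunn's post-hoc test
#'
#' All pairwise z-tests on mean ranks after a Kruskal-Wallis test, with the
#' usual tie correction; p-values are Bonferroni-adjusted (multiplied by
#' the number of comparisons, capped at 1).
#'
#' @param values numeric vector.
#' @param groups factor of the same length.
#' @return data.frame: \code{group_a, group_b, z, p, adjusted_p}.
#' @export
dunnTest <- function(values, groups) {
  g <- droplevels(as.factor(groups))
  N <- length(values)
  r <- rank(values)
  Rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  ties <- table(values)
  tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(g)
  prs <- utils::combn(seq_along(lv), 2)
  m <- ncol(prs)
  out <- data.frame(group_a = lv[prs[1, ]], group_b = lv[prs[2, ]])
  se <- sqrt((N * (N + 1) / 12 - tieTerm) *
               (1 / n[prs[1, ]] + 1 / n[prs[2, ]]))
  out$z <- (Rbar[prs[1, ]] - Rbar[prs[2, ]]) / se
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out$adjusted_p <- pmin(1, out$p * m)
  rownames(out) <- NULL
  out
}

#' Normality-gated group comparison
#'
#' The published decision rule: Shapiro-Wilk on every group at alpha; if
#' all groups look normal, one-way ANOVA with Tukey HSD post-hoc tests,
#' otherwise Kruskal-Wallis with Dunn post-hoc tests (Bonferroni-adjusted).
#' For small samples the Kruskal-Wallis p-value is computed by exhaustive
#' enumeration over all rank partitions; otherwise the chi-square
#' approximation is used. Groups larger than 5000 are gated on a
#' deterministic order-statistic subsample (Shapiro-Wilk's size limit).
#'
#' @param values numeric vector of observations.
#' @param groups group labels.
#' @param alpha normality-gate significance level.
#' @param exact \code{"auto"} (exact Kruskal-Wallis p when the enumeration
#'   has at most \code{maxEnum} partitions), \code{"always"}, or
#'   \code{"never"}.
#' @param maxEnum enumeration budget for the exact p.
#' @return list of class \code{groupComparison}: \code{test_name},
#'   \code{statistic}, \code{p_value}, \code{normality} (per-group
#'   Shapiro-Wilk), \code{pairwise} (group_a, group_b, p, adjusted_p).
#' @export
compareGroups <- function(values, groups, alpha = 0.05,
                          exact = c("auto", "never", "always"),
                          maxEnum = 300000) {
  exact <- match.arg(exact)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  g <- droplevels(as.factor(groups[keep]))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  n <- tabulate(g)
  if (any(n < 3))
    stop(sprintf("group '%s' has n = %d (< 3)",
                 levels(g)[which.min(n)], min(n)))
  shap <- lapply(levels(g), function(lv) {
    v <- values[g == lv]
    if (length(v) > 5000) v <- sort(v)[round(seq(1, length(v), length.out = 5000))]
    if (stats::sd(v) == 0) return(list(statistic = NA_real_, p.value = 0))
    s <- stats::shapiro.test(v)
    list(statistic = unname(s$statistic), p.value = s$p.value)
  })
  normality <- data.frame(group = levels(g),
                          W = vapply(shap, function(s) s$statistic, numeric(1)),
                          p = vapply(shap, function(s) s$p.value, numeric(1)))
  allNormal <- all(normality$p > alpha)
  if (allNormal) {
    fit <- stats::aov(values ~ g)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    prs <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(group_a = vapply(prs, `[`, "", 2),
                           group_b = vapply(prs, `[`, "", 1),
                           p = tk[, "p adj"], adjusted_p = tk[, "p adj"])
    rownames(pairwise) <- NULL
    res <- list(test_name = "anova_oneway", statistic = an[["F value"]][1],
                p_value = an[["Pr(>F)"]][1], posthoc = "tukey")
  } else {
    kw <- kruskalWallisTest(values, g, exact = exact, maxEnum = maxEnum)
    pairwise <- dunnTest(values, g)[c("group_a", "group_b", "p", "adjusted_p")]
    res <- list(test_name = "kruskal_wallis", statistic = kw$statistic,
                p_value = kw$p_value, posthoc = "dunn", exact = kw$exact)
  }
  res$normality <- normality
  res$pairwise <- pairwise
  structure(res, class = "groupComparison")
}

#' @export
print.groupComparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (post-hoc: %s)\n",
              x$test_name, x$statistic, x$p_value, x$posthoc))
  print(x$pairwise, digits = 3)
  invisible(x)
}

#' Two-way group x ring analysis
#'
#' Fixed-effects two-way ANOVA with interaction on per-region observations
#' (disease group x ring index, the islet region counting as index 0),
#' using partial (Type III) sums of squares so unbalanced region counts are
#' handled, with Tukey-adjusted pairwise comparisons for each factor
#' (via estimated marginal means). Terms with zero sum of squares report
#' F = 0.
#'
#' @param df data.frame with columns \code{value}, \code{group},
#'   \code{ring} (factor-coercible).
#' @return list of class \code{twoWayAnova}: \code{anova} (term, F, p),
#'   \code{pairwise_group}, \code{pairwise_ring}.
#' @export
twoWayRingAnova <- function(df) {
  stopifnot(all(c("value", "group", "ring") %in% names(df)))
  df <- df[is.finite(df$value), ]
  df$group <- droplevels(as.factor(df$group))
  df$ring <- droplevels(as.factor(df$ring))
  cells <- table(df$group, df$ring)
  if (any(cells == 0)) {
    empt <- which(cells == 0, arr.ind = TRUE)
    stop(sprintf("empty design cell(s): %s",
                 paste(sprintf("%s x %s", rownames(cells)[empt[, 1]],
                               colnames(cells)[empt[, 2]]), collapse = ", ")))
  }
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  fit <- stats::lm(value ~ group * ring, data = df)
  terms <- c("group", "ring", "group:ring")
  aa <- tryCatch(car::Anova(fit, type = 3, singular.ok = TRUE),
                 error = function(e) NULL)
  if (is.null(aa)) {
    # degenerate zero-residual fit: partial SS by dropping each term's
    # columns from the sum-contrast model matrix
    X <- stats::model.matrix(fit)
    asn <- attr(X, "assign")
    y <- df$value
    rss <- function(M) {
      f <- stats::lm.fit(M, y)
      sum(f$residuals^2)
    }
    rss0 <- rss(X)
    SS <- vapply(1:3, function(tt) rss(X[, asn != tt, drop = FALSE]) - rss0,
                 numeric(1))
    dfe <- nrow(X) - ncol(X)
    Fv <- ifelse(SS < 1e-12, 0,
                 ifelse(rss0 < 1e-12, Inf, (SS / 1) / (rss0 / max(dfe, 1))))
    Pv <- ifelse(SS < 1e-12, 1, ifelse(rss0 < 1e-12, 0, NA))
    aa <- data.frame(`Sum Sq` = SS, `F value` = Fv, `Pr(>F)` = Pv,
                     row.names = terms, check.names = FALSE)
  }
  Fv <- aa[terms, "F value"]; Pv <- aa[terms, "Pr(>F)"]; SS <- aa[terms, "Sum Sq"]
  zero <- !is.na(SS) & SS < 1e-12
  Fv[zero] <- 0
  Pv[zero] <- 1
  anova_tab <- data.frame(term = terms, F = Fv, p = Pv, sum_sq = SS)
  rownames(anova_tab) <- NULL
  pw <- function(spec) {
    em <- emmeans::emmeans(fit, spec)
    as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
  }
  res <- list(anova = anova_tab,
              pairwise_group = tryCatch(pw("group"), error = function(e) NULL),
              pairwise_ring = tryCatch(pw("ring"), error = function(e) NULL))
  structure(res, class = "twoWayAnova")
}

#' @export
print.twoWayAnova <- function(x, ...) {
  print(x$anova, digits = 4)
  invisible(x)
}

#' Spearman correlation with Fisher-z confidence interval
#'
#' Spearman's rho as the Pearson correlation of (average) ranks; a 95
#' percent confidence interval through the Fisher z-transform with
#' \code{SE = sqrt(1.06 / (n - 3))}; a p-value from the t approximation
#' \code{t = rho sqrt((n - 2) / (1 - rho^2))}.
#'
#' @param x,y paired numeric vectors (pairs with non-finite entries are
#'   dropped; at least 4 pairs required).
#' @param conf confidence level.
#' @return list of class \code{CorrelationResult}: \code{rho, ci_low,
#'   ci_high, p_value, n}.
#' @examples
#' set.seed(2)
#' u <- runif(100)
#' spearmanWithCI(u, u^3 + rnorm(100, 0, 0.1))
#' @export
spearmanWithCI <- function(x, y, conf = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  rho <- stats::cor(rank(x), rank(y))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1.06 / (n - 3))
  if (abs(rho) >= 1) {
    ci <- c(if (rho > 0) tanh(atanh(1 - 1e-12) - zq * se) else -1,
            if (rho > 0) 1 else tanh(atanh(-1 + 1e-12) + zq * se))
    p <- 0
  } else {
    z <- atanh(rho)
    ci <- tanh(c(z - zq * se, z + zq * se))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, ci_low = ci[1], ci_high = ci[2],
                 p_value = p, n = n), class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, 95%% CI [%.3f, %.3f], p = %.3g, n = %d\n",
              x$rho, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}
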