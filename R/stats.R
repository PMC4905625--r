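# Statistics battery: Kruskal-Wallis, Dunn post hoc, Kendall and partial
# Kendall correlation, chi-square, multi-rater kappa, BCa bootstrap.

#' Construct a test-result record
#'
#' @param method test name.
#' @param statistic test statistic.
#' @param df degrees of freedom (scalar or length-2).
#' @param p p-value.
#' @param ci optional length-2 confidence interval.
#' @param n sample size used.
#' @return a `stat_test_result` list.
#' @export
stat_result <- function(method, statistic, df = NA, p = NA_real_,
                        ci = NULL, n = NA_integer_) {
  if (!is.na(p) && (p < 0 || p > 1))
    stop("p must lie in [0, 1]", call. = FALSE)
  if (!is.null(ci) && ci[1] > ci[2])
    stop("ci must be ordered", call. = FALSE)
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p = unname(p), ci = ci, n = n),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      if (!all(is.na(x$df))) paste0(", df = ", paste(x$df, collapse = ", ")),
      ", p = ", format(round(x$p, 3), nsmall = 3),
      " (raw ", format(x$p, digits = 4), ")", "\n", sep = "")
  if (!is.null(x$ci))
    cat("  ", 100 * attr(x$ci, "level"), "% CI: [",
        format(x$ci[1], digits = 4), ", ", format(x$ci[2], digits = 4),
        "]\n", sep = "")
  invisible(x)
}

#' Kruskal-Wallis rank-sum test
#'
#' H computed on mid-ranks with tie correction, compared to a chi-square
#' distribution with (number of groups - 1) degrees of freedom. When every
#' observation is identical the tie correction denominator vanishes; H is
#' then defined as 0 with p = 1.
#'
#' @param groups list of numeric vectors, one per group, each non-empty.
#' @return a \code{\link{stat_result}}.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("empty group", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  df <- length(groups) - 1L
  if (length(unique(x)) == 1L)
    return(stat_result("Kruskal-Wallis", 0, df, 1, n = length(x)))
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- kruskal.test(x, g)
  stat_result("Kruskal-Wallis", kt$statistic, unname(kt$parameter),
              kt$p.value, n = length(x))
}

#' Dunn's pairwise post hoc comparisons
#'
#' Pairwise z statistics on the joint mid-ranking of all groups, with the
#' tie-corrected variance; both the unadjusted two-sided p and its
#' Bonferroni adjustment (multiplied by the number of pairs, capped at 1)
#' are reported.
#'
#' @param groups named (or unnamed) list of numeric vectors.
#' @return data.frame, one row per pair: `group1`, `group2`, `z`,
#'   `p_unadjusted`, `p_bonferroni`.
#' @export
pairwise_posthoc <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0L)) stop("empty group", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)  # mid-ranks
  g <- rep(names(groups), sizes)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    se <- sqrt(v0 * (1 / sizes[pr[1]] + 1 / sizes[pr[2]]))
    z <- if (se > 0) (rbar[pr[1]] - rbar[pr[2]]) / se else 0
    p <- 2 * pnorm(-abs(z))
    c(z = unname(z), p = unname(p))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = res["z", ], p_unadjusted = res["p", ],
                    p_bonferroni = pmin(1, res["p", ] * ncol(pairs)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Kendall rank correlation (tau-b)
#'
#' Tau-b with tie handling; the p-value uses the normal approximation with
#' tie-corrected variance.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a \code{\link{stat_result}} with the tau estimate as statistic.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("correlation undefined for a constant vector", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
  stat_result("Kendall tau-b", ct$estimate, NA, ct$p.value, n = length(x))
}

#' Partial Kendall correlation
#'
#' Partial tau of x and y controlling for z:
#' `(t_xy - t_xz * t_zy) / sqrt((1 - t_xz^2) (1 - t_zy^2))` with each tau
#' a tau-b. The p-value uses the tau normal approximation with variance
#' `2(2n + 5) / (9 n (n - 1))`, which is approximate for the partial
#' coefficient.
#'
#' @param x,y,z numeric vectors of equal length >= 3.
#' @return a \code{\link{stat_result}}.
#' @export
kendall_partial <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("lengths differ", call. = FALSE)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  for (v in list(x, y, z))
    if (length(unique(v)) == 1L)
      stop("correlation undefined for a constant vector", call. = FALSE)
  txy <- cor(x, y, method = "kendall")
  txz <- cor(x, z, method = "kendall")
  tzy <- cor(z, y, method = "kendall")
  denom <- sqrt((1 - txz^2) * (1 - tzy^2))
  if (denom == 0)
    stop("partial correlation undefined: control variable fully ",
         "determines x or y", call. = FALSE)
  tp <- (txy - txz * tzy) / denom
  se <- sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  p <- 2 * pnorm(-abs(tp) / se)
  stat_result("partial Kendall tau", tp, NA, p, n = n)
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson X2 without continuity correction, df = (r-1)(c-1).
#'
#' @param table r x c matrix of nonnegative counts with no zero row or
#'   column marginal.
#' @return a \code{\link{stat_result}}.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table has a zero row or column marginal", call. = FALSE)
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  stat_result("chi-square", ct$statistic, unname(ct$parameter),
              ct$p.value, n = sum(table))
}

#' Interpretation band for a kappa coefficient
#'
#' Lower-inclusive bands: below 0.2 poor, 0.2 to below 0.4 fair, 0.4 to
#' below 0.6 moderate, 0.6 to below 0.8 good, 0.8 to 1 very good.
#'
#' @param kappa numeric kappa value (<= 1).
#' @return character band label.
#' @export
kappa_band <- function(kappa) {
  if (kappa > 1) stop("kappa cannot exceed 1", call. = FALSE)
  if (kappa < 0.2) "poor"
  else if (kappa < 0.4) "fair"
  else if (kappa < 0.6) "moderate"
  else if (kappa < 0.8) "good"
  else "very good"
}

#' Chance-corrected inter-rater agreement
#'
#' Two raters: Cohen's kappa on the confusion of their label assignments.
#' Three or more raters: Fleiss' kappa on per-case category counts. The
#' degenerate design in which every rater assigns one identical category
#' to every case has expected agreement 1; kappa is then reported as 1
#' with `degenerate = TRUE`.
#'
#' @param ratings n x m matrix (cases x raters) of categorical labels
#'   (character or factor-coercible), no missing entries.
#' @return a `kappa_result` list: `kappa`, `band`, `method`, `degenerate`,
#'   `n_cases`, `n_raters`.
#' @export
interrater_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("missing ratings", call. = FALSE)
  m <- ncol(ratings)
  if (m < 2L) stop("need at least 2 raters", call. = FALSE)
  cats <- sort(unique(as.vector(ratings)))
  n <- nrow(ratings)
  degenerate <- length(cats) == 1L
  if (degenerate) {
    k <- 1
    method <- if (m == 2L) "Cohen" else "Fleiss"
  } else if (m == 2L) {
    method <- "Cohen"
    f1 <- factor(ratings[, 1], levels = cats)
    f2 <- factor(ratings[, 2], levels = cats)
    tab <- table(f1, f2) / n
    po <- sum(diag(tab))
    pe <- sum(rowSums(tab) * colSums(tab))
    k <- if (pe == 1) 1 else (po - pe) / (1 - pe)
    degenerate <- pe == 1
  } else {
    method <- "Fleiss"
    counts <- t(apply(ratings, 1, function(r)
      table(factor(r, levels = cats))))
    p_i <- (rowSums(counts^2) - m) / (m * (m - 1))
    pbar <- mean(p_i)
    pj <- colSums(counts) / (n * m)
    pe <- sum(pj^2)
    k <- if (pe == 1) 1 else (pbar - pe) / (1 - pe)
    degenerate <- pe == 1
  }
  structure(list(kappa = k, band = kappa_band(k), method = method,
                 degenerate = degenerate, n_cases = n, n_raters = m),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(x$method, " kappa = ", format(x$kappa, digits = 4), " (",
      x$band, " agreement; ", x$n_cases, " cases, ", x$n_raters,
      " raters", if (x$degenerate) "; degenerate design", ")\n", sep = "")
  invisible(x)
}

#' Bias-corrected and accelerated bootstrap interval
#'
#' B resamples with replacement; the bias correction z0 comes from the
#' fraction of resample statistics below the observed value and the
#' acceleration from jackknife skewness, with the percentile endpoints
#' adjusted accordingly (via \code{boot::boot.ci}). A degenerate resample
#' distribution (all resample statistics equal) collapses to a point
#' interval with a warning. The same seed reproduces the interval exactly.
#'
#' @param data numeric vector, length >= 8.
#' @param statistic function of a numeric vector returning a scalar.
#' @param B number of bootstrap resamples, default 1000.
#' @param level confidence level, default 0.95.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a \code{\link{stat_result}} carrying the observed statistic and
#'   the `ci` attribute-bearing interval.
#' @export
bca_bootstrap <- function(data, statistic, B = 1000L, level = 0.95,
                          seed = NULL) {
  n <- length(data)
  if (n < 8L) stop("need n >= 8", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  t0 <- statistic(data)
  bt <- boot::boot(data, function(d, i) statistic(d[i]), R = B)
  if (length(unique(bt$t)) == 1L) {
    warning("degenerate resample distribution; point interval",
            call. = FALSE)
    ci <- c(bt$t[1], bt$t[1])
  } else {
    bci <- boot::boot.ci(bt, conf = level, type = "bca")
    ci <- bci$bca[1, 4:5]
  }
  attr(ci, "level") <- level
  stat_result("BCa bootstrap", t0, ci = ci, n = n)
}
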