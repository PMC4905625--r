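test_that("Kruskal-Wallis: degenerate ties, exact hand-ranked H, errors", {
  res <- kruskal_wallis(list(c(2, 2, 2), c(2, 2), c(2, 2, 2, 2)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # no ties: H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2 = 7.2 by hand
  res2 <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(res2$statistic, 7.2)
  expect_equal(res2$df, 2)
  expect_equal(res2$p, pchisq(7.2, 2, lower.tail = FALSE))
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("Dunn post hoc: null pair, Bonferroni identity, planted shift", {
  res <- pairwise_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res$z, 0)
  expect_equal(res$p_unadjusted, 1)
  # Bonferroni = min(1, unadjusted x number of pairs)
  set.seed(1)
  gr <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  res2 <- pairwise_posthoc(gr)
  expect_equal(res2$p_bonferroni, pmin(1, res2$p_unadjusted * 3))
  # the maximally shifted pair attains the smallest p in >= 95% of seeds
  hits <- 0L
  for (s in 1:200) {
    set.seed(s)
    gr <- list(a = rnorm(15), b = rnorm(15, 1.5), c = rnorm(15, 3))
    res3 <- pairwise_posthoc(gr)
    # pair a-c spans the full 3-sigma shift
    ac <- res3$group1 == "a" & res3$group2 == "c"
    if (res3$p_unadjusted[ac] <= min(res3$p_unadjusted)) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("Kendall tau: monotone bounds, brute-force tie case, partial identity", {
  x <- c(1, 3, 5, 7, 9)
  expect_equal(kendall_tau(x, x^3)$statistic, 1)
  expect_equal(kendall_tau(x, rev(x))$statistic, -1)
  # 4 concordant and 2 discordant of the 6 pairs -> tau = 1/3
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(2, 1, 4, 3))$statistic, 1 / 3)
  expect_error(kendall_tau(c(1, 1, 1), 1:3), "constant")
  # partial tau reduces to plain tau when the control is independent
  set.seed(10)
  n <- 2000
  x <- rnorm(n); y <- x + rnorm(n); z <- rnorm(n)
  expect_lt(abs(kendall_partial(x, y, z)$statistic -
                  kendall_tau(x, y)$statistic), 0.05)
  # and shrinks toward zero when the association runs through the control
  zc <- rnorm(n); xc <- zc + 0.3 * rnorm(n); yc <- zc + 0.3 * rnorm(n)
  expect_lt(abs(kendall_partial(xc, yc, zc)$statistic),
            abs(kendall_tau(xc, yc)$statistic))
})

test_that("chi-square: null table, closed-form diagonal table, symmetry", {
  res <- chi_square(matrix(5, 2, 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  res2 <- chi_square(tab)
  expect_equal(res2$statistic, 20)  # n(ad-bc)^2 / (marginal product)
  expect_equal(res2$df, 1)
  res3 <- chi_square(t(matrix(c(8, 3, 2, 9, 5, 1), 2, 3)))
  expect_equal(chi_square(matrix(c(8, 3, 2, 9, 5, 1), 2, 3))$statistic,
               res3$statistic)
  expect_error(chi_square(matrix(c(1, 0, 2, 0), 2, 2, byrow = TRUE)),
               "marginal")
})

test_that("kappa: perfect agreement, chance level, banding, Cohen cross-check", {
  # 6 raters, 10 cases, identical labels within each case
  ratings <- matrix(rep(rep(c("A", "B", "C"), length.out = 10), 6), 10, 6)
  res <- interrater_kappa(ratings)
  expect_equal(res$kappa, 1)
  expect_equal(res$band, "very good")
  expect_equal(res$method, "Fleiss")
  # independent uniform raters agree only by chance
  set.seed(3)
  r2 <- matrix(sample(c("A", "B", "C"), 2 * 10000, replace = TRUE),
               10000, 2)
  expect_lt(abs(interrater_kappa(r2)$kappa), 0.03)
  # banding at the printed cutpoints (lower-inclusive)
  expect_equal(kappa_band(0.973), "very good")
  expect_equal(kappa_band(0.8), "very good")
  expect_equal(kappa_band(0.7999), "good")
  expect_equal(kappa_band(0.6), "good")
  expect_equal(kappa_band(0.4), "moderate")
  expect_equal(kappa_band(0.2), "fair")
  expect_equal(kappa_band(0.19), "poor")
  expect_equal(kappa_band(-0.2), "poor")
  expect_error(kappa_band(1.2), "exceed")
  # degenerate design: a single identical category everywhere
  deg <- interrater_kappa(matrix("A", 5, 3))
  expect_equal(deg$kappa, 1)
  expect_true(deg$degenerate)
})

test_that("Cohen kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(8)
  r <- matrix(sample(c("x", "y", "z"), 120, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2)), 60, 2)
  r[1:30, 2] <- r[1:30, 1]  # induce real agreement
  mine <- interrater_kappa(r)$kappa
  tab <- table(factor(r[, 1]), factor(r[, 2]))
  ref <- e1071::classAgreement(tab)$kappa
  expect_equal(mine, ref)
})

test_that("BCa bootstrap: degenerate data, symmetry, determinism", {
  expect_warning(res <- bca_bootstrap(rep(4, 10), mean, B = 100, seed = 1),
                 "degenerate")
  expect_equal(unname(res$ci[1:2]), c(4, 4))
  # symmetric data: BCa endpoints approach plain percentile endpoints
  set.seed(2)
  x <- rnorm(200)
  res2 <- bca_bootstrap(x, mean, B = 2000, seed = 5)
  set.seed(5)
  t_star <- replicate(2000, mean(sample(x, replace = TRUE)))
  perc <- quantile(t_star, c(0.025, 0.975))
  # absolute closeness on the scale of the interval half-width
  expect_lt(abs(res2$ci[1] - perc[[1]]), 0.02)
  expect_lt(abs(res2$ci[2] - perc[[2]]), 0.02)
  # same seed, same interval
  a <- bca_bootstrap(x, stats::median, B = 500, seed = 9)
  b <- bca_bootstrap(x, stats::median, B = 500, seed = 9)
  expect_identical(a$ci, b$ci)
  expect_error(bca_bootstrap(1:5, mean), "n >= 8")
})
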