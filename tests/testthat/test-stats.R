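# Statistical primitives against exhaustive-enumeration oracles and the
# base-R reference implementations (the latter as independent cross-checks).

test_that("spearman_rho matches closed forms and the permutation oracle", {
  expect_equal(spearman_rho(1:3, c(2, 4, 6))$rho, 1)
  expect_equal(spearman_rho(1:3, c(6, 4, 2))$rho, -1)
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4))$rho, 0.8)

  set.seed(11)
  for (n in c(4, 5, 6, 7)) {
    for (rep in 1:3) {
      x <- rnorm(n)
      y <- rnorm(n)
      res <- spearman_rho(x, y)
      expect_identical(res$method, "exact permutation")
      expect_equal(res$p, oracle_spearman_p(x, y), tolerance = 1e-12)
      # tied data: oracle enumerates the same mid-rank definition
      xt <- round(x)
      if (length(unique(xt)) >= 2) {
        expect_equal(spearman_rho(xt, y)$p, oracle_spearman_p(xt, y),
                     tolerance = 1e-12)
      }
    }
  }
  # cross-check against cor.test's exact mode on untied data
  set.seed(12)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(spearman_rho(x, y)$p,
               cor.test(x, y, method = "spearman", exact = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("spearman_rho is invariant under monotone transforms and flags degenerate input", {
  set.seed(21)
  x <- rexp(15)
  y <- rnorm(15)
  base <- spearman_rho(x, y)
  expect_equal(spearman_rho(log(x), y)$rho, base$rho)
  expect_equal(spearman_rho(x, y^3)$p, base$p)
  expect_warning(res <- spearman_rho(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(res$rho))
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("wilcoxon_rank_sum matches the enumeration oracle and wilcox.test", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6)$p, 0.1)
  expect_equal(wilcoxon_rank_sum(c(5, 6, 7), c(5, 6, 7))$p, 1)
  set.seed(31)
  for (rep in 1:10) {
    na <- sample(2:6, 1)
    nb <- sample(2:6, 1)
    a <- rnorm(na)
    b <- rnorm(nb)
    res <- wilcoxon_rank_sum(a, b)
    expect_identical(res$method, "exact enumeration")
    expect_equal(res$p, oracle_ranksum_p(a, b), tolerance = 1e-12)
    expect_equal(res$p, wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-10)
    # symmetry under group swap
    expect_equal(wilcoxon_rank_sum(b, a)$p, res$p)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("wilcoxon_signed_rank matches the sign-pattern oracle", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3))$p, 0.25)
  expect_equal(wilcoxon_signed_rank(c(2, -2))$p, 1)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "all differences are zero")
  set.seed(41)
  for (rep in 1:10) {
    d <- rnorm(sample(3:10, 1))
    res <- wilcoxon_signed_rank(d)
    expect_identical(res$method, "exact sign enumeration")
    expect_equal(res$p, oracle_signedrank_p(d), tolerance = 1e-12)
  }
  # untied case agrees with wilcox.test's exact mode
  set.seed(42)
  d <- rnorm(9)
  expect_equal(wilcoxon_signed_rank(d)$p, wilcox.test(d, exact = TRUE)$p.value,
               tolerance = 1e-10)
  # tied |d|: enumeration still exhaustive, matches oracle
  dt <- c(1, -1, 2, 2, -3)
  expect_equal(wilcoxon_signed_rank(dt)$p, oracle_signedrank_p(dt),
               tolerance = 1e-12)
})

test_that("fisher_exact_2x2 matches enumeration, fisher.test, and is transpose-invariant", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$odds_ratio, 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$p, 34 / 70)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))$p,
               2 / choose(20, 10))
  set.seed(51)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    res <- fisher_exact_2x2(tab)
    expect_equal(res$p, oracle_fisher_p(tab), tolerance = 1e-12)
    expect_equal(res$p, fisher.test(tab)$p.value, tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(t(tab))$p, res$p, tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 1, 2), 2)), "zero margin")
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("exact and approximate p-values agree near the crossover sizes", {
  # verified property: the maximum exact-vs-approximate gap over the full
  # null support is < 0.02 at each crossover size for untied data
  set.seed(61)
  for (rep in 1:50) {
    a <- rnorm(6); b <- rnorm(6)
    pe <- wilcoxon_rank_sum(a, b, exact_limit = 12)$p
    pa <- wilcoxon_rank_sum(a, b, exact_limit = 0)$p
    expect_lt(abs(pe - pa), 0.02)

    d <- rnorm(12)
    pe <- wilcoxon_signed_rank(d, exact_limit = 12)$p
    pa <- wilcoxon_signed_rank(d, exact_limit = 0)$p
    expect_lt(abs(pe - pa), 0.02)
  }
  for (rep in 1:50) {
    x <- rnorm(10); y <- rnorm(10)
    pe <- spearman_rho(x, y, exact_limit = 10)$p
    pa <- spearman_rho(x, y, exact_limit = 0)$p
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("loess_smooth reproduces lines exactly and tracks the direct WLS oracle", {
  x <- seq(0, 10, length.out = 25)
  expect_equal(loess_smooth(x, 2 * x, span = 0.5)$fitted, 2 * x,
               tolerance = 1e-8)
  expect_equal(loess_smooth(x, rep(3, 25), span = 0.4)$fitted, rep(3, 25))
  set.seed(71)
  xs <- sort(runif(40, 0, 2 * pi))
  ys <- sin(xs) + rnorm(40, sd = 0.2)
  fit <- loess_smooth(xs, ys, span = 0.5)
  ref <- oracle_loess_fit(xs, ys, 0.5)
  expect_lt(max(abs(fit$fitted - ref)), 1e-8)
  expect_error(loess_smooth(1:4, 1:4), "at least 5")
  expect_error(loess_smooth(1:20, rnorm(20), span = 0.05), "span too small")
})

test_that("rank-sum null p-values are uniform enough for nominal alpha", {
  # small companion to the full calibration check; 400 null replicates
  set.seed(81)
  rej <- mean(replicate(400, wilcoxon_rank_sum(rnorm(15), rnorm(15))$p < 0.05))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})
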