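# Inferential primitives: mid-p hypergeometric tests, adaptive FDR,
# empirical mid-p, Mann-Whitney.

test_that("upper-tail mid-p reproduces the printed consensus-overlap values", {
  expect_equal(midp_upper(60, 3, 1, 1), 0.025, tolerance = 1e-12)
  expect_equal(signif(midp_upper(60, 3, 11, 2), 2), 0.044)
  expect_equal(signif(midp_upper(1770, 3, 11, 1), 2), 9.3e-3)
})

test_that("one-sided mid-p matches full-support enumeration", {
  cases <- expand.grid(N = c(5, 12, 40), K = c(0, 2, 5), n = c(1, 4, 5))
  for (i in seq_len(nrow(cases))) {
    N <- cases$N[i]; K <- min(cases$K[i], N); n <- min(cases$n[i], N)
    for (k in max(0, n + K - N):min(n, K)) {
      expect_equal(midp_upper(N, K, n, k), oracle_midp(N, K, n, k, "upper"),
                   tolerance = 1e-12)
      expect_equal(midp_lower(N, K, n, k), oracle_midp(N, K, n, k, "lower"),
                   tolerance = 1e-12)
    }
  }
})

test_that("K = 0 draws give the degenerate mid-p of one half", {
  expect_equal(midp_upper(10, 0, 3, 0), 0.5)
  expect_equal(midp_upper(100, 0, 100, 0), 0.5)
})

test_that("two-tailed mid-p doubles the smaller tail, capped at one", {
  # Hypergeometric(4,2,2): P(X=1) = 2/3, both one-sided mid-p = 1/2
  expect_equal(midp_two_tailed(4, 2, 2, 1), 1.0)
  # Hypergeometric(10,4,3): P(X=3) = 1/30, upper mid-p = 1/60
  expect_equal(midp_two_tailed(10, 4, 3, 3), 2 / 60, tolerance = 1e-12)
  # degenerate distribution: K = N forces X = n
  expect_equal(midp_two_tailed(5, 5, 3, 3), 1.0)
})

test_that("mid-p never exceeds the conventional exact p", {
  set.seed(11)
  for (rep in 1:200) {
    N <- sample(2:80, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    supp <- max(0, n + K - N):min(n, K)
    k <- supp[sample(length(supp), 1)]
    conv <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    mp <- midp_upper(N, K, n, k)
    expect_lte(mp, conv + 1e-12)
    expect_gt(mp, 0)
    expect_lte(mp, 1)
  }
})

test_that("hypergeometric PMF sums to one over its support", {
  set.seed(5)
  for (rep in 1:50) {
    N <- sample(2:60, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    expect_equal(sum(oracle_hyper_pmf(N, K, n)), 1, tolerance = 1e-12)
  }
})

test_that("invalid hypergeometric parameters are rejected by name", {
  expect_error(midp_upper(10, 12, 3, 1), "K exceeds population")
  expect_error(midp_upper(10, 4, 12, 1), "n exceed population")
  expect_error(midp_upper(10, 4, 3, 4), "k exceeds draws")
  expect_error(midp_upper(10, 2, 3, 3), "k exceeds successes")
  expect_error(midp_upper(4, 3, 3, 0), "support")
})

test_that("two-stage step-up FDR matches an independent reference", {
  expect_equal(bky_fdr(1.0), 1.0)
  expect_equal(bky_fdr(c(0.01, 0.01, 0.01)), oracle_bky(c(0.01, 0.01, 0.01)))
  expect_equal(length(unique(bky_fdr(c(0.01, 0.01, 0.01)))), 1L)
  set.seed(42)
  for (rep in 1:200) {
    m <- sample(c(1, 2, 5, 60), 1)
    p <- runif(m)
    expect_equal(bky_fdr(p), oracle_bky(p), tolerance = 1e-12)
  }
})

test_that("FDR adjustment is permutation-equivariant", {
  set.seed(9)
  p <- runif(60)
  perm <- sample(60)
  expect_equal(bky_fdr(p)[perm], bky_fdr(p[perm]))
})

test_that("adjusted q can undershoot BH when few nulls remain", {
  p <- c(rep(1e-5, 8), 0.04)
  expect_true(all(bky_fdr(p) <= p.adjust(p, "BH")))
  expect_error(bky_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("Bonferroni cutoff is alpha over the family size", {
  expect_equal(signif(bonferroni_cutoff(1770, 0.05), 2), 2.8e-5)
  expect_equal(bonferroni_cutoff(60, 0.05), 0.05 / 60)
  expect_equal(bonferroni_cutoff(1, 0.05), 0.05)
  expect_error(bonferroni_cutoff(0, 0.05), "positive integer")
})

test_that("empirical mid-p agrees with closed form on exact nulls", {
  # two-point null {0: 1/2, 1: 1/2}
  null <- c("0" = 0.5, "1" = 0.5)
  expect_equal(discrete_midp(null, 1, "upper", n_total = 100)$p, 0.25)
  expect_equal(discrete_midp(null, 0, "upper", n_total = 100)$p, 0.75)
  # observed at either point of a symmetric two-point null: the smaller
  # tail is 0.25, so doubling gives 0.5
  expect_equal(discrete_midp(null, 1, "two", n_total = 100)$p, 0.5)
  # null symmetric around the observed mode: both tails 0.5, capped at 1
  sym <- c("0" = 0.25, "1" = 0.5, "2" = 0.25)
  expect_equal(discrete_midp(sym, 1, "two", n_total = 100)$p, 1.0)
  # fully enumerated Poisson-binomial null equals closed-form mid-p
  probs <- c(0.3, 0.6, 0.8)
  pmf <- oracle_poisbin_pmf(probs)
  for (obs in 0:3) {
    upper <- sum(pmf[as.numeric(names(pmf)) > obs]) + 0.5 * pmf[[as.character(obs)]]
    expect_equal(discrete_midp(pmf, obs, "upper", n_total = 1e6)$p, upper,
                 tolerance = 1e-12)
  }
})

test_that("observations beyond the simulated support return the resolution bound", {
  sims <- rep(c(2, 3, 4), c(10, 80, 10))
  r <- discrete_midp(sims, 9, "upper")
  expect_true(r$upper_bound)
  expect_equal(r$p, 1 / 100)
  r2 <- discrete_midp(sims, 3, "two")
  expect_false(r2$upper_bound)
  expect_error(discrete_midp(numeric(0), 1), "empty")
})

test_that("Mann-Whitney is exact for small samples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2 of C(6,3)=20 arrangements as extreme
  r <- mann_whitney(1, 2)
  expect_equal(r$U, 0)
  expect_equal(r$p, 1.0)
  expect_equal(mann_whitney(c(1, 2), c(1, 2))$p, 1.0)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney agrees with wilcox.test where both are exact", {
  set.seed(3)
  for (rep in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    ours <- mann_whitney(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("large-sample Mann-Whitney detects a clear shift", {
  set.seed(8)
  a <- rpois(40, 9); b <- rpois(40, 3)
  r <- mann_whitney(a, b)
  expect_match(r$method, "normal")
  expect_lt(r$p, 1e-6)
  # identical large samples: no evidence
  expect_gt(mann_whitney(rep(1:5, 10), rep(1:5, 10))$p, 0.9)
})
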