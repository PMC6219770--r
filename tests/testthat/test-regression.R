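test_that("univariate regression matches closed-form least squares", {
  # exact line: slope 2, R = 1, zero-width CI (lm warns on the perfect fit)
  fit <- suppressWarnings(univariate_regression(2 * (1:5), 1:5))
  expect_equal(fit$beta, 2)
  expect_equal(fit$R, 1)
  expect_equal(fit$beta_ci[1], fit$beta_ci[2])
  expect_equal(fit$p, 0)

  # hand-computed: x = {1,2,3}, y = {1,3,2} -> beta = 0.5, R = 0.5
  fit2 <- univariate_regression(c(1, 3, 2), c(1, 2, 3))
  expect_equal(fit2$beta, 0.5)
  expect_equal(fit2$R, 0.5)

  # R^2 equals squared Pearson correlation for random data
  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(15); y <- 0.4 * x + rnorm(15)
    expect_equal(univariate_regression(y, x)$R^2, cor(x, y)^2,
                 tolerance = 1e-12)
  }

  expect_error(univariate_regression(rnorm(5), rep(3, 5)), "zero variance")
  expect_error(univariate_regression(rnorm(2), rnorm(2)), "at least 3")
})

test_that("slope confidence intervals achieve nominal coverage", {
  set.seed(72)
  n <- 20; beta_true <- 1.5
  covered <- logical(1000)
  for (i in seq_along(covered)) {
    x <- rnorm(n)
    y <- 2 + beta_true * x + rnorm(n)
    ci <- univariate_regression(y, x)$beta_ci
    covered[i] <- ci[1] <= beta_true && beta_true <= ci[2]
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("stepwise selection keeps strong candidates and drops duplicates", {
  set.seed(73)
  n <- 29
  x <- rnorm(n)
  y <- 4 + 1.2 * x + rnorm(n, 0, 0.8)
  res <- stepwise_multivariate(y, data.frame(A = x))
  expect_identical(res$status[res$predictor == "A"], "In")
  expect_lt(res$multi_p[res$predictor == "A"], 0.05)

  # exact duplicate of an earlier candidate is dropped as functionally
  # dependent: the original goes In, the copy stays Out
  expect_warning(
    res2 <- stepwise_multivariate(y, data.frame(A = x, A_copy = x)),
    "functionally dependent")
  expect_identical(res2$status[res2$predictor == "A"], "In")
  expect_identical(res2$status[res2$predictor == "A_copy"], "Out")

  # an affine rescaling (a rate and its monthly version) is also dependent
  expect_warning(
    res3 <- stepwise_multivariate(y, data.frame(A = x, A_monthly = x / 12)),
    "functionally dependent")
  expect_identical(res3$status[res3$predictor == "A_monthly"], "Out")
})

test_that("stepwise selection is consistent over repeated simulations", {
  n <- 29
  a_in <- b_out <- logical(100)
  for (s in seq_along(a_in)) {
    set.seed(1000 + s)
    A <- rnorm(n); B <- rnorm(n)
    y <- 2 + 1 * A + rnorm(n, 0, 0.8)
    res <- stepwise_multivariate(y, data.frame(A = A, B = B))
    a_in[s] <- res$status[res$predictor == "A"] == "In"
    b_out[s] <- res$status[res$predictor == "B"] == "Out"
  }
  expect_gte(sum(a_in), 95)
  expect_gte(sum(b_out), 85)
})

test_that("no predictor is reported In with a final p above p_remove", {
  set.seed(74)
  for (i in 1:25) {
    n <- 25
    X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    y <- 0.5 * X$a + 0.3 * X$b + rnorm(n)
    res <- suppressWarnings(stepwise_multivariate(y, X))
    in_rows <- res[res$status == "In", ]
    if (nrow(in_rows)) expect_true(all(in_rows$multi_p <= 0.10))
  }
})

test_that("visit-wise summaries report means, SDs and paired tests", {
  # constant cohort: identical means, all p = 1
  df <- make_cohort_df(sprintf("c%d", 1:6), VISIT_LABELS,
                       c(0, 1, 3, 6, 20),
                       matrix(64, 5, 6))
  vs <- visitwise_summary(df, "RNFL.G")
  expect_equal(vs$mean, rep(64, 5))
  expect_equal(vs$sd, rep(0, 5))
  expect_equal(vs$p_vs_base[-1], rep(1, 4))
  expect_equal(vs$p_vs_prev[-1], rep(1, 4))

  # built-in +5.6 um swelling at 1 month shows up at large n
  sim <- generate_cohort(cohort_config(n_subjects = 500L), seed = 81)
  vs2 <- visitwise_summary(sim$cohort, "RNFL.G")
  swell <- vs2$mean[vs2$visit == "1pv"] - vs2$mean[vs2$visit == "base"]
  # expected difference = swelling (5.6) plus one month of the thinning
  # trend (-2.8/12); allow ~3 SE of Monte-Carlo error on top
  expect_lt(abs(swell - (5.6 - 2.8 / 12)), 0.6)
  expect_lt(vs2$p_vs_base[vs2$visit == "1pv"], 1e-6)
})
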