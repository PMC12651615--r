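test_that("Beta-Bernoulli predictive equals (alpha + k)/(alpha + beta + t)", {
  expect_equal(bernoulli_predictive(beta_bernoulli_state(1, 1)), 0.5)
  expect_equal(bernoulli_predictive(beta_bernoulli_state(1, 1, k = 2L, t = 4L)),
               0.5)
  st <- beta_bernoulli_state(2, 6, k = 3L, t = 10L)
  expect_equal(bernoulli_predictive(st), 5 / 18)
  # the predictive is the mean of the posterior Beta(5, 13): Monte-Carlo
  # oracle within 3 MC standard errors
  set.seed(99)
  draws <- rbeta(2e5, 2 + 3, 6 + 7)
  expect_lt(abs(bernoulli_predictive(st) - mean(draws)),
            3 * sd(draws) / sqrt(length(draws)))
})

test_that("binary updates carry counts and respect exchangeability", {
  st <- update_bernoulli(beta_bernoulli_state(1, 1), 1)
  expect_equal(st$k, 1L)
  expect_equal(st$t, 1L)
  expect_equal(st$alpha, 1)  # hyperparameters unchanged; counts separate
  expect_equal(bernoulli_predictive(st), 2 / 3)

  a <- update_bernoulli(update_bernoulli(beta_bernoulli_state(2, 3), 0), 1)
  b <- update_bernoulli(update_bernoulli(beta_bernoulli_state(2, 3), 1), 0)
  expect_equal(bernoulli_predictive(a), bernoulli_predictive(b))

  st <- beta_bernoulli_state(1, 1)
  for (i in 1:28) st <- update_bernoulli(st, 0)
  expect_equal(bernoulli_predictive(st), 1 / 30)

  expect_error(update_bernoulli(st, 2), "0 or 1")
  expect_error(update_bernoulli(st, NA), "0 or 1")
})

test_that("sequential and batch updates agree to 1e-12 for both conjugate models", {
  set.seed(31)
  for (rep in 1:10) {
    x <- rbinom(25, 1, runif(1))
    seq_st <- beta_bernoulli_state(1.5, 2.5)
    for (xi in x) seq_st <- update_bernoulli(seq_st, xi)
    batch_st <- beta_bernoulli_state(1.5, 2.5, k = sum(x), t = length(x))
    expect_equal(bernoulli_predictive(seq_st), bernoulli_predictive(batch_st),
                 tolerance = 1e-12)

    y <- pmax(0, rnorm(25, 7, 1.5))
    seq_ns <- normal_mean_state(7, 100, obs_var = 2.25)
    for (yi in y) seq_ns <- update_normal_mean(seq_ns, yi)
    batch_ns <- normal_mean_state(7, 100, obs_var = 2.25,
                                  n = length(y), sum_obs = sum(y))
    ps <- dsurprisal:::normal_posterior(seq_ns)
    pb <- dsurprisal:::normal_posterior(batch_ns)
    expect_equal(ps$mu, pb$mu, tolerance = 1e-12)
    expect_equal(ps$pred_var, pb$pred_var, tolerance = 1e-12)
  }
})

test_that("Normal mean update matches a grid-posterior oracle", {
  st <- update_normal_mean(normal_mean_state(7, 100, obs_var = 2.25), 8)
  post <- dsurprisal:::normal_posterior(st)
  # closed form: precision-weighted combination of prior and observation
  expect_equal(post$mu, (7 / 100 + 8 / 2.25) / (1 / 100 + 1 / 2.25),
               tolerance = 1e-12)
  # independent oracle: discretise the posterior density on a fine grid
  grid <- seq(-20, 40, by = 1e-3)
  w <- dnorm(8, grid, 1.5) * dnorm(grid, 7, 10)
  expect_equal(post$mu, sum(grid * w) / sum(w), tolerance = 1e-4)

  expect_error(update_normal_mean(st, -1), "non-negative")
})

test_that("posterior variance of the mean strictly decreases with data", {
  st <- normal_mean_state(7, 100, obs_var = 2.25)
  vars <- numeric(5)
  for (i in 1:5) {
    st <- update_normal_mean(st, 7 + i / 10)
    vars[i] <- dsurprisal:::normal_posterior(st)$var_mu
  }
  expect_true(all(diff(c(100, vars)) < 0))
})

test_that("a diffuse prior washes out: posterior mean tends to the sample mean", {
  y <- c(5, 6.5, 8, 7.25)
  st <- normal_mean_state(7, 1e10, obs_var = 2.25,
                          n = length(y), sum_obs = sum(y))
  expect_equal(dsurprisal:::normal_posterior(st)$mu, mean(y),
               tolerance = 1e-6)
})

test_that("half-integer discretisation matches the Normal CDF oracle", {
  d <- discretize_predictive(7, 1)
  # before truncation renormalisation the mass at z = 8 is Phi(1.5) - Phi(0.5)
  raw8 <- pnorm(1.5) - pnorm(0.5)
  total <- pnorm((24.5 - 7) / 1) - pnorm((-0.5 - 7) / 1)
  expect_equal(d$mass[d$support == 8], raw8 / total, tolerance = 1e-12)
  expect_equal(sum(d$mass), 1, tolerance = 1e-9)

  tight <- discretize_predictive(7, 0.1)
  expect_gt(tight$mass[tight$support == 7], 0.999)

  expect_error(discretize_predictive(7, 1, z_min = 10, z_max = 5), "z_min")
})

test_that("sleep reports are rounded half-up before scoring", {
  st <- normal_mean_state(7, 100, obs_var = 2.25, n = 3L, sum_obs = 21)
  expect_equal(sleep_surprisal(8.4, st), sleep_surprisal(8, st))
  expect_equal(sleep_surprisal(7.5, st), sleep_surprisal(8, st))  # half-up
  tight <- normal_mean_state(7, 1e-4, obs_var = 1e-4)
  expect_lt(sleep_surprisal(7, tight), 1e-6)

  # mu = 7, sigma = 1 predictive: surprisal of an 8-hour report is the
  # negative log of the renormalised CDF-difference mass
  one <- structure(list(mu_prior = 7, var_prior = 1e-12, obs_var = 1 - 1e-12,
                        n = 0L, sum_obs = 0, z_min = 0L, z_max = 24L),
                   class = "normal_mean_state")
  d <- dsurprisal:::sleep_predictive(one)
  expect_equal(sleep_surprisal(8, one), -log(d$mass[d$support == 8]))
})

test_that("far-tail sleep reports warn and return a large finite surprisal", {
  tight <- normal_mean_state(7, 1e-6, obs_var = 1e-6)
  expect_warning(s <- sleep_surprisal(23, tight), "underflow")
  expect_true(is.finite(s) && s > 100)
})

test_that("dynamic surprisal converges toward the static benchmark within four weeks", {
  # 200 participants simulated from each model family: the mean absolute
  # dynamic-static gap must shrink from week 1 to week 4
  set.seed(202)
  gap_ex <- matrix(0, 200, 28)
  gap_sl <- matrix(0, 200, 28)
  for (i in 1:200) {
    p <- rbeta(1, 2, 6)
    x <- rbinom(28, 1, p)
    dyn <- run_prequential(x, beta_bernoulli_state(1, 1))
    sta <- static_reference(x, "exercise")
    gap_ex[i, ] <- abs(dyn$surprisal - sta$surprisal$surprisal)

    mu <- rnorm(1, 7, 1)
    y <- round(pmax(0, rnorm(28, mu, 1)))
    dyn <- run_prequential(y, normal_mean_state(7, 100, obs_var = 1))
    sta <- static_reference(y, "sleep")
    gap_sl[i, ] <- abs(dyn$surprisal - sta$surprisal$surprisal)
  }
  expect_lt(mean(gap_ex[, 22:28]), mean(gap_ex[, 1:7]))
  expect_lt(mean(gap_sl[, 22:28]), mean(gap_sl[, 1:7]))
})
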