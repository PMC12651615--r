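test_that("uninformative priors are the documented constants", {
  ex <- uninformative_prior("exercise")
  expect_equal(ex$parameters$alpha, 1)
  expect_equal(ex$parameters$beta, 1)
  expect_equal(bernoulli_predictive(ex$parameters), 0.5)

  sl <- uninformative_prior("sleep")
  expect_equal(sl$parameters$mu_prior, 7)
  expect_equal(sl$parameters$var_prior, 100)
  expect_equal(sqrt(sl$parameters$var_prior), 10)  # prior SD 10 h

  st <- uninformative_prior("stress")
  expect_equal(st$parameters$shape_prior, c(2, 0.1))
  expect_equal(st$parameters$rate_prior, c(2, 0.1))
  expect_equal(st$parameters$hurdle_alpha, 1)

  expect_error(uninformative_prior("caffeine"))
})

test_that("Beta moment matching inverts the uniform and reproduces input moments", {
  mm <- dsurprisal:::beta_moment_match(0.5, 1 / 12)
  expect_equal(mm$alpha, 1)
  expect_equal(mm$beta, 1)

  set.seed(9)
  for (rep in 1:20) {
    m <- runif(1, 0.05, 0.95)
    v <- runif(1, 0.1, 0.9) * m * (1 - m)
    mm <- dsurprisal:::beta_moment_match(m, v)
    a <- mm$alpha; b <- mm$beta
    expect_equal(a / (a + b), m, tolerance = 1e-12)
    expect_equal(a * b / ((a + b)^2 * (a + b + 1)), v, tolerance = 1e-12)
  }
})

test_that("degenerate exercise rates take the mean-matched fallback with a warning", {
  expect_warning(spec <- empirical_prior_exercise(c(0.25, 0.25, 0.25)),
                 "infeasible")
  expect_equal(bernoulli_predictive(spec$parameters), 0.25)
  expect_equal(spec$parameters$alpha + spec$parameters$beta, 2)

  expect_error(empirical_prior_exercise(0.5), "at least 2")
  expect_error(empirical_prior_exercise(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("empirical sleep prior uses between/within variance decomposition", {
  rec <- data.frame(participant_id = rep(c("a", "b"), each = 3),
                    sleep_hours = c(6, 7, 8, 7, 8, 9))  # means 7 and 8
  spec <- empirical_prior_sleep(rec)
  expect_equal(spec$parameters$mu_prior, 7.5)
  expect_equal(spec$parameters$var_prior, 0.5)          # sample variance
  expect_equal(spec$parameters$obs_var, 1)              # pooled within

  # homogeneous cohort: zero between-person variance floored at 0.25
  rec2 <- data.frame(participant_id = rep(c("a", "b"), each = 2),
                     sleep_hours = c(7, 8, 7, 8))
  spec2 <- empirical_prior_sleep(rec2)
  expect_equal(spec2$parameters$var_prior, 0.25)

  expect_error(empirical_prior_sleep(
    data.frame(participant_id = "a", sleep_hours = c(7, 8))), "at least 2")
})

test_that("sleep variance components are recovered from a simulated cohort", {
  d <- simulate_cohort(cohort_config(n_participants = 100, n_days = 28,
                                     seed = 21, sleep_between_sd = 1,
                                     sleep_within_sd = 1))
  spec <- empirical_prior_sleep(d)
  # integer rounding adds ~1/12 to the within-person variance and the
  # between-person variance of means picks up within/n_days
  expect_lt(abs(spec$parameters$obs_var - (1 + 1 / 12)), 0.1 * (1 + 1 / 12))
  expect_lt(abs(spec$parameters$var_prior - 1), 0.25)
})

test_that("Gamma MLE recovers parameters and matches a grid-search oracle", {
  set.seed(33)
  x <- rgamma(5000, 2, 0.1)
  fit <- gamma_mle(x)
  expect_lt(abs(fit$shape - 2) / 2, 0.05)
  expect_lt(abs(fit$rate - 0.1) / 0.1, 0.05)

  # small-sample oracle: profile the rate and scan the shape on a fine grid
  set.seed(34)
  for (rep in 1:5) {
    y <- rgamma(sample(5:30, 1), runif(1, 0.5, 5), runif(1, 0.1, 2))
    fit <- gamma_mle(y)
    shapes <- seq(fit$shape * 0.5, fit$shape * 2, length.out = 4000)
    grid_ll <- vapply(shapes, function(a)
      sum(dgamma(y, shape = a, rate = a / mean(y), log = TRUE)), numeric(1))
    expect_gte(fit$loglik, max(grid_ll) - 1e-4)
  }

  # cross-check against an independent fitter
  set.seed(35)
  w <- rgamma(300, 2.4, 0.7)
  fit <- gamma_mle(w)
  ref <- fitdistrplus::fitdist(w, "gamma")
  expect_equal(fit$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$rate, unname(ref$estimate["rate"]), tolerance = 1e-3)
  expect_gte(fit$loglik, ref$loglik - 1e-8)  # Newton lands at least as high

  # two distinct values: fitted mean equals the sample mean (first-order
  # condition of the MLE)
  fit <- gamma_mle(c(1, 4))
  expect_equal(fit$shape / fit$rate, 2.5, tolerance = 1e-8)

  expect_error(gamma_mle(c(3, 3, 3)), "degenerate")
  expect_error(gamma_mle(c(1, -1)), "positive")
  expect_error(gamma_mle(2), "at least 2")
})

test_that("empirical stress prior centres hyperpriors on the leave-one-out MLEs", {
  set.seed(44)
  vals <- rgamma(400, 2, 0.1)
  spec <- empirical_prior_stress(vals, loo_zero_rates = c(0.2, 0.3, 0.4),
                                 cv = 0.5)
  mle <- gamma_mle(vals)
  pr <- spec$parameters
  expect_equal(pr$shape_prior[1] / pr$shape_prior[2], mle$shape,
               tolerance = 1e-10)  # hyperprior mean = MLE
  expect_equal(pr$rate_prior[1] / pr$rate_prior[2], mle$rate,
               tolerance = 1e-10)
  expect_equal(1 / sqrt(pr$shape_prior[1]), 0.5)  # hyperprior CV
  # hurdle Beta moment-matched to the zero rates
  expect_equal(pr$hurdle_alpha / (pr$hurdle_alpha + pr$hurdle_beta), 0.3,
               tolerance = 1e-10)

  expect_error(empirical_prior_stress(rgamma(5, 2, 1), c(0.2, 0.3)),
               "at least 10")
})

test_that("a participant's own data never enters their empirical prior", {
  d <- small_cohort(n = 8, seed = 61)
  target <- "P003"
  perturbed <- d
  rows <- perturbed$participant_id == target
  perturbed$exercise[rows] <- 1
  perturbed$sleep_hours[rows] <- 12
  perturbed$stress[rows] <- 55
  for (v in c("exercise", "sleep", "stress")) {
    p1 <- prior_for(d, v, "empirical", target_id = target)
    p2 <- prior_for(perturbed, v, "empirical", target_id = target)
    expect_equal(p1$parameters, p2$parameters)
  }
  # but the prior does change when someone else's data changes
  other <- d
  other$exercise[other$participant_id == "P001"] <- 1
  p3 <- prior_for(other, "exercise", "empirical", target_id = target)
  p1 <- prior_for(d, "exercise", "empirical", target_id = target)
  expect_false(isTRUE(all.equal(p1$parameters, p3$parameters)))
})
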