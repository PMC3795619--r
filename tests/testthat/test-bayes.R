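test_that("the default asymptotic-size prior has natural-scale mean 77 cm", {
  pr <- growth_priors()
  analytic_mean <- exp(pr$w_inf_meanlog + pr$w_inf_sdlog^2 / 2)
  expect_equal(analytic_mean, 77, tolerance = 1e-12)
  # Monte-Carlo cross-check
  set.seed(1234)
  draws <- rlnorm(1e6, pr$w_inf_meanlog, pr$w_inf_sdlog)
  expect_equal(mean(draws), 77, tolerance = 0.01)
  # alternative parameterization: 77 is the natural-scale median
  pr_log <- growth_priors(mean_scale = "log")
  expect_equal(exp(pr_log$w_inf_meanlog), 77, tolerance = 1e-12)
})

test_that("prior densities integrate to one and log_prior matches closed forms", {
  pr <- growth_priors()
  # numeric normalization spot-checks
  expect_equal(integrate(dlnorm, 0, Inf, meanlog = pr$w_inf_meanlog,
                         sdlog = pr$w_inf_sdlog)$value, 1, tolerance = 1e-6)
  expect_equal(integrate(dbeta, 0, 1, shape1 = pr$k_shape1,
                         shape2 = pr$k_shape2)$value, 1, tolerance = 1e-6)
  inv_gamma_dens <- function(x) {
    pr$var_rate^pr$var_shape / gamma(pr$var_shape) *
      x^(-pr$var_shape - 1) * exp(-pr$var_rate / x)
  }
  expect_equal(integrate(inv_gamma_dens, 0, Inf, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-4)

  # support violations map to -Inf
  expect_identical(log_prior(77, 1.2, 25, pr), -Inf)
  expect_identical(log_prior(-5, 0.12, 25, pr), -Inf)
  expect_identical(log_prior(77, 0.12, -1, pr), -Inf)

  # finite value matches an independent evaluation of the three densities
  manual <- dlnorm(77, pr$w_inf_meanlog, pr$w_inf_sdlog, log = TRUE) +
    dbeta(0.119, pr$k_shape1, pr$k_shape2, log = TRUE) +
    log(inv_gamma_dens(25))
  expect_equal(log_prior(77, 0.119, 25, pr), manual, tolerance = 1e-10)
})

test_that("the Gaussian log likelihood obeys closed form, additivity and tails", {
  d1 <- data.frame(age = 5,
                   disc_width = 100 - (100 - 20) * exp(-0.2 * 5))
  expect_equal(log_likelihood(100, 0.2, 1, d1$age, d1$disc_width, w0 = 20),
               -0.5 * log(2 * pi), tolerance = 1e-12)

  tpl <- species_template("s", w_inf = 100, k = 0.2, w0 = 20,
                          age_min = 1, age_max = 15, n = 30, noise_sd = 3)
  d <- generate_sample(tpl, seed = 4)
  ll1 <- log_likelihood(100, 0.2, 9, d$age, d$disc_width, w0 = 20)
  ll2 <- log_likelihood(100, 0.2, 9, rep(d$age, 2), rep(d$disc_width, 2),
                        w0 = 20)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)

  # with nonzero residuals the likelihood falls monotonically as sigma2 -> 0
  lls <- vapply(c(1e-2, 1e-4, 1e-6), function(s2) {
    log_likelihood(100, 0.2, s2, d$age, d$disc_width, w0 = 20)
  }, 0)
  expect_true(all(diff(lls) < 0))
  expect_identical(log_likelihood(100, 0.2, 0, d$age, d$disc_width, 20), -Inf)
})

test_that("MCMC configuration accounting and presets are consistent", {
  cfg <- mcmc_config(2e6, 1e5, 100, seed = 1)
  expect_equal(cfg$retained, 19000L)
  expect_equal(mcmc_preset("full")$retained, 19000L)
  expect_equal(mcmc_preset("desk")$retained, 9000L)
  expect_equal(mcmc_preset("sim")$retained, 4500L)
  expect_error(mcmc_config(1e4, 2e4, 10), "iterations > burn_in")
  expect_error(mcmc_config(2e4, 1e4, 100), "1000 draws")
})

test_that("the sampler is reproducible bit-for-bit given seed, config and data", {
  tpl <- species_template("s", w_inf = 90, k = 0.2, w0 = 20,
                          age_min = 1, age_max = 15, n = 40, noise_sd = 3)
  d <- generate_sample(tpl, seed = 5)
  cfg <- mcmc_config(4e4, 4e3, 10, seed = 99)
  b1 <- fit_growth_bayes(d, w0 = 20, config = cfg)
  b2 <- fit_growth_bayes(d, w0 = 20, config = cfg)
  expect_identical(b1$draws, b2$draws)
  expect_identical(b1$acceptance_rate, b2$acceptance_rate)
  b3 <- fit_growth_bayes(d, w0 = 20, config = mcmc_config(4e4, 4e3, 10,
                                                          seed = 100))
  expect_false(identical(b1$draws, b3$draws))
  # draws respect the parameter supports
  expect_true(all(b1$draws[, "w_inf"] > 0))
  expect_true(all(b1$draws[, "k"] > 0 & b1$draws[, "k"] < 1))
  expect_true(all(b1$draws[, "sigma2"] > 0))
  expect_true(b1$acceptance_rate > 0 && b1$acceptance_rate < 1)
})

test_that("posterior recovery on synthetic 2VBGF data (n = 500)", {
  tpl <- species_template("s", w_inf = 100, k = 0.2, w0 = 20,
                          age_min = 1, age_max = 20, n = 500, noise_sd = 3)
  d <- generate_sample(tpl, seed = 6)
  b <- fit_growth_bayes(d, w0 = 20, config = mcmc_preset("desk", seed = 7))
  s <- summarize_posterior(b)
  med <- setNames(s$median, s$parameter)
  expect_gt(med[["w_inf"]], 95)
  expect_lt(med[["w_inf"]], 105)
  expect_gt(med[["k"]], 0.18)
  expect_lt(med[["k"]], 0.22)
  # credibility intervals bracket the generating values
  expect_true(s$lower[s$parameter == "w_inf"] < 100 &&
                s$upper[s$parameter == "w_inf"] > 100)
  expect_true(s$lower[s$parameter == "k"] < 0.2 &&
                s$upper[s$parameter == "k"] > 0.2)
})

test_that("with uninformative data the posterior reproduces the priors", {
  # huge residual scatter: the likelihood is nearly flat over the prior's
  # support, so the chain should return the priors
  pr <- growth_priors()
  d <- data.frame(age = c(1, 2, 3, 4, 5),
                  disc_width = c(500, 30, 800, 200, 650))
  b <- fit_growth_bayes(d, w0 = 20, priors = pr,
                        config = mcmc_config(2e5, 2e4, 20, seed = 11))
  q <- apply(b$draws, 2, quantile, c(0.25, 0.5, 0.75))
  q_prior_w <- qlnorm(c(0.25, 0.5, 0.75), pr$w_inf_meanlog, pr$w_inf_sdlog)
  q_prior_k <- qbeta(c(0.25, 0.5, 0.75), pr$k_shape1, pr$k_shape2)
  expect_equal(unname(q[, "w_inf"]), q_prior_w, tolerance = 0.1)
  expect_equal(unname(q[, "k"]), q_prior_k, tolerance = 0.1)
})

test_that("a least-squares k above 1/yr triggers the truncation warning", {
  # very fast growth: NLS k > 1, the Beta prior truncates k to (0, 1)
  tpl <- species_template("fast", w_inf = 40, k = 1.3, w0 = 15,
                          age_min = 0.5, age_max = 8, n = 60, noise_sd = 1)
  d <- generate_sample(tpl, seed = 13)
  expect_warning(
    fit_growth_bayes(d, w0 = 15, config = mcmc_config(3e4, 3e3, 20, seed = 14)),
    "truncates")
})

test_that("Geweke diagnostic behaves on constant, stationary and trending chains", {
  expect_error(geweke_z(rep(5, 5000)), "zero-variance")
  expect_error(geweke_z(rnorm(50)), "too short")
  set.seed(21)
  z <- geweke_z(rnorm(10000))
  expect_lt(abs(z), 3)
  # a deterministic trend is flagged far beyond the 1.96 threshold
  expect_gt(abs(geweke_z(seq(0, 1, length.out = 10000))), 10)
})

test_that("posterior summaries are empirical quantiles with sane ordering", {
  expect_error(summarize_posterior(matrix(rnorm(300), ncol = 3)), "1000")
  s <- summarize_posterior(matrix(5, nrow = 1500, ncol = 2,
                                  dimnames = list(NULL, c("a", "b"))))
  expect_equal(s$median, c(5, 5))
  expect_equal(s$lower, c(5, 5))
  expect_equal(s$upper, c(5, 5))
  set.seed(31)
  u <- matrix(runif(1e5), dimnames = list(NULL, "u"))
  s2 <- summarize_posterior(u)
  expect_lt(abs(s2$median - 0.5), 0.005)
  expect_lt(abs(s2$lower - 0.025), 0.005)
  expect_lt(abs(s2$upper - 0.975), 0.005)
})

test_that("95% credibility intervals for k attain nominal coverage", {
  # 100 simulated data sets (n = 50); the interval should cover the
  # generating k in 90-99 of them
  tpl <- species_template("cov", w_inf = 100, k = 0.12, w0 = 20,
                          age_min = 1, age_max = 20, n = 50, noise_sd = 4)
  hits <- 0L
  for (r in 1:100) {
    d <- generate_sample(tpl, seed = 5000 + r)
    b <- fit_growth_bayes(d, w0 = 20,
                          config = mcmc_config(25000, 5000, 10,
                                               seed = 6000 + r))
    s <- summarize_posterior(b)
    k_row <- s[s$parameter == "k", ]
    if (k_row$lower <= 0.12 && k_row$upper >= 0.12) hits <- hits + 1L
  }
  expect_gte(hits, 90)
  expect_lte(hits, 99)
})
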