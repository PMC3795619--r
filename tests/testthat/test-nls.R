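test_that("AICc matches its closed form and guards its domain", {
  # n log(rss/n) + 2p + 2p(p+1)/(n-p-1)
  expect_equal(aicc(rss = 80, n = 20, p = 3), 20 * log(4) + 6 + 1.5,
               tolerance = 1e-12)
  expect_equal(aicc(rss = 80, n = 20, p = 3), 35.226, tolerance = 1e-3)
  expect_equal(aicc(rss = 20, n = 20, p = 3), 7.5, tolerance = 1e-12)
  expect_error(aicc(rss = 10, n = 4, p = 3), "exceed")
  expect_error(aicc(rss = 0, n = 20, p = 3), "positive")
  # strictly increasing in p at fixed rss and n
  vals <- vapply(2:6, function(p) aicc(80, 20, p), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("noise-free 2VBGF data are recovered to numerical precision", {
  d <- exact_vbgf2()
  f <- fit_growth(d, model = "vbgf2", w0 = 20)
  expect_true(f$converged)
  expect_lt(f$rss, 1e-6)
  expect_equal(f$params$w_inf, 100, tolerance = 1e-4)
  expect_equal(f$params$k, 0.2, tolerance = 1e-4)
})

test_that("noisy 2VBGF data are recovered within 5% at n = 100", {
  tpl <- species_template("sim", w_inf = 100, k = 0.2, w0 = 20,
                          age_min = 1, age_max = 15, n = 100, noise_sd = 2)
  d <- generate_sample(tpl, seed = 42)
  f <- fit_growth(d, model = "vbgf2", w0 = 20)
  expect_true(f$converged)
  expect_lt(abs(f$params$w_inf - 100) / 100, 0.05)
  expect_lt(abs(f$params$k - 0.2) / 0.2, 0.05)

  # cross-check against an independent optimizer (Gauss-Newton via nls)
  ref <- stats::nls(disc_width ~ w_inf * (1 - ((w_inf - 20) / w_inf) *
                                            exp(-k * age)),
                    data = d, start = list(w_inf = 110, k = 0.15))
  expect_equal(f$params$w_inf, coef(ref)[["w_inf"]], tolerance = 1e-3)
  expect_equal(f$params$k, coef(ref)[["k"]], tolerance = 1e-3)
})

test_that("degenerate designs are rejected", {
  d <- data.frame(age = c(5, 5, 5, 5, 5, 5), disc_width = c(50, 52, 51, 49, 50, 53))
  expect_error(fit_growth(d, model = "vbgf2", w0 = 20), "span")
  expect_error(fit_growth(exact_vbgf2(ages = 1:3), model = "vbgf", w0 = NULL),
               "too few")
  expect_error(fit_growth(exact_vbgf2(), model = "vbgf2"), "w0")
})

test_that("all four models fit and their fitted methods are coherent", {
  tpl <- species_template("sim", w_inf = 120, k = 0.18, w0 = 30,
                          age_min = 1, age_max = 20, n = 80, noise_sd = 3)
  d <- generate_sample(tpl, seed = 9)
  for (m in c("vbgf2", "vbgf", "logistic", "gompertz")) {
    f <- fit_growth(d, model = m, w0 = 30)
    expect_s3_class(f, "growth_fit")
    expect_equal(f$p, if (m == "vbgf2") 3L else 4L)
    expect_equal(length(residuals(f)), 80L)
    expect_equal(predict(f) + residuals(f), d$disc_width, tolerance = 1e-10)
    expect_gt(f$rss, 0)
  }
})

test_that("AICc ranking computes deltas, support labels and tie-breaks", {
  stub <- function(model, aicc_val, p) {
    structure(list(model = model, aicc = aicc_val, p = p, n = 40L,
                   rss = 1, converged = TRUE,
                   params = growth_params(model, w_inf = 100, k = 0.2,
                                          t0 = if (model == "vbgf") 0 else NULL,
                                          w0 = if (model != "vbgf") 20 else NULL)),
              class = "growth_fit")
  }
  rk <- rank_models(list(stub("vbgf", 10, 4), stub("gompertz", 12, 4),
                         stub("logistic", 11, 4)))
  expect_equal(rk$delta_aicc, c(0, 1, 2))
  expect_equal(rk$support, rep("highest", 3))

  rk2 <- rank_models(list(stub("vbgf", 10, 4), stub("gompertz", 13, 4)))
  expect_equal(rk2$delta_aicc, c(0, 3))
  expect_equal(rk2$support, c("highest", "lower"))

  # exact tie: fewer parameters ranked first
  rk3 <- rank_models(list(stub("vbgf", 10, 4), stub("vbgf2", 10, 3)))
  expect_equal(rk3$model[1], "vbgf2")

  # permutation invariance
  fits <- list(stub("vbgf", 12.4, 4), stub("vbgf2", 10.1, 3),
               stub("logistic", 11.7, 4), stub("gompertz", 15, 4))
  rk_a <- rank_models(fits)
  rk_b <- rank_models(rev(fits))
  expect_equal(as.data.frame(rk_a), as.data.frame(rk_b))

  # differing sample sizes are not comparable
  bad <- stub("vbgf", 10, 4)
  bad$n <- 39L
  expect_error(rank_models(list(bad, stub("vbgf2", 10, 3))), "sample sizes")
})

test_that("with ample data the generating model attains the lowest expected delta", {
  tpl <- species_template("sim", w_inf = 100, k = 0.2, w0 = 20,
                          age_min = 1, age_max = 20, n = 500, noise_sd = 4)
  deltas <- matrix(NA_real_, 10, 4,
                   dimnames = list(NULL, c("vbgf2", "vbgf", "logistic",
                                           "gompertz")))
  for (r in 1:10) {
    d <- generate_sample(tpl, seed = 70 + r)
    rk <- compare_growth_models(d, w0 = 20)$ranking
    expect_true(all(rk$delta_aicc >= 0))
    expect_equal(min(rk$delta_aicc), 0)
    deltas[r, rk$model] <- rk$delta_aicc
  }
  mean_delta <- colMeans(deltas)
  expect_equal(names(which.min(mean_delta)), "vbgf2")
})
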