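# Independent oracles used by the tests. These deliberately avoid the
# package's own computational paths.

# Posterior medians of (w_inf, k) for the 2VBGF Gaussian model by direct
# grid integration, with the variance marginalized analytically under its
# inverse-Gamma prior:
#   p(data | w_inf, k) ∝ (rate + RSS/2)^-(shape + n/2)
grid_posterior_2vbgf <- function(data, w0, priors = growth_priors(),
                                 w_range = c(40, 400),
                                 k_range = c(0.01, 0.99), n_grid = 400) {
  a <- priors$var_shape
  b <- priors$var_rate
  n <- nrow(data)
  wg <- seq(w_range[1], w_range[2], length.out = n_grid)
  kg <- seq(k_range[1], k_range[2], length.out = n_grid)
  lp <- matrix(NA_real_, n_grid, n_grid)
  for (i in seq_along(wg)) {
    mu <- outer(data$age, kg, function(t, k) wg[i] - (wg[i] - w0) * exp(-k * t))
    rss <- colSums((data$disc_width - mu)^2)
    lp[i, ] <- dlnorm(wg[i], priors$w_inf_meanlog, priors$w_inf_sdlog,
                      log = TRUE) +
      dbeta(kg, priors$k_shape1, priors$k_shape2, log = TRUE) -
      (a + n / 2) * log(b + rss / 2)
  }
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  med <- function(grid, marg) grid[which.min(abs(cumsum(marg) - 0.5))]
  c(w_inf = med(wg, rowSums(post)), k = med(kg, colSums(post)))
}

# Expected per-animal average percent error under the +/-1-band reader
# error model, by enumeration of the 3^R outcome patterns.
expected_ape_enum <- function(true_age, epsilon, n_readers = 3) {
  outcomes <- c(-1, 0, 1)
  probs <- c(epsilon / 2, 1 - epsilon, epsilon / 2)
  grid <- expand.grid(rep(list(seq_along(outcomes)), n_readers))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    reads <- true_age + outcomes[idx]
    p <- prod(probs[idx])
    xbar <- mean(reads)
    total <- total + p * (100 / n_readers) * sum(abs(reads - xbar) / xbar)
  }
  total
}

# small noise-free fixture shared by several tests
exact_vbgf2 <- function(w_inf = 100, k = 0.2, w0 = 20, ages = 1:15) {
  p <- growth_params("vbgf2", w_inf = w_inf, k = k, w0 = w0)
  data.frame(species = "fixture", age = ages,
             disc_width = predict_size(p, ages))
}
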