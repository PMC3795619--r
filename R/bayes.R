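#' Prior distributions for Bayesian growth estimation
#'
#' Builds the prior set for the two-parameter von Bertalanffy model:
#' a lognormal prior on the asymptotic disc width `w_inf`, a Beta prior on
#' the growth coefficient `k` (restricting it to (0, 1) per year) and a
#' non-informative inverse-Gamma prior on the residual variance.
#'
#' The default lognormal is parameterized so that its natural-scale mean is
#' exactly `w_inf_mean` (77 cm by default): the log-scale location is
#' `log(w_inf_mean) - w_inf_sdlog^2 / 2`. Setting `mean_scale = "log"`
#' instead places the location at `log(w_inf_mean)` (so `w_inf_mean`
#' becomes the natural-scale median). The default Beta(21.9, 162.3) prior
#' on `k` concentrates around 0.12 per year, reflecting published growth
#' coefficients for sub-tropical/tropical dasyatid rays aged from vertebral
#' sections.
#'
#' @param w_inf_mean prior mean of the asymptotic disc width, cm.
#' @param w_inf_sdlog prior standard deviation of `log(w_inf)`.
#' @param mean_scale `"natural"` (default; natural-scale mean equals
#'   `w_inf_mean`) or `"log"` (location is `log(w_inf_mean)`).
#' @param k_shape1,k_shape2 Beta shape parameters for the prior on `k`.
#' @param var_shape,var_rate inverse-Gamma shape and rate for the prior on
#'   the residual variance, cm^2.
#' @return an object of class `"growth_priors"`.
#' @examples
#' pr <- growth_priors()
#' exp(pr$w_inf_meanlog + pr$w_inf_sdlog^2 / 2) # natural-scale mean: 77
#' @export
growth_priors <- function(w_inf_mean = 77, w_inf_sdlog = 0.5,
                          mean_scale = c("natural", "log"),
                          k_shape1 = 21.9, k_shape2 = 162.3,
                          var_shape = 0.01, var_rate = 0.01) {
  mean_scale <- match.arg(mean_scale)
  stopifnot(w_inf_mean > 0, w_inf_sdlog > 0, k_shape1 > 0, k_shape2 > 0,
            var_shape > 0, var_rate > 0)
  meanlog <- if (mean_scale == "natural") {
    log(w_inf_mean) - w_inf_sdlog^2 / 2
  } else {
    log(w_inf_mean)
  }
  structure(list(
    w_inf_meanlog = meanlog, w_inf_sdlog = w_inf_sdlog,
    mean_scale = mean_scale, w_inf_mean = w_inf_mean,
    k_shape1 = k_shape1, k_shape2 = k_shape2,
    var_shape = var_shape, var_rate = var_rate
  ), class = "growth_priors")
}

#' @export
print.growth_priors <- function(x, ...) {
  cat("Priors for Bayesian 2VBGF estimation\n")
  cat(sprintf("  w_inf ~ Lognormal(meanlog = %.4f, sdlog = %.3f)  [natural mean %.4g cm]\n",
              x$w_inf_meanlog, x$w_inf_sdlog,
              exp(x$w_inf_meanlog + x$w_inf_sdlog^2 / 2)))
  cat(sprintf("  k     ~ Beta(%.4g, %.4g) on (0, 1) per year\n",
              x$k_shape1, x$k_shape2))
  cat(sprintf("  sigma^2 ~ Inverse-Gamma(%.3g, %.3g)\n", x$var_shape, x$var_rate))
  invisible(x)
}

# log inverse-gamma density on the variance
dinvgamma_log <- function(x, shape, rate) {
  ifelse(x > 0,
         shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x,
         -Inf)
}

#' Log prior density
#'
#' Sum of the three log prior densities at `(w_inf, k, sigma2)`; returns
#' `-Inf` outside the support (`w_inf > 0`, `0 < k < 1`, `sigma2 > 0`).
#'
#' @param w_inf,k,sigma2 parameter values.
#' @param priors a [growth_priors] object.
#' @return log density (scalar; `-Inf` encodes support violations).
#' @export
log_prior <- function(w_inf, k, sigma2, priors = growth_priors()) {
  if (!is.finite(w_inf) || !is.finite(k) || !is.finite(sigma2) ||
      w_inf <= 0 || k <= 0 || k >= 1 || sigma2 <= 0) {
    return(-Inf)
  }
  stats::dlnorm(w_inf, priors$w_inf_meanlog, priors$w_inf_sdlog, log = TRUE) +
    stats::dbeta(k, priors$k_shape1, priors$k_shape2, log = TRUE) +
    dinvgamma_log(sigma2, priors$var_shape, priors$var_rate)
}

#' Log likelihood of the two-parameter von Bertalanffy model
#'
#' Gaussian likelihood of observed disc widths around the 2VBGF mean curve
#' with constant variance `sigma2`.
#'
#' @param w_inf,k,sigma2 parameter values.
#' @param age,disc_width observed ages (years) and disc widths (cm).
#' @param w0 fixed disc width at age zero, cm.
#' @return log likelihood (scalar; `-Inf` for `sigma2 <= 0`).
#' @export
log_likelihood <- function(w_inf, k, sigma2, age, disc_width, w0) {
  if (!is.finite(sigma2) || sigma2 <= 0) return(-Inf)
  stopifnot(length(age) == length(disc_width), length(age) >= 1L)
  mu <- vbgf2_curve(age, w_inf, k, w0)
  n <- length(age)
  -0.5 * n * log(2 * pi * sigma2) - sum((disc_width - mu)^2) / (2 * sigma2)
}

#' MCMC run configuration
#'
#' Chain length, burn-in, thinning and proposal settings for the
#' Metropolis-Hastings sampler. Presets via [mcmc_preset]: `"full"`
#' (2,000,000 iterations, 100,000 burn-in, thin 100 — the full-length run),
#' `"desk"` (200,000 / 20,000 / 20, a few minutes) and `"sim"`
#' (50,000 / 5,000 / 10, for use inside simulation replicates).
#'
#' @param iterations total Metropolis-Hastings iterations.
#' @param burn_in iterations discarded before retention; must be smaller
#'   than `iterations`.
#' @param thin retain every `thin`-th post-burn-in draw.
#' @param seed integer RNG seed; the chain is reproducible given
#'   (seed, config, data).
#' @param proposal_scales positive step sizes for the random-walk proposal
#'   on (log w_inf, logit k, log sigma2).
#' @param adapt adapt the proposal covariance during burn-in (frozen
#'   afterwards so the retained chain has detailed balance).
#' @return an object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(iterations = 2e6, burn_in = 1e5, thin = 100,
                        seed = 1L, proposal_scales = c(0.1, 0.2, 0.3),
                        adapt = TRUE) {
  stopifnot(iterations > burn_in, burn_in >= 0, thin >= 1,
            length(proposal_scales) == 3L, all(proposal_scales > 0))
  retained <- floor((iterations - burn_in) / thin)
  if (retained < 1000) stop("configuration retains fewer than 1000 draws")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 proposal_scales = proposal_scales, adapt = adapt,
                 retained = as.integer(retained)),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @param preset one of `"full"`, `"desk"`, `"sim"`.
#' @param ... passed on to [mcmc_config] (e.g. `seed`).
#' @export
mcmc_preset <- function(preset = c("desk", "full", "sim"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    full = list(iterations = 2e6, burn_in = 1e5, thin = 100),
    desk  = list(iterations = 2e5, burn_in = 2e4, thin = 20),
    sim   = list(iterations = 5e4, burn_in = 5e3, thin = 10)
  )
  do.call(mcmc_config, c(args, list(...)))
}

# run RNG-consuming code under a local seed, restoring the caller's state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Bayesian fit of the two-parameter von Bertalanffy model
#'
#' Approximates the posterior of `(w_inf, k, sigma2)` under the priors of
#' [growth_priors] by random-walk Metropolis-Hastings on the transformed
#' parameters `(log w_inf, logit k, log sigma2)` (with the Jacobian
#' correction), so proposals always respect the support. During burn-in the
#' proposal covariance is adapted toward 20-40% acceptance using the
#' empirical covariance of the recent history; adaptation is frozen at the
#' end of burn-in. The chain starts from least-squares point estimates
#' clipped into the prior support, with the variance initialized at the
#' least-squares residual variance.
#'
#' @param data a data frame with columns `age` and `disc_width`; at least
#'   5 records spanning at least 2 distinct ages.
#' @param w0 fixed disc width at age zero, cm (`0 < w0 <` max observed
#'   size).
#' @param priors a [growth_priors] object.
#' @param config an [mcmc_config] object.
#' @return an object of class `"growth_bayes"` with `draws` (retained
#'   samples, columns `w_inf`, `k`, `sigma2`), `acceptance_rate`,
#'   `geweke_z`, `config`, `priors`, `w0`, `data`.
#' @examples
#' tpl <- species_template("demo", w_inf = 90, k = 0.2, w0 = 20,
#'                         age_min = 1, age_max = 15, n = 80, noise_sd = 3)
#' d <- generate_sample(tpl, seed = 7)
#' \donttest{
#' fit <- fit_growth_bayes(d, w0 = 20,
#'                         config = mcmc_config(6e4, 5e3, 10, seed = 7))
#' summary(fit)
#' }
#' @export
fit_growth_bayes <- function(data, w0, priors = growth_priors(),
                             config = mcmc_preset("desk")) {
  stopifnot(inherits(priors, "growth_priors"), inherits(config, "mcmc_config"))
  data <- validate_size_at_age(data, require_species = FALSE)
  if (nrow(data) < 5L) stop("need at least 5 records")
  if (length(unique(data$age)) < 2L) stop("ages span < 2 values")
  stopifnot(is.numeric(w0), length(w0) == 1L, w0 > 0)

  age <- data$age
  obs <- data$disc_width
  n <- length(age)

  # initial state: NLS point estimates clipped into the prior support
  init <- tryCatch({
    f <- fit_growth(data, model = "vbgf2", w0 = min(w0, 0.9 * max(obs)))
    c(w_inf = f$params$w_inf, k = f$params$k, sigma2 = max(f$sigma2, 1e-4))
  }, error = function(e) c(w_inf = 1.2 * max(obs), k = 0.2, sigma2 = stats::var(obs)))
  if (init[["k"]] >= 1) {
    warning("least-squares estimate of k exceeds 1/yr; the Beta prior ",
            "truncates k to (0, 1)")
    init[["k"]] <- 0.95
  }
  init[["w_inf"]] <- max(init[["w_inf"]], w0 * 1.01)

  # log posterior on the transformed scale, including the Jacobian
  log_post_theta <- function(th) {
    w <- exp(th[1L]); k <- stats::plogis(th[2L]); s2 <- exp(th[3L])
    lp <- log_prior(w, k, s2, priors)
    if (!is.finite(lp)) return(-Inf)
    mu <- w - (w - w0) * exp(-k * age)
    ll <- -0.5 * n * log(2 * pi * s2) - sum((obs - mu)^2) / (2 * s2)
    lp + ll + th[1L] + th[3L] + log(k) + log1p(-k)
  }

  res <- with_local_seed(config$seed, {
    run_mh(log_post_theta,
           theta0 = c(log(init[["w_inf"]]), stats::qlogis(min(max(init[["k"]], 1e-3), 1 - 1e-3)),
                      log(init[["sigma2"]])),
           config = config)
  })

  draws <- cbind(w_inf = exp(res$chain[, 1L]),
                 k = stats::plogis(res$chain[, 2L]),
                 sigma2 = exp(res$chain[, 3L]))
  gz <- apply(draws, 2L, function(x) {
    tryCatch(geweke_z(x), error = function(e) NA_real_)
  })
  out <- list(draws = draws, acceptance_rate = res$acceptance_rate,
              geweke_z = gz, config = config, priors = priors, w0 = w0,
              data = data, init = init, call = match.call())
  class(out) <- "growth_bayes"
  out
}

# random-walk MH with adaptive covariance during burn-in
run_mh <- function(log_post, theta0, config) {
  d <- length(theta0)
  n_iter <- config$iterations
  burn <- config$burn_in
  thin <- config$thin
  n_keep <- config$retained
  chain <- matrix(NA_real_, n_keep, d)

  chol_prop <- diag(config$proposal_scales, d)
  theta <- theta0
  lp <- log_post(theta)
  if (!is.finite(lp)) stop("initial state has zero posterior density")

  adapt_block <- 1000L
  hist_block <- matrix(NA_real_, adapt_block, d)
  acc_block <- 0L
  accepted_post <- 0L
  kept <- 0L

  for (i in seq_len(n_iter)) {
    prop <- theta + drop(chol_prop %*% stats::rnorm(d))
    lp_prop <- log_post(prop)
    if (is.finite(lp_prop) && log(stats::runif(1L)) < lp_prop - lp) {
      theta <- prop
      lp <- lp_prop
      if (i <= burn) acc_block <- acc_block + 1L else accepted_post <- accepted_post + 1L
    }
    if (i <= burn) {
      j <- ((i - 1L) %% adapt_block) + 1L
      hist_block[j, ] <- theta
      if (config$adapt && j == adapt_block) {
        rate <- acc_block / adapt_block
        sc <- exp(rate - 0.3)  # nudge toward ~30% acceptance
        cv <- stats::cov(hist_block)
        ch <- tryCatch(chol(cv * (2.38^2 / d) + diag(1e-8, d)),
                       error = function(e) NULL)
        if (!is.null(ch) && rate > 0.01) {
          chol_prop <- t(ch) * sc
        } else {
          chol_prop <- chol_prop * sc
        }
        acc_block <- 0L
      }
    } else {
      if ((i - burn) %% thin == 0L && kept < n_keep) {
        kept <- kept + 1L
        chain[kept, ] <- theta
      }
    }
  }
  acc_rate <- accepted_post / (n_iter - burn)
  if (acc_rate == 0) {
    stop("no proposals accepted after burn-in; adjust 'proposal_scales'")
  }
  list(chain = chain[seq_len(kept), , drop = FALSE], acceptance_rate = acc_rate)
}

#' Geweke convergence diagnostic
#'
#' Compares the means of an early and a late segment of a chain with a
#' z-test whose variances are long-run (spectral density at zero)
#' estimates, obtained from an AR fit to each segment. For a converged
#' chain the statistic is approximately standard normal; `|z| > 1.96`
#' flags non-convergence.
#'
#' @param x numeric vector of retained draws for one parameter.
#' @param frac_a fraction of the chain in the early segment (default 0.1).
#' @param frac_b fraction in the late segment (default 0.5).
#' @return the z score.
#' @export
geweke_z <- function(x, frac_a = 0.1, frac_b = 0.5) {
  stopifnot(is.numeric(x), frac_a > 0, frac_b > 0, frac_a + frac_b <= 1)
  n <- length(x)
  if (n < 100L) stop("chain too short for the Geweke diagnostic")
  if (stats::var(x) == 0) stop("zero-variance chain")
  n_a <- max(2L, floor(frac_a * n))
  a <- x[seq_len(n_a)]
  b <- x[seq.int(n - floor(frac_b * n) + 1L, n)]
  (mean(a) - mean(b)) / sqrt(spectrum0_ar(a) / length(a) +
                             spectrum0_ar(b) / length(b))
}

# spectral density at frequency zero via an AR fit (long-run variance);
# a segment that is an exact linear trend has zero innovation variance
spectrum0_ar <- function(x) {
  if (stats::var(x) == 0) return(0)
  res <- stats::lm.fit(cbind(1, seq_along(x)), x)$residuals
  if (isTRUE(all.equal(stats::sd(res), 0))) return(0)
  ord_max <- min(30L, length(x) - 1L, floor(10 * log10(length(x))))
  fit <- tryCatch(stats::ar(x, aic = TRUE, order.max = ord_max),
                  error = function(e) NULL)
  if (is.null(fit)) return(stats::var(x))
  if (fit$order == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Posterior summary: medians and 95% credibility intervals
#'
#' @param draws a matrix of retained draws (columns are parameters) or a
#'   `growth_bayes` object; at least 1000 draws are required.
#' @param probs quantiles to report.
#' @return a data frame with one row per parameter: `median`, `lower`,
#'   `upper`.
#' @export
summarize_posterior <- function(draws, probs = c(0.025, 0.5, 0.975)) {
  if (inherits(draws, "growth_bayes")) draws <- draws$draws
  draws <- as.matrix(draws)
  if (nrow(draws) < 1000L) stop("need at least 1000 retained draws")
  q <- t(apply(draws, 2L, stats::quantile, probs = probs, names = FALSE))
  out <- data.frame(parameter = colnames(draws),
                    median = q[, 2L], lower = q[, 1L], upper = q[, 3L],
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' @export
print.growth_bayes <- function(x, ...) {
  cat("Bayesian 2VBGF fit (Metropolis-Hastings)\n")
  cat(sprintf("  n = %d, w0 = %.4g cm, retained draws = %d, acceptance = %.1f%%\n",
              nrow(x$data), x$w0, nrow(x$draws), 100 * x$acceptance_rate))
  s <- summarize_posterior(x)
  s[, -1L] <- round(s[, -1L], 4)
  print(s, row.names = FALSE)
  cat("Geweke z:", paste(names(x$geweke_z), round(x$geweke_z, 2),
                         sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.growth_bayes <- function(object, ...) {
  s <- summarize_posterior(object)
  s$geweke_z <- object$geweke_z[s$parameter]
  s$converged <- abs(s$geweke_z) <= 1.96
  attr(s, "acceptance_rate") <- object$acceptance_rate
  class(s) <- c("summary.growth_bayes", "data.frame")
  s
}

#' @export
print.summary.growth_bayes <- function(x, ...) {
  cat("Posterior summary (median with 95% credibility interval)\n")
  df <- as.data.frame(x)
  df[, c("median", "lower", "upper", "geweke_z")] <-
    round(df[, c("median", "lower", "upper", "geweke_z")], 4)
  print(df, row.names = FALSE)
  cat(sprintf("acceptance rate: %.1f%%\n", 100 * attr(x, "acceptance_rate")))
  invisible(x)
}

#' @export
coef.growth_bayes <- function(object, ...) {
  s <- summarize_posterior(object)
  stats::setNames(s$median, s$parameter)
}

#' @export
predict.growth_bayes <- function(object, newdata = NULL, interval = FALSE, ...) {
  age <- if (is.null(newdata)) object$data$age else {
    if (is.data.frame(newdata)) newdata$age else newdata
  }
  med <- coef(object)
  fit <- vbgf2_curve(age, med[["w_inf"]], med[["k"]], object$w0)
  if (!interval) return(fit)
  curves <- apply(object$draws, 1L, function(d) {
    vbgf2_curve(age, d[["w_inf"]], d[["k"]], object$w0)
  })
  curves <- matrix(curves, nrow = length(age))
  data.frame(age = age, fit = fit,
             lower = apply(curves, 1L, stats::quantile, 0.025),
             upper = apply(curves, 1L, stats::quantile, 0.975))
}

#' @export
plot.growth_bayes <- function(x, which = c("posterior", "trace", "fit"), ...) {
  which <- match.arg(which)
  if (which == "posterior") {
    op <- graphics::par(mfrow = c(1, 3))
    on.exit(graphics::par(op))
    for (p in colnames(x$draws)) {
      graphics::hist(x$draws[, p], breaks = 50, main = p, xlab = p,
                     freq = FALSE)
    }
  } else if (which == "trace") {
    op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
    on.exit(graphics::par(op))
    for (p in colnames(x$draws)) {
      plot(x$draws[, p], type = "l", ylab = p, xlab = "")
    }
  } else {
    plot(x$data$age, x$data$disc_width, xlab = "Age (years)",
         ylab = "Disc width (cm)", main = "Bayesian 2VBGF fit")
    ages <- seq(min(x$data$age), max(x$data$age), length.out = 200)
    pr <- predict(x, ages, interval = TRUE)
    graphics::lines(ages, pr$fit, lwd = 2)
    graphics::lines(ages, pr$lower, lty = 2)
    graphics::lines(ages, pr$upper, lty = 2)
  }
  invisible(x)
}

#' @export
as.matrix.growth_bayes <- function(x, ...) x$draws
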