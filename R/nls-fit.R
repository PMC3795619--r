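# Free parameters estimated by least squares, per model. The 2VBGF fixes
# size at birth (that is its definition); logistic and Gompertz estimate it.
free_params <- function(model) {
  switch(model,
    vbgf2    = c("w_inf", "k"),
    vbgf     = c("w_inf", "k", "t0"),
    logistic = c("w_inf", "k", "w0"),
    gompertz = c("w_inf", "k", "w0")
  )
}

# assemble a growth_params object from a named vector of free parameters
assemble_params <- function(model, theta, w0) {
  if (model == "vbgf") {
    growth_params("vbgf", w_inf = theta[["w_inf"]], k = theta[["k"]],
                  t0 = theta[["t0"]])
  } else if (model == "vbgf2") {
    growth_params("vbgf2", w_inf = theta[["w_inf"]], k = theta[["k"]], w0 = w0)
  } else {
    growth_params(model, w_inf = theta[["w_inf"]], k = theta[["k"]],
                  w0 = theta[["w0"]])
  }
}

#' Bias-corrected AIC for a least-squares fit
#'
#' Computes the small-sample corrected Akaike information criterion from a
#' Gaussian least-squares fit:
#' `AICc = n * log(rss / n) + 2p + 2p(p + 1) / (n - p - 1)`,
#' where `p` counts the estimated parameters including the residual
#' variance. The correction matters for the sample sizes typical of
#' elasmobranch ageing studies (well under 200).
#'
#' @param rss residual sum of squares (must be positive; a perfect fit is
#'   reported separately, not through AICc).
#' @param n number of observations; must exceed `p + 1`.
#' @param p number of estimated parameters, growth parameters plus one
#'   variance term.
#' @return the AICc value.
#' @examples
#' aicc(rss = 80, n = 20, p = 3)
#' @export
aicc <- function(rss, n, p) {
  stopifnot(is.numeric(rss), is.numeric(n), is.numeric(p),
            length(rss) == 1L, length(n) == 1L, length(p) == 1L)
  if (rss <= 0) stop("'rss' must be positive (perfect fits are reported separately)")
  if (n <= p + 1) stop("'n' must exceed p + 1 for the AICc correction")
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

# default optimization bounds; max_size/min_age taken from the data.
# The lower bound on w_inf stays well below the largest observation:
# observation noise routinely pushes individual sizes above the true
# asymptote, so bounding w_inf at the sample maximum would bias it upward.
nls_bounds <- function(model, max_size, min_age) {
  lower <- c(w_inf = 0.5 * max_size, k = 1e-4)
  upper <- c(w_inf = 5 * max_size, k = 50)
  if (model == "vbgf") {
    lower <- c(lower, t0 = -10)
    upper <- c(upper, t0 = min_age)
  } else if (model %in% c("logistic", "gompertz")) {
    lower <- c(lower, w0 = 1e-3)
    upper <- c(upper, w0 = 0.9 * max_size)
  }
  list(lower = lower, upper = upper)
}

default_start <- function(model, fw, data, w0) {
  max_size <- max(data$disc_width)
  w_start <- if (isTRUE(fw$ok)) max(fw$w_inf, 1.05 * max_size) else 1.2 * max_size
  k_start <- if (isTRUE(fw$ok)) fw$k else 0.2
  st <- c(w_inf = w_start, k = min(k_start, 45))
  if (model == "vbgf") st <- c(st, t0 = min(0, min(data$age)) - 0.1)
  if (model %in% c("logistic", "gompertz")) st <- c(st, w0 = w0)
  st
}

#' Fit a growth model by nonlinear least squares
#'
#' Minimizes the residual sum of squares of observed disc widths around the
#' chosen growth curve using bounded quasi-Newton optimization (L-BFGS-B)
#' with jittered restarts. Starting values default to Ford-Walford
#' estimates ([ford_walford]); restarts guard against the sensitivity of
#' least squares to starting values. Bounds keep `w_inf` between the
#' largest observed size and five times it, `k` in (1e-4, 50) and, for the
#' VBGF, `t0` in (-10, min age).
#'
#' @param data a data frame with numeric columns `age` (years, >= 0) and
#'   `disc_width` (cm, > 0).
#' @param model growth function to fit; see [growth_params].
#' @param w0 disc width at age zero, cm. Fixed (not estimated) for the
#'   2VBGF; used as the starting value for the logistic and Gompertz, whose
#'   `w0` is estimated.
#' @param start optional named vector of starting values for the free
#'   parameters; defaults to Ford-Walford starts.
#' @param n_restarts number of jittered restarts around the start values.
#' @return an object of class `"growth_fit"` with components `params`
#'   (a [growth_params]), `rss`, `n`, `p` (free parameters + 1 variance
#'   term), `aicc`, `converged`, `fitted`, `residuals` and `data`.
#' @examples
#' set.seed(1)
#' tpl <- species_template("demo", w_inf = 100, k = 0.2, w0 = 20,
#'                         age_min = 1, age_max = 15, n = 60, noise_sd = 3)
#' d <- generate_sample(tpl, seed = 1)
#' fit_growth(d, model = "vbgf2", w0 = 20)
#' @export
fit_growth <- function(data, model = c("vbgf2", "vbgf", "logistic", "gompertz"),
                       w0 = NULL, start = NULL, n_restarts = 5L) {
  model <- match.arg(model)
  data <- validate_size_at_age(data, require_species = FALSE)
  pars <- free_params(model)
  p <- length(pars) + 1L  # + residual variance
  if (nrow(data) < p + 2L) stop("too few records: need at least p + 2")
  if (length(unique(data$age)) < 2L) stop("ages span < 2 values")
  if (model != "vbgf" && is.null(w0)) stop("'w0' is required for this model")
  if (!is.null(w0) && model != "vbgf") {
    stopifnot(is.numeric(w0), length(w0) == 1L, w0 > 0)
  }

  b <- nls_bounds(model, max(data$disc_width), min(data$age))
  if (is.null(start)) {
    fw <- ford_walford(data$age, data$disc_width)
    start <- default_start(model, fw, data, w0)
  } else {
    if (!all(pars %in% names(start))) {
      stop("'start' must name values for: ", paste(pars, collapse = ", "))
    }
    start <- start[pars]
  }
  start <- pmin(pmax(start, b$lower + 1e-8), b$upper - 1e-8)

  obj <- function(theta) {
    names(theta) <- pars
    prm <- tryCatch(assemble_params(model, theta, w0), error = function(e) NULL)
    if (is.null(prm)) return(1e12)
    val <- sum((data$disc_width - predict_size(prm, data$age))^2)
    if (!is.finite(val)) 1e12 else val
  }

  # deterministic jitters: the fit is a pure function of its arguments
  n_restarts <- max(0L, n_restarts)
  jitters <- with_local_seed(1L, {
    matrix(stats::rnorm(n_restarts * length(start), sd = 0.15), n_restarts)
  })
  best <- NULL
  for (r in seq_len(n_restarts + 1L)) {
    th0 <- if (r == 1L) start else {
      jit <- start * exp(jitters[r - 1L, ])
      pmin(pmax(jit, b$lower + 1e-8), b$upper - 1e-8)
    }
    res <- tryCatch(
      stats::optim(th0, obj, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(maxit = 500, factr = 1e2,
                                  ndeps = rep(1e-6, length(th0)))),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("optimization failed for every start")

  theta <- best$par
  names(theta) <- pars
  params <- assemble_params(model, theta, w0)
  fitted <- predict_size(params, data$age)
  rss <- sum((data$disc_width - fitted)^2)
  out <- list(
    model = model, params = params, rss = rss, n = nrow(data), p = p,
    aicc = if (rss > 0) aicc(rss, nrow(data), p) else -Inf,
    converged = best$convergence == 0,
    fitted = fitted, residuals = data$disc_width - fitted,
    sigma2 = rss / nrow(data), w0_fixed = if (model == "vbgf2") w0 else NULL,
    data = data, call = match.call()
  )
  class(out) <- "growth_fit"
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Nonlinear least-squares growth fit [", x$model, "]\n", sep = "")
  est <- unlist(x$params[setdiff(names(x$params), "model")])
  print(round(est, 4))
  cat(sprintf("n = %d, RSS = %.4g, AICc = %.3f, converged: %s\n",
              x$n, x$rss, x$aicc, x$converged))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  unlist(object$params[setdiff(names(object$params), "model")])
}

#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  age <- if (is.null(newdata)) object$data$age else {
    if (is.data.frame(newdata)) newdata$age else newdata
  }
  predict_size(object$params, age)
}

#' @export
residuals.growth_fit <- function(object, ...) object$residuals

#' @export
summary.growth_fit <- function(object, ...) {
  cat("Model:", object$model, "\n")
  print(object$params)
  cat(sprintf("n = %d\nRSS = %.6g cm^2\nresidual sd = %.4g cm\nAICc = %.4f (p = %d)\nconverged = %s\n",
              object$n, object$rss, sqrt(object$sigma2), object$aicc,
              object$p, object$converged))
  invisible(object)
}

#' @export
plot.growth_fit <- function(x, ...) {
  ord <- order(x$data$age)
  plot(x$data$age, x$data$disc_width, xlab = "Age (years)",
       ylab = "Disc width (cm)",
       main = paste("Size at age:", x$model), ...)
  ages <- seq(min(x$data$age), max(x$data$age), length.out = 200)
  graphics::lines(ages, predict_size(x$params, ages), lwd = 2)
  invisible(x)
}

#' Rank growth-model fits by AICc
#'
#' Computes AICc differences (delta) relative to the best fit and labels
#' support: models within two AICc units of the best have the highest
#' support, larger differences lower support. Ties in AICc are broken in
#' favor of the model with fewer parameters.
#'
#' @param fits a list of [fit_growth] results on the same data.
#' @return a data frame of class `"growth_ranking"`, sorted by delta, with
#'   columns `model`, `delta_aicc`, `support`, `aicc`, `w_inf`, `k`,
#'   `t0_or_w0`, `rss`, `n`, `p`, `converged`.
#' @export
rank_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2L,
            all(vapply(fits, inherits, TRUE, "growth_fit")))
  n <- vapply(fits, `[[`, 0, "n")
  if (length(unique(n)) != 1L) stop("fits were made on differing sample sizes")
  a <- vapply(fits, `[[`, 0, "aicc")
  p <- vapply(fits, `[[`, 0, "p")
  delta <- a - min(a)
  third <- vapply(fits, function(f) {
    if (f$model == "vbgf") f$params$t0
    else if (f$model == "vbgf2") f$params$w0
    else f$params$w0
  }, 0)
  out <- data.frame(
    model = vapply(fits, `[[`, "", "model"),
    delta_aicc = delta,
    support = ifelse(delta <= 2, "highest", "lower"),
    aicc = a,
    w_inf = vapply(fits, function(f) f$params$w_inf, 0),
    k = vapply(fits, function(f) f$params$k, 0),
    t0_or_w0 = third,
    rss = vapply(fits, `[[`, 0, "rss"),
    n = n, p = p,
    converged = vapply(fits, `[[`, TRUE, "converged"),
    stringsAsFactors = FALSE
  )
  # ascending delta; near-ties (< 1e-9) resolved toward fewer parameters
  ord <- order(round(out$delta_aicc / 1e-9) * 1e-9, out$p)
  out <- out[ord, , drop = FALSE]
  out$delta_aicc <- out$aicc - out$aicc[1L]
  rownames(out) <- NULL
  class(out) <- c("growth_ranking", "data.frame")
  out
}

#' @export
print.growth_ranking <- function(x, digits = 3, ...) {
  cat("Growth model ranking by AICc\n")
  df <- as.data.frame(x)
  df$delta_aicc <- round(df$delta_aicc, digits)
  df$aicc <- round(df$aicc, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Fit and rank all growth models on one data set
#'
#' Convenience wrapper running [ford_walford] starts, [fit_growth] for each
#' requested model and [rank_models] on the results.
#'
#' @inheritParams fit_growth
#' @param models character vector of models to fit.
#' @return a list with `fits` (named list of `growth_fit`) and `ranking`
#'   (a `growth_ranking`).
#' @export
compare_growth_models <- function(data, w0,
                                  models = c("vbgf2", "vbgf", "logistic",
                                             "gompertz")) {
  fits <- lapply(models, function(m) fit_growth(data, model = m, w0 = w0))
  names(fits) <- models
  list(fits = fits, ranking = rank_models(fits))
}
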