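#' Growth model parameter sets
#'
#' Construct a validated parameter set for one of the four growth functions
#' used to model disc width at age: the three-parameter von Bertalanffy
#' (`"vbgf"`), the two-parameter von Bertalanffy with size at birth fixed
#' (`"vbgf2"`), the logistic (`"logistic"`) and the Gompertz (`"gompertz"`).
#'
#' Each model is parameterized by an asymptotic disc width `w_inf` (cm) and a
#' growth coefficient `k` (per year). The VBGF additionally uses `t0`, the
#' theoretical age at zero size (years, may be negative); the other three
#' use `w0`, the disc width at age zero (cm), which must lie strictly
#' between 0 and `w_inf`.
#'
#' @param model one of `"vbgf"`, `"vbgf2"`, `"logistic"`, `"gompertz"`.
#' @param w_inf asymptotic disc width, cm; must be positive.
#' @param k growth coefficient, per year; must be positive.
#' @param t0 theoretical age at zero size, years (VBGF only).
#' @param w0 disc width at age zero, cm (2VBGF, logistic, Gompertz).
#' @return an object of class `"growth_params"`.
#' @examples
#' p <- growth_params("vbgf2", w_inf = 145, k = 0.13, w0 = 25)
#' predict_size(p, age = c(0, 5, 10))
#' @export
growth_params <- function(model = c("vbgf", "vbgf2", "logistic", "gompertz"),
                          w_inf, k, t0 = NULL, w0 = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(w_inf), length(w_inf) == 1L, is.finite(w_inf),
            is.numeric(k), length(k) == 1L, is.finite(k))
  if (w_inf <= 0) stop("'w_inf' must be positive")
  if (k <= 0) stop("'k' must be positive")
  if (model == "vbgf") {
    if (is.null(t0)) stop("model 'vbgf' requires 't0'")
    if (!is.null(w0)) stop("model 'vbgf' does not use 'w0'")
    stopifnot(is.numeric(t0), length(t0) == 1L, is.finite(t0))
    out <- list(model = model, w_inf = w_inf, k = k, t0 = t0)
  } else {
    if (is.null(w0)) stop(sprintf("model '%s' requires 'w0'", model))
    if (!is.null(t0)) stop(sprintf("model '%s' does not use 't0'", model))
    stopifnot(is.numeric(w0), length(w0) == 1L, is.finite(w0))
    if (w0 <= 0 || w0 >= w_inf) stop("'w0' must satisfy 0 < w0 < w_inf")
    out <- list(model = model, w_inf = w_inf, k = k, w0 = w0)
  }
  structure(out, class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Growth parameters [", x$model, "]\n", sep = "")
  nm <- setdiff(names(x), "model")
  cat(paste0("  ", nm, " = ", vapply(x[nm], format, "")), sep = "\n")
  invisible(x)
}

# raw curve evaluations; ages vectorized, parameters scalar
vbgf_curve <- function(age, w_inf, k, t0) w_inf * (1 - exp(-k * (age - t0)))

vbgf2_curve <- function(age, w_inf, k, w0) {
  b <- (w_inf - w0) / w_inf
  w_inf * (1 - b * exp(-k * age))
}

logistic_curve <- function(age, w_inf, k, w0) {
  # e^{-kt} form avoids overflow at large k * age
  em <- exp(-k * age)
  w_inf * w0 / (w_inf * em + w0 * (1 - em))
}

gompertz_curve <- function(age, w_inf, k, w0) {
  w_inf * exp(log(w0 / w_inf) * exp(-k * age))
}

#' Predicted disc width at age
#'
#' Evaluates the mean growth curve of a [growth_params] set at the given
#' ages. All four curves are non-decreasing in age and approach `w_inf` as
#' age grows large; the three size-at-birth forms satisfy `W(0) = w0` and
#' the VBGF satisfies `W(t0) = 0`.
#'
#' @param params a [growth_params] object.
#' @param age ages in years; must be `>= 0` (the VBGF also accepts negative
#'   ages down to `t0`).
#' @return predicted disc widths, cm (same length as `age`).
#' @export
predict_size <- function(params, age) {
  if (!inherits(params, "growth_params")) {
    stop("'params' must be a 'growth_params' object")
  }
  stopifnot(is.numeric(age), all(is.finite(age)))
  lo <- if (params$model == "vbgf") min(0, params$t0) else 0
  if (any(age < lo)) stop("'age' below the model's domain")
  switch(params$model,
    vbgf     = vbgf_curve(age, params$w_inf, params$k, params$t0),
    vbgf2    = vbgf2_curve(age, params$w_inf, params$k, params$w0),
    logistic = logistic_curve(age, params$w_inf, params$k, params$w0),
    gompertz = gompertz_curve(age, params$w_inf, params$k, params$w0)
  )
}

#' Ford-Walford starting values
#'
#' Estimates `w_inf` and `k` from mean sizes at consecutive integer ages by
#' regressing size at age t+1 on size at age t (a Ford-Walford plot). Under
#' von Bertalanffy growth the regression has slope `exp(-k)` and intercept
#' `w_inf * (1 - exp(-k))`, so `w_inf = intercept / (1 - slope)` and
#' `k = -log(slope)`. These serve as starting values for nonlinear fits.
#'
#' Ages are binned to the nearest integer and sizes averaged within bins
#' before the regression, so raw (unequally spaced, half-year) records can
#' be passed directly. When the fitted slope falls outside (0, 1) no
#' asymptote can be inferred and the result is flagged (`ok = FALSE`);
#' callers then fall back to configured defaults.
#'
#' @param age ages in years.
#' @param size disc widths, cm (same length as `age`).
#' @return a list with `w_inf`, `k`, `slope`, `intercept`, `ok`, `n_pairs`.
#' @examples
#' a <- 1:10
#' s <- 100 * (1 - exp(-0.2 * a))
#' ford_walford(a, s) # recovers w_inf = 100, k = 0.2
#' @export
ford_walford <- function(age, size) {
  stopifnot(is.numeric(age), is.numeric(size), length(age) == length(size),
            all(is.finite(age)), all(is.finite(size)))
  bin <- round(age)
  means <- tapply(size, bin, mean)
  t_bin <- as.numeric(names(means))
  fail <- function(msg) list(w_inf = NA_real_, k = NA_real_,
                             slope = NA_real_, intercept = NA_real_,
                             ok = FALSE, n_pairs = 0L, reason = msg)
  # pairs of consecutive integer ages both observed
  idx <- match(t_bin + 1, t_bin)
  keep <- !is.na(idx)
  if (sum(keep) < 2L) return(fail("fewer than 3 consecutive age bins"))
  s_t <- as.numeric(means[keep])
  s_t1 <- as.numeric(means[idx[keep]])
  fit <- stats::lm.fit(cbind(1, s_t), s_t1)
  slope <- fit$coefficients[2L]
  intercept <- fit$coefficients[1L]
  if (!is.finite(slope) || slope <= 0 || slope >= 1) {
    out <- fail("slope outside (0, 1); no asymptote inferable")
    out$slope <- slope
    out$intercept <- intercept
    return(out)
  }
  list(w_inf = unname(intercept / (1 - slope)), k = unname(-log(slope)),
       slope = unname(slope), intercept = unname(intercept),
       ok = TRUE, n_pairs = sum(keep), reason = NA_character_)
}

# t0 making the VBGF pass through (0, w0); used to relate vbgf2 to vbgf
vbgf2_equivalent_t0 <- function(w_inf, k, w0) log(1 - w0 / w_inf) / k
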