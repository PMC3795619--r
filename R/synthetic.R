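#' Species template for synthetic size-at-age data
#'
#' Describes the generating conditions for one species: the mean growth
#' curve (two-parameter von Bertalanffy by default), the observable age
#' range, the sample size and the observation-noise model. Noise is
#' additive Gaussian on disc width; by default its standard deviation is
#' 4% of `w_inf`, a scatter typical of vertebral size-at-age data, and it
#' can instead be made proportional to the predicted size via `noise_cv`.
#'
#' @param name species label.
#' @param w_inf,k generating growth parameters (cm, per year).
#' @param w0 disc width at age zero, cm.
#' @param age_min,age_max observable age range, years (within 0-50).
#' @param n sample size.
#' @param noise_sd additive Gaussian sd, cm; default `0.04 * w_inf`.
#' @param noise_cv optional proportional noise: sd is `noise_cv` times the
#'   predicted size (overrides `noise_sd`).
#' @param model generating model name (see [growth_params]).
#' @return an object of class `"species_template"`.
#' @export
species_template <- function(name, w_inf, k, w0, age_min, age_max, n,
                             noise_sd = 0.04 * w_inf, noise_cv = NULL,
                             model = "vbgf2") {
  stopifnot(age_min >= 0, age_max <= 50, age_max > age_min, n >= 1)
  if (is.null(noise_cv)) stopifnot(noise_sd > 0) else stopifnot(noise_cv > 0)
  params <- growth_params(model, w_inf = w_inf, k = k, w0 = w0)
  structure(list(name = name, params = params, w_inf = w_inf, k = k,
                 w0 = w0, age_min = age_min, age_max = age_max,
                 n = as.integer(n), noise_sd = noise_sd, noise_cv = noise_cv),
            class = "species_template")
}

#' @export
print.species_template <- function(x, ...) {
  cat(sprintf("Species template '%s' [%s]: w_inf = %.4g, k = %.3g, w0 = %.4g\n",
              x$name, x$params$model, x$w_inf, x$k, x$w0))
  cat(sprintf("  ages %.1f-%.1f yr, n = %d, noise %s\n", x$age_min, x$age_max,
              x$n, if (is.null(x$noise_cv)) sprintf("sd = %.3g cm", x$noise_sd)
                   else sprintf("cv = %.3g", x$noise_cv)))
  invisible(x)
}

#' Built-in ray species presets
#'
#' Four templates matching the study system: reticulate whipray
#' (*Himantura uarnak*), bluespotted maskray (*Neotrygon kuhlii*), cowtail
#' ray (*Pastinachus atrus*) and bluespotted fantail ray (*Taeniura
#' lymma*). Generating `w_inf` and `k` are the Bayesian posterior medians
#' for each species; age ranges, sample sizes and `w0` (the species'
#' minimum observed disc width, standing in for size at birth) follow the
#' observed data.
#'
#' @return a named list of [species_template] objects.
#' @export
ray_presets <- function() {
  list(
    H_uarnak = species_template("H_uarnak", w_inf = 149, k = 0.12, w0 = 25,
                                age_min = 1, age_max = 25, n = 19),
    N_kuhlii = species_template("N_kuhlii", w_inf = 42, k = 0.38, w0 = 17,
                                age_min = 1.5, age_max = 13, n = 34),
    P_atrus  = species_template("P_atrus", w_inf = 156, k = 0.16, w0 = 36.5,
                                age_min = 1, age_max = 27, n = 32),
    T_lymma  = species_template("T_lymma", w_inf = 33, k = 0.24, w0 = 14,
                                age_min = 1, age_max = 11, n = 40)
  )
}

# ages observed at half-year resolution (band count plus forming-edge rule)
round_half_year <- function(age) round(age * 2) / 2

add_noise <- function(mu, template) {
  sd <- if (is.null(template$noise_cv)) template$noise_sd else template$noise_cv * mu
  w <- mu + stats::rnorm(length(mu), 0, sd)
  # truncate at positive size by redrawing
  bad <- which(w <= 0)
  tries <- 0L
  while (length(bad) && tries < 100L) {
    w[bad] <- mu[bad] + stats::rnorm(length(bad), 0,
                                     if (is.null(template$noise_cv)) template$noise_sd
                                     else template$noise_cv * mu[bad])
    bad <- which(w <= 0)
    tries <- tries + 1L
  }
  if (length(bad)) w[bad] <- mu[bad] * 0.01
  w
}

#' Generate a synthetic size-at-age sample
#'
#' Draws `n` ages uniformly on the template's age range (rounded to the
#' half-year grid of the ageing protocol) and sizes from the template's
#' growth curve plus observation noise, truncated to positive disc widths.
#' Pure function of (template, seed).
#'
#' @param template a [species_template].
#' @param seed integer seed.
#' @return a data frame of records: `species`, `age`, `disc_width`.
#' @export
generate_sample <- function(template, seed) {
  stopifnot(inherits(template, "species_template"))
  with_local_seed(seed, {
    age <- round_half_year(stats::runif(template$n, template$age_min,
                                        template$age_max))
    mu <- predict_size(template$params, age)
    data.frame(species = template$name, age = age,
               disc_width = add_noise(mu, template),
               stringsAsFactors = FALSE)
  })
}

#' Generate a fully-designed (well-represented) sample
#'
#' The balanced design of the estimator-comparison study: `m` observations
#' at each integer age in `ages`, with sizes from the template curve plus
#' noise. The default (20 age classes, 10 observations each) is the
#' well-represented reference data set from which data-poor subsamples are
#' drawn.
#'
#' @param template a [species_template].
#' @param ages integer age classes (default `1:20`).
#' @param m observations per age class (default 10).
#' @param seed integer seed.
#' @return a data frame of `length(ages) * m` records.
#' @export
generate_full_design <- function(template, ages = 1:20, m = 10, seed) {
  stopifnot(length(ages) >= 2L, m >= 1)
  with_local_seed(seed, {
    age <- rep(ages, each = m)
    mu <- predict_size(template$params, age)
    data.frame(species = template$name, age = age,
               disc_width = add_noise(mu, template),
               stringsAsFactors = FALSE)
  })
}

#' Data-poor subsampling schemes
#'
#' Emulates data-poor sampling from a well-represented data set:
#' `"random_n"` takes a simple random sample of `n` records;
#' `"truncate_old"` / `"truncate_young"` first remove the oldest /
#' youngest third of the age classes (the sampling-selectivity case where
#' large old or small young animals are missed), then sample `n` of the
#' remainder.
#'
#' @param records a size-at-age data frame.
#' @param scheme one of `"random_n"`, `"truncate_old"`, `"truncate_young"`.
#' @param n records to retain; must not exceed what the scheme leaves
#'   available.
#' @param seed integer seed.
#' @return a data frame of `n` records.
#' @export
data_poor_subsample <- function(records,
                                scheme = c("random_n", "truncate_old",
                                           "truncate_young"),
                                n, seed) {
  scheme <- match.arg(scheme)
  if (scheme != "random_n") {
    classes <- sort(unique(records$age))
    drop_n <- ceiling(length(classes) / 3)
    dropped <- if (scheme == "truncate_old") {
      utils::tail(classes, drop_n)
    } else {
      utils::head(classes, drop_n)
    }
    records <- records[!(records$age %in% dropped), , drop = FALSE]
  }
  if (n > nrow(records)) {
    stop(sprintf("requested n = %d but only %d records available", n,
                 nrow(records)))
  }
  with_local_seed(seed, {
    out <- records[sample.int(nrow(records), n), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic multi-reader age matrix
#'
#' Simulates the blind multi-reader protocol: each reader's count equals
#' the true age, except that with probability `epsilon` the reader
#' miscounts by one band (sign random). Readability scores are sampled
#' from the configured proportions (defaults follow the observed shares of
#' scores 1:2:3 of 50:75:45).
#'
#' @param true_ages vector of true ages.
#' @param epsilon per-reader miscount probability in [0, 1).
#' @param n_readers number of readers (default 3).
#' @param readability_probs probabilities of scores 1, 2, 3.
#' @param seed integer seed.
#' @return a [reader_matrix].
#' @export
generate_reader_matrix <- function(true_ages, epsilon, n_readers = 3,
                                   readability_probs = c(50, 75, 45) / 170,
                                   seed) {
  stopifnot(epsilon >= 0, epsilon < 1, n_readers >= 2,
            length(readability_probs) == 3L, all(readability_probs >= 0))
  readability_probs <- readability_probs / sum(readability_probs)
  n <- length(true_ages)
  with_local_seed(seed, {
    err <- matrix(stats::rbinom(n * n_readers, 1L, epsilon) *
                    sample(c(-1, 1), n * n_readers, replace = TRUE),
                  n, n_readers)
    reads <- pmax(outer(true_ages, rep(1, n_readers)) + err, 0)
    readability <- sample.int(3L, n, replace = TRUE, prob = readability_probs)
    reader_matrix(reads, readability = readability)
  })
}
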