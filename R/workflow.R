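# shared validation of size-at-age records
validate_size_at_age <- function(data, require_species = TRUE) {
  if (!is.data.frame(data)) stop("size-at-age data must be a data frame")
  need <- c(if (require_species) "species", "age", "disc_width")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!is.numeric(data$age) || !is.numeric(data$disc_width)) {
    stop("'age' and 'disc_width' must be numeric")
  }
  bad <- which(!is.finite(data$age) | data$age < 0 |
                 !is.finite(data$disc_width) | data$disc_width <= 0)
  if (length(bad)) {
    stop("invalid records (age < 0 or disc_width <= 0) at rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (!is.null(data$readability) &&
      !all(is.na(data$readability) | data$readability %in% 1:3)) {
    stop("readability scores must be in {1, 2, 3}")
  }
  data
}

#' Read size-at-age records from CSV
#'
#' Expects columns `species`, `age` (years), `disc_width` (cm); optional
#' `total_length`, `sex`, `readability`. Lines starting with `#` are
#' treated as comments. Malformed rows are reported with their line
#' numbers.
#'
#' @param path CSV file path.
#' @return a validated data frame of records.
#' @export
read_size_at_age <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("species", "age", "disc_width")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "))
  suppressWarnings({
    d$age <- as.numeric(d$age)
    d$disc_width <- as.numeric(d$disc_width)
  })
  bad <- which(is.na(d$age) | d$age < 0 | is.na(d$disc_width) |
                 d$disc_width <= 0)
  if (length(bad)) {
    # + 1 header line -> file line numbers
    stop("malformed rows in ", path, " at line(s): ",
         paste(bad + 1L, collapse = ", "))
  }
  validate_size_at_age(d)
}

#' Write size-at-age records to CSV
#'
#' @param records a data frame of records.
#' @param path output path.
#' @param header_comment optional `# ...` comment line written first
#'   (used by the pipeline to stamp seed and config hash).
#' @export
write_size_at_age <- function(records, path, header_comment = NULL) {
  records <- validate_size_at_age(records)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' Read a reader matrix from CSV
#'
#' Expects columns `animal_id`, `reader_1` .. `reader_R` and optionally
#' `readability`.
#'
#' @param path CSV file path.
#' @return a [reader_matrix].
#' @export
read_reader_matrix <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  rd_cols <- grep("^reader_", names(d), value = TRUE)
  if (length(rd_cols) < 2L) stop("need at least two reader_* columns")
  reader_matrix(as.matrix(d[rd_cols]),
                readability = d$readability,
                animal_ids = if (!is.null(d$animal_id)) d$animal_id else NULL)
}

#' Write a reader matrix to CSV
#'
#' @param m a [reader_matrix].
#' @param path output path.
#' @param header_comment optional comment line.
#' @export
write_reader_matrix <- function(m, path, header_comment = NULL) {
  stopifnot(inherits(m, "reader_matrix"))
  d <- data.frame(animal_id = m$animal_ids, m$reads)
  if (!is.null(m$readability)) d$readability <- m$readability
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

# deterministic hash of a configuration list
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(config[order(names(config))]), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

#' Run configuration for the full workflow
#'
#' @param size_file path to a size-at-age CSV (or `NULL` when `records`
#'   are passed to [run_full_workflow] directly).
#' @param reader_file optional path to a reader-matrix CSV.
#' @param w0 named vector of size-at-birth values, cm, one per species
#'   (by default the species' minimum observed disc width is used).
#' @param models models for the least-squares comparison stage.
#' @param bayes_model model fitted in the Bayesian stage; the Bayesian
#'   machinery supports the two-parameter von Bertalanffy.
#' @param priors a [growth_priors] object.
#' @param mcmc_preset `"full"` (2M/100k/100), `"desk"` (200k/20k/20) or
#'   `"sim"` (50k/5k/10).
#' @param seed integer master seed.
#' @param out_dir output directory (created if absent).
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(size_file = NULL, reader_file = NULL, w0 = NULL,
                       models = c("vbgf2", "vbgf", "logistic", "gompertz"),
                       bayes_model = "vbgf2", priors = growth_priors(),
                       mcmc_preset = c("desk", "full", "sim"), seed = 0L,
                       out_dir = tempfile("raygrowth_run_")) {
  mcmc_preset <- match.arg(mcmc_preset)
  if (!is.null(size_file) && !file.exists(size_file)) {
    stop("input file not found: ", size_file)
  }
  if (!is.null(reader_file) && !file.exists(reader_file)) {
    stop("input file not found: ", reader_file)
  }
  stopifnot(inherits(priors, "growth_priors"))
  structure(list(size_file = size_file, reader_file = reader_file, w0 = w0,
                 models = models, bayes_model = bayes_model, priors = priors,
                 mcmc_preset = mcmc_preset, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a workflow configuration from YAML
#'
#' Accepts keys `size_file`, `reader_file`, `w0` (map species -> cm),
#' `models`, `mcmc_preset`, `seed`, `out_dir`, and a `priors` map with
#' `w_inf_mean`, `w_inf_sdlog`, `mean_scale`, `k_shape1`, `k_shape2`,
#' `var_shape`, `var_rate`.
#'
#' @param path YAML file path.
#' @return a [run_config].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  pr <- if (is.null(y$priors)) growth_priors() else do.call(growth_priors, y$priors)
  args <- y[intersect(names(y), c("size_file", "reader_file", "models",
                                  "bayes_model", "mcmc_preset", "seed",
                                  "out_dir"))]
  if (!is.null(y$w0)) args$w0 <- unlist(y$w0)
  args$priors <- pr
  do.call(run_config, args)
}

#' Run the full three-stage growth-estimation workflow
#'
#' For each species in the input: (1) readability filtering and consensus
#' ageing when a reader matrix is supplied; (2) Ford-Walford starting
#' values, least-squares fits of the configured growth models and AICc
#' ranking; (3) Bayesian estimation of the two-parameter von Bertalanffy
#' model under the configured priors. The Bayesian stage always fits the
#' 2VBGF unless `bayes_model` overrides it; if another model wins the
#' AICc ranking a warning is emitted. Failures for one species are
#' isolated and recorded, not fatal for the rest.
#'
#' All output CSVs carry a `# seed=... config=...` header line, and a JSON
#' manifest records the seed, configuration hash and files written, so a
#' run is reproducible end to end.
#'
#' @param config a [run_config].
#' @param records optional size-at-age data frame (overrides
#'   `config$size_file`).
#' @param readers optional [reader_matrix] (overrides
#'   `config$reader_file`).
#' @return invisibly, a list with `model_selection` (per-species AICc
#'   tables), `posterior` (per-species posterior summaries), `precision`
#'   (precision report or `NULL`), `manifest`, `failures`.
#' @export
run_full_workflow <- function(config, records = NULL, readers = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(records)) {
    if (is.null(config$size_file)) stop("no size-at-age input configured")
    records <- read_size_at_age(config$size_file)
  } else {
    records <- validate_size_at_age(records)
  }
  if (is.null(readers) && !is.null(config$reader_file)) {
    readers <- read_reader_matrix(config$reader_file)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  chash <- config_hash(list(models = config$models,
                            bayes_model = config$bayes_model,
                            mcmc_preset = config$mcmc_preset,
                            seed = config$seed,
                            w0 = config$w0,
                            priors = unclass(config$priors)))
  stamp <- sprintf("seed=%d config=%s", config$seed, chash)

  if (!is.null(records$readability)) {
    records <- filter_readability(records)$retained
  }

  precision <- NULL
  if (!is.null(readers)) {
    precision <- ageing_precision(readers)
  }

  species <- unique(records$species)
  sel_rows <- list()
  post_rows <- list()
  failures <- list()
  for (sp in species) {
    d <- records[records$species == sp, , drop = FALSE]
    w0 <- if (!is.null(config$w0) && sp %in% names(config$w0)) {
      config$w0[[sp]]
    } else {
      min(d$disc_width)  # species minimum observed size stands in for birth size
    }
    res <- tryCatch({
      cmp <- compare_growth_models(d, w0 = w0, models = config$models)
      rk <- as.data.frame(cmp$ranking)
      rk <- cbind(species = sp, rk)
      if (rk$model[1L] != config$bayes_model) {
        warning(sprintf("species %s: AICc favors '%s' but the Bayesian stage fits '%s'",
                        sp, rk$model[1L], config$bayes_model), call. = FALSE)
      }
      bay <- fit_growth_bayes(
        d, w0 = w0, priors = config$priors,
        config = mcmc_preset(config$mcmc_preset, seed = config$seed +
                               match(sp, species)))
      ps <- summarize_posterior(bay)
      ps <- cbind(species = sp, ps,
                  geweke_z = unname(bay$geweke_z[ps$parameter]),
                  acceptance_rate = bay$acceptance_rate,
                  n = nrow(d), w0 = w0)
      list(rk = rk, ps = ps)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[sp]] <- conditionMessage(res)
    } else {
      sel_rows[[sp]] <- res$rk
      post_rows[[sp]] <- res$ps
    }
  }

  write_stamped_csv <- function(df, file) {
    path <- file.path(config$out_dir, file)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", stamp), con)
    utils::write.csv(df, con, row.names = FALSE)
    path
  }

  files <- character()
  model_selection <- if (length(sel_rows)) do.call(rbind, sel_rows) else NULL
  if (!is.null(model_selection)) {
    rownames(model_selection) <- NULL
    files <- c(files, write_stamped_csv(model_selection, "model_selection.csv"))
  }
  posterior <- if (length(post_rows)) do.call(rbind, post_rows) else NULL
  if (!is.null(posterior)) {
    rownames(posterior) <- NULL
    files <- c(files, write_stamped_csv(posterior, "posterior_summary.csv"))
  }
  if (!is.null(precision)) {
    prec_df <- cbind(precision$per_reader,
                     overall_iape = precision$iape,
                     overall_cv = precision$cv, n_used = precision$n_used)
    files <- c(files, write_stamped_csv(prec_df, "precision.csv"))
  }
  manifest <- list(package = "raygrowth",
                   version = as.character(utils::packageVersion("raygrowth")),
                   seed = config$seed, config_hash = unname(chash),
                   mcmc_preset = config$mcmc_preset,
                   species = as.list(species),
                   failures = failures,
                   files = as.list(basename(files)))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  if (length(failures) == length(species) && length(species) > 0) {
    stop("all species failed: ",
         paste(names(failures), unlist(failures), sep = ": ",
               collapse = "; "))
  }
  invisible(list(model_selection = model_selection, posterior = posterior,
                 precision = precision, manifest = manifest,
                 failures = failures, out_dir = config$out_dir))
}
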