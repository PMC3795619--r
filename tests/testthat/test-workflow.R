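make_bundle <- function(dir, n_species = 2) {
  presets <- ray_presets()[seq_len(n_species)]
  records <- do.call(rbind, lapply(seq_along(presets), function(i) {
    tpl <- presets[[i]]
    tpl$n <- 60L  # enough records for all four models
    generate_sample(tpl, seed = 100 + i)
  }))
  size_path <- file.path(dir, "size_at_age.csv")
  write_size_at_age(records, size_path)
  m <- generate_reader_matrix(rep(3:9, 10), epsilon = 0.15, seed = 55)
  reader_path <- file.path(dir, "readers.csv")
  write_reader_matrix(m, reader_path)
  list(size = size_path, readers = reader_path, records = records)
}

test_that("size-at-age CSV round-trips and rejects malformed rows", {
  dir <- withr::local_tempdir()
  tpl <- ray_presets()$T_lymma
  tpl$n <- 200L
  d <- generate_sample(tpl, seed = 31)
  path <- file.path(dir, "d.csv")
  write_size_at_age(d, path, header_comment = "seed=31")
  back <- read_size_at_age(path)
  expect_equal(back, d, tolerance = 1e-12)

  # a single valid row
  p1 <- file.path(dir, "one.csv")
  writeLines(c("species,age,disc_width", "P_atrus,10,112.3"), p1)
  r1 <- read_size_at_age(p1)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$disc_width, 112.3)

  # a negative disc width is reported with its file line number
  p2 <- file.path(dir, "bad.csv")
  writeLines(c("species,age,disc_width", "P_atrus,10,112.3",
               "P_atrus,4,-3"), p2)
  expect_error(read_size_at_age(p2), "line.*3")
  expect_error(read_size_at_age(file.path(dir, "missing.csv")), "not found")
})

test_that("reader matrix CSV round-trips", {
  dir <- withr::local_tempdir()
  m <- generate_reader_matrix(rep(2:8, 4), epsilon = 0.2, seed = 32)
  path <- file.path(dir, "readers.csv")
  write_reader_matrix(m, path)
  back <- read_reader_matrix(path)
  expect_equal(back$reads, m$reads)
  expect_equal(back$readability, m$readability)
})

test_that("the full workflow produces ranked models, posteriors and precision", {
  dir <- withr::local_tempdir()
  bundle <- make_bundle(dir)
  cfg <- run_config(size_file = bundle$size, reader_file = bundle$readers,
                    mcmc_preset = "sim", seed = 7,
                    out_dir = file.path(dir, "out"))
  res <- suppressWarnings(run_full_workflow(cfg))
  expect_equal(length(unique(res$model_selection$species)), 2L)
  expect_true(all(c("model", "delta_aicc", "w_inf", "k") %in%
                    names(res$model_selection)))
  # each species has a ranking over four models with one delta of zero
  for (sp in unique(res$model_selection$species)) {
    sub <- res$model_selection[res$model_selection$species == sp, ]
    expect_equal(nrow(sub), 4L)
    expect_equal(min(sub$delta_aicc), 0)
  }
  expect_equal(nrow(res$posterior), 2L * 3L)  # 3 parameters per species
  expect_s3_class(res$precision, "precision_report")
  expect_equal(length(res$failures), 0L)

  out_files <- list.files(res$out_dir)
  expect_true(all(c("model_selection.csv", "posterior_summary.csv",
                    "precision.csv", "manifest.json") %in% out_files))
  # every CSV is stamped with the seed and config hash
  for (f in grep("csv$", out_files, value = TRUE)) {
    first <- readLines(file.path(res$out_dir, f), n = 1L)
    expect_match(first, "^# seed=7 config=[0-9a-f]{32}$")
  }
  manifest <- jsonlite::read_json(file.path(res$out_dir, "manifest.json"))
  expect_equal(manifest$seed, 7L)
  expect_equal(manifest$package, "raygrowth")
})

test_that("identical config and seed give byte-identical outputs", {
  dir <- withr::local_tempdir()
  bundle <- make_bundle(dir, n_species = 1)
  run_once <- function(out) {
    cfg <- run_config(size_file = bundle$size, mcmc_preset = "sim",
                      seed = 11, out_dir = file.path(dir, out))
    suppressWarnings(run_full_workflow(cfg))$out_dir
  }
  d1 <- run_once("out1")
  d2 <- run_once("out2")
  for (f in c("model_selection.csv", "posterior_summary.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("missing inputs fail cleanly with the offending path named", {
  expect_error(run_config(size_file = "/nonexistent/input.csv"),
               "/nonexistent/input.csv")
  cfg <- run_config(seed = 1)
  expect_error(run_full_workflow(cfg), "no size-at-age input")
})

test_that("YAML configuration is read into a run_config", {
  dir <- withr::local_tempdir()
  bundle <- make_bundle(dir, n_species = 1)
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c(
    paste0("size_file: ", bundle$size),
    "mcmc_preset: sim",
    "seed: 3",
    "w0:",
    "  H_uarnak: 25",
    "priors:",
    "  w_inf_mean: 77",
    "  w_inf_sdlog: 0.5"
  ), yml)
  cfg <- read_run_config(yml)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$seed, 3L)
  expect_equal(cfg$w0[["H_uarnak"]], 25)
  expect_equal(exp(cfg$priors$w_inf_meanlog + cfg$priors$w_inf_sdlog^2 / 2),
               77, tolerance = 1e-12)
})
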