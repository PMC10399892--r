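#' Read and write trial tables
#'
#' Trial tables are plain CSV with columns `subject`, `condition`, `block`,
#' `trial` (0-based within block), `choice` (0/1), `outcome` (-1/0/+1),
#' `p0`, `p1`. [read_trials()] validates the schema and outcome codes.
#'
#' @param trials a trial data frame.
#' @param path file path.
#' @return `read_trials` returns the validated data frame.
#' @export
write_trials <- function(trials, path) {
  cols <- c("subject", "condition", "block", "trial", "choice", "outcome",
            "p0", "p1")
  miss <- setdiff(cols, names(trials))
  if (length(miss))
    stop("cannot write ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  write.csv(trials[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_trials(df)
  for (cond in unique(df$condition))
    check_trials(df[df$condition == cond, , drop = FALSE], cond)
  df
}

#' Load a run configuration
#'
#' Configurations are JSON objects whose keys mirror the function arguments
#' of the pipeline stage being run (e.g. the [recovery_grid_design()] fields
#' for `run_simulate`). Unknown keys are rejected.
#'
#' @param path JSON file path.
#' @param allowed character vector of legal keys.
#' @return named list.
#' @export
read_run_config <- function(path, allowed = NULL) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(allowed)) {
    unknown <- setdiff(names(cfg), allowed)
    if (length(unknown))
      stop("unknown config key(s) in ", path, ": ",
           paste(unknown, collapse = ", "))
  }
  cfg
}

write_manifest <- function(out_dir, stage, config, seed, extra = list()) {
  manifest <- c(list(stage = stage,
                     package_version =
                       as.character(utils::packageVersion("qshadow")),
                     seed = seed, config = config,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

as_grid_design <- function(config) {
  lr_pairs <- config$lr_pairs
  if (is.matrix(lr_pairs))
    lr_pairs <- lapply(seq_len(nrow(lr_pairs)), function(i) lr_pairs[i, ])
  recovery_grid_design(
    q0_levels = config$q0_levels, lr_pairs = lr_pairs,
    n_datasets_per_cell = config$n_datasets_per_cell,
    n_subjects = config$n_subjects,
    beta = if (is.null(config$beta)) 10 else config$beta,
    condition = if (is.null(config$condition)) "gain" else config$condition,
    task = if (is.null(config$task)) "random_walk" else config$task,
    n_trials = if (is.null(config$n_trials)) 100 else config$n_trials,
    trials_per_block = if (is.null(config$trials_per_block)) 32 else
      config$trials_per_block)
}

config_fit <- function(config) {
  fit_config(profile = if (is.null(config$profile)) "test" else
               config$profile,
             n_chains = config$n_chains, n_warmup = config$n_warmup,
             n_keep = config$n_keep,
             seed = if (is.null(config$seed)) 1L else config$seed)
}

#' Pipeline stage: simulate grid datasets to disk
#'
#' Dispatches to [simulate_grid()] and writes one CSV trial table per
#' dataset plus a JSON manifest recording the design, seeds and package
#' version.
#'
#' @param config list (or path to a JSON file) with the
#'   [recovery_grid_design()] fields plus `seed` and `out_dir`.
#' @return invisibly, the vector of files written.
#' @export
run_simulate <- function(config) {
  if (is.character(config))
    config <- read_run_config(config)
  design <- as_grid_design(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must name `out_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- simulate_grid(design, seed = seed)
  files <- character(length(grid))
  for (i in seq_along(grid)) {
    files[i] <- file.path(out_dir,
                          sprintf("dataset_c%03d_d%03d.csv", grid[[i]]$cell,
                                  grid[[i]]$dataset))
    write_trials(grid[[i]]$data, files[i])
  }
  write_manifest(out_dir, "simulate", config, seed,
                 list(n_datasets = length(grid),
                      dataset_seeds = vapply(grid, `[[`, 0L, "seed")))
  invisible(files)
}

#' Pipeline stage: fit one trial table
#'
#' Fits a variant by [sample_posterior()] and writes the posterior summary
#' table, subject-level estimates and tidy hyper-level draws.
#'
#' @param config list or JSON path with keys `trials` (CSV path), `variant`,
#'   `out_dir`, and optional `profile`/`n_chains`/`n_warmup`/`n_keep`/`seed`.
#' @return invisibly, the `rl_fit`.
#' @export
run_fit <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  trials <- read_trials(config$trials)
  cfg <- config_fit(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- sample_posterior(trials, config$variant, config = cfg)
  write.csv(summary(fit), file.path(out_dir, "posterior_summary.csv"),
            row.names = FALSE)
  write.csv(subject_estimates(fit),
            file.path(out_dir, "subject_estimates.csv"), row.names = FALSE)
  write.csv(tidy_draws(fit), file.path(out_dir, "hyper_draws.csv"),
            row.names = FALSE)
  write_manifest(out_dir, "fit", config, cfg$seed,
                 list(diagnostics = fit$diagnostics))
  invisible(fit)
}

#' Pipeline stage: compare variants on one trial table
#'
#' @param config list or JSON path with keys `trials`, `out_dir`, optional
#'   `variants` and fit-profile keys.
#' @return invisibly, the `variant_comparison`.
#' @export
run_compare <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  trials <- read_trials(config$trials)
  cfg <- config_fit(config)
  variants <- if (is.null(config$variants))
    c("A-VI", "A-FI", "S-VI", "S-FI") else config$variants
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cmp <- compare_variants(trials, variants, config = cfg, keep_fits = FALSE)
  write.csv(cmp$table, file.path(out_dir, "dic_table.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(models = cmp$table$variant, ep = cmp$bms$ep, pxp = cmp$bms$pxp,
         bor = cmp$bms$bor, alpha = cmp$bms$alpha),
    file.path(out_dir, "bms.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "compare", config, cfg$seed)
  invisible(cmp)
}

#' Pipeline stage: run a recovery study
#'
#' Simulates a grid, fits the requested variants, and writes the tidy
#' recovery table and bias curves.
#'
#' @param config list or JSON path with the grid-design fields plus
#'   `out_dir`, optional `variants` and fit-profile keys.
#' @return invisibly, the `recovery_results`.
#' @export
run_recover <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  design <- as_grid_design(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cfg <- config_fit(config)
  variants <- if (is.null(config$variants)) c("A-VI", "A-FI") else
    config$variants
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- simulate_grid(design, seed = seed)
  results <- fit_grid(grid, variants, cfg)
  write.csv(as.data.frame(results),
            file.path(out_dir, "recovery_results.csv"), row.names = FALSE)
  write.csv(bias_curves(results), file.path(out_dir, "bias_curves.csv"),
            row.names = FALSE)
  write_manifest(out_dir, "recover", config, seed)
  invisible(results)
}

#' Pipeline stage: behavioral report for a trial table
#'
#' Writes the correct-choice-rate curves, per-subject behavioral summary and
#' the stay regression.
#'
#' @param config list or JSON path with keys `trials` and `out_dir`.
#' @return invisibly, a list with the computed tables.
#' @export
run_report <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  trials <- read_trials(config$trials)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ccr <- correct_choice_rate(trials)
  bs <- behavior_summary(trials)
  stay <- stay_probability_regression(trials)
  write.csv(ccr, file.path(out_dir, "correct_choice_rate.csv"),
            row.names = FALSE)
  write.csv(bs, file.path(out_dir, "behavior_summary.csv"),
            row.names = FALSE)
  jsonlite::write_json(stay, file.path(out_dir, "stay_regression.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "report", config,
                 if (is.null(config$seed)) NA else config$seed)
  invisible(list(correct_choice_rate = ccr, behavior_summary = bs,
                 stay_regression = stay))
}
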