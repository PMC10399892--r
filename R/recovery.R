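#' Fit model variants across a simulated recovery grid
#'
#' Every dataset of the grid is fitted by each requested variant (by default
#' the free-Q0 and fixed-Q0 asymmetric models, as in the recovery study).
#' Sampler failures are recorded per dataset rather than aborting the batch.
#'
#' @param grid a `sim_grid` from [simulate_grid()].
#' @param variants variant names to fit (default `c("A-VI", "A-FI")`).
#' @param config a [fit_config()]; each dataset/variant fit derives its seed
#'   deterministically from `config$seed`.
#' @param verbose print one line per fit.
#' @return a `recovery_results` list, one record per (dataset, variant):
#'   generating parameters, hyper-level and subject-level trimmed-mean
#'   estimates, pooled mu_delta draws (asymmetric variants), and any error.
#' @export
fit_grid <- function(grid, variants = c("A-VI", "A-FI"),
                     config = fit_config("test"), verbose = FALSE) {
  stopifnot(inherits(grid, "sim_grid"))
  out <- list()
  for (i in seq_along(grid)) {
    ds <- grid[[i]]
    for (v in variants) {
      cfg <- config
      cfg$seed <- (config$seed + 7919L * i + 104729L * match(v, variants)) %%
        .Machine$integer.max
      rec <- list(q0 = ds$q0, alpha_p = ds$alpha_p, alpha_n = ds$alpha_n,
                  beta = ds$beta, cell = ds$cell, dataset = ds$dataset,
                  variant = v, error = NA_character_)
      res <- tryCatch({
        fit <- suppressWarnings(sample_posterior(ds$data, v, config = cfg))
        rec$hyper <- hyper_estimates(fit)
        rec$subjects <- subject_estimates(fit)
        if (as_variant(v)$asymmetric) rec$mu_delta <- mu_delta_draws(fit)
        rec
      }, error = function(e) {
        rec$error <- conditionMessage(e)
        rec
      })
      if (verbose)
        cat(sprintf("fit cell %d dataset %d %s%s\n", ds$cell, ds$dataset, v,
                    if (!is.na(res$error)) " [FAILED]" else ""))
      out[[length(out) + 1]] <- res
    }
  }
  structure(out, class = "recovery_results")
}

#' @export
as.data.frame.recovery_results <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) {
    h <- if (is.null(r$hyper)) c(q0 = NA, alpha_p = NA, alpha_n = NA,
                                 beta = NA) else r$hyper
    data.frame(cell = r$cell, dataset = r$dataset, variant = r$variant,
               true_q0 = r$q0, true_alpha_p = r$alpha_p,
               true_alpha_n = r$alpha_n, true_beta = r$beta,
               est_q0 = h[["q0"]], est_alpha_p = h[["alpha_p"]],
               est_alpha_n = h[["alpha_n"]], est_beta = h[["beta"]],
               error = r$error)
  }))
}

#' Estimation-bias curves over the recovery grid
#'
#' Bias = estimate - truth of the group-level learning rates (and of their
#' difference, the learning asymmetry), averaged over datasets within each
#' (Q0 level, rate pair, variant) cell.
#'
#' @param results a `recovery_results`.
#' @return data frame indexed by `variant`, `true_q0`, `true_alpha_p`,
#'   `true_alpha_n` with mean and sd of the biases of `alpha_p`, `alpha_n`
#'   and `asym = alpha_p - alpha_n`.
#' @export
bias_curves <- function(results) {
  df <- as.data.frame(results)
  df <- df[is.na(df$error), , drop = FALSE]
  if (nrow(df) == 0) stop("no successful fits")
  df$bias_alpha_p <- df$est_alpha_p - df$true_alpha_p
  df$bias_alpha_n <- df$est_alpha_n - df$true_alpha_n
  df$bias_asym <- (df$est_alpha_p - df$est_alpha_n) -
    (df$true_alpha_p - df$true_alpha_n)
  agg <- aggregate(
    df[c("bias_alpha_p", "bias_alpha_n", "bias_asym")],
    by = df[c("variant", "true_q0", "true_alpha_p", "true_alpha_n")],
    FUN = mean)
  sds <- aggregate(
    df[c("bias_alpha_p", "bias_alpha_n", "bias_asym")],
    by = df[c("variant", "true_q0", "true_alpha_p", "true_alpha_n")],
    FUN = sd)
  names(sds)[5:7] <- paste0("sd_", names(sds)[5:7])
  merge(agg, sds)
}

#' Pooled asymmetry posterior for one grid cell
#'
#' Concatenates the mu_delta draws of every dataset fitted in the requested
#' cell and classifies the recovered learning-asymmetry direction: the sign
#' of the pooled posterior median (mu_delta > 0 means alpha_n > alpha_p).
#' For a symmetric generating cell the classification is "correct" iff the
#' central 95% interval covers 0; otherwise iff the median's sign matches
#' the generating sign of alpha_n - alpha_p.
#'
#' @param results a `recovery_results`.
#' @param q0,alpha_p,alpha_n generating parameters identifying the cell.
#' @param variant which fitted variant to pool (default "A-FI").
#' @return list with `draws` (pooled mu_delta), `median`, `ci95`,
#'   `p_negative` (posterior mass on alpha_p > alpha_n), `classification`
#'   ("alpha_p > alpha_n", "alpha_n > alpha_p" or "symmetric"), `correct`.
#' @export
pooled_mu_delta <- function(results, q0, alpha_p, alpha_n,
                            variant = "A-FI") {
  recs <- Filter(function(r) {
    is.na(r$error) && r$variant == variant && isTRUE(r$q0 == q0) &&
      isTRUE(r$alpha_p == alpha_p) && isTRUE(r$alpha_n == alpha_n) &&
      !is.null(r$mu_delta)
  }, results)
  if (length(recs) == 0) stop("no fitted datasets in the requested cell")
  draws <- unlist(lapply(recs, `[[`, "mu_delta"))
  ci <- unname(quantile(draws, c(0.025, 0.975)))
  med <- median(draws)
  covers0 <- ci[1] <= 0 && ci[2] >= 0
  classification <- if (covers0) "symmetric" else if (med > 0)
    "alpha_n > alpha_p" else "alpha_p > alpha_n"
  true_sign <- sign(alpha_n - alpha_p)
  correct <- if (true_sign == 0) covers0 else
    (!covers0 && sign(med) == true_sign)
  list(draws = draws, median = med, ci95 = ci,
       p_negative = mean(draws < 0), classification = classification,
       correct = correct, n_datasets = length(recs))
}
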