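#' Configuration of the hierarchical MCMC fit
#'
#' The default ("paper") profile reproduces the study's chain geometry:
#' 4 chains, 4000 warmup iterations discarded, 6000 retained per chain
#' (24,000 retained draws per parameter), with 10% trimmed means as point
#' estimates. The "reduced" and "test" profiles scale the geometry down for
#' desk-scale and test-suite runs.
#'
#' @param profile "paper" (4 x 4000/6000), "reduced" (4 x 1000/1500) or
#'   "test" (2 x 1000/1000).
#' @param n_chains,n_warmup,n_keep override the profile's chain geometry.
#' @param trim trimmed-mean fraction per tail (default 0.10).
#' @param rhat_threshold split-R-hat value above which a convergence warning
#'   is raised (default 1.05).
#' @param seed integer seed; every chain derives deterministically from it.
#' @param mu_prior_sd sd of the Normal(0, .) prior on hyper means (default 2).
#' @param sigma_prior_scale scale of the half-Cauchy prior on hyper sds
#'   (default 5).
#' @return a `fit_config` list.
#' @export
fit_config <- function(profile = c("paper", "reduced", "test"),
                       n_chains = NULL, n_warmup = NULL, n_keep = NULL,
                       trim = 0.10, rhat_threshold = 1.05, seed = 1L,
                       mu_prior_sd = 2, sigma_prior_scale = 5) {
  profile <- match.arg(profile)
  geom <- switch(profile,
    paper   = c(4L, 4000L, 6000L),
    reduced = c(4L, 1000L, 1500L),
    test    = c(2L, 1000L, 1000L)
  )
  cfg <- list(profile = profile,
              n_chains = if (is.null(n_chains)) geom[1] else as.integer(n_chains),
              n_warmup = if (is.null(n_warmup)) geom[2] else as.integer(n_warmup),
              n_keep = if (is.null(n_keep)) geom[3] else as.integer(n_keep),
              trim = trim, rhat_threshold = rhat_threshold,
              seed = as.integer(seed), mu_prior_sd = mu_prior_sd,
              sigma_prior_scale = sigma_prior_scale)
  if (cfg$n_chains < 1 || cfg$n_warmup < 0 || cfg$n_keep < 1)
    stop("invalid chain geometry")
  if (trim < 0 || trim >= 0.5) stop("`trim` must lie in [0, 0.5)")
  structure(cfg, class = "fit_config")
}

# Raw (transformed-scale) parameter names present under a variant.
raw_param_names <- function(variant) {
  variant <- as_variant(variant)
  c(if (variant$free_q0) "q0", "alpha_p", if (variant$asymmetric) "delta",
    "beta")
}

split_subjects <- function(data, condition) {
  check_trials(data, condition)
  ids <- unique(data$subject)
  subj <- lapply(ids, function(id) {
    d <- data[data$subject == id, , drop = FALSE]
    list(choice = as.integer(d$choice), outcome = as.numeric(d$outcome),
         block = as.integer(d$block))
  })
  list(ids = ids, subjects = subj)
}

#' Joint log density of the hierarchical model
#'
#' Sum of (a) the hyper-prior log densities (Normal(0, `mu_prior_sd`) on
#' each hyper mean, half-Cauchy(0, `sigma_prior_scale`) on each hyper sd),
#' (b) the Normal(mu_k, sigma_k) log densities of every subject's raw
#' parameters, and (c) the Q-learning log likelihood of every subject's data
#' at the probit-transformed natural parameters. This is the target density
#' that [sample_posterior()] draws from.
#'
#' @param hyper list with named numeric vectors `mu` and `sigma` over
#'   [raw_param_names()] of the variant.
#' @param subjects_raw matrix (subjects x raw parameters, named columns) of
#'   unbounded subject-level parameters.
#' @param data multi-subject trial table (may have zero subjects).
#' @param variant model variant.
#' @param condition valence condition.
#' @param mu_prior_sd,sigma_prior_scale hyper-prior settings.
#' @return the joint log density (scalar).
#' @export
joint_log_density <- function(hyper, subjects_raw, data, variant, condition,
                              mu_prior_sd = 2, sigma_prior_scale = 5) {
  variant <- as_variant(variant)
  pn <- raw_param_names(variant)
  if (any(hyper$sigma <= 0)) stop("hyper sds must be positive")
  ld <- sum(dnorm(hyper$mu[pn], 0, mu_prior_sd, log = TRUE)) +
    sum(log(2) - log(pi * sigma_prior_scale *
                       (1 + (hyper$sigma[pn] / sigma_prior_scale)^2)))
  n <- if (is.null(subjects_raw)) 0L else nrow(subjects_raw)
  if (n == 0L) return(ld)
  ids <- unique(data$subject)
  if (length(ids) != n) stop("subject set mismatch between draws and data")
  b <- q0_bounds(condition)
  for (i in seq_len(n)) {
    raw <- subjects_raw[i, pn]
    ld <- ld + sum(dnorm(raw, hyper$mu[pn], hyper$sigma[pn], log = TRUE))
    nat <- list(
      q0 = if (variant$free_q0) to_natural(raw[["q0"]], b[1], b[2]) else
        unname(variant$fixed_q0[condition]),
      alpha_p = phi(raw[["alpha_p"]]),
      alpha_n = if (variant$asymmetric)
        neg_lr_from_offset(raw[["alpha_p"]], raw[["delta"]]) else
          phi(raw[["alpha_p"]]),
      beta = to_natural(raw[["beta"]], 0, 20))
    d <- data[data$subject == ids[i], , drop = FALSE]
    ld <- ld + cpp_loglik(as.integer(d$choice), as.numeric(d$outcome),
                          as.integer(d$block), nat$q0, nat$alpha_p,
                          nat$alpha_n, nat$beta)
  }
  ld
}

#' Sample the hierarchical posterior
#'
#' Draws from the posterior defined by [joint_log_density()] using an
#' adaptive Metropolis-within-Gibbs scheme (componentwise random-walk
#' Metropolis on subject-level parameters with likelihood caching, conjugate
#' Gibbs updates for the hyper means, log-scale Metropolis for the hyper
#' sds; proposal scales adapted toward 44% acceptance during warmup only).
#' Chains run sequentially from the configuration seed, so results are fully
#' reproducible.
#'
#' @param data multi-subject trial table (columns `subject`, `block`,
#'   `trial`, `choice`, `outcome`).
#' @param variant variant name or [model_variant()].
#' @param condition valence condition; defaults to the table's `condition`
#'   column.
#' @param config a [fit_config()].
#' @return an `rl_fit` object holding per-chain draws of hyper parameters,
#'   subject-level raw parameters and per-subject log likelihoods, plus
#'   split-R-hat / effective-sample-size diagnostics. A warning is raised if
#'   any hyper-parameter split-R-hat exceeds the configured threshold.
#' @export
sample_posterior <- function(data, variant, condition = NULL,
                             config = fit_config()) {
  variant <- as_variant(variant)
  if (is.null(condition)) condition <- as.character(data$condition[1])
  condition <- match.arg(condition, CONDITIONS)
  sp <- split_subjects(data, condition)
  n <- length(sp$ids)
  if (n < 1) stop("need at least one subject")
  pn <- raw_param_names(variant)
  K <- length(pn)
  b <- q0_bounds(condition)
  fixed_q0 <- if (variant$free_q0) NA_real_ else
    unname(variant$fixed_q0[condition])

  set.seed(config$seed)
  chains <- lapply(seq_len(config$n_chains), function(ch) {
    cpp_sample_chain(sp$subjects, 0L, variant$free_q0, variant$asymmetric,
                     if (is.na(fixed_q0)) 0 else fixed_q0, b[1], b[2], 20,
                     config$n_warmup, config$n_keep, config$mu_prior_sd,
                     config$sigma_prior_scale)
  })

  mu <- array(NA_real_, c(config$n_keep, config$n_chains, K),
              dimnames = list(NULL, NULL, pn))
  sigma <- mu
  raw <- array(NA_real_, c(config$n_keep, config$n_chains, n, K),
               dimnames = list(NULL, NULL, sp$ids, pn))
  loglik <- array(NA_real_, c(config$n_keep, config$n_chains, n))
  for (ch in seq_along(chains)) {
    mu[, ch, ] <- chains[[ch]]$mu
    sigma[, ch, ] <- chains[[ch]]$sigma
    raw[, ch, , ] <- aperm(array(t(chains[[ch]]$raw), c(K, n, config$n_keep)),
                           c(3, 2, 1))
    loglik[, ch, ] <- chains[[ch]]$loglik
  }

  diag <- data.frame(
    parameter = c(paste0("mu_", pn), paste0("sigma_", pn)),
    rhat = c(vapply(seq_len(K), function(k) split_rhat(mu[, , k, drop = FALSE]),
                    0),
             vapply(seq_len(K), function(k)
               split_rhat(sigma[, , k, drop = FALSE]), 0)),
    ess = c(vapply(seq_len(K), function(k) ess_basic(mu[, , k, drop = FALSE]),
                   0),
            vapply(seq_len(K), function(k)
              ess_basic(sigma[, , k, drop = FALSE]), 0)))

  fit <- structure(list(mu = mu, sigma = sigma, raw = raw, loglik = loglik,
                        subjects = sp$ids, param_names = pn,
                        variant = variant, condition = condition,
                        bounds = b, fixed_q0 = fixed_q0, config = config,
                        diagnostics = diag),
                   class = "rl_fit")
  bad <- diag$parameter[is.finite(diag$rhat) &
                          diag$rhat > config$rhat_threshold]
  if (length(bad))
    warning(sprintf("split-R-hat above %.2f for: %s", config$rhat_threshold,
                    paste(bad, collapse = ", ")),
            call. = FALSE)
  fit
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf(
    "<rl_fit: %s, %s, %d subjects, %d chains x %d draws (%d retained)>\n",
    x$variant$name, x$condition, length(x$subjects), x$config$n_chains,
    x$config$n_keep, n_draws(x)))
  invisible(x)
}

#' Number of retained posterior draws per parameter
#'
#' @param fit an `rl_fit`.
#' @return `n_chains * n_keep`.
#' @export
n_draws <- function(fit) fit$config$n_chains * fit$config$n_keep

# Flatten an [iter, chain, ...] array over its first two dims.
flatten_draws <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1] * d[2], d[-(1:2)])
  a
}

#' Pooled draws of the asymmetry hyper mean mu_delta
#'
#' @param fit an `rl_fit` of an asymmetric variant.
#' @return vector of all retained mu_delta draws (chains concatenated).
#' @export
mu_delta_draws <- function(fit) {
  if (!fit$variant$asymmetric)
    stop("mu_delta exists only for asymmetric variants")
  as.vector(fit$mu[, , "delta"])
}

# Natural-scale draws of the group-level (hyper-mean) parameters:
# one row per retained draw, columns q0, alpha_p, alpha_n, beta.
hyper_natural_draws <- function(fit) {
  pn <- fit$param_names
  mu <- flatten_draws(fit$mu)
  colnames(mu) <- pn
  q0 <- if (fit$variant$free_q0)
    to_natural(mu[, "q0"], fit$bounds[1], fit$bounds[2]) else
      rep(fit$fixed_q0, nrow(mu))
  ap <- phi(mu[, "alpha_p"])
  an <- if (fit$variant$asymmetric)
    phi(mu[, "alpha_p"] + mu[, "delta"]) else ap
  cbind(q0 = q0, alpha_p = ap, alpha_n = an,
        beta = to_natural(mu[, "beta"], 0, 20))
}

#' Group-level natural-scale estimates
#'
#' Trimmed means, over all retained draws, of the hyper means pushed through
#' the probit transform: the group-typical Q0, learning rates and inverse
#' temperature implied by the fitted hyper distribution.
#'
#' @param fit an `rl_fit`.
#' @param trim trimmed-mean fraction (defaults to the fit configuration's).
#' @return named vector `c(q0, alpha_p, alpha_n, beta)`.
#' @export
hyper_estimates <- function(fit, trim = fit$config$trim) {
  nat <- hyper_natural_draws(fit)
  apply(nat, 2, trimmed_mean, trim = trim)
}

# Natural-scale draws per subject: array [draw, subject, param4].
subject_natural_draws <- function(fit) {
  raw <- flatten_draws(fit$raw)  # [draw, subject, K]
  pn <- fit$param_names
  nd <- dim(raw)[1]
  n <- dim(raw)[2]
  out <- array(NA_real_, c(nd, n, 4),
               dimnames = list(NULL, fit$subjects,
                               c("q0", "alpha_p", "alpha_n", "beta")))
  ap_raw <- raw[, , which(pn == "alpha_p"), drop = FALSE]
  dim(ap_raw) <- c(nd, n)
  out[, , "q0"] <- if (fit$variant$free_q0) {
    q0r <- raw[, , which(pn == "q0"), drop = FALSE]
    dim(q0r) <- c(nd, n)
    to_natural(q0r, fit$bounds[1], fit$bounds[2])
  } else fit$fixed_q0
  out[, , "alpha_p"] <- phi(ap_raw)
  out[, , "alpha_n"] <- if (fit$variant$asymmetric) {
    dr <- raw[, , which(pn == "delta"), drop = FALSE]
    dim(dr) <- c(nd, n)
    phi(ap_raw + dr)
  } else phi(ap_raw)
  out[, , "beta"] <- {
    br <- raw[, , which(pn == "beta"), drop = FALSE]
    dim(br) <- c(nd, n)
    to_natural(br, 0, 20)
  }
  out
}

#' Subject-level natural-scale estimates
#'
#' Per-subject trimmed means of the natural-scale posterior draws.
#'
#' @inheritParams hyper_estimates
#' @return data frame with columns `subject`, `q0`, `alpha_p`, `alpha_n`,
#'   `beta`.
#' @export
subject_estimates <- function(fit, trim = fit$config$trim) {
  nat <- subject_natural_draws(fit)
  est <- apply(nat, c(2, 3), trimmed_mean, trim = trim)
  data.frame(subject = fit$subjects, est, row.names = NULL)
}

#' @export
summary.rl_fit <- function(object, ...) {
  pn <- object$param_names
  rows <- lapply(seq_along(pn), function(k) {
    m <- as.vector(object$mu[, , k])
    s <- as.vector(object$sigma[, , k])
    data.frame(parameter = c(paste0("mu_", pn[k]), paste0("sigma_", pn[k])),
               trimmed_mean = c(trimmed_mean(m, object$config$trim),
                                trimmed_mean(s, object$config$trim)),
               posterior_sd = c(sd(m), sd(s)))
  })
  out <- do.call(rbind, rows)
  merge(out, object$diagnostics, by = "parameter", sort = FALSE)
}

#' Export posterior draws as a tidy table
#'
#' @param fit an `rl_fit`.
#' @return data frame with columns `chain`, `iteration`, `parameter`,
#'   `value` covering the hyper-level draws.
#' @export
tidy_draws <- function(fit) {
  pn <- fit$param_names
  n_keep <- fit$config$n_keep
  out <- list()
  for (k in seq_along(pn)) {
    for (ch in seq_len(fit$config$n_chains)) {
      out[[length(out) + 1]] <- data.frame(
        chain = ch, iteration = seq_len(n_keep),
        parameter = paste0("mu_", pn[k]), value = fit$mu[, ch, k])
      out[[length(out) + 1]] <- data.frame(
        chain = ch, iteration = seq_len(n_keep),
        parameter = paste0("sigma_", pn[k]), value = fit$sigma[, ch, k])
    }
  }
  do.call(rbind, out)
}

# --- convergence diagnostics -----------------------------------------------

#' Split R-hat of a set of chains
#'
#' Each chain is split in half and the usual potential-scale-reduction
#' statistic is computed over the split halves.
#'
#' @param x matrix or array \[iteration, chain\].
#' @return the split R-hat (>= 1 in expectation; NaN for constant chains).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(flatten_chain_matrix(x))
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  v <- (half - 1) / half * W + B / half
  sqrt(v / W)
}

#' Basic effective sample size
#'
#' Sum-of-autocorrelations estimator truncated at the first negative pair
#' (Geyer's initial positive sequence), averaged across chains.
#'
#' @inheritParams split_rhat
#' @return estimated effective sample size over all chains.
#' @export
ess_basic <- function(x) {
  x <- as.matrix(flatten_chain_matrix(x))
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4) return(NA_real_)
  max_lag <- min(n - 2, 500)
  rho <- sapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1]
    a
  })
  rho <- rowMeans(as.matrix(rho))
  s <- 0
  lag <- 1
  while (lag + 1 <= length(rho)) {
    pair <- rho[lag] + rho[lag + 1]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    lag <- lag + 2
  }
  n * m / (1 + 2 * s)
}

flatten_chain_matrix <- function(x) {
  if (is.array(x) && length(dim(x)) > 2) {
    d <- dim(x)
    dim(x) <- c(d[1], d[2])
  }
  x
}
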