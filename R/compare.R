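#' Deviance of a trial sequence at fixed parameters
#'
#' `-2 *` [log_likelihood()].
#'
#' @inheritParams log_likelihood
#' @return the deviance (nonnegative for any nonempty sequence).
#' @export
deviance_rl <- function(params, variant, trials, condition) {
  -2 * log_likelihood(params, variant, trials, condition)
}

# Plug-in deviance per subject at the subject-level trimmed-mean natural
# parameters.
plugin_deviance <- function(fit, data) {
  est <- subject_estimates(fit)
  vapply(seq_along(fit$subjects), function(i) {
    d <- data[data$subject == fit$subjects[i], , drop = FALSE]
    -2 * cpp_loglik(as.integer(d$choice), as.numeric(d$outcome),
                    as.integer(d$block), est$q0[i], est$alpha_p[i],
                    est$alpha_n[i], est$beta[i])
  }, 0)
}

#' Deviance information criterion of a hierarchical fit
#'
#' `D_bar` is the posterior mean of the total deviance (summed over
#' subjects, using each draw's subject-level parameters); `D_hat` the
#' deviance at the per-subject trimmed-mean natural parameters;
#' `p_D = D_bar - D_hat` the effective number of parameters; and
#' `DIC = D_bar + p_D`. Per-subject decompositions are returned so the same
#' quantities feed the group-level model selection.
#'
#' @param fit an `rl_fit`.
#' @param data the trial table the fit was run on.
#' @return a `dic_summary` list with `D_bar`, `D_hat`, `p_D`, `DIC` and a
#'   per-subject data frame of the same decomposition.
#' @export
dic <- function(fit, data) {
  dev <- -2 * flatten_draws(fit$loglik)  # [draw, subject]
  if (ncol(dev) != length(fit$subjects)) stop("draw/data mismatch")
  d_bar_i <- colMeans(dev)
  d_hat_i <- plugin_deviance(fit, data)
  p_d_i <- d_bar_i - d_hat_i
  per_subject <- data.frame(subject = fit$subjects, D_bar = d_bar_i,
                            D_hat = d_hat_i, p_D = p_d_i,
                            DIC = d_bar_i + p_d_i)
  structure(list(D_bar = sum(d_bar_i), D_hat = sum(d_hat_i),
                 p_D = sum(p_d_i), DIC = sum(d_bar_i + p_d_i),
                 per_subject = per_subject),
            class = "dic_summary")
}

#' @export
print.dic_summary <- function(x, ...) {
  cat(sprintf("DIC = %.2f  (D_bar = %.2f, D_hat = %.2f, p_D = %.2f)\n",
              x$DIC, x$D_bar, x$D_hat, x$p_D))
  invisible(x)
}

#' Subject-wise approximate log model evidence
#'
#' The evidence proxy feeding the group-level model selection: per subject,
#' `-DIC_i / 2`, with `DIC_i` the subject's deviance decomposition from
#' [dic()].
#'
#' @inheritParams dic
#' @return named numeric vector of per-subject log evidences.
#' @export
subject_evidence <- function(fit, data) {
  d <- dic(fit, data)
  stats::setNames(-d$per_subject$DIC / 2, d$per_subject$subject)
}

# Variational free energy of the random-effects model (Dirichlet posterior
# `alpha`, responsibilities `u`, log evidences `lme`, prior `alpha0`).
bms_free_energy <- function(lme, u, alpha, alpha0) {
  elog_r <- digamma(alpha) - digamma(sum(alpha))
  s_qf <- sum(lgamma(alpha)) - lgamma(sum(alpha)) - sum((alpha - 1) * elog_r)
  s_qm <- -sum(u * log(u + .Machine$double.eps))
  elj <- lgamma(sum(alpha0)) - sum(lgamma(alpha0)) +
    sum((alpha0 - 1) * elog_r) +
    sum(u * sweep(lme, 2, elog_r, "+"))
  elj + s_qf + s_qm
}

#' Group-level random-effects Bayesian model selection
#'
#' Runs the variational scheme over model frequencies: subject-wise
#' posterior model assignments are iterated against a Dirichlet posterior
#' over frequencies until convergence. Exceedance probabilities (EP) are
#' estimated by Monte-Carlo draws from the Dirichlet posterior; the Bayes
#' omnibus risk (BOR) is the posterior probability of the null
#' (equal-frequency) model obtained from the variational free-energy
#' comparison; and the protected exceedance probability is
#' `PXP = EP * (1 - BOR) + BOR / K`.
#'
#' @param evidence subjects x models matrix of (approximate) log model
#'   evidences, e.g. built from [subject_evidence()] columns.
#' @param n_mc Monte-Carlo draws for the EP estimate (default 1e6).
#' @param alpha0 Dirichlet prior concentration (default 1 per model).
#' @param max_iter,tol variational iteration controls.
#' @return a `bms_result` with fields `alpha` (Dirichlet posterior),
#'   `expected_freq`, `ep`, `bor`, `pxp`, `u` (subject responsibilities).
#' @export
group_bms <- function(evidence, n_mc = 1e6, alpha0 = 1, max_iter = 1000,
                      tol = 1e-8) {
  evidence <- as.matrix(evidence)
  if (any(!is.finite(evidence))) stop("non-finite evidence")
  n <- nrow(evidence)
  K <- ncol(evidence)
  if (n < 1 || K < 2) stop("need >= 1 subject and >= 2 models")
  alpha0 <- rep_len(alpha0, K)

  alpha <- alpha0 + n / K
  u <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    w <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    w <- w - apply(w, 1, max)
    u <- exp(w)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
    if (it == max_iter) warning("group BMS did not converge", call. = FALSE)
  }

  # EP by Monte Carlo from the Dirichlet posterior
  g <- matrix(rgamma(n_mc * K, shape = rep(alpha, each = n_mc)), n_mc, K)
  ep <- tabulate(max.col(g), nbins = K) / n_mc

  # BOR: null model has fixed equal frequencies; its evidence is exact
  f1 <- bms_free_energy(evidence, u, alpha, alpha0)
  lse <- apply(evidence, 1, function(r) {
    m <- max(r)
    m + log(sum(exp(r - m)))
  })
  f0 <- sum(lse - log(K))
  bor <- 1 / (1 + exp(f1 - f0))

  structure(list(alpha = alpha, expected_freq = alpha / sum(alpha),
                 ep = ep, bor = bor, pxp = ep * (1 - bor) + bor / K,
                 u = u, models = colnames(evidence)),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  nm <- if (is.null(x$models)) paste0("M", seq_along(x$pxp)) else x$models
  cat("Group Bayesian model selection\n")
  cat(sprintf("  BOR = %.4f\n", x$bor))
  for (k in seq_along(x$pxp))
    cat(sprintf("  %-8s EP = %.4f  PXP = %.4f\n", nm[k], x$ep[k], x$pxp[k]))
  invisible(x)
}

#' Fit and compare model variants on one dataset
#'
#' Fits every requested variant by [sample_posterior()], assembles the DIC
#' table, and runs [group_bms()] on the subject-evidence matrix.
#'
#' @param data multi-subject trial table.
#' @param variants character vector of variant names (default the four core
#'   variants).
#' @param condition valence condition (default from the data).
#' @param config a [fit_config()].
#' @param n_mc Monte-Carlo draws for the EP estimate.
#' @param keep_fits return the individual `rl_fit` objects (default TRUE).
#' @return a `variant_comparison` with `table` (one row per variant, DIC
#'   decomposition and PXP, ranked by DIC), `bms`, `evidence`, and
#'   optionally `fits`.
#' @export
compare_variants <- function(data, variants = c("A-VI", "A-FI", "S-VI",
                                                "S-FI"),
                             condition = NULL, config = fit_config(),
                             n_mc = 1e5, keep_fits = TRUE) {
  if (is.null(condition)) condition <- as.character(data$condition[1])
  fits <- lapply(variants, function(v)
    sample_posterior(data, v, condition, config))
  names(fits) <- variants
  dics <- lapply(fits, dic, data = data)
  tab <- data.frame(
    variant = variants,
    D_bar = vapply(dics, `[[`, 0, "D_bar"),
    D_hat = vapply(dics, `[[`, 0, "D_hat"),
    p_D = vapply(dics, `[[`, 0, "p_D"),
    DIC = vapply(dics, `[[`, 0, "DIC"))
  if (length(variants) >= 2) {
    ev <- vapply(dics, function(d)
      stats::setNames(-d$per_subject$DIC / 2, d$per_subject$subject),
      numeric(nrow(dics[[1]]$per_subject)))
    bms <- group_bms(ev, n_mc = n_mc)
    tab$PXP <- bms$pxp
  } else {
    ev <- NULL
    bms <- list(pxp = 1, ep = 1, bor = 0)
    tab$PXP <- 1
  }
  tab <- tab[order(tab$DIC), ]
  structure(list(table = tab, bms = bms, evidence = ev,
                 fits = if (keep_fits) fits),
            class = "variant_comparison")
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat("Variant comparison (ranked by DIC)\n")
  print(x$table, row.names = FALSE, digits = 5)
  invisible(x)
}
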