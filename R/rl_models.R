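#' Agent parameters for the asymmetric Q-learning model
#'
#' Bundles the natural-scale parameters (Q0, alpha_p, alpha_n, beta) with
#' validation: learning rates in \[0, 1\], inverse temperature in \[0, 20\],
#' and Q0 within the condition's outcome range ([q0_bounds()]).
#'
#' @param q0 initial expectation, shared by both options.
#' @param alpha_p,alpha_n learning rates for positive / negative prediction
#'   errors, each in \[0, 1\].
#' @param beta softmax inverse temperature in \[0, 20\].
#' @param condition optional valence condition against which `q0` is checked.
#' @return an `agent_params` list.
#' @export
agent_params <- function(q0, alpha_p, alpha_n = alpha_p, beta,
                         condition = NULL) {
  if (alpha_p < 0 || alpha_p > 1 || alpha_n < 0 || alpha_n > 1)
    stop("learning rates must lie in [0, 1]")
  if (beta < 0 || beta > 20) stop("`beta` must lie in [0, 20]")
  if (!is.null(condition)) {
    b <- q0_bounds(condition)
    if (q0 < b[1] || q0 > b[2])
      stop(sprintf("`q0` = %g outside [%g, %g] for the %s condition",
                   q0, b[1], b[2], condition))
  }
  structure(list(q0 = q0, alpha_p = alpha_p, alpha_n = alpha_n, beta = beta),
            class = "agent_params")
}

#' Model variant registry
#'
#' The four core variants cross Asymmetric vs Symmetric learning rates with
#' Variable (free) vs Fixed initial expectation, plus the primed fixed
#' variants with Q0 pinned to 0 in every condition:
#' \describe{
#'   \item{A-VI}{asymmetric rates, free Q0 (the full model)}
#'   \item{A-FI}{asymmetric rates, Q0 fixed at the condition's mean outcome
#'     (gain 0.5, loss -0.5, mixed 0)}
#'   \item{S-VI}{symmetric rates (`alpha_n = alpha_p`), free Q0}
#'   \item{S-FI}{symmetric rates, fixed Q0 as A-FI}
#'   \item{A-FI', S-FI'}{as A-FI / S-FI but with Q0 fixed at 0 everywhere}
#' }
#'
#' @param name one of `variant_names()`.
#' @return a `model_variant` with fields `name`, `asymmetric`, `free_q0`,
#'   `fixed_q0` (named vector by condition, NA for free-Q0 variants).
#' @export
model_variant <- function(name) {
  name <- match.arg(name, variant_names())
  asymmetric <- substr(name, 1, 1) == "A"
  free_q0 <- grepl("VI", name)
  fixed_q0 <- if (free_q0) {
    c(gain = NA_real_, loss = NA_real_, mixed = NA_real_)
  } else if (grepl("'", name)) {
    c(gain = 0, loss = 0, mixed = 0)
  } else {
    c(gain = 0.5, loss = -0.5, mixed = 0)
  }
  structure(list(name = name, asymmetric = asymmetric, free_q0 = free_q0,
                 fixed_q0 = fixed_q0),
            class = "model_variant")
}

#' @rdname model_variant
#' @export
variant_names <- function() c("A-VI", "A-FI", "S-VI", "S-FI", "A-FI'", "S-FI'")

as_variant <- function(x) if (inherits(x, "model_variant")) x else
  model_variant(x)

# Resolve natural parameters under a variant's rules: symmetric variants
# force alpha_n = alpha_p; fixed-Q0 variants override q0.
resolve_params <- function(params, variant, condition) {
  variant <- as_variant(variant)
  p <- unclass(params)
  if (!variant$asymmetric) p$alpha_n <- p$alpha_p
  if (!variant$free_q0) p$q0 <- unname(variant$fixed_q0[condition])
  p
}

#' Asymmetric value update
#'
#' One Q-learning step for the chosen option:
#' `Q <- Q + alpha_p * (r - Q)` when the prediction error (r minus Q) is >= 0,
#' and `Q + alpha_n * (r - Q)` otherwise. A zero prediction error takes the
#' positive branch (which leaves Q unchanged either way).
#'
#' @param q current value (vectorized).
#' @param r obtained outcome code.
#' @param alpha_p,alpha_n learning rates in \[0, 1\].
#' @return updated value(s).
#' @export
q_update <- function(q, r, alpha_p, alpha_n) {
  if (any(c(alpha_p, alpha_n) < 0) || any(c(alpha_p, alpha_n) > 1))
    stop("learning rates must lie in [0, 1]")
  delta <- r - q
  q + ifelse(delta >= 0, alpha_p, alpha_n) * delta
}

#' Softmax choice probability
#'
#' Probability of choosing the left option,
#' `1 / (1 + exp(-beta * (q_left - q_right)))`, numerically stable over the
#' full \[0, 20\] range of the inverse temperature.
#'
#' @param q_left,q_right current option values.
#' @param beta inverse temperature in \[0, 20\].
#' @return probability of the left option.
#' @export
choice_prob <- function(q_left, q_right, beta) {
  stats::plogis(beta * (q_left - q_right))
}

check_trials <- function(trials, condition = NULL) {
  need <- c("block", "trial", "choice", "outcome")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(trials$choice %in% c(0L, 1L)))
    stop("choices must be coded 0/1")
  if (!is.null(condition)) {
    legal <- unname(valence_outcomes(condition))
    bad <- setdiff(unique(trials$outcome), legal)
    if (length(bad))
      stop(sprintf("outcome code(s) %s illegal for the %s condition",
                   paste(bad, collapse = ", "), condition))
  }
  invisible(trials)
}

#' Log likelihood of one subject's choice sequence
#'
#' Replays the trial sequence under a model variant: both options start at
#' the variant's Q0 at each block start, each observed choice contributes the
#' log softmax probability, and only the chosen option's value is updated via
#' the asymmetric rule.
#'
#' @param params an [agent_params()] (or list with the same fields).
#' @param variant a variant name or [model_variant()].
#' @param trials single-subject trial data frame with columns `block`,
#'   `trial`, `choice` (0/1), `outcome` (-1/0/+1).
#' @param condition valence condition of the data.
#' @return total log likelihood (scalar).
#' @export
log_likelihood <- function(params, variant, trials, condition) {
  condition <- match.arg(condition, CONDITIONS)
  check_trials(trials, condition)
  p <- resolve_params(params, variant, condition)
  b <- q0_bounds(condition)
  if (p$q0 < b[1] || p$q0 > b[2]) stop("`q0` outside condition bounds")
  if (p$beta < 0 || p$beta > 20) stop("`beta` outside [0, 20]")
  cpp_loglik(as.integer(trials$choice), as.numeric(trials$outcome),
             as.integer(trials$block), p$q0, p$alpha_p, p$alpha_n, p$beta)
}

#' Per-trial value trajectory and prediction errors
#'
#' Same replay as [log_likelihood()], returning the internals per trial:
#' both options' pre-update values, the chosen option's pre-update value,
#' the prediction error, and the model probability of the observed choice.
#'
#' @inheritParams log_likelihood
#' @return data frame with columns `q0_pre`, `q1_pre`, `q_chosen`, `delta`,
#'   `p_choice`, one row per trial.
#' @export
q_trajectory <- function(params, variant, trials, condition) {
  condition <- match.arg(condition, CONDITIONS)
  check_trials(trials, condition)
  p <- resolve_params(params, variant, condition)
  m <- cpp_q_trajectory(as.integer(trials$choice), as.numeric(trials$outcome),
                        as.integer(trials$block), p$q0, p$alpha_p, p$alpha_n,
                        p$beta)
  out <- as.data.frame(m)
  names(out) <- c("q0_pre", "q1_pre", "q_chosen", "delta", "p_choice")
  out
}
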