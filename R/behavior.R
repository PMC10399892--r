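#' Correct-choice rate by trial position
#'
#' "Correct" means choosing the option with the higher expected value:
#' the higher reinforcement probability in gain and mixed conditions, the
#' lower loss probability in the loss condition. Rates are aggregated across
#' subjects by probability pair and within-block trial index. Trials whose
#' two options have equal probability have no defined correct answer and
#' are reported with `rate = NA`.
#'
#' @param trials multi-subject trial table with `p0`, `p1` columns.
#' @return data frame with columns `pair` (probability pair label), `trial`,
#'   `rate`, `n` (subjects contributing).
#' @export
correct_choice_rate <- function(trials) {
  check_trials(trials)
  condition <- as.character(trials$condition[1])
  better <- if (condition == "loss")
    ifelse(trials$p0 < trials$p1, 0L, 1L) else
      ifelse(trials$p0 > trials$p1, 0L, 1L)
  defined <- trials$p0 != trials$p1
  correct <- ifelse(defined, as.numeric(trials$choice == better), NA)
  pair <- sprintf("%g/%g", pmin(trials$p0, trials$p1) * 100,
                  pmax(trials$p0, trials$p1) * 100)
  df <- data.frame(pair = pair, trial = trials$trial, correct = correct)
  n <- aggregate(correct ~ pair + trial, df, FUN = length,
                 na.action = stats::na.pass)
  names(n)[3] <- "n"
  rate <- aggregate(correct ~ pair + trial, df,
                    FUN = function(z) if (all(is.na(z))) NA_real_ else
                      mean(z, na.rm = TRUE),
                    na.action = stats::na.pass)
  names(rate)[3] <- "rate"
  out <- merge(rate, n)
  out[order(out$pair, out$trial), c("pair", "trial", "rate", "n")]
}

# Iteratively reweighted least squares for a logistic regression y ~ 1 + x.
irls_logistic <- function(y, x, max_iter = 50, tol = 1e-10) {
  X <- cbind(1, x)
  b <- c(0, 0)
  separated <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    if (any(w < 1e-12)) w <- pmax(w, 1e-12)
    z <- eta + (y - p) / w
    XtW <- t(X * w)
    b_new <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
    if (is.null(b_new)) {
      separated <- TRUE
      break
    }
    b_new <- drop(b_new)
    if (max(abs(b_new - b)) < tol) {
      b <- b_new
      break
    }
    b <- b_new
  }
  if (max(abs(b)) > 15) separated <- TRUE
  eta <- drop(X %*% b)
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  cov <- tryCatch(solve(t(X * w) %*% X), error = function(e)
    matrix(NA_real_, 2, 2))
  list(coef = unname(b), se = unname(sqrt(diag(cov))),
       separated = separated)
}

#' Stay-probability regression on the previous outcome
#'
#' Fixed-effects logistic regression (own iteratively-reweighted least
#' squares) of staying (repeating the previous trial's choice) on whether
#' the previous trial's outcome was the condition's reinforced event.
#' A positive coefficient is the win-stay signature of reward learning.
#'
#' @param trials multi-subject trial table.
#' @return list with `coefficient` (slope of previous reinforcement),
#'   `se`, `intercept`, `separated` (perfect-separation flag), `n_obs`.
#' @export
stay_probability_regression <- function(trials) {
  check_trials(trials)
  condition <- as.character(trials$condition[1])
  rein <- valence_outcomes(condition)[["reinforced"]]
  pieces <- split(trials, list(trials$subject, trials$block), drop = TRUE)
  ys <- xs <- list()
  for (d in pieces) {
    if (nrow(d) < 2) next
    d <- d[order(d$trial), , drop = FALSE]
    ys[[length(ys) + 1]] <- as.numeric(d$choice[-1] == d$choice[-nrow(d)])
    xs[[length(xs) + 1]] <- as.numeric(d$outcome[-nrow(d)] == rein)
  }
  y <- unlist(ys)
  x <- unlist(xs)
  if (length(y) < 2) stop("need at least 2 trials per block")
  fit <- irls_logistic(y, x)
  list(coefficient = fit$coef[2], se = fit$se[2], intercept = fit$coef[1],
       separated = fit$separated, n_obs = length(y))
}

#' Preferred response rate of a block
#'
#' The choice rate of the option the subject selected most often; 0.5 for a
#' perfectly balanced block, 1 for exclusive choice of one option.
#'
#' @param choices vector of 0/1 choices within one block.
#' @return rate in \[0.5, 1\].
#' @export
preferred_response_rate <- function(choices) {
  if (length(choices) == 0) stop("empty choice vector")
  max(mean(choices == 0), mean(choices == 1))
}

#' Pearson correlation with two-sided significance
#'
#' Sums-of-products implementation of the Pearson coefficient with the
#' t-distribution transform for the two-sided p value.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `r`, `t`, `df`, `p`.
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3) stop("need >= 3 paired observations")
  sx <- sum(x)
  sy <- sum(y)
  sxx <- sum(x^2) - sx^2 / n
  syy <- sum(y^2) - sy^2 / n
  if (sxx <= 0 || syy <= 0) stop("zero variance in `x` or `y`")
  r <- (sum(x * y) - sx * sy / n) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  df <- n - 2
  t <- if (abs(r) == 1) Inf * sign(r) else r * sqrt(df / (1 - r^2))
  list(r = r, t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Association between preferred response rate and fitted Q0
#'
#' @param prr per-subject preferred response rates.
#' @param q0 per-subject fitted initial expectations.
#' @return as [pearson_cor()].
#' @export
prr_q0_association <- function(prr, q0) pearson_cor(prr, q0)

#' Paired t test (closed form)
#'
#' @param x,y paired numeric vectors.
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  if (n < 2) stop("need >= 2 pairs")
  m <- mean(d)
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1), mean_diff = m)
}

#' Per-subject behavioral summary
#'
#' Preferred response rates per subject and block, plus the stay regression
#' inputs, as a tidy table.
#'
#' @param trials multi-subject trial table.
#' @return data frame keyed by `subject`, `condition`, `block` with `prr`
#'   and `n_trials`.
#' @export
behavior_summary <- function(trials) {
  check_trials(trials)
  pieces <- split(trials, list(trials$subject, trials$block), drop = TRUE)
  do.call(rbind, lapply(pieces, function(d) {
    data.frame(subject = d$subject[1], condition = d$condition[1],
               block = d$block[1], prr = preferred_response_rate(d$choice),
               n_trials = nrow(d), row.names = NULL)
  }))
}
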