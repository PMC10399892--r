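# Independent reference implementations used as oracles. These deliberately
# mirror the model definitions step by step in plain R, independent of the
# package's compiled code paths.

# Step-by-step replay of the asymmetric Q-learning likelihood.
ref_loglik <- function(trials, q0, alpha_p, alpha_n, beta) {
  q <- c(q0, q0)
  cur <- trials$block[1]
  ll <- 0
  for (t in seq_len(nrow(trials))) {
    if (trials$block[t] != cur) {
      cur <- trials$block[t]
      q <- c(q0, q0)
    }
    ch <- trials$choice[t] + 1
    ot <- 3 - ch
    p <- 1 / (1 + exp(-beta * (q[ch] - q[ot])))
    ll <- ll + log(p)
    d <- trials$outcome[t] - q[ch]
    q[ch] <- q[ch] + (if (d >= 0) alpha_p else alpha_n) * d
  }
  ll
}

# Same replay returning pre-update chosen values and prediction errors.
ref_trajectory <- function(trials, q0, alpha_p, alpha_n) {
  q <- c(q0, q0)
  cur <- trials$block[1]
  out <- matrix(NA_real_, nrow(trials), 2)
  for (t in seq_len(nrow(trials))) {
    if (trials$block[t] != cur) {
      cur <- trials$block[t]
      q <- c(q0, q0)
    }
    ch <- trials$choice[t] + 1
    d <- trials$outcome[t] - q[ch]
    out[t, ] <- c(q[ch], d)
    q[ch] <- q[ch] + (if (d >= 0) alpha_p else alpha_n) * d
  }
  out
}

# Random single-subject gain-condition trial table.
random_trials <- function(n_trials, n_blocks = 1, condition = "gain") {
  codes <- switch(condition, gain = c(0, 1), loss = c(-1, 0),
                  mixed = c(-1, 1))
  per <- ceiling(n_trials / n_blocks)
  data.frame(
    subject = 1L,
    condition = condition,
    block = rep(seq_len(n_blocks), each = per)[seq_len(n_trials)],
    trial = unlist(lapply(seq_len(n_blocks),
                          function(b) seq_len(per) - 1L))[seq_len(n_trials)],
    choice = sample(0:1, n_trials, replace = TRUE),
    outcome = sample(codes, n_trials, replace = TRUE),
    p0 = 0.5, p1 = 0.5)
}

quiet_fit <- function(...) suppressWarnings(sample_posterior(...))
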