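#' @title Task schedules for the two-armed bandit
#' @description Helpers defining outcome valence conditions and building the
#'   two schedule families: stable mini-blocks with fixed reinforcement
#'   probability pairs, and reflecting random walks on \[0.25, 0.75\].
#' @name schedules
NULL

CONDITIONS <- c("gain", "loss", "mixed")

#' Outcome codes for a valence condition
#'
#' Outcomes are coded on a unit scale: +10 points -> +1, 0 points -> 0,
#' -10 points -> -1. The "reinforced" event is the one occurring with the
#' scheduled probability: winning (+1) in gain, losing (-1) in loss, winning
#' (+1) in mixed (the alternative in mixed being -1).
#'
#' @param condition "gain", "loss" or "mixed".
#' @return named numeric `c(reinforced =, alternative =)`.
#' @export
valence_outcomes <- function(condition) {
  condition <- match.arg(condition, CONDITIONS)
  switch(condition,
    gain  = c(reinforced = 1,  alternative = 0),
    loss  = c(reinforced = -1, alternative = 0),
    mixed = c(reinforced = 1,  alternative = -1)
  )
}

#' Bounds of the initial expectation Q0 for a condition
#'
#' Q0 is constrained between the worst and the best outcome code of the
#' condition: \[0, 1\] in gain, \[-1, 0\] in loss, \[-1, 1\] in mixed.
#'
#' @inheritParams valence_outcomes
#' @return numeric `c(lo, hi)`.
#' @export
q0_bounds <- function(condition) {
  r <- sort(unname(valence_outcomes(condition)))
  c(r[1], r[2])
}

#' The four stable probability pairs of the mini-block task
#'
#' @return list of four `c(p0, p1)` pairs: 40/60%, 25/75%, 25/25%, 75/75%.
#' @export
stable_pairs <- function() {
  list(c(0.40, 0.60), c(0.25, 0.75), c(0.25, 0.25), c(0.75, 0.75))
}

new_task_schedule <- function(trials, condition, type) {
  structure(list(trials = trials, condition = condition, type = type,
                 outcomes = valence_outcomes(condition)),
            class = "task_schedule")
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("<task_schedule: %s, %s, %d block(s), %d trials>\n",
              x$type, x$condition, length(unique(x$trials$block)),
              nrow(x$trials)))
  invisible(x)
}

#' Build a stable mini-block schedule
#'
#' Each probability pair becomes a mini-block with constant per-option
#' reinforcement probabilities; the order of the mini-blocks is randomly
#' permuted (as cue pairs were randomly assigned to block positions).
#'
#' @param condition "gain", "loss" or "mixed".
#' @param pair_probs list of `c(p0, p1)` reinforcement probability pairs;
#'   defaults to [stable_pairs()].
#' @param trials_per_block trials per mini-block (default 32).
#' @param randomize_order permute block order (default TRUE; uses the current
#'   RNG state).
#' @return a `task_schedule` whose `$trials` data frame has columns
#'   `block`, `trial` (0-based within block), `p0`, `p1`.
#' @export
make_stable_schedule <- function(condition, pair_probs = stable_pairs(),
                                 trials_per_block = 32,
                                 randomize_order = TRUE) {
  condition <- match.arg(condition, CONDITIONS)
  if (trials_per_block < 1) stop("`trials_per_block` must be >= 1")
  for (i in seq_along(pair_probs)) {
    p <- pair_probs[[i]]
    if (length(p) != 2 || any(!is.finite(p)) || any(p < 0) || any(p > 1))
      stop(sprintf("invalid probability pair #%d: (%s)", i,
                   paste(format(p), collapse = ", ")))
  }
  ord <- if (randomize_order) sample(seq_along(pair_probs)) else
    seq_along(pair_probs)
  trials <- do.call(rbind, lapply(seq_along(ord), function(b) {
    p <- pair_probs[[ord[b]]]
    data.frame(block = b, trial = seq_len(trials_per_block) - 1L,
               p0 = p[1], p1 = p[2])
  }))
  new_task_schedule(trials, condition, "stable")
}

# Reflect a probability back inside [lo, hi]; values exactly on a boundary
# are legal and unreflected.
reflect_into <- function(p, lo, hi) {
  if (p > hi) p <- 2 * hi - p
  if (p < lo) p <- 2 * lo - p
  p
}

# One reflecting random walk of length n on [lo, hi] with +/- step moves,
# started from Uniform(lo, hi).
reflecting_walk <- function(n, lo = 0.25, hi = 0.75, step = 0.05) {
  p <- numeric(n)
  cur <- runif(1, lo, hi)
  p[1] <- cur
  if (n > 1) {
    moves <- ifelse(runif(n - 1) < 0.5, -step, step)
    for (t in 2:n) {
      cur <- reflect_into(cur + moves[t - 1], lo, hi)
      p[t] <- cur
    }
  }
  p
}

#' Build a random-walk schedule
#'
#' A single block of `n_trials` in which each option's reinforcement
#' probability starts from an independent Uniform(0.25, 0.75) draw and then
#' moves up or down by 0.05 equiprobably and independently each trial,
#' reflecting off the boundaries \[0.25, 0.75\].
#'
#' @inheritParams make_stable_schedule
#' @param n_trials number of trials (default 100).
#' @return a `task_schedule` (single block).
#' @export
make_random_walk_schedule <- function(condition, n_trials = 100) {
  condition <- match.arg(condition, CONDITIONS)
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  trials <- data.frame(block = 1L, trial = seq_len(n_trials) - 1L,
                       p0 = reflecting_walk(n_trials),
                       p1 = reflecting_walk(n_trials))
  new_task_schedule(trials, condition, "random_walk")
}

#' Draw the outcome of one option on one trial
#'
#' With the scheduled reinforcement probability the condition's reinforced
#' outcome code is returned, otherwise the alternative. Only the queried
#' option is realized (partial feedback).
#'
#' @param schedule a `task_schedule`.
#' @param block block id.
#' @param trial 0-based trial index within the block.
#' @param option option id, 0 or 1.
#' @return outcome code in \{-1, 0, +1\}.
#' @export
sample_outcome <- function(schedule, block, trial, option) {
  stopifnot(inherits(schedule, "task_schedule"))
  if (!option %in% c(0, 1)) stop("`option` must be 0 or 1")
  row <- schedule$trials[schedule$trials$block == block &
                           schedule$trials$trial == trial, , drop = FALSE]
  if (nrow(row) != 1) stop(sprintf("no trial %d in block %s", trial, block))
  p <- if (option == 0) row$p0 else row$p1
  oc <- schedule$outcomes
  if (runif(1) < p) unname(oc["reinforced"]) else unname(oc["alternative"])
}
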