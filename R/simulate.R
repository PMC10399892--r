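#' Simulate a softmax Q-learning agent on a task schedule
#'
#' Per trial the choice is drawn from the softmax probability given the
#' current Q values; only the chosen option's outcome is realized (partial
#' feedback) and only its value is updated. Both options reset to Q0 at each
#' block start (each mini-block introduces novel cues).
#'
#' @param params an [agent_params()].
#' @param schedule a `task_schedule`.
#' @param variant variant whose rules resolve the effective parameters
#'   (default "A-VI", the generating model of the recovery study).
#' @param subject subject id recorded in the output.
#' @return trial data frame with columns `subject`, `condition`, `block`,
#'   `trial`, `choice` (0/1), `outcome` (-1/0/+1), `p0`, `p1`, and the
#'   derived `q_chosen` (pre-update chosen value) and `delta` (prediction
#'   error).
#' @export
simulate_agent <- function(params, schedule, variant = "A-VI", subject = 1L) {
  stopifnot(inherits(schedule, "task_schedule"))
  condition <- schedule$condition
  p <- resolve_params(params, variant, condition)
  b <- q0_bounds(condition)
  if (p$q0 < b[1] || p$q0 > b[2])
    stop(sprintf("`q0` = %g outside [%g, %g]", p$q0, b[1], b[2]))
  if (p$alpha_p < 0 || p$alpha_p > 1 || p$alpha_n < 0 || p$alpha_n > 1)
    stop("learning rates must lie in [0, 1]")
  if (p$beta < 0 || p$beta > 20) stop("`beta` outside [0, 20]")
  oc <- schedule$outcomes
  sim <- cpp_simulate_agent(schedule$trials$p0, schedule$trials$p1,
                            as.integer(schedule$trials$block),
                            p$q0, p$alpha_p, p$alpha_n, p$beta,
                            oc[["reinforced"]], oc[["alternative"]])
  data.frame(subject = subject, condition = condition,
             block = schedule$trials$block, trial = schedule$trials$trial,
             choice = as.integer(sim[, 1]), outcome = sim[, 2],
             p0 = schedule$trials$p0, p1 = schedule$trials$p1,
             q_chosen = sim[, 3], delta = sim[, 4])
}

#' Design of the parameter-recovery simulation grid
#'
#' The factorial design crossing initial-expectation levels with
#' (alpha_p, alpha_n) pairs; each cell yields `n_datasets_per_cell` datasets
#' of `n_subjects` agents, all sharing the cell's parameters, each agent on a
#' fresh schedule.
#'
#' @param q0_levels initial-expectation values (within the condition's
#'   bounds).
#' @param lr_pairs list of `c(alpha_p, alpha_n)` pairs, each rate in
#'   \[0, 1\].
#' @param n_datasets_per_cell datasets simulated per grid cell.
#' @param n_subjects agents per dataset.
#' @param beta fixed inverse temperature (default 10, as used throughout the
#'   recovery study).
#' @param condition valence condition.
#' @param task schedule family: "random_walk" (one 100-trial block) or
#'   "stable" (four 32-trial mini-blocks).
#' @param n_trials trials for random-walk schedules.
#' @param trials_per_block trials per mini-block for stable schedules.
#' @return a `recovery_grid_design`.
#' @export
recovery_grid_design <- function(q0_levels, lr_pairs, n_datasets_per_cell,
                                 n_subjects, beta = 10, condition = "gain",
                                 task = c("random_walk", "stable"),
                                 n_trials = 100, trials_per_block = 32) {
  task <- match.arg(task)
  condition <- match.arg(condition, CONDITIONS)
  b <- q0_bounds(condition)
  if (any(q0_levels < b[1] | q0_levels > b[2]))
    stop("q0 level outside the condition's bounds")
  for (lr in lr_pairs)
    if (length(lr) != 2 || any(lr < 0) || any(lr > 1))
      stop("each learning-rate pair must be two rates in [0, 1]")
  if (n_datasets_per_cell < 1 || n_subjects < 1)
    stop("counts must be positive")
  structure(list(q0_levels = q0_levels, lr_pairs = lr_pairs,
                 n_datasets_per_cell = n_datasets_per_cell,
                 n_subjects = n_subjects, beta = beta, condition = condition,
                 task = task, n_trials = n_trials,
                 trials_per_block = trials_per_block),
            class = "recovery_grid_design")
}

#' The full recovery grid of the study
#'
#' Five Q0 levels crossed with seven learning-rate pairs, 30 datasets per
#' cell, 30 subjects per dataset, beta = 10: 1050 datasets in total. Gain
#' levels are (0, 0.25, 0.5, 0.75, 1); loss levels are mirrored onto
#' \[-1, 0\].
#'
#' @inheritParams recovery_grid_design
#' @return a `recovery_grid_design`.
#' @export
paper_grid_design <- function(condition = "gain",
                              task = c("random_walk", "stable")) {
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  if (condition == "loss") levels <- -levels
  recovery_grid_design(
    q0_levels = levels,
    lr_pairs = list(c(0.1, 0.7), c(0.2, 0.6), c(0.3, 0.5), c(0.4, 0.4),
                    c(0.5, 0.3), c(0.6, 0.2), c(0.7, 0.1)),
    n_datasets_per_cell = 30, n_subjects = 30, beta = 10,
    condition = condition, task = match.arg(task)
  )
}

#' A reduced recovery grid for desk-scale runs
#'
#' Three Q0 levels (the fixed value and both extremes) by three rate pairs
#' by five datasets per cell, 30 subjects each.
#'
#' @inheritParams recovery_grid_design
#' @export
reduced_grid_design <- function(condition = "gain",
                                task = c("random_walk", "stable"),
                                n_datasets_per_cell = 5) {
  levels <- c(0, 0.5, 1)
  if (condition == "loss") levels <- -levels
  recovery_grid_design(
    q0_levels = levels,
    lr_pairs = list(c(0.2, 0.6), c(0.4, 0.4), c(0.6, 0.2)),
    n_datasets_per_cell = n_datasets_per_cell, n_subjects = 30, beta = 10,
    condition = condition, task = match.arg(task)
  )
}

# Fresh schedule per the design's task family.
design_schedule <- function(design) {
  if (design$task == "random_walk")
    make_random_walk_schedule(design$condition, design$n_trials)
  else
    make_stable_schedule(design$condition,
                         trials_per_block = design$trials_per_block)
}

#' Simulate one multi-subject dataset at fixed generating parameters
#'
#' @param q0,alpha_p,alpha_n,beta generating parameters shared by all agents.
#' @param n_subjects number of agents.
#' @param condition valence condition.
#' @param task,n_trials,trials_per_block schedule family, see
#'   [recovery_grid_design()].
#' @return one trial data frame stacking all subjects.
#' @export
simulate_dataset <- function(q0, alpha_p, alpha_n, beta, n_subjects,
                             condition = "gain",
                             task = c("random_walk", "stable"),
                             n_trials = 100, trials_per_block = 32) {
  design <- recovery_grid_design(q0, list(c(alpha_p, alpha_n)), 1,
                                 n_subjects, beta, condition,
                                 match.arg(task), n_trials, trials_per_block)
  params <- agent_params(q0, alpha_p, alpha_n, beta, condition)
  do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    simulate_agent(params, design_schedule(design), subject = i)
  }))
}

#' Simulate the full recovery grid
#'
#' Emits `n_datasets_per_cell` datasets for every (Q0 level, learning-rate
#' pair) cell. Each dataset draws a per-dataset seed from the grid seed, so
#' individual datasets are independently reproducible.
#'
#' @param design a [recovery_grid_design()].
#' @param seed integer seed controlling all randomness.
#' @return a `sim_grid`: list of datasets, each a list with fields `data`
#'   (trial table), `q0`, `alpha_p`, `alpha_n`, `beta`, `cell`, `dataset`,
#'   `seed`.
#' @export
simulate_grid <- function(design, seed = 1L) {
  stopifnot(inherits(design, "recovery_grid_design"))
  cells <- expand.grid(pair = seq_along(design$lr_pairs),
                       q0 = design$q0_levels)
  n_total <- nrow(cells) * design$n_datasets_per_cell
  set.seed(seed)
  dataset_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  out <- vector("list", n_total)
  idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    q0 <- cells$q0[ci]
    lr <- design$lr_pairs[[cells$pair[ci]]]
    for (d in seq_len(design$n_datasets_per_cell)) {
      idx <- idx + 1L
      set.seed(dataset_seeds[idx])
      dat <- simulate_dataset(q0, lr[1], lr[2], design$beta,
                              design$n_subjects, design$condition,
                              design$task, design$n_trials,
                              design$trials_per_block)
      out[[idx]] <- list(data = dat, q0 = q0, alpha_p = lr[1],
                         alpha_n = lr[2], beta = design$beta, cell = ci,
                         dataset = d, seed = dataset_seeds[idx])
    }
  }
  structure(out, class = "sim_grid", design = design, seed = seed)
}

#' @export
print.sim_grid <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf(
    "<sim_grid: %d datasets (%d q0 levels x %d lr pairs x %d/cell), %s %s>\n",
    length(x), length(d$q0_levels), length(d$lr_pairs),
    d$n_datasets_per_cell, d$condition, d$task))
  invisible(x)
}
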