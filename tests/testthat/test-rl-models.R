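test_that("q_update follows the asymmetric rule with the >= tie branch", {
  expect_equal(q_update(0, 1, 0.3, 0.9), 0.3)
  expect_equal(q_update(0.5, 0.5, 0.2, 0.8), 0.5)  # zero PE: unchanged
  expect_equal(q_update(1, 0, 0.3, 1), 0)          # full overwrite
  expect_equal(q_update(0.4, 0, 0.3, 0.5), 0.4 + 0.5 * (0 - 0.4))
  expect_error(q_update(0, 1, 1.5, 0.5), "\\[0, 1\\]")
})

test_that("choice_prob is a symmetric, bounded softmax", {
  expect_equal(choice_prob(0.3, 0.3, 10), 0.5)
  expect_equal(choice_prob(0.9, 0.1, 0), 0.5)
  expect_equal(choice_prob(1, 0, 10), 1 / (1 + exp(-10)))
  # complementarity over random inputs
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, -1, 1); b <- runif(1, -1, 1); bet <- runif(1, 0, 20)
    expect_equal(choice_prob(a, b, bet) + choice_prob(b, a, bet), 1)
  }
  # numerically stable at the bound
  expect_equal(choice_prob(1, 0, 20), 1 / (1 + exp(-20)))
  expect_gte(choice_prob(1, 0, 20), 0.999999)
})

test_that("log_likelihood matches the step-by-step recursion oracle", {
  set.seed(11)
  for (i in 1:25) {
    tr <- random_trials(50, n_blocks = sample(1:4, 1))
    q0 <- runif(1); ap <- runif(1); an <- runif(1); bet <- runif(1, 0, 20)
    pars <- agent_params(q0, ap, an, bet)
    expect_equal(log_likelihood(pars, "A-VI", tr, "gain"),
                 ref_loglik(tr, q0, ap, an, bet), tolerance = 1e-12)
  }
})

test_that("flat softmax gives exactly T * log(0.5)", {
  tr <- random_trials(37)
  pars <- agent_params(0.2, 0.5, 0.7, 0)
  expect_equal(log_likelihood(pars, "A-VI", tr, "gain"), 37 * log(0.5))
})

test_that("variants nest: symmetric and fixed-Q0 reductions agree exactly", {
  set.seed(12)
  tr <- random_trials(60, n_blocks = 2)
  pars <- agent_params(0.5, 0.35, 0.35, 8)
  ll_avi <- log_likelihood(pars, "A-VI", tr, "gain")
  expect_identical(ll_avi, log_likelihood(pars, "S-VI", tr, "gain"))
  expect_identical(ll_avi, log_likelihood(pars, "A-FI", tr, "gain"))
  expect_identical(ll_avi, log_likelihood(pars, "S-FI", tr, "gain"))
  # primed variants pin q0 at 0
  pars0 <- agent_params(0, 0.35, 0.35, 8)
  expect_identical(log_likelihood(pars0, "A-VI", tr, "gain"),
                   log_likelihood(pars0, "A-FI'", tr, "gain"))
})

test_that("log_likelihood is invariant to consistent option relabeling", {
  set.seed(13)
  tr <- random_trials(40, n_blocks = 2)
  pars <- agent_params(0.3, 0.25, 0.6, 12)
  flipped <- tr
  flipped$choice <- 1L - tr$choice
  expect_equal(log_likelihood(pars, "A-VI", tr, "gain"),
               log_likelihood(pars, "A-VI", flipped, "gain"),
               tolerance = 1e-12)
})

test_that("illegal outcome codes and out-of-bound parameters are rejected", {
  tr <- random_trials(10)
  tr$outcome[3] <- -1  # illegal in gain
  pars <- agent_params(0.5, 0.4, 0.4, 10)
  expect_error(log_likelihood(pars, "A-VI", tr, "gain"), "illegal")
  tr2 <- random_trials(10)
  expect_error(log_likelihood(list(q0 = 2, alpha_p = .4, alpha_n = .4,
                                   beta = 10), "A-VI", tr2, "gain"),
               "bounds")
})

test_that("q_trajectory matches the oracle and the constant-alpha closed form", {
  set.seed(14)
  tr <- random_trials(50, n_blocks = 2)
  q0 <- 0.4; ap <- 0.3; an <- 0.7
  pars <- agent_params(q0, ap, an, 9)
  traj <- q_trajectory(pars, "A-VI", tr, "gain")
  ref <- ref_trajectory(tr, q0, ap, an)
  expect_equal(traj$q_chosen, ref[, 1], tolerance = 1e-12)
  expect_equal(traj$delta, ref[, 2], tolerance = 1e-12)
  expect_equal(traj$delta, tr$outcome - traj$q_chosen, tolerance = 1e-15)

  # symmetric alpha, single option always chosen: exponential-recency form
  a <- 0.35
  T <- 30
  r <- sample(c(0, 1), T, replace = TRUE)
  tr1 <- data.frame(subject = 1, condition = "gain", block = 1,
                    trial = 0:(T - 1), choice = 0L, outcome = r,
                    p0 = 0.5, p1 = 0.5)
  traj1 <- q_trajectory(agent_params(0.2, a, a, 5), "A-VI", tr1, "gain")
  qT <- traj1$q_chosen[T] + a * traj1$delta[T]  # value after the last update
  closed <- 0.2 * (1 - a)^T + sum(a * (1 - a)^(T - seq_len(T)) * r)
  expect_equal(qT, closed, tolerance = 1e-12)

  # no learning: trajectory pinned at q0
  traj0 <- q_trajectory(agent_params(0.2, 0, 0, 5), "A-VI", tr1, "gain")
  expect_equal(traj0$q_chosen, rep(0.2, T))
})

test_that("Q values stay within the outcome range (boundedness)", {
  set.seed(15)
  for (i in 1:10) {
    tr <- random_trials(80, n_blocks = 3, condition = "mixed")
    traj <- q_trajectory(agent_params(runif(1, -1, 1), runif(1), runif(1),
                                      5), "A-VI", tr, "mixed")
    expect_true(all(traj$q0_pre >= -1 & traj$q0_pre <= 1))
    expect_true(all(traj$q1_pre >= -1 & traj$q1_pre <= 1))
  }
})

test_that("model_variant encodes the asymmetry/Q0 rules of each variant", {
  v <- model_variant("A-VI")
  expect_true(v$asymmetric && v$free_q0)
  v <- model_variant("S-FI")
  expect_false(v$asymmetric || v$free_q0)
  expect_equal(unname(v$fixed_q0), c(0.5, -0.5, 0))
  vp <- model_variant("A-FI'")
  expect_equal(unname(vp$fixed_q0), c(0, 0, 0))
  expect_error(model_variant("B-XX"))
})
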