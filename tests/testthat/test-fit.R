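test_that("fit configuration encodes the chain geometry profiles", {
  cfg <- fit_config()
  expect_equal(cfg$n_chains, 4)
  expect_equal(cfg$n_warmup, 4000)
  expect_equal(cfg$n_keep, 6000)
  expect_equal(cfg$n_chains * cfg$n_keep, 24000)
  expect_equal(cfg$trim, 0.10)
  t <- fit_config("test")
  expect_equal(t$n_chains * t$n_keep, 2000)
  expect_error(fit_config(n_keep = 0), "geometry")
  expect_error(fit_config(trim = 0.6), "trim")
})

test_that("joint_log_density equals the sum of its terms on a toy dataset", {
  set.seed(41)
  dat <- rbind(transform(random_trials(8), subject = 1L),
               transform(random_trials(8), subject = 2L))
  pn <- c("q0", "alpha_p", "delta", "beta")
  hyper <- list(mu = stats::setNames(c(0.2, -0.3, 0.1, 0.5), pn),
                sigma = stats::setNames(c(0.8, 1.2, 0.6, 1.0), pn))
  raw <- matrix(rnorm(8), 2, 4, dimnames = list(NULL, pn))
  got <- joint_log_density(hyper, raw, dat, "A-VI", "gain")

  # independent term-by-term computation
  want <- sum(dnorm(hyper$mu, 0, 2, log = TRUE)) +
    sum(log(2) - log(pi * 5 * (1 + (hyper$sigma / 5)^2)))
  for (i in 1:2) {
    want <- want + sum(dnorm(raw[i, ], hyper$mu, hyper$sigma, log = TRUE))
    d <- dat[dat$subject == i, ]
    want <- want + ref_loglik(d, pnorm(raw[i, "q0"]),
                              pnorm(raw[i, "alpha_p"]),
                              pnorm(raw[i, "alpha_p"] + raw[i, "delta"]),
                              20 * pnorm(raw[i, "beta"]))
  }
  expect_equal(got, as.numeric(want), tolerance = 1e-10)
})

test_that("joint_log_density reduces to the hyper prior with zero subjects", {
  pn <- c("alpha_p", "beta")
  hyper <- list(mu = stats::setNames(c(0, 0), pn),
                sigma = stats::setNames(c(1, 1), pn))
  got <- joint_log_density(hyper, NULL, random_trials(0), "S-FI", "gain")
  want <- sum(dnorm(c(0, 0), 0, 2, log = TRUE)) +
    2 * (log(2) - log(pi * 5 * (1 + (1 / 5)^2)))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(joint_log_density(list(mu = hyper$mu,
                                      sigma = c(alpha_p = -1, beta = 1)),
                                 NULL, random_trials(0), "S-FI", "gain"),
               "positive")
})

test_that("a vanishing inverse temperature drives the data term to T log 0.5", {
  dat <- random_trials(20)
  pn <- c("q0", "alpha_p", "delta", "beta")
  hyper <- list(mu = stats::setNames(rep(0, 4), pn),
                sigma = stats::setNames(rep(1, 4), pn))
  raw <- matrix(c(0, 0, 0, -40), 1, 4, dimnames = list(NULL, pn))
  got <- joint_log_density(hyper, raw, dat, "A-VI", "gain")
  prior_part <- sum(dnorm(hyper$mu, 0, 2, log = TRUE)) +
    4 * (log(2) - log(pi * 5 * (1 + (1 / 5)^2))) +
    sum(dnorm(raw[1, ], 0, 1, log = TRUE))
  expect_equal(got - prior_part, 20 * log(0.5), tolerance = 1e-9)
})

test_that("sampler retains n_chains x n_keep draws and is seed-reproducible", {
  set.seed(42)
  dat <- simulate_dataset(0.5, 0.4, 0.4, 10, n_subjects = 4, n_trials = 30)
  cfg <- fit_config("test", n_warmup = 200, n_keep = 150, seed = 9)
  f1 <- quiet_fit(dat, "A-VI", config = cfg)
  expect_equal(n_draws(f1), 2 * 150)
  expect_equal(dim(f1$mu), c(150, 2, 4))
  expect_equal(dim(f1$raw), c(150, 2, 4, 4))
  f2 <- quiet_fit(dat, "A-VI", config = cfg)
  expect_identical(f1$mu, f2$mu)
  expect_identical(summary(f1), summary(f2))
  cfg3 <- cfg; cfg3$seed <- 10L
  f3 <- quiet_fit(dat, "A-VI", config = cfg3)
  expect_false(identical(f1$mu, f3$mu))
})

test_that("variant structure is reflected in the sampled parameters", {
  set.seed(43)
  dat <- simulate_dataset(0.5, 0.4, 0.4, 10, n_subjects = 3, n_trials = 20)
  cfg <- fit_config("test", n_warmup = 100, n_keep = 50, seed = 1)
  expect_equal(quiet_fit(dat, "S-FI", config = cfg)$param_names,
               c("alpha_p", "beta"))
  expect_equal(quiet_fit(dat, "A-FI", config = cfg)$param_names,
               c("alpha_p", "delta", "beta"))
  f <- quiet_fit(dat, "S-VI", config = cfg)
  expect_equal(f$param_names, c("q0", "alpha_p", "beta"))
  expect_error(mu_delta_draws(f), "asymmetric")
  # natural-scale subject draws respect bounds
  nat <- qshadow:::subject_natural_draws(f)
  expect_true(all(nat[, , "q0"] >= 0 & nat[, , "q0"] <= 1))
  expect_true(all(nat[, , "beta"] >= 0 & nat[, , "beta"] <= 20))
})

test_that("sampler matches numerical quadrature on a Gaussian hierarchy", {
  # Same hierarchy (mu ~ N(0,2), sigma ~ half-Cauchy(5), raw_i ~ N(mu, sigma))
  # with a Normal(raw_i, 1) data term, solvable by 2-D quadrature after
  # integrating the subject levels analytically.
  set.seed(44)
  true_means <- c(-1, 0, 0.5, 1.5)
  J <- 6
  ys <- lapply(true_means, function(m) rnorm(J, m, 1))
  ybar <- sapply(ys, mean)

  mu_grid <- seq(-4, 4, length.out = 161)
  sg_grid <- seq(0.005, 12, length.out = 481)
  lp <- outer(mu_grid, sg_grid, function(m, s) {
    t1 <- dnorm(m, 0, 2, log = TRUE) - log1p((s / 5)^2)
    t2 <- 0
    for (i in 1:4)
      t2 <- t2 + dnorm(ybar[i], m, sqrt(s^2 + 1 / J), log = TRUE)
    t1 + t2
  })
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  mu_mean_q <- sum(rowSums(w) * mu_grid)
  mu_sd_q <- sqrt(sum(rowSums(w) * (mu_grid - mu_mean_q)^2))
  # posterior mean of subject 1's raw parameter: shrinkage average over grid
  shrink <- outer(mu_grid, sg_grid, function(m, s)
    (J * ybar[1] + m / s^2) / (J + 1 / s^2))
  raw1_q <- sum(w * shrink)

  subj <- lapply(ys, function(y) list(y = y))
  set.seed(101)
  draws_mu <- c(); draws_raw1 <- c()
  for (ch in 1:2) {
    out <- qshadow:::cpp_sample_chain(subj, 1L, FALSE, FALSE, 0, 0, 1, 20,
                                      2000L, 6000L, 2, 5)
    draws_mu <- c(draws_mu, out$mu[, 1])
    draws_raw1 <- c(draws_raw1, out$raw[, 1])
  }
  expect_equal(mean(draws_mu), mu_mean_q, tolerance = 0.08)
  expect_equal(sd(draws_mu), mu_sd_q, tolerance = 0.1)
  expect_equal(mean(draws_raw1), raw1_q, tolerance = 0.08)
})

test_that("subject-level estimates track heterogeneous true parameters", {
  set.seed(45)
  n <- 14
  true_ap <- runif(n, 0.15, 0.85)
  true_q0 <- runif(n, 0, 1)
  dat <- do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_agent(agent_params(true_q0[i], true_ap[i], true_ap[i], 10),
                   make_random_walk_schedule("gain", 100), subject = i)
  }))
  fit <- quiet_fit(dat, "A-VI", config = fit_config("test", seed = 6))
  est <- subject_estimates(fit)
  expect_gt(cor(est$alpha_p, true_ap), 0)
  expect_gt(cor(est$q0, true_q0), 0)
})

test_that("convergence warning fires when the threshold is made strict", {
  set.seed(46)
  dat <- simulate_dataset(0.5, 0.4, 0.4, 10, n_subjects = 3, n_trials = 20)
  cfg <- fit_config("test", n_warmup = 100, n_keep = 100, seed = 2,
                    rhat_threshold = 0.5)
  expect_warning(sample_posterior(dat, "S-FI", config = cfg), "split-R-hat")
})

test_that("split R-hat and ESS behave on well-mixed white noise", {
  set.seed(47)
  x <- matrix(rnorm(4000), 1000, 4)
  expect_lt(abs(split_rhat(x) - 1), 0.02)
  e <- ess_basic(x)
  expect_gt(e, 1500)
  # strongly autocorrelated chains: far smaller ESS
  y <- apply(matrix(rnorm(4000, sd = 0.05), 1000, 4), 2, cumsum)
  expect_lt(ess_basic(y), 200)
  expect_gt(split_rhat(y), 1.1)
})
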