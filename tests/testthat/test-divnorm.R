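test_that("static normalization follows the defining ratio", {
  expect_equal(static_normalization(c(1, 1), 0), c(0.5, 0.5))
  expect_equal(static_normalization(c(2, 0, 0), 2), c(0.5, 0, 0))
  u <- c(0.3, 1.2, 0.5)
  expect_true(all(static_normalization(u, 3) < static_normalization(u, 1)))
  expect_lte(sum(static_normalization(u, 2)), 1)
  expect_equal(sum(static_normalization(u, 0)), 1)
  expect_error(static_normalization(c(0, 0), 0), "domain")
})

test_that("dynamics fixed point and closed-form single-click limits hold", {
  empty <- click_train(numeric(0), integer(0), 1)
  traj <- simulate_dynamics(ref_dyn_params, empty)
  expect_true(all(traj$R_left == 0 & traj$R_right == 0 & traj$G == 0))

  p0 <- divnorm_params(tau_R = 0.8, tau_G = 3, omega_I = 0)
  one <- click_train(0, 1L, 1)
  traj <- simulate_dynamics(p0, one, dt = 1e-3)
  expect_true(all(traj$G == 0))
  expected <- (1 / 0.8) * exp(-traj$time / 0.8)
  expect_lt(max(abs(traj$R_left - expected)), 1e-8)
})

test_that("coarse-step integration matches a fine-step re-integration", {
  tr <- fixed_train()
  coarse <- simulate_dynamics(ref_dyn_params, tr, dt = 1e-3)
  fine <- simulate_dynamics(ref_dyn_params, tr, dt = 1e-5)
  shared <- dplyr::inner_join(coarse, tibble::as_tibble(fine),
                              by = "time", suffix = c("", "_fine"))
  expect_gt(nrow(shared), 900)
  sup <- max(
    abs(shared$R_left - shared$R_left_fine),
    abs(shared$R_right - shared$R_right_fine),
    abs(shared$G - shared$G_fine)
  )
  expect_lt(sup, 1e-4)
  # G rises monotonically to its maximum after stimulus onset
  g <- coarse$G
  expect_true(all(diff(g[seq_len(which.max(g))]) >= -1e-12))
})

test_that("the protocol-shared gain equals the per-trial gain", {
  p <- ref_dyn_params
  g <- gain_trajectory(p, default_proto, dt = 1e-3)
  for (seed in 1:2) {
    set.seed(seed)
    traj <- simulate_dynamics(p, random_train(), dt = 1e-3)
    shared <- dplyr::inner_join(g, tibble::as_tibble(traj), by = "time")
    expect_lt(max(abs(shared$G.x - shared$G.y)), 1e-10)
    expect_lt(max(abs(shared$A - (shared$R_left + shared$R_right))), 1e-10)
  }
  g0 <- gain_trajectory(divnorm_params(1, 1, 0), default_proto)
  expect_true(all(g0$G == 0))
})

test_that("kernel weights reduce to the pure-leak closed form at omega_I = 0", {
  p0 <- divnorm_params(tau_R = 1.3, tau_G = 5, omega_I = 0)
  kw <- kernel_weights(p0, default_proto)
  expected <- (1 / 1.3) * exp(-(1 - kw$time) / 1.3)
  expect_identical(kw$K, expected)
})

test_that("closed-form and ODE kernel routes agree", {
  for (p in list(ref_dyn_params, bump_preset,
                 divnorm_params(0.3, 0.9, 8))) {
    kw1 <- kernel_weights(p, default_proto)
    kw2 <- kernel_weights(p, default_proto, method = "ode", dt = 1e-4)
    expect_lt(max(abs(kw1$K - kw2$K)), 1e-8)
  }
})

test_that("the documented bump preset has an interior kernel peak", {
  kw <- kernel_weights(bump_preset, default_proto)
  i_star <- which.max(kw$K)
  expect_gt(i_star, 1)
  expect_lt(i_star, 20)
  beta <- regression_kernel(bump_preset, default_proto)$beta
  expect_identical(classify_kernel_shape(beta)$label, "bump")
})

test_that("kernels are positive and vary continuously with parameters", {
  taus <- c(0.1, 0.5, 2, 10)
  for (tr in taus) for (tg in taus) {
    K <- kernel_weights(divnorm_params(tr, tg, 5), default_proto)$K
    expect_true(all(K > 0))
    K_eps <- kernel_weights(divnorm_params(tr * (1 + 1e-6), tg, 5),
                            default_proto)$K
    expect_lt(max(abs(K_eps - K) / K), 1e-4)
  }
})

test_that("decision variable is linear in the click signs", {
  p <- divnorm_params(1.5, 6, 1.2, mu = 0)
  tr <- fixed_train()
  expect_identical(decision_variable(p, flip_train(tr)),
                   -decision_variable(p, tr))
  all_left <- click_train(tr$times, rep(1L, 20), tr$duration)
  kw <- kernel_weights(p, default_proto)
  expect_equal(decision_variable(p, all_left), sum(kw$K))
  expect_gt(decision_variable(p, all_left), 0)
})

test_that("ODE-integrated delta equals the kernel-sum decision variable", {
  set.seed(21)
  for (i in 1:10) {
    p <- divnorm_params(
      tau_R = exp(runif(1, log(0.05), log(20))),
      tau_G = exp(runif(1, log(0.05), log(20))),
      omega_I = runif(1, 0, 40)
    )
    tr <- random_train()
    traj <- simulate_dynamics(p, tr, dt = 1e-4)
    delta_ode <- traj$delta[nrow(traj)]
    expect_lt(abs(delta_ode - decision_variable(p, tr)), 1e-4)
  }
})

test_that("choice probability follows the logit rule and its symmetries", {
  p <- divnorm_params(1.5, 6, 1.2, sigma = 0.3, mu = -0.1, bias = 0)
  tr <- fixed_train()
  expect_equal(choice_probability(p, tr) + choice_probability(p, flip_train(tr)),
               1)
  pb <- divnorm_params(1.5, 6, 1.2, sigma = 0.3, mu = -0.1, bias = 0.7)
  expect_equal(
    choice_probability(pb, tr),
    plogis(decision_variable(pb, tr) / 0.3 + 0.7)
  )
})

test_that("log-likelihood matches per-trial and entropy oracles", {
  trials <- generate_trials(default_proto, 100, seed = 4)
  p <- divnorm_params(1.5, 6, 1.2, sigma = 0.3, mu = -0.1, bias = 0.2)
  trials <- simulate_choices(trials, divnorm_observer(p, default_proto),
                             seed = 5)
  # brute-force per-trial loop
  ll_loop <- sum(vapply(seq_len(nrow(trials)), function(k) {
    tr <- train_row(trials, k)
    pk <- choice_probability(p, tr)
    if (trials$choice[k] == "L") log(pk) else log(1 - pk)
  }, numeric(1)))
  expect_equal(log_likelihood(trials, p), ll_loop, tolerance = 1e-12)

  # near-guessing observer: Bernoulli entropy
  pg <- divnorm_params(1.5, 6, 1.2, sigma = 1e9, mu = 0, bias = 0)
  n <- nrow(trials)
  expect_lt(abs(log_likelihood(trials, pg) - n * log(0.5)), 1e-6 * n)

  # single trial with a plain probability
  one <- trials[1, ]
  one$choice <- "L"
  expect_equal(log_likelihood(one, 0.9), log(0.9))

  # exact mirror symmetry at zero bias
  p0 <- divnorm_params(1.5, 6, 1.2, sigma = 0.3, mu = -0.1, bias = 0)
  expect_identical(log_likelihood(trials, p0),
                   log_likelihood(mirror_trials(trials), p0))
  expect_error(log_likelihood(generate_trials(default_proto, 5, seed = 1), p),
               "choices")
})

test_that("the compiled likelihood agrees with the reference implementation", {
  trials <- generate_trials(default_proto, 400, seed = 8)
  p <- divnorm_params(0.9, 4.2, 1.2, sigma = 0.31, mu = -0.22, bias = 0.12)
  trials <- simulate_choices(trials, divnorm_observer(p, default_proto),
                             seed = 9)
  X <- click_matrix(trials)
  storage.mode(X) <- "double"
  y <- as.numeric(trials$choice == "L")
  nll_cpp <- divnorm:::.dn_negll(X, y, click_times(default_proto), 1,
                                 0.9, 4.2, 1.2, 0.31, -0.22, 0.12, 1e-10)
  expect_equal(-nll_cpp, log_likelihood(trials, p), tolerance = 1e-10)
  lp <- lca_params(-2, 1.7, 0.3)
  nll_lca <- divnorm:::.lca_negll(X, y, click_times(default_proto), 1,
                                  -2, 1.7, 0.3, 1e-10)
  expect_equal(-nll_lca, log_likelihood(trials, lp), tolerance = 1e-10)
})
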