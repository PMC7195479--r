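test_that("null data produce null kernels with nominal coverage", {
  trials <- generate_trials(default_proto, 20000, seed = 11)
  trials <- simulate_choices(trials, constant_observer(0.5), seed = 12)
  est <- fit_logistic_kernel(trials)
  expect_true(est$converged)
  z <- abs(c(est$beta_click, est$beta_bias)) /
    c(est$se_click, est$se_bias)
  expect_gte(sum(z < 3), 19)
})

test_that("the IRLS fit matches glm on the same design", {
  trials <- generate_trials(default_proto, 2000, seed = 13)
  p <- divnorm_params(1.56, 6.2, 1.2, sigma = 0.05, mu = -0.33, bias = 0.1)
  trials <- simulate_choices(trials, divnorm_observer(p, default_proto),
                             seed = 14)
  est <- fit_logistic_kernel(trials)
  X <- click_matrix(trials)
  g <- suppressWarnings(glm.fit(cbind(X, 1),
                                as.numeric(trials$choice == "L"),
                                family = binomial()))
  expect_equal(est$beta_click, unname(g$coefficients[1:20]), tolerance = 1e-6)
  expect_equal(est$beta_bias, unname(g$coefficients[21]), tolerance = 1e-6)
})

test_that("a known generative kernel is recovered within 3 SE", {
  beta_true <- 0.1 + 0.4 * exp(-((1:20) - 8)^2 / 18)
  bias_true <- 0.2
  trials <- generate_trials(default_proto, 20000, seed = 15)
  X <- click_matrix(trials)
  obs <- function(tr) plogis(as.numeric(click_matrix(tr) %*% beta_true) +
                               bias_true)
  trials <- simulate_choices(trials, obs, seed = 16)
  est <- fit_logistic_kernel(trials)
  expect_true(all(abs(est$beta_click - beta_true) < 3 * est$se_click))
  expect_lt(abs(est$beta_bias - bias_true), 3 * est$se_bias)
  expect_identical(classify_kernel_shape(est)$label, "bump")
})

test_that("estimates tighten with sample size (consistency)", {
  beta_true <- 0.1 + 0.4 * exp(-((1:20) - 8)^2 / 18)
  rmse <- vapply(c(5000, 50000), function(n) {
    trials <- generate_trials(default_proto, n, seed = 17)
    obs <- function(tr) plogis(as.numeric(click_matrix(tr) %*% beta_true))
    trials <- simulate_choices(trials, obs, seed = 18)
    est <- fit_logistic_kernel(trials)
    sqrt(mean((est$beta_click - beta_true)^2))
  }, numeric(1))
  expect_gt(rmse[1] / rmse[2], 2)
  expect_lt(rmse[1] / rmse[2], 5)
})

test_that("separation raises an informative error unless ridged", {
  trials <- counter_choices(generate_trials(default_proto, 120, seed = 19))
  expect_error(fit_logistic_kernel(trials), "ridge")
  est <- fit_logistic_kernel(trials, ridge = 1e-3)
  expect_true(est$converged)
  expect_true(all(est$beta_click > 0))
})

test_that("mirroring the data mirrors only the bias, exactly", {
  trials <- generate_trials(default_proto, 3000, seed = 20)
  p <- divnorm_params(1.56, 6.2, 1.2, sigma = 0.05, mu = -0.33, bias = 0.4)
  trials <- simulate_choices(trials, divnorm_observer(p, default_proto),
                             seed = 21)
  a <- fit_logistic_kernel(trials)
  b <- fit_logistic_kernel(mirror_trials(trials))
  expect_equal(a$beta_click, b$beta_click, tolerance = 1e-10)
  expect_equal(a$beta_bias, -b$beta_bias, tolerance = 1e-10)
})

test_that("shape classification follows the segment-contrast rule", {
  expect_identical(classify_kernel_shape(rep(0.4, 20))$label, "flat")
  expect_identical(classify_kernel_shape(seq(1, 0.1, length.out = 20))$label,
                   "primacy")
  expect_identical(classify_kernel_shape(seq(0.1, 1, length.out = 20))$label,
                   "recency")
  bump <- 0.1 + 0.4 * exp(-((1:20) - 10)^2 / 18)
  expect_identical(classify_kernel_shape(bump)$label, "bump")
  # threshold scales with the mean: a tiny ripple on a large baseline is flat
  expect_identical(classify_kernel_shape(1 + 0.01 * sin(1:20))$label, "flat")
  est <- structure(list(beta_click = rep(1, 20), converged = FALSE),
                   class = "kernel_estimate")
  expect_error(classify_kernel_shape(est), "converged")
})

test_that("psychometric curves behave for deterministic and model observers", {
  trials <- counter_choices(generate_trials(default_proto, 4000, seed = 22))
  pc <- psychometric_curve(trials)
  expect_true(all(pc$p_left[pc$delta_clicks > 0] == 1))
  expect_true(all(pc$p_left[pc$delta_clicks < 0] == 0))
  # model-predicted curve via probabilities is monotone within noise
  p <- bump_preset
  trials2 <- generate_trials(default_proto, 20000, seed = 23)
  probs <- divnorm_observer(p, default_proto)(trials2)
  pcm <- psychometric_curve(trials2, p_left = probs)
  big <- pcm[pcm$n >= 100, ]
  expect_true(all(diff(big$p_left) > -0.05))
  fit <- attr(pcm, "sigmoid_fit")
  expect_gt(fit$slope, 0)
  # symmetry of an unbiased observer
  trials3 <- simulate_choices(trials2, lca_observer(lca_params(0, 2, 0),
                                                    default_proto), seed = 24)
  pc3 <- psychometric_curve(trials3)
  neg <- pc3[match(-pc3$delta_clicks, pc3$delta_clicks), ]
  big <- !is.na(neg$p_left) & pc3$n >= 200 & neg$n >= 200
  expect_true(all(abs(pc3$p_left[big] + neg$p_left[big] - 1) <
                    4 * sqrt(0.25 / 200 + 0.25 / 200)))
})

test_that("cohort-mean kernels average correctly", {
  mk <- function(b) structure(
    list(beta_click = b, beta_bias = 0, se_click = rep(0.1, 20),
         se_bias = 0.1, converged = TRUE, n_trials = 100, ridge = 0,
         participant_id = "x"),
    class = "kernel_estimate"
  )
  same <- cohort_mean_kernel(list(mk(1:20 / 10), mk(1:20 / 10)))
  expect_equal(same$mean_beta, 1:20 / 10)
  expect_true(all(same$sem == 0))
  pair <- cohort_mean_kernel(list(mk(1:20 / 10), mk(20:1 / 10)))
  expect_equal(pair$mean_beta, rev(pair$mean_beta))
  expect_error(cohort_mean_kernel(list(mk(1:20 / 10))), "at least 2")
})

test_that("the bump group's mean estimated kernel is itself a bump", {
  spec <- cohort_spec(
    n_participants = 8,
    shape_mixture = c(primacy = 0, bump = 1, flat = 0, recency = 0),
    trials_per_participant = 2500, seed = 515
  )
  cohort <- make_synthetic_cohort(spec)
  ests <- lapply(unique(cohort$trials$participant_id), function(id) {
    tr <- dplyr::filter(cohort$trials, participant_id == id)
    attr(tr, "protocol") <- default_proto
    fit_logistic_kernel(tr)
  })
  mk <- cohort_mean_kernel(ests)
  expect_identical(classify_kernel_shape(mk$mean_beta)$label, "bump")
})

test_that("model-reconstruction loop: fitted labels match analytic labels", {
  spec <- cohort_spec(
    n_participants = 12,
    shape_mixture = c(primacy = .25, bump = .25, flat = .25, recency = .25),
    trials_per_participant = 4000, seed = 303
  )
  cohort <- make_synthetic_cohort(spec)
  labels <- vapply(seq_len(12), function(i) {
    tr <- cohort$truth[i, ]
    trials <- dplyr::filter(cohort$trials, participant_id == tr$participant_id)
    attr(trials, "protocol") <- default_proto
    est <- fit_logistic_kernel(trials)
    fitted_label <- classify_kernel_shape(est)$label
    params <- divnorm_params(tr$tau_R, tr$tau_G, tr$omega_I, tr$sigma,
                             tr$mu, tr$bias)
    analytic_label <- classify_kernel_shape(
      regression_kernel(params, default_proto)$beta
    )$label
    c(fitted_label, analytic_label, tr$shape)
  }, character(3))
  expect_true(all(labels[2, ] == labels[3, ])) # priors express their shapes
  expect_gte(mean(labels[1, ] == labels[2, ]), 0.9)
})
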