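test_that("protocol validation enforces the task invariants", {
  expect_s3_class(task_protocol(), "task_protocol")
  expect_error(task_protocol(n_clicks = 0), "n_clicks")
  expect_error(task_protocol(inter_click_interval = 0), "inter_click_interval")
  expect_error(task_protocol(stimulus_duration = 0.9), "stimulus_duration")
  expect_error(task_protocol(stimulus_duration = 1.1), "stimulus_duration")
  expect_error(task_protocol(p_correct_ear = 0), "p_correct_ear")
  expect_error(task_protocol(p_correct_left = 1.2), "p_correct_left")
  expect_equal(click_times(task_protocol())[1:3], c(0, 0.05, 0.10))
})

test_that("generated trains sit on the exact 50 ms grid", {
  set.seed(1)
  tr <- generate_click_train(default_proto, "L")
  expect_length(tr$times, 20)
  expect_lt(max(abs(diff(tr$times) - 0.05)), 1e-12)
  expect_equal(tr$duration, 1.0)
  expect_true(all(tr$signs %in% c(-1L, 1L)))
})

test_that("degenerate click probabilities are honoured exactly", {
  proto1 <- task_protocol(p_correct_ear = 1)
  set.seed(2)
  expect_identical(generate_click_train(proto1, "L")$signs, rep(1L, 20))
  expect_identical(generate_click_train(proto1, "R")$signs, rep(-1L, 20))
  protoL <- task_protocol(p_correct_left = 1)
  trials <- generate_trials(protoL, 25, seed = 3)
  expect_true(all(trials$correct_side == "L"))
})

test_that("per-position correct-side frequency matches p_correct_ear", {
  trials <- generate_trials(default_proto, 10000, seed = 42)
  X <- click_matrix(trials)
  correct_sign <- ifelse(trials$correct_side == "L", 1L, -1L)
  on_correct <- X == correct_sign
  se <- sqrt(0.55 * 0.45 / nrow(trials))
  per_position <- colMeans(on_correct)
  expect_true(all(abs(per_position - 0.55) < 4 * se))
  # pooled left-correct fraction
  expect_lt(abs(mean(trials$correct_side == "L") - 0.5), 0.015)
})

test_that("trial generation is reproducible and mirror-closed", {
  a <- generate_trials(default_proto, 100, seed = 7)
  b <- generate_trials(default_proto, 100, seed = 7)
  expect_identical(a, b)
  m <- mirror_trials(mirror_trials(a))
  expect_identical(as.data.frame(m), as.data.frame(a))
})

test_that("single-trial datasets carry a missing choice", {
  t1 <- generate_trials(default_proto, 1, seed = 1)
  expect_identical(nrow(t1), 1L)
  expect_true(is.na(t1$choice))
  expect_error(generate_trials(default_proto, 0), "n_trials")
})

test_that("simulate_choices draws Bernoulli choices and guards the contract", {
  trials <- generate_trials(default_proto, 200, seed = 1)
  all_left <- simulate_choices(trials, constant_observer(1))
  expect_true(all(all_left$choice == "L"))
  expect_true(all(is.na(trials$choice))) # input unmodified
  expect_error(
    simulate_choices(trials, function(tr) rep(1.5, nrow(tr))),
    "outside"
  )
  # symmetry: unbiased observer on a dataset plus its mirror
  obs <- lca_observer(lca_params(0, 2, 0), default_proto)
  both <- dplyr::bind_rows(trials, mirror_trials(trials))
  attr(both, "protocol") <- default_proto
  sim <- simulate_choices(both, obs, seed = 5)
  p_hat <- mean(sim$choice == "L")
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / nrow(sim)))
})

test_that("simulated accuracy matches a large Monte-Carlo oracle", {
  params <- divnorm_params(2.27, 11.10, 36.20, sigma = 0.05, mu = -0.05,
                           bias = 0)
  obs <- divnorm_observer(params, default_proto)
  small <- simulate_choices(generate_trials(default_proto, 5000, seed = 11),
                            obs, seed = 12)
  big <- simulate_choices(generate_trials(default_proto, 200000, seed = 13),
                          obs, seed = 14)
  acc_small <- mean(small$choice == small$correct_side)
  acc_big <- mean(big$choice == big$correct_side)
  se <- sqrt(acc_big * (1 - acc_big) * (1 / 5000 + 1 / 200000))
  expect_lt(abs(acc_small - acc_big), 3 * se)
})

test_that("largest-remainder allocation reproduces the reference group sizes", {
  expect_identical(largest_remainder(4, rep(0.25, 4)), rep(1L, 4))
  expect_identical(
    largest_remainder(133, c(0.31, 0.53, 0.12, 0.04)),
    c(41L, 71L, 16L, 5L)
  )
  expect_identical(sum(largest_remainder(7, c(0.5, 0.3, 0.2))), 7L)
})

test_that("synthetic cohorts are deterministic and invariant to cohort size", {
  spec <- cohort_spec(n_participants = 4, shape_mixture =
                        c(primacy = .25, bump = .25, flat = .25, recency = .25),
                      trials_per_participant = 40, seed = 9)
  a <- make_synthetic_cohort(spec)
  b <- make_synthetic_cohort(spec)
  expect_identical(a$truth, b$truth)
  expect_identical(as.data.frame(a$trials), as.data.frame(b$trials))
  expect_identical(sort(unique(a$truth$shape)),
                   c("bump", "flat", "primacy", "recency"))
  # participant 1 unchanged when the cohort grows
  spec8 <- cohort_spec(n_participants = 8, shape_mixture =
                         c(primacy = .25, bump = .25, flat = .25, recency = .25),
                       trials_per_participant = 40, seed = 9)
  c8 <- make_synthetic_cohort(spec8)
  expect_identical(
    as.data.frame(dplyr::filter(a$trials, participant_id == "S001")[-1]),
    as.data.frame(dplyr::filter(c8$trials, participant_id == "S001")[-1])
  )
})

test_that("inclusion criterion retains by accuracy with a recount oracle", {
  proto <- default_proto
  mk <- function(id, acc, n = 100) {
    tr <- generate_trials(proto, n, participant_id = id, seed = 17)
    n_ok <- round(acc * n)
    tr$choice <- ifelse(seq_len(n) <= n_ok, tr$correct_side,
                        ifelse(tr$correct_side == "L", "R", "L"))
    tr
  }
  trials <- dplyr::bind_rows(mk("lo", 0.59), mk("hi", 1.0))
  attr(trials, "protocol") <- proto
  res <- apply_inclusion_criterion(trials)
  expect_identical(unique(res$excluded$participant_id), "lo")
  expect_identical(unique(res$retained$participant_id), "hi")
  expect_error(apply_inclusion_criterion(generate_trials(proto, 5, seed = 1)),
               "choices")

  # 10 participants, 3 of them guessing: excluded count equals direct recount
  set.seed(31)
  cohort <- dplyr::bind_rows(lapply(1:10, function(i) {
    tr <- generate_trials(proto, 800, participant_id = sprintf("G%02d", i))
    obs <- if (i <= 3) constant_observer(0.5) else
      lca_observer(lca_params(0, 1.5, 0), proto)
    simulate_choices(tr, obs)
  }))
  attr(cohort, "protocol") <- proto
  res <- apply_inclusion_criterion(cohort, 0.6)
  recount <- cohort |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(acc = mean(choice == correct_side)) |>
    dplyr::filter(acc < 0.6) |>
    nrow()
  expect_identical(length(unique(res$excluded$participant_id)), recount)
})
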