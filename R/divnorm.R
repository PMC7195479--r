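#' Parameters of the dynamic divisive-normalization observer
#'
#' The circuit holds two excitatory pools `R_left`, `R_right` (leak time
#' constant `tau_R`) receiving the left/right click inputs, and one inhibitory
#' gain unit `G` (time constant `tau_G`) driven by the summed excitatory
#' activity with weight `omega_I`; `G` divisively scales the input to both
#' pools:
#'
#' \deqn{\tau_R \dot R_i = -R_i + C_i / (1 + G)}
#' \deqn{\tau_G \dot G   = -G + \omega_I (R_{left} + R_{right})}
#'
#' The decision variable is `delta = R_left - R_right` at stimulus end, the
#' choice rule `logit(p_left) = delta'/sigma + bias` with `delta'` the kernel
#' sum offset by `mu` per click (see [decision_variable()]).
#'
#' @param tau_R Excitatory leak time constant, seconds (> 0).
#' @param tau_G Inhibitory time constant, seconds (> 0).
#' @param omega_I Inhibitory drive weight (>= 0), dimensionless.
#' @param sigma Decision noise scale (> 0).
#' @param mu Additive per-click kernel offset.
#' @param bias Log-odds side bias (positive favours left).
#' @return An object of class `divnorm_params`.
#' @examples
#' divnorm_params(tau_R = 2.27, tau_G = 11.10, omega_I = 36.20)
#' @export
divnorm_params <- function(tau_R, tau_G, omega_I, sigma = 1, mu = 0,
                           bias = 0) {
  p <- list(
    tau_R = as.numeric(tau_R), tau_G = as.numeric(tau_G),
    omega_I = as.numeric(omega_I), sigma = as.numeric(sigma),
    mu = as.numeric(mu), bias = as.numeric(bias)
  )
  if (!is.finite(p$tau_R) || p$tau_R <= 0) stop("`tau_R` must be > 0", call. = FALSE)
  if (!is.finite(p$tau_G) || p$tau_G <= 0) stop("`tau_G` must be > 0", call. = FALSE)
  if (!is.finite(p$omega_I) || p$omega_I < 0) stop("`omega_I` must be >= 0", call. = FALSE)
  if (!is.finite(p$sigma) || p$sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  structure(p, class = "divnorm_params")
}

#' @export
print.divnorm_params <- function(x, ...) {
  cat(sprintf(
    "<divnorm_params> tau_R=%g tau_G=%g omega_I=%g sigma=%g mu=%g bias=%g\n",
    x$tau_R, x$tau_G, x$omega_I, x$sigma, x$mu, x$bias
  ))
  invisible(x)
}

#' Static divisive normalization
#'
#' The classic single-step normalization `f_i = u_i / (S + sum_j u_j)`, the
#' stationary computation whose dynamic counterpart drives the accumulator
#' model in this package.
#'
#' @param u Non-negative input vector.
#' @param S Non-negative semi-saturation constant.
#' @return The normalized vector, summing to at most 1 (equality iff `S = 0`).
#' @examples
#' static_normalization(c(1, 1), S = 0)
#' @export
static_normalization <- function(u, S = 0) {
  u <- as.numeric(u)
  if (any(u < 0) || S < 0) {
    stop("`u` and `S` must be non-negative", call. = FALSE)
  }
  denom <- S + sum(u)
  if (denom == 0) {
    stop("division domain error: S + sum(u) = 0", call. = FALSE)
  }
  u / denom
}

# ---------------------------------------------------------------------------
# Numerical core
#
# Clicks are Dirac impulses of unit area: integrating tau_R dR/dt = -R +
# C/(1+G) across the impulse gives a jump dR = 1/(tau_R (1 + G(t-))) on the
# click's side, with G continuous across the click (its ODE has no impulse
# input). G is evaluated just before the impulse. Between clicks the system is
# smooth (C = 0) and is advanced with classical fixed-step RK4 whose grid is
# forced to land on every click time.

rk4_piece <- function(state, deriv, t0, t1, dt) {
  span <- t1 - t0
  if (span <= 0) {
    return(list(state = state, times = numeric(0), states = NULL))
  }
  n_steps <- max(1L, ceiling(span / dt - 1e-9))
  h <- span / n_steps
  times <- t0 + h * seq_len(n_steps)
  states <- matrix(0, nrow = n_steps, ncol = length(state))
  for (k in seq_len(n_steps)) {
    k1 <- deriv(state)
    k2 <- deriv(state + h / 2 * k1)
    k3 <- deriv(state + h / 2 * k2)
    k4 <- deriv(state + h * k3)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    states[k, ] <- state
  }
  list(state = state, times = times, states = states)
}

#' Simulate the divisive-normalization dynamics for one trial
#'
#' Integrates the coupled `R_left`/`R_right`/`G` system driven by a click
#' train. Each click is a unit-area impulse: the corresponding pool jumps by
#' `1 / (tau_R * (1 + G))` with `G` taken just before the impulse; between
#' clicks the smooth system is advanced with classical 4th-order Runge-Kutta
#' on a grid containing every click time exactly. Values stored at a click
#' time are post-impulse.
#'
#' @param params A [divnorm_params()] (only `tau_R`, `tau_G`, `omega_I` are
#'   used).
#' @param train A [click_train()].
#' @param dt Integrator step, seconds; must be positive and no larger than the
#'   smallest inter-click gap.
#' @return A tibble of class `divnorm_trajectory` with columns `time`,
#'   `R_left`, `R_right`, `G`, `delta`.
#' @examples
#' tr <- click_train(c(0, 0.05), c(1, -1), 1)
#' head(simulate_dynamics(divnorm_params(2.27, 11.10, 36.20), tr))
#' @export
simulate_dynamics <- function(params, train, dt = 1e-3) {
  stopifnot(inherits(params, "divnorm_params"), inherits(train, "click_train"))
  gaps <- diff(c(0, train$times, train$duration))
  if (!is.finite(dt) || dt <= 0) {
    stop("`dt` must be > 0", call. = FALSE)
  }
  if (dt > min(gaps[gaps > 0])) {
    stop("`dt` larger than the smallest inter-click gap; decrease it",
         call. = FALSE)
  }
  tau_R <- params$tau_R; tau_G <- params$tau_G; omega_I <- params$omega_I
  deriv <- function(s) {
    c(-s[1] / tau_R, -s[2] / tau_R, (-s[3] + omega_I * (s[1] + s[2])) / tau_G)
  }
  state <- c(0, 0, 0) # R_left, R_right, G
  times <- 0
  states <- matrix(state, nrow = 1)
  t_now <- 0
  for (i in seq_along(train$times)) {
    piece <- rk4_piece(state, deriv, t_now, train$times[i], dt)
    state <- piece$state
    if (length(piece$times) > 0) {
      times <- c(times, piece$times)
      states <- rbind(states, piece$states)
    }
    jump <- 1 / (tau_R * (1 + state[3]))
    if (train$signs[i] == 1L) state[1] <- state[1] + jump else state[2] <- state[2] + jump
    if (t_now == train$times[i] || length(piece$times) > 0) {
      # overwrite / append the node at the click time with post-impulse state
      if (utils::tail(times, 1) == train$times[i]) {
        states[nrow(states), ] <- state
      } else {
        times <- c(times, train$times[i])
        states <- rbind(states, state)
      }
    }
    t_now <- train$times[i]
  }
  piece <- rk4_piece(state, deriv, t_now, train$duration, dt)
  if (length(piece$times) > 0) {
    times <- c(times, piece$times)
    states <- rbind(states, piece$states)
  }
  out <- tibble::tibble(
    time = times,
    R_left = states[, 1],
    R_right = states[, 2],
    G = states[, 3],
    delta = states[, 1] - states[, 2]
  )
  class(out) <- c("divnorm_trajectory", class(out))
  attr(out, "params") <- params
  out
}

#' Shared inhibitory gain trajectory under a fixed-grid protocol
#'
#' On the fixed grid every slot carries exactly one click (left or right), so
#' the total excitatory activity `A = R_left + R_right` -- and therefore `G`
#' -- is identical across all trials of the protocol. This computes that
#' shared `G(t)` from the total-activity system (one unit impulse per slot)
#' with the same RK4 scheme as [simulate_dynamics()], so the two agree to
#' floating-point rounding.
#'
#' @param params A [divnorm_params()].
#' @param protocol A [task_protocol()].
#' @param dt Integrator step, seconds.
#' @return A tibble with columns `time`, `A`, `G`.
#' @export
gain_trajectory <- function(params, protocol, dt = 1e-3) {
  validate_protocol(protocol)
  stopifnot(inherits(params, "divnorm_params"))
  tau_R <- params$tau_R; tau_G <- params$tau_G; omega_I <- params$omega_I
  deriv <- function(s) c(-s[1] / tau_R, (-s[2] + omega_I * s[1]) / tau_G)
  state <- c(0, 0) # A, G
  ts <- click_times(protocol)
  times <- 0
  states <- matrix(state, nrow = 1)
  t_now <- 0
  for (i in seq_along(ts)) {
    piece <- rk4_piece(state, deriv, t_now, ts[i], dt)
    state <- piece$state
    if (length(piece$times) > 0) {
      times <- c(times, piece$times)
      states <- rbind(states, piece$states)
    }
    state[1] <- state[1] + 1 / (tau_R * (1 + state[2]))
    if (utils::tail(times, 1) == ts[i]) {
      states[nrow(states), ] <- state
    } else {
      times <- c(times, ts[i])
      states <- rbind(states, state)
    }
    t_now <- ts[i]
  }
  piece <- rk4_piece(state, deriv, t_now, protocol$stimulus_duration, dt)
  if (length(piece$times) > 0) {
    times <- c(times, piece$times)
    states <- rbind(states, piece$states)
  }
  tibble::tibble(time = times, A = states[, 1], G = states[, 2])
}

# Exact pre-click gain values G(t_i-) by closed-form propagation.
#
# Between impulses the (A, G) system is linear with eigenvalues -1/tau_R and
# -1/tau_G, so it propagates exactly over an interval s:
#   A1 = A0 exp(-s/tau_R)
#   G1 = exp(-s/tau_G) * (G0 + omega_I * A0 * h / tau_G),
#   h  = (1 - exp(-s d)) / d,  d = 1/tau_R - 1/tau_G   (h -> s as d -> 0).
# Works for any strictly increasing impulse times (every impulse adds
# 1/(tau_R (1+G)) to A regardless of side).
gain_at_clicks <- function(tau_R, tau_G, omega_I, times) {
  d <- 1 / tau_R - 1 / tau_G
  A <- 0; G <- 0; t_prev <- 0
  G_pre <- numeric(length(times))
  for (i in seq_along(times)) {
    s <- times[i] - t_prev
    if (s > 0) {
      h <- if (abs(d) < 1e-12) s else -expm1(-s * d) / d
      G <- exp(-s / tau_G) * (G + omega_I * A * h / tau_G)
      A <- A * exp(-s / tau_R)
    }
    G_pre[i] <- G
    A <- A + 1 / (tau_R * (1 + G))
    t_prev <- times[i]
  }
  G_pre
}

# Fast path: per-click kernel values for arbitrary click times.
kernel_values <- function(tau_R, tau_G, omega_I, times, decision_time) {
  G_pre <- gain_at_clicks(tau_R, tau_G, omega_I, times)
  (1 / tau_R) * exp(-(decision_time - times) / tau_R) / (1 + G_pre)
}

#' Analytic per-click integration kernel
#'
#' The divisive-normalization decision variable admits the closed form
#' \deqn{\delta(T) = \frac{1}{\tau_R}\int_0^T
#'   \frac{e^{-(T-t)/\tau_R}}{1+G(t)}\,\Delta C(t)\,dt,}
#' so with impulse clicks each click `i` contributes with weight
#' `K_i = (1/tau_R) exp(-(T - t_i)/tau_R) / (1 + G(t_i-))`, the gain taken
#' just before the click's own impulse. The kernel is the product of an
#' exponential increasing in `t_i` (the leak forgets early clicks) and the
#' decreasing `1/(1+G)` (inhibition discounts late clicks); their balance sets
#' the kernel shape.
#'
#' @param params A [divnorm_params()].
#' @param train A [click_train()], or a [task_protocol()] (all trains of a
#'   fixed-grid protocol share the same kernel).
#' @param method `"closed_form"` (exact piecewise propagation of the linear
#'   inter-click system; default) or `"ode"` (RK4 gain integration at step
#'   `dt`, available as an independent cross-check).
#' @param dt RK4 step for `method = "ode"`.
#' @return A tibble of class `kernel_weights` with columns `click`, `time`,
#'   `K`, and attributes `mu` and `decision_time`.
#' @examples
#' kernel_weights(divnorm_params(2.27, 11.10, 36.20), task_protocol())
#' @export
kernel_weights <- function(params, train, method = c("closed_form", "ode"),
                           dt = 1e-3) {
  stopifnot(inherits(params, "divnorm_params"))
  method <- match.arg(method)
  if (inherits(train, "task_protocol")) {
    times <- click_times(train)
    decision_time <- train$stimulus_duration
  } else {
    stopifnot(inherits(train, "click_train"))
    times <- train$times
    decision_time <- train$duration
  }
  if (method == "closed_form") {
    K <- kernel_values(params$tau_R, params$tau_G, params$omega_I,
                       times, decision_time)
  } else {
    G_pre <- gain_at_clicks_ode(params, times, dt)
    K <- (1 / params$tau_R) *
      exp(-(decision_time - times) / params$tau_R) / (1 + G_pre)
  }
  out <- tibble::tibble(click = seq_along(times), time = times, K = K)
  class(out) <- c("kernel_weights", class(out))
  attr(out, "mu") <- params$mu
  attr(out, "decision_time") <- decision_time
  out
}

# RK4 route to the pre-click gains (independent of the closed form).
gain_at_clicks_ode <- function(params, times, dt = 1e-3) {
  tau_R <- params$tau_R; tau_G <- params$tau_G; omega_I <- params$omega_I
  deriv <- function(s) c(-s[1] / tau_R, (-s[2] + omega_I * s[1]) / tau_G)
  state <- c(0, 0)
  t_now <- 0
  G_pre <- numeric(length(times))
  for (i in seq_along(times)) {
    piece <- rk4_piece(state, deriv, t_now, times[i], dt)
    state <- piece$state
    G_pre[i] <- state[2]
    state[1] <- state[1] + 1 / (tau_R * (1 + state[2]))
    t_now <- times[i]
  }
  G_pre
}

#' Decision variable of the divisive-normalization observer
#'
#' `delta'(T) = sum_i (K_i + mu) * sign_i`: the kernel-weighted signed click
#' sum, with the offset `mu` added to every click's weight.
#'
#' @param params A [divnorm_params()].
#' @param train A [click_train()].
#' @return The scalar decision variable at stimulus end.
#' @export
decision_variable <- function(params, train) {
  stopifnot(inherits(train, "click_train"))
  K <- kernel_values(params$tau_R, params$tau_G, params$omega_I,
                     train$times, train$duration)
  sum((K + params$mu) * train$signs)
}

#' Choice probability of the divisive-normalization observer
#'
#' `logit(p_left) = delta'(T)/sigma + bias`.
#'
#' @inheritParams decision_variable
#' @return Probability of choosing left, in (0, 1).
#' @export
choice_probability <- function(params, train) {
  stats::plogis(decision_variable(params, train) / params$sigma + params$bias)
}

# Vectorized choice probabilities over a signed click matrix (fixed grid:
# all trials share the kernel, computed once per parameter set).
divnorm_p_left <- function(params, X, protocol) {
  K <- kernel_values(params$tau_R, params$tau_G, params$omega_I,
                     click_times(protocol), protocol$stimulus_duration)
  dv <- as.numeric(X %*% (K + params$mu))
  stats::plogis(dv / params$sigma + params$bias)
}

#' Divisive-normalization observer for [simulate_choices()]
#'
#' @param params A [divnorm_params()].
#' @param protocol Optional [task_protocol()]; defaults to the protocol
#'   attached to the trial table at call time.
#' @return An observer function.
#' @export
divnorm_observer <- function(params, protocol = NULL) {
  stopifnot(inherits(params, "divnorm_params"))
  function(trials) {
    divnorm_p_left(params, click_matrix(trials),
                   trials_protocol(trials, protocol))
  }
}

#' Regression-scale kernel of a divisive-normalization observer
#'
#' The kernel the observer exhibits in the click logistic regression:
#' `beta_i = (K_i + mu) / sigma`. This is the object on the same scale as
#' [fit_logistic_kernel()] estimates and the one fed to
#' [classify_kernel_shape()].
#'
#' @param params A [divnorm_params()].
#' @param protocol A [task_protocol()].
#' @return A tibble with columns `click`, `time`, `K`, `beta`.
#' @export
regression_kernel <- function(params, protocol = task_protocol()) {
  kw <- kernel_weights(params, protocol)
  out <- tibble::as_tibble(kw)
  out$beta <- (out$K + params$mu) / params$sigma
  out
}
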