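#' Parameters of the leaky/unstable accumulator (LCA) observer
#'
#' A single accumulator integrating the signed clicks with memory drift `lam`
#' and diffusion noise: `da = (lam * a + C(t)) dt + sigma_a dW`. Negative
#' `lam` leaks the accumulated evidence (recency weighting), positive `lam`
#' amplifies early evidence (primacy), `lam = 0` recovers the basic
#' drift-diffusion model with a flat kernel. The choice compares `a(T)` with
#' the threshold `bias`.
#'
#' @param lam Memory drift rate, 1/seconds (any sign).
#' @param sigma_a Diffusion scale per square-root second (> 0).
#' @param bias Decision threshold on the accumulator at stimulus end.
#' @return An object of class `lca_params`.
#' @export
lca_params <- function(lam = 0, sigma_a = 1, bias = 0) {
  p <- list(lam = as.numeric(lam), sigma_a = as.numeric(sigma_a),
            bias = as.numeric(bias))
  if (!is.finite(p$sigma_a) || p$sigma_a <= 0) {
    stop("`sigma_a` must be > 0", call. = FALSE)
  }
  structure(p, class = "lca_params")
}

#' @export
print.lca_params <- function(x, ...) {
  cat(sprintf("<lca_params> lam=%g sigma_a=%g bias=%g\n",
              x$lam, x$sigma_a, x$bias))
  invisible(x)
}

# Per-click impulse weights and terminal variance of the unbounded linear
# accumulator: a(T) | train ~ Normal(m, v) with
#   m = sum_i sign_i * exp(lam * (T - t_i))
#   v = sigma_a^2 * (exp(2 lam T) - 1) / (2 lam)   (v = sigma_a^2 T at lam = 0)
lca_click_weights <- function(lam, times, decision_time) {
  exp(lam * (decision_time - times))
}

lca_terminal_variance <- function(lam, sigma_a, decision_time) {
  if (abs(lam) < 1e-12) {
    sigma_a^2 * decision_time
  } else {
    sigma_a^2 * expm1(2 * lam * decision_time) / (2 * lam)
  }
}

#' Choice probability of the (unbounded) LCA observer
#'
#' Clicks are unit impulses, so `a(T)` is Gaussian conditional on the train
#' and the choice probability has the probit closed form
#' `p_left = Phi((m - bias) / sqrt(v))`.
#'
#' @param params An [lca_params()].
#' @param train A [click_train()].
#' @return Probability of choosing left.
#' @export
lca_choice_probability <- function(params, train) {
  stopifnot(inherits(params, "lca_params"), inherits(train, "click_train"))
  w <- lca_click_weights(params$lam, train$times, train$duration)
  m <- sum(train$signs * w)
  v <- lca_terminal_variance(params$lam, params$sigma_a, train$duration)
  stats::pnorm((m - params$bias) / sqrt(v))
}

lca_p_left <- function(params, X, protocol) {
  w <- lca_click_weights(params$lam, click_times(protocol),
                         protocol$stimulus_duration)
  m <- as.numeric(X %*% w)
  v <- lca_terminal_variance(params$lam, params$sigma_a,
                             protocol$stimulus_duration)
  stats::pnorm((m - params$bias) / sqrt(v))
}

#' LCA observer for [simulate_choices()]
#'
#' @param params An [lca_params()].
#' @param protocol Optional [task_protocol()].
#' @return An observer function.
#' @export
lca_observer <- function(params, protocol = NULL) {
  stopifnot(inherits(params, "lca_params"))
  function(trials) {
    lca_p_left(params, click_matrix(trials), trials_protocol(trials, protocol))
  }
}

#' Basic drift-diffusion observer (LCA with `lam = 0`)
#'
#' @param sigma_a Diffusion scale (> 0).
#' @param bias Decision threshold at stimulus end.
#' @param protocol Optional [task_protocol()].
#' @return An observer function.
#' @export
ddm_observer <- function(sigma_a = 1, bias = 0, protocol = NULL) {
  lca_observer(lca_params(lam = 0, sigma_a = sigma_a, bias = bias), protocol)
}
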