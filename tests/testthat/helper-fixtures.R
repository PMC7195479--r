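# Shared fixtures: small deterministic trains and parameter presets.

default_proto <- task_protocol()

# Fig-style reference dynamics parameters used in the integration oracles.
ref_dyn_params <- divnorm_params(tau_R = 2.27, tau_G = 11.10, omega_I = 36.20)

# The package's documented bump-regime preset (see the methods vignette).
bump_preset <- divnorm_params(tau_R = 1.596, tau_G = 6.5, omega_I = 1.2,
                              sigma = 0.05, mu = -0.32)

# A fixed 20-click train (balanced but asymmetric in time).
fixed_train <- function(proto = default_proto) {
  signs <- rep(c(1L, 1L, -1L, 1L, -1L), 4)
  click_train(click_times(proto), signs, proto$stimulus_duration)
}

random_train <- function(proto = default_proto) {
  signs <- sample(c(-1L, 1L), proto$n_clicks, replace = TRUE)
  click_train(click_times(proto), signs, proto$stimulus_duration)
}

# The click train of row k of a trial tibble.
train_row <- function(trials, k, proto = default_proto) {
  click_train(click_times(proto), unlist(click_matrix(trials[k, ])),
              proto$stimulus_duration)
}

# Trials whose choices follow the deterministic click counter (ties -> left).
counter_choices <- function(trials) {
  dc <- rowSums(click_matrix(trials))
  out <- trials
  out$choice <- ifelse(dc >= 0, "L", "R")
  attr(out, "protocol") <- attr(trials, "protocol")
  out
}
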