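#' Default observer-parameter priors for the four kernel phenotypes
#'
#' Uniform ranges for the divisive-normalization parameters of each
#' kernel-shape group. The boxes sit in the regions of (tau_R, tau_G,
#' omega_I) space where the analytic regression-scale kernel
#' `(K + mu)/sigma` carries the group's shape with margin under the default
#' classifier: primacy at large tau_R/tau_G (inhibition outruns the leak),
#' bump and flat near the leak/inhibition balance at ratios ~0.25, recency at
#' small ratios where the leak dominates. The `mu` ranges offset the kernel
#' baseline (~`1/tau_R` scale) so the implied regression weights are on the
#' human scale (mean roughly 0.3-1.5) and `sigma` sets realistic accuracy.
#'
#' @return Named list of groups (`primacy`, `bump`, `flat`, `recency`), each a
#'   named list of `c(lower, upper)` ranges for `tau_R`, `tau_G`, `omega_I`,
#'   `sigma`, `mu`, `bias`.
#' @export
default_shape_priors <- function() {
  list(
    primacy = list(
      tau_R = c(3.5, 6.0), tau_G = c(0.6, 1.6), omega_I = c(1.0, 1.4),
      sigma = c(0.04, 0.07), mu = c(-0.10, -0.04), bias = c(-0.15, 0.15)
    ),
    bump = list(
      tau_R = c(1.52, 1.64), tau_G = c(5.9, 6.4), omega_I = c(1.15, 1.25),
      sigma = c(0.04, 0.07), mu = c(-0.337, -0.327), bias = c(-0.15, 0.15)
    ),
    flat = list(
      tau_R = c(5.2, 5.8), tau_G = c(9.7, 10.3), omega_I = c(1.15, 1.25),
      sigma = c(0.04, 0.07), mu = c(-0.10, -0.06), bias = c(-0.15, 0.15)
    ),
    recency = list(
      tau_R = c(0.40, 0.65), tau_G = c(6.0, 12.0), omega_I = c(1.1, 1.3),
      sigma = c(0.04, 0.07), mu = c(-0.45, -0.35), bias = c(-0.15, 0.15)
    )
  )
}

#' Specify a synthetic cohort
#'
#' Defines a heterogeneous cohort of divisive-normalization observers whose
#' kernel phenotypes follow a mixture over the four shape groups. Defaults
#' mirror the reference cohort: 133 participants at mixture 31/53/12/4%
#' (giving group sizes 41/71/16/5 by largest remainder) and 750 trials per
#' participant.
#'
#' @param n_participants Number of participants (>= 1).
#' @param shape_mixture Named proportions over
#'   `c(primacy, bump, flat, recency)`; must sum to 1.
#' @param trials_per_participant Trials per participant (>= 1).
#' @param parameter_priors Per-group parameter ranges
#'   (see [default_shape_priors()]).
#' @param seed Master seed; participants get child seeds derived from it, so
#'   a participant's data are invariant to cohort size.
#' @param protocol A [task_protocol()].
#' @return An object of class `synthetic_cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 133L,
                        shape_mixture = c(primacy = 0.31, bump = 0.53,
                                          flat = 0.12, recency = 0.04),
                        trials_per_participant = 750L,
                        parameter_priors = default_shape_priors(),
                        seed = 1L,
                        protocol = task_protocol()) {
  n_participants <- as.integer(n_participants)
  trials_per_participant <- as.integer(trials_per_participant)
  if (n_participants < 1L || trials_per_participant < 1L) {
    stop("participant and trial counts must be >= 1", call. = FALSE)
  }
  groups <- c("primacy", "bump", "flat", "recency")
  if (!setequal(names(shape_mixture), groups)) {
    stop("`shape_mixture` must be named over primacy/bump/flat/recency",
         call. = FALSE)
  }
  shape_mixture <- shape_mixture[groups]
  if (abs(sum(shape_mixture) - 1) > 1e-8 || any(shape_mixture < 0)) {
    stop("`shape_mixture` proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (!setequal(names(parameter_priors), groups)) {
    stop("`parameter_priors` must cover all four shape groups", call. = FALSE)
  }
  validate_protocol(protocol)
  structure(
    list(
      n_participants = n_participants,
      shape_mixture = shape_mixture,
      trials_per_participant = trials_per_participant,
      parameter_priors = parameter_priors,
      seed = as.integer(seed),
      protocol = protocol
    ),
    class = "synthetic_cohort_spec"
  )
}

#' Largest-remainder allocation of counts to proportions
#'
#' @param n Total count.
#' @param props Proportions summing to 1.
#' @return Integer counts summing to `n`; leftover units go to the largest
#'   fractional remainders (earlier entries win ties).
#' @export
largest_remainder <- function(n, props) {
  raw <- n * props
  counts <- floor(raw)
  rem <- raw - counts
  left <- n - sum(counts)
  if (left > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic cohort with ground truth
#'
#' Allocates participants to shape groups by largest remainder, draws each
#' participant's divisive-normalization parameters uniformly from the group's
#' prior box, generates that participant's trials under the protocol and
#' simulates choices from their observer. Each participant uses a child seed
#' derived from `spec$seed` and the participant index, so the output is fully
#' deterministic and a participant's data do not depend on cohort size.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `truth` (tibble: `participant_id`, `shape`, the six
#'   generating parameters, `seed`) and `trials` (the combined trial tibble
#'   with choices).
#' @export
make_synthetic_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  groups <- names(spec$shape_mixture)
  counts <- largest_remainder(spec$n_participants, spec$shape_mixture)
  shapes <- rep(groups, counts)
  ids <- sprintf("S%03d", seq_len(spec$n_participants))
  child_seeds <- with_local_seed(
    spec$seed,
    sample.int(.Machine$integer.max - 1L, spec$n_participants)
  )
  one <- function(i) {
    prior <- spec$parameter_priors[[shapes[i]]]
    with_local_seed(child_seeds[i], {
      draw <- vapply(prior, function(r) stats::runif(1, r[1], r[2]), numeric(1))
      params <- divnorm_params(
        tau_R = draw[["tau_R"]], tau_G = draw[["tau_G"]],
        omega_I = draw[["omega_I"]], sigma = draw[["sigma"]],
        mu = draw[["mu"]], bias = draw[["bias"]]
      )
      trials <- generate_trials(spec$protocol, spec$trials_per_participant,
                                participant_id = ids[i])
      trials <- simulate_choices(trials, divnorm_observer(params, spec$protocol))
      list(params = draw, trials = trials)
    })
  }
  sims <- lapply(seq_len(spec$n_participants), one)
  truth <- dplyr::bind_cols(
    tibble::tibble(participant_id = ids, shape = shapes),
    dplyr::bind_rows(lapply(sims, function(s) as.list(s$params))),
    tibble::tibble(seed = child_seeds)
  )
  trials <- dplyr::bind_rows(lapply(sims, function(s) s$trials))
  attr(trials, "protocol") <- spec$protocol
  list(truth = truth, trials = trials)
}
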