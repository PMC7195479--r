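#' Generate a single click train
#'
#' Draws one stimulus under a protocol: clicks on the fixed grid, each landing
#' on `correct_side` independently with probability `p_correct_ear`. Uses the
#' current R random-number stream; seed with [set.seed()] or wrap in
#' `withr::with_seed()` for reproducibility.
#'
#' @param protocol A [task_protocol()].
#' @param correct_side `"L"` or `"R"`.
#' @return A [click_train()].
#' @examples
#' set.seed(1)
#' generate_click_train(task_protocol(), "L")
#' @export
generate_click_train <- function(protocol, correct_side = c("L", "R")) {
  validate_protocol(protocol)
  correct_side <- match.arg(correct_side)
  correct_sign <- if (correct_side == "L") 1L else -1L
  on_correct <- stats::runif(protocol$n_clicks) < protocol$p_correct_ear
  signs <- ifelse(on_correct, correct_sign, -correct_sign)
  click_train(click_times(protocol), signs, protocol$stimulus_duration)
}

#' Generate a trial table without choices
#'
#' Produces the package's canonical trial tibble: one row per trial with the
#' signed click indicators in columns `click_01 ... click_NN` (+1 = left ear,
#' -1 = right ear), the designated `correct_side`, and an empty `choice`
#' column. The correct side of each trial is drawn left with probability
#' `p_correct_left`; clicks then land on it with probability `p_correct_ear`.
#' The protocol is attached as the `"protocol"` attribute and travels with the
#' tibble through the rest of the pipeline.
#'
#' @param protocol A [task_protocol()].
#' @param n_trials Number of trials (>= 1).
#' @param participant_id Participant label stored with every trial.
#' @param seed Optional integer; if supplied, the RNG state is set locally so
#'   the call is reproducible and does not disturb the caller's stream.
#' @return A tibble with columns `participant_id`, `trial_index`,
#'   `correct_side`, `choice` (all `NA`), `click_01 ...`.
#' @examples
#' trials <- generate_trials(task_protocol(), 5, seed = 1)
#' trials
#' @export
generate_trials <- function(protocol, n_trials, participant_id = "P01",
                            seed = NULL) {
  validate_protocol(protocol)
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) {
    stop("`n_trials` must be >= 1", call. = FALSE)
  }
  draw <- function() {
    correct_left <- stats::runif(n_trials) < protocol$p_correct_left
    correct_sign <- ifelse(correct_left, 1L, -1L)
    on_correct <- matrix(
      stats::runif(n_trials * protocol$n_clicks) < protocol$p_correct_ear,
      nrow = n_trials
    )
    clicks <- ifelse(on_correct, correct_sign, -correct_sign)
    list(correct_side = ifelse(correct_left, "L", "R"), clicks = clicks)
  }
  d <- with_local_seed(seed, draw())
  click_cols <- tibble::as_tibble(
    as.data.frame(d$clicks),
    .name_repair = ~ click_col_names(protocol$n_clicks)
  )
  trials <- dplyr::bind_cols(
    tibble::tibble(
      participant_id = participant_id,
      trial_index = seq_len(n_trials),
      correct_side = d$correct_side,
      choice = NA_character_
    ),
    click_cols
  )
  attr(trials, "protocol") <- protocol
  trials
}

click_col_names <- function(n_clicks) {
  sprintf("click_%02d", seq_len(n_clicks))
}

# Run code with a locally-set RNG state (restores the caller's stream).
with_local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Extract the signed click matrix from a trial table
#'
#' @param trials A trial tibble (see [generate_trials()]).
#' @return An integer matrix, one row per trial, one column per click.
#' @export
click_matrix <- function(trials) {
  cols <- grep("^click_\\d+$", names(trials), value = TRUE)
  if (length(cols) == 0) {
    stop("no `click_NN` columns found in `trials`", call. = FALSE)
  }
  m <- as.matrix(trials[cols])
  storage.mode(m) <- "integer"
  if (!all(m %in% c(-1L, 1L))) {
    stop("click columns must contain only +1 / -1", call. = FALSE)
  }
  m
}

trials_protocol <- function(trials, protocol = NULL) {
  protocol <- protocol %||% attr(trials, "protocol")
  if (is.null(protocol)) {
    stop(
      "no protocol attached to `trials`; pass `protocol =` explicitly",
      call. = FALSE
    )
  }
  validate_protocol(protocol)
}

#' Simulate choices from an observer model
#'
#' Applies an observer (any function mapping the trial table to per-trial
#' probabilities of choosing left) to every trial and draws choices from a
#' Bernoulli with that probability. Observers built with [divnorm_observer()],
#' [lca_observer()], [ddm_observer()], [brunton_observer()] or
#' [constant_observer()] all conform; a plain function
#' `function(trials) p_left` works too.
#'
#' @param trials A trial tibble.
#' @param observer An observer function/object; must return probabilities in
#'   `[0, 1]`, one per trial.
#' @param seed Optional integer for a locally-set RNG state.
#' @return A copy of `trials` with the `choice` column filled with `"L"`/`"R"`.
#' @examples
#' trials <- generate_trials(task_protocol(), 10, seed = 1)
#' simulate_choices(trials, constant_observer(1))$choice
#' @export
simulate_choices <- function(trials, observer, seed = NULL) {
  p_left <- observer_p_left(observer, trials)
  draw <- function() stats::runif(nrow(trials)) < p_left
  left <- with_local_seed(seed, draw())
  out <- trials
  out$choice <- ifelse(left, "L", "R")
  attr(out, "protocol") <- attr(trials, "protocol")
  out
}

observer_p_left <- function(observer, trials) {
  p <- observer(trials)
  if (!is.numeric(p) || length(p) != nrow(trials)) {
    stop("observer must return one probability per trial", call. = FALSE)
  }
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop(
      "observer returned probabilities outside [0, 1]: model contract violated",
      call. = FALSE
    )
  }
  p
}

#' Observer that always reports the same choice probability
#'
#' @param p Probability of choosing left, in `[0, 1]`.
#' @return An observer function for [simulate_choices()].
#' @export
constant_observer <- function(p) {
  force(p)
  function(trials) rep(p, nrow(trials))
}

#' Retain participants by accuracy
#'
#' Splits a multi-participant trial table into participants retained
#' (accuracy >= `min_accuracy`) and excluded, mirroring the usual
#' poor-performance exclusion at 60% accuracy.
#'
#' @param trials Trial tibble with choices for every trial.
#' @param min_accuracy Retention threshold on the fraction of trials where
#'   `choice == correct_side` (default 0.60).
#' @return A list with elements `retained` and `excluded` (trial tibbles) and
#'   `summary` (one row per participant: `participant_id`, `n_trials`,
#'   `accuracy`, `retained`).
#' @export
apply_inclusion_criterion <- function(trials, min_accuracy = 0.60) {
  if (anyNA(trials$choice)) {
    stop("all trials must have choices before applying the inclusion criterion",
         call. = FALSE)
  }
  summary <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      accuracy = mean(.data$choice == .data$correct_side),
      .groups = "drop"
    ) |>
    dplyr::mutate(retained = .data$accuracy >= min_accuracy)
  keep <- summary$participant_id[summary$retained]
  protocol <- attr(trials, "protocol")
  retained <- dplyr::filter(trials, .data$participant_id %in% keep)
  excluded <- dplyr::filter(trials, !(.data$participant_id %in% keep))
  attr(retained, "protocol") <- protocol
  attr(excluded, "protocol") <- protocol
  list(retained = retained, excluded = excluded, summary = summary)
}
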