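#' Define a fixed-grid clicks-task protocol
#'
#' The task presents a fixed number of auditory clicks on a regular temporal
#' grid; each click falls on the designated "correct" ear independently with
#' probability `p_correct_ear`, and the correct side itself is drawn left with
#' probability `p_correct_left`. The decision is read out at
#' `stimulus_duration` (interrogation paradigm). Defaults encode the standard
#' protocol: 20 clicks, one every 50 ms over 1 s, `p = 0.55` on the correct
#' ear, correct side left with probability 0.5.
#'
#' Click onsets are placed at `t_i = (i - 1) * inter_click_interval`, i.e. the
#' first click at `t = 0` and the last at `stimulus_duration -
#' inter_click_interval` under the defaults. This origin convention is a
#' package choice (the grid spacing, not its origin, is fixed by the task) and
#' is used consistently by every model in the package.
#'
#' @param n_clicks Number of clicks per trial (>= 1).
#' @param inter_click_interval Spacing of the click grid, seconds.
#' @param stimulus_duration Decision time `T`, seconds. Must satisfy
#'   `(n_clicks - 1) * inter_click_interval < stimulus_duration <=
#'   n_clicks * inter_click_interval`.
#' @param p_correct_ear Probability that a click lands on the correct ear,
#'   in (0, 1] (1 gives a deterministic stimulus, useful for testing).
#' @param p_correct_left Probability that the correct side is left, in
#'   \[0, 1\].
#'
#' @return An object of class `task_protocol`.
#' @examples
#' task_protocol()
#' click_times(task_protocol())
#' @export
task_protocol <- function(n_clicks = 20L,
                          inter_click_interval = 0.05,
                          stimulus_duration = 1.0,
                          p_correct_ear = 0.55,
                          p_correct_left = 0.5) {
  protocol <- structure(
    list(
      n_clicks = as.integer(n_clicks),
      inter_click_interval = as.numeric(inter_click_interval),
      stimulus_duration = as.numeric(stimulus_duration),
      p_correct_ear = as.numeric(p_correct_ear),
      p_correct_left = as.numeric(p_correct_left)
    ),
    class = "task_protocol"
  )
  validate_protocol(protocol)
}

#' @export
print.task_protocol <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<task_protocol>\n",
      "  %d clicks every %g ms, decision at T = %g s\n",
      "  P(click on correct ear) = %g, P(correct side = left) = %g\n"
    ),
    x$n_clicks, 1000 * x$inter_click_interval, x$stimulus_duration,
    x$p_correct_ear, x$p_correct_left
  ))
  invisible(x)
}

validate_protocol <- function(protocol) {
  stopifnot(inherits(protocol, "task_protocol"))
  p <- protocol
  if (is.na(p$n_clicks) || p$n_clicks < 1L) {
    stop("invalid protocol: `n_clicks` must be >= 1", call. = FALSE)
  }
  if (!is.finite(p$inter_click_interval) || p$inter_click_interval <= 0) {
    stop("invalid protocol: `inter_click_interval` must be > 0", call. = FALSE)
  }
  span <- (p$n_clicks - 1L) * p$inter_click_interval
  if (!is.finite(p$stimulus_duration) ||
      p$stimulus_duration <= span ||
      p$stimulus_duration > p$n_clicks * p$inter_click_interval) {
    stop(
      "invalid protocol: need (n_clicks - 1) * inter_click_interval < ",
      "stimulus_duration <= n_clicks * inter_click_interval",
      call. = FALSE
    )
  }
  if (!is.finite(p$p_correct_ear) ||
      p$p_correct_ear <= 0 || p$p_correct_ear > 1) {
    stop("invalid protocol: `p_correct_ear` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(p$p_correct_left) ||
      p$p_correct_left < 0 || p$p_correct_left > 1) {
    stop("invalid protocol: `p_correct_left` must lie in [0, 1]", call. = FALSE)
  }
  protocol
}

#' Click onset times of a protocol
#'
#' @param protocol A [task_protocol()].
#' @return Numeric vector of click onsets `t_i = (i - 1) *
#'   inter_click_interval`, seconds.
#' @export
click_times <- function(protocol) {
  validate_protocol(protocol)
  (seq_len(protocol$n_clicks) - 1) * protocol$inter_click_interval
}

#' Construct a click train
#'
#' A click train is the stimulus of one trial: strictly increasing click
#' onsets with a per-click side sign (+1 = left ear, -1 = right ear) and the
#' decision time `duration`.
#'
#' @param times Strictly increasing click onsets, seconds, all in
#'   `[0, duration)`.
#' @param signs Integer vector of the same length, entries in `{+1, -1}`.
#' @param duration Decision time `T`, seconds.
#' @return An object of class `click_train`.
#' @examples
#' click_train(times = c(0, 0.05, 0.1), signs = c(1, -1, 1), duration = 0.15)
#' @export
click_train <- function(times, signs, duration) {
  times <- as.numeric(times)
  signs <- as.integer(signs)
  duration <- as.numeric(duration)
  if (length(times) != length(signs)) {
    stop("`times` and `signs` must have the same length", call. = FALSE)
  }
  if (length(times) > 0) {
    if (any(diff(times) <= 0)) {
      stop("`times` must be strictly increasing", call. = FALSE)
    }
    if (any(times < 0) || any(times >= duration)) {
      stop("click times must satisfy 0 <= t < duration", call. = FALSE)
    }
    if (!all(signs %in% c(-1L, 1L))) {
      stop("`signs` must be +1 (left) or -1 (right)", call. = FALSE)
    }
  }
  structure(
    list(times = times, signs = signs, duration = duration),
    class = "click_train"
  )
}

#' @export
print.click_train <- function(x, ...) {
  cat(sprintf(
    "<click_train> %d clicks over %g s (%d left / %d right)\n",
    length(x$times), x$duration, sum(x$signs == 1L), sum(x$signs == -1L)
  ))
  invisible(x)
}

#' Mirror a click train (swap ears)
#'
#' @param train A [click_train()].
#' @return The train with every sign negated.
#' @export
flip_train <- function(train) {
  stopifnot(inherits(train, "click_train"))
  click_train(train$times, -train$signs, train$duration)
}

# Build a click_train from one row of signs under a protocol.
train_from_signs <- function(signs, protocol) {
  click_train(click_times(protocol), signs, protocol$stimulus_duration)
}
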