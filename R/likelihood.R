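#' Bernoulli choice log-likelihood of an observer model
#'
#' `LL = sum_k [ d_k log p_k + (1 - d_k) log(1 - p_k) ]` with `d_k = 1` for a
#' left choice and `p_k` the model's probability of choosing left on trial
#' `k`. Probabilities are clipped to `[clip, 1 - clip]` before logging so the
#' likelihood stays finite for degenerate observers.
#'
#' @param trials Trial tibble with a complete `choice` column.
#' @param params Model parameters: a [divnorm_params()], [lca_params()] or
#'   [brunton_params()] object (the model is dispatched on the class), or a
#'   plain numeric vector of per-trial `p_left` values.
#' @param protocol Optional [task_protocol()]; defaults to the one attached
#'   to `trials`.
#' @param clip Probability clipping bound (default `1e-10`).
#' @param ... Passed to the model's probability routine (e.g. `n_nodes`, `dt`
#'   for the bounded accumulator).
#' @return The scalar log-likelihood (<= 0).
#' @examples
#' trials <- generate_trials(task_protocol(), 50, seed = 1)
#' trials <- simulate_choices(trials, constant_observer(0.5), seed = 2)
#' log_likelihood(trials, lca_params(0, 2, 0))
#' @export
log_likelihood <- function(trials, params, protocol = NULL, clip = 1e-10,
                           ...) {
  if (anyNA(trials$choice)) {
    stop("all trials must have choices to compute a likelihood", call. = FALSE)
  }
  if (is.numeric(params)) {
    p <- params
    if (length(p) != nrow(trials)) {
      stop("`params` as a probability vector must have one entry per trial",
           call. = FALSE)
    }
  } else {
    p <- model_p_left(params, click_matrix(trials),
                      trials_protocol(trials, protocol), ...)
  }
  d <- as.numeric(trials$choice == "L")
  p <- pmin(pmax(p, clip), 1 - clip)
  sum(d * log(p) + (1 - d) * log1p(-p))
}

model_p_left <- function(params, X, protocol, ...) {
  if (inherits(params, "divnorm_params")) {
    divnorm_p_left(params, X, protocol)
  } else if (inherits(params, "lca_params")) {
    lca_p_left(params, X, protocol)
  } else if (inherits(params, "brunton_params")) {
    brunton_p_left(params, X, protocol, ...)
  } else {
    stop("unsupported parameter object of class ",
         paste(class(params), collapse = "/"), call. = FALSE)
  }
}

#' Mirror a trial table (swap ears and sides)
#'
#' Negates every click indicator and swaps the `correct_side` and `choice`
#' labels. Mirroring is an involution and, for any observer with zero side
#' bias, leaves the likelihood unchanged.
#'
#' @param trials A trial tibble.
#' @return The mirrored trial tibble.
#' @export
mirror_trials <- function(trials) {
  out <- trials
  cols <- grep("^click_\\d+$", names(out), value = TRUE)
  for (col in cols) out[[col]] <- -out[[col]]
  swap <- function(x) ifelse(is.na(x), NA_character_, ifelse(x == "L", "R", "L"))
  out$correct_side <- swap(out$correct_side)
  out$choice <- swap(out$choice)
  attr(out, "protocol") <- attr(trials, "protocol")
  out
}
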