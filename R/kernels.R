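#' Estimate the integration kernel by logistic regression
#'
#' Fits `logit(p_left) = sum_i beta_i^click * dC_i + beta_bias` where `dC_i`
#' is the signed indicator of click `i` (+1 left, -1 right). The per-click
#' weights are the model-free integration kernel: how much each moment of
#' evidence contributed to choice. Estimation is by Newton/IRLS on the
#' (optionally ridge-penalized) log-likelihood; iterations stop when the
#' score's sup-norm falls below `1e-8` (or after 100 iterations). Standard
#' errors come from the observed information at the estimate. The ridge
#' penalty `ridge * sum(beta_click^2)` (the intercept is not penalized)
#' guards against perfect separation in small or deterministic data sets.
#'
#' @param trials Trial tibble with a complete `choice` column (>= 50 trials).
#' @param ridge Non-negative ridge penalty (default 0; try `1e-3` if the fit
#'   fails to converge through separation).
#' @return An object of class `kernel_estimate` with fields `beta_click`,
#'   `beta_bias`, `se_click`, `se_bias`, `converged`, `n_trials`, `ridge`,
#'   `participant_id`.
#' @examples
#' trials <- generate_trials(task_protocol(), 500, seed = 1)
#' trials <- simulate_choices(trials, ddm_observer(sigma_a = 2), seed = 2)
#' fit_logistic_kernel(trials)
#' @export
fit_logistic_kernel <- function(trials, ridge = 0) {
  if (anyNA(trials$choice)) {
    stop("all trials must have choices", call. = FALSE)
  }
  if (nrow(trials) < 50) {
    stop("need at least 50 trials to estimate a 21-parameter kernel",
         call. = FALSE)
  }
  if (ridge < 0) stop("`ridge` must be >= 0", call. = FALSE)
  Xc <- click_matrix(trials)
  X <- cbind(Xc, intercept = 1)
  y <- as.numeric(trials$choice == "L")
  n_clicks <- ncol(Xc)
  pen <- c(rep(ridge, n_clicks), 0)
  beta <- numeric(ncol(X))
  converged <- FALSE
  for (iter in seq_len(100)) {
    eta <- as.numeric(X %*% beta)
    p <- stats::plogis(eta)
    score <- as.numeric(crossprod(X, y - p)) - 2 * pen * beta
    if (max(abs(score)) < 1e-8) {
      converged <- TRUE
      break
    }
    w <- p * (1 - p)
    info <- crossprod(X * w, X) + diag(2 * pen, ncol(X))
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    # dampen huge Newton steps (separation drives |beta| to infinity)
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    beta <- beta + step
    if (max(abs(beta)) > 50) break
  }
  # separation drives |beta| to infinity; in floating point the score can hit
  # zero once every fitted probability saturates at its observed choice, so a
  # perfectly-fitting unpenalized model is also treated as non-convergence
  p_fit <- stats::plogis(as.numeric(X %*% beta))
  separated <- ridge == 0 &&
    (max(abs(beta)) > 30 || all(abs(y - p_fit) < 1e-6))
  if (ridge == 0 && (!converged || separated)) {
    stop(paste(
      "logistic kernel fit did not converge (likely perfect separation);",
      "refit with `ridge > 0` (e.g. 1e-3)"
    ), call. = FALSE)
  }
  eta <- as.numeric(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  info <- crossprod(X * w, X) + diag(2 * pen, ncol(X))
  se <- sqrt(diag(solve(info)))
  pid <- unique(trials$participant_id)
  structure(
    list(
      beta_click = unname(beta[seq_len(n_clicks)]),
      beta_bias = unname(beta[n_clicks + 1]),
      se_click = unname(se[seq_len(n_clicks)]),
      se_bias = unname(se[n_clicks + 1]),
      converged = converged,
      n_trials = nrow(trials),
      ridge = ridge,
      participant_id = if (length(pid) == 1) pid else NA_character_
    ),
    class = "kernel_estimate"
  )
}

#' @export
print.kernel_estimate <- function(x, ...) {
  cat(sprintf(
    "<kernel_estimate> %d clicks, n = %d trials, bias = %.3f%s\n",
    length(x$beta_click), x$n_trials, x$beta_bias,
    if (x$converged) "" else " (NOT converged)"
  ))
  cat("  beta:", paste(sprintf("%.3f", x$beta_click), collapse = " "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a kernel estimate into one row per click
#'
#' @param x A `kernel_estimate`.
#' @param ... Unused.
#' @return A tibble with columns `participant_id`, `term`, `click`,
#'   `estimate`, `std.error` (the intercept row has `click = NA`).
#' @export
tidy.kernel_estimate <- function(x, ...) {
  n <- length(x$beta_click)
  tibble::tibble(
    participant_id = x$participant_id,
    term = c(click_col_names(n), "bias"),
    click = c(seq_len(n), NA_integer_),
    estimate = c(x$beta_click, x$beta_bias),
    std.error = c(x$se_click, x$se_bias)
  )
}

#' @export
glance.kernel_estimate <- function(x, ...) {
  tibble::tibble(
    participant_id = x$participant_id,
    n_trials = x$n_trials,
    beta_bias = x$beta_bias,
    converged = x$converged,
    ridge = x$ridge
  )
}

#' Classify an integration kernel's shape
#'
#' A deterministic descriptive rule over three segment means of the per-click
#' weights -- early `e` (clicks 1-5), middle `m` (8-13), late `l` (16-20) --
#' against a flatness threshold `theta = flatness_fraction * |mean(beta)|`:
#' flat if all pairwise segment contrasts are within `theta`; else bump if
#' `m` exceeds both `e` and `l` by more than `theta`; else primacy if
#' `e > l + theta`; else recency if `l > e + theta`; else flat. The windows
#' and fraction are package conventions, exposed for sensitivity analyses.
#'
#' @param x A `kernel_estimate` (must have converged) or a bare numeric
#'   vector of per-click weights.
#' @param flatness_fraction Fraction of `|mean|` used as the contrast
#'   threshold (default 0.15).
#' @param segments List with integer index vectors `early`, `middle`, `late`.
#' @return An object of class `kernel_shape`: `label` (one of `"primacy"`,
#'   `"bump"`, `"flat"`, `"recency"`) and `evidence` (segment means and the
#'   threshold used).
#' @examples
#' classify_kernel_shape(rep(1, 20))
#' classify_kernel_shape(seq(1, 0.2, length.out = 20))
#' @export
classify_kernel_shape <- function(x, flatness_fraction = 0.15,
                                  segments = list(early = 1:5, middle = 8:13,
                                                  late = 16:20)) {
  if (inherits(x, "kernel_estimate")) {
    if (!x$converged) {
      stop("cannot classify a non-converged kernel estimate", call. = FALSE)
    }
    beta <- x$beta_click
  } else {
    beta <- as.numeric(x)
  }
  if (max(unlist(segments)) > length(beta)) {
    stop("segment indices exceed kernel length", call. = FALSE)
  }
  e <- mean(beta[segments$early])
  m <- mean(beta[segments$middle])
  l <- mean(beta[segments$late])
  g <- mean(beta)
  theta <- flatness_fraction * abs(g)
  label <- if (max(abs(e - m), abs(m - l), abs(e - l)) <= theta) {
    "flat"
  } else if (m > e + theta && m > l + theta) {
    "bump"
  } else if (e > l + theta) {
    "primacy"
  } else if (l > e + theta) {
    "recency"
  } else {
    "flat"
  }
  structure(
    list(
      label = label,
      evidence = tibble::tibble(
        segment = c("early", "middle", "late", "overall"),
        mean = c(e, m, l, g)
      ),
      threshold = theta,
      flatness_fraction = flatness_fraction
    ),
    class = "kernel_shape"
  )
}

#' @export
print.kernel_shape <- function(x, ...) {
  ev <- x$evidence
  cat(sprintf(
    "<kernel_shape> %s (early %.3f / middle %.3f / late %.3f; theta = %.3f)\n",
    x$label, ev$mean[1], ev$mean[2], ev$mean[3], x$threshold
  ))
  invisible(x)
}

#' Psychometric curve over the net click difference
#'
#' Groups trials by `dC = (#left clicks - #right clicks)` and reports the
#' observed probability of choosing left per level, optionally with a
#' two-parameter logistic fit `p = plogis(slope * (dC - midpoint))`. Passing
#' model probabilities via `p_left` produces the model-predicted curve by the
#' identical procedure.
#'
#' @param trials Trial tibble with choices (unless `p_left` is given).
#' @param p_left Optional vector of per-trial model probabilities used in
#'   place of the observed choices.
#' @param fit_sigmoid Fit the 2-parameter logistic by maximum likelihood?
#' @return A tibble of class `psychometric_curve` with columns
#'   `delta_clicks`, `n`, `p_left`; the fit (slope, midpoint) is stored in the
#'   `"sigmoid_fit"` attribute when requested.
#' @export
psychometric_curve <- function(trials, p_left = NULL, fit_sigmoid = TRUE) {
  dc <- rowSums(click_matrix(trials))
  if (is.null(p_left)) {
    if (anyNA(trials$choice)) stop("all trials must have choices", call. = FALSE)
    y <- as.numeric(trials$choice == "L")
  } else {
    if (length(p_left) != nrow(trials)) {
      stop("`p_left` must have one entry per trial", call. = FALSE)
    }
    y <- p_left
  }
  curve <- tibble::tibble(delta_clicks = dc, y = y) |>
    dplyr::group_by(.data$delta_clicks) |>
    dplyr::summarise(n = dplyr::n(), p_left = mean(.data$y), .groups = "drop") |>
    dplyr::arrange(.data$delta_clicks)
  fit <- NULL
  if (fit_sigmoid) {
    g <- suppressWarnings(
      stats::glm(y ~ dc, family = stats::binomial())
    )
    slope <- unname(stats::coef(g)[2])
    fit <- list(slope = slope, midpoint = -unname(stats::coef(g)[1]) / slope)
  }
  class(curve) <- c("psychometric_curve", class(curve))
  attr(curve, "sigmoid_fit") <- fit
  curve
}

#' Cohort-average integration kernel
#'
#' Unweighted across-participant mean and standard error of the per-click
#' weights.
#'
#' @param estimates A list of `kernel_estimate` objects (>= 2, equal lengths).
#' @return A tibble with columns `click`, `mean_beta`, `sem`.
#' @export
cohort_mean_kernel <- function(estimates) {
  if (length(estimates) < 2) {
    stop("need at least 2 kernel estimates", call. = FALSE)
  }
  lens <- vapply(estimates, function(e) length(e$beta_click), integer(1))
  if (length(unique(lens)) != 1) {
    stop("kernel estimates have different click counts", call. = FALSE)
  }
  B <- do.call(rbind, lapply(estimates, function(e) e$beta_click))
  tibble::tibble(
    click = seq_len(ncol(B)),
    mean_beta = colMeans(B),
    sem = apply(B, 2, stats::sd) / sqrt(nrow(B))
  )
}
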