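#' Model catalogue for fitting
#'
#' Free parameters, default box bounds and optimization scale for every model
#' tag. Positive-only parameters are optimized on the log scale. The basic
#' DDM is the LCA with `lam` fixed at 0; the bounded LCA is the adaptive
#' accumulator with `phi` fixed at 1.
#'
#' @param model One of `"divnorm"`, `"lca"`, `"ddm"`, `"lca_bounded"`,
#'   `"brunton"`.
#' @return A list with `par_names`, `k`, `lower`, `upper`, `log_scale`, and a
#'   `make_params(theta)` constructor.
#' @export
model_spec <- function(model = c("divnorm", "lca", "ddm", "lca_bounded",
                                 "brunton")) {
  model <- match.arg(model)
  switch(model,
    divnorm = list(
      model = model,
      par_names = c("tau_R", "tau_G", "omega_I", "sigma", "mu", "bias"),
      k = 6L,
      lower = c(0.01, 0.01, 1e-4, 1e-3, -5, -10),
      upper = c(100, 100, 1e3, 1e3, 5, 10),
      log_scale = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
      make_params = function(th) {
        divnorm_params(th[["tau_R"]], th[["tau_G"]], th[["omega_I"]],
                       th[["sigma"]], th[["mu"]], th[["bias"]])
      }
    ),
    lca = list(
      model = model,
      par_names = c("lam", "sigma_a", "bias"),
      k = 3L,
      lower = c(-20, 0.01, -10),
      upper = c(20, 100, 10),
      log_scale = c(FALSE, TRUE, FALSE),
      make_params = function(th) {
        lca_params(th[["lam"]], th[["sigma_a"]], th[["bias"]])
      }
    ),
    ddm = list(
      model = model,
      par_names = c("sigma_a", "bias"),
      k = 2L,
      lower = c(0.01, -10),
      upper = c(100, 10),
      log_scale = c(TRUE, FALSE),
      make_params = function(th) {
        lca_params(0, th[["sigma_a"]], th[["bias"]])
      }
    ),
    lca_bounded = list(
      model = model,
      par_names = c("lam", "sigma_a", "B", "bias"),
      k = 4L,
      lower = c(-20, 0.01, 0.1, -10),
      upper = c(20, 100, 100, 10),
      log_scale = c(FALSE, TRUE, TRUE, FALSE),
      make_params = function(th) {
        brunton_params(sigma_a = th[["sigma_a"]], lam = th[["lam"]],
                       B = th[["B"]], phi = 1, tau_phi = 0.1,
                       bias = sign(th[["bias"]]) *
                         min(abs(th[["bias"]]), 0.999 * th[["B"]]))
      }
    ),
    brunton = list(
      model = model,
      par_names = c("sigma_a", "lam", "B", "phi", "tau_phi", "bias"),
      k = 6L,
      lower = c(0.01, -20, 0.1, 0.01, 1e-3, -10),
      upper = c(100, 20, 100, 10, 100, 10),
      log_scale = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
      make_params = function(th) {
        brunton_params(sigma_a = th[["sigma_a"]], lam = th[["lam"]],
                       B = th[["B"]], phi = th[["phi"]],
                       tau_phi = th[["tau_phi"]],
                       bias = sign(th[["bias"]]) *
                         min(abs(th[["bias"]]), 0.999 * th[["B"]]))
      }
    )
  )
}

to_transformed <- function(theta, ms) {
  out <- theta
  out[ms$log_scale] <- log(theta[ms$log_scale])
  out
}

from_transformed <- function(z, ms) {
  th <- z
  th[ms$log_scale] <- exp(z[ms$log_scale])
  names(th) <- ms$par_names
  th
}

#' Fit a model to one participant's choices by multi-start ML
#'
#' Maximizes the Bernoulli choice log-likelihood with `n_starts` bounded
#' local optimizations (`nlminb`) from random interior starting points
#' (uniform on the optimization scale; positive parameters are searched in
#' log space). The best endpoint wins. Fully deterministic given `seed`, and
#' the start sequence is nested: increasing `n_starts` can only improve the
#' best log-likelihood.
#'
#' @param trials Trial tibble of a single participant, with choices.
#' @param model Model tag (see [model_spec()]).
#' @param n_starts Number of random restarts (default 50).
#' @param bounds Optional list with `lower`/`upper` numeric vectors (natural
#'   scale) overriding the defaults.
#' @param seed Integer seed for the restart draw.
#' @param protocol Optional [task_protocol()].
#' @param ... Passed to the model's probability routine (e.g. `n_nodes`, `dt`
#'   for the density-propagation models).
#' @return An object of class `accum_fit`: `model`, `theta_hat`,
#'   `log_likelihood`, `k`, `n`, `aic`, `bic`, `n_starts`, `all_optima`.
#' @export
fit_model <- function(trials, model = "divnorm", n_starts = 50L,
                      bounds = NULL, seed = 1L, protocol = NULL, ...) {
  if (anyNA(trials$choice)) {
    stop("all trials must have choices", call. = FALSE)
  }
  ms <- model_spec(model)
  if (!is.null(bounds)) {
    stopifnot(length(bounds$lower) == ms$k, length(bounds$upper) == ms$k)
    ms$lower <- bounds$lower
    ms$upper <- bounds$upper
  }
  proto <- trials_protocol(trials, protocol)
  X <- click_matrix(trials)
  storage.mode(X) <- "double"
  y <- as.numeric(trials$choice == "L")
  i_left <- which(y == 1)
  i_right <- which(y == 0)
  times <- click_times(proto)
  t_end <- proto$stimulus_duration
  lo <- to_transformed(ms$lower, ms)
  hi <- to_transformed(ms$upper, ms)
  bernoulli_nll <- function(p) {
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -(sum(log(p[i_left])) + sum(log1p(-p[i_right])))
  }
  # closed-form models get a compiled likelihood; density-propagation models
  # go through the generic probability routine
  negll <- if (model == "divnorm") {
    function(z) {
      th <- from_transformed(z, ms)
      .dn_negll(X, y, times, t_end, th[[1]], th[[2]], th[[3]], th[[4]],
                th[[5]], th[[6]], 1e-10)
    }
  } else if (model %in% c("lca", "ddm")) {
    function(z) {
      th <- from_transformed(z, ms)
      lam <- if (model == "ddm") 0 else th[["lam"]]
      .lca_negll(X, y, times, t_end, lam, th[["sigma_a"]], th[["bias"]],
                 1e-10)
    }
  } else {
    function(z) {
      th <- from_transformed(z, ms)
      bernoulli_nll(model_p_left(ms$make_params(th), X, proto, ...))
    }
  }
  # one start drawn per row so the sequence is nested in n_starts
  starts <- with_local_seed(seed, t(vapply(
    seq_len(n_starts),
    function(i) stats::runif(ms$k, lo, hi),
    numeric(ms$k)
  )))
  run_one <- function(i) {
    z0 <- starts[i, ]
    f0 <- negll(z0)
    opt <- tryCatch(
      stats::nlminb(z0, negll, lower = lo, upper = hi,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$objective) || opt$objective > f0) {
      list(z = z0, negll = f0, converged = FALSE)
    } else {
      list(z = opt$par, negll = opt$objective, converged = opt$convergence == 0)
    }
  }
  runs <- lapply(seq_len(n_starts), run_one)
  nlls <- vapply(runs, function(r) r$negll, numeric(1))
  if (all(!is.finite(nlls))) {
    stop("all optimization starts failed", call. = FALSE)
  }
  best <- which.min(nlls)
  theta_hat <- from_transformed(runs[[best]]$z, ms)
  ll <- -nlls[best]
  n <- nrow(trials)
  ic <- information_criteria(ll, ms$k, n)
  all_optima <- tibble::tibble(
    start = seq_len(n_starts),
    log_likelihood = -nlls,
    converged = vapply(runs, function(r) r$converged, logical(1))
  )
  pid <- unique(trials$participant_id)
  structure(
    list(
      model = ms$model,
      participant_id = if (length(pid) == 1) pid else NA_character_,
      theta_hat = theta_hat,
      log_likelihood = ll,
      k = ms$k,
      n = n,
      aic = ic[["aic"]],
      bic = ic[["bic"]],
      n_starts = n_starts,
      seed = seed,
      all_optima = all_optima
    ),
    class = "accum_fit"
  )
}

#' @export
print.accum_fit <- function(x, ...) {
  cat(sprintf(
    "<accum_fit> %s: LL = %.2f, AIC = %.2f, BIC = %.2f (k = %d, n = %d, %d starts)\n",
    x$model, x$log_likelihood, x$aic, x$bic, x$k, x$n, x$n_starts
  ))
  cat(" ", paste(sprintf("%s = %.4g", names(x$theta_hat), x$theta_hat),
                 collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.accum_fit <- function(x, ...) {
  tibble::tibble(
    participant_id = x$participant_id,
    model = x$model,
    term = names(x$theta_hat),
    estimate = unname(x$theta_hat)
  )
}

#' @export
glance.accum_fit <- function(x, ...) {
  tibble::tibble(
    participant_id = x$participant_id,
    model = x$model,
    log_likelihood = x$log_likelihood,
    k = x$k,
    n = x$n,
    aic = x$aic,
    bic = x$bic,
    n_starts = x$n_starts
  )
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = 2k - 2 LL`; `BIC = k log(n) - 2 LL`.
#'
#' @param log_likelihood Maximized log-likelihood.
#' @param k Number of free parameters (>= 0).
#' @param n Number of observations (>= 1; a non-integer cohort-mean trial
#'   count is accepted).
#' @return Named numeric vector `c(aic, bic)`.
#' @examples
#' information_criteria(-357.7, 6, 750.8)
#' @export
information_criteria <- function(log_likelihood, k, n) {
  if (n < 1 || k < 0) stop("need n >= 1 and k >= 0", call. = FALSE)
  c(aic = 2 * k - 2 * log_likelihood,
    bic = k * log(n) - 2 * log_likelihood)
}

#' Fit a model to every participant of a cohort
#'
#' @param trials Multi-participant trial tibble with choices.
#' @param model Model tag.
#' @param n_starts,bounds,seed,protocol,... As in [fit_model()]; participants
#'   receive child seeds derived from `seed`.
#' @return A tibble with one row per participant: `participant_id`, `model`,
#'   `log_likelihood`, `k`, `n`, `aic`, `bic`, and the fit object in the
#'   list-column `fit`.
#' @export
fit_cohort <- function(trials, model = "divnorm", n_starts = 50L,
                       bounds = NULL, seed = 1L, protocol = NULL, ...) {
  proto <- trials_protocol(trials, protocol)
  ids <- unique(trials$participant_id)
  child_seeds <- with_local_seed(seed,
                                 sample.int(.Machine$integer.max - 1L,
                                            length(ids)))
  fits <- purrr::map2(ids, child_seeds, function(id, s) {
    tr <- dplyr::filter(trials, .data$participant_id == id)
    attr(tr, "protocol") <- proto
    fit_model(tr, model = model, n_starts = n_starts, bounds = bounds,
              seed = s, protocol = proto, ...)
  })
  out <- dplyr::bind_rows(lapply(fits, glance))
  out$fit <- fits
  out
}

#' Cohort-level model comparison
#'
#' Averages per-participant log-likelihood, AIC and BIC per model (over the
#' identical participant set) and tallies per-participant AIC winners.
#'
#' @param fits A tibble of per-participant fits for two or more models, as
#'   returned by [fit_cohort()] (rows of several calls bound together), or a
#'   list of such tibbles.
#' @return A tibble of class `model_comparison`: one row per model with
#'   `n_participants`, `mean_log_likelihood`, `mean_aic`, `mean_bic`,
#'   `n_best_aic`.
#' @export
compare_models <- function(fits) {
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- dplyr::bind_rows(fits)
  }
  needed <- c("participant_id", "model", "log_likelihood", "aic", "bic")
  if (!all(needed %in% names(fits))) {
    stop("`fits` must carry columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  sets <- split(fits$participant_id, fits$model)
  ref <- sort(sets[[1]])
  same <- all(vapply(sets, function(s) identical(sort(s), ref), logical(1)))
  if (!same) {
    stop("every model must be fitted to the identical participant set",
         call. = FALSE)
  }
  winners <- fits |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::slice_min(.data$aic, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::count(.data$model, name = "n_best_aic")
  out <- fits |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      n_participants = dplyr::n(),
      mean_log_likelihood = mean(.data$log_likelihood),
      mean_aic = mean(.data$aic),
      mean_bic = mean(.data$bic),
      .groups = "drop"
    ) |>
    dplyr::left_join(winners, by = "model") |>
    dplyr::mutate(n_best_aic = dplyr::coalesce(.data$n_best_aic, 0L)) |>
    dplyr::arrange(.data$mean_aic)
  class(out) <- c("model_comparison", class(out))
  out
}

#' Parameter- and shape-recovery experiment
#'
#' Generates a synthetic cohort, refits the requested model to every
#' participant, reconstructs each participant's regression-scale kernel from
#' the fitted parameters and classifies its shape, and reports truth against
#' estimate. Degenerate participants (e.g. near-deterministic observers whose
#' kernel regression separates) are flagged rather than fatal.
#'
#' @param spec A [cohort_spec()].
#' @param model Model tag to refit (default `"divnorm"`).
#' @param n_starts,seed As in [fit_model()].
#' @param flatness_fraction Classifier setting for both true and recovered
#'   kernels.
#' @return An object of class `recovery_report`: `results` (one row per
#'   participant with true/recovered parameters, shapes and a `flag` column),
#'   `shape_agreement`, `ratio_rank_correlation`, and `cohort` (the generated
#'   data and truth).
#' @export
recovery_experiment <- function(spec, model = "divnorm", n_starts = 50L,
                                seed = 1L, flatness_fraction = 0.15) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  cohort <- make_synthetic_cohort(spec)
  proto <- spec$protocol
  fits <- fit_cohort(cohort$trials, model = model, n_starts = n_starts,
                     seed = seed, protocol = proto)
  truth <- cohort$truth
  rows <- purrr::map(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    fit <- fits$fit[[which(fits$participant_id == tr$participant_id)]]
    th <- fit$theta_hat
    flag <- ""
    recovered_shape <- NA_character_
    rec_ratio <- NA_real_
    if (model == "divnorm") {
      rp <- divnorm_params(th[["tau_R"]], th[["tau_G"]], th[["omega_I"]],
                           th[["sigma"]], th[["mu"]], th[["bias"]])
      beta_hat <- regression_kernel(rp, proto)$beta
      recovered_shape <- classify_kernel_shape(
        beta_hat, flatness_fraction = flatness_fraction
      )$label
      rec_ratio <- log(th[["tau_R"]] / th[["tau_G"]])
      at_bound <- any(
        abs(log(th[c("tau_R", "tau_G", "omega_I", "sigma")])) > log(100) - 1e-3
      )
      if (at_bound) flag <- "boundary"
    }
    gen_params <- divnorm_params(tr$tau_R, tr$tau_G, tr$omega_I, tr$sigma,
                                 tr$mu, tr$bias)
    true_shape <- classify_kernel_shape(
      regression_kernel(gen_params, proto)$beta,
      flatness_fraction = flatness_fraction
    )$label
    tibble::tibble(
      participant_id = tr$participant_id,
      group = tr$shape,
      true_shape = true_shape,
      recovered_shape = recovered_shape,
      shape_match = identical(true_shape, recovered_shape),
      true_log_ratio = log(tr$tau_R / tr$tau_G),
      recovered_log_ratio = rec_ratio,
      log_likelihood = fit$log_likelihood,
      aic = fit$aic,
      flag = flag
    )
  })
  results <- dplyr::bind_rows(rows)
  ok <- !is.na(results$recovered_log_ratio)
  structure(
    list(
      results = results,
      shape_agreement = mean(results$shape_match, na.rm = TRUE),
      ratio_rank_correlation = if (sum(ok) >= 3) {
        stats::cor(results$true_log_ratio[ok], results$recovered_log_ratio[ok],
                   method = "spearman")
      } else {
        NA_real_
      },
      cohort = cohort,
      fits = fits
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> %d participants: shape agreement %.0f%%, log-ratio rank corr %.2f\n",
    nrow(x$results), 100 * x$shape_agreement, x$ratio_rank_correlation
  ))
  print(x$results)
  invisible(x)
}
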