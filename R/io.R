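#' Write a trial table to the canonical CSV
#'
#' Header `participant_id,trial_index,correct_side,choice,click_01,...`;
#' click columns hold `+1`/`-1`, side columns `L`/`R` (`choice` may be
#' empty), UTF-8, comma separator, one row per trial. Deterministic: column
#' order is fixed and rows are written as given.
#'
#' @param trials Trial tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- c("participant_id", "trial_index", "correct_side", "choice",
            grep("^click_\\d+$", names(trials), value = TRUE))
  missing <- setdiff(cols, names(trials))
  if (length(missing) > 0) {
    stop("trial table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(trials[cols], path, na = "")
  invisible(path)
}

#' Read a trial table from the canonical CSV
#'
#' Validates the header, the click values (must be +1/-1) and the side codes
#' (`L`/`R`, `choice` may be empty) and attaches the protocol. Errors name
#' the offending column and data row.
#'
#' @param path CSV file path.
#' @param protocol A [task_protocol()] describing the click grid; its
#'   `n_clicks` must match the number of click columns.
#' @return A trial tibble with the protocol attached.
#' @export
read_trials <- function(path, protocol = task_protocol()) {
  validate_protocol(protocol)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  click_cols <- grep("^click_\\d+$", names(raw), value = TRUE)
  needed <- c("participant_id", "trial_index", "correct_side", "choice")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(raw), c(needed, click_cols))
  if (length(unknown) > 0) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!identical(click_cols, click_col_names(protocol$n_clicks))) {
    stop(sprintf("expected click columns click_01..click_%02d in order",
                 protocol$n_clicks), call. = FALSE)
  }
  out <- tibble::tibble(
    participant_id = raw$participant_id,
    trial_index = as.integer(raw$trial_index),
    correct_side = raw$correct_side,
    choice = ifelse(raw$choice == "", NA_character_, raw$choice)
  )
  check_side <- function(x, col, allow_na = FALSE) {
    bad <- !(x %in% c("L", "R")) & !(allow_na & is.na(x))
    if (any(bad)) {
      stop(sprintf("invalid `%s` value in row %d", col, which(bad)[1]),
           call. = FALSE)
    }
  }
  check_side(out$correct_side, "correct_side")
  check_side(out$choice, "choice", allow_na = TRUE)
  for (col in click_cols) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- is.na(v) | !(v %in% c(-1L, 1L))
    if (any(bad)) {
      stop(sprintf("invalid click value in column `%s`, row %d",
                   col, which(bad)[1]), call. = FALSE)
    }
    out[[col]] <- v
  }
  attr(out, "protocol") <- protocol
  out
}

#' Read a run configuration (JSON or YAML)
#'
#' A run configuration bundles the protocol block with optional model,
#' fitting, solver and classifier blocks:
#' `protocol: {n_clicks, inter_click_interval_s, stimulus_duration_s,
#' p_correct_ear, p_correct_left}`, `divnorm: {tau_R, tau_G, omega_I, sigma,
#' mu, bias}`, `lca: {lam, sigma_a, bias}`, `brunton: {sigma_a, lam, B, phi,
#' tau_phi, bias}`, `fp: {n_nodes, dt}`, `fit: {n_starts, seed}`,
#' `classifier: {flatness_fraction}`.
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @return A list of class `run_config` with parsed blocks; the `protocol`
#'   block is converted to a [task_protocol()] and model blocks to their
#'   parameter objects.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be .json or .yaml/.yml", call. = FALSE)
  )
  as_run_config(cfg)
}

#' Validate and normalize a configuration list
#'
#' @param cfg A named list (see [read_run_config()] for the block layout).
#' @return A `run_config` list with typed blocks.
#' @export
as_run_config <- function(cfg) {
  out <- list()
  if (!is.null(cfg$protocol)) {
    p <- cfg$protocol
    out$protocol <- task_protocol(
      n_clicks = p$n_clicks %||% 20L,
      inter_click_interval = p$inter_click_interval_s %||% 0.05,
      stimulus_duration = p$stimulus_duration_s %||% 1.0,
      p_correct_ear = p$p_correct_ear %||% 0.55,
      p_correct_left = p$p_correct_left %||% 0.5
    )
  } else {
    out$protocol <- task_protocol()
  }
  if (!is.null(cfg$divnorm)) {
    out$divnorm <- do.call(divnorm_params, cfg$divnorm)
  }
  if (!is.null(cfg$lca)) {
    out$lca <- do.call(lca_params, cfg$lca)
  }
  if (!is.null(cfg$brunton)) {
    out$brunton <- do.call(brunton_params, cfg$brunton)
  }
  out$fp <- list(
    n_nodes = as.integer(cfg$fp$n_nodes %||% 501L),
    dt = as.numeric(cfg$fp$dt %||% 2.5e-4)
  )
  out$fit <- list(
    n_starts = as.integer(cfg$fit$n_starts %||% 50L),
    seed = as.integer(cfg$fit$seed %||% 1L)
  )
  out$classifier <- list(
    flatness_fraction = as.numeric(cfg$classifier$flatness_fraction %||% 0.15)
  )
  if (!is.null(cfg$cohort)) {
    out$cohort <- list(
      n_participants = as.integer(cfg$cohort$n_participants %||% 12L),
      trials_per_participant =
        as.integer(cfg$cohort$trials_per_participant %||% 750L)
    )
  }
  structure(out, class = "run_config")
}

#' Write per-participant kernel estimates to CSV
#'
#' Two files: `<stem>_kernels.csv` with one row per participant and click
#' (`participant_id,click_index,beta,se`) and `<stem>_shapes.csv` with one
#' row per participant (`participant_id,bias,shape_label`).
#'
#' @param estimates List of `kernel_estimate` objects.
#' @param stem Output path stem.
#' @param flatness_fraction Classifier setting for the shape labels.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_kernel_estimates <- function(estimates, stem,
                                   flatness_fraction = 0.15) {
  kern <- dplyr::bind_rows(lapply(estimates, function(e) {
    tibble::tibble(
      participant_id = e$participant_id,
      click_index = seq_along(e$beta_click),
      beta = e$beta_click,
      se = e$se_click
    )
  }))
  shapes <- dplyr::bind_rows(lapply(estimates, function(e) {
    tibble::tibble(
      participant_id = e$participant_id,
      bias = e$beta_bias,
      shape_label = classify_kernel_shape(
        e, flatness_fraction = flatness_fraction
      )$label
    )
  }))
  paths <- c(
    kernels = paste0(stem, "_kernels.csv"),
    shapes = paste0(stem, "_shapes.csv")
  )
  readr::write_csv(kern, paths[["kernels"]])
  readr::write_csv(shapes, paths[["shapes"]])
  invisible(paths)
}

#' Export a simulated trajectory as tidy CSV
#'
#' Columns `t,R_left,R_right,G,delta`, ready for plotting outside R.
#'
#' @param trajectory A tibble from [simulate_dynamics()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  out <- tibble::tibble(
    t = trajectory$time,
    R_left = trajectory$R_left,
    R_right = trajectory$R_right,
    G = trajectory$G,
    delta = trajectory$delta
  )
  readr::write_csv(out, path)
  invisible(path)
}
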