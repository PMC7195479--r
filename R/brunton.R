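#' Parameters of the bounded adaptive accumulator observer
#'
#' The six-parameter accumulator: diffusion noise `sigma_a`, memory drift
#' `lam`, an absorbing (sticky) bound at `+/- B` -- evidence arriving after
#' the bound has been crossed is ignored -- per-side sensory adaptation
#' (`phi`, `tau_phi`) scaling the impact of successive same-side clicks, and a
#' comparison threshold `bias` applied at stimulus end.
#'
#' @param sigma_a Diffusion scale per square-root second (> 0).
#' @param lam Memory drift rate, 1/seconds.
#' @param B Absorbing bound magnitude (> 0).
#' @param phi Adaptation direction: successive same-side clicks are scaled
#'   towards `phi` (facilitation if `phi > 1`, depression if `phi < 1`;
#'   `phi = 1` disables adaptation). Must be > 0.
#' @param tau_phi Adaptation recovery time constant, seconds (> 0).
#' @param bias Comparison threshold at stimulus end, `|bias| < B`.
#' @return An object of class `brunton_params`.
#' @export
brunton_params <- function(sigma_a = 1, lam = 0, B = 10, phi = 1,
                           tau_phi = 0.1, bias = 0) {
  p <- list(sigma_a = as.numeric(sigma_a), lam = as.numeric(lam),
            B = as.numeric(B), phi = as.numeric(phi),
            tau_phi = as.numeric(tau_phi), bias = as.numeric(bias))
  if (!is.finite(p$sigma_a) || p$sigma_a <= 0) stop("`sigma_a` must be > 0", call. = FALSE)
  if (!is.finite(p$B) || p$B <= 0) stop("`B` must be > 0", call. = FALSE)
  if (!is.finite(p$phi) || p$phi <= 0) stop("`phi` must be > 0", call. = FALSE)
  if (!is.finite(p$tau_phi) || p$tau_phi <= 0) stop("`tau_phi` must be > 0", call. = FALSE)
  if (abs(p$bias) >= p$B) stop("`bias` must satisfy |bias| < B", call. = FALSE)
  structure(p, class = "brunton_params")
}

#' @export
print.brunton_params <- function(x, ...) {
  cat(sprintf(
    "<brunton_params> sigma_a=%g lam=%g B=%g phi=%g tau_phi=%g bias=%g\n",
    x$sigma_a, x$lam, x$B, x$phi, x$tau_phi, x$bias
  ))
  invisible(x)
}

#' Per-click adapted click magnitudes
#'
#' Sensory adaptation acts independently per side: each side carries a state
#' starting at 1; a click's effective magnitude is the state at its onset,
#' after which the state is multiplied by `phi` and relaxes back towards 1
#' with time constant `tau_phi` (`d state/dt = (1 - state)/tau_phi`). Clicks
#' on the other side are unaffected.
#'
#' @param train A [click_train()].
#' @param phi Adaptation direction (> 0); `phi = 1` leaves all magnitudes 1.
#' @param tau_phi Recovery time constant, seconds (> 0).
#' @return Numeric vector of effective magnitudes, one per click.
#' @examples
#' tr <- click_train(c(0, 0.05), c(1, 1), 1)
#' adaptation_magnitudes(tr, phi = 0.5, tau_phi = 0.05)
#' @export
adaptation_magnitudes <- function(train, phi, tau_phi) {
  stopifnot(inherits(train, "click_train"))
  if (phi <= 0 || tau_phi <= 0) {
    stop("`phi` and `tau_phi` must be > 0", call. = FALSE)
  }
  mags <- numeric(length(train$times))
  state <- c(`1` = 1, `-1` = 1)
  last_time <- c(`1` = -Inf, `-1` = -Inf)
  for (i in seq_along(train$times)) {
    side <- as.character(train$signs[i])
    gap <- train$times[i] - last_time[side]
    if (is.finite(gap)) {
      state[side] <- 1 + (state[side] - 1) * exp(-gap / tau_phi)
    }
    mags[i] <- state[side]
    state[side] <- phi * state[side]
    last_time[side] <- train$times[i]
  }
  mags
}

#' Create a probability-density grid for the bounded accumulator
#'
#' @param B Bound magnitude (> 0).
#' @param n_nodes Number of grid nodes spanning `[-B, B]` (odd, >= 201, so
#'   the origin is a node).
#' @return An object of class `density_grid`: node positions `a`, interior
#'   point masses `mass` (initially a unit mass at 0), and accumulated
#'   boundary masses `absorbed_left` (+B side) and `absorbed_right` (-B side).
#' @export
fp_grid <- function(B, n_nodes = 501L) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 201L) stop("`n_nodes` must be >= 201", call. = FALSE)
  if (n_nodes %% 2L == 0L) n_nodes <- n_nodes + 1L
  a <- seq(-B, B, length.out = n_nodes)
  mass <- numeric(n_nodes)
  mass[(n_nodes + 1L) %/% 2L] <- 1
  structure(
    list(a = a, mass = mass, absorbed_left = 0, absorbed_right = 0, B = B),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "<density_grid> %d nodes on [-%g, %g]; interior %.6f, absorbed L %.6f / R %.6f\n",
    length(x$a), x$B, x$B, sum(x$mass), x$absorbed_left, x$absorbed_right
  ))
  invisible(x)
}

# Linear re-binning of point masses moved to arbitrary positions. Mass pushed
# beyond +B is absorbed left, beyond -B absorbed right; the boundary nodes
# themselves are absorbing. Conserves total mass exactly.
rebin_mass <- function(pos, m, a, absorbed_left, absorbed_right) {
  n <- length(a)
  dx <- a[2] - a[1]
  new <- numeric(n)
  hi <- pos >= a[n]
  lo <- pos <= a[1]
  absorbed_left <- absorbed_left + sum(m[hi])
  absorbed_right <- absorbed_right + sum(m[lo])
  keep <- !(hi | lo) & m > 0
  if (any(keep)) {
    p <- pos[keep]; mk <- m[keep]
    j <- pmin(pmax(floor((p - a[1]) / dx) + 1, 1), n - 1)
    w <- (p - a[j]) / dx
    add_l <- mk * (1 - w)
    add_r <- mk * w
    new <- new +
      as.numeric(tapply_sum(j, add_l, n)) +
      as.numeric(tapply_sum(j + 1L, add_r, n))
  }
  # boundary nodes absorb
  absorbed_left <- absorbed_left + new[n]
  absorbed_right <- absorbed_right + new[1]
  new[c(1, n)] <- 0
  list(mass = new, absorbed_left = absorbed_left,
       absorbed_right = absorbed_right)
}

tapply_sum <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, group = idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Band representation of the exact one-step Ornstein-Uhlenbeck transition on
# the grid: mass at node j moves to mean a_j * exp(lam dt) with standard
# deviation sqrt(sigma_a^2 (e^{2 lam dt} - 1) / (2 lam)), integrated over the
# destination cells. `offsets` are destination-node offsets relative to the
# nearest node to each row's mean; weights beyond the band (< 1e-12 in total)
# are folded into the outermost band cells so each row sums to 1 exactly.
ou_transition_band <- function(a, lam, sigma_a, dt) {
  n <- length(a)
  dx <- a[2] - a[1]
  f <- exp(lam * dt)
  sd <- sigma_a * sqrt(if (abs(lam) < 1e-12) dt else expm1(2 * lam * dt) /
                         (2 * lam))
  # Sheppard correction: placing cell mass at centres inflates the chain's
  # variance by dx^2/12 per step; narrow the kernel to compensate
  sd <- sqrt(max(sd^2 - dx^2 / 12, (0.2 * dx)^2))
  centre <- a * f
  j_near <- round((centre - a[1]) / dx)  # 0-based nearest node to the mean
  h <- max(2L, ceiling(7 * sd / dx))
  offsets <- -h:h
  W <- matrix(0, nrow = n, ncol = length(offsets))
  for (o in seq_along(offsets)) {
    cell_centre <- a[1] + (j_near + offsets[o]) * dx
    upper <- pnorm(cell_centre + dx / 2, centre, sd)
    lower <- pnorm(cell_centre - dx / 2, centre, sd)
    W[, o] <- upper - lower
    if (offsets[o] == -h) W[, o] <- W[, o] + lower
    if (offsets[o] == h) W[, o] <- W[, o] + (1 - upper)
  }
  list(W = W, j_near = j_near, offsets = offsets)
}

apply_band <- function(grid, band) {
  n <- length(grid$a)
  new <- numeric(n)
  al <- 0; ar <- 0
  m <- grid$mass
  # rows grouped by their integer displacement so every scatter-add below has
  # duplicate-free destination indices
  disp <- band$j_near - (seq_len(n) - 1L)
  for (s in unique(disp)) {
    rows <- which(disp == s & m > 0)
    if (length(rows) == 0) next
    for (o in seq_along(band$offsets)) {
      shift <- s + band$offsets[o]
      contrib <- m[rows] * band$W[rows, o]
      dest <- rows + shift
      inside <- dest > 1L & dest < n
      if (any(inside)) {
        di <- dest[inside]
        new[di] <- new[di] + contrib[inside]
      }
      al <- al + sum(contrib[dest >= n])
      ar <- ar + sum(contrib[dest <= 1L])
    }
  }
  grid$mass <- new
  grid$absorbed_left <- grid$absorbed_left + al
  grid$absorbed_right <- grid$absorbed_right + ar
  grid
}

fp_step_width <- function(lam, sigma_a, dt) {
  sigma_a * sqrt(if (abs(lam) < 1e-12) dt else expm1(2 * lam * dt) /
                   (2 * lam))
}

#' Advance the bounded-accumulator density one time step
#'
#' Uses the exact Ornstein-Uhlenbeck transition over the step: mass at `a`
#' moves to mean `a * exp(lam * dt)` with the OU step variance, integrated
#' over the destination cells (a banded, mass-conserving, unconditionally
#' stable update with a Sheppard correction for the cell-centre binning);
#' mass landing on or beyond a boundary node is absorbed. When the step's
#' diffusion width is below one grid cell, the drift is applied as a
#' linear re-binning remap and the (sub-cell) diffusion as one explicit
#' three-point substep, which is stable by construction in that regime.
#'
#' @param grid A [fp_grid()].
#' @param lam Memory drift rate, 1/seconds.
#' @param sigma_a Diffusion scale (>= 0).
#' @param dt Time step, seconds.
#' @return The advanced `density_grid`.
#' @export
fokker_planck_step <- function(grid, lam, sigma_a, dt) {
  stopifnot(inherits(grid, "density_grid"))
  a <- grid$a
  dx <- a[2] - a[1]
  sd <- fp_step_width(lam, sigma_a, dt)
  if (sd < dx) {
    if (lam != 0) {
      reb <- rebin_mass(a * exp(lam * dt), grid$mass, a,
                        grid$absorbed_left, grid$absorbed_right)
      grid$mass <- reb$mass
      grid$absorbed_left <- reb$absorbed_left
      grid$absorbed_right <- reb$absorbed_right
    }
    if (sd > 0) {
      r <- sd^2 / (2 * dx^2) # <= 0.5 here
      n <- length(a)
      m <- grid$mass
      m2 <- (1 - 2 * r) * m + r * c(0, m[-n]) + r * c(m[-1], 0)
      grid$absorbed_left <- grid$absorbed_left + m2[n]
      grid$absorbed_right <- grid$absorbed_right + m2[1]
      m2[c(1, n)] <- 0
      grid$mass <- m2
    }
    return(grid)
  }
  apply_band(grid, ou_transition_band(a, lam, sigma_a, dt))
}

# Apply one click: shift the interior mass by `shift` (signed, adapted
# magnitude), absorbing anything pushed past a bound.
fp_apply_click <- function(grid, shift) {
  if (shift == 0) return(grid)
  reb <- rebin_mass(grid$a + shift, grid$mass, grid$a,
                    grid$absorbed_left, grid$absorbed_right)
  grid$mass <- reb$mass
  grid$absorbed_left <- reb$absorbed_left
  grid$absorbed_right <- reb$absorbed_right
  grid
}

#' Choice probability of the bounded adaptive accumulator
#'
#' Propagates the accumulator density between clicks under drift and
#' diffusion with absorbing bounds at `+/- B`; each click shifts the interior
#' mass by its signed, adaptation-scaled magnitude (mass pushed past a bound
#' is absorbed and committed -- later evidence cannot move it). At stimulus
#' end, `p_left` is the mass absorbed at `+B` plus the interior mass above
#' `bias` (mass exactly at `bias` splits evenly).
#'
#' @param params A [brunton_params()].
#' @param train A [click_train()].
#' @param n_nodes Grid resolution (>= 201; default 501).
#' @param dt Density-propagation step, seconds (default 2.5e-4).
#' @return Probability of choosing left.
#' @export
brunton_choice_probability <- function(params, train, n_nodes = 501L,
                                       dt = 2.5e-4) {
  stopifnot(inherits(params, "brunton_params"), inherits(train, "click_train"))
  mags <- adaptation_magnitudes(train, params$phi, params$tau_phi)
  grid <- fp_grid(params$B, n_nodes)
  dx <- grid$a[2] - grid$a[1]
  band_cache <- new.env(parent = emptyenv())
  advance <- function(grid, t0, t1) {
    span <- t1 - t0
    if (span <= 0) return(grid)
    n_steps <- max(1L, ceiling(span / dt - 1e-9))
    # coarsen so the banded kernel stays resolved (>= one grid cell per
    # step); below that over the whole span the small-width branch handles it
    while (n_steps > 1L &&
           fp_step_width(params$lam, params$sigma_a, span / n_steps) < dx) {
      n_steps <- n_steps - 1L
    }
    h <- span / n_steps
    if (fp_step_width(params$lam, params$sigma_a, h) < dx) {
      return(fokker_planck_step(grid, params$lam, params$sigma_a, h))
    }
    key <- sprintf("%.17g", h)
    if (!exists(key, envir = band_cache)) {
      assign(key, ou_transition_band(grid$a, params$lam, params$sigma_a, h),
             envir = band_cache)
    }
    band <- get(key, envir = band_cache)
    for (k in seq_len(n_steps)) grid <- apply_band(grid, band)
    grid
  }
  t_now <- 0
  for (i in seq_along(train$times)) {
    grid <- advance(grid, t_now, train$times[i])
    grid <- fp_apply_click(grid, train$signs[i] * mags[i])
    t_now <- train$times[i]
  }
  grid <- advance(grid, t_now, train$duration)
  # each node's mass represents its cell; the cell straddling the threshold
  # contributes its fraction above it (mass exactly at the bias splits evenly)
  frac_above <- pmin(1, pmax(0, (grid$a + dx / 2 - params$bias) / dx))
  grid$absorbed_left + sum(grid$mass * frac_above)
}

brunton_p_left <- function(params, X, protocol, n_nodes = 501L, dt = 2.5e-4) {
  times <- click_times(protocol)
  apply(X, 1, function(signs) {
    brunton_choice_probability(
      params, click_train(times, signs, protocol$stimulus_duration),
      n_nodes = n_nodes, dt = dt
    )
  })
}

#' Bounded adaptive accumulator observer for [simulate_choices()]
#'
#' @param params A [brunton_params()].
#' @param protocol Optional [task_protocol()].
#' @param n_nodes,dt Solver resolution (see [brunton_choice_probability()]).
#' @return An observer function.
#' @export
brunton_observer <- function(params, protocol = NULL, n_nodes = 501L,
                             dt = 2.5e-4) {
  stopifnot(inherits(params, "brunton_params"))
  function(trials) {
    brunton_p_left(params, click_matrix(trials),
                   trials_protocol(trials, protocol), n_nodes, dt)
  }
}

#' Choice probability of the bounded (non-adaptive) LCA
#'
#' The LCA with the addition of just an absorbing bound: delegates to the
#' bounded-accumulator solver with adaptation disabled (`phi = 1`; the
#' recovery constant is then inert).
#'
#' @param params An [lca_params()].
#' @param B Bound magnitude (> 0).
#' @param train A [click_train()].
#' @param n_nodes,dt Solver resolution.
#' @return Probability of choosing left.
#' @export
lca_bounded_choice_probability <- function(params, B, train, n_nodes = 501L,
                                           dt = 2.5e-4) {
  stopifnot(inherits(params, "lca_params"))
  bp <- brunton_params(sigma_a = params$sigma_a, lam = params$lam, B = B,
                       phi = 1, tau_phi = 0.1, bias = params$bias)
  brunton_choice_probability(bp, train, n_nodes = n_nodes, dt = dt)
}
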