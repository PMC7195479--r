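#' The package's documented kernel-shape sweep path
#'
#' A path through (tau_R, tau_G) space along which the ratio tau_R/tau_G
#' decreases monotonically and the regression-scale kernel of the
#' divisive-normalization observer traverses all four phenotypes in order:
#' primacy, bump, flat, recency. The path interpolates log-linearly between
#' four anchor settings -- (6, 0.6), (1.596, 6.5), (0.978, 4.193), (0.4, 12)
#' seconds -- chosen where each phenotype is expressed with margin at the
#' sweep observer settings `omega_I = 1.2`, `mu = -0.32`, `sigma = 0.05`.
#' Primacy occurs while inhibition outruns the leak (ratio >> 1); as the
#' ratio falls towards ~0.25 the leak first carves the early clicks down
#' (bump), then balances inhibition exactly (flat), and finally dominates
#' (recency).
#'
#' @param points_per_segment Interpolation points per anchor segment.
#' @return A tibble with columns `tau_R`, `tau_G`, `ratio` (monotonically
#'   decreasing).
#' @export
shape_sweep_path <- function(points_per_segment = 8L) {
  anchors <- rbind(
    c(6, 0.6),
    c(1.596, 6.5),
    c(0.978, 4.193),
    c(0.4, 12)
  )
  rows <- list()
  for (s in 1:(nrow(anchors) - 1)) {
    u <- seq(0, 1, length.out = points_per_segment)
    if (s > 1) u <- u[-1]
    for (ui in u) {
      rows[[length(rows) + 1]] <-
        exp((1 - ui) * log(anchors[s, ]) + ui * log(anchors[s + 1, ]))
    }
  }
  m <- do.call(rbind, rows)
  tibble::tibble(tau_R = m[, 1], tau_G = m[, 2], ratio = m[, 1] / m[, 2])
}

#' Classify kernel shapes along a tau_R/tau_G sweep
#'
#' Computes the analytic regression-scale kernel `(K + mu)/sigma` at every
#' point of a sweep path and classifies its shape, reproducing the
#' phase-ordering analysis of how the leak/inhibition balance sets the
#' integration kernel.
#'
#' @param path Tibble with `tau_R`, `tau_G` columns (default
#'   [shape_sweep_path()]).
#' @param omega_I,mu,sigma Observer parameters held fixed along the sweep
#'   (defaults are the documented sweep settings).
#' @param protocol A [task_protocol()].
#' @param flatness_fraction Classifier setting.
#' @return `path` with an added `shape` column.
#' @examples
#' sweep <- kernel_shape_sweep(shape_sweep_path(3L))
#' rle(sweep$shape)$values
#' @export
kernel_shape_sweep <- function(path = shape_sweep_path(),
                               omega_I = 1.2, mu = -0.32, sigma = 0.05,
                               protocol = task_protocol(),
                               flatness_fraction = 0.15) {
  validate_protocol(protocol)
  path$shape <- vapply(seq_len(nrow(path)), function(i) {
    params <- divnorm_params(path$tau_R[i], path$tau_G[i], omega_I,
                             sigma = sigma, mu = mu)
    classify_kernel_shape(
      regression_kernel(params, protocol)$beta,
      flatness_fraction = flatness_fraction
    )$label
  }, character(1))
  path
}
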