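#' Fit a normal distribution to an 8-gate cell-count vector
#'
#' The cells of one barcode replicate, distributed over the eight sorting
#' gates, are modeled as `N * (Phi((b_g - mu)/sigma) - Phi((a_g - mu)/sigma))`
#' where `(a_g, b_g]` are the gate bounds (open-ended for the darkest and
#' brightest gates) and `Phi` the standard normal CDF. Parameters are
#' estimated by unweighted least squares with the amplitude `N` profiled
#' out; the initial guess places `mu` in the gate with the highest count
#' and sets `sigma` to that gate's width.
#'
#' @param counts Numeric vector of 8 cell counts (gate 1 = darkest).
#' @param gates A [gate_scheme()] (only `boundaries` is used).
#' @return One-row tibble: `mu`, `sigma`, `n_cells` (input total),
#'   `n_fit` (fitted amplitude), `fit_ok`.
#' @export
fit_gate_distribution <- function(counts, gates = gate_scheme()) {
  b <- gates$boundaries
  stopifnot(length(counts) == gates$n_gates, all(counts >= 0))
  total <- sum(counts)
  if (total <= 0) stop("total cells must be positive")

  lo <- c(-Inf, b)
  hi <- c(b, Inf)
  widths <- c(diff(b)[1], diff(b), diff(b)[length(diff(b))])
  mids <- c(b[1] - widths[1] / 2, (head(b, -1) + tail(b, -1)) / 2,
            b[length(b)] + widths[length(widths)] / 2)

  g0 <- which.max(counts)
  mu0 <- mids[g0]
  sigma0 <- widths[g0]
  mu_bounds <- c(b[1] - 2, b[length(b)] + 2)
  sigma_bounds <- c(0.005, 2)

  obj <- function(par) {
    p <- pnorm(hi, par[1], exp(par[2])) - pnorm(lo, par[1], exp(par[2]))
    sp2 <- sum(p^2)
    n_hat <- if (sp2 > 0) max(sum(counts * p) / sp2, 0) else 0
    sum((counts - n_hat * p)^2)
  }
  fit <- optim(c(mu0, log(sigma0)), obj, method = "L-BFGS-B",
               lower = c(mu_bounds[1], log(sigma_bounds[1])),
               upper = c(mu_bounds[2], log(sigma_bounds[2])),
               control = list(factr = 10, pgtol = 1e-12, maxit = 500,
                              ndeps = c(1e-6, 1e-6)))
  mu <- fit$par[1]
  sigma <- exp(fit$par[2])
  p <- pnorm(hi, mu, sigma) - pnorm(lo, mu, sigma)
  n_fit <- if (sum(p^2) > 0) max(sum(counts * p) / sum(p^2), 0) else 0
  at_bound <- sigma <= sigma_bounds[1] * 1.01 ||
    sigma >= sigma_bounds[2] * 0.99 ||
    mu <= mu_bounds[1] + 1e-6 || mu >= mu_bounds[2] - 1e-6
  tibble::tibble(mu = mu, sigma = sigma, n_cells = total, n_fit = n_fit,
                 fit_ok = fit$convergence == 0 && !at_bound)
}

#' Estimate fluorescence for every barcode replicate
#'
#' Applies [fit_gate_distribution()] to each (primary, secondary, sorter)
#' group of a normalized gate-count table.
#'
#' @param records Tibble with `primary`, `secondary`, `sorter`, `gate`,
#'   and `cells` (from [normalize_by_count_controls()]; a `reads` column
#'   is used if `cells` is absent).
#' @param gates A [gate_scheme()].
#' @return Tibble: one row per replicate with `mu`, `sigma`, `n_cells`,
#'   `fit_ok`.
#' @export
estimate_fluorescence <- function(records, gates = gate_scheme()) {
  value_col <- if ("cells" %in% names(records)) "cells" else "reads"
  records |>
    dplyr::group_by(.data$primary, .data$secondary, .data$sorter) |>
    dplyr::group_modify(function(df, key) {
      v <- numeric(gates$n_gates)
      v[df$gate] <- df[[value_col]]
      fit_gate_distribution(v, gates)
    }) |>
    dplyr::ungroup()
}

#' Calibrate sorter B onto sorter A's fluorescence scale
#'
#' Ordinary least-squares regression of sorter-A fluorescence on
#' sorter-B fluorescence over shared anchor genotypes (known wildtypes
#' measured on both machines). Sorter A is the reference frame.
#'
#' @param estimates Tibble from [estimate_fluorescence()].
#' @param anchor_primaries Primary barcodes of the anchor (wildtype)
#'   genotypes.
#' @return Object of class `machine_calibration` with `slope`,
#'   `intercept`, `n_anchors`.
#' @export
calibrate_machines <- function(estimates, anchor_primaries) {
  anchors <- estimates |>
    dplyr::filter(.data$primary %in% anchor_primaries, .data$fit_ok) |>
    dplyr::group_by(.data$primary, .data$sorter) |>
    dplyr::summarise(mu = weighted.mean(.data$mu, .data$n_cells),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sorter", values_from = "mu")
  if (!all(c("A", "B") %in% names(anchors))) {
    stop("need anchor genotypes measured on both sorters")
  }
  anchors <- anchors[complete.cases(anchors[, c("A", "B")]), ]
  if (nrow(anchors) < 2) {
    stop("need at least 2 anchor genotypes with fits on both sorters")
  }
  fit <- stats::lm(A ~ B, data = anchors)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be positive")
  }
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 n_anchors = nrow(anchors),
                 anchors = anchors,
                 reference = "A"), class = "machine_calibration")
}

#' Apply a machine calibration to fluorescence estimates
#'
#' Maps sorter-B `mu` values onto the sorter-A scale; `sigma` is scaled
#' by the slope. Sorter-A rows are unchanged.
#'
#' @param estimates Tibble from [estimate_fluorescence()].
#' @param calibration A [calibrate_machines()] object.
#' @return The estimates with calibrated `mu`/`sigma`.
#' @export
apply_calibration <- function(estimates, calibration) {
  is_b <- estimates$sorter == "B"
  estimates$mu[is_b] <- calibration$intercept +
    calibration$slope * estimates$mu[is_b]
  estimates$sigma[is_b] <- calibration$slope * estimates$sigma[is_b]
  estimates
}

#' @export
print.machine_calibration <- function(x, ...) {
  cat("<machine_calibration> B -> A: A = ", signif(x$intercept, 4), " + ",
      signif(x$slope, 4), " * B  (", x$n_anchors, " anchors)\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.machine_calibration <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.machine_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 n_anchors = x$n_anchors, reference = x$reference)
}
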