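#' Turn an object into a tidy tibble
#'
#' @param x object to tidy.
#' @param ... method-specific arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' @param x object to summarize.
#' @param ... method-specific arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @describeIn tidy one row per unidirectional flux with its estimate
#'   (and bounds).
#' @export
tidy.fia_fit <- function(x, ...) {
  tibble::tibble(flux = names(x$u_star),
                 estimate = as.numeric(x$u_star),
                 upper_bound = as.numeric(
                   x$problem$u_ub[names(x$u_star)]))
}

#' @describeIn glance objective, iteration counts and convergence flag.
#' @export
glance.fia_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective,
                 residual_norm = sqrt(x$objective),
                 outer_iterations = x$iterations,
                 inner_iterations = x$inner_iterations,
                 converged = x$converged,
                 n_fluxes = length(x$u_star),
                 n_measurement_rows = nrow(x$problem$model$info))
}

#' @describeIn tidy measured vs fitted quantities, one row per
#'   measurement.
#' @export
tidy.residual_model <- function(x, ...) x$info

#' Measured vs model-predicted fractions of a fit
#'
#' @param fit a [fia_fit()].
#' @return tibble with `pool`, `kind`, `spec`, `measured`, `predicted`.
#' @export
fitted_measurements <- function(fit) {
  pred <- predict_measurements(fit$steady_state, fit$problem$system,
                               fit$problem$measurements)
  info <- fit$problem$model$info
  lab <- info[info$type == "label", c("pool", "spec", "yhat")]
  dplyr::left_join(pred,
                   dplyr::rename(lab, measured = "yhat"),
                   by = c("pool", "spec"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot measured against fitted labeling quantities
#'
#' @param object a `fia_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fia_fit
#' @export
autoplot.fia_fit <- function(object, ...) {
  d <- fitted_measurements(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$measured,
                                  y = .data$predicted,
                                  colour = .data$pool)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "measured fraction", y = "fitted fraction",
                  title = "Labeling measurements: fit quality") +
    ggplot2::theme_minimal()
}

#' Plot the per-flux spread of a noise study
#'
#' Shows replicate flux estimates as points over the base (noiseless)
#' estimate, which makes the contrast between tightly determined
#' unidirectional fluxes and weakly identified exchange fluxes visible.
#'
#' @param object a `fia_noise_study`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fia_noise_study
#' @export
autoplot.fia_noise_study <- function(object, ...) {
  reps <- attr(object, "replicates")
  d <- tibble::as_tibble(reps) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "flux",
                        values_to = "estimate") |>
    dplyr::filter(is.finite(.data$estimate))
  base <- tibble::tibble(flux = object$flux, base = object$base)
  d$flux <- factor(d$flux, levels = object$flux)
  base$flux <- factor(base$flux, levels = object$flux)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$flux,
                                  y = .data$estimate)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::geom_point(data = base,
                        ggplot2::aes(y = .data$base),
                        colour = "red", shape = 3, size = 3) +
    ggplot2::labs(x = NULL, y = "flux estimate",
                  title = sprintf(
                    "Replicate spread under noise (sd = %g)",
                    attr(object, "sigma"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Sparsity of the system matrices before and after reduction
#'
#' @param system a `fluxomer_system` with a valid LU reduction.
#' @return a tibble of nonzero counts per matrix.
#' @export
sparsity_summary <- function(system) {
  out <- tibble::tibble(
    matrix = c("H1", "H2"),
    nnz = c(Matrix::nnzero(system$H1), Matrix::nnzero(system$H2)),
    reduced = FALSE)
  if (!is.null(system$lu) && isTRUE(system$lu$ok)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      matrix = c("L_H1", "L_H2", "U_H"),
      nnz = c(Matrix::nnzero(system$lu$L1),
              Matrix::nnzero(system$lu$L2),
              Matrix::nnzero(system$lu$UH)),
      reduced = TRUE))
  }
  out
}

#' @importFrom rlang .data
NULL
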