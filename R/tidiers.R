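## broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a fit
#'
#' @param x A `gegnn_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `loss`, `gd_penalty`).
#' @method tidy gegnn_fit
#' @export
tidy.gegnn_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x A `gegnn_fit`.
#' @param ... Unused.
#' @return A one-row tibble with mode, epochs, number of parameters,
#'   training-set size and final training loss.
#' @method glance gegnn_fit
#' @export
glance.gegnn_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$control$mode,
    epochs = x$control$epochs,
    n_parameters = n_parameters(x$model),
    n_train = x$n_train,
    final_loss = utils::tail(x$history$loss, 1)
  )
}

#' Plot the training loss curve
#'
#' @param object A `gegnn_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gegnn_fit
#' @export
autoplot.gegnn_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "training MSE (ln gamma)",
                  title = paste0("training history (", object$control$mode, ")")) +
    ggplot2::theme_minimal()
}

#' Plot predicted activity-coefficient curves for one mixture
#'
#' Predicted `ln gamma` curves over the full composition range, optionally
#' overlaid with labeled data points.
#'
#' @param model A `gegnn_fit` or `gegnn_model`.
#' @param smiles_1,smiles_2 The mixture components.
#' @param data Optional mixture-record tibble with reference labels for
#'   this pair.
#' @param n_grid Curve resolution.
#' @return A ggplot.
#' @export
plot_activity_curves <- function(model, smiles_1, smiles_2, data = NULL,
                                 n_grid = 101) {
  afn <- model_activity_fn(as_model(model), smiles_1, smiles_2)
  xs <- seq(0, 1, length.out = n_grid)
  lg <- afn(xs)
  curves <- tidyr::pivot_longer(
    tibble::tibble(x1 = xs, `ln gamma 1` = lg$ln_gamma_1,
                   `ln gamma 2` = lg$ln_gamma_2),
    -"x1", names_to = "component", values_to = "ln_gamma")
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$x1, y = .data$ln_gamma,
                                            colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x1", y = "ln gamma",
                  title = paste(smiles_1, "/", smiles_2)) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    pts <- data[data$smiles_1 == canonical_smiles(smiles_1) &
                  data$smiles_2 == canonical_smiles(smiles_2), ]
    if (nrow(pts)) {
      ref <- tidyr::pivot_longer(
        pts[, c("x1", "ln_gamma_1", "ln_gamma_2")],
        -"x1", names_to = "component", values_to = "ln_gamma")
      ref$component <- ifelse(ref$component == "ln_gamma_1",
                              "ln gamma 1", "ln gamma 2")
      p <- p + ggplot2::geom_point(data = ref)
    }
  }
  p
}

#' Plot a vapor-liquid equilibrium curve
#'
#' Pxy plot: bubble- and dew-point pressure against liquid and vapor
#' composition at fixed temperature.
#'
#' @param curve A tibble from [vle_curve()].
#' @return A ggplot.
#' @export
plot_vle <- function(curve) {
  stopifnot(all(c("x1", "y1", "P") %in% names(curve)))
  d <- dplyr::bind_rows(
    tibble::tibble(z = curve$x1, P = curve$P, branch = "bubble (liquid x1)"),
    tibble::tibble(z = curve$y1, P = curve$P, branch = "dew (vapor y1)")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z, y = .data$P,
                                  colour = .data$branch)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "x1, y1", y = paste0("P (", curve$T[1], " K)"),
                  title = if (isTRUE(attr(curve, "azeotrope")))
                    "VLE (azeotropic)" else "VLE") +
    ggplot2::theme_minimal()
}

#' Four-panel mixture diagnostic plot
#'
#' The standard diagnostic layout for one mixture: activity coefficients,
#' their composition gradients with the Gibbs-Duhem deviation, the excess
#' Gibbs energy, and the VLE curve. Requires the patchwork package.
#'
#' @param model A `gegnn_fit` or `gegnn_model`.
#' @param smiles_1,smiles_2 The mixture components.
#' @param antoine_1,antoine_2 [antoine_params()] for the two components.
#' @param data Optional reference records.
#' @param n_grid Curve resolution.
#' @return A patchwork composite plot.
#' @export
plot_mixture_panels <- function(model, smiles_1, smiles_2,
                                antoine_1, antoine_2, data = NULL,
                                n_grid = 101) {
  if (!requireNamespace("patchwork", quietly = TRUE)) {
    stop("plot_mixture_panels() requires the patchwork package",
         call. = FALSE)
  }
  model <- as_model(model)
  afn <- model_activity_fn(model, smiles_1, smiles_2)
  xs <- seq(0.01, 0.99, length.out = n_grid)
  grad <- attr(afn, "grad")(xs)
  gd <- xs * grad[, 1] + (1 - xs) * grad[, 2]
  p1 <- plot_activity_curves(model, smiles_1, smiles_2, data, n_grid)
  dgrad <- tibble::tibble(x1 = rep(xs, 3),
                          value = c(grad[, 1], grad[, 2], gd),
                          series = rep(c("d ln gamma1/dx1",
                                         "d ln gamma2/dx1",
                                         "GD deviation"), each = length(xs)))
  p2 <- ggplot2::ggplot(dgrad, ggplot2::aes(x = .data$x1, y = .data$value,
                                            colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::theme_minimal() +
    ggplot2::labs(y = "gradient")
  if (model$head == "ge") {
    gfn <- model_gE_fn(model, smiles_1, smiles_2)
    ge <- gfn(xs)
  } else {
    lg <- afn(xs)
    ge <- reconstruct_gE(cbind(tibble::tibble(x1 = xs), lg))
  }
  p3 <- ggplot2::ggplot(tibble::tibble(x1 = xs, gE_RT = ge),
                        ggplot2::aes(x = .data$x1, y = .data$gE_RT)) +
    ggplot2::geom_line() + ggplot2::theme_minimal() +
    ggplot2::labs(y = "gE/RT")
  p4 <- plot_vle(vle_curve(afn, antoine_1, antoine_2))
  (p1 + p2) / (p3 + p4)
}
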