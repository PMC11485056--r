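## Exact thermodynamics connecting gE/RT to binary activity coefficients.
##
## For a binary mixture at constant T and P, with g = gE/RT and
## g' = dg/dx1:
##     ln gamma1 = g + (1 - x1) g'          ln gamma2 = g - x1 g'
## so that x1 ln gamma1 + x2 ln gamma2 = g identically, and
## ln gamma1 - ln gamma2 = g'. Any twice-differentiable g therefore yields
## activity coefficients satisfying the Gibbs-Duhem equation
##     x1 d(ln gamma1)/dx1 + x2 d(ln gamma2)/dx1 = 0
## by construction: both derivatives are proportional to g'' with exactly
## cancelling prefactors.

#' Activity coefficients from a differentiable gE/RT function
#'
#' Evaluates `ln gamma1 = g + (1 - x1) g'` and `ln gamma2 = g - x1 g'` in
#' one differentiation pass. If `gE_fn` carries a `"grad"` attribute (a
#' function `x1 -> dg/dx1`, as produced by [analytic_gE_fn()] and
#' [model_gE_fn()]) that exact derivative is used; otherwise the derivative
#' falls back to a second-order finite difference (documented fallback for
#' arbitrary black-box functions -- model predictions always use exact
#' differentiation).
#'
#' Boundary compositions are allowed: the formulas are evaluated at
#' `x1 = 0` / `x1 = 1` directly (the smooth surrogate is differentiable on
#' a neighbourhood), giving the infinite-dilution values, e.g.
#' `ln gamma1(0) = g'(0)`.
#'
#' @param gE_fn Function `x1 -> gE/RT`, vectorised.
#' @param x1 Numeric vector of mole fractions in `[0, 1]`.
#' @return A tibble with columns `x1`, `gE_RT`, `dgE_dx1`, `ln_gamma_1`,
#'   `ln_gamma_2`.
#' @examples
#' margules <- analytic_gE_fn(analytic_ge_model("margules2", c(A12 = 1, A21 = 1)))
#' activity_from_gE(margules, 0.5)   # ln gamma1 = ln gamma2 = 0.25
#' @export
activity_from_gE <- function(gE_fn, x1) {
  stopifnot(is.function(gE_fn))
  check_x1(x1)
  g <- gE_fn(x1)
  grad <- attr(gE_fn, "grad")
  dg <- if (is.function(grad)) grad(x1) else numeric_deriv(gE_fn, x1)
  if (any(!is.finite(g)) || any(!is.finite(dg))) {
    stop("gE function or its derivative is not finite at the requested ",
         "compositions", call. = FALSE)
  }
  tibble::tibble(
    x1 = x1,
    gE_RT = g,
    dgE_dx1 = dg,
    ln_gamma_1 = g + (1 - x1) * dg,
    ln_gamma_2 = g - x1 * dg
  )
}

#' Reconstruct gE/RT from an activity pair
#'
#' The identity `gE/RT = x1 ln gamma1 + (1 - x1) ln gamma2`; inverts
#' [activity_from_gE()] exactly (to machine precision).
#'
#' @param pair A data frame with columns `x1`, `ln_gamma_1`, `ln_gamma_2`.
#' @return Numeric vector of gE/RT values.
#' @export
reconstruct_gE <- function(pair) {
  stopifnot(all(c("x1", "ln_gamma_1", "ln_gamma_2") %in% names(pair)))
  pair$x1 * pair$ln_gamma_1 + (1 - pair$x1) * pair$ln_gamma_2
}

#' Gibbs-Duhem residual of an activity-coefficient function
#'
#' Computes `x1 d(ln gamma1)/dx1 + (1 - x1) d(ln gamma2)/dx1` at interior
#' compositions. Zero indicates perfect thermodynamic consistency. If
#' `activity_fn` carries a `"grad"` attribute (a function returning the two
#' composition derivatives, as attached by [model_activity_fn()]) it is
#' used; otherwise derivatives fall back to central finite differences.
#'
#' @param activity_fn Function `x1 -> ` two-column object
#'   `(ln_gamma_1, ln_gamma_2)`.
#' @param x1 Numeric vector of interior mole fractions (0 and 1 excluded:
#'   the consistency audit is defined at interior points only).
#' @return Numeric vector of residuals.
#' @examples
#' # a deliberately inconsistent toy: ln gamma1 = ln gamma2 = x1
#' toy <- function(x1) cbind(ln_gamma_1 = x1, ln_gamma_2 = x1)
#' gibbs_duhem_residual(toy, 0.5)   # 1
#' @export
gibbs_duhem_residual <- function(activity_fn, x1) {
  stopifnot(is.function(activity_fn))
  if (any(x1 <= 0) || any(x1 >= 1)) {
    stop("Gibbs-Duhem residuals are audited at interior compositions only ",
         "(0 < x1 < 1)", call. = FALSE)
  }
  grad <- attr(activity_fn, "grad")
  d <- if (is.function(grad)) {
    as.matrix(grad(x1))
  } else {
    h <- 1e-6
    hh <- pmin(h, x1 / 2, (1 - x1) / 2)  # stay inside (0, 1)
    up <- eval_activity(activity_fn, x1 + hh)
    dn <- eval_activity(activity_fn, x1 - hh)
    (up - dn) / (2 * hh)
  }
  unname(x1 * d[, 1] + (1 - x1) * d[, 2])
}

eval_activity <- function(activity_fn, x1) {
  v <- activity_fn(x1)
  v <- as.matrix(as.data.frame(v))
  stopifnot(ncol(v) >= 2)
  v[, 1:2, drop = FALSE]
}

#' Root-mean-square Gibbs-Duhem deviation over a composition set
#'
#' @inheritParams gibbs_duhem_residual
#' @param compositions Nonempty numeric vector of interior mole fractions.
#' @return Scalar GD-RMSE.
#' @export
gd_rmse <- function(activity_fn, compositions) {
  if (length(compositions) == 0) {
    stop("gd_rmse() requires a nonempty composition set", call. = FALSE)
  }
  sqrt(mean(gibbs_duhem_residual(activity_fn, compositions)^2))
}

## ---- model-derived differentiable functions ------------------------------

#' Differentiable gE and activity functions of a fitted model
#'
#' `model_gE_fn()` returns `x1 -> gE/RT` with its exact automatic
#' derivative attached as the `"grad"` attribute. `model_activity_fn()`
#' returns `x1 -> tibble(ln_gamma_1, ln_gamma_2)` whose `"grad"` attribute
#' carries the exact composition derivatives of both activity coefficients
#' (nested forward-mode differentiation; for the `"ge"` head these are
#' `(1 - x1) g''` and `-x1 g''`, whose Gibbs-Duhem combination cancels
#' identically).
#'
#' @param model A `gegnn_model` (or `gegnn_fit`).
#' @param graph_1,graph_2 `molecule_graph`s or SMILES strings.
#' @return A function of `x1`.
#' @export
model_gE_fn <- function(model, graph_1, graph_2) {
  model <- as_model(model)
  if (model$head != "ge") {
    stop("model_gE_fn() requires the 'ge' head", call. = FALSE)
  }
  gt1 <- graph_tensors(as_graph(graph_1))
  gt2 <- graph_tensors(as_graph(graph_2))
  f <- function(x1) {
    check_x1(x1)
    ge_forward(model, gt1, gt2, x1, order = 0)$g
  }
  attr(f, "grad") <- function(x1) {
    check_x1(x1)
    ge_forward(model, gt1, gt2, x1, order = 1)$dg
  }
  f
}

#' @rdname model_gE_fn
#' @export
model_activity_fn <- function(model, graph_1, graph_2) {
  model <- as_model(model)
  gt1 <- graph_tensors(as_graph(graph_1))
  gt2 <- graph_tensors(as_graph(graph_2))
  if (model$head == "ge") {
    f <- function(x1) {
      check_x1(x1)
      fw <- ge_forward(model, gt1, gt2, x1, order = 1)
      tibble::tibble(ln_gamma_1 = fw$g + (1 - x1) * fw$dg,
                     ln_gamma_2 = fw$g - x1 * fw$dg)
    }
    attr(f, "grad") <- function(x1) {
      fw <- ge_forward(model, gt1, gt2, x1, order = 2)
      cbind(dln_gamma_1 = (1 - x1) * fw$d2g, dln_gamma_2 = -x1 * fw$d2g)
    }
  } else {
    f <- function(x1) {
      check_x1(x1)
      fw <- direct_forward(model, gt1, gt2, x1, order = 0)
      tibble::tibble(ln_gamma_1 = fw$lg1, ln_gamma_2 = fw$lg2)
    }
    attr(f, "grad") <- function(x1) {
      fw <- direct_forward(model, gt1, gt2, x1, order = 1)
      cbind(dln_gamma_1 = fw$dlg1, dln_gamma_2 = fw$dlg2)
    }
  }
  f
}

#' Predict activity coefficients for a table of mixtures
#'
#' Tidy prediction surface: takes a data frame with columns `smiles_1`,
#' `smiles_2`, `x1` and returns it with predictions appended. For the
#' `"ge"` head the activity coefficients derive from the excess-Gibbs
#' output by exact differentiation; `gd_residual` is the Gibbs-Duhem
#' residual (reported at interior compositions, `NA` at 0/1 where the
#' audit is not defined).
#'
#' @param model A `gegnn_model` or `gegnn_fit`.
#' @param newdata Data frame with `smiles_1`, `smiles_2`, `x1`.
#' @return The input tibble with columns `gE_RT`, `dgE_RT_dx1`,
#'   `ln_gamma_1`, `ln_gamma_2`, `gd_residual` appended.
#' @export
predict_activity <- function(model, newdata) {
  model <- as_model(model)
  stopifnot(all(c("smiles_1", "smiles_2", "x1") %in% names(newdata)))
  newdata <- tibble::as_tibble(newdata)
  key <- paste(newdata$smiles_1, newdata$smiles_2, sep = "\r")
  out <- vector("list", length(unique(key)))
  for (i in seq_along(unique(key))) {
    k <- unique(key)[i]
    idx <- which(key == k)
    rows <- newdata[idx, ]
    xs <- rows$x1
    interior <- xs > 0 & xs < 1
    afn <- model_activity_fn(model, rows$smiles_1[1], rows$smiles_2[1])
    lg <- afn(xs)
    gd <- rep(NA_real_, length(xs))
    if (any(interior)) {
      gd[interior] <- gibbs_duhem_residual(afn, xs[interior])
    }
    if (model$head == "ge") {
      gfn <- model_gE_fn(model, rows$smiles_1[1], rows$smiles_2[1])
      gE <- gfn(xs)
      dgE <- attr(gfn, "grad")(xs)
    } else {
      gE <- reconstruct_gE(cbind(tibble::tibble(x1 = xs), lg))
      d <- attr(afn, "grad")(xs)
      dgE <- lg$ln_gamma_1 - lg$ln_gamma_2 + xs * d[, 1] + (1 - xs) * d[, 2]
    }
    out[[i]] <- dplyr::mutate(rows, gE_RT = gE, dgE_RT_dx1 = dgE,
                              ln_gamma_1 = lg$ln_gamma_1,
                              ln_gamma_2 = lg$ln_gamma_2,
                              gd_residual = gd, .row = idx)
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::arrange(res, .data$.row)
  dplyr::select(res, -".row")
}

as_model <- function(x) {
  if (inherits(x, "gegnn_fit")) x$model else x
}

# second-order finite differences, respecting the [0, 1] domain
numeric_deriv <- function(f, x, h = 1e-6) {
  d <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    if (xi >= h && xi <= 1 - h) {
      d[i] <- (f(xi + h) - f(xi - h)) / (2 * h)
    } else if (xi < h) {
      d[i] <- (-3 * f(xi) + 4 * f(xi + h) - f(xi + 2 * h)) / (2 * h)
    } else {
      d[i] <- (3 * f(xi) - 4 * f(xi - h) + f(xi - 2 * h)) / (2 * h)
    }
  }
  d
}
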