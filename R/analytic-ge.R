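## Classical closed-form excess-Gibbs models (two-parameter Margules,
## van Laar, NRTL). They serve two roles: ground truth for the synthetic
## data generator, and independent oracles for the automatic-differentiation
## thermodynamics head. All quantities are dimensionless (gE/RT, ln gamma).

GE_FAMILIES <- c("margules2", "van_laar", "nrtl")

#' Construct an analytic excess-Gibbs model
#'
#' @param family One of `"margules2"`, `"van_laar"`, `"nrtl"`.
#' @param params Named numeric vector of family parameters:
#'   `margules2` and `van_laar` take `A12`, `A21`; `nrtl` takes
#'   `tau12`, `tau21`, `alpha`.
#' @return An object of class `analytic_ge_model`.
#' @details All families satisfy the pure-component limits
#'   `gE/RT(0) = gE/RT(1) = 0` and their closed-form activity coefficients
#'   satisfy the Gibbs-Duhem equation analytically. `nrtl` with
#'   `alpha = 0` is allowed but degenerate: both `G` factors collapse to 1
#'   and the model reduces to a Margules-type form in `tau12 + tau21`.
#' @examples
#' m <- analytic_ge_model("margules2", c(A12 = 1, A21 = 1))
#' analytic_gE(m, 0.5)        # 0.25
#' analytic_lngamma(m, 0.5)   # both 0.25
#' @export
analytic_ge_model <- function(family, params) {
  family <- as.character(family)
  if (!family %in% GE_FAMILIES) {
    stop("unknown excess-Gibbs family: '", family, "' (expected one of ",
         paste(GE_FAMILIES, collapse = ", "), ")", call. = FALSE)
  }
  need <- if (family == "nrtl") c("tau12", "tau21", "alpha") else c("A12", "A21")
  if (!all(need %in% names(params))) {
    stop("family '", family, "' requires parameters ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  structure(list(family = family, params = as.list(params)[need]),
            class = "analytic_ge_model")
}

#' @export
print.analytic_ge_model <- function(x, ...) {
  cat("<analytic_ge_model> ", x$family, ": ",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Closed-form excess Gibbs energy and its composition derivative
#'
#' `analytic_gE()` evaluates gE/RT at mole fraction `x1`;
#' `analytic_dgE_dx1()` evaluates its derivative with respect to `x1`
#' (derived symbolically per family, independent of the activity
#' coefficient closed forms).
#'
#' @param model An `analytic_ge_model`.
#' @param x1 Numeric vector of mole fractions in `[0, 1]`.
#' @return Numeric vector.
#' @export
analytic_gE <- function(model, x1) {
  stopifnot(inherits(model, "analytic_ge_model"))
  check_x1(x1)
  p <- model$params
  x2 <- 1 - x1
  switch(model$family,
    margules2 = x1 * x2 * (p$A21 * x1 + p$A12 * x2),
    van_laar = {
      d <- p$A12 * x1 + p$A21 * x2
      out <- ifelse(abs(d) < 1e-300, 0, p$A12 * p$A21 * x1 * x2 / d)
      out[x1 %in% c(0, 1)] <- 0
      out
    },
    nrtl = {
      G12 <- exp(-p$alpha * p$tau12); G21 <- exp(-p$alpha * p$tau21)
      x1 * x2 * (p$tau21 * G21 / (x1 + x2 * G21) +
                 p$tau12 * G12 / (x2 + x1 * G12))
    }
  )
}

#' @rdname analytic_gE
#' @export
analytic_dgE_dx1 <- function(model, x1) {
  stopifnot(inherits(model, "analytic_ge_model"))
  check_x1(x1)
  p <- model$params
  x2 <- 1 - x1
  switch(model$family,
    margules2 =
      (1 - 2 * x1) * (p$A21 * x1 + p$A12 * x2) + x1 * x2 * (p$A21 - p$A12),
    van_laar = {
      d <- p$A12 * x1 + p$A21 * x2
      ifelse(abs(d) < 1e-300, 0,
             p$A12 * p$A21 * ((1 - 2 * x1) * d - x1 * x2 * (p$A12 - p$A21)) / d^2)
    },
    nrtl = {
      G12 <- exp(-p$alpha * p$tau12); G21 <- exp(-p$alpha * p$tau21)
      t1 <- p$tau21 * G21 / (x1 + x2 * G21)
      t2 <- p$tau12 * G12 / (x2 + x1 * G12)
      dt1 <- -p$tau21 * G21 * (1 - G21) / (x1 + x2 * G21)^2
      dt2 <-  p$tau12 * G12 * (1 - G12) / (x2 + x1 * G12)^2
      (1 - 2 * x1) * (t1 + t2) + x1 * x2 * (dt1 + dt2)
    }
  )
}

#' Closed-form activity coefficients of an analytic excess-Gibbs model
#'
#' Standard literature closed forms, coded directly (not via
#' differentiation), so they can serve as an independent oracle for
#' [activity_from_gE()].
#'
#' @inheritParams analytic_gE
#' @return A tibble with columns `x1`, `ln_gamma_1`, `ln_gamma_2`.
#' @export
analytic_lngamma <- function(model, x1) {
  stopifnot(inherits(model, "analytic_ge_model"))
  check_x1(x1)
  p <- model$params
  x2 <- 1 - x1
  res <- switch(model$family,
    margules2 = list(
      lg1 = x2^2 * (p$A12 + 2 * (p$A21 - p$A12) * x1),
      lg2 = x1^2 * (p$A21 + 2 * (p$A12 - p$A21) * x2)
    ),
    van_laar = {
      d <- p$A12 * x1 + p$A21 * x2
      lg1 <- ifelse(abs(d) < 1e-300, 0, p$A12 * (p$A21 * x2 / d)^2)
      lg2 <- ifelse(abs(d) < 1e-300, 0, p$A21 * (p$A12 * x1 / d)^2)
      list(lg1 = lg1, lg2 = lg2)
    },
    nrtl = {
      G12 <- exp(-p$alpha * p$tau12); G21 <- exp(-p$alpha * p$tau21)
      lg1 <- x2^2 * (p$tau21 * (G21 / (x1 + x2 * G21))^2 +
                     p$tau12 * G12 / (x2 + x1 * G12)^2)
      lg2 <- x1^2 * (p$tau12 * (G12 / (x2 + x1 * G12))^2 +
                     p$tau21 * G21 / (x1 + x2 * G21)^2)
      list(lg1 = lg1, lg2 = lg2)
    }
  )
  tibble::tibble(x1 = x1, ln_gamma_1 = res$lg1, ln_gamma_2 = res$lg2)
}

#' Turn an analytic model into differentiable gE and activity functions
#'
#' `analytic_gE_fn()` returns a function `x1 -> gE/RT` carrying its exact
#' symbolic derivative as the `"grad"` attribute, in the form expected by
#' [activity_from_gE()]. `analytic_activity_fn()` returns a function
#' `x1 -> tibble(ln_gamma_1, ln_gamma_2)` for consistency audits.
#'
#' @inheritParams analytic_gE
#' @return A function of `x1`.
#' @export
analytic_gE_fn <- function(model) {
  force(model)
  f <- function(x1) analytic_gE(model, x1)
  attr(f, "grad") <- function(x1) analytic_dgE_dx1(model, x1)
  f
}

#' @rdname analytic_gE_fn
#' @export
analytic_activity_fn <- function(model) {
  force(model)
  function(x1) analytic_lngamma(model, x1)[, c("ln_gamma_1", "ln_gamma_2")]
}

check_x1 <- function(x1) {
  if (!is.numeric(x1) || any(!is.finite(x1)) || any(x1 < 0) || any(x1 > 1)) {
    stop("mole fraction x1 must lie in [0, 1]", call. = FALSE)
  }
  invisible(x1)
}
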