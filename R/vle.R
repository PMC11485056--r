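## Isothermal vapor-liquid equilibrium from predicted activity
## coefficients, via modified Raoult's law
##     P = x1 gamma1 Psat1 + x2 gamma2 Psat2,   y1 = x1 gamma1 Psat1 / P
## with pure-component saturation pressures from the Antoine equation
##     log10(Psat) = A - B / (T + C).
## A small fixtures table of Antoine coefficients (NIST-webbook log10/bar/K
## convention) for the example compounds ships with the package.

#' Antoine parameters
#'
#' @param A,B,C Antoine coefficients in the `log10(Psat) = A - B/(T + C)`
#'   convention.
#' @param T_min,T_max Validity range in kelvin.
#' @param P_unit Pressure unit of `Psat` (recorded; default `"bar"`).
#' @param name Optional compound name.
#' @return An object of class `antoine_params`.
#' @export
antoine_params <- function(A, B, C, T_min, T_max, P_unit = "bar",
                           name = NULL) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C), T_min < T_max)
  structure(list(A = A, B = B, C = C, T_min = T_min, T_max = T_max,
                 P_unit = P_unit, basis = "log10", T_unit = "K",
                 name = name),
            class = "antoine_params")
}

#' Antoine saturation pressure
#'
#' @param params An [antoine_params()] (or a one-row data frame with
#'   columns `A`, `B`, `C`, `T_min`, `T_max`).
#' @param temperature Temperature in kelvin, within the validity range.
#' @return Saturation pressure in the declared pressure unit.
#' @examples
#' w <- antoine_params(5.40221, 1838.675, -31.737, 273, 333)
#' antoine_psat(w, 298.15)   # ~0.0317 bar
#' @export
antoine_psat <- function(params, temperature) {
  if (is.data.frame(params)) {
    params <- antoine_params(params$A[1], params$B[1], params$C[1],
                             params$T_min[1], params$T_max[1],
                             P_unit = params$P_unit[1] %||% "bar",
                             name = params$name[1])
  }
  stopifnot(inherits(params, "antoine_params"))
  if (any(temperature < params$T_min | temperature > params$T_max)) {
    stop("temperature outside Antoine validity range [", params$T_min, ", ",
         params$T_max, "] K", if (!is.null(params$name)) paste0(" for ", params$name),
         call. = FALSE)
  }
  10^(params$A - params$B / (temperature + params$C))
}

#' Load the bundled Antoine coefficient table
#'
#' Coefficients for the example compounds (water, methanol, ethanol,
#' acetone, chloroform, benzene) in the NIST-webbook convention
#' (`log10`, bar, K); sources are documented in the file itself.
#'
#' @param compound Optional compound name to select one row (returned as an
#'   [antoine_params()]).
#' @return A tibble, or an `antoine_params` if `compound` is given.
#' @export
load_antoine <- function(compound = NULL) {
  path <- system.file("extdata", "antoine_nist.csv", package = "gegnn")
  d <- tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                         stringsAsFactors = FALSE))
  if (is.null(compound)) return(d)
  row <- d[d$name == compound, ]
  if (nrow(row) == 0) {
    stop("no Antoine parameters bundled for '", compound, "'", call. = FALSE)
  }
  antoine_params(row$A, row$B, row$C, row$T_min, row$T_max,
                 P_unit = row$P_unit, name = row$name)
}

#' Isothermal VLE curve from an activity-coefficient function
#'
#' Evaluates modified Raoult's law on a composition grid. At the pure
#' limits `x1 = 0` and `x1 = 1` the pure component's activity coefficient
#' is set to exactly 1 (its thermodynamic definition), so the endpoint
#' pressures equal the pure-component saturation pressures even though the
#' network does not enforce `gamma_i(x_i = 1) = 1`. An azeotrope flag marks
#' a `y1 = x1` crossing in the interior.
#'
#' @param activity_fn Function `x1 ->` two columns `(ln_gamma_1,
#'   ln_gamma_2)`, e.g. from [model_activity_fn()] or
#'   [analytic_activity_fn()].
#' @param antoine_1,antoine_2 [antoine_params()] for the two components.
#' @param temperature Temperature in kelvin (default 298.15).
#' @param grid Composition grid (default 101 points).
#' @return A tibble with columns `x1`, `y1`, `P`, `T` and attribute
#'   `azeotrope` (logical).
#' @examples
#' ideal <- function(x1) cbind(ln_gamma_1 = 0 * x1, ln_gamma_2 = 0 * x1)
#' a <- antoine_params(0.30103, 0, 0, 200, 400)   # Psat = 2
#' b <- antoine_params(0, 0, 0, 200, 400)         # Psat = 1
#' vle_curve(ideal, a, b)[51, ]                   # P = 1.5, y1 = 2/3
#' @export
vle_curve <- function(activity_fn, antoine_1, antoine_2,
                      temperature = 298.15, grid = seq(0, 1, length.out = 101)) {
  check_x1(grid)
  p1 <- antoine_psat(antoine_1, temperature)
  p2 <- antoine_psat(antoine_2, temperature)
  lg <- eval_activity(activity_fn, grid)
  g1 <- exp(lg[, 1]); g2 <- exp(lg[, 2])
  g1[abs(grid - 1) < 1e-12] <- 1   # pure-component convention
  g2[abs(grid) < 1e-12] <- 1
  part1 <- grid * g1 * p1
  P <- part1 + (1 - grid) * g2 * p2
  y1 <- part1 / P
  az <- FALSE
  interior <- grid > 0 & grid < 1
  if (sum(interior) > 1) {
    d <- (y1 - grid)[interior]
    az <- any(d[-1] * d[-length(d)] < 0)
  }
  out <- tibble::tibble(x1 = grid, y1 = y1, P = P, T = temperature)
  attr(out, "azeotrope") <- az
  out
}
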