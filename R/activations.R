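#' Smooth activation functions
#'
#' The excess-Gibbs head differentiates the network twice with respect to the
#' mole fraction, so every activation in the composition-dependent part of the
#' model must be at least twice continuously differentiable. `softplus` (the
#' default) and `silu` qualify; piecewise-linear activations such as ReLU are
#' rejected at configuration time because their kink makes the derived
#' activity-coefficient curves non-smooth and is known to stall training of
#' excess-Gibbs networks.
#'
#' @param name Activation name, one of `"softplus"`, `"silu"`.
#' @return A list with elements `f`, `df`, `d2f` (the function and its first
#'   two derivatives, all vectorised) and `name`.
#' @examples
#' act <- activation_fns("softplus")
#' act$f(0)        # log(2)
#' act$df(0)       # 0.5
#' @export
activation_fns <- function(name = c("softplus", "silu")) {
  if (length(name) == 1 && identical(tolower(name), "relu")) {
    stop("activation 'relu' is not continuously differentiable; ",
         "the thermodynamic head requires a smooth activation ",
         "(use 'softplus' or 'silu')", call. = FALSE)
  }
  name <- match.arg(name)
  switch(name,
    softplus = list(
      name = "softplus",
      f   = softplus,
      df  = stats::plogis,
      d2f = function(x) { s <- stats::plogis(x); s * (1 - s) }
    ),
    silu = list(
      name = "silu",
      f   = function(x) x * stats::plogis(x),
      df  = function(x) {
        s <- stats::plogis(x)
        s + x * s * (1 - s)
      },
      d2f = function(x) {
        s <- stats::plogis(x)
        s * (1 - s) * (2 + x * (1 - 2 * s))
      }
    )
  )
}

# numerically stable log(1 + exp(x))
softplus <- function(x) {
  out <- x
  lo <- x < 30
  out[lo] <- log1p(exp(x[lo]))
  hi <- !lo
  out[hi] <- x[hi] + log1p(exp(-x[hi]))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic small-integer sub-seed derived from a master seed and a tag,
# kept below 2^31
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 2654435 + h * 97 + 13) %% 2147483629)
}
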