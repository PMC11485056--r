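## The excess-Gibbs graph neural network.
##
## Architecture: per-molecule graph convolutions + sum pooling give molecular
## fingerprints; a two-node mixture graph (one undirected edge, self-loops)
## models component interactions; the mole fraction of each component is
## concatenated to its post-interaction fingerprint; a shared single-layer
## perceptron (SLP) followed by MEAN pooling over the two components yields a
## permutation-invariant mixture fingerprint; an MLP maps it to the scalar
## gE/RT. Activity coefficients come from exact differentiation with respect
## to x1 (see thermo.R). All activations are smooth so the network is C^inf
## in x1; derivative channels are propagated by forward-mode dual numbers.
##
## The baseline "direct" head shares the encoder and SLP but skips pooling:
## each component's SLP output passes through the (shared) MLP and readout,
## giving (ln gamma1, ln gamma2) directly -- permutation-equivariant but not
## thermodynamically consistent.

#' Model configuration
#'
#' @param hidden_dim Width of all hidden representations (default 64).
#' @param n_mol_conv_layers Number of molecular graph-convolution layers
#'   (default 2).
#' @param n_mlp_layers Number of hidden layers in the output MLP (default 2).
#' @param activation Name of a smooth (twice continuously differentiable)
#'   activation: `"softplus"` (default) or `"silu"`. Non-smooth activations
#'   such as ReLU are rejected because the thermodynamic head requires
#'   well-defined first and second derivatives in the mole fraction.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `gegnn_config`.
#' @examples
#' cfg <- model_config(hidden_dim = 16, seed = 1)
#' @export
model_config <- function(hidden_dim = 64L, n_mol_conv_layers = 2L,
                         n_mlp_layers = 2L, activation = "softplus",
                         seed = 0L) {
  stopifnot(hidden_dim >= 1, n_mol_conv_layers >= 1, n_mlp_layers >= 1)
  activation_fns(activation)  # validates; rejects non-smooth activations
  structure(list(
    hidden_dim = as.integer(hidden_dim),
    n_mol_conv_layers = as.integer(n_mol_conv_layers),
    n_mlp_layers = as.integer(n_mlp_layers),
    activation = activation,
    seed = as.integer(seed)
  ), class = "gegnn_config")
}

#' Construct a (randomly initialised) model
#'
#' @param config A [model_config()].
#' @param head `"ge"` for the excess-Gibbs scalar head (thermodynamically
#'   consistent by construction) or `"direct"` for the two-output baseline
#'   head predicting `(ln gamma1, ln gamma2)` directly.
#' @return An object of class `gegnn_model` with elements `config`, `head`
#'   and `params`. The two heads have identical parameter shapes (they share
#'   the encoder, SLP, MLP and readout structure), so accuracy comparisons
#'   isolate the consistency mechanism.
#' @examples
#' m <- gegnn_model(model_config(hidden_dim = 8, seed = 1))
#' @export
gegnn_model <- function(config = model_config(), head = c("ge", "direct")) {
  stopifnot(inherits(config, "gegnn_config"))
  head <- match.arg(head)
  h <- config$hidden_dim
  Fa <- atom_feature_dim()
  Fb <- bond_feature_dim()
  params <- withr::with_seed(config$seed, {
    glorot <- function(nin, nout) {
      matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
    }
    enc <- vector("list", config$n_mol_conv_layers)
    d_in <- Fa
    for (l in seq_len(config$n_mol_conv_layers)) {
      enc[[l]] <- list(W_self = glorot(d_in, h), W_nb = glorot(d_in, h),
                       W_edge = glorot(Fb, h), b = rep(0, h))
      d_in <- h
    }
    mix <- list(W_self = glorot(h, h), W_nb = glorot(h, h), b = rep(0, h))
    slp <- list(W = t(glorot(h + 1, h)), b = rep(0, h))  # h x (h+1)
    mlp <- lapply(seq_len(config$n_mlp_layers), function(k) {
      list(W = t(glorot(h, h)), b = rep(0, h))
    })
    out <- list(w = stats::rnorm(h, 0, sqrt(2 / (h + 1))), b = 0)
    list(enc = enc, mix = mix, slp = slp, mlp = mlp, out = out)
  })
  structure(list(config = config, head = head, params = params),
            class = "gegnn_model")
}

#' @export
print.gegnn_model <- function(x, ...) {
  cat("<gegnn_model> head=", x$head,
      " hidden_dim=", x$config$hidden_dim,
      " conv_layers=", x$config$n_mol_conv_layers,
      " mlp_layers=", x$config$n_mlp_layers,
      " activation=", x$config$activation,
      " (", n_parameters(x), " parameters)\n", sep = "")
  invisible(x)
}

#' Total number of trainable parameters
#' @param model A `gegnn_model`.
#' @return Integer.
#' @export
n_parameters <- function(model) {
  sum(rapply(model$params, length, how = "unlist"))
}

## ---- graph tensors -------------------------------------------------------

# dense adjacency and summed incident-bond features; constant per graph
graph_tensors <- function(graph) {
  n <- graph$n_atoms
  A <- matrix(0, n, n)
  Binc <- matrix(0, n, bond_feature_dim())
  if (nrow(graph$bonds) > 0) {
    for (b in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds[b, 1]; j <- graph$bonds[b, 2]
      A[i, j] <- A[i, j] + 1
      A[j, i] <- A[j, i] + 1
      Binc[i, ] <- Binc[i, ] + graph$bond_features[b, ]
      Binc[j, ] <- Binc[j, ] + graph$bond_features[b, ]
    }
  }
  list(X = graph$atom_features, A = A, Binc = Binc)
}

as_graph <- function(g) {
  if (is.character(g)) smiles_to_graph(g) else g
}

## ---- forward passes ------------------------------------------------------

# molecular encoder: graph convolutions + sum pooling; returns cache
encode_forward <- function(params, act, gt) {
  L <- length(params$enc)
  H <- vector("list", L + 1)
  P <- vector("list", L)
  H[[1]] <- gt$X
  AH <- NULL
  for (l in seq_len(L)) {
    w <- params$enc[[l]]
    P[[l]] <- H[[l]] %*% w$W_self + (gt$A %*% H[[l]]) %*% w$W_nb +
      gt$Binc %*% w$W_edge + matrix(w$b, nrow(gt$X), length(w$b), byrow = TRUE)
    H[[l + 1]] <- act$f(P[[l]])
  }
  f <- colSums(H[[L + 1]])
  list(H = H, P = P, f = f, gt = gt)
}

# two-node mixture graph convolution with self-loops
mix_forward <- function(params, act, f1, f2) {
  w <- params$mix
  pre1 <- drop(f1 %*% w$W_self + f2 %*% w$W_nb) + w$b
  pre2 <- drop(f2 %*% w$W_self + f1 %*% w$W_nb) + w$b
  list(pre1 = pre1, pre2 = pre2, c1 = act$f(pre1), c2 = act$f(pre2),
       f1 = f1, f2 = f2)
}

# shared SLP on [c_i ; x_i] with forward-mode dual channels in x1.
# Returns h x k matrices; component 1 carries dx_1/dx1 = +1, component 2 -1.
slp_forward <- function(params, act, c1, c2, xs, order = 1) {
  h <- length(c1); k <- length(xs)
  W <- params$slp$W
  Wc <- W[, seq_len(h), drop = FALSE]
  wx <- W[, h + 1]
  base1 <- drop(Wc %*% c1) + params$slp$b
  base2 <- drop(Wc %*% c2) + params$slp$b
  U1 <- matrix(base1, h, k) + outer(wx, xs)
  U2 <- matrix(base2, h, k) + outer(wx, 1 - xs)
  out <- list(U1 = U1, U2 = U2, S1 = act$f(U1), S2 = act$f(U2),
              xs = xs, wx = wx)
  if (order >= 1) {
    out$dphi1 <- act$df(U1); out$dphi2 <- act$df(U2)
    out$dS1 <- out$dphi1 * wx          # recycles wx down columns
    out$dS2 <- -(out$dphi2 * wx)
  }
  if (order >= 2) {
    out$d2S1 <- act$d2f(U1) * wx^2
    out$d2S2 <- act$d2f(U2) * wx^2
  }
  out
}

# MLP + linear readout on a stream of column vectors, with dual channels.
# Z: h x k; dZ/d2Z optional.
mlp_forward <- function(params, act, Z, dZ = NULL, d2Z = NULL) {
  layers <- vector("list", length(params$mlp))
  for (kk in seq_along(params$mlp)) {
    w <- params$mlp[[kk]]
    P <- w$W %*% Z + w$b
    lay <- list(P = P, Zin = Z, dZin = dZ, d2Zin = d2Z)
    dphi <- NULL
    if (!is.null(dZ)) {
      dphi <- act$df(P)
      Q <- w$W %*% dZ
      lay$Q <- Q
      if (!is.null(d2Z)) {
        Q2 <- w$W %*% d2Z
        d2Z <- act$d2f(P) * Q * Q + dphi * Q2
      }
      dZ <- dphi * Q
    }
    Z <- act$f(P)
    lay$Zout <- Z
    layers[[kk]] <- lay
  }
  g <- drop(crossprod(params$out$w, Z)) + params$out$b
  res <- list(layers = layers, Z = Z, g = g)
  if (!is.null(dZ)) res$dg <- drop(crossprod(params$out$w, dZ))
  if (!is.null(d2Z)) res$d2g <- drop(crossprod(params$out$w, d2Z))
  res$dZ <- dZ; res$d2Z <- d2Z
  res
}

# full GE forward for one mixture over a vector of compositions.
# order: 0 = gE only, 1 = + dgE/dx1, 2 = + d2gE/dx1^2
ge_forward <- function(model, gt1, gt2, xs, order = 1) {
  act <- activation_fns(model$config$activation)
  p <- model$params
  e1 <- encode_forward(p, act, gt1)
  e2 <- encode_forward(p, act, gt2)
  mx <- mix_forward(p, act, e1$f, e2$f)
  sl <- slp_forward(p, act, mx$c1, mx$c2, xs, order = order)
  M <- (sl$S1 + sl$S2) / 2
  dM <- if (order >= 1) (sl$dS1 + sl$dS2) / 2 else NULL
  d2M <- if (order >= 2) (sl$d2S1 + sl$d2S2) / 2 else NULL
  hd <- mlp_forward(p, act, M, dM, d2M)
  list(e1 = e1, e2 = e2, mx = mx, sl = sl, M = M, dM = dM, hd = hd,
       xs = xs, act = act,
       g = hd$g, dg = hd$dg, d2g = hd$d2g)
}

# direct-head forward: per-component streams through the shared MLP/readout.
# order 1 adds d ln gamma_i / dx1.
direct_forward <- function(model, gt1, gt2, xs, order = 0) {
  act <- activation_fns(model$config$activation)
  p <- model$params
  e1 <- encode_forward(p, act, gt1)
  e2 <- encode_forward(p, act, gt2)
  mx <- mix_forward(p, act, e1$f, e2$f)
  sl <- slp_forward(p, act, mx$c1, mx$c2, xs, order = order)
  hd1 <- mlp_forward(p, act, sl$S1, if (order >= 1) sl$dS1 else NULL)
  hd2 <- mlp_forward(p, act, sl$S2, if (order >= 1) sl$dS2 else NULL)
  list(e1 = e1, e2 = e2, mx = mx, sl = sl, hd1 = hd1, hd2 = hd2,
       xs = xs, act = act,
       lg1 = hd1$g, lg2 = hd2$g, dlg1 = hd1$dg, dlg2 = hd2$dg)
}

## ---- exported operations -------------------------------------------------

#' Encode a molecule into a fingerprint vector
#'
#' Graph convolutions followed by sum pooling; invariant to atom input order
#' and deterministic given the model parameters.
#'
#' @param model A `gegnn_model`.
#' @param graph A `molecule_graph` or SMILES string.
#' @return Numeric vector of length `hidden_dim`.
#' @export
encode_molecule <- function(model, graph) {
  stopifnot(inherits(model, "gegnn_model"))
  g <- as_graph(graph)
  if (ncol(g$atom_features) != atom_feature_dim()) {
    stop("atom feature dimension mismatch with model configuration",
         call. = FALSE)
  }
  act <- activation_fns(model$config$activation)
  encode_forward(model$params, act, graph_tensors(g))$f
}

#' One interaction step on the two-node mixture graph
#'
#' Swapping the two fingerprints swaps the outputs exactly (equivariance of
#' the symmetric two-node graph with self-loops).
#'
#' @param model A `gegnn_model`.
#' @param fp1,fp2 Molecular fingerprints from [encode_molecule()].
#' @return A list with `fp1_updated` and `fp2_updated`.
#' @export
mixture_interaction <- function(model, fp1, fp2) {
  stopifnot(inherits(model, "gegnn_model"),
            length(fp1) == model$config$hidden_dim,
            length(fp2) == model$config$hidden_dim)
  act <- activation_fns(model$config$activation)
  mx <- mix_forward(model$params, act, fp1, fp2)
  list(fp1_updated = mx$c1, fp2_updated = mx$c2)
}

#' Composition-aware permutation-invariant mixture fingerprint
#'
#' Each updated fingerprint is concatenated with its own mole fraction
#' (`x_1 = x1`, `x_2 = 1 - x1`), passed through a shared SLP with smooth
#' activation, and MEAN-pooled over the two components. The result is
#' invariant under the simultaneous swap (component 1 <-> 2,
#' `x1 <-> 1 - x1`).
#'
#' @param model A `gegnn_model`.
#' @param fp1_updated,fp2_updated Post-interaction fingerprints.
#' @param x1 Mole fraction of component 1, in `[0, 1]` (scalar).
#' @return Numeric vector of length `hidden_dim`.
#' @export
mixture_fingerprint <- function(model, fp1_updated, fp2_updated, x1) {
  stopifnot(inherits(model, "gegnn_model"), length(x1) == 1)
  check_x1(x1)
  act <- activation_fns(model$config$activation)
  sl <- slp_forward(model$params, act, fp1_updated, fp2_updated, x1, order = 0)
  drop((sl$S1 + sl$S2) / 2)
}

#' Predict the molar excess Gibbs energy gE/RT of a binary mixture
#'
#' The scalar network output; dimensionless, smooth in `x1`, and invariant
#' under the simultaneous component swap. Temperature is fixed at 298.15 K
#' and recorded for provenance only -- it is not a model input.
#'
#' @param model A `gegnn_model` with the `"ge"` head.
#' @param graph_1,graph_2 `molecule_graph`s or SMILES strings.
#' @param x1 Numeric vector of mole fractions in `[0, 1]`.
#' @param temperature Fixed at 298.15 (K); provenance only.
#' @return Numeric vector of gE/RT values, one per element of `x1`.
#' @examples
#' m <- gegnn_model(model_config(hidden_dim = 8, seed = 1))
#' predict_gE(m, "CCO", "O", c(0.25, 0.5, 0.75))
#' @export
predict_gE <- function(model, graph_1, graph_2, x1, temperature = 298.15) {
  stopifnot(inherits(model, "gegnn_model"))
  if (model$head != "ge") {
    stop("predict_gE() requires a model with the 'ge' head", call. = FALSE)
  }
  check_x1(x1)
  gt1 <- graph_tensors(as_graph(graph_1))
  gt2 <- graph_tensors(as_graph(graph_2))
  ge_forward(model, gt1, gt2, x1, order = 0)$g
}

#' Directly predict activity coefficients with the baseline head
#'
#' The two-output baseline ("direct") head predicts
#' `(ln gamma1, ln gamma2)` without the thermodynamic differential relation;
#' it is permutation-equivariant but has no built-in Gibbs-Duhem
#' consistency.
#'
#' @param model A `gegnn_model` with the `"direct"` head.
#' @inheritParams predict_gE
#' @return A tibble with columns `x1`, `ln_gamma_1`, `ln_gamma_2`.
#' @export
predict_direct <- function(model, graph_1, graph_2, x1, temperature = 298.15) {
  stopifnot(inherits(model, "gegnn_model"))
  if (model$head != "direct") {
    stop("predict_direct() requires a model with the 'direct' head",
         call. = FALSE)
  }
  check_x1(x1)
  gt1 <- graph_tensors(as_graph(graph_1))
  gt2 <- graph_tensors(as_graph(graph_2))
  fw <- direct_forward(model, gt1, gt2, x1, order = 0)
  tibble::tibble(x1 = x1, ln_gamma_1 = fw$lg1, ln_gamma_2 = fw$lg2)
}

#' Save / load a model or fit (exact round trip)
#'
#' Checkpoints are self-describing R serialisations of the configuration and
#' parameters; `load_gegnn(save_gegnn(m, path))` reproduces predictions
#' bit-for-bit.
#'
#' @param object A `gegnn_model` or `gegnn_fit`.
#' @param path File path.
#' @return `save_gegnn()` returns `path` invisibly; `load_gegnn()` the
#'   restored object.
#' @export
save_gegnn <- function(object, path) {
  stopifnot(inherits(object, c("gegnn_model", "gegnn_fit")))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_gegnn
#' @export
load_gegnn <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, c("gegnn_model", "gegnn_fit")))
  obj
}
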