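# shared fixtures: small model configs and datasets built in code

tiny_config <- function(seed = 1, hidden_dim = 8) {
  model_config(hidden_dim = hidden_dim, n_mol_conv_layers = 1,
               n_mlp_layers = 1, seed = seed)
}

tiny_dataset <- function(n_mixtures = 10, seed = 1, family = "margules2") {
  lib <- compound_library()
  generate_dataset(lib, n_mixtures = n_mixtures, seed = seed, family = family)
}

# independent central-difference derivative (test oracle only)
fd_deriv <- function(f, x, h = 1e-6) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# a few analytic models exercising all families and asymmetry
example_models <- function() {
  list(
    analytic_ge_model("margules2", c(A12 = 1.0, A21 = 1.0)),
    analytic_ge_model("margules2", c(A12 = 2.0, A21 = 0.8)),
    analytic_ge_model("van_laar", c(A12 = 1.5, A21 = 0.7)),
    analytic_ge_model("nrtl", c(tau12 = 1.2, tau21 = 0.5, alpha = 0.3))
  )
}
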