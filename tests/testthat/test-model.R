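test_that("non-smooth activations are rejected at configuration time", {
  expect_error(model_config(activation = "relu"), "smooth")
  expect_silent(model_config(activation = "silu", hidden_dim = 4))
})

test_that("molecular fingerprints are order-invariant and deterministic", {
  m <- gegnn_model(tiny_config())
  f1 <- encode_molecule(m, "CC(C)=O")
  f2 <- encode_molecule(m, "O=C(C)C")   # same molecule, different atom order
  expect_equal(f1, f2, tolerance = 1e-14)
  expect_identical(encode_molecule(m, "CCO"), encode_molecule(m, "CCO"))
  # distinct molecules -> distinct fingerprints for a random model
  expect_gt(max(abs(encode_molecule(m, "CCO") - encode_molecule(m, "O"))), 1e-6)
})

test_that("zeroed weights give a constant fingerprint", {
  m <- gegnn_model(tiny_config())
  m$params <- gegnn:::map_params(function(x) x * 0, m$params)
  f <- encode_molecule(m, "CCO")
  expect_equal(max(f) - min(f), 0)   # all hidden dims identical
})

test_that("mixture interaction is swap-equivariant and mixes information", {
  m <- gegnn_model(tiny_config())
  fa <- encode_molecule(m, "CCO")
  fb <- encode_molecule(m, "c1ccccc1")
  ab <- mixture_interaction(m, fa, fb)
  ba <- mixture_interaction(m, fb, fa)
  expect_equal(ab$fp1_updated, ba$fp2_updated, tolerance = 1e-15)
  expect_equal(ab$fp2_updated, ba$fp1_updated, tolerance = 1e-15)
  aa <- mixture_interaction(m, fa, fa)
  expect_equal(aa$fp1_updated, aa$fp2_updated, tolerance = 1e-15)
  # the neighbour message actually crosses the edge: one-step hand
  # computation on the two-node graph
  act <- activation_fns(m$config$activation)
  by_hand <- act$f(drop(fa %*% m$params$mix$W_self + fb %*% m$params$mix$W_nb) +
                     m$params$mix$b)
  expect_equal(ab$fp1_updated, by_hand, tolerance = 1e-14)
  expect_gt(max(abs(ab$fp1_updated - aa$fp1_updated)), 1e-8)
})

test_that("mixture fingerprint is invariant under the simultaneous swap", {
  m <- gegnn_model(tiny_config())
  fa <- encode_molecule(m, "CCO")
  fb <- encode_molecule(m, "CC(C)=O")
  up <- mixture_interaction(m, fa, fb)
  fp_ab <- mixture_fingerprint(m, up$fp1_updated, up$fp2_updated, 0.3)
  fp_ba <- mixture_fingerprint(m, up$fp2_updated, up$fp1_updated, 0.7)
  expect_equal(fp_ab, fp_ba, tolerance = 1e-15)
  # identical components: the pooled multiset is composition-symmetric
  fp_s1 <- mixture_fingerprint(m, up$fp1_updated, up$fp1_updated, 0.3)
  fp_s2 <- mixture_fingerprint(m, up$fp1_updated, up$fp1_updated, 0.7)
  expect_equal(fp_s1, fp_s2, tolerance = 1e-15)
  # equal inputs at x1 = 0.5: mean pooling reduces to the single SLP output
  act <- activation_fns(m$config$activation)
  h <- m$config$hidden_dim
  slp_one <- act$f(drop(m$params$slp$W %*% c(up$fp1_updated, 0.5)) +
                     m$params$slp$b)
  expect_equal(mixture_fingerprint(m, up$fp1_updated, up$fp1_updated, 0.5),
               slp_one, tolerance = 1e-14)
  expect_error(mixture_fingerprint(m, up$fp1_updated, up$fp2_updated, 1.2),
               "0, 1")
})

test_that("gE predictions are permutation-invariant and smooth in x1", {
  m <- gegnn_model(tiny_config(seed = 5))
  xs <- seq(0, 1, by = 0.125)
  expect_equal(predict_gE(m, "CCO", "O", xs),
               predict_gE(m, "O", "CCO", 1 - xs), tolerance = 1e-15)
  expect_true(all(is.finite(predict_gE(m, "CCO", "O", seq(0, 1, 0.01)))))

  # autodiff gradient vs central differences at x1 = 0.5 (step 1e-5)
  gfn <- model_gE_fn(m, "CCO", "O")
  ad <- attr(gfn, "grad")(0.5)
  fd <- (gfn(0.5 + 1e-5) - gfn(0.5 - 1e-5)) / 2e-5
  expect_lt(abs(ad - fd) / max(abs(fd), 1e-8), 1e-6)

  # property: agreement over interior grids for several random mixtures
  lib <- compound_library()
  pairs <- withr::with_seed(1, cbind(sample.int(50, 5), sample.int(50, 5)))
  grid <- seq(0.02, 0.98, length.out = 33)
  for (r in seq_len(nrow(pairs))) {
    if (pairs[r, 1] == pairs[r, 2]) next
    gfn <- model_gE_fn(m, lib$smiles[pairs[r, 1]], lib$smiles[pairs[r, 2]])
    ad <- attr(gfn, "grad")(grid)
    fd <- (gfn(grid + 1e-6) - gfn(grid - 1e-6)) / 2e-6
    expect_lt(max(abs(ad - fd) / pmax(abs(fd), 1e-3)), 1e-4)
  }
})

test_that("derived activity pairs swap exactly under relabeling", {
  m <- gegnn_model(tiny_config(seed = 2))
  f_ab <- model_activity_fn(m, "CCO", "CC#N")
  f_ba <- model_activity_fn(m, "CC#N", "CCO")
  xs <- c(0, 0.25, 0.5, 0.75, 1)
  ab <- f_ab(xs); ba <- f_ba(1 - xs)
  expect_lt(max(abs(ab$ln_gamma_1 - ba$ln_gamma_2)), 1e-13)
  expect_lt(max(abs(ab$ln_gamma_2 - ba$ln_gamma_1)), 1e-13)
})

test_that("checkpoints round-trip exactly", {
  m <- gegnn_model(tiny_config(seed = 9))
  path <- withr::local_tempfile(fileext = ".rds")
  save_gegnn(m, path)
  m2 <- load_gegnn(path)
  expect_identical(predict_gE(m, "CCO", "O", c(0.2, 0.8)),
                   predict_gE(m2, "CCO", "O", c(0.2, 0.8)))
})

test_that("parameter gradients match finite differences on a tiny model", {
  skip_if_not_installed("pracma")
  g1 <- smiles_to_graph("CCO"); g2 <- smiles_to_graph("O")
  gt1 <- gegnn:::graph_tensors(g1); gt2 <- gegnn:::graph_tensors(g2)
  m <- gegnn_model(model_config(hidden_dim = 4, n_mol_conv_layers = 1,
                                n_mlp_layers = 1, seed = 11))
  xs <- c(0, 0.4, 1); y1 <- c(0.8, 0.3, 0); y2 <- c(0, 0.1, 0.9)
  mx <- list(gt1 = gt1, gt2 = gt2, xs = xs, y1 = y1, y2 = y2,
             interior = xs > 0 & xs < 1)
  res <- gegnn:::mixture_step_ge(m, mx, length(xs))
  loss_of <- function(v) {
    mm <- m; mm$params <- utils::relist(v, m$params)
    fw <- gegnn:::ge_forward(mm, gt1, gt2, xs, order = 1)
    lg1 <- fw$g + (1 - xs) * fw$dg; lg2 <- fw$g - xs * fw$dg
    sum((lg1 - y1)^2 + (lg2 - y2)^2) / (2 * length(xs))
  }
  v0 <- unlist(m$params, use.names = FALSE)
  ng <- pracma::grad(loss_of, v0, heps = 1e-6)
  ag <- unlist(res$grads, use.names = FALSE)
  expect_lt(max(abs(ng - ag)), 1e-7)
})
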