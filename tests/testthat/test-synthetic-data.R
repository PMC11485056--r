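test_that("descriptor-to-parameter mapping has the required symmetries", {
  d_polar <- c(polarity = 0.8, size = 0.3)
  d_apolar <- c(polarity = 0.2, size = 0.6)

  m <- assign_ge_model(d_polar, d_apolar)
  m_sw <- assign_ge_model(d_apolar, d_polar)
  expect_equal(m$params$A12, m_sw$params$A21)
  expect_equal(m$params$A21, m_sw$params$A12)

  m_same <- assign_ge_model(d_polar, d_polar)
  expect_equal(m_same$params$A12, m_same$params$A21)
  expect_equal(m_same$params$A12, 0)   # zero polarity difference -> ideal

  iso <- assign_ge_model(c(polarity = 0.5, size = 0.2),
                         c(polarity = 0.5, size = 0.9))
  expect_equal(iso$params$A12, 0)      # size contrast alone stays ideal

  expect_error(assign_ge_model(d_polar, d_apolar, family = "wilson"),
               "unknown")

  nr <- assign_ge_model(d_polar, d_apolar, family = "nrtl")
  nr_sw <- assign_ge_model(d_apolar, d_polar, family = "nrtl")
  expect_equal(nr$params$tau12, nr_sw$params$tau21)
  expect_equal(nr$params$alpha, nr_sw$params$alpha)
})

test_that("pair-keyed noise preserves the swap property", {
  d1 <- c(polarity = 0.8, size = 0.3)
  d2 <- c(polarity = 0.2, size = 0.6)
  m <- assign_ge_model(d1, d2, seed = 5, noise_sd = 0.2, pair_key = "A|B")
  m_sw <- assign_ge_model(d2, d1, seed = 5, noise_sd = 0.2, pair_key = "B|A")
  expect_equal(m$params$A12, m_sw$params$A21)
  expect_equal(m$params$A21, m_sw$params$A12)
})

test_that("closed forms match hand-computed Margules values", {
  m <- analytic_ge_model("margules2", c(A12 = 1, A21 = 1))
  lg <- analytic_lngamma(m, 0.5)
  expect_equal(lg$ln_gamma_1, 0.25)
  expect_equal(lg$ln_gamma_2, 0.25)

  m2 <- analytic_ge_model("margules2", c(A12 = 2, A21 = 1))
  expect_equal(analytic_lngamma(m2, 0)$ln_gamma_1, 2)   # infinite dilution
  expect_equal(analytic_lngamma(m2, 1)$ln_gamma_1, 0)   # pure-component limit
  expect_equal(analytic_lngamma(m2, 0)$ln_gamma_2, 0)
})

test_that("pure-component gE limits vanish for every family", {
  for (m in example_models()) {
    expect_equal(analytic_gE(m, 0), 0)
    expect_equal(analytic_gE(m, 1), 0)
  }
})

test_that("generated datasets have the documented shape and determinism", {
  lib <- compound_library()
  d <- generate_dataset(lib, n_mixtures = 10, seed = 3)
  expect_equal(nrow(d), 70)   # 10 mixtures x 7-point grid
  expect_equal(sort(unique(d$x1)), c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1))
  expect_equal(d$is_infinite_dilution, d$x1 %in% c(0, 1))
  # boundary labels: the pure component's ln gamma is exactly 0
  expect_true(all(d$ln_gamma_2[d$x1 == 0] == 0))
  expect_true(all(d$ln_gamma_1[d$x1 == 1] == 0))

  d2 <- generate_dataset(lib, n_mixtures = 10, seed = 3)
  expect_identical(d, d2)     # same seed -> identical dataset
  d3 <- generate_dataset(lib, n_mixtures = 10, seed = 4)
  expect_false(identical(d$smiles_1, d3$smiles_1))
})

test_that("requesting too many or duplicate pairs is handled", {
  lib <- compound_library()[1:4, ]
  expect_error(generate_dataset(lib, n_mixtures = 7), "exceeds")
  expect_warning(
    d <- generate_dataset(lib, pairs = rbind(c(1, 2), c(2, 1), c(3, 4))),
    "duplicate")
  expect_equal(length(unique(d$mixture_id)), 2)
})

test_that("every generated record is Gibbs-Duhem consistent", {
  d <- tiny_dataset(n_mixtures = 5, seed = 2, family = "nrtl")
  mods <- attr(d, "ge_models")
  for (m in seq_along(mods)) {
    afn <- analytic_activity_fn(mods[[m]])
    xs <- d$x1[d$mixture_id == m]
    xs <- xs[xs > 0 & xs < 1]
    expect_lt(max(abs(gibbs_duhem_residual(afn, xs))), 1e-8)
  }
})

test_that("swapping all pairs mirrors the labels", {
  lib <- compound_library()
  pairs <- rbind(c(1, 20), c(5, 30))
  d <- generate_dataset(lib, pairs = pairs, seed = 1)
  d_sw <- generate_dataset(lib, pairs = pairs[, 2:1], seed = 1)
  for (m in unique(d$mixture_id)) {
    a <- d[d$mixture_id == m, ]
    b <- d_sw[d_sw$mixture_id == m, ]
    # record of (j, i) at 1 - x1 carries the exchanged labels
    b_m <- b[match(round(1 - a$x1, 10), round(b$x1, 10)), ]
    expect_equal(a$ln_gamma_1, b_m$ln_gamma_2, tolerance = 1e-12)
    expect_equal(a$ln_gamma_2, b_m$ln_gamma_1, tolerance = 1e-12)
  }
})

test_that("mixture CSV schema round-trips", {
  d <- tiny_dataset(n_mixtures = 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mixture_csv(d, path)
  back <- read_mixture_csv(path)
  expect_equal(back$ln_gamma_1, d$ln_gamma_1, tolerance = 1e-12)
  expect_equal(back$is_infinite_dilution, d$is_infinite_dilution)
})
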