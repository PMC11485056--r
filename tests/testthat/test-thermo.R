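test_that("activity_from_gE reproduces hand-derived Margules values", {
  ideal <- function(x1) rep(0, length(x1))
  out <- activity_from_gE(ideal, c(0, 0.3, 1))
  expect_equal(out$ln_gamma_1, rep(0, 3))
  expect_equal(out$ln_gamma_2, rep(0, 3))

  # one-parameter Margules gE/RT = A x1 x2, A = 1:
  # ln gamma1 = A x2^2, ln gamma2 = A x1^2 (derived symbolically)
  m1 <- function(x1) x1 * (1 - x1)
  attr(m1, "grad") <- function(x1) 1 - 2 * x1
  mid <- activity_from_gE(m1, 0.5)
  expect_equal(mid$gE_RT, 0.25)
  expect_equal(mid$dgE_dx1, 0)
  expect_equal(mid$ln_gamma_1, 0.25)
  expect_equal(mid$ln_gamma_2, 0.25)

  bdry <- activity_from_gE(m1, 0)   # infinite dilution of component 1
  expect_equal(bdry$ln_gamma_1, 1)
  expect_equal(bdry$ln_gamma_2, 0)
})

test_that("reconstruct_gE inverts activity_from_gE to machine precision", {
  set.seed(42)
  for (rep in 1:5) {
    a <- stats::rnorm(3)
    g <- function(x1) x1 * (1 - x1) * (a[1] + a[2] * x1 + a[3] * x1^2)
    attr(g, "grad") <- function(x1) {
      (1 - 2 * x1) * (a[1] + a[2] * x1 + a[3] * x1^2) +
        x1 * (1 - x1) * (a[2] + 2 * a[3] * x1)
    }
    xs <- seq(0, 1, length.out = 21)
    pair <- activity_from_gE(g, xs)
    expect_lt(max(abs(reconstruct_gE(pair) - g(xs))), 1e-12)
    # ln gamma1 - ln gamma2 = dgE/dx1 identity
    expect_lt(max(abs((pair$ln_gamma_1 - pair$ln_gamma_2) - attr(g, "grad")(xs))),
              1e-12)
  }
})

test_that("closed-form oracle equivalence holds for all three families", {
  xs <- seq(0.01, 0.99, length.out = 99)
  for (m in example_models()) {
    derived <- activity_from_gE(analytic_gE_fn(m), xs)
    closed <- analytic_lngamma(m, xs)
    expect_lt(max(abs(derived$ln_gamma_1 - closed$ln_gamma_1)), 1e-10)
    expect_lt(max(abs(derived$ln_gamma_2 - closed$ln_gamma_2)), 1e-10)
  }
})

test_that("symbolic gE derivatives agree with finite differences", {
  xs <- c(0.1, 0.37, 0.62, 0.9)
  for (m in example_models()) {
    fd <- fd_deriv(function(x) analytic_gE(m, x), xs)
    expect_lt(max(abs(analytic_dgE_dx1(m, xs) - fd)), 1e-7)
  }
})

test_that("Gibbs-Duhem residuals flag inconsistency and pass consistency", {
  toy <- function(x1) cbind(ln_gamma_1 = x1, ln_gamma_2 = x1)
  expect_equal(gibbs_duhem_residual(toy, 0.5), 1, tolerance = 1e-7)
  expect_equal(gd_rmse(toy, 0.5), 1, tolerance = 1e-7)

  const <- function(x1) cbind(ln_gamma_1 = rep(0.7, length(x1)),
                              ln_gamma_2 = rep(-0.2, length(x1)))
  expect_lt(gd_rmse(const, c(0.2, 0.5, 0.8)), 1e-9)

  nrtl <- analytic_activity_fn(
    analytic_ge_model("nrtl", c(tau12 = 1, tau21 = 1.5, alpha = 0.3)))
  expect_lt(abs(gibbs_duhem_residual(nrtl, 0.5)), 1e-8)

  # consistent-by-construction: any smooth gE yields zero residual
  g <- function(x1) sin(2 * x1) * x1 * (1 - x1)
  attr(g, "grad") <- function(x1) {
    2 * cos(2 * x1) * x1 * (1 - x1) + sin(2 * x1) * (1 - 2 * x1)
  }
  afn <- function(x1) {
    p <- activity_from_gE(g, x1)
    cbind(p$ln_gamma_1, p$ln_gamma_2)
  }
  expect_lt(abs(gibbs_duhem_residual(afn, 0.37)), 1e-6)
})

test_that("residual audits are defined at interior compositions only", {
  toy <- function(x1) cbind(x1, x1)
  expect_error(gibbs_duhem_residual(toy, c(0.5, 1)), "interior")
  expect_error(gd_rmse(toy, numeric(0)), "nonempty")
})

test_that("component relabeling preserves residual magnitude", {
  m <- analytic_ge_model("margules2", c(A12 = 1.8, A21 = 0.6))
  f12 <- analytic_activity_fn(m)
  m_sw <- analytic_ge_model("margules2", c(A12 = 0.6, A21 = 1.8))
  f21 <- analytic_activity_fn(m_sw)
  # swapped function audited at 1 - x1, with components exchanged
  f21_relabel <- function(x1) {
    v <- as.matrix(as.data.frame(f21(1 - x1)))
    cbind(v[, 2], v[, 1])
  }
  xs <- c(0.15, 0.5, 0.85)
  r1 <- gibbs_duhem_residual(f12, xs)
  r2 <- gibbs_duhem_residual(f21_relabel, xs)
  expect_equal(abs(r1), abs(r2), tolerance = 1e-6)
})
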