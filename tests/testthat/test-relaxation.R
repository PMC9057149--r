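test_that("physical constants convert gyromagnetic ratios to angular units", {
  k <- physical_constants()
  expect_equal(k$gamma_c, 2 * pi * 1e6 * 10.7084)
  expect_equal(k$gamma_h, 2 * pi * 1e6 * 42.577)
  expect_equal(k$omega_c, 2 * pi * 125.758e6)
  expect_error(physical_constants(B0 = -1), "positive")
})

test_that("S^2 combines anisotropy and asymmetry as (dd)^2 (1 + eta^2/3)", {
  m <- relaxation_model(anisotropy = 171.1, asymmetry = 0.2)
  expect_equal(m$s2_ppm2, 171.1^2 * (1 + 0.2^2 / 3))  # 29665.5 ppm^2
  expect_equal(relaxation_model(s2_ppm2 = 123)$s2_ppm2, 123)
})

test_that("CSA rate is linear in tau2 at extreme narrowing and peaks at 1/omega", {
  m <- relaxation_model(anisotropy = 100, asymmetry = 0.5)
  w <- m$constants$omega_c
  a <- (2 / 15) * w^2 * m$s2_ppm2 * 1e-12
  expect_equal(r1_csa(1e-15, m), a * 1e-15, tolerance = 1e-9)
  # dense scan: single interior maximum at tau2 = 1/omega
  tau <- 10^seq(-12, -3, length.out = 400)
  r <- r1_csa(tau, m)
  expect_equal(tau[which.max(r)], 1 / w, tolerance = 0.05)
  expect_equal(sum(diff(sign(diff(r))) != 0), 1)  # one turning point
  expect_error(r1_csa(-1e-9, m), "positive")
})

test_that("dipolar rate obeys the r^-6 law and an independent evaluation", {
  k <- physical_constants()
  m1 <- relaxation_model(pairs = list(dipolar_pair("H", 1.09)),
                         constants = k)
  m2 <- relaxation_model(pairs = list(dipolar_pair("H", 2.18)),
                         constants = k)
  tau <- 1e-5
  expect_equal(r1_dipolar(tau, m2), r1_dipolar(tau, m1) / 64,
               tolerance = 1e-12)

  # independent arithmetic evaluation of the same physical expression
  gc <- 2 * pi * 1e6 * 10.7084
  gh <- 2 * pi * 1e6 * 42.577
  wc <- gc * 11.74
  wh <- gh * 11.74
  d <- 1e-7 * 1.054e-34 * gc * gh / (1.09e-10)^3
  jj <- function(w) tau / (1 + (w * tau)^2)
  expected <- d^2 / 10 * (jj(wh - wc) + 3 * jj(wc) + 6 * jj(wh + wc))
  expect_equal(r1_dipolar(tau, m1), expected, tolerance = 1e-12)

  # no partners: zero for any correlation time
  m0 <- relaxation_model(anisotropy = 50)
  expect_equal(r1_dipolar(c(1e-9, 1e-5, 1e-3), m0), c(0, 0, 0))

  # first-term-only mode keeps just the difference-frequency density
  mf <- relaxation_model(pairs = list(dipolar_pair("H", 1.09)),
                         constants = k, spectral_density = "first_term_only")
  expect_equal(r1_dipolar(tau, mf), d^2 / 10 * jj(wh - wc),
               tolerance = 1e-12)
})

test_that("total rate vanishes at both tau extremes with one interior peak", {
  m <- relaxation_model(anisotropy = 100, asymmetry = 0.3,
                        pairs = list(dipolar_pair("H", 1.09)))
  tau <- 10^seq(-15, -1, length.out = 500)
  r <- r1_total(tau, m)
  expect_lt(r[1], 1e-4 * max(r))
  expect_lt(r[length(r)], 1e-4 * max(r))
  expect_equal(sum(diff(sign(diff(r))) != 0), 1)
})

test_that("T1 fit is exact on noiseless decays across the working range", {
  for (t1 in c(1, 5, 20, 97, 190, 321, 500)) {
    d <- default_delays(t1)
    f <- fit_t1(d, 0.8 * exp(-d / t1))
    expect_equal(f$t1, t1, tolerance = 1e-6)
    expect_equal(f$m0, 0.8, tolerance = 1e-6)
  }
})

test_that("T1 fit fails loudly on non-decaying or malformed data", {
  d <- c(1, 5, 10, 50, 100)
  expect_error(fit_t1(d, rep(1, 5)), "fit failure")
  expect_error(fit_t1(d, exp(d / 100)), "fit failure")
  expect_error(fit_t1(c(1, 2, 3), c(1, 0.5, 0.2)), "at least 4")
  expect_error(fit_t1(c(1, 2, 2, 4), c(1, 0.9, 0.8, 0.7)), "increasing")
})

test_that("forward T1 then inversion recovers tau_c on the right branch", {
  set.seed(20)
  n_ok <- 0
  for (i in 1:100) {
    m <- relaxation_model(
      s2_ppm2 = 10^runif(1, 2, 4.7),
      pairs = if (runif(1) < 0.5) list() else
        rep(list(dipolar_pair("H", runif(1, 1.0, 3.0))),
            sample(1:3, 1)))
    tau_true <- 10^runif(1, -9, -3)
    t1 <- 1 / r1_total(tau_true, m)
    res <- invert_tau_c(t1, m)
    rec <- if (tau_true >= res$tau_peak) res$tau_c else res$tau_c_fast
    expect_lt(abs(rec - tau_true) / tau_true, 1e-6)
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 100)
})

test_that("CSA-only inversion matches the closed-form quadratic solution", {
  m <- relaxation_model(anisotropy = 171.1, asymmetry = 0.2)
  w <- m$constants$omega_c
  a <- (2 / 15) * w^2 * m$s2_ppm2 * 1e-12
  t1 <- 190
  target <- 1 / t1
  disc <- sqrt(a^2 - 4 * target^2 * w^2)
  tau2_fast <- (a - disc) / (2 * target * w^2)
  tau2_slow <- (a + disc) / (2 * target * w^2)
  res <- invert_tau_c(t1, m)
  expect_equal(res$tau_c, 3 * tau2_slow, tolerance = 1e-9)
  expect_equal(res$tau_c_fast, 3 * tau2_fast, tolerance = 1e-9)
  # extreme narrowing: the fast root approaches the linear form R1/a
  t1_long <- 1e6
  res2 <- invert_tau_c(t1_long, m)
  expect_equal(res2$tau_c_fast, 3 / (t1_long * a), tolerance = 1e-6)
})

test_that("infeasible T1 reports the maximum achievable rate", {
  m <- relaxation_model(anisotropy = 20, asymmetry = 0)
  expect_error(invert_tau_c(1e-3, m), "infeasible T1")
  expect_error(invert_tau_c(-5, m), "t1 must be > 0")
})

test_that("contribution fractions sum to one and follow the model content", {
  m_csa <- relaxation_model(anisotropy = 100, asymmetry = 0.2)
  res <- invert_tau_c(200, m_csa)
  expect_equal(contribution_report(res), c(csa = 1, dipolar = 0))

  m_dd <- relaxation_model(s2_ppm2 = 0,
                           pairs = list(dipolar_pair("H", 1.09)))
  res_dd <- invert_tau_c(200, m_dd)
  expect_equal(contribution_report(res_dd), c(csa = 0, dipolar = 1))

  m_mix <- relaxation_model(anisotropy = 100, asymmetry = 0.2,
                            pairs = list(dipolar_pair("H", 1.09)))
  res_mix <- invert_tau_c(200, m_mix)
  fr <- contribution_report(res_mix)
  expect_equal(sum(fr), 1)
  rc <- r1_csa(res_mix$tau_c / 3, m_mix)
  rd <- r1_dipolar(res_mix$tau_c, m_mix)
  expect_equal(unname(fr["csa"]), rc / (rc + rd))
})
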