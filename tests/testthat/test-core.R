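test_that("temperature correction is normalised, damped above T_H, monotone", {
  p <- default_pars
  expect_identical(temp_correction(p$T_ref, p), 1)
  # frozen values from direct arithmetic evaluation of the closed form
  expect_equal(temp_correction(288.15, p), 0.6992858, tolerance = 1e-6)
  expect_equal(temp_correction(303.15, p), 1.6783160, tolerance = 1e-6)
  # at 30 degC the upper-boundary term damps the pure Arrhenius factor
  pure <- exp(p$T_A / p$T_ref - p$T_A / 303.15)
  expect_equal(pure, 2.05937, tolerance = 1e-4)
  expect_lt(temp_correction(303.15, p), pure)
  # strictly increasing across the working thermal range
  grid <- temp_correction(seq(283.15, 303.15, by = 0.25), p)
  expect_true(all(diff(grid) > 0))
  expect_error(temp_correction(NaN, p), "finite")
  expect_error(temp_correction(250, p), "validity window")
})

test_that("Holling type II functional response", {
  expect_equal(functional_response(2, 2), 0.5)
  expect_equal(functional_response(0, 1), 0)
  expect_equal(functional_response(3, 1), 0.75)
  x <- seq(0, 50, by = 0.5)
  expect_true(all(diff(functional_response(x, 3)) > 0))
  expect_true(all(functional_response(x, 3) < 1))
  expect_error(functional_response(-1, 1), "non-negative")
  expect_error(functional_response(1, 0), "positive")
})

test_that("acceleration factor clamps at 1 and at L_p/L_b", {
  Lb <- 0.008; Lp <- 0.038
  expect_equal(acceleration_factor(0.5 * Lb, Lb, Lp), 1)
  expect_equal(acceleration_factor(2 * Lp, Lb, Lp), Lp / Lb)
  mid <- (Lb + Lp) / 2
  expect_equal(acceleration_factor(mid, Lb, Lp), (1 + Lp / Lb) / 2)
  L <- seq(0, 0.06, by = 0.001)
  expect_true(all(diff(acceleration_factor(L, Lb, Lp)) >= 0))
  expect_error(acceleration_factor(0.01, 0, Lp), "positive")
  expect_error(acceleration_factor(0.01, Lp, Lb), "L_p")
})

test_that("kappa-rule fluxes conserve mobilised energy to machine precision", {
  p <- default_pars
  set.seed(7)
  stages <- c("EMBRYO", "L1", "L2", "L3", "L4_PHASE1", "PUPA")
  for (i in 1:60) {
    st <- list(E = runif(1, 1e-4, 50), V = 10^runif(1, -7, -3),
               E_H = runif(1, 1e-4, 1),
               stage = sample(stages, 1), s_M = runif(1, 1, 4.7))
    fx <- deb_fluxes(st, f = runif(1, 0, 1.5), p,
                     c_T = runif(1, 0.5, 1.7))
    gap <- abs(fx$p_C - (fx$p_S + fx$p_G + fx$p_J + fx$p_R))
    expect_lt(gap, 1e-12 * fx$p_C)
  }
})

test_that("non-feeding stages assimilate nothing", {
  p <- default_pars
  for (stage in c("EMBRYO", "PUPA", "IMAGO")) {
    st <- list(E = 1, V = 1e-4, E_H = 0.1, stage = stage, s_M = 2)
    expect_identical(deb_fluxes(st, f = 1, p)$p_A, 0)
  }
})

test_that("weak homeostasis: at e = f the reserve density is stationary", {
  p <- default_pars
  Em <- reserve_capacity(p)
  for (f in c(0.4, 1)) {
    # V1-morphic immature larva: s_M = L / L_b
    Lb <- 0.0084
    V <- 1e-5
    sM <- V^(1 / 3) / Lb
    st <- list(E = f * Em * V, V = V, E_H = 0.05, stage = "L2", s_M = sM)
    fx <- deb_fluxes(st, f = f, p)
    dE <- fx$p_A - fx$p_C
    dV <- fx$p_G / p$E_G
    # d(E/V)/dt = (dE - (E/V) dV)/V = 0
    expect_equal(dE, f * Em * dV, tolerance = 1e-10)
    # isomorphic L4 Phase I with frozen s_M
    st <- list(E = f * Em * 2e-4, V = 2e-4, E_H = p$E_Hp,
               stage = "L4_PHASE1", s_M = 4.5)
    fx <- deb_fluxes(st, f = f, p)
    expect_equal(fx$p_A - fx$p_C, f * Em * fx$p_G / p$E_G,
                 tolerance = 1e-10)
  }
})

test_that("Phase II and imago override the kappa rule as specified", {
  p <- default_pars
  st <- list(E = 5, V = 9e-4, E_H = p$E_Hp, stage = "L4_PHASE2", s_M = 4.5)
  fx <- deb_fluxes(st, f = 0.5, p)
  expect_identical(fx$p_G, 0)
  expect_equal(fx$p_C, fx$p_S + fx$p_J)
  expect_identical(fx$p_R, 0)
  st <- list(E = 40, V = 8e-4, E_H = p$E_He, stage = "IMAGO", s_M = 4.5)
  fx <- deb_fluxes(st, f = 0, p, c_T = 1.2)
  expect_equal(fx$p_C, 40 * p$v * 1.2 * 4.5 / (8e-4)^(1 / 3))
  expect_equal(fx$p_R, fx$p_C - fx$p_S - fx$p_J)
  expect_identical(fx$p_G, 0)
})

test_that("degenerate flux inputs are rejected", {
  p <- default_pars
  expect_error(deb_fluxes(list(E = 1, V = 1e-4, E_H = 0.1, stage = "LARVA"),
                          1, p), "unknown stage")
  expect_error(deb_fluxes(list(E = 1, V = 0, E_H = 1, stage = "IMAGO",
                               s_M = 4), 1, p), "positive structural volume")
  expect_error(deb_fluxes(list(E = 1, V = 1e-4, E_H = 0.1, stage = "L1"),
                          -0.5, p), "non-negative")
})
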