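test_that("egg reserve shooting hits the birth event with full reserve", {
  p <- default_pars
  ir <- initial_reserve(p, T_c = 21)
  # birth is defined by maturity reaching E_Hb
  expect_lt(abs(ir$state_at_birth[["E_H"]] - p$E_Hb) / p$E_Hb, 1e-6)
  # abundant-food maternal condition: scaled reserve density 1 at birth
  expect_lt(abs(ir$e_b - 1), 1e-6)
  # the embryo spends reserve and cannot assimilate
  expect_lt(ir$state_at_birth[["E"]], ir$E_0)
  expect_gt(ir$age_at_birth, 1)
  expect_lt(ir$age_at_birth, 6)
})

test_that("life-history events are ordered and their triggers exact", {
  lc <- baseline_sim()
  r <- lc$report
  expect_identical(r$status, "completed")
  ev <- c(0, r$t_molt1, r$t_molt2, r$t_puberty, r$t_phase_switch,
          r$t_emergence)
  expect_true(all(diff(ev) > 0))
  expect_gte(r$t_pupation, r$t_phase_switch)
  expect_true(r$L_b <= r$L_p && r$L_p <= r$L_j)
  # trigger residuals at the located events
  p <- default_pars
  expect_lt(abs(r$states$puberty[["E_H"]] - p$E_Hp) / p$E_Hp, 1e-6)
  sw <- r$states$phase_switch
  expect_lt(abs(sw[["E_R"]] / sw[["V"]] - p$E_Rj) / p$E_Rj, 1e-6)
  em <- r$states$emergence
  expect_lt(abs(em[["E_H"]] - p$E_He) / p$E_He, 1e-6)
  # at abundant food the reserve density is already at capacity when
  # Phase II starts, so its duration collapses to zero
  expect_lt(r$t_pupation - r$t_phase_switch, 0.05)
  pu <- r$states$pupation
  expect_gte(pu[["E"]] / pu[["V"]], reserve_capacity(p) * (1 - 1e-6))
})

test_that("maturity and the reproduction buffer freeze when they should", {
  lc <- baseline_sim()
  p <- default_pars
  tr <- lc$trajectory
  l4 <- tr[tr$stage %in% c("L4_PHASE1", "L4_PHASE2"), ]
  # E_H stays at E_Hp throughout the fourth instar
  expect_lt(max(abs(l4$EH_J - p$E_Hp)) / p$E_Hp, 1e-9)
  # E_R is constant from the phase switch through emergence
  late <- tr[tr$stage %in% c("L4_PHASE2", "PUPA", "IMAGO"), ]
  er0 <- lc$report$E_R_at_pupation
  expect_lt(max(abs(late$ER_J - er0)) / er0, 1e-9)
})

test_that("pupation converts structure to reserve and keeps the buffer", {
  p <- default_pars
  st <- list(E = 28, V = 9.7e-4, E_R = 5.2, s_M = 4.5)
  ps <- pupation_transition(st, p, V_seed = 1e-8)
  expect_identical(ps$E_R, st$E_R)
  expect_identical(ps$E_H, 0)
  expect_identical(ps$stage, "PUPA")
  gain <- ps$E - st$E
  expect_equal(gain, p$kap_V * p$E_G * st$V)
  expect_lt(gain, 1e-5 * p$E_G * st$V)
  # maturity is rebuilt from zero up to E_He during the pupal stage
  lc <- baseline_sim()
  pup <- lc$trajectory[lc$trajectory$stage == "PUPA", ]
  expect_lt(pup$EH_J[1], 1e-6)
  expect_true(all(diff(pup$EH_J) >= 0))
})

test_that("egg number is linear in structure and rejects bad input", {
  p <- default_pars
  n1 <- egg_number(p, 1e-3, 0.02)
  n2 <- egg_number(p, 2e-3, 0.02)
  expect_equal(n2$N_i, 2 * n1$N_i)
  expect_equal(n1$N_i, p$kap_R * p$E_Rj * 1e-3 / 0.02)
  expect_identical(n1$N_i_floor, floor(n1$N_i))
  expect_error(egg_number(p, 1e-3, 0), "positive")
})

test_that("emergence age is insensitive to the pupal seed structure", {
  lc1 <- baseline_sim()
  lc2 <- deb_lifecycle(default_pars, deb_scenario(T_c = 21, f = 1),
                       V_seed = 5e-9)
  rel <- abs(lc2$report$t_emergence - lc1$report$t_emergence) /
    lc1$report$t_emergence
  expect_lt(rel, 0.005)
})

test_that("development responds monotonically to food and temperature", {
  fs <- c(0.5, 0.75, 1)
  sims <- lapply(fs, function(f) baseline_sim(f = f)$report)
  tj <- vapply(sims, `[[`, numeric(1), "t_pupation")
  ni <- vapply(sims, `[[`, numeric(1), "N_i")
  te <- vapply(sims, `[[`, numeric(1), "t_emergence")
  expect_true(all(diff(tj) < 0))   # pupation earlier at better food
  expect_true(all(diff(te) < 0))
  expect_true(all(diff(ni) > 0))   # more eggs at better food
  temps <- c(15, 21, 27)
  tem <- vapply(temps, function(T_c) baseline_sim(T_c = T_c)$report$t_emergence,
                numeric(1))
  expect_true(all(diff(tem) < 0))  # faster development when warmer
})

test_that("immature larva grows as a V1-morph (exponential structure)", {
  lc <- baseline_sim()
  tr <- lc$trajectory
  imm <- tr[tr$stage %in% c("L1", "L2", "L3"), ]
  tb <- imm$t_d - lc$report$age_at_birth
  keep <- tb > 0.5          # discard the short post-hatch transient
  fit <- stats::lm(log(imm$V_cm3[keep]) ~ tb[keep])
  expect_lt(max(abs(stats::residuals(fit))), 0.01)
})

test_that("fixed-step RK4 oracle reproduces the adaptive event ages", {
  p <- default_pars
  cT <- temp_correction(294.15, p)
  ir <- initial_reserve(p, T_c = 21)
  # embryo: integrate E, V, E_H to the birth threshold at step 1e-4 d
  deriv_emb <- function(t, y) {
    k <- chirodeb:::flux_kernel(y[1], max(y[2], 0), y[3], 1L, 1, 0, p, cT)
    c(k[[1]] - k[[2]], k[[4]] / p$E_G, k[[6]])
  }
  oracle <- rk4_until(c(ir$E_0, 1e-12, 0), deriv_emb, p$E_Hb, 3L)
  expect_lt(abs(oracle$t - ir$age_at_birth) / ir$age_at_birth, 1e-3)
  # immature larva to puberty
  lc <- baseline_sim()
  Lb <- lc$report$L_b
  deriv_imm <- function(t, y) {
    sM <- max(1, y[2]^(1 / 3) / Lb)
    k <- chirodeb:::flux_kernel(y[1], y[2], y[3], 2L, sM, 1, p, cT)
    c(k[[1]] - k[[2]], k[[4]] / p$E_G, k[[6]])
  }
  y0 <- c(ir$state_at_birth[["E"]], ir$state_at_birth[["V"]], p$E_Hb)
  oracle <- rk4_until(y0, deriv_imm, p$E_Hp, 3L, t_max = 12)
  expect_lt(abs(oracle$t - lc$report$t_puberty) / lc$report$t_puberty, 1e-3)
})

test_that("instar partition pins the L3->L4 molt at puberty", {
  lc <- baseline_sim()
  r <- lc$report
  ib <- instar_boundaries(lc)
  durs <- c(ib$duration, r$t_puberty - ib$age_since_birth[2])
  # endpoint constraint: instar durations sum to the age at puberty
  expect_equal(sum(durs), r$t_puberty, tolerance = 1e-6)
  # equal molt constants give equal threshold ratios, so the first two
  # instars last (nearly) equally long under exponential growth
  expect_equal(durs[1], durs[2], tolerance = 0.02)
  # interpolated boundaries agree with the root-located molt times
  expect_equal(ib$age_since_birth[1], r$t_molt1, tolerance = 1e-3)
  expect_equal(ib$age_since_birth[2], r$t_molt2, tolerance = 1e-3)
  # the volume-ratio mapping puts the second threshold beyond the puberty
  # length for this parameter set and must be rejected
  expect_error(instar_boundaries(lc, rule = "length"), "outside")
})

test_that("survival decomposes into background and starvation hazards", {
  p <- default_pars
  lc <- baseline_sim()
  cT <- lc$c_T
  tr <- lc$trajectory
  # abundant food: background hazard only, S = exp(-h_b t) since hatch
  i <- max(which(tr$stage == "L4_PHASE1"))
  t_since_birth <- tr$t_d[i] - lc$report$age_at_birth
  expect_equal(tr$survival[i], exp(-p$h_b * cT * t_since_birth),
               tolerance = 1e-6)
  expect_true(all(diff(tr$survival) <= 1e-12))
  expect_equal(tr$survival[tr$stage == "EMBRYO"][1], 1)
  # food deprivation: faster decay than background once reserve runs out
  starv <- deb_lifecycle(p, deb_scenario(T_c = 21, f = 0, horizon = 25))
  expect_false(starv$report$status == "completed")
  st <- starv$trajectory
  j <- nrow(st)
  tb <- st$t_d[j] - starv$report$age_at_birth
  expect_lt(st$survival[j], exp(-p$h_b * cT * tb) - 1e-4)
})

test_that("unreachable triggers end with an explicit status, not an error", {
  lc <- deb_lifecycle(default_pars,
                      deb_scenario(T_c = 21, f = 0.08, horizon = 60))
  expect_identical(lc$report$status, "pupation_not_reached")
  expect_true(is.na(lc$report$t_pupation))
  expect_true(is.na(lc$report$N_i))
  # trajectory still runs to the horizon
  expect_gt(max(lc$trajectory$t_d), 59)
  # and too short a horizon stops before puberty
  early <- deb_lifecycle(default_pars,
                         deb_scenario(T_c = 21, f = 1, horizon = 8))
  expect_identical(early$report$status, "puberty_not_reached")
})

test_that("males develop with the reduced assimilation ceiling", {
  f_lc <- baseline_sim()
  m_lc <- baseline_sim(sex = "male")
  expect_identical(m_lc$report$status, "completed")
  # lower [Em] target and lower assimilation: later pupation, fewer eggs
  expect_gt(m_lc$report$t_pupation, f_lc$report$t_pupation)
})
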