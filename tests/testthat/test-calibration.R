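test_that("symmetric bounded loss has the stated algebra", {
  expect_identical(sb_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(sb_loss(1, 3), 0.4)                       # (1-3)^2/(1+9)
  expect_identical(sb_loss(1, 3), sb_loss(3, 1))         # symmetry
  expect_equal(sb_loss(1, 3), sb_loss(7, 21))            # scale invariance
  expect_identical(sb_loss(0, 0), 0)                     # 0/0 defined as 0
  # per-point contribution bounded by its weight for non-negative values
  set.seed(2)
  d <- runif(50, 0, 100); pr <- runif(50, 0, 100); w <- runif(50)
  expect_lte(sb_loss(d, pr, w), sum(w))
  expect_equal(sb_loss(d, pr, 2 * w), 2 * sb_loss(d, pr, w))
  expect_error(sb_loss(1, 2, -1), "non-negative")
  expect_error(sb_loss(1:3, 1:2), "equal length")
})

make_zv <- function(name, y, weight = 1) {
  deb_dataset(name, "zero_variate", "age_event", y = y, event = "pupation",
              weight = weight)
}

test_that("MRE and SMSE satisfy their unit identities", {
  d1 <- make_zv("a", 10)
  g <- goodness_of_fit(list(d1), predictions = list(10))
  expect_identical(g$MRE, 0)
  expect_identical(g$SMSE, 0)
  expect_identical(g$loss, 0)
  g <- goodness_of_fit(list(d1), predictions = list(11))
  expect_equal(g$MRE, 0.1)
  expect_equal(g$SMSE, 1 / 221)
  # SMSE bounded in [0, 1]; loss invariant to dataset order
  d2 <- make_zv("b", 3, weight = 2)
  g12 <- goodness_of_fit(list(d1, d2), predictions = list(14, 1))
  g21 <- goodness_of_fit(list(d2, d1), predictions = list(1, 14))
  expect_identical(g12$loss, g21$loss)
  expect_identical(g12$SMSE, g21$SMSE)
  expect_true(g12$SMSE >= 0 && g12$SMSE <= 1)
  # zero-valued data are excluded from the MRE with a warning
  expect_warning(
    gz <- goodness_of_fit(
      list(deb_dataset("z", "uni_variate", "length", y = c(0, 2),
                       x = c(1, 2))),
      predictions = list(c(0.5, 2))),
    "zero-valued")
  expect_identical(gz$MRE, 0)
})

test_that("packaged zero-variate table supports a prediction-only fit", {
  ds <- zero_variate_data(horizon = 60)
  expect_length(ds, 13)
  fit <- deb_calibrate(ds[c(1, 2, 6)], free = character(0))
  expect_s3_class(fit, "deb_fit")
  expect_identical(fit$params, deb_params())
  expect_true(is.finite(fit$gof$MRE))
  expect_lt(fit$gof$SMSE, 1)
})

test_that("pseudo-data contributions vanish with their weight", {
  ds <- list(make_zv("a", 14))
  base <- chirodeb:::calibration_objective(
    log(unlist(deb_params()["p_M"])), "p_M", deb_params(), ds,
    comp_params(), pseudo = NULL, pseudo_weight = 0, rtol = 1e-8,
    E0_tol = 1e-8)
  for (w in c(0.1, 1e-3, 0)) {
    v <- chirodeb:::calibration_objective(
      log(unlist(deb_params()["p_M"])), "p_M", deb_params(), ds,
      comp_params(), pseudo = list(k = 1), pseudo_weight = w, rtol = 1e-8,
      E0_tol = 1e-8)
    expect_lt(abs(v - base), w * 1e-3 + 1e-12)  # k is within 0.33% of 1
  }
})

test_that("noiseless truth is recovered with near-zero loss", {
  sc <- deb_scenario(T_c = 21, f = 1, horizon = 60)
  ds <- synthetic_datasets(default_pars, sc, times = c(2, 5, 8, 11),
                           events = c("birth", "puberty", "pupation"),
                           cv = 0, seed = 1, include_eggs = TRUE)
  fit <- deb_calibrate(ds, free = "p_Am",
                       start = deb_params(p_Am = 203 * 1.05),
                       pseudo = NULL, restarts = 0,
                       control = list(maxit = 120, reltol = 1e-10))
  expect_lt(fit$loss, 1e-6)
  expect_equal(unname(coef(fit)["p_Am"]), 203, tolerance = 5e-3)
  expect_identical(fit$convergence, 0L)
  expect_gt(nrow(fit$trace), 1)
})

test_that("the k = 1 pseudo-datum pulls a mis-specified k_J back", {
  # a dataset that barely identifies k_J: length at birth only
  sc <- deb_scenario(T_c = 21, f = 1, horizon = 6)
  lb <- deb_dataset("length_birth", "zero_variate", "length",
                    y = 0.1009, event = "birth", scenario = sc)
  start <- deb_params(k_J = 0.06)       # k = 1.66, deliberately wrong
  k_target <- deb_params()$p_M / deb_params()$E_G   # 0.0361
  fit_without <- deb_calibrate(list(lb), free = "k_J", start = start,
                               pseudo = NULL, restarts = 0,
                               control = list(maxit = 60))
  fit_with <- deb_calibrate(list(lb), free = "k_J", start = start,
                            pseudo = list(k = 1), pseudo_weight = 0.1,
                            restarts = 0, control = list(maxit = 60))
  expect_lt(abs(coef(fit_with)[["k_J"]] - k_target),
            abs(coef(fit_without)[["k_J"]] - k_target))
})
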