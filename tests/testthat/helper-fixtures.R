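# Shared fixtures: the reference parameter set and memoised baseline
# simulations (several test files interrogate the same trajectories).

default_pars <- deb_params()

.sim_cache <- new.env(parent = emptyenv())

baseline_sim <- function(T_c = 21, f = 1, horizon = 200, sex = "female") {
  key <- paste("T", T_c, "f", f, "h", horizon, sex, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- deb_lifecycle(
      default_pars,
      deb_scenario(T_c = T_c, f = f, horizon = horizon, sex = sex))
  }
  .sim_cache[[key]]
}

# Classical fixed-step RK4 on the package flux kernel, used as a brute-force
# integration oracle for the adaptive event-located solver.
rk4_until <- function(y0, deriv, stop_value, stop_index, h = 1e-4,
                      t_max = 50) {
  y <- y0
  t <- 0
  prev <- y[stop_index]
  repeat {
    k1 <- deriv(t, y)
    k2 <- deriv(t + h / 2, y + h / 2 * k1)
    k3 <- deriv(t + h / 2, y + h / 2 * k2)
    k4 <- deriv(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    if (y[stop_index] >= stop_value) {
      # linear interpolation inside the final step
      w <- (stop_value - prev) / (y[stop_index] - prev)
      return(list(t = t - h + w * h, y = y))
    }
    prev <- y[stop_index]
    if (t > t_max) stop("RK4 oracle did not reach the stopping threshold")
  }
}
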