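# Synthetic calibration data: simulate the model under a scenario, sample
# the observables at a design, and apply multiplicative lognormal noise.
# Stands in for raw rearing-experiment data in estimation studies.

#' Generate synthetic calibration datasets
#'
#' Simulates a life cycle under `scenario` with parameters `p` (the truth),
#' samples length-at-age and weight-at-age at the design times plus the
#' event ages and fecundity, and perturbs every observation with
#' multiplicative lognormal noise of coefficient of variation `cv`
#' (mean-preserving: the noise multiplier has expectation 1). With `cv = 0`
#' the observations equal the model predictions exactly. Event observables
#' whose trigger was not reached are omitted rather than fabricated.
#'
#' @param p a [deb_params()] object (the generating truth).
#' @param scenario a [deb_scenario()] object.
#' @param times sampling ages since hatch (d) for the uni-variate length and
#'   wet-weight series.
#' @param events which zero-variate event ages to include.
#' @param cv coefficient of variation of the multiplicative noise.
#' @param replicates number of replicate series per observable.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param include_eggs include an eggs-per-female zero-variate datum.
#' @param comp a [comp_params()] object.
#' @return list of [deb_dataset()] objects with attributes `truth`
#'   (the generating parameters) and `noiseless` (the unperturbed values).
#' @export
synthetic_datasets <- function(p, scenario = deb_scenario(),
                               times = seq(1, 13, by = 1),
                               events = c("birth", "puberty", "pupation",
                                          "emergence"),
                               cv = 0.1, replicates = 1L, seed = 1L,
                               include_eggs = TRUE, comp = comp_params()) {
  stopifnot(inherits(p, "deb_params"), cv >= 0, replicates >= 1L)
  sim <- deb_lifecycle(p, scenario)
  r <- sim$report
  noise <- local({
    sdlog <- sqrt(log(1 + cv^2))
    function(mu, rng) {
      if (cv == 0) return(mu)
      mu * exp(rng(length(mu)) * sdlog - sdlog^2 / 2)
    }
  })
  out <- list()
  noiseless <- list()
  set.seed(as.integer(seed))
  rng <- function(n) stats::rnorm(n)
  reached <- c(birth = !is.na(r$age_at_birth),
               molt1 = !is.na(r$t_molt1), molt2 = !is.na(r$t_molt2),
               puberty = !is.na(r$t_puberty),
               phase_switch = !is.na(r$t_phase_switch),
               pupation = !is.na(r$t_pupation),
               emergence = !is.na(r$t_emergence))
  for (ev in events) {
    if (!isTRUE(reached[ev])) next     # trigger not reached: omit, not fake
    ds <- deb_dataset(paste0("age_", ev), "zero_variate", "age_event",
                      y = NA_real_, event = ev, scenario = scenario)
    mu <- predict_from_sim(ds, sim, comp)
    noiseless[[ds$name]] <- mu
    ds$y <- noise(mu, rng)
    out[[ds$name]] <- ds
  }
  if (include_eggs && isTRUE(reached["pupation"]) &&
      isTRUE(reached["emergence"])) {
    ds <- deb_dataset("eggs", "zero_variate", "eggs_per_female",
                      y = NA_real_, scenario = scenario)
    mu <- predict_from_sim(ds, sim, comp)
    noiseless[["eggs"]] <- mu
    ds$y <- noise(mu, rng)
    out[["eggs"]] <- ds
  }
  if (length(times)) {
    for (rep_i in seq_len(replicates)) {
      sfx <- if (replicates > 1L) paste0("_rep", rep_i) else ""
      for (obs in c("length", "wet_weight")) {
        ds <- deb_dataset(paste0(obs, "_at_age", sfx), "uni_variate", obs,
                          y = rep(NA_real_, length(times)), x = times,
                          scenario = scenario)
        mu <- predict_from_sim(ds, sim, comp)
        if (rep_i == 1L) noiseless[[paste0(obs, "_at_age")]] <- mu
        ds$y <- noise(mu, rng)
        out[[ds$name]] <- ds
      }
    }
  }
  attr(out, "truth") <- p
  attr(out, "noiseless") <- noiseless
  attr(out, "seed") <- seed
  out
}
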