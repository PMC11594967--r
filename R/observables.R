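# Mapping state variables to measurable quantities: physical length via the
# shape coefficients, wet and dry weight via composition coefficients, and an
# approximate oxygen-consumption proxy.

#' Composition parameters for weight observables
#'
#' Coefficients linking structure and reserve to mass. These are not part of
#' the published species parameter table; the defaults follow common DEB
#' practice (specific dry mass of structure 0.17 g/cm^3, reserve mass per
#' unit energy w_E/mu_E = 23.9 g mol^-1 / 550 kJ mol^-1, water fraction 0.83
#' so that hydrated structure has density about 1 g/cm^3). Weight-valued
#' predictions (wet weight at pupation, imago dry weight, egg dry weight)
#' are sensitive to these coefficients and should be treated as
#' order-of-magnitude outputs unless the coefficients are calibrated.
#'
#' @param d_V_dry volume-specific dry mass of structure, g/cm^3.
#' @param mass_per_energy dry reserve mass per unit of reserve energy
#'   (w_E/mu_E), g/J.
#' @param water_fraction water mass fraction of hydrated structure and
#'   reserve, in \[0, 1). The reproduction buffer is counted as dry mass
#'   only (eggs of aquatic insects absorb water after laying), so it
#'   contributes identically to wet and dry weight.
#' @return an object of class `comp_params`.
#' @export
comp_params <- function(d_V_dry = 0.17, mass_per_energy = 23.9 / 550e3,
                        water_fraction = 0.83) {
  if (d_V_dry <= 0 || mass_per_energy <= 0) {
    stop("composition coefficients must be positive")
  }
  if (water_fraction < 0 || water_fraction >= 1) {
    stop("water_fraction must lie in [0, 1)")
  }
  structure(list(d_V_dry = d_V_dry, mass_per_energy = mass_per_energy,
                 water_fraction = water_fraction), class = "comp_params")
}

#' Structural to physical length conversion
#'
#' `Lw = V^(1/3) / delta_M`. Datasets measured on living animals use the
#' alive shape coefficient `del_M1`; datasets measured on dead (preserved)
#' animals use `del_M2`, which is smaller and therefore yields longer
#' physical lengths for the same structure.
#'
#' @param V structural volume(s), cm^3.
#' @param delta_M shape coefficient (dimensionless, positive).
#' @return physical length(s), cm.
#' @export
physical_length <- function(V, delta_M) {
  if (!is.numeric(delta_M) || any(delta_M <= 0)) {
    stop("delta_M must be positive")
  }
  if (any(V < 0)) stop("V must be non-negative")
  V^(1 / 3) / delta_M
}

#' Wet and dry weight
#'
#' Additive decomposition of body mass: dry weight sums the dry masses of
#' structure, reserve and reproduction buffer; wet weight hydrates structure
#' and reserve with the water fraction but not the reproduction buffer,
#' which consists of dry mass only. Increasing the buffer at fixed `E` and
#' `V` therefore raises the dry-weight fraction, the mechanism behind the
#' rising dry-weight percentage through the fourth instar.
#'
#' @param E reserve energy, J (vectorised).
#' @param V structural volume, cm^3.
#' @param ER reproduction buffer energy, J.
#' @param comp a [comp_params()] object.
#' @return list with `wet` and `dry` weights, g.
#' @export
deb_weights <- function(E, V, ER = 0, comp = comp_params()) {
  stopifnot(inherits(comp, "comp_params"))
  if (any(V < 0) || any(E < 0) || any(ER < 0)) {
    stop("state variables must be non-negative")
  }
  hyd <- 1 / (1 - comp$water_fraction)
  dry <- comp$d_V_dry * V + comp$mass_per_energy * (E + ER)
  wet <- comp$d_V_dry * hyd * V + comp$mass_per_energy * hyd * E +
    comp$mass_per_energy * ER
  list(wet = wet, dry = dry)
}

#' Approximate respiration proxy
#'
#' A dissipation-based proxy for the oxygen-consumption rate: the sum of
#' somatic and maturity maintenance plus a growth-overhead term, scaled by a
#' single configurable coefficient. A faithful mineral-flux computation
#' would require chemical indices and composition coefficients that are not
#' part of the parameterisation, so this output is explicitly approximate
#' and intended for qualitative comparison only.
#'
#' @param powers a flux list as returned by [deb_fluxes()].
#' @param coefficient proportionality coefficient (set to 0 to disable).
#' @param growth_overhead fraction of the growth flux counted as overhead.
#' @return list with `value` (J/d scale) and `approximate = TRUE`.
#' @export
respiration_proxy <- function(powers, coefficient = 1, growth_overhead = 0.2) {
  v <- coefficient * (powers$p_S + powers$p_J +
                        growth_overhead * max(powers$p_G, 0))
  list(value = v, approximate = TRUE)
}

#' Observable columns for a simulated trajectory
#'
#' Appends measurable quantities to the trajectory of a [deb_lifecycle()]
#' object: physical length under both shape coefficients and wet/dry weight
#' in mg.
#'
#' @param x a `deb_lifecycle` object.
#' @param comp a [comp_params()] object.
#' @return the trajectory data frame with columns `length_cm_alive`,
#'   `length_cm_dead`, `wet_weight_mg`, `dry_weight_mg` appended.
#' @export
deb_observables <- function(x, comp = comp_params()) {
  stopifnot(inherits(x, "deb_lifecycle"))
  p <- x$params
  tr <- x$trajectory
  V <- pmax(tr$V_cm3, 0)
  w <- deb_weights(pmax(tr$E_J, 0), V, pmax(tr$ER_J, 0), comp)
  tr$length_cm_alive <- physical_length(V, p$del_M1)
  tr$length_cm_dead <- physical_length(V, p$del_M2)
  tr$wet_weight_mg <- 1e3 * w$wet
  tr$dry_weight_mg <- 1e3 * w$dry
  tr
}
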