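# Core energetics: temperature correction, functional response, metabolic
# acceleration and the stage-dependent energy fluxes.

# Stage codes used throughout the integrator. The four-instar larval stage is
# partitioned for flux purposes into the immature (V1-morphic) larva and the
# two phases of the fourth instar.
STAGES <- c(EMBRYO = 1L, L1 = 2L, L2 = 2L, L3 = 2L,
            L4_PHASE1 = 3L, L4_PHASE2 = 4L, PUPA = 5L, IMAGO = 6L)

stage_code <- function(stage) {
  code <- STAGES[toupper(stage)]
  if (any(is.na(code))) {
    stop("unknown stage tag(s): ",
         paste(unique(stage[is.na(code)]), collapse = ", "))
  }
  unname(code)
}

#' Arrhenius temperature correction factor
#'
#' Correction factor `c_T` by which every rate parameter is multiplied at body
#' temperature `T`. The form is the upper-bounded Arrhenius correction of DEB
#' theory,
#' \deqn{c_T(T) = e^{T_A/T_{ref} - T_A/T} \,
#'       \frac{1 + e^{T_{AH}/T_H - T_{AH}/T_{ref}}}
#'            {1 + e^{T_{AH}/T_H - T_{AH}/T}},}
#' normalised so that `c_T(T_ref) = 1`. The upper-boundary term damps rates
#' above `T_H`; no lower boundary is applied (the data underlying the
#' parameterisation did not support one).
#'
#' @param T_K body temperature(s), K.
#' @param p a [deb_params()] object.
#' @return numeric vector of correction factors, same length as `T_K`.
#' @examples
#' p <- deb_params()
#' temp_correction(p$T_ref, p)        # exactly 1
#' temp_correction(273.15 + 15, p)    # about 0.70
#' @export
temp_correction <- function(T_K, p) {
  if (!is.numeric(T_K) || any(!is.finite(T_K))) {
    stop("temperature must be finite (in K)")
  }
  if (any(T_K <= 273 | T_K >= 320)) {
    stop("temperature outside the simulation validity window (273, 320) K")
  }
  u <- function(t) 1 + exp(p$T_AH / p$T_H - p$T_AH / t)
  exp(p$T_A / p$T_ref - p$T_A / T_K) * u(p$T_ref) / u(T_K)
}

#' Holling type II scaled functional response
#'
#' `f = X / (X_K + X)`: feeding rate as a fraction of the size-specific
#' maximum, as a function of food density `X` with half-saturation constant
#' `X_K`. The map itself yields values in \[0, 1); scenario files may set `f`
#' directly, including values above 1 to represent richer diets or protocols.
#'
#' @param X food density (same units as `X_K`), non-negative.
#' @param X_K half-saturation constant, positive.
#' @return scaled functional response in \[0, 1).
#' @export
functional_response <- function(X, X_K) {
  if (!is.numeric(X_K) || any(X_K <= 0)) stop("X_K must be positive")
  if (!is.numeric(X) || any(X < 0)) stop("food density X must be non-negative")
  X / (X_K + X)
}

#' Metabolic acceleration factor
#'
#' `s_M = max(1, min(L, L_p) / L_b)`: the factor by which the
#' surface-area-specific assimilation rate and the energy conductance are
#' multiplied. It is 1 up to birth, grows linearly with structural length
#' `L = V^(1/3)` while the immature larva grows as a V1-morph, and is frozen
#' at `L_p / L_b` from puberty onwards (including the pupa, whose structural
#' length restarts near zero).
#'
#' @param L structural length(s), cm.
#' @param L_b structural length at birth, cm.
#' @param L_p structural length at puberty, cm.
#' @return acceleration factor(s) in \[1, `L_p/L_b`\].
#' @export
acceleration_factor <- function(L, L_b, L_p) {
  if (!is.numeric(L_b) || L_b <= 0) stop("L_b must be positive")
  if (!is.numeric(L_p) || L_p < L_b) stop("L_p must satisfy L_p >= L_b")
  pmax(1, pmin(L, L_p) / L_b)
}

# Lean scalar flux kernel used by the integrator. `stage` is an integer code
# (see STAGES); `sM` is the current acceleration factor; all rates are
# multiplied by cT. Returns c(pA, pC, pS, pG, pJ, pR, deficit) where deficit
# is the relative somatic-maintenance shortfall feeding the starvation hazard.
flux_kernel <- function(E, V, EH, stage, sM, f, p, cT) {
  E <- max(E, 0)
  pAm <- p$p_Am * cT * sM
  v   <- p$v * cT * sM
  pMv <- p$p_M * cT
  kJ  <- p$k_J * cT
  pS <- pMv * V
  pJ <- kJ * EH
  V23 <- V^(2 / 3)
  if (stage == 4L) {                      # L4 Phase II: no growth, top up E
    pA <- pAm * f * V23
    dem <- pS + pJ
    pC <- if (E > 0) dem else min(pA, dem)
    pG <- 0
    pR <- 0
    deficit <- if (dem > 0) max(0, 1 - pC / dem) else 0
  } else if (stage == 6L) {               # imago: non-feeding, non-growing
    if (V <= 0) stop("imago requires positive structural volume")
    pA <- 0
    pC <- E * v / V^(1 / 3)
    pG <- 0
    pR <- pC - pS - pJ
    dem <- pS + pJ
    deficit <- if (dem > 0) max(0, 1 - pC / dem) else 0
  } else {                                # kappa-rule stages
    pA <- if (stage == 1L || stage == 5L) 0 else pAm * f * V23
    pC <- E * (p$E_G * v * V23 + pMv * V) / (p$kap * E + p$E_G * V)
    pG <- p$kap * pC - pS
    pR <- (1 - p$kap) * pC - pJ
    deficit <- if (pS > 0) max(0, 1 - p$kap * pC / pS) else 0
  }
  c(pA = pA, pC = pC, pS = pS, pG = pG, pJ = pJ, pR = pR, deficit = deficit)
}

#' Stage-dependent energy fluxes
#'
#' Evaluates the assimilation, mobilisation, maintenance, growth and
#' maturation/reproduction fluxes of the hax model for a given organismal
#' state, scaled functional response and temperature correction factor.
#'
#' In feeding kappa-rule stages (immature larva, Phase I of the fourth
#' instar) the fluxes satisfy the kappa-rule bookkeeping
#' `pC = pS + pG + pJ + pR` exactly. Assimilation is zero in the embryo, pupa
#' and imago. In Phase II of the fourth instar mobilisation equals total
#' maintenance (`pC = pS + pJ`) and growth stops; in the imago mobilisation
#' is `E v s_M V^(-1/3)`, growth is zero, and `pR = pC - pS - pJ`.
#'
#' @param state named list or vector with elements `E` (J), `V` (cm^3), `E_H`
#'   (J) and `stage` (one of `"EMBRYO"`, `"L1"`, `"L2"`, `"L3"`,
#'   `"L4_PHASE1"`, `"L4_PHASE2"`, `"PUPA"`, `"IMAGO"`), plus `s_M`
#'   (acceleration factor; defaults to 1).
#' @param f scaled functional response; values above 1 are allowed (richer
#'   diets), values must be non-negative.
#' @param p a [deb_params()] object.
#' @param c_T temperature correction factor from [temp_correction()].
#' @return named list with components `p_A`, `p_C`, `p_S`, `p_G`, `p_J`,
#'   `p_R` (J/d) and `deficit` (the relative maintenance shortfall driving
#'   the starvation hazard).
#' @export
deb_fluxes <- function(state, f, p, c_T = 1) {
  if (is.null(state$stage)) stop("state must carry a stage tag")
  code <- stage_code(state$stage)
  sM <- if (is.null(state$s_M)) 1 else state$s_M
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 0) {
    stop("f must be a non-negative scalar")
  }
  if (state$V < 0 || state$E_H < 0) stop("state variables must be non-negative")
  k <- flux_kernel(state$E, state$V, state$E_H, code, sM, f, p, c_T)
  as.list(c(p_A = unname(k["pA"]), p_C = unname(k["pC"]),
            p_S = unname(k["pS"]), p_G = unname(k["pG"]),
            p_J = unname(k["pJ"]), p_R = unname(k["pR"]),
            deficit = unname(k["deficit"])))
}
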