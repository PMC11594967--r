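# Stage-structured integration of the full life cycle with event detection:
# embryo -> immature larva (L1-L3, V1-morph) -> L4 Phase I -> L4 Phase II ->
# pupa -> imago. Thresholds are located by the root-finding machinery of
# lsodar on the continuous solution, so event states satisfy their defining
# equalities to solver precision.

# State vector: y = (E, V, E_H, E_R, H) with H the cumulative hazard since
# birth (survival S = exp(-H); the embryo accrues no hazard).

.noop_event <- function(t, y, parms) y

make_rhs <- function(code, p, cT, f_fun, L_b = NA_real_, s_M = 1) {
  force(code); force(p); force(cT); force(f_fun); force(L_b); force(s_M)
  function(t, y, parms) {
    V <- max(y[2], 0)
    sM <- if (code == 2L) max(1, V^(1 / 3) / L_b) else s_M
    k <- flux_kernel(y[1], V, y[3], code, sM, f_fun(t), p, cT)
    dE <- k[[1]] - k[[2]]
    dV <- k[[4]] / p$E_G
    dEH <- if (code == 1L || code == 2L || code == 5L) k[[6]] else 0
    dER <- if (code == 3L) k[[6]] else 0
    h <- if (code == 1L) 0 else cT * (p$h_b + p$k_starv * k[[7]])
    list(c(dE, dV, dEH, dER, h))
  }
}

# Integrate one stage, restarting at forcing breakpoints so that roots are
# never bracketed across a derivative discontinuity. Returns the recorded
# rows, the terminal state, whether the terminal root fired, and the times of
# all (terminal and non-terminal) roots.
run_stage <- function(y0, t0, t_end, rhs, rootfun, terminal_idx = 1L,
                      breaks = numeric(0), rtol = 1e-10,
                      atol = c(1e-10, 1e-16, 1e-12, 1e-10, 1e-10),
                      pts_per_day = 24) {
  cuts <- sort(unique(breaks[breaks > t0 & breaks < t_end]))
  bounds <- c(t0, cuts, t_end)
  rows <- NULL
  roots <- list()
  y <- y0
  hit <- FALSE
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    n <- max(3L, ceiling((b - a) * pts_per_day) + 1L)
    times <- seq(a, b, length.out = n)
    out <- deSolve::ode(y, times, rhs, parms = NULL, method = "lsodar",
                        rootfunc = rootfun, rtol = rtol, atol = atol,
                        events = list(func = .noop_event, root = TRUE,
                                      terminalroot = terminal_idx))
    tr <- attr(out, "troot"); ir <- attr(out, "indroot")
    if (!is.null(tr) && length(tr)) {
      roots[[length(roots) + 1L]] <- data.frame(t = tr, which = ir)
    }
    rows <- rbind(rows, unclass(out))
    y <- out[nrow(out), -1L]
    if (!is.null(ir) && any(ir %in% terminal_idx)) {
      hit <- TRUE
      break
    }
  }
  roots <- if (length(roots)) do.call(rbind, roots) else
    data.frame(t = numeric(0), which = integer(0))
  list(rows = rows, y = unname(y), t = unname(rows[nrow(rows), 1L]),
       hit = hit, roots = roots)
}

#' Initial egg reserve by shooting
#'
#' Solves for the initial energy content of the egg, `E_0`, such that the
#' scaled reserve density at birth equals `e_b` (default 1: the
#' abundant-food maternal condition, used for all scenarios since egg size is
#' taken to be independent of the mother's condition). The embryo is
#' integrated with zero assimilation, `s_M = 1` and isomorphic fluxes, and
#' birth is the event `E_H = E_Hb`. The search interval for `E_0` is widened
#' automatically up to a hard cap before failing.
#'
#' @param p a [deb_params()] object (already sex-specific if required).
#' @param T_c temperature, degC.
#' @param e_b target scaled reserve density at birth.
#' @param rtol,pts_per_day integration controls.
#' @param E0_tol absolute tolerance of the shooting solve, J.
#' @return list with `E_0` (J), `age_at_birth` (d since oviposition),
#'   `state_at_birth` (named vector E, V, E_H), `L_b` (cm), `e_b` (achieved
#'   scaled reserve density), `c_T`, and the embryo `trajectory` matrix.
#' @export
initial_reserve <- function(p, T_c = 21, e_b = 1, rtol = 1e-10,
                            pts_per_day = 24, E0_tol = 1e-12) {
  stopifnot(inherits(p, "deb_params"))
  cT <- temp_correction(273.15 + T_c, p)
  Em <- reserve_capacity(p)
  t_cap <- 400 / cT
  rhs <- make_rhs(1L, p, cT, function(t) 0)
  root <- function(t, y, parms) y[3] - p$E_Hb
  one <- function(E0) {
    run_stage(c(E0, 1e-12, 0, 0, 0), 0, t_cap, rhs, root, rtol = rtol,
              pts_per_day = pts_per_day)
  }
  g <- function(E0) {
    s <- one(E0)
    if (!s$hit) return(-1)   # reserve exhausted before reaching E_Hb
    s$y[1] / (Em * s$y[2]) - e_b
  }
  lo <- 2 * p$E_Hb; hi <- 50 * p$E_Hb
  glo <- g(lo); i <- 0L
  while (glo > 0 && i < 8L) { lo <- lo / 4; glo <- g(lo); i <- i + 1L }
  ghi <- g(hi); i <- 0L
  while (ghi < 0 && i < 8L) { hi <- hi * 4; ghi <- g(hi); i <- i + 1L }
  if (glo > 0 || ghi < 0) {
    stop("could not bracket the initial egg reserve E_0 (search cap reached)")
  }
  r <- stats::uniroot(g, c(lo, hi), f.lower = glo, f.upper = ghi,
                      tol = E0_tol)
  s <- one(r$root)
  list(E_0 = r$root, age_at_birth = s$t,
       state_at_birth = c(E = s$y[1], V = s$y[2], E_H = s$y[3]),
       L_b = s$y[2]^(1 / 3), e_b = s$y[1] / (Em * s$y[2]), c_T = cT,
       trajectory = s$rows)
}

#' Pupation transition
#'
#' The instantaneous breakdown of larval structure at pupation and its
#' conversion into reserve with efficiency `kap_V`: reserve gains
#' `kap_V E_G V_j`, structure restarts from a small seed, maturity restarts
#' from zero (to be rebuilt to `E_He`), and the reproduction buffer filled
#' during the larval stage is retained. The acceleration factor stays frozen
#' at its puberty value.
#'
#' @param state named list with at least `E`, `V`, `E_R` (J, cm^3, J).
#' @param p a [deb_params()] object.
#' @param V_seed seed structural volume of the pupa, cm^3. Emergence age is
#'   insensitive to its exact value because mobilisation vanishes with
#'   structural surface area.
#' @return the pupal initial state (named list, stage `"PUPA"`).
#' @export
pupation_transition <- function(state, p, V_seed = 1e-8) {
  stopifnot(is.numeric(V_seed), V_seed > 0)
  list(E = state$E + p$kap_V * p$E_G * state$V, V = V_seed, E_H = 0,
       E_R = state$E_R, stage = "PUPA",
       s_M = state$s_M %||% 1)
}

#' Eggs per female
#'
#' `N_i = kap_R [E_Rj] V_j / E_0`: the reproduction buffer accumulated to
#' density `[E_Rj]` over the structure at pupation, converted into eggs of
#' initial energy `E_0` with efficiency `kap_R`.
#'
#' @param p a [deb_params()] object.
#' @param V_j structural volume at pupation, cm^3.
#' @param E_0 initial egg energy, J.
#' @return list with `N_i` (real-valued) and `N_i_floor`.
#' @export
egg_number <- function(p, V_j, E_0) {
  if (!is.numeric(E_0) || E_0 <= 0) stop("E_0 must be positive")
  if (!is.numeric(V_j) || V_j < 0) stop("V_j must be non-negative")
  n <- p$kap_R * p$E_Rj * V_j / E_0
  list(N_i = n, N_i_floor = floor(n))
}

# Dyar-type molt thresholds on the immature track. The molt constants are
# applied as ratios of squared structural length (i.e. of surface area)
# between consecutive molts, with the L3 -> L4 transition pinned at puberty:
#   rule "surface": L_molt1 = L_b sqrt(s_1), L_molt2 = L_b sqrt(s_1 s_2)
# Alternative mappings interpret the constants as length or volume ratios.
molt_thresholds <- function(p, L_b, rule = c("surface", "length", "volume")) {
  rule <- match.arg(rule)
  ex <- switch(rule, surface = 1 / 2, length = 1, volume = 1 / 3)
  c(L_b * p$s_1^ex, L_b * (p$s_1 * p$s_2)^ex)
}

#' Simulate the full life cycle
#'
#' Integrates the hax model from oviposition through emergence under a
#' forcing scenario. Stages and their terminating events:
#' \describe{
#'   \item{embryo}{no feeding, isomorphic, `s_M = 1`; birth at `E_H = E_Hb`
#'     (initial reserve solved by [initial_reserve()]).}
#'   \item{immature larva (L1-L3)}{feeding V1-morph: `s_M = L / L_b` grows
#'     with structural length; puberty at `E_H = E_Hp`; molts located at the
#'     Dyar-type thresholds (see [instar_boundaries()]).}
#'   \item{L4 Phase I}{feeding isomorph, `s_M` frozen; kappa rule with the
#'     maturation flux redirected to the reproduction buffer; ends when
#'     `E_R / V = [E_Rj]`.}
#'   \item{L4 Phase II}{growth and buffer filling stop; assimilation tops up
#'     the reserve; pupation when `E / V = [Em]` (immediate when the reserve
#'     density is already at capacity, as happens at f = 1).}
#'   \item{pupa}{no feeding; structure converted to reserve at entry
#'     ([pupation_transition()]); rebuilds structure and maturity;
#'     emergence at `E_H = E_He`.}
#'   \item{imago}{no feeding or growth; simulated until mobilisation can no
#'     longer cover maintenance or the horizon ends.}
#' }
#' Unreachable triggers (e.g. food too low for the buffer density to attain
#' `[E_Rj]` within the horizon) terminate the simulation with an explicit
#' status rather than an error.
#'
#' @param p a [deb_params()] object.
#' @param scenario a [deb_scenario()] object.
#' @param instar_rule mapping of the molt constants to length thresholds;
#'   default `"surface"` (see [instar_boundaries()]).
#' @param V_seed pupal seed structure, cm^3.
#' @param rtol relative integration tolerance.
#' @param pts_per_day trajectory recording density.
#' @param E0_tol tolerance of the egg-reserve shooting solve.
#' @return an object of class `deb_lifecycle`: a list with `trajectory`
#'   (data frame: `t_d` since oviposition, `E_J`, `V_cm3`, `EH_J`, `ER_J`,
#'   `stage`, `survival`, `s_M`), `report` (event ages and states, egg
#'   number, status), `params`, `scenario`.
#' @examples
#' \donttest{
#' lc <- deb_lifecycle(deb_params(), deb_scenario(T_c = 21, f = 1))
#' lc$report$t_pupation   # days from hatching to pupation
#' }
#' @export
deb_lifecycle <- function(p, scenario = deb_scenario(),
                          instar_rule = c("surface", "length", "volume"),
                          V_seed = 1e-8, rtol = 1e-10, pts_per_day = 24,
                          E0_tol = 1e-12) {
  stopifnot(inherits(p, "deb_params"), inherits(scenario, "deb_scenario"))
  instar_rule <- match.arg(instar_rule)
  p_eff <- params_for_sex(p, scenario$sex)
  cT <- temp_correction(scenario_T_K(scenario), p_eff)
  Em <- reserve_capacity(p_eff)
  horizon <- scenario$horizon
  f_fun <- function(t) f_at(scenario, t)
  breaks <- f_breakpoints(scenario)
  atol <- c(1e-10, 1e-16, 1e-12, 1e-10, 1e-10)

  rep0 <- list(E_0 = NA_real_, age_at_birth = NA_real_, t_molt1 = NA_real_,
               t_molt2 = NA_real_, t_puberty = NA_real_,
               t_phase_switch = NA_real_, t_pupation = NA_real_,
               t_emergence = NA_real_, t_imago_end = NA_real_,
               imago_end_reason = NA_character_,
               L_b = NA_real_, L_p = NA_real_, L_j = NA_real_,
               V_j = NA_real_, E_R_at_pupation = NA_real_,
               s_M_final = NA_real_, N_i = NA_real_, N_i_floor = NA_real_,
               status = "embryo_not_hatched", T_c = scenario$T_c,
               sex = scenario$sex, instar_rule = instar_rule,
               states = list(), params_hash = params_hash(p))

  # --- embryo --------------------------------------------------------------
  ir <- initial_reserve(p_eff, scenario$T_c, rtol = rtol,
                        pts_per_day = pts_per_day, E0_tol = E0_tol)
  rep <- rep0
  rep$E_0 <- ir$E_0
  rep$age_at_birth <- ir$age_at_birth
  rep$L_b <- ir$L_b
  rep$states$birth <- ir$state_at_birth
  ab <- ir$age_at_birth
  emb <- ir$trajectory
  traj <- list(cbind(emb[, 1, drop = FALSE], emb[, 2:5, drop = FALSE],
                     stage = 1L, H = emb[, 6]))
  L_b <- ir$L_b

  finish <- function(rep, traj, status) {
    rep$status <- status
    out <- assemble_trajectory(traj, ab, rep, L_b, p_eff, instar_rule)
    structure(list(trajectory = out, report = rep, params = p,
                   scenario = scenario, c_T = cT, Em = Em),
              class = "deb_lifecycle")
  }

  # Larval clock runs in days since birth; horizon applies since oviposition.
  t_cap <- horizon - ab
  if (t_cap <= 0) return(finish(rep, traj, "horizon_before_birth"))

  # --- immature larva (L1-L3) ---------------------------------------------
  th <- molt_thresholds(p_eff, L_b, instar_rule)
  rhs <- make_rhs(2L, p_eff, cT, f_fun, L_b = L_b)
  root <- function(t, y, parms) {
    L <- max(y[2], 0)^(1 / 3)
    c(L - th[1], L - th[2], y[3] - p_eff$E_Hp)
  }
  y0 <- c(ir$state_at_birth[["E"]], ir$state_at_birth[["V"]], p_eff$E_Hb, 0, 0)
  st <- run_stage(y0, 0, t_cap, rhs, root, terminal_idx = 3L, breaks = breaks,
                  rtol = rtol, atol = atol, pts_per_day = pts_per_day)
  molts <- st$roots
  if (nrow(molts)) {
    m1 <- molts$t[molts$which == 1L]
    m2 <- molts$t[molts$which == 2L]
    rep$t_molt1 <- if (length(m1)) m1[1] else NA_real_
    rep$t_molt2 <- if (length(m2)) m2[1] else NA_real_
  }
  traj <- c(traj, list(cbind(st$rows[, 1, drop = FALSE] + ab,
                             st$rows[, 2:5, drop = FALSE], stage = 2L,
                             H = st$rows[, 6])))
  if (!st$hit) return(finish(rep, traj, "puberty_not_reached"))
  t_p <- st$t
  L_p <- st$y[2]^(1 / 3)
  s_M <- max(1, L_p / L_b)
  rep$t_puberty <- t_p
  rep$L_p <- L_p
  rep$s_M_final <- s_M
  rep$states$puberty <- c(E = st$y[1], V = st$y[2], E_H = st$y[3])

  # --- L4 Phase I ----------------------------------------------------------
  rhs <- make_rhs(3L, p_eff, cT, f_fun, s_M = s_M)
  root <- function(t, y, parms) y[4] / max(y[2], 1e-300) - p_eff$E_Rj
  y0 <- c(st$y[1], st$y[2], p_eff$E_Hp, 0, st$y[5])
  st <- run_stage(y0, t_p, t_cap, rhs, root, breaks = breaks, rtol = rtol,
                  atol = atol, pts_per_day = pts_per_day)
  traj <- c(traj, list(cbind(st$rows[, 1, drop = FALSE] + ab,
                             st$rows[, 2:5, drop = FALSE], stage = 3L,
                             H = st$rows[, 6])))
  if (!st$hit) return(finish(rep, traj, "phase_switch_not_reached"))
  t_sw <- st$t
  rep$t_phase_switch <- t_sw
  rep$states$phase_switch <- c(E = st$y[1], V = st$y[2], E_R = st$y[4])

  # --- L4 Phase II ---------------------------------------------------------
  y_sw <- st$y
  if (y_sw[1] / y_sw[2] >= Em) {
    # reserve density already at capacity (the abundant-food case):
    # Phase II has zero duration
    t_j <- t_sw
    y_j <- y_sw
  } else {
    rhs <- make_rhs(4L, p_eff, cT, f_fun, s_M = s_M)
    root <- function(t, y, parms) y[1] / max(y[2], 1e-300) - Em
    st <- run_stage(y_sw, t_sw, t_cap, rhs, root, breaks = breaks,
                    rtol = rtol, atol = atol, pts_per_day = pts_per_day)
    traj <- c(traj, list(cbind(st$rows[, 1, drop = FALSE] + ab,
                               st$rows[, 2:5, drop = FALSE], stage = 4L,
                               H = st$rows[, 6])))
    if (!st$hit) return(finish(rep, traj, "pupation_not_reached"))
    t_j <- st$t
    y_j <- st$y
  }
  rep$t_pupation <- t_j
  rep$L_j <- y_j[2]^(1 / 3)
  rep$V_j <- y_j[2]
  rep$E_R_at_pupation <- y_j[4]
  rep$states$pupation <- c(E = y_j[1], V = y_j[2], E_R = y_j[4])
  eggs <- egg_number(p_eff, y_j[2], ir$E_0)
  rep$N_i <- eggs$N_i
  rep$N_i_floor <- eggs$N_i_floor

  # --- pupa ---------------------------------------------------------------
  ps <- pupation_transition(list(E = y_j[1], V = y_j[2], E_R = y_j[4],
                                 s_M = s_M), p_eff, V_seed)
  rhs <- make_rhs(5L, p_eff, cT, function(t) 0, s_M = s_M)
  root <- function(t, y, parms) y[3] - p_eff$E_He
  y0 <- c(ps$E, ps$V, 0, ps$E_R, y_j[5])
  st <- run_stage(y0, t_j, t_cap, rhs, root, rtol = rtol, atol = atol,
                  pts_per_day = pts_per_day)
  traj <- c(traj, list(cbind(st$rows[, 1, drop = FALSE] + ab,
                             st$rows[, 2:5, drop = FALSE], stage = 5L,
                             H = st$rows[, 6])))
  if (!st$hit) return(finish(rep, traj, "emergence_not_reached"))
  t_e <- st$t
  rep$t_emergence <- t_e
  rep$states$emergence <- c(E = st$y[1], V = st$y[2], E_H = st$y[3],
                            E_R = st$y[4])

  # --- imago ---------------------------------------------------------------
  rhs <- make_rhs(6L, p_eff, cT, function(t) 0, s_M = s_M)
  root <- function(t, y, parms) {
    k <- flux_kernel(y[1], y[2], y[3], 6L, s_M, 0, p_eff, cT)
    k[[2]] - (k[[3]] + k[[5]])
  }
  y0 <- c(st$y[1], st$y[2], p_eff$E_He, st$y[4], st$y[5])
  st <- run_stage(y0, t_e, t_cap, rhs, root, rtol = rtol, atol = atol,
                  pts_per_day = pts_per_day)
  traj <- c(traj, list(cbind(st$rows[, 1, drop = FALSE] + ab,
                             st$rows[, 2:5, drop = FALSE], stage = 6L,
                             H = st$rows[, 6])))
  rep$t_imago_end <- st$t
  rep$imago_end_reason <- if (st$hit) "reserve_depleted" else "horizon"
  finish(rep, traj, "completed")
}

# Bind per-stage blocks into the trajectory data frame, labelling the
# immature larva rows L1/L2/L3 from the molt times.
assemble_trajectory <- function(blocks, ab, report, L_b, p, instar_rule) {
  m <- do.call(rbind, blocks)
  t <- m[, 1]
  code <- m[, 6]
  stage <- character(length(t))
  stage[code == 1] <- "EMBRYO"
  stage[code == 3] <- "L4_PHASE1"
  stage[code == 4] <- "L4_PHASE2"
  stage[code == 5] <- "PUPA"
  stage[code == 6] <- "IMAGO"
  imm <- code == 2
  if (any(imm)) {
    tb <- t[imm] - ab
    lab <- rep("L1", sum(imm))
    if (!is.na(report$t_molt1)) lab[tb >= report$t_molt1] <- "L2"
    if (!is.na(report$t_molt2)) lab[tb >= report$t_molt2] <- "L3"
    stage[imm] <- lab
  }
  sM <- numeric(length(t))
  sM[code == 1] <- 1
  sM[imm] <- pmax(1, pmax(m[imm, 3], 0)^(1 / 3) / L_b)
  sM[code >= 3] <- report$s_M_final %||% NA_real_
  out <- data.frame(t_d = t, E_J = m[, 2], V_cm3 = m[, 3], EH_J = m[, 4],
                    ER_J = m[, 5], stage = stage, survival = exp(-m[, 7]),
                    s_M = sM, row.names = NULL)
  # drop duplicated sample points (segment boundaries and event rows appear
  # twice); the first row of each (time, stage) pair is kept, so stage
  # changes remain visible at the event times
  out[!duplicated(out[, c("t_d", "stage")]), , drop = FALSE]
}

#' Instar boundaries on the immature larval track
#'
#' Ages (since birth) of the L1 to L2 and L2 to L3 molts, obtained by
#' partitioning the immature phase with Dyar-type thresholds built from the
#' molt constants `s_1`, `s_2` under the constraint that the L3 to L4
#' transition coincides with puberty. The default rule applies the constants
#' as surface-area (squared-length) ratios between consecutive molts, which
#' best matches the reported instar durations; `"length"` and `"volume"`
#' interpret them as length or volume ratios instead.
#'
#' @param x a `deb_lifecycle` object whose immature phase completed.
#' @param rule threshold mapping (see above).
#' @return data frame with the molt ages since birth, the structural length
#'   thresholds, and the implied instar durations (L3 duration ends at
#'   puberty by construction).
#' @export
instar_boundaries <- function(x, rule = c("surface", "length", "volume")) {
  stopifnot(inherits(x, "deb_lifecycle"))
  rule <- match.arg(rule)
  rep <- x$report
  if (is.na(rep$t_puberty)) stop("immature phase did not complete")
  th <- molt_thresholds(params_for_sex(x$params, x$scenario$sex), rep$L_b,
                        rule)
  if (any(th <= rep$L_b) || any(th >= rep$L_p)) {
    stop("molt thresholds fall outside (L_b, L_p) under rule '", rule, "'")
  }
  tr <- x$trajectory
  imm <- tr$stage %in% c("L1", "L2", "L3")
  tb <- tr$t_d[imm] - rep$age_at_birth
  L <- pmax(tr$V_cm3[imm], 0)^(1 / 3)
  cross <- function(thr) {
    i <- which(L >= thr)[1]
    if (is.na(i) || i == 1L) return(NA_real_)
    # monotone log-linear interpolation between recorded samples
    w <- (log(thr) - log(L[i - 1])) / (log(L[i]) - log(L[i - 1]))
    tb[i - 1] + w * (tb[i] - tb[i - 1])
  }
  t1 <- cross(th[1]); t2 <- cross(th[2])
  data.frame(molt = c("L1_L2", "L2_L3"), age_since_birth = c(t1, t2),
             L_threshold = th,
             duration = c(t1, t2 - t1))
}

#' Survival curve of a simulated life cycle
#'
#' The survival probability S(t) = exp(-integral of the hazard), with hazard
#' `h = c_T (h_b + k_starv max(0, 1 - kap pC / pS))` in kappa-rule stages
#' (relative shortfall of the somatic-maintenance share) and the analogous
#' total-maintenance shortfall in Phase II and the imago. Hazard accrues from
#' hatching; the embryo is assigned survival 1.
#'
#' @param x a `deb_lifecycle` object.
#' @return data frame with columns `t_d` (days since oviposition), `stage`
#'   and `S`.
#' @export
survival_curve <- function(x) {
  stopifnot(inherits(x, "deb_lifecycle"))
  data.frame(t_d = x$trajectory$t_d, stage = x$trajectory$stage,
             S = x$trajectory$survival)
}

#' Life-history report of a simulation
#'
#' @param x a `deb_lifecycle` object.
#' @return the report list: egg energy `E_0`, `age_at_birth` (since
#'   oviposition), event ages since birth (`t_molt1`, `t_molt2`,
#'   `t_puberty`, `t_phase_switch`, `t_pupation`, `t_emergence`), structural
#'   lengths at events, `s_M_final`, egg number `N_i`, and `status`.
#' @export
life_history <- function(x) {
  stopifnot(inherits(x, "deb_lifecycle"))
  x$report
}
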