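# Calibration dataset schema: zero-variate points and uni-variate series in
# the observation space of the estimation procedure.

DATASET_OBSERVABLES <- c("age_event", "instar_duration", "length",
                         "wet_weight", "dry_weight", "eggs_per_female",
                         "survival_fraction")
DATASET_EVENTS <- c("birth", "molt1", "molt2", "puberty", "phase_switch",
                    "pupation", "emergence", "egg")

#' Calibration dataset
#'
#' A single dataset in the estimation schema: either zero-variate (one
#' point, e.g. an event age or a length at an event) or uni-variate (a
#' series against age since hatch). Each dataset carries the forcing
#' scenario under which it was observed and a weight coefficient.
#'
#' @param name dataset label.
#' @param kind `"zero_variate"` or `"uni_variate"`.
#' @param observable one of `"age_event"`, `"instar_duration"`, `"length"`,
#'   `"wet_weight"`, `"dry_weight"`, `"eggs_per_female"`,
#'   `"survival_fraction"`. Ages and durations are in d, lengths in cm,
#'   weights in mg.
#' @param y observed value(s).
#' @param x ages since hatch (d) for uni-variate datasets; `NA` for
#'   zero-variate ones.
#' @param event for zero-variate event-linked observables: one of
#'   `"birth"`, `"molt1"`, `"molt2"`, `"puberty"`, `"phase_switch"`,
#'   `"pupation"`, `"emergence"`, `"egg"`. Event ages are reported since
#'   oviposition for `"birth"` and since hatch for all later events.
#' @param scenario the [deb_scenario()] under which the data were collected.
#' @param weight dataset weight coefficient (non-negative).
#' @param shape `"alive"` or `"dead"`: which shape coefficient converts
#'   structure to physical length for this dataset.
#' @param units free-text unit label (documentation only).
#' @return an object of class `deb_dataset`.
#' @export
deb_dataset <- function(name, kind = c("zero_variate", "uni_variate"),
                        observable, y, x = NA_real_, event = NA_character_,
                        scenario = deb_scenario(), weight = 1,
                        shape = c("alive", "dead"), units = "") {
  kind <- match.arg(kind)
  shape <- match.arg(shape)
  if (!observable %in% DATASET_OBSERVABLES) {
    stop("unknown observable '", observable, "'")
  }
  if (!is.na(event) && !event %in% DATASET_EVENTS) {
    stop("unknown event '", event, "'")
  }
  if (!is.numeric(weight) || weight < 0) stop("weight must be non-negative")
  if (kind == "zero_variate" && length(y) != 1L) {
    stop("zero-variate datasets have a single value")
  }
  if (kind == "uni_variate" && (anyNA(x) || length(x) != length(y))) {
    stop("uni-variate datasets need matching x and y")
  }
  structure(list(name = name, kind = kind, observable = observable,
                 x = as.numeric(x), y = as.numeric(y), event = event,
                 scenario = scenario, weight = weight, shape = shape,
                 units = units),
            class = "deb_dataset")
}

#' @export
print.deb_dataset <- function(x, ...) {
  cat(sprintf("<deb_dataset '%s': %s %s, n = %d, weight = %g>\n", x$name,
              x$kind, x$observable, length(x$y), x$weight))
  invisible(x)
}

# A key identifying the simulation a dataset needs, so that datasets sharing
# a scenario share one simulation per parameter evaluation.
scenario_key <- function(sc) {
  paste(sc$T_c, sc$f_mode,
        if (sc$f_mode == "constant") sc$f_value else
          paste(sc$breakpoints$t, sc$breakpoints$f, collapse = ","),
        sc$sex, sc$horizon, sep = "|")
}

# Model predictions for one dataset given a completed simulation.
predict_from_sim <- function(ds, sim, comp = comp_params()) {
  r <- sim$report
  p <- params_for_sex(sim$params, sim$scenario$sex)
  dm <- if (ds$shape == "dead") p$del_M2 else p$del_M1
  event_age <- function(ev) switch(ev,
    birth = r$age_at_birth,        # since oviposition
    molt1 = r$t_molt1, molt2 = r$t_molt2, puberty = r$t_puberty,
    phase_switch = r$t_phase_switch, pupation = r$t_pupation,
    emergence = r$t_emergence, stop("no age for event '", ev, "'"))
  event_V <- function(ev) switch(ev,
    birth = r$states$birth[["V"]], puberty = r$states$puberty[["V"]],
    phase_switch = r$states$phase_switch[["V"]], pupation = r$V_j,
    emergence = r$states$emergence[["V"]],
    stop("no structural volume recorded for event '", ev, "'"))
  tr <- sim$trajectory
  keep <- !duplicated(tr$t_d)
  tb <- tr$t_d[keep] - r$age_at_birth   # age since hatch
  interp <- function(vals, xout) stats::approx(tb, vals[keep], xout = xout,
                                               rule = 2)$y
  if (ds$observable == "age_event") {
    return(event_age(ds$event))
  }
  if (ds$observable == "instar_duration") {
    d <- switch(ds$event,
      molt1 = r$t_molt1,
      molt2 = r$t_molt2 - r$t_molt1,
      puberty = r$t_puberty - r$t_molt2,
      stop("instar durations are keyed by events molt1/molt2/puberty"))
    return(d)
  }
  if (ds$observable == "eggs_per_female") {
    return(r$N_i)
  }
  if (ds$observable == "length") {
    if (ds$kind == "zero_variate") {
      return(physical_length(event_V(ds$event), dm))
    }
    return(physical_length(pmax(interp(tr$V_cm3, ds$x), 0), dm))
  }
  if (ds$observable %in% c("wet_weight", "dry_weight")) {
    if (ds$kind == "zero_variate" && identical(ds$event, "egg")) {
      # the freshly laid egg is all reserve
      w <- comp$mass_per_energy * r$E_0
      return(1e3 * w)
    }
    if (ds$kind == "zero_variate") {
      st <- r$states[[ds$event]]
      if (is.null(st)) stop("no state recorded at event '", ds$event, "'")
      w <- deb_weights(st[["E"]], st[["V"]],
                       if ("E_R" %in% names(st)) st[["E_R"]] else 0, comp)
    } else {
      w <- deb_weights(pmax(interp(tr$E_J, ds$x), 0),
                       pmax(interp(tr$V_cm3, ds$x), 0),
                       pmax(interp(tr$ER_J, ds$x), 0), comp)
    }
    return(1e3 * if (ds$observable == "wet_weight") w$wet else w$dry)
  }
  if (ds$observable == "survival_fraction") {
    return(interp(tr$survival, ds$x))
  }
  stop("unhandled observable")
}

#' Model predictions for calibration datasets
#'
#' Simulates each distinct scenario once and maps the resulting life-history
#' report and trajectory onto the observation space of every dataset.
#'
#' @param p a [deb_params()] object.
#' @param datasets a list of [deb_dataset()] objects.
#' @param comp a [comp_params()] object.
#' @param rtol,E0_tol integration controls (looser defaults than
#'   [deb_lifecycle()] for speed during estimation).
#' @return list of numeric prediction vectors, parallel to `datasets`.
#' @export
predict_datasets <- function(p, datasets, comp = comp_params(),
                             rtol = 1e-8, E0_tol = 1e-10) {
  if (inherits(datasets, "deb_dataset")) datasets <- list(datasets)
  keys <- vapply(datasets, function(d) scenario_key(d$scenario), character(1))
  sims <- list()
  for (k in unique(keys)) {
    sc <- datasets[[match(k, keys)]]$scenario
    sims[[k]] <- deb_lifecycle(p, sc, rtol = rtol, pts_per_day = 12,
                               E0_tol = E0_tol)
  }
  out <- lapply(seq_along(datasets), function(i) {
    predict_from_sim(datasets[[i]], sims[[keys[i]]], comp)
  })
  names(out) <- vapply(datasets, `[[`, character(1), "name")
  out
}

#' Packaged zero-variate observations
#'
#' Loads the bundled table of zero-variate observations (event ages, lengths,
#' weights, instar durations) for *C. riparius* as a list of
#' [deb_dataset()] objects, so the calibration machinery can be exercised
#' without transcribing anything. Where the feeding conditions of the source
#' were unspecified, the conventional abundant-food scenario (f = 1) at the
#' recorded temperature is attached.
#'
#' @param horizon scenario horizon passed to the attached scenarios, d.
#' @return list of `deb_dataset` objects.
#' @export
zero_variate_data <- function(horizon = 200) {
  path <- system.file("extdata", "zero_variate_data.csv",
                      package = "chirodeb")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    deb_dataset(name = row$name, kind = "zero_variate",
                observable = row$observable, y = row$y,
                event = row$event,
                scenario = deb_scenario(T_c = row$temperature_C, f = 1,
                                        horizon = horizon),
                weight = row$weight, shape = row$shape, units = row$units)
  })
}
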