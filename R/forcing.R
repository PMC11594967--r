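# Forcing scenarios: constant temperature plus a constant or piecewise-linear
# scaled functional response f(t), with t measured in days since birth
# (the embryo does not feed, so f before birth is irrelevant).

#' Food and temperature forcing scenario
#'
#' @param T_c water temperature, degC (constant within a scenario).
#' @param f constant scaled functional response (ignored when `breakpoints`
#'   is given). Values above 1 are allowed and represent diets or protocols
#'   richer than the reference ad libitum condition.
#' @param breakpoints optional data frame with columns `t` (days since
#'   birth, strictly increasing) and `f` (non-negative): a piecewise-linear
#'   profile, held constant beyond the first and last breakpoint.
#' @param sex `"female"` or `"male"`. Males use the male maximum assimilation
#'   rate; all other parameters are shared.
#' @param horizon simulation cap, days since oviposition.
#' @return an object of class `deb_scenario`.
#' @seealso [scenario_variable_f()], [f_at()]
#' @export
deb_scenario <- function(T_c = 21, f = 1, breakpoints = NULL,
                         sex = c("female", "male"), horizon = 200) {
  sex <- match.arg(sex)
  if (!is.numeric(T_c) || length(T_c) != 1L || !is.finite(T_c)) {
    stop("T_c must be a finite scalar (degC)")
  }
  if (!is.null(breakpoints)) {
    bp <- as.data.frame(breakpoints)
    if (!all(c("t", "f") %in% names(bp))) {
      stop("breakpoints must have columns 't' and 'f'")
    }
    if (any(diff(bp$t) <= 0)) stop("breakpoint times must be strictly increasing")
    if (any(bp$f < 0)) stop("f values must be non-negative")
    mode <- "piecewise"
  } else {
    if (!is.numeric(f) || length(f) != 1L || f < 0) {
      stop("f must be a non-negative scalar")
    }
    bp <- NULL
    mode <- "constant"
  }
  if (horizon <= 0) stop("horizon must be positive")
  structure(list(T_c = T_c, f_mode = mode, f_value = if (mode == "constant") f,
                 breakpoints = bp, sex = sex, horizon = horizon),
            class = "deb_scenario")
}

#' Declining-food scenario of the growth experiments
#'
#' The time-variable functional response used for the growth and reproduction
#' experiments: food is ad libitum (`f = 1`) from birth until puberty, then
#' declines linearly to `f_min` over `decline_duration` days, and is held at
#' `f_min` afterwards.
#'
#' @param f_min terminal scaled functional response in \[0, 1\]; richer
#'   profiles (f above 1) must be supplied as explicit breakpoints to
#'   [deb_scenario()].
#' @param t_puberty time since birth at which the decline starts, d.
#' @param decline_duration duration of the linear decline, d (default 7.5,
#'   the value estimated for the growth experiments at 21 degC).
#' @param ... passed on to [deb_scenario()] (`T_c`, `sex`, `horizon`).
#' @return a `deb_scenario` with a piecewise-linear f profile.
#' @export
scenario_variable_f <- function(f_min, t_puberty, decline_duration = 7.5, ...) {
  if (!is.numeric(f_min) || length(f_min) != 1L || f_min < 0 || f_min > 1) {
    stop("f_min must lie in [0, 1]; use explicit breakpoints for f > 1")
  }
  if (t_puberty < 0 || decline_duration <= 0) {
    stop("t_puberty must be non-negative and decline_duration positive")
  }
  deb_scenario(breakpoints = data.frame(
    t = c(0, t_puberty, t_puberty + decline_duration),
    f = c(1, 1, f_min)), ...)
}

#' Evaluate the scaled functional response of a scenario
#'
#' Pure evaluation of `f(t)`; repeated calls at the same time return the same
#' value. Piecewise profiles interpolate linearly between breakpoints and are
#' constant outside them.
#'
#' @param scenario a [deb_scenario()] object.
#' @param t time(s) since birth, d.
#' @return numeric vector of f values.
#' @export
f_at <- function(scenario, t) {
  stopifnot(inherits(scenario, "deb_scenario"))
  if (scenario$f_mode == "constant") {
    return(rep(scenario$f_value, length(t)))
  }
  bp <- scenario$breakpoints
  stats::approx(bp$t, bp$f, xout = t, rule = 2)$y
}

# Breakpoint times (since birth) at which integration must be restarted so
# that event roots are never bracketed across a derivative discontinuity.
f_breakpoints <- function(scenario) {
  if (scenario$f_mode == "constant") numeric(0) else scenario$breakpoints$t
}

scenario_T_K <- function(scenario) scenario$T_c + 273.15

#' @export
print.deb_scenario <- function(x, ...) {
  fdesc <- if (x$f_mode == "constant") {
    paste0("constant f = ", format(x$f_value))
  } else {
    paste0("piecewise-linear f through (",
           paste(sprintf("%g d: %g", x$breakpoints$t, x$breakpoints$f),
                 collapse = "; "), ")")
  }
  cat("Forcing scenario: T =", x$T_c, "degC;", fdesc, ";", x$sex,
      "; horizon", x$horizon, "d\n")
  invisible(x)
}

#' Read / write scenarios as YAML
#'
#' @param path file path.
#' @return `read_deb_scenario()` returns a `deb_scenario`;
#'   `write_deb_scenario()` returns `path` invisibly.
#' @rdname scenario_io
#' @export
read_deb_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  if (identical(x$f_mode, "piecewise")) {
    deb_scenario(T_c = x$T_celsius,
                 breakpoints = data.frame(t = as.numeric(x$breakpoint_t),
                                          f = as.numeric(x$breakpoint_f)),
                 sex = x$sex %||% "female",
                 horizon = x$horizon_days %||% 200)
  } else {
    deb_scenario(T_c = x$T_celsius, f = x$f_value %||% 1,
                 sex = x$sex %||% "female",
                 horizon = x$horizon_days %||% 200)
  }
}

#' @param scenario a `deb_scenario` object.
#' @rdname scenario_io
#' @export
write_deb_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "deb_scenario"))
  x <- list(T_celsius = scenario$T_c, f_mode = scenario$f_mode,
            sex = scenario$sex, horizon_days = scenario$horizon)
  if (scenario$f_mode == "constant") {
    x$f_value <- scenario$f_value
  } else {
    x$breakpoint_t <- scenario$breakpoints$t
    x$breakpoint_f <- scenario$breakpoints$f
  }
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
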