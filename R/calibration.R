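# Estimation machinery: symmetric bounded loss, goodness-of-fit metrics
# (MRE, SMSE) and simultaneous Nelder-Mead fitting across datasets with
# pseudo-data support.

#' Symmetric bounded loss
#'
#' Per-point contribution `w (d - p)^2 / (d^2 + p^2)` with the 0/0 case
#' defined as 0. Each contribution is symmetric in data and prediction,
#' invariant under common rescaling of both, and bounded by its weight for
#' non-negative values.
#'
#' @param data,predictions numeric vectors of equal length.
#' @param weights non-negative weights (default 1).
#' @return scalar loss.
#' @export
sb_loss <- function(data, predictions, weights = 1) {
  if (length(data) != length(predictions)) {
    stop("data and predictions must have equal length")
  }
  if (any(weights < 0)) stop("weights must be non-negative")
  den <- data^2 + predictions^2
  contrib <- ifelse(den == 0, 0, (data - predictions)^2 / den)
  sum(weights * contrib)
}

#' Goodness of fit: MRE and SMSE
#'
#' The mean relative error and symmetric mean squared error over a
#' collection of datasets. Within each dataset, points are weighted by the
#' normalised point weights; across datasets, the per-dataset means are
#' combined weighted by the dataset weight coefficients. Data equal to zero
#' are excluded from the MRE (with a warning) since their relative error is
#' undefined; the SMSE handles them through its bounded symmetric form.
#' Both metrics are 0 exactly when predictions equal the data on all
#' weighted points, and the SMSE is bounded in \[0, 1\].
#'
#' @param datasets list of [deb_dataset()] objects.
#' @param predictions list of prediction vectors parallel to `datasets`
#'   (e.g. from [predict_datasets()]). If `NULL`, computed from `p`.
#' @param p parameters used to compute predictions when `predictions` is
#'   `NULL`.
#' @param comp composition parameters for weight observables.
#' @return object of class `deb_gof`: list with `loss`, `MRE`, `SMSE` and a
#'   `per_dataset` data frame of relative errors.
#' @export
goodness_of_fit <- function(datasets, predictions = NULL, p = NULL,
                            comp = comp_params()) {
  if (inherits(datasets, "deb_dataset")) datasets <- list(datasets)
  if (is.null(predictions)) {
    if (is.null(p)) stop("supply either predictions or parameters")
    predictions <- predict_datasets(p, datasets, comp)
  }
  stopifnot(length(predictions) == length(datasets))
  W <- vapply(datasets, `[[`, numeric(1), "weight")
  rel <- smse <- lossv <- numeric(length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]$y
    pr <- as.numeric(predictions[[i]])
    ok <- is.finite(d) & is.finite(pr)
    d <- d[ok]; pr <- pr[ok]
    n <- length(d)
    if (!n) { rel[i] <- smse[i] <- lossv[i] <- NA_real_; next }
    nz <- d != 0
    if (any(!nz)) {
      warning("excluding ", sum(!nz), " zero-valued point(s) from the MRE in dataset '",
              datasets[[i]]$name, "'")
    }
    rel[i] <- if (any(nz)) mean(abs(pr[nz] - d[nz]) / abs(d[nz])) else NA_real_
    den <- d^2 + pr^2
    smse[i] <- mean(ifelse(den == 0, 0, (d - pr)^2 / den))
    lossv[i] <- sb_loss(d, pr, weights = W[i] / n)
  }
  use <- is.finite(rel) & W > 0
  mre <- if (any(use)) sum(W[use] * rel[use]) / sum(W[use]) else NA_real_
  use2 <- is.finite(smse) & W > 0
  sm <- if (any(use2)) sum(W[use2] * smse[use2]) / sum(W[use2]) else NA_real_
  structure(list(loss = sum(lossv, na.rm = TRUE), MRE = mre, SMSE = sm,
                 per_dataset = data.frame(
                   name = vapply(datasets, `[[`, character(1), "name"),
                   n = vapply(datasets, function(d) length(d$y), numeric(1)),
                   weight = W, mean_relative_error = rel,
                   symmetric_squared_error = smse)),
            class = "deb_gof")
}

#' @export
print.deb_gof <- function(x, ...) {
  cat(sprintf("Goodness of fit: loss = %.4g, MRE = %.4g, SMSE = %.4g\n",
              x$loss, x$MRE, x$SMSE))
  print(x$per_dataset, row.names = FALSE, digits = 4)
  invisible(x)
}

# Total objective: symmetric bounded loss over the datasets plus pseudo-data
# terms (the maintenance ratio k with target 1 by default).
calibration_objective <- function(theta, free, base, datasets, comp,
                                  pseudo, pseudo_weight, rtol, E0_tol) {
  p <- base
  p[free] <- as.list(exp(theta))
  p <- tryCatch(validate_deb_params(p), error = function(e) NULL)
  if (is.null(p)) return(1e8)
  preds <- tryCatch(
    predict_datasets(p, datasets, comp, rtol = rtol, E0_tol = E0_tol),
    error = function(e) NULL)
  if (is.null(preds)) return(1e8)
  total <- 0
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]$y
    pr <- as.numeric(preds[[i]])
    ok <- is.finite(d) & is.finite(pr)
    if (!any(ok)) return(1e8)   # a trigger became unreachable
    total <- total + sb_loss(d[ok], pr[ok],
                             weights = datasets[[i]]$weight / sum(ok))
  }
  if (!is.null(pseudo$k)) {
    k <- maintenance_ratio(p)
    total <- total + pseudo_weight * (k - pseudo$k)^2 / (k^2 + pseudo$k^2)
  }
  total
}

#' Fit DEB parameters to datasets
#'
#' Simultaneous estimation of a free subset of the parameters across all
#' supplied datasets by Nelder-Mead minimisation of the symmetric bounded
#' loss, in log-transformed parameter space (which enforces positivity).
#' Pseudo-data are weakly weighted prior-like targets added to the loss; by
#' default the maintenance ratio k = `k_J E_G / p_M` with target 1, which
#' stabilises the maintenance parameters and keeps event lengths nearly
#' food-independent. Optional jittered restarts (deterministic under the
#' seed) guard against simplex stagnation; the best run is returned.
#'
#' @param datasets list of [deb_dataset()] objects.
#' @param free character vector of parameter names to estimate (subset of
#'   the [deb_params()] names). Empty: no optimisation, the start values are
#'   evaluated and returned.
#' @param start starting (and fixed-value) parameter set.
#' @param pseudo named list of pseudo-data targets; currently `k` (the
#'   maintenance ratio) is supported. `NULL` disables pseudo-data.
#' @param pseudo_weight weight of each pseudo-datum relative to a unit-weight
#'   data point.
#' @param restarts number of additional jittered starts.
#' @param seed seed making the jittered restarts reproducible.
#' @param control passed to [stats::optim()] (`maxit`, `reltol`).
#' @param comp composition parameters for weight observables.
#' @param rtol,E0_tol integration controls used during estimation.
#' @return an object of class `deb_fit` with components `params` (fitted
#'   full parameter set), `estimate` (named vector of fitted values),
#'   `start`, `free`, `loss`, `gof` (a [goodness_of_fit()] report at the
#'   optimum), `convergence` (0 = converged), `trace` (accepted-step log)
#'   and `datasets`.
#' @export
deb_calibrate <- function(datasets, free = character(0),
                          start = deb_params(), pseudo = list(k = 1),
                          pseudo_weight = 0.1, restarts = 0L, seed = 1L,
                          control = list(maxit = 500, reltol = 1e-8),
                          comp = comp_params(), rtol = 1e-8, E0_tol = 1e-10) {
  stopifnot(inherits(start, "deb_params"))
  if (inherits(datasets, "deb_dataset")) datasets <- list(datasets)
  if (!length(datasets)) stop("no datasets supplied")
  bad <- setdiff(free, names(.default_params()))
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  trace_env <- new.env(parent = emptyenv())
  trace_env$log <- list()
  trace_env$best <- Inf
  obj <- function(theta) {
    v <- calibration_objective(theta, free, start, datasets, comp, pseudo,
                               pseudo_weight, rtol, E0_tol)
    if (v < trace_env$best) {
      trace_env$best <- v
      trace_env$log[[length(trace_env$log) + 1L]] <-
        c(value = v, exp(theta))
    }
    v
  }
  if (!length(free)) {
    gof <- goodness_of_fit(datasets, p = start, comp = comp)
    return(structure(list(params = start, estimate = numeric(0),
                          start = start, free = free, loss = gof$loss,
                          gof = gof, convergence = 0L,
                          trace = data.frame(), datasets = datasets),
                     class = "deb_fit"))
  }
  theta0 <- log(unlist(start[free]))
  set.seed(as.integer(seed))
  starts <- c(list(theta0),
              lapply(seq_len(restarts), function(i) {
                theta0 + stats::rnorm(length(theta0), sd = 0.05)
              }))
  best <- NULL
  for (th in starts) {
    # Nelder-Mead also in one dimension, for a uniform deterministic path
    # (optim warns that 1-d simplex search can be unreliable)
    o <- suppressWarnings(
      stats::optim(th, obj, method = "Nelder-Mead", control = control))
    if (is.null(best) || o$value < best$value) best <- o
  }
  fitted <- start
  fitted[free] <- as.list(exp(best$par))
  fitted <- validate_deb_params(fitted)
  gof <- goodness_of_fit(datasets, p = fitted, comp = comp)
  trace <- if (length(trace_env$log)) {
    as.data.frame(do.call(rbind, trace_env$log))
  } else data.frame()
  structure(list(params = fitted,
                 estimate = stats::setNames(exp(best$par), free),
                 start = start, free = free, loss = best$value, gof = gof,
                 convergence = best$convergence, trace = trace,
                 datasets = datasets, seed = seed, restarts = restarts),
            class = "deb_fit")
}

#' @export
print.deb_fit <- function(x, ...) {
  cat("DEB model fit (Nelder-Mead, symmetric bounded loss)\n")
  cat(sprintf("  %d dataset(s); %d free parameter(s); loss = %.5g; %s\n",
              length(x$datasets), length(x$free), x$loss,
              if (identical(x$convergence, 0L)) "converged"
              else "NOT converged (best-so-far returned)"))
  if (length(x$free)) {
    st <- unlist(x$start[x$free])
    tab <- data.frame(start = st, fitted = x$estimate,
                      change = x$estimate / st - 1)
    print(tab, digits = 4)
  }
  cat(sprintf("  MRE = %.4g, SMSE = %.4g\n", x$gof$MRE, x$gof$SMSE))
  invisible(x)
}

#' @export
coef.deb_fit <- function(object, ...) object$estimate

#' @export
summary.deb_fit <- function(object, ...) {
  out <- list(fit = object, gof = object$gof,
              n_eval = nrow(object$trace))
  class(out) <- "summary.deb_fit"
  out
}

#' @export
print.summary.deb_fit <- function(x, ...) {
  print(x$fit)
  print(x$gof)
  cat(sprintf("accepted improvements logged: %d\n", x$n_eval))
  invisible(x)
}

#' @export
predict.deb_fit <- function(object, newdata = NULL, ...) {
  ds <- if (is.null(newdata)) object$datasets else newdata
  predict_datasets(object$params, ds)
}

#' @export
residuals.deb_fit <- function(object, ...) {
  preds <- predict_datasets(object$params, object$datasets)
  lapply(seq_along(object$datasets), function(i) {
    as.numeric(preds[[i]]) - object$datasets[[i]]$y
  })
}

#' @export
simulate.deb_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(1e6, nsim)
  sc <- object$datasets[[1]]$scenario
  lapply(seeds, function(s) {
    synthetic_datasets(object$params, sc, seed = s, ...)
  })
}
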