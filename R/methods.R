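# S3 methods for simulated life cycles.

#' @export
print.deb_lifecycle <- function(x, ...) {
  r <- x$report
  cat("Simulated C. riparius life cycle (hax DEB model)\n")
  print(x$scenario)
  cat(sprintf("  status: %s\n", r$status))
  cat(sprintf("  E_0 = %.4g J; age at birth %.2f d; L_b = %.4g cm\n",
              r$E_0, r$age_at_birth, r$L_b))
  ev <- c("molt L1->L2" = r$t_molt1, "molt L2->L3" = r$t_molt2,
          "puberty (L3->L4)" = r$t_puberty,
          "phase switch (ER/V = [ERj])" = r$t_phase_switch,
          "pupation (E/V = [Em])" = r$t_pupation,
          "emergence" = r$t_emergence)
  for (i in seq_along(ev)) {
    if (!is.na(ev[i])) {
      cat(sprintf("  %-28s %7.2f d since birth\n", names(ev)[i], ev[i]))
    }
  }
  if (!is.na(r$N_i)) {
    cat(sprintf("  s_M = %.3f; L_j = %.4g cm; eggs/female N_i = %.1f\n",
                r$s_M_final, r$L_j, r$N_i))
  }
  invisible(x)
}

#' @export
summary.deb_lifecycle <- function(object, comp = comp_params(), ...) {
  r <- object$report
  p <- object$params
  out <- list(status = r$status, scenario = object$scenario, report = r)
  if (!is.na(r$t_pupation)) {
    st <- r$states$pupation
    w <- deb_weights(st[["E"]], st[["V"]], st[["E_R"]], comp)
    out$wet_weight_at_pupation_mg <- 1e3 * w$wet
    out$length_at_pupation_cm <- c(
      alive = physical_length(r$V_j, p$del_M1),
      dead = physical_length(r$V_j, p$del_M2))
  }
  if (!is.na(r$t_emergence)) {
    st <- r$states$emergence
    w <- deb_weights(st[["E"]], st[["V"]], st[["E_R"]], comp)
    out$imago_dry_weight_mg <- 1e3 * w$dry
  }
  out$egg_dry_weight_mg <- 1e3 * comp$mass_per_energy * r$E_0
  class(out) <- "summary.deb_lifecycle"
  out
}

#' @export
print.summary.deb_lifecycle <- function(x, ...) {
  r <- x$report
  cat("Life-history summary\n")
  df <- data.frame(
    quantity = c("age at birth (d)", "time since birth at puberty (d)",
                 "time since birth at pupation (d)",
                 "time since birth at emergence (d)",
                 "acceleration factor s_M", "eggs per female"),
    value = c(r$age_at_birth, r$t_puberty, r$t_pupation, r$t_emergence,
              r$s_M_final, r$N_i))
  print(df, row.names = FALSE, digits = 4)
  if (!is.null(x$length_at_pupation_cm)) {
    cat(sprintf("length at pupation: %.3f cm (alive) / %.3f cm (dead)\n",
                x$length_at_pupation_cm[["alive"]],
                x$length_at_pupation_cm[["dead"]]))
  }
  if (!is.null(x$wet_weight_at_pupation_mg)) {
    cat(sprintf("wet weight at pupation: %.2f mg\n",
                x$wet_weight_at_pupation_mg))
  }
  if (!is.null(x$imago_dry_weight_mg)) {
    cat(sprintf("imago dry weight: %.2f mg\n", x$imago_dry_weight_mg))
  }
  cat(sprintf("egg dry weight: %.3g mg\n", x$egg_dry_weight_mg))
  invisible(x)
}

#' @export
as.data.frame.deb_lifecycle <- function(x, ...) x$trajectory

#' Plot a simulated life cycle
#'
#' Four panels: physical length, wet and dry weight, reserve and
#' reproduction-buffer densities (with their pupation thresholds), and the
#' survival curve, all against age since oviposition with life-history
#' events marked.
#'
#' @param x a `deb_lifecycle` object.
#' @param comp a [comp_params()] object for the weight panel.
#' @param ... ignored.
#' @export
plot.deb_lifecycle <- function(x, comp = comp_params(), ...) {
  tr <- deb_observables(x, comp)
  r <- x$report
  ev <- r$age_at_birth + c(r$t_puberty, r$t_phase_switch, r$t_pupation,
                           r$t_emergence)
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  mark <- function() graphics::abline(v = ev, lty = 3, col = "grey50")
  graphics::plot(tr$t_d, tr$length_cm_alive, type = "l",
                 xlab = "age (d)", ylab = "physical length (cm)",
                 main = "length (alive shape)")
  mark()
  graphics::matplot(tr$t_d, cbind(tr$wet_weight_mg, tr$dry_weight_mg),
                    type = "l", lty = 1, col = c("steelblue", "tomato"),
                    xlab = "age (d)", ylab = "weight (mg)", main = "weight")
  graphics::legend("topleft", c("wet", "dry"), lty = 1, bty = "n",
                   col = c("steelblue", "tomato"))
  mark()
  dens <- cbind(tr$E_J / pmax(tr$V_cm3, 1e-300),
                tr$ER_J / pmax(tr$V_cm3, 1e-300))
  graphics::matplot(tr$t_d, dens, type = "l", lty = 1,
                    col = c("black", "purple"), xlab = "age (d)",
                    ylab = "density (J/cm3)", main = "[E] and [ER]",
                    ylim = c(0, 1.1 * max(x$Em, x$params$E_Rj)))
  graphics::abline(h = c(x$Em, x$params$E_Rj), lty = 2,
                   col = c("black", "purple"))
  mark()
  graphics::plot(tr$t_d, tr$survival, type = "l", ylim = c(0, 1),
                 xlab = "age (d)", ylab = "S(t)", main = "survival")
  mark()
  invisible(x)
}

#' Write trajectory and report files
#'
#' @param x a `deb_lifecycle` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @rdname lifecycle_io
#' @export
write_trajectory_csv <- function(x, path) {
  stopifnot(inherits(x, "deb_lifecycle"))
  tr <- x$trajectory[, c("t_d", "E_J", "V_cm3", "EH_J", "ER_J", "stage",
                         "survival")]
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}

#' @rdname lifecycle_io
#' @export
write_report_json <- function(x, path) {
  stopifnot(inherits(x, "deb_lifecycle"))
  r <- x$report
  r$states <- lapply(r$states, as.list)
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
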