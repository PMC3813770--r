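# Print, summary, and plot methods for the result classes.

#' @export
print.pool_state <- function(x, ...) {
  cat("<pool_state> ", length(x$soc), " layers\n", sep = "")
  cat(sprintf("  SOC %.4g  MBC %.4g  aqueous-DOC conc. range [%.3g, %.3g]\n",
              sum(x$soc), sum(x$mbc), min(x$doc), max(x$doc)))
  invisible(x)
}

#' @export
print.season_run <- function(x, ...) {
  l <- x$ledger
  cat("<season_run> ", x$hours, " h, ", x$column$n_layers, " layers\n",
      sep = "")
  cat(sprintf("  CO2 (g C m-2): hydrolysis %.3f, growth %.3f, maintenance %.3f\n",
              g_cm2_to_g_m2(sum(l$co2_hydrolysis)),
              g_cm2_to_g_m2(sum(l$co2_growth)),
              g_cm2_to_g_m2(sum(l$co2_maintenance))))
  cat(sprintf("  DOC export %.3f, inputs: SOC %.3f + DOC %.3f g C m-2\n",
              g_cm2_to_g_m2(l$doc_export),
              g_cm2_to_g_m2(l$i_soc_applied),
              g_cm2_to_g_m2(l$i_doc_applied)))
  cat(sprintf("  mass-balance residual (relative): %.2e\n", x$residual))
  invisible(x)
}

#' @export
summary.season_run <- function(object, ...) {
  l <- object$ledger
  out <- data.frame(
    component = c("co2_hydrolysis", "co2_growth", "co2_maintenance",
                  "doc_export", "i_soc", "i_doc"),
    g_C_m2 = g_cm2_to_g_m2(c(sum(l$co2_hydrolysis), sum(l$co2_growth),
                             sum(l$co2_maintenance), l$doc_export,
                             l$i_soc_applied, l$i_doc_applied)))
  out
}

#' @export
print.priming_result <- function(x, ...) {
  cat("<priming_result>\n")
  cat(sprintf("  total real priming: %.4f g C m-2 season-1 (%s)\n",
              x$total,
              if (x$total >= 0) "stimulation" else "suppression"))
  cat(sprintf("  treatment CO2 %.2f vs baseline CO2 %.2f g C m-2\n",
              x$treatment_co2, x$baseline_co2))
  invisible(x)
}

#' @export
plot.priming_result <- function(x, ...) {
  graphics::plot(x$per_layer, -x$depth, type = "b", pch = 16,
                 xlab = "priming (g C m-2 season-1)",
                 ylab = "depth (cm)", ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' @export
plot.doc_forcing <- function(x, layers = c(1, ncol(x$T)), ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::matplot(x$time / 24, x$T[, layers], type = "l", lty = 1,
                    xlab = "day of season", ylab = "T (degC)", ...)
  graphics::matplot(x$time / 24, x$M[, layers], type = "l", lty = 1,
                    xlab = "day of season", ylab = "theta", ...)
  invisible(x)
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> ", x$param_name, "\n", sep = "")
  cat(sprintf("  SI = %.4g (reference priming %.4g g C m-2)\n",
              x$si, x$reference_pe))
  print(x$table, row.names = FALSE)
  invisible(x)
}
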