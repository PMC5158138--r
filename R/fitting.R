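# Quality-of-fit between simulated and experimental engulfment dynamics:
# chi^2 = sum_i [ (Vi_exp - Vi_sim)^2 / sd^2(Vi_exp)
#               + (Si_exp - Si_sim)^2 / sd^2(Si_exp)
#               + (Ei_exp - Ei_sim)^2 / sd^2(Ei_exp) ]
# summed over experimental time points, with the simulated trace linearly
# interpolated to the experimental times (the experimental sd is defined
# per experimental point).

#' Chi-square comparison of two engulfment traces
#'
#' @param exp_trace experimental [engulfment_trace()] with positive
#'   standard-deviation columns `sd_V`, `sd_S`, `sd_E`.
#' @param sim_trace simulated [engulfment_trace()]; must cover the
#'   experimental time range.
#' @return object of class `fit_result`: `chi2`, per-channel contributions
#'   `chi2_V`, `chi2_S`, `chi2_E`, `n_points` and `params` (free slot).
#' @export
chi2 <- function(exp_trace, sim_trace) {
  for (s in c("sd_V", "sd_S", "sd_E")) {
    if (any(!is.finite(exp_trace[[s]])) || any(exp_trace[[s]] <= 0))
      stop("every experimental point needs a positive standard deviation ('",
           s, "')")
  }
  t_exp <- exp_trace$time
  if (min(t_exp) < min(sim_trace$time) - 1e-9 ||
      max(t_exp) > max(sim_trace$time) + 1e-9)
    stop("simulated trace does not cover the experimental time range")
  interp <- function(col)
    approx(sim_trace$time, sim_trace[[col]], xout = t_exp, rule = 2)$y
  cV <- sum(((exp_trace$V - interp("V")) / exp_trace$sd_V)^2)
  cS <- sum(((exp_trace$S - interp("S")) / exp_trace$sd_S)^2)
  cE <- sum(((exp_trace$E - interp("E")) / exp_trace$sd_E)^2)
  structure(list(chi2 = cV + cS + cE, chi2_V = cV, chi2_S = cS, chi2_E = cE,
                 n_points = length(t_exp), params = NULL),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> chi2 = %.4g over %d time points (V %.4g, S %.4g, E %.4g)\n",
              x$chi2, x$n_points, x$chi2_V, x$chi2_S, x$chi2_E))
  if (!is.null(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params), sep = " = ",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Chi-square sweep over the (kpep, kgly) parameter grid
#'
#' Runs an engulfment simulation for every grid cell (and replicate seed)
#' and compares it with the experimental trace via [chi2()]. Failed
#' simulation cells are marked missing and excluded with a message, never
#' silently imputed.
#'
#' @param kpep_values,kgly_values grid values, pN/nm.
#' @param exp_trace experimental [engulfment_trace()] with sd columns.
#' @param cfg base [simulation_config()].
#' @param rcfg a [remodeling_config()].
#' @param geom a [forespore_geometry()].
#' @param reps replicate simulations per cell (seeds derived from
#'   `cfg$seed`).
#' @param ... passed to [run_engulfment()].
#' @return data.frame of class `chi2_surface` with columns kpep, kgly, rep,
#'   chi2, chi2_V, chi2_S, chi2_E; the minimum-chi2 cell of the
#'   replicate-averaged surface is stored in `attr(, "argmin")`.
#' @export
grid_sweep <- function(kpep_values, kgly_values, exp_trace, cfg, rcfg, geom,
                       reps = 1L, ...) {
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max, reps)
  rows <- list()
  for (kp in kpep_values) {
    for (kg in kgly_values) {
      for (r in seq_len(reps)) {
        cc <- cfg
        cc$kpep <- kp; cc$kgly <- kg; cc$seed <- seeds[r]
        res <- tryCatch({
          run <- run_engulfment(cc, rcfg, geom, ...)
          fit <- chi2(exp_trace, run$trace)
          data.frame(kpep = kp, kgly = kg, rep = r, chi2 = fit$chi2,
                     chi2_V = fit$chi2_V, chi2_S = fit$chi2_S,
                     chi2_E = fit$chi2_E)
        }, error = function(e) {
          message(sprintf("grid cell (kpep=%g, kgly=%g, rep=%d) failed: %s",
                          kp, kg, r, conditionMessage(e)))
          data.frame(kpep = kp, kgly = kg, rep = r, chi2 = NA_real_,
                     chi2_V = NA_real_, chi2_S = NA_real_, chi2_E = NA_real_)
        })
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  means <- aggregate(chi2 ~ kpep + kgly, data = out[!is.na(out$chi2), ],
                     FUN = mean)
  amin <- means[which.min(means$chi2), , drop = FALSE]
  attr(out, "argmin") <- amin
  class(out) <- c("chi2_surface", "data.frame")
  out
}

#' Classify the engulfment phenotype of a completed run
#'
#' `stalled` when the final percent engulfment is below the completion
#' threshold and its late-time slope is negligible; otherwise `asymmetric`
#' when the angular height spread of the leading edge exceeds
#' `asym_frac` of the forespore circumference; otherwise `symmetric`. The
#' thresholds used are reported with the call.
#'
#' @param run an `engulf_run`.
#' @param complete_E completion threshold, percent.
#' @param asym_frac leading-edge spread threshold as a fraction of the
#'   circumference.
#' @param slope_eps stall threshold on |dE/dt|, percent per second (default
#'   0.02, small against the percent-per-second progress of active runs).
#' @return object of class `phenotype_call`: `phenotype`, `final_E`,
#'   `spread_nm`, `circumference_nm`, `dEdt`, thresholds.
#' @export
classify_phenotype <- function(run, complete_E = 95, asym_frac = 0.25,
                               slope_eps = 0.02) {
  tr <- run$trace
  n <- nrow(tr)
  finalE <- tr$E[n]
  tail_i <- seq(max(1L, floor(0.8 * n)), n)
  dEdt <- if (length(tail_i) > 1)
    unname(coef(stats::lm(tr$E[tail_i] ~ tr$time[tail_i]))[2]) else 0
  circ <- 2 * pi * run$geom$cell_radius
  phen <- if (finalE < complete_E && abs(dEdt) < slope_eps) "stalled"
  else if (run$spread_nm > asym_frac * circ) "asymmetric"
  else "symmetric"
  structure(list(phenotype = phen, final_E = finalE,
                 spread_nm = run$spread_nm, circumference_nm = circ,
                 dEdt = dEdt, complete_E = complete_E,
                 asym_frac = asym_frac, slope_eps = slope_eps),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(sprintf("<phenotype_call> %s (final E %.1f%%, LE spread %.3g nm = %.2f x circumference, dE/dt %.3g %%/s)\n",
              x$phenotype, x$final_E, x$spread_nm,
              x$spread_nm / x$circumference_nm, x$dEdt))
  cat(sprintf("  thresholds: completion %.3g%%, asymmetry %.3g x circumference, stall slope %.3g %%/s\n",
              x$complete_E, x$asym_frac, x$slope_eps))
  invisible(x)
}
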