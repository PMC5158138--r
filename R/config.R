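#' Mechanical and numerical parameters of the meshwork simulation
#'
#' Collects every constant of the coarse-grained peptidoglycan model in the
#' fixed unit system nm / s / pN / pN nm / pN/nm^2. Each simulated glycan
#' filament stands for a bundle of `n_bundle` glycan strands; its effective
#' persistence length defaults to the strongly cross-linked bundle rule
#' `n_bundle^2 * lp0` (the weakly cross-linked rule `n_bundle * lp0` can be
#' selected via `bundle_rule`), see [effective_persistence_length()].
#'
#' @param kgly glycan spring constant, pN/nm.
#' @param kpep peptide spring constant, pN/nm.
#' @param lp effective glycan persistence length, nm. Default
#'   `effective_persistence_length(n_bundle, lp0, bundle_rule)`.
#' @param n_bundle number of glycans per simulated filament.
#' @param lp0 single-glycan persistence length, nm.
#' @param bundle_rule `"strong"` (`n^2 lp0`) or `"weak"` (`n lp0`).
#' @param l0 equilibrium bead spacing along a strand, nm.
#' @param d_pep nominal peptide equilibrium length, nm (used for strain
#'   bookkeeping; bonds are created relaxed at their as-built separation).
#' @param delta_p pressure difference forespore minus mother, pN/nm^2.
#'   86.31 kPa = 0.08631 pN/nm^2.
#' @param eta_med medium viscosity, pN s/nm^2. The drag coefficient is
#'   derived, not stored: `zeta = 4 * pi * eta_med * l0`.
#' @param kBT thermal energy, pN nm.
#' @param dt integration time step, s.
#' @param seed RNG seed (integer).
#' @param ring_sep spacing between successive glycan hoops, nm. Defaults to
#'   `l0` (coarse inter-bundle spacing).
#' @param k_wall stiffness of the old-cell-wall exclusion, pN/nm.
#' @return An object of class `engulf_config` (named list).
#' @examples
#' cfg <- simulation_config()
#' drag_coefficient(cfg)
#' @export
simulation_config <- function(kgly = 200, kpep = 25, lp = NULL, n_bundle = 7,
                              lp0 = 40, bundle_rule = c("strong", "weak"),
                              l0 = 25, d_pep = 2, delta_p = 0.08631,
                              eta_med = 1e-6, kBT = 4.1, dt = 1e-7,
                              seed = 1L, ring_sep = NULL, k_wall = 100) {
  bundle_rule <- match.arg(bundle_rule)
  if (is.null(lp)) lp <- effective_persistence_length(n_bundle, lp0, bundle_rule)
  if (is.null(ring_sep)) ring_sep <- l0
  cfg <- list(kgly = kgly, kpep = kpep, lp = lp, n_bundle = n_bundle,
              lp0 = lp0, bundle_rule = bundle_rule, l0 = l0, d_pep = d_pep,
              delta_p = delta_p, eta_med = eta_med, kBT = kBT, dt = dt,
              seed = as.integer(seed), ring_sep = ring_sep, k_wall = k_wall)
  mech <- c("kgly", "kpep", "lp", "lp0", "l0", "d_pep", "delta_p", "eta_med",
            "ring_sep", "k_wall")
  for (f in mech) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop("configuration error: '", f, "' must be a positive number")
  }
  if (cfg$dt <= 0) stop("configuration error: 'dt' must be > 0")
  if (cfg$kBT < 0) stop("configuration error: 'kBT' must be >= 0")
  if (cfg$n_bundle < 1) stop("configuration error: 'n_bundle' must be >= 1")
  class(cfg) <- "engulf_config"
  cfg
}

#' @export
print.engulf_config <- function(x, ...) {
  cat("<engulf_config>  (nm / s / pN units)\n")
  cat(sprintf("  kgly %.6g pN/nm, kpep %.6g pN/nm, lp %.6g nm (%s bundle of %d, lp0 %.6g nm)\n",
              x$kgly, x$kpep, x$lp, x$bundle_rule, x$n_bundle, x$lp0))
  cat(sprintf("  l0 %.6g nm, ring_sep %.6g nm, d_pep %.6g nm, k_wall %.6g pN/nm\n",
              x$l0, x$ring_sep, x$d_pep, x$k_wall))
  cat(sprintf("  delta_p %.6g pN/nm^2, eta_med %.3g pN s/nm^2 (zeta %.4g pN s/nm)\n",
              x$delta_p, x$eta_med, drag_coefficient(x)))
  cat(sprintf("  kBT %.4g pN nm, dt %.3g s, seed %d\n", x$kBT, x$dt, x$seed))
  invisible(x)
}

#' Drag coefficient of a bead
#'
#' `zeta = 4 * pi * eta_med * l0`, uniform across beads.
#'
#' @param cfg an [simulation_config()] object.
#' @return drag coefficient, pN s/nm.
#' @export
drag_coefficient <- function(cfg) 4 * pi * cfg$eta_med * cfg$l0

#' Effective persistence length of a glycan bundle
#'
#' Each simulated filament represents a bundle of `n` glycans. Strongly
#' cross-linked bundles stiffen as `n^2 * lp0`; weakly cross-linked bundles
#' as `n * lp0`. With the defaults (7 glycans of 40 nm persistence length)
#' the strong rule gives 1960 nm, i.e. an effective persistence length of
#' about 2 um.
#'
#' @param n glycans per bundle.
#' @param lp0 single-glycan persistence length, nm.
#' @param rule `"strong"` or `"weak"`.
#' @return persistence length, nm.
#' @examples
#' effective_persistence_length(7, 40) # 1960 nm ~ 2 um
#' @export
effective_persistence_length <- function(n = 7, lp0 = 40,
                                         rule = c("strong", "weak")) {
  rule <- match.arg(rule)
  if (rule == "strong") n^2 * lp0 else n * lp0
}

#' Convert kPa to the internal pressure unit
#'
#' The internal unit system measures pressure in pN/nm^2 (= MPa), so
#' 1 kPa = 1e-3 pN/nm^2 and 86.31 kPa = 0.08631 pN/nm^2.
#'
#' @param kpa pressure in kPa.
#' @return pressure in pN/nm^2.
#' @export
kpa_to_pn_nm2 <- function(kpa) kpa * 1e-3

#' Stochastic remodeling parameters of the insertion-degradation complexes
#'
#' @param prep probability that an idle IDC resumes polymerization at an
#'   exposed glycan end (repairs a defect), in \[0,1\].
#' @param ppro probability that an IDC continues polymerization across a gap
#'   in the template layer (processivity), in \[0,1\].
#' @param NIDC number of complexes (integer >= 0).
#' @param VIDC per-complex insertion speed, nm/s. Default 30 nm/s, the
#'   midpoint of the 20-40 nm/s range of processive PG-synthase speeds.
#' @param tau_delay synthesis-to-degradation delay, s (decoupled mode).
#' @param ppcut probability that a scheduled junction cut erroneously severs
#'   a vertical peptide bond instead, in \[0,1\] (decoupled mode).
#' @param prpep random peptide degradation rate, min^-1 (used by
#'   [random_peptide_degradation()]).
#' @param coupled logical; `TRUE` = insertion and junction degradation happen
#'   in the same event (forces `tau_delay = 0`, `ppcut = 0`).
#' @param f0 seeded fraction of template holes in the founding row.
#' @return An object of class `remodeling_config`.
#' @export
remodeling_config <- function(prep = 1, ppro = 1, NIDC = 5L, VIDC = 30,
                              tau_delay = 0, ppcut = 0, prpep = 0,
                              coupled = TRUE, f0 = 0.01) {
  for (p in c(prep = prep, ppro = ppro, ppcut = ppcut)) {
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("configuration error: probabilities must lie in [0,1]")
  }
  if (NIDC < 0) stop("configuration error: 'NIDC' must be >= 0")
  if (VIDC <= 0) stop("configuration error: 'VIDC' must be > 0")
  if (tau_delay < 0 || prpep < 0)
    stop("configuration error: rates and delays must be >= 0")
  if (f0 < 0 || f0 >= 1) stop("configuration error: 'f0' must be in [0,1)")
  if (coupled && (tau_delay != 0 || ppcut != 0))
    stop("configuration error: coupled mode forces tau_delay = 0 and ppcut = 0")
  structure(list(prep = prep, ppro = ppro, NIDC = as.integer(NIDC),
                 VIDC = VIDC, tau_delay = tau_delay, ppcut = ppcut,
                 prpep = prpep, coupled = coupled, f0 = f0),
            class = "remodeling_config")
}

#' @export
print.remodeling_config <- function(x, ...) {
  cat("<remodeling_config>\n")
  cat(sprintf("  prep %.3g, ppro %.3g, NIDC %d, VIDC %.3g nm/s, %s mode\n",
              x$prep, x$ppro, x$NIDC, x$VIDC,
              if (x$coupled) "coupled" else "decoupled"))
  if (!x$coupled)
    cat(sprintf("  tau_delay %.3g s, ppcut %.3g\n", x$tau_delay, x$ppcut))
  if (x$prpep > 0) cat(sprintf("  prpep %.3g min^-1\n", x$prpep))
  cat(sprintf("  founding-row hole fraction f0 %.3g\n", x$f0))
  invisible(x)
}

#' Load a simulation configuration from a YAML file
#'
#' Flat key-value document whose keys are the [simulation_config()] argument
#' names; unknown keys are errors. The pressure may alternatively be given
#' in kPa under the key `delta_p_kPa`, which the loader converts
#' (86.31 kPa -> 0.08631 pN/nm^2).
#'
#' @param path path to a YAML file.
#' @return An `engulf_config` object.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("configuration error: expected a key-value document")
  if ("delta_p_kPa" %in% names(vals)) {
    if ("delta_p" %in% names(vals))
      stop("configuration error: give 'delta_p' or 'delta_p_kPa', not both")
    vals$delta_p <- kpa_to_pn_nm2(vals$delta_p_kPa)
    vals$delta_p_kPa <- NULL
  }
  known <- setdiff(names(formals(simulation_config)), "...")
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("configuration error: unknown key(s): ", paste(bad, collapse = ", "))
  do.call(simulation_config, vals)
}

#' Number of insertion complexes implied by an insertion flux
#'
#' Divides a measured total insertion flux interval (`NIDC * VIDC`, nm of
#' glycan per second) by a per-complex speed interval and rounds the extreme
#' quotients to whole complexes. With the literature flux estimates
#' 110-117 nm/s and per-complex speeds of 20-40 nm/s this gives 3-6
#' complexes.
#'
#' @param flux_low,flux_high bounds on total insertion flux, nm/s.
#' @param v_low,v_high bounds on per-complex speed, nm/s.
#' @return integer vector `c(min, max)` of implied complex counts.
#' @examples
#' implied_complex_count(110, 117, 20, 40) # 3 6
#' @export
implied_complex_count <- function(flux_low, flux_high, v_low, v_high) {
  if (min(flux_low, flux_high, v_low, v_high) <= 0)
    stop("fluxes and speeds must be positive")
  c(round(flux_low / v_high), round(flux_high / v_low))
}
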