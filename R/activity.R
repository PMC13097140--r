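#' Background-corrected intrinsic activity
#'
#' Corrects an apparent first-order rate constant for the solvent-system
#' background and for the trace piperidine impurity, normalizes by the
#' catalyst concentration, and multiplies by the initial substrate
#' concentration to give the turnover frequency:
#' \deqn{k_{cat} = \frac{k_{app} - k_{app,blank} - k_{pip}[pip]}{[cat]},
#'       \qquad TOF = k_{cat} \cdot [ester]_i}
#' \code{k_piperidine} is a second-order constant (min^-1 M^-1) whose
#' contribution is \code{k_piperidine * c_piperidine}. A negative corrected
#' rate is returned with a warning flag, never silently zeroed.
#'
#' @param k_app apparent rate constant, min^-1.
#' @param k_app_blank background hydrolysis rate of the solvent system,
#'   min^-1.
#' @param k_piperidine second-order rate constant of the piperidine
#'   impurity, min^-1 M^-1.
#' @param c_piperidine piperidine concentration, M.
#' @param c_catalyst catalyst concentration, M (> 0).
#' @param c_ester_initial initial ester concentration, M.
#' @return object of class \code{activity_result}: list with \code{k_cat}
#'   (min^-1 M^-1), \code{tof} (min^-1), the inputs, and \code{flagged}.
#' @examples
#' # TOF from a printed k_cat: supply k_app = k_cat * c_catalyst with zero
#' # backgrounds
#' res <- compute_activity(k_app = 59.8 * 0.010e-3, k_app_blank = 0,
#'                         k_piperidine = 0, c_piperidine = 0,
#'                         c_catalyst = 0.010e-3, c_ester_initial = 0.104e-3)
#' signif(res$tof, 2)   # 0.0062 min^-1
#' @export
compute_activity <- function(k_app, k_app_blank = 0, k_piperidine = 0,
                             c_piperidine = 0, c_catalyst,
                             c_ester_initial) {
  if (c_catalyst == 0) stop("division undefined: c_catalyst is zero")
  k_cat <- (k_app - k_app_blank - k_piperidine * c_piperidine) / c_catalyst
  tof <- k_cat * c_ester_initial
  flagged <- k_cat < 0
  if (flagged)
    warning(sprintf("corrected k_cat is negative (%.4g); reported unclipped",
                    k_cat))
  structure(list(k_cat = k_cat, tof = tof, k_app = k_app,
                 k_app_blank = k_app_blank, k_piperidine = k_piperidine,
                 c_piperidine = c_piperidine, c_catalyst = c_catalyst,
                 c_ester_initial = c_ester_initial, flagged = flagged),
            class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat("Intrinsic activity\n")
  cat(sprintf("  k_cat = %.4g min^-1 M^-1%s\n", x$k_cat,
              if (x$flagged) "  [negative: check backgrounds]" else ""))
  cat(sprintf("  TOF   = %.4g min^-1  ([ester]_i = %.4g M)\n",
              x$tof, x$c_ester_initial))
  invisible(x)
}

#' Catalyst composition for loading arithmetic
#'
#' @param metal_wt_frac metal weight fraction, g/g (e.g. 0.048 for 4.8 wt\%).
#' @param dispersion fraction of metal atoms exposed at the particle surface
#'   (from CO chemisorption), in (0, 1].
#' @param s_wt_frac sulfur weight fraction, g/g.
#' @param molar_mass_metal g/mol; default palladium, 106.42.
#' @param molar_mass_s g/mol; default sulfur, 32.06.
#' @param s_per_linker sulfur atoms per linker molecule; default 2
#'   (1,6-hexanedithiol).
#' @return object of class \code{catalyst_composition}.
#' @export
catalyst_composition <- function(metal_wt_frac = 0, dispersion = 1,
                                 s_wt_frac = 0, molar_mass_metal = 106.42,
                                 molar_mass_s = 32.06, s_per_linker = 2) {
  if (dispersion < 0 || dispersion > 1) stop("dispersion must be in [0, 1]")
  if (metal_wt_frac < 0 || metal_wt_frac > 1 ||
      s_wt_frac < 0 || s_wt_frac > 1)
    stop("weight fractions must be in [0, 1]")
  if (s_per_linker < 1) stop("s_per_linker must be >= 1")
  structure(list(metal_wt_frac = metal_wt_frac, dispersion = dispersion,
                 s_wt_frac = s_wt_frac, molar_mass_metal = molar_mass_metal,
                 molar_mass_s = molar_mass_s, s_per_linker = s_per_linker),
            class = "catalyst_composition")
}

#' Surface metal loading
#'
#' Moles of surface-exposed metal per gram of supported catalyst:
#' weight fraction / molar mass x dispersion, in mmol/g.
#'
#' @param comp a \code{\link{catalyst_composition}}.
#' @return surface metal loading, mmol/g.
#' @examples
#' # 4.8 wt% Pd at 4% dispersion -> 0.018 mmol/g
#' surface_metal_loading(catalyst_composition(metal_wt_frac = 0.048,
#'                                            dispersion = 0.04))
#' @export
surface_metal_loading <- function(comp) {
  stopifnot(inherits(comp, "catalyst_composition"))
  if (comp$dispersion <= 0) stop("dispersion must be positive")
  comp$metal_wt_frac / comp$molar_mass_metal * comp$dispersion * 1000
}

#' Linker loading from elemental sulfur content
#'
#' Moles of thiol linker per gram of catalyst, from the sulfur weight
#' fraction and the number of sulfur atoms per linker molecule.
#'
#' @param comp a \code{\link{catalyst_composition}}.
#' @return linker loading, mmol/g.
#' @examples
#' # 0.085 wt% S, dithiol (2 S per linker) -> 0.013 mmol/g
#' linker_loading_from_sulfur(catalyst_composition(s_wt_frac = 0.00085))
#' @export
linker_loading_from_sulfur <- function(comp) {
  stopifnot(inherits(comp, "catalyst_composition"))
  comp$s_wt_frac / comp$molar_mass_s / comp$s_per_linker * 1000
}

#' Linker coverage relative to surface metal
#'
#' @param linker_mmol_g linker loading, mmol/g.
#' @param surface_metal_mmol_g surface metal loading, mmol/g (> 0).
#' @return dimensionless coverage ratio.
#' @export
coverage_ratio <- function(linker_mmol_g, surface_metal_mmol_g) {
  if (surface_metal_mmol_g <= 0)
    stop("division undefined: surface metal loading must be positive")
  linker_mmol_g / surface_metal_mmol_g
}
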