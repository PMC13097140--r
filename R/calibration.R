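#' Calibration set for three-wavelength Beer--Lambert deconvolution
#'
#' Holds per-species absorbance calibration constants (path length folded in,
#' units absorbance per mM) at the three analytical wavelengths 250, 320 and
#' 400 nm. The ester (4NP4HB) and its hydrolysis products 4-nitrophenol (4NP)
#' and 4-hydroxybenzoic acid (4HB) absorb at overlapping wavelengths; only
#' 4HB contributes at 250 nm in addition to the other two species, while the
#' 400 and 320 nm channels contain 4NP and 4NP4HB terms only, so the 4HB
#' coefficients at 320 and 400 nm are fixed at zero.
#'
#' @param coeff named list (or matrix) of calibration constants. Either a
#'   3x3 numeric matrix with rownames \code{c("4NP4HB","4NP","4HB")} and
#'   colnames \code{c("250","320","400")}, or a named list
#'   \code{list(`4NP4HB` = c(`250`=, `320`=, `400`=), ...)}. 4HB entries at
#'   320/400 nm must be zero (missing entries default to zero).
#' @return An object of class \code{calibration_set}: a 3x3 numeric matrix
#'   with a precomputed 2x2 inverse for the 400/320 nm channels.
#' @examples
#' calib <- calibration_set(matrix(
#'   c(2.1, 9.0, 0.4,
#'     1.5, 1.2, 12.0,
#'     6.0, 0, 0),
#'   nrow = 3, byrow = TRUE,
#'   dimnames = list(c("4NP4HB", "4NP", "4HB"), c("250", "320", "400"))))
#' @export
calibration_set <- function(coeff) {
  species <- c("4NP4HB", "4NP", "4HB")
  wl <- c("250", "320", "400")
  m <- matrix(0, 3, 3, dimnames = list(species, wl))
  if (is.matrix(coeff)) {
    m[rownames(coeff), colnames(coeff)] <- coeff
  } else if (is.list(coeff)) {
    for (sp in names(coeff)) {
      v <- coeff[[sp]]
      m[sp, names(v)] <- as.numeric(v)
    }
  } else {
    stop("coeff must be a matrix or a named list")
  }
  if (any(m < 0)) stop("calibration coefficients must be non-negative")
  if (m["4HB", "320"] != 0 || m["4HB", "400"] != 0)
    stop("4HB coefficients at 320 and 400 nm must be zero")
  # 2x2 system for [4NP] and [4NP4HB] from the 400/320 nm channels
  a <- matrix(c(m["4NP", "400"], m["4NP4HB", "400"],
                m["4NP", "320"], m["4NP4HB", "320"]),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("400", "320"), c("4NP", "4NP4HB")))
  if (abs(det(a)) < .Machine$double.eps * max(abs(a), 1)^2 ||
      !is.finite(kappa(a)))
    stop("invalid calibration: 2x2 submatrix for {4NP,4NP4HB}x{400,320} is singular")
  if (m["4HB", "250"] <= 0)
    stop("invalid calibration: 4HB coefficient at 250 nm must be positive")
  structure(m, a22 = a, a22inv = solve(a), class = c("calibration_set", "matrix"))
}

#' @export
print.calibration_set <- function(x, ...) {
  cat("Beer-Lambert calibration set (absorbance / mM)\n")
  print(unclass(x)[, , drop = FALSE])
  cat(sprintf("2x2 condition number (400/320 channels): %.3g\n",
              kappa(attr(x, "a22"))))
  invisible(x)
}

#' Forward Beer--Lambert model: concentrations to absorbances
#'
#' Computes the diluted absorbances at 250/320/400 nm for a given
#' concentration state, the exact forward model that
#' \code{\link{deconvolve_spectra}} inverts. Used by the synthetic kinetics
#' generator and as the round-trip oracle in tests.
#'
#' @param conc numeric vector \code{c(c_ester, c_4np, c_4hb)} in mM
#'   (undiluted).
#' @param calib a \code{\link{calibration_set}}.
#' @param dilution_factor dilution applied before measurement (default 10).
#' @return named numeric vector \code{c(abs250, abs320, abs400)}.
#' @export
forward_absorbance <- function(conc, calib, dilution_factor = 10) {
  stopifnot(inherits(calib, "calibration_set"), length(conc) == 3,
            dilution_factor > 0)
  cd <- conc / dilution_factor      # measured (diluted) concentrations
  m <- unclass(calib)
  abs250 <- m["4NP4HB", "250"] * cd[1] + m["4NP", "250"] * cd[2] +
    m["4HB", "250"] * cd[3]
  abs320 <- m["4NP4HB", "320"] * cd[1] + m["4NP", "320"] * cd[2]
  abs400 <- m["4NP4HB", "400"] * cd[1] + m["4NP", "400"] * cd[2]
  c(abs250 = unname(abs250), abs320 = unname(abs320), abs400 = unname(abs400))
}

#' Deconvolve a three-wavelength absorbance sample into concentrations
#'
#' Solves the 400 and 320 nm channels jointly for the 4NP and 4NP4HB
#' concentrations, then uses the 250 nm channel for 4HB, and multiplies back
#' by the dilution factor. Small negative concentrations (measurement noise)
#' are reported with a warning, never clipped.
#'
#' @param sample list or numeric vector with elements \code{abs250},
#'   \code{abs320}, \code{abs400} and optionally \code{dilution_factor}
#'   (default 10).
#' @param calib a \code{\link{calibration_set}}.
#' @param tol negativity tolerance in mM: concentrations below \code{-tol}
#'   trigger a warning and set the \code{flagged} attribute.
#' @return named numeric vector \code{c(c_ester, c_4np, c_4hb)} in mM,
#'   undiluted, with attribute \code{flagged} (logical).
#' @examples
#' calib <- calibration_set(list(
#'   `4NP4HB` = c(`250` = 2.1, `320` = 9.0, `400` = 0.4),
#'   `4NP`    = c(`250` = 1.5, `320` = 1.2, `400` = 12.0),
#'   `4HB`    = c(`250` = 6.0)))
#' a <- forward_absorbance(c(0.4, 0.6, 0.2), calib)
#' deconvolve_spectra(as.list(a), calib)
#' @export
deconvolve_spectra <- function(sample, calib, tol = 1e-6) {
  stopifnot(inherits(calib, "calibration_set"))
  s <- as.list(sample)
  dil <- if (is.null(s$dilution_factor)) 10 else s$dilution_factor
  if (dil <= 0) stop("dilution_factor must be positive")
  ainv <- attr(calib, "a22inv")
  xy <- ainv %*% c(s$abs400, s$abs320)   # c(4NP, 4NP4HB), diluted mM
  c_4np <- xy[1]
  c_ester <- xy[2]
  m <- unclass(calib)
  c_4hb <- (s$abs250 - m["4NP", "250"] * c_4np -
              m["4NP4HB", "250"] * c_ester) / m["4HB", "250"]
  out <- c(c_ester = c_ester, c_4np = c_4np, c_4hb = c_4hb) * dil
  flagged <- any(out < -tol)
  if (flagged)
    warning(sprintf(
      "deconvolved concentration below -tol (min %.4g mM); reported unclipped",
      min(out)))
  attr(out, "flagged") <- flagged
  out
}

#' Conversion, yield and carbon balance at a time point
#'
#' Conversion of the ester, yield of 4NP, and the carbon balance using the
#' per-molecule carbon counts 13 (4NP4HB), 6 (4NP) and 7 (4HB):
#' \deqn{\%CB = \frac{13[ester]_t + 6[4NP]_t + 7[4HB]_t}{13[ester]_i} \times 100}
#'
#' @param state_t numeric vector \code{c(c_ester, c_4np, c_4hb)} in mM.
#' @param c_ester_initial initial ester concentration in mM (> 0).
#' @return named numeric vector with \code{conversion_pct}, \code{yield_pct},
#'   \code{carbon_balance_pct}.
#' @export
conversion_yield_balance <- function(state_t, c_ester_initial) {
  if (!is.numeric(c_ester_initial) || c_ester_initial <= 0)
    stop("undefined metric: c_ester_initial must be positive")
  st <- as.numeric(state_t)
  stopifnot(length(st) == 3)
  conv <- (c_ester_initial - st[1]) / c_ester_initial * 100
  yld <- st[2] / c_ester_initial * 100
  cb <- (13 * st[1] + 6 * st[2] + 7 * st[3]) / (13 * c_ester_initial) * 100
  c(conversion_pct = conv, yield_pct = yld, carbon_balance_pct = cb)
}
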