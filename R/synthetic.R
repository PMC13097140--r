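#' Generate a bimodal (Gaussian-mixture) NH-O distance series
#'
#' Emulates the distance samples of one steered window replicate: a
#' two-component (or k-component) Gaussian mixture with stated weights,
#' means and widths. Negative draws are reflected at zero. The generative
#' component labels are kept as an attribute for oracle testing only; the
#' analysis path never reads them.
#'
#' @param weights mixture weights, summing to 1.
#' @param means component means, nm.
#' @param sds component standard deviations, nm (> 0).
#' @param n number of samples.
#' @param seed RNG seed (reproducible draws under a fixed seed).
#' @param replicate_id,window_com_distance metadata passed to
#'   \code{\link{distance_series}}.
#' @return a \code{\link{distance_series}} with attribute \code{labels}
#'   (integer component index per sample).
#' @export
gen_bimodal_distances <- function(weights, means, sds, n, seed = 1,
                                  replicate_id = "r1",
                                  window_com_distance = NA_real_) {
  stopifnot(length(weights) == length(means), length(means) == length(sds),
            all(sds > 0), all(weights >= 0), n >= 1)
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  set.seed(seed)
  lab <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  x <- abs(stats::rnorm(n, mean = means[lab], sd = sds[lab]))
  out <- distance_series(x, replicate_id = replicate_id,
                         window_com_distance = window_com_distance)
  attr(out, "labels") <- lab
  out
}

#' Generate a solvent box around a toy solute with a radial water bias
#'
#' Places water-oxygen and acetonitrile-carbon sites in an orthorhombic box
#' by rejection sampling: proposals are uniform over the box, rejected
#' within a hard-sphere exclusion distance of the solute, and water
#' proposals are additionally thinned by the bias factor of the radial
#' interval containing their minimal distance to the solute (acetonitrile
#' placement is uniform outside the exclusion). A bias factor of 0 gives a
#' hard water exclusion in that interval; factors > 1 enrich. Default
#' counts correspond to a 50\% v/v water/acetonitrile mixture in a
#' (5 nm)^3 box (about 16.7 waters and 5.6 acetonitriles per nm^3 from the
#' component densities 1.008 and 0.770 g/cm^3).
#'
#' @param box box lengths, nm (default \code{c(5, 5, 5)}).
#' @param n_water,n_acn site counts (defaults scale with box volume at the
#'   50\% v/v composition).
#' @param solute_coords n x 3 matrix, nm; default a small rigid 5-atom toy
#'   solute at the box center.
#' @param bias list of water-bias intervals, each \code{c(r_lo, r_hi,
#'   factor)} in nm; non-overlapping; factor >= 0. Empty list = uniform.
#' @param exclusion hard-sphere exclusion radius around solute atoms, nm.
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling attempt cap per site on average.
#' @return a \code{\link{traj_frame}} with attribute \code{bias} recording
#'   the generative bias.
#' @export
gen_solvent_box <- function(box = c(5, 5, 5), n_water = NULL, n_acn = NULL,
                            solute_coords = NULL, bias = list(),
                            exclusion = 0.15, seed = 1,
                            max_attempts = 1000) {
  box <- as.numeric(box)
  vol <- prod(box)
  if (is.null(n_water)) n_water <- round(16.7 * vol)
  if (is.null(n_acn)) n_acn <- round(5.6 * vol)
  if (is.null(solute_coords)) {
    c0 <- box / 2
    solute_coords <- rbind(c0,
                           c0 + c(0.15, 0, 0), c0 - c(0.15, 0, 0),
                           c0 + c(0, 0.15, 0), c0 + c(0, 0, 0.15))
  }
  solute_coords <- as.matrix(solute_coords)
  if (length(bias)) {
    iv <- do.call(rbind, bias)
    stopifnot(ncol(iv) == 3, all(iv[, 3] >= 0), all(iv[, 1] < iv[, 2]))
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("bias intervals must be non-overlapping")
  } else iv <- NULL

  set.seed(seed)
  bias_factor <- function(r) {
    f <- rep(1, length(r))
    if (!is.null(iv)) for (i in seq_len(nrow(iv)))
      f[r >= iv[i, 1] & r < iv[i, 2]] <- iv[i, 3]
    f
  }
  fmax <- max(1, if (is.null(iv)) 1 else max(iv[, 3]))

  draw <- function(n_target, biased) {
    placed <- matrix(numeric(0), 0, 3)
    attempts <- 0
    while (nrow(placed) < n_target) {
      if (attempts > max_attempts * n_target)
        stop("infeasible spec: rejection sampling failed to place all sites")
      m <- max(2 * (n_target - nrow(placed)), 100)
      attempts <- attempts + m
      prop <- cbind(stats::runif(m, 0, box[1]), stats::runif(m, 0, box[2]),
                    stats::runif(m, 0, box[3]))
      d <- minimal_distance(prop, solute_coords, box)
      keep <- d >= exclusion
      if (biased) {
        acc <- bias_factor(d) / fmax
        keep <- keep & (stats::runif(m) < acc)
      }
      placed <- rbind(placed, prop[keep, , drop = FALSE])
    }
    placed[seq_len(n_target), , drop = FALSE]
  }

  w <- draw(n_water, biased = TRUE)
  a <- draw(n_acn, biased = FALSE)
  fr <- traj_frame(solute_coords, rbind(w, a),
                   c(rep("waterO", n_water), rep("acnC", n_acn)), box)
  attr(fr, "bias") <- iv
  fr
}

#' Generate a synthetic kinetic run
#'
#' Draws a first-order hydrolysis trajectory (ester decay; 4NP and 4HB rise
#' stoichiometrically, so the carbon balance of a noiseless run is exactly
#' 100\%), maps the concentrations to diluted absorbances through the
#' forward Beer--Lambert model, and adds i.i.d. Gaussian noise on the
#' absorbances.
#'
#' @param k_app true rate constant, min^-1 (>= 0).
#' @param c0 initial ester concentration, mM.
#' @param times sampling times, min.
#' @param calib a \code{\link{calibration_set}}.
#' @param noise_sd absorbance noise standard deviation (default 0).
#' @param dilution dilution factor before measurement.
#' @param c_catalyst,c_piperidine,acn_vv,temperature run metadata.
#' @param seed RNG seed.
#' @return a \code{\link{kinetic_run}} holding absorbance traces, with
#'   attribute \code{truth} = \code{list(k_app, c0, conc)}.
#' @export
gen_kinetics <- function(k_app, c0, times, calib, noise_sd = 0,
                         dilution = 10, c_catalyst = 0.5, c_piperidine = 0,
                         acn_vv = 50, temperature = 50, seed = 1) {
  stopifnot(inherits(calib, "calibration_set"), k_app >= 0, noise_sd >= 0)
  set.seed(seed)
  times <- as.numeric(times)
  e <- c0 * exp(-k_app * times)
  conc <- cbind(c_ester = e, c_4np = c0 - e, c_4hb = c0 - e)
  ab <- t(apply(conc, 1, forward_absorbance, calib = calib,
                dilution_factor = dilution))
  if (noise_sd > 0)
    ab <- ab + matrix(stats::rnorm(length(ab), 0, noise_sd), nrow(ab))
  run <- kinetic_run(times = times, abs250 = ab[, "abs250"],
                     abs320 = ab[, "abs320"], abs400 = ab[, "abs400"],
                     c_ester_initial = c0, c_catalyst = c_catalyst,
                     c_piperidine = c_piperidine, acn_vv = acn_vv,
                     temperature = temperature, dilution_factor = dilution)
  attr(run, "truth") <- list(k_app = k_app, c0 = c0, conc = conc)
  run
}

#' A default synthetic calibration set
#'
#' Plausible calibration constants for the three analytical wavelengths
#' (absorbance per mM at 1 cm path after dilution), with the ester dominant
#' at 320 nm, 4NP dominant at 400 nm, and all three species contributing at
#' 250 nm. Synthetic values for testing and simulation; not instrument
#' calibrations.
#'
#' @return a \code{\link{calibration_set}}.
#' @export
synthetic_calibration <- function() {
  calibration_set(list(
    `4NP4HB` = c(`250` = 2.1, `320` = 9.0, `400` = 0.4),
    `4NP`    = c(`250` = 1.5, `320` = 1.2, `400` = 12.0),
    `4HB`    = c(`250` = 6.0)))
}
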