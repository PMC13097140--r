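#' Construct a kinetic run
#'
#' Bundles a timed series of either absorbance samples or concentration
#' states with the run metadata (initial ester, catalyst and piperidine
#' concentrations, solvent composition, temperature). Times must be strictly
#' increasing.
#'
#' @param times sampling times in minutes.
#' @param abs250,abs320,abs400 absorbance traces (all three required if
#'   concentrations are not given).
#' @param conc optional matrix/data.frame with columns \code{c_ester},
#'   \code{c_4np}, \code{c_4hb} in mM (undiluted); used directly when given.
#' @param c_ester_initial initial ester concentration, mM (> 0).
#' @param c_catalyst catalyst concentration, mM.
#' @param c_piperidine piperidine impurity concentration, mM.
#' @param acn_vv acetonitrile content, \% v/v.
#' @param temperature reaction temperature, degrees C.
#' @param dilution_factor dilution applied before the UV-vis measurement.
#' @return object of class \code{kinetic_run}.
#' @export
kinetic_run <- function(times, abs250 = NULL, abs320 = NULL, abs400 = NULL,
                        conc = NULL, c_ester_initial, c_catalyst = 0,
                        c_piperidine = 0, acn_vv = 50, temperature = 50,
                        dilution_factor = 10) {
  times <- as.numeric(times)
  if (any(times < 0)) stop("times must be non-negative")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (c_ester_initial <= 0) stop("c_ester_initial must be positive")
  if (c_catalyst < 0) stop("c_catalyst must be non-negative")
  if (is.null(conc)) {
    if (is.null(abs250) || is.null(abs320) || is.null(abs400))
      stop("supply either conc or all of abs250/abs320/abs400")
    stopifnot(length(abs250) == length(times),
              length(abs320) == length(times),
              length(abs400) == length(times))
  } else {
    conc <- as.matrix(conc)
    stopifnot(nrow(conc) == length(times), ncol(conc) == 3)
    colnames(conc) <- c("c_ester", "c_4np", "c_4hb")
  }
  structure(list(times = times, abs250 = abs250, abs320 = abs320,
                 abs400 = abs400, conc = conc,
                 c_ester_initial = c_ester_initial, c_catalyst = c_catalyst,
                 c_piperidine = c_piperidine, acn_vv = acn_vv,
                 temperature = temperature,
                 dilution_factor = dilution_factor),
            class = "kinetic_run")
}

#' @export
print.kinetic_run <- function(x, ...) {
  cat(sprintf(
    "Kinetic run: %d time points over [%g, %g] min\n",
    length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  [ester]_i = %g mM, [cat] = %g mM, %g%% v/v ACN, %g C\n",
              x$c_ester_initial, x$c_catalyst, x$acn_vv, x$temperature))
  cat(sprintf("  data: %s\n",
              if (is.null(x$conc)) "absorbances (undeconvolved)"
              else "concentrations"))
  invisible(x)
}

#' Deconvolve every time point of a run
#'
#' @param run a \code{\link{kinetic_run}} holding absorbance traces.
#' @param calib a \code{\link{calibration_set}}.
#' @param tol negativity tolerance forwarded to
#'   \code{\link{deconvolve_spectra}}.
#' @return the run with its \code{conc} slot filled (mM, undiluted).
#' @export
deconvolve_run <- function(run, calib, tol = 1e-6) {
  stopifnot(inherits(run, "kinetic_run"))
  if (!is.null(run$conc)) return(run)
  n <- length(run$times)
  conc <- matrix(NA_real_, n, 3,
                 dimnames = list(NULL, c("c_ester", "c_4np", "c_4hb")))
  for (i in seq_len(n)) {
    conc[i, ] <- deconvolve_spectra(
      list(abs250 = run$abs250[i], abs320 = run$abs320[i],
           abs400 = run$abs400[i], dilution_factor = run$dilution_factor),
      calib, tol = tol)
  }
  run$conc <- conc
  run
}

#' Fit the first-order hydrolysis model to a kinetic run
#'
#' Fits the first-order model of ester disappearance jointly on the ester and
#' 4NP traces by nonlinear least squares (Levenberg--Marquardt):
#' \deqn{[ester](t) = c_0 e^{-k_{app} t}, \quad [4NP](t) = c_0 (1 - e^{-k_{app} t})}
#' with shared \eqn{c_0} and \eqn{k_{app}} and equal per-species weights.
#' 4HB is excluded from the objective: its 250 nm channel overlaps the
#' absorbances of the other species and the catalyst, so including it
#' inflates the model error. The 95\% confidence interval on \eqn{k_{app}}
#' comes from the parameter covariance of the local linearization with a
#' Student-t critical value at \eqn{n - p} degrees of freedom; a residual
#' bootstrap is available as an option.
#'
#' @param run a \code{\link{kinetic_run}}. If it holds absorbances,
#'   \code{calib} is required and the run is deconvolved first.
#' @param calib optional \code{\link{calibration_set}}.
#' @param fix_c0 if \code{TRUE}, hold \eqn{c_0} at the nominal initial
#'   concentration instead of fitting it.
#' @param species which traces enter the objective; default both.
#' @param ci one of \code{"t"} (default, linearized covariance) or
#'   \code{"bootstrap"} (residual bootstrap, \code{n_boot} resamples).
#' @param n_boot bootstrap resamples when \code{ci = "bootstrap"}.
#' @return object of class \code{first_order_fit} with components
#'   \code{k_app} (min^-1), \code{ci95_halfwidth}, \code{fitted_c0} (mM),
#'   \code{residual_rms} (mM), \code{n_points}, plus the stacked data and
#'   the underlying \code{nls} object.
#' @seealso \code{\link{compute_activity}} for the background-corrected
#'   intrinsic activity.
#' @export
fit_first_order <- function(run, calib = NULL, fix_c0 = FALSE,
                            species = c("ester", "4np"),
                            ci = c("t", "bootstrap"), n_boot = 500) {
  stopifnot(inherits(run, "kinetic_run"))
  ci <- match.arg(ci)
  species <- match.arg(species, c("ester", "4np"), several.ok = TRUE)
  if (is.null(run$conc)) {
    if (is.null(calib))
      stop("run holds absorbances; a calibration_set is required")
    run <- deconvolve_run(run, calib)
  }
  t_ <- run$times
  if (length(t_) < 3) stop("insufficient data: need at least 3 time points")

  dat <- NULL
  if ("ester" %in% species)
    dat <- rbind(dat, data.frame(t = t_, y = run$conc[, "c_ester"],
                                 is_ester = 1))
  if ("4np" %in% species)
    dat <- rbind(dat, data.frame(t = t_, y = run$conc[, "c_4np"],
                                 is_ester = 0))

  # starting values: c0 from data, k from a log-linear slope on the ester
  c0_start <- max(run$conc[1, "c_ester"], run$c_ester_initial, 1e-6)
  ce <- pmax(run$conc[, "c_ester"], c0_start * 1e-6)
  # floor keeps the gradient wrt k numerically non-degenerate for flat runs
  k_start <- max(-stats::coef(stats::lm(log(ce) ~ t_))[2], 1e-5)

  model <- if (fix_c0) {
    c0_nom <- run$c_ester_initial
    y ~ is_ester * c0_nom * exp(-k * t) +
      (1 - is_ester) * c0_nom * (1 - exp(-k * t))
  } else {
    y ~ is_ester * c0 * exp(-k * t) + (1 - is_ester) * c0 * (1 - exp(-k * t))
  }
  start <- if (fix_c0) list(k = k_start) else list(c0 = c0_start, k = k_start)
  lower <- if (fix_c0) c(k = 0) else c(c0 = 0, k = 0)

  do_fit <- function(st) minpack.lm::nlsLM(
    model, data = dat, start = st, lower = lower,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  fit <- tryCatch(do_fit(start), error = function(e) e)
  if (inherits(fit, "error")) {
    # retry from a coarser rate before declaring failure
    for (k_try in c(1e-3, 1e-2)) {
      start$k <- k_try
      fit <- tryCatch(do_fit(start), error = function(e) e)
      if (!inherits(fit, "error")) break
    }
    if (inherits(fit, "error"))
      stop("fit failure: ", conditionMessage(fit))
  }

  cf <- stats::coef(fit)
  k_app <- unname(cf["k"])
  fitted_c0 <- if (fix_c0) run$c_ester_initial else unname(cf["c0"])
  res <- stats::residuals(fit)
  n <- nrow(dat)
  p <- length(cf)
  dof <- max(n - p, 1)

  se_k <- tryCatch(sqrt(diag(stats::vcov(fit)))["k"],
                   error = function(e) NA_real_)
  half <- if (ci == "t") {
    unname(stats::qt(0.975, dof) * se_k)
  } else {
    fitted_vals <- stats::fitted(fit)
    kb <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      db <- dat
      db$y <- fitted_vals + sample(res, n, replace = TRUE)
      fb <- try(minpack.lm::nlsLM(model, data = db, start = as.list(cf),
                                  lower = lower), silent = TRUE)
      kb[b] <- if (inherits(fb, "try-error")) NA else stats::coef(fb)["k"]
    }
    unname(diff(stats::quantile(kb, c(0.025, 0.975), na.rm = TRUE)) / 2)
  }
  if (!is.finite(half)) half <- 0

  structure(list(k_app = k_app, ci95_halfwidth = half,
                 fitted_c0 = fitted_c0,
                 residual_rms = sqrt(mean(res^2)),
                 n_points = length(t_), dof = dof, se_k = unname(se_k),
                 fix_c0 = fix_c0, species = species, data = dat,
                 run = run, nls = fit),
            class = "first_order_fit")
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat("First-order hydrolysis fit\n")
  cat(sprintf("  k_app = %.4g min^-1  (95%% CI +/- %.3g)\n",
              x$k_app, x$ci95_halfwidth))
  cat(sprintf("  c0 = %.4g mM%s, residual RMS = %.3g mM, %d time points\n",
              x$fitted_c0, if (x$fix_c0) " (fixed)" else "",
              x$residual_rms, x$n_points))
  invisible(x)
}

#' @export
summary.first_order_fit <- function(object, ...) {
  s <- summary(object$nls)
  out <- list(fit = object, nls_summary = s,
              half_life = log(2) / object$k_app)
  class(out) <- "summary.first_order_fit"
  out
}

#' @export
print.summary.first_order_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  half-life = %.4g min\n", x$half_life))
  cat("\nParameter table (stacked ester + 4NP residuals):\n")
  stats::printCoefmat(x$nls_summary$coefficients)
  invisible(x)
}

#' @export
coef.first_order_fit <- function(object, ...) {
  c(k_app = object$k_app, c0 = object$fitted_c0)
}

#' @export
confint.first_order_fit <- function(object, parm = "k_app", level = 0.95, ...) {
  half <- stats::qt(1 - (1 - level) / 2, object$dof) * object$se_k
  m <- matrix(c(object$k_app - half, object$k_app + half), nrow = 1,
              dimnames = list("k_app",
                              sprintf("%g %%", c((1 - level) / 2,
                                                 1 - (1 - level) / 2) * 100)))
  m
}

#' Predicted species concentrations from a first-order fit
#'
#' @param object a \code{first_order_fit}.
#' @param times minutes at which to predict (default: the fitted times).
#' @param ... unused.
#' @return data.frame with \code{time}, \code{c_ester}, \code{c_4np},
#'   \code{c_4hb} (mM); 4HB follows the ester by stoichiometry.
#' @export
predict.first_order_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$run$times
  e <- object$fitted_c0 * exp(-object$k_app * times)
  data.frame(time = times, c_ester = e,
             c_4np = object$fitted_c0 - e, c_4hb = object$fitted_c0 - e)
}

#' @export
residuals.first_order_fit <- function(object, ...) {
  stats::residuals(object$nls)
}

#' Simulate noisy runs from a fitted first-order model
#'
#' Draws concentration trajectories at the fitted \code{k_app} and \code{c0}
#' with i.i.d. Gaussian noise at the fitted residual RMS.
#'
#' @param object a \code{first_order_fit}.
#' @param nsim number of simulated runs.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of \code{\link{kinetic_run}} objects.
#' @export
simulate.first_order_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  run0 <- object$run
  pred <- predict(object)
  sd <- object$residual_rms
  lapply(seq_len(nsim), function(i) {
    conc <- cbind(c_ester = pred$c_ester + stats::rnorm(nrow(pred), 0, sd),
                  c_4np = pred$c_4np + stats::rnorm(nrow(pred), 0, sd),
                  c_4hb = pred$c_4hb + stats::rnorm(nrow(pred), 0, sd))
    kinetic_run(times = run0$times, conc = conc,
                c_ester_initial = run0$c_ester_initial,
                c_catalyst = run0$c_catalyst,
                c_piperidine = run0$c_piperidine, acn_vv = run0$acn_vv,
                temperature = run0$temperature)
  })
}

#' @export
plot.first_order_fit <- function(x, ...) {
  run <- x$run
  tt <- seq(min(run$times), max(run$times), length.out = 200)
  pred <- predict(x, tt)
  graphics::plot(run$times, run$conc[, "c_ester"], pch = 16,
                 xlab = "time (min)", ylab = "concentration (mM)",
                 ylim = range(0, run$conc, x$fitted_c0), ...)
  graphics::points(run$times, run$conc[, "c_4np"], pch = 1)
  graphics::lines(tt, pred$c_ester)
  graphics::lines(tt, pred$c_4np, lty = 2)
  graphics::legend("right", c("ester (obs)", "4NP (obs)", "ester (fit)",
                              "4NP (fit)"),
                   pch = c(16, 1, NA, NA), lty = c(NA, NA, 1, 2), bty = "n")
  invisible(x)
}
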