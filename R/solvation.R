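#' Trajectory frame: solute, labelled solvent sites, orthorhombic box
#'
#' Only one site per solvent molecule is tracked: the water oxygen
#' (\code{"waterO"}) and the acetonitrile cyano carbon (\code{"acnC"}).
#' Coordinates are wrapped into the primary cell on construction.
#'
#' @param solute n x 3 matrix of solute atom coordinates, nm.
#' @param solvent m x 3 matrix of solvent site coordinates, nm.
#' @param species character vector of length m, values \code{"waterO"} or
#'   \code{"acnC"}.
#' @param box orthorhombic box lengths \code{c(Lx, Ly, Lz)}, nm.
#' @param wrap wrap coordinates into [0, L) per axis (default TRUE).
#' @return object of class \code{traj_frame}.
#' @export
traj_frame <- function(solute, solvent, species, box, wrap = TRUE) {
  solute <- as.matrix(solute)
  solvent <- as.matrix(solvent)
  box <- as.numeric(box)
  stopifnot(ncol(solute) == 3, ncol(solvent) == 3 || nrow(solvent) == 0,
            length(box) == 3, length(species) == nrow(solvent))
  if (any(!is.finite(solute)) || any(!is.finite(solvent)))
    stop("coordinates must be finite")
  if (any(box <= 0)) stop("box lengths must be positive")
  if (!all(species %in% c("waterO", "acnC")))
    stop("species must be 'waterO' or 'acnC'")
  if (wrap) {
    solute <- wrap_coords(solute, box)
    if (nrow(solvent)) solvent <- wrap_coords(solvent, box)
  }
  structure(list(solute = solute, solvent = solvent,
                 species = as.character(species), box = box),
            class = "traj_frame")
}

#' @export
print.traj_frame <- function(x, ...) {
  cat(sprintf(
    "Frame: %d solute atoms, %d waterO + %d acnC sites, box %.2f x %.2f x %.2f nm\n",
    nrow(x$solute), sum(x$species == "waterO"), sum(x$species == "acnC"),
    x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

wrap_coords <- function(xyz, box) {
  for (k in 1:3) xyz[, k] <- xyz[, k] %% box[k]
  xyz
}

#' Minimum-image distance from sites to the nearest solute atom
#'
#' For each query site, the minimum over solute atoms of the periodic
#' minimum-image Euclidean distance in an orthorhombic box.
#'
#' @param sites m x 3 matrix (or length-3 vector) of site coordinates, nm.
#' @param solute_coords n x 3 matrix of solute coordinates, nm.
#' @param box box lengths \code{c(Lx, Ly, Lz)}, nm.
#' @return numeric vector of length m.
#' @export
minimal_distance <- function(sites, solute_coords, box) {
  if (is.null(dim(sites))) sites <- matrix(sites, ncol = 3)
  solute_coords <- as.matrix(solute_coords)
  if (nrow(solute_coords) == 0) stop("empty solute")
  box <- as.numeric(box)
  out <- rep(Inf, nrow(sites))
  for (j in seq_len(nrow(solute_coords))) {
    d2 <- 0
    for (k in 1:3) {
      dk <- sites[, k] - solute_coords[j, k]
      dk <- dk - box[k] * round(dk / box[k])
      d2 <- d2 + dk * dk
    }
    out <- pmin(out, d2)
  }
  sqrt(out)
}

#' Count solvent sites in a contour shell around the solute
#'
#' Local counts are solvent sites whose minimal distance to any solute atom
#' falls in the centered shell \code{[r - width/2, r + width/2)}; totals are
#' all sites of each species in the frame. The union of per-atom shells
#' gives a 0.1 nm-thick 3D shell shaped to the solute's contour.
#'
#' @param frame a \code{\link{traj_frame}}.
#' @param r shell radius, nm (must satisfy \code{r - width/2 >= 0}).
#' @param width shell width, nm (default 0.1).
#' @return named numeric vector \code{c(n_w_local, n_c_local, n_w_total,
#'   n_c_total)}.
#' @export
shell_counts <- function(frame, r, width = 0.1) {
  stopifnot(inherits(frame, "traj_frame"), width > 0)
  if (r - width / 2 < 0) stop("shell extends below zero: r - width/2 < 0")
  is_w <- frame$species == "waterO"
  n_w_total <- sum(is_w)
  n_c_total <- sum(!is_w)
  if (nrow(frame$solvent) == 0)
    return(c(n_w_local = 0, n_c_local = 0, n_w_total = 0, n_c_total = 0))
  d <- minimal_distance(frame$solvent, frame$solute, frame$box)
  in_shell <- d >= r - width / 2 & d < r + width / 2
  c(n_w_local = sum(in_shell & is_w), n_c_local = sum(in_shell & !is_w),
    n_w_total = n_w_total, n_c_total = n_c_total)
}

#' Preferential hydration parameter from shell counts
#'
#' \deqn{\Gamma^* = \frac{n_W^L (n_W^T + n_C^T)}{n_W^T (n_W^L + n_C^L)}}
#' compares the water fraction in the local shell to the water fraction of
#' the whole mixture: 1 means bulk-like, > 1 water-enriched, < 1
#' water-depleted.
#'
#' @param counts named vector from \code{\link{shell_counts}}, or four
#'   numbers \code{(n_w_local, n_c_local, n_w_total, n_c_total)}.
#' @return Gamma*, dimensionless; \code{NA} if the shell is empty.
#' @examples
#' preferential_hydration(c(10, 0, 100, 100))   # 2.0
#' @export
preferential_hydration <- function(counts) {
  cc <- as.numeric(counts)
  stopifnot(length(cc) == 4)
  nwl <- cc[1]; ncl <- cc[2]; nwt <- cc[3]; nct <- cc[4]
  if (nwt <= 0) stop("undefined: no water in the frame")
  if (nwl + ncl == 0) return(NA_real_)   # empty shell: excluded upstream
  nwl * (nwt + nct) / (nwt * (nwl + ncl))
}

#' Preferential-hydration profile with replicate errors
#'
#' For each replicate, shell counts are averaged over frames and Gamma* is
#' computed from the averaged counts (ratio of means; robust to sparse
#' shells). The profile reports the mean and the standard error of Gamma*
#' across replicates at each radius. \code{mode = "per_frame"} instead
#' averages per-frame Gamma* values, excluding empty-shell frames.
#'
#' @param replicates list of replicates, each a list of
#'   \code{\link{traj_frame}} objects (a single flat list of frames is
#'   treated as one replicate).
#' @param radii shell radii, nm.
#' @param width shell width, nm.
#' @param mode \code{"ratio_of_means"} (default) or \code{"per_frame"}.
#' @return object of class \code{hydration_profile}: data.frame with
#'   \code{radius}, \code{gamma_star}, \code{se}, \code{n_replicates}, plus
#'   an \code{excluded} attribute counting empty-shell exclusions.
#' @export
gamma_profile <- function(replicates, radii, width = 0.1,
                          mode = c("ratio_of_means", "per_frame")) {
  mode <- match.arg(mode)
  if (inherits(replicates, "traj_frame")) replicates <- list(list(replicates))
  if (length(replicates) && inherits(replicates[[1]], "traj_frame"))
    replicates <- list(replicates)
  stopifnot(length(replicates) >= 1)
  n_excluded <- 0
  per_rep <- matrix(NA_real_, length(replicates), length(radii))
  for (i in seq_along(replicates)) {
    frames <- replicates[[i]]
    counts <- lapply(radii, function(r)
      t(vapply(frames, shell_counts, numeric(4), r = r, width = width)))
    for (j in seq_along(radii)) {
      cm <- counts[[j]]
      if (mode == "ratio_of_means") {
        avg <- colMeans(cm)
        if (avg[1] + avg[2] == 0) { n_excluded <- n_excluded + 1; next }
        per_rep[i, j] <- preferential_hydration(avg)
      } else {
        g <- apply(cm, 1, preferential_hydration)
        n_excluded <- n_excluded + sum(is.na(g))
        if (all(is.na(g))) next
        per_rep[i, j] <- mean(g, na.rm = TRUE)
      }
    }
  }
  gamma <- colMeans(per_rep, na.rm = TRUE)
  n_rep <- colSums(!is.na(per_rep))
  se <- vapply(seq_along(radii), function(j) {
    v <- per_rep[!is.na(per_rep[, j]), j]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  }, numeric(1))
  gamma[n_rep == 0] <- NA_real_
  out <- data.frame(radius = radii, gamma_star = gamma, se = se,
                    n_replicates = n_rep)
  structure(out, excluded = n_excluded, per_replicate = per_rep,
            class = c("hydration_profile", "data.frame"))
}

#' @export
print.hydration_profile <- function(x, ...) {
  cat("Preferential-hydration profile (Gamma*)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  ex <- attr(x, "excluded")
  if (!is.null(ex) && ex > 0)
    cat(sprintf("  (%d empty-shell exclusions)\n", ex))
  invisible(x)
}

#' @export
plot.hydration_profile <- function(x, ...) {
  graphics::plot(x$radius, x$gamma_star, type = "b", pch = 16,
                 xlab = "r (nm)", ylab = expression(Gamma * "*"), ...)
  graphics::arrows(x$radius, x$gamma_star - x$se, x$radius,
                   x$gamma_star + x$se, angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Frame-averaged raw shell counts per radius
#'
#' Average number of water and acetonitrile sites in each shell, without any
#' normalization — the companion table to the Gamma* profile showing
#' absolute local populations.
#'
#' @param frames list of \code{\link{traj_frame}} objects.
#' @param radii shell radii, nm.
#' @param width shell width, nm.
#' @return data.frame with \code{radius}, \code{n_water}, \code{n_acn}.
#' @export
local_counts_table <- function(frames, radii, width = 0.1) {
  if (inherits(frames, "traj_frame")) frames <- list(frames)
  rows <- t(vapply(radii, function(r) {
    cm <- t(vapply(frames, shell_counts, numeric(4), r = r, width = width))
    colMeans(cm)[1:2]
  }, numeric(2)))
  data.frame(radius = radii, n_water = rows[, 1], n_acn = rows[, 2])
}
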