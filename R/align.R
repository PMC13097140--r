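#' Superpose frames onto a reference solute
#'
#' Rigid-body least-squares superposition (rotation + translation, no
#' scaling; Kabsch algorithm) of each frame's solute onto the reference
#' coordinates; solvent sites are co-transformed. Periodic images of the
#' solute are resolved before fitting by unwrapping each atom to the minimum
#' image relative to the solute centroid, and each solvent site to the
#' minimum image relative to the solute centroid.
#'
#' @param frames list of \code{\link{traj_frame}} objects with identical
#'   solute atom count and order.
#' @param reference n x 3 matrix of reference solute coordinates, nm
#'   (default: the first frame's unwrapped solute).
#' @return list of aligned frames (class \code{traj_frame}, unwrapped
#'   coordinates, \code{box} retained) with per-frame attribute \code{rmsd}.
#' @export
align_frames <- function(frames, reference = NULL) {
  if (inherits(frames, "traj_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  n_atoms <- nrow(frames[[1]]$solute)
  if (n_atoms < 3) stop("alignment undefined: need >= 3 solute atoms")
  unwrapped <- lapply(frames, unwrap_frame)
  if (is.null(reference)) reference <- unwrapped[[1]]$solute
  reference <- as.matrix(reference)
  if (nrow(reference) != n_atoms)
    stop("reference solute atom count mismatch")
  if (collinear(reference)) stop("alignment undefined: collinear solute")
  ref_c <- colMeans(reference)
  ref0 <- sweep(reference, 2, ref_c)
  lapply(unwrapped, function(fr) {
    mob <- fr$solute
    mob_c <- colMeans(mob)
    mob0 <- sweep(mob, 2, mob_c)
    rot <- kabsch_rotation(mob0, ref0)
    new_solute <- sweep(mob0 %*% rot, 2, ref_c, `+`)
    new_solvent <- if (nrow(fr$solvent))
      sweep(sweep(fr$solvent, 2, mob_c) %*% rot, 2, ref_c, `+`)
    else fr$solvent
    out <- traj_frame(new_solute, new_solvent, fr$species, fr$box,
                      wrap = FALSE)
    attr(out, "rmsd") <- sqrt(mean(rowSums((new_solute - reference)^2)))
    out
  })
}

# unwrap a frame so the solute is whole and solvent sites sit in the image
# nearest the solute centroid
unwrap_frame <- function(fr) {
  box <- fr$box
  ref <- fr$solute[1, ]
  solute <- fr$solute
  for (k in 1:3) {
    dk <- solute[, k] - ref[k]
    solute[, k] <- ref[k] + dk - box[k] * round(dk / box[k])
  }
  cen <- colMeans(solute)
  solvent <- fr$solvent
  if (nrow(solvent)) for (k in 1:3) {
    dk <- solvent[, k] - cen[k]
    solvent[, k] <- cen[k] + dk - box[k] * round(dk / box[k])
  }
  traj_frame(solute, solvent, fr$species, box, wrap = FALSE)
}

collinear <- function(m) {
  m0 <- sweep(m, 2, colMeans(m))
  qr(m0)$rank < 2
}

kabsch_rotation <- function(mob0, ref0) {
  h <- t(mob0) %*% ref0
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Spatial distribution function on a voxel grid
#'
#' Bins solvent sites of one species from aligned frames into a regular 3-D
#' voxel grid, converts counts to number density (count / voxel volume /
#' n_frames) and normalizes by the species' bulk number density (total
#' species count / box volume, averaged over frames). Voxels at or above
#' \code{threshold} times bulk density are flagged as isosurface members
#' (default 10x, the conventional drawing level).
#'
#' @param frames list of aligned \code{\link{traj_frame}} objects.
#' @param spacing voxel edge length, nm (default 0.05).
#' @param species \code{"waterO"} or \code{"acnC"}.
#' @param threshold isosurface flag level in multiples of bulk density.
#' @param bulk \code{"species"} (default) normalizes by the species' own
#'   bulk density; \code{"total"} by the combined solvent density.
#' @return object of class \code{density_grid}: list with \code{origin},
#'   \code{spacing}, \code{dims}, \code{density} (3-D array, bulk-normalized),
#'   \code{iso} (logical array), \code{bulk_density} (nm^-3),
#'   \code{n_frames}, \code{n_binned}.
#' @export
sdf_grid <- function(frames, spacing = 0.05, species = "waterO",
                     threshold = 10, bulk = c("species", "total")) {
  bulk <- match.arg(bulk)
  if (inherits(frames, "traj_frame")) frames <- list(frames)
  if (length(frames) == 0) stop("zero frames")
  stopifnot(spacing > 0)
  pts <- do.call(rbind, lapply(frames, function(fr)
    fr$solvent[fr$species == species, , drop = FALSE]))
  vol <- mean(vapply(frames, function(fr) prod(fr$box), numeric(1)))
  n_sp <- mean(vapply(frames, function(fr)
    sum(fr$species == species), numeric(1)))
  n_all <- mean(vapply(frames, function(fr)
    length(fr$species), numeric(1)))
  bulk_density <- (if (bulk == "species") n_sp else n_all) / vol
  if (is.null(pts) || nrow(pts) == 0) {
    dims <- c(1L, 1L, 1L)
    return(structure(list(origin = c(0, 0, 0), spacing = spacing,
                          dims = dims, density = array(0, dims),
                          iso = array(FALSE, dims),
                          bulk_density = bulk_density,
                          n_frames = length(frames), n_binned = 0L),
                     class = "density_grid"))
  }
  lo <- apply(pts, 2, min) - spacing / 2
  hi <- apply(pts, 2, max) + spacing / 2
  dims <- pmax(ceiling((hi - lo) / spacing), 1L)
  idx <- sweep(pts, 2, lo)
  ijk <- pmin(floor(idx / spacing), matrix(rep(dims - 1, each = nrow(pts)),
                                           ncol = 3)) + 1
  lin <- ijk[, 1] + dims[1] * (ijk[, 2] - 1) + dims[1] * dims[2] * (ijk[, 3] - 1)
  counts <- array(tabulate(lin, nbins = prod(dims)), dim = dims)
  dens <- counts / (spacing^3 * length(frames)) / bulk_density
  structure(list(origin = lo, spacing = spacing, dims = dims,
                 density = dens, iso = dens >= threshold,
                 bulk_density = bulk_density, n_frames = length(frames),
                 n_binned = nrow(pts)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "SDF grid: %d x %d x %d voxels @ %.3g nm, %d sites over %d frames\n",
    x$dims[1], x$dims[2], x$dims[3], x$spacing, x$n_binned, x$n_frames))
  cat(sprintf("  bulk density %.3g nm^-3; %d voxel(s) above isosurface level\n",
              x$bulk_density, sum(x$iso)))
  invisible(x)
}
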