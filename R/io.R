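#' Read trajectory frames from an XYZ-dialect or GRO file
#'
#' Two plain-text formats are supported. The XYZ dialect is a standard
#' multi-frame XYZ file whose comment line declares the box:
#' \preformatted{
#'   5
#'   box 5.0 5.0 5.0 nm
#'   OW  1.20 3.40 0.55
#'   ...
#' }
#' (coordinates in nm). GRO files are parsed by their fixed columns with
#' positions natively in nm and the box on the final line of each frame.
#' Atom names are partitioned through \code{species_map}, a named character
#' vector mapping atom name to \code{"solute"}, \code{"waterO"},
#' \code{"acnC"} or \code{"ignore"}; an unmapped name is an error.
#'
#' @param path file path.
#' @param species_map named character vector, e.g.
#'   \code{c(C1 = "solute", OW = "waterO", CZ = "acnC", HW = "ignore")}.
#' @param format \code{"auto"} (by extension), \code{"xyz"} or \code{"gro"}.
#' @return list of \code{\link{traj_frame}} objects.
#' @export
read_frames <- function(path, species_map, format = c("auto", "xyz", "gro")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "xyz"
  lines <- readLines(path)
  if (format == "xyz") parse_xyz(lines, species_map, path)
  else parse_gro(lines, species_map, path)
}

frame_from_atoms <- function(names, xyz, box, species_map, path, line0) {
  unmapped <- setdiff(unique(names), names(species_map))
  if (length(unmapped))
    stop(sprintf("%s: unmapped atom name(s): %s (near line %d)", path,
                 paste(unmapped, collapse = ", "), line0))
  role <- unname(species_map[names])
  keep <- role != "ignore"
  role <- role[keep]; xyz <- xyz[keep, , drop = FALSE]
  is_solute <- role == "solute"
  traj_frame(xyz[is_solute, , drop = FALSE], xyz[!is_solute, , drop = FALSE],
             role[!is_solute], box)
}

parse_xyz <- function(lines, species_map, path) {
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop(sprintf("%s: expected atom count at line %d", path, i))
    if (i + 1 + n > length(lines))
      stop(sprintf("%s: truncated frame starting at line %d", path, i))
    cm <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(cm) < 4 || cm[1] != "box")
      stop(sprintf("%s: line %d must read 'box Lx Ly Lz nm'", path, i + 1))
    box <- as.numeric(cm[2:4])
    rec <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    bad <- which(vapply(rec, length, integer(1)) < 4)
    if (length(bad))
      stop(sprintf("%s: malformed atom record at line %d", path, i + 1 + bad[1]))
    nm <- vapply(rec, `[`, character(1), 1)
    xyz <- matrix(as.numeric(unlist(lapply(rec, `[`, 2:4))), ncol = 3,
                  byrow = TRUE)
    if (any(!is.finite(xyz)))
      stop(sprintf("%s: non-numeric coordinate in frame at line %d", path, i))
    frames[[length(frames) + 1]] <-
      frame_from_atoms(nm, xyz, box, species_map, path, i)
    i <- i + 2 + n
  }
  if (!length(frames)) stop(sprintf("%s: no frames found", path))
  frames
}

parse_gro <- function(lines, species_map, path) {
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    if (i + 1 > length(lines))
      stop(sprintf("%s: truncated header at line %d", path, i))
    n <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(n))
      stop(sprintf("%s: expected atom count at line %d", path, i + 1))
    if (i + 2 + n > length(lines))
      stop(sprintf("%s: truncated frame starting at line %d", path, i))
    atom_lines <- lines[(i + 2):(i + 1 + n)]
    nm <- trimws(substr(atom_lines, 11, 15))
    x <- as.numeric(substr(atom_lines, 21, 28))
    y <- as.numeric(substr(atom_lines, 29, 36))
    z <- as.numeric(substr(atom_lines, 37, 44))
    if (any(is.na(x) | is.na(y) | is.na(z)))
      stop(sprintf("%s: malformed coordinates near line %d", path,
                   i + 1 + which(is.na(x) | is.na(y) | is.na(z))[1]))
    box <- as.numeric(strsplit(trimws(lines[i + 2 + n]), "\\s+")[[1]][1:3])
    if (any(is.na(box)))
      stop(sprintf("%s: malformed box line at %d", path, i + 2 + n))
    frames[[length(frames) + 1]] <-
      frame_from_atoms(nm, cbind(x, y, z), box, species_map, path, i)
    i <- i + 3 + n
  }
  if (!length(frames)) stop(sprintf("%s: no frames found", path))
  frames
}

#' Write frames in the XYZ dialect
#'
#' @param frames list of \code{\link{traj_frame}} objects (or one frame).
#' @param path output path.
#' @param solute_name,digits atom label used for solute atoms and printed
#'   coordinate precision.
#' @return \code{path}, invisibly.
#' @export
write_frames_xyz <- function(frames, path, solute_name = "SOL",
                             digits = 6) {
  if (inherits(frames, "traj_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (fr in frames) {
    nm <- c(rep(solute_name, nrow(fr$solute)),
            ifelse(fr$species == "waterO", "OW", "CZ"))
    xyz <- rbind(fr$solute, fr$solvent)
    writeLines(as.character(nrow(xyz)), con)
    writeLines(sprintf("box %g %g %g nm", fr$box[1], fr$box[2], fr$box[3]),
               con)
    writeLines(sprintf(fmt, nm, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a calibration set from JSON
#'
#' Expects a JSON object mapping species to wavelength to coefficient, e.g.
#' \code{{"4NP4HB": {"250": 2.1, "320": 9.0, "400": 0.4}, ...}}.
#'
#' @param path JSON file path.
#' @return a \code{\link{calibration_set}}.
#' @export
read_calibration_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_set(lapply(raw, unlist))
}

#' Read a kinetic run from CSV plus a metadata file
#'
#' The CSV must have columns \code{time_min}, \code{abs250}, \code{abs320},
#' \code{abs400}; metadata is a JSON or YAML file with fields
#' \code{c_ester_initial_mM}, \code{c_catalyst_mM}, \code{c_piperidine_mM},
#' \code{acn_vv}, \code{temperature_C}, \code{dilution_factor}.
#'
#' @param csv_path CSV of the absorbance trace.
#' @param meta_path JSON/YAML metadata.
#' @return a \code{\link{kinetic_run}}.
#' @export
read_kinetic_run <- function(csv_path, meta_path) {
  d <- utils::read.csv(csv_path, comment.char = "#")
  need <- c("time_min", "abs250", "abs320", "abs400")
  if (!all(need %in% names(d)))
    stop("kinetics CSV must have columns: ", paste(need, collapse = ", "))
  meta <- if (grepl("\\.ya?ml$", meta_path, ignore.case = TRUE))
    yaml::read_yaml(meta_path) else jsonlite::read_json(meta_path,
                                                        simplifyVector = TRUE)
  kinetic_run(times = d$time_min, abs250 = d$abs250, abs320 = d$abs320,
              abs400 = d$abs400,
              c_ester_initial = meta$c_ester_initial_mM,
              c_catalyst = meta$c_catalyst_mM %||% 0,
              c_piperidine = meta$c_piperidine_mM %||% 0,
              acn_vv = meta$acn_vv %||% 50,
              temperature = meta$temperature_C %||% 50,
              dilution_factor = meta$dilution_factor %||% 10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read long-format distance series
#'
#' CSV with columns \code{replicate_id}, \code{window_nm},
#' \code{distance_nm}; returns one \code{\link{distance_series}} per
#' (replicate, window) group.
#'
#' @param path CSV path.
#' @return named list of \code{distance_series}.
#' @export
read_distance_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("replicate_id", "window_nm", "distance_nm")
  if (!all(need %in% names(d)))
    stop("distance CSV must have columns: ", paste(need, collapse = ", "))
  key <- interaction(d$replicate_id, d$window_nm, drop = TRUE)
  lapply(split(d, key), function(g)
    distance_series(g$distance_nm, replicate_id = as.character(g$replicate_id[1]),
                    window_com_distance = g$window_nm[1]))
}

#' Export a density grid as OpenDX-style text
#'
#' Writes the bulk-normalized density array in the OpenDX "regular
#' positions, regular connections" scalar format readable by VMD and PyMOL.
#'
#' @param grid a \code{\link{sdf_grid}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0 0", grid$spacing),
    sprintf("delta 0 %g 0", grid$spacing),
    sprintf("delta 0 0 %g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # dx order: z fastest
  vals <- as.vector(aperm(grid$density, c(3, 2, 1)))
  n3 <- (length(vals) %/% 3) * 3
  if (n3 > 0)
    writeLines(sprintf("%g %g %g", vals[seq(1, n3, 3)], vals[seq(2, n3, 3)],
                       vals[seq(3, n3, 3)]), con)
  if (n3 < length(vals))
    writeLines(paste(sprintf("%g", vals[(n3 + 1):length(vals)]),
                     collapse = " "), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
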