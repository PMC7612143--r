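# Format readers and writers. Internal units are nm and ns everywhere;
# angstroms appear only at the PDB boundary.

#' Construct a Trajectory from long-format coordinates
#'
#' Normalizes a long-format table (one row per water per frame) into a
#' \linkS4class{Trajectory}: frames are indexed 0..nFrames-1 in time
#' order and the full frame time vector is retained even for frames that
#' end up with no waters.
#'
#' @param coords data.frame with columns \code{time} (ns), \code{molId},
#'   \code{x}, \code{y}, \code{z} (nm); a \code{frame} column, if present,
#'   is recomputed from the times.
#' @param times optional full frame-time vector (ns); defaults to the
#'   sorted unique times present in \code{coords}.
#' @param persistentIds logical, whether molIds are stable across frames.
#' @param metadata list.
#' @return a \linkS4class{Trajectory}.
#' @export
makeTrajectory <- function(coords, times = NULL, persistentIds = TRUE,
                           metadata = list()) {
  need <- c("time", "molId", "x", "y", "z")
  miss <- setdiff(need, names(coords))
  if (length(miss))
    stop("coords is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(times)) times <- sort(unique(coords$time))
  idx <- match(coords$time, times)
  if (anyNA(idx))
    stop("coords contain times absent from the frame time vector")
  out <- data.frame(frame = idx - 1L, time = coords$time,
                    molId = coords$molId, x = coords$x, y = coords$y,
                    z = coords$z)
  out <- out[order(out$frame, out$molId), , drop = FALSE]
  rownames(out) <- NULL
  new("Trajectory", coords = out, times = as.numeric(times),
      persistentIds = persistentIds, metadata = metadata)
}

#' Read a pore structure from PDB or GRO
#'
#' PDB files are parsed with bio3d and converted from angstrom to nm; GRO
#' files (already in nm) are parsed directly. Van der Waals radii are
#' assigned from a bundled element table (H 0.12, C 0.17, N 0.155,
#' O 0.152, S 0.18 nm; unknown elements fall back to carbon), unless
#' \code{pseudoRadiiFromB = TRUE}, in which case the PDB B-factor column
#' is taken to hold per-atom radii in nm (the convention used by
#' \code{\link{writeStructure}} for pseudo-atom walls).
#'
#' @param path file path ending in .pdb or .gro.
#' @param pseudoRadiiFromB logical, read radii from the B-factor column
#'   (PDB only).
#' @return a \linkS4class{PoreStructure}.
#' @export
readStructure <- function(path, pseudoRadiiFromB = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path)
    at <- pdb$atom
    el <- at$elesy
    el[is.na(el) | el == ""] <- substr(trimws(at$elety[is.na(el) | el == ""]), 1, 1)
    radius <- if (pseudoRadiiFromB) as.numeric(at$b) else .vdwRadius(el)
    atoms <- data.frame(id = seq_len(nrow(at)), name = trimws(at$elety),
                        element = trimws(el), x = at$x / 10, y = at$y / 10,
                        z = at$z / 10, radius = radius,
                        resid = at$resno, resname = trimws(at$resid))
  } else if (ext == "gro") {
    atoms <- .readGro(path)
  } else {
    stop("unrecognized structure extension '.", ext, "' (expected .pdb or .gro)")
  }
  new("PoreStructure", atoms = atoms,
      metadata = list(source = path, format = ext))
}

# GRO fixed-width parser: resno(5) resname(5) atomname(5) atomnum(5)
# x y z in %8.3f nm.
.readGro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GRO file: ", path)
  nAtoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nAtoms)) stop("GRO line 2 must hold the atom count: ", path)
  if (length(lines) < 2L + nAtoms)
    stop(sprintf("truncated GRO file: expected %d atom lines, found %d",
                 nAtoms, length(lines) - 3L))
  al <- lines[3:(2 + nAtoms)]
  parseNum <- function(txt, ln) {
    v <- suppressWarnings(as.numeric(txt))
    if (anyNA(v))
      stop(sprintf("malformed GRO coordinate at line %d", ln[which(is.na(v))[1]]))
    v
  }
  ln <- 2L + seq_len(nAtoms)
  name <- trimws(substr(al, 11, 15))
  resname <- trimws(substr(al, 6, 10))
  x <- parseNum(substr(al, 21, 28), ln)
  y <- parseNum(substr(al, 29, 36), ln)
  z <- parseNum(substr(al, 37, 44), ln)
  el <- substr(name, 1, 1)
  data.frame(id = seq_len(nAtoms), name = name, element = el,
             x = x, y = y, z = z, radius = .vdwRadius(el),
             resid = suppressWarnings(as.integer(substr(al, 1, 5))),
             resname = resname)
}

#' Write a pore structure to PDB or GRO
#'
#' PDB output stores coordinates in angstrom and per-atom radii (nm) in
#' the B-factor column, so pseudo-atom walls round-trip through
#' \code{readStructure(..., pseudoRadiiFromB = TRUE)}. GRO output is in
#' nm.
#'
#' @param structure a \linkS4class{PoreStructure}.
#' @param path output path ending in .pdb or .gro.
#' @return the path, invisibly.
#' @export
writeStructure <- function(structure, path) {
  stopifnot(is(structure, "PoreStructure"))
  a <- structure@atoms
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    n <- nrow(a)
    xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")]))) * 10
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = if ("resid" %in% names(a)) a$resid else seq_len(n),
                     resid = rep(if ("resname" %in% names(a)) a$resname else "WAL",
                                 length.out = n),
                     elety = rep(a$name, length.out = n),
                     b = rep(a$radius, length.out = n))
  } else if (ext == "gro") {
    hdr <- c("PoreHydration structure", sprintf("%5d", nrow(a)))
    resid <- if ("resid" %in% names(a)) a$resid else seq_len(nrow(a))
    resname <- if ("resname" %in% names(a)) a$resname else "WAL"
    body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    resid %% 100000L, substr(resname, 1, 5),
                    substr(a$name, 1, 5), a$id %% 100000L, a$x, a$y, a$z)
    writeLines(c(hdr, body, "  10.00000  10.00000  10.00000"), path)
  } else {
    stop("unrecognized structure extension '.", ext, "'")
  }
  invisible(path)
}

#' Read a trajectory from the CSV dialect
#'
#' The CSV dialect is long-format with columns \code{frame},
#' \code{time_ns}, \code{mol_id}, \code{x}, \code{y}, \code{z}
#' (coordinates in nm, one row per water per frame). XTC input is not
#' supported by this implementation; convert binary trajectories to the
#' CSV dialect first.
#'
#' @param path file path ending in .csv.
#' @param persistentIds logical, whether mol_id is stable across frames
#'   (default TRUE).
#' @return a \linkS4class{Trajectory}.
#' @export
readTrajectory <- function(path, persistentIds = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xtc")
    stop("XTC reading is not supported; convert the trajectory to the CSV dialect (frame,time_ns,mol_id,x,y,z)")
  if (ext != "csv")
    stop("unrecognized trajectory extension '.", ext, "' (expected .csv)")
  if (!file.exists(path)) stop("file not found: ", path)
  d <- data.table::fread(path, data.table = FALSE)
  need <- c("frame", "time_ns", "mol_id", "x", "y", "z")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("trajectory CSV is missing column(s): ", paste(miss, collapse = ", "))
  makeTrajectory(data.frame(time = d$time_ns, molId = d$mol_id,
                            x = d$x, y = d$y, z = d$z),
                 persistentIds = persistentIds,
                 metadata = list(source = path))
}

#' Write a trajectory in the CSV dialect
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path output .csv path.
#' @return the path, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  co <- traj@coords
  data.table::fwrite(data.frame(frame = co$frame, time_ns = co$time,
                                mol_id = co$molId, x = co$x, y = co$y,
                                z = co$z), path)
  invisible(path)
}

#' Write / read a pathway as CSV plus JSON metadata
#'
#' The CSV holds columns \code{s}, \code{x}, \code{y}, \code{z},
#' \code{R}; the sidecar JSON (same path with extension .json) records the
#' construction metadata (seed point, step, rng seed, axis, convention).
#'
#' @param pathway a \linkS4class{Pathway}.
#' @param path output .csv path.
#' @return the path, invisibly.
#' @export
writePathway <- function(pathway, path) {
  stopifnot(is(pathway, "Pathway"))
  d <- data.frame(s = pathway@s, x = pathway@points[, 1],
                  y = pathway@points[, 2], z = pathway@points[, 3],
                  R = pathway@radius)
  data.table::fwrite(d, path)
  meta <- c(pathway@metadata, list(axis = pathway@axis, step = pathway@step))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePathway
#' @param path input .csv path (the sidecar .json is read when present).
#' @export
readPathway <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  need <- c("s", "x", "y", "z", "R")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("pathway CSV is missing column(s): ", paste(miss, collapse = ", "))
  metaPath <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(metaPath))
    jsonlite::read_json(metaPath, simplifyVector = TRUE) else list()
  axis <- if (!is.null(meta$axis)) as.numeric(meta$axis) else c(0, 0, 1)
  step <- if (!is.null(meta$step)) as.numeric(meta$step) else
    stats::median(diff(d$s))
  meta$axis <- NULL; meta$step <- NULL
  pts <- unname(as.matrix(d[, c("x", "y", "z")]))
  new("Pathway", points = pts, s = d$s, radius = d$R, axis = axis,
      step = step, metadata = meta)
}

#' Write a density or free-energy profile as CSV
#'
#' Density profiles are written with columns \code{s,n,sd,n_repeats};
#' free-energy profiles with \code{s,G,sd,capped}.
#'
#' @param profile a \linkS4class{DensityProfile} or
#'   \linkS4class{FreeEnergyProfile}.
#' @param path output .csv path.
#' @return the path, invisibly.
#' @export
writeProfile <- function(profile, path) {
  if (is(profile, "DensityProfile")) {
    d <- data.frame(s = profile@sGrid, n = profile@density, sd = profile@sd,
                    n_repeats = nrow(profile@repeatDensity))
  } else if (is(profile, "FreeEnergyProfile")) {
    d <- data.frame(s = profile@sGrid, G = profile@G, sd = profile@sd,
                    capped = as.integer(profile@capped))
  } else stop("profile must be a DensityProfile or FreeEnergyProfile")
  data.table::fwrite(d, path)
  invisible(path)
}
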