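# Structure and trajectory I/O.  PDB and DCD reading go through bio3d; GRO
# (both directions), PDB writing (CRYST1 + ATOM records) and DCD writing
# (CHARMM dialect, matching what bio3d::read.dcd parses) are implemented
# here.  Coordinates are Angstrom in memory; GRO files are nm on disk.

#' Read a structure file (PDB or GRO) into a one-frame trajectory
#'
#' @param path file ending in \code{.pdb} or \code{.gro}; must carry box
#'   information (CRYST1 record / box line).
#' @param specs lipid-definition list for topology annotation.
#' @param replicate_id,condition labels for the resulting trajectory.
#' @return A one-frame \code{\link{mem_trajectory}} with atom order
#'   preserved.
#' @export
read_structure <- function(path, specs = lipid_definitions(),
                           replicate_id = basename(path),
                           condition = "other") {
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
                   gro = parse_gro(path),
                   pdb = parse_pdb(path),
                   stop("unsupported structure format: .", ext))
  if (ext == "pdb") {
    # the 4-character PDB resName field truncates longer residue codes
    # (PVCL2 -> PVCL); resolve by unique prefix match against the table
    rn <- parsed$raw$resname
    for (nm in setdiff(unique(rn), names(specs))) {
      hit <- names(specs)[startsWith(names(specs), nm)]
      if (length(hit) == 1L) parsed$raw$resname[rn == nm] <- hit
    }
  }
  topo <- annotate_topology(parsed$raw, specs)
  mem_trajectory(topo, array(parsed$xyz, c(nrow(parsed$xyz), 3, 1)),
                 matrix(parsed$box, 1), times = 0,
                 replicate_id = replicate_id, condition = condition)
}

parse_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed GRO file (fewer than 3 lines)")
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms)) stop("malformed GRO record at line 2: atom count")
  if (length(lines) < natoms + 3L)
    stop("GRO file truncated: expected ", natoms, " atom lines")
  al <- lines[3:(natoms + 2L)]
  resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resname <- trimws(substr(al, 6, 10))
  atom <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed GRO record at line ", bad[1] + 2L)
  box <- suppressWarnings(as.numeric(strsplit(trimws(
    lines[natoms + 3L]), "\\s+")[[1]]))
  if (length(box) < 3L || anyNA(box[1:3]))
    stop("missing or malformed GRO box line")
  if (any(box[1:3] <= 0)) stop("zero-length box vector in GRO file")
  list(raw = data.frame(resid = resid, resname = resname, atom = atom,
                        stringsAsFactors = FALSE),
       xyz = cbind(x, y, z) * 10, box = box[1:3] * 10)
}

parse_pdb <- function(path) {
  cl <- grep("^CRYST1", readLines(path), value = TRUE)
  if (!length(cl)) stop("PDB file has no CRYST1 record (missing box)")
  box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                      substr(cl[1], 25, 33)))
  if (anyNA(box) || any(box <= 0)) stop("zero-length box vector in PDB file")
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  list(raw = data.frame(resid = pdb$atom$resno, resname = pdb$atom$resid,
                        atom = pdb$atom$elety, stringsAsFactors = FALSE),
       xyz = cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z), box = box)
}

#' Write one frame to a structure file (GRO or PDB)
#'
#' @param traj a \code{\link{mem_trajectory}}.
#' @param path output path ending in \code{.gro} or \code{.pdb}.
#' @param frame frame index to write.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(traj, path, frame = 1L) {
  fr <- get_frame(traj, frame)
  a <- traj$topology$atoms
  ext <- tolower(tools::file_ext(path))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (ext == "gro") {
    lines <- c("memiso structure",
               sprintf("%5d", nrow(a)),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$resid %% 100000L, substr(a$resname, 1, 5),
                       substr(a$atom, 1, 5), a$index %% 100000L,
                       fr$xyz[, 1] / 10, fr$xyz[, 2] / 10, fr$xyz[, 3] / 10),
               sprintf("%10.5f%10.5f%10.5f", fr$box[1] / 10, fr$box[2] / 10,
                       fr$box[3] / 10))
  } else if (ext == "pdb") {
    nm <- ifelse(nchar(a$atom) >= 4L, substr(a$atom, 1, 4),
                 sprintf(" %-3s", a$atom))
    lines <- c(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       fr$box[1], fr$box[2], fr$box[3], 90, 90, 90),
               sprintf("ATOM  %5d %4s %-4s%5d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                       a$index %% 100000L, nm, substr(a$resname, 1, 4),
                       a$resid %% 10000L, fr$xyz[, 1], fr$xyz[, 2],
                       fr$xyz[, 3], 1, 0),
               "END")
  } else stop("unsupported structure format: .", ext)
  writeLines(lines, con)
  invisible(path)
}

#' Write a trajectory to a CHARMM-style DCD file
#'
#' Binary DCD with a per-frame crystal record (orthorhombic cell), readable
#' by \code{bio3d::read.dcd} and common MD tools.
#'
#' @param traj a \code{\link{mem_trajectory}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_dcd <- function(traj, path) {
  nf <- n_frames(traj)
  natom <- dim(traj$coords)[1]
  con <- file(path, open = "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4,
                               endian = "little")
  # header block: 'CORD' + 20 control ints (nframes, istart, nsavc, nstep,
  # ..., delta as float in slot 10, crystal flag in slot 11, version 24)
  wint(84)
  writeChar("CORD", con, 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 0L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- 1L; icntrl[20] <- 24L
  wint(icntrl[1:9])
  dt <- if (nf > 1L) diff(traj$times)[1] else 1
  writeBin(as.numeric(dt), con, size = 4, endian = "little")  # delta, float32
  wint(icntrl[11:20])
  wint(84)
  title <- sprintf("%-80s", "memiso trajectory")
  wint(4L + 80L)
  wint(1L)
  writeChar(title, con, 80, eos = NULL)
  wint(4L + 80L)
  wint(4); wint(natom); wint(4)
  for (f in seq_len(nf)) {
    # crystal record: a, cos(gamma), b, cos(beta), cos(alpha), c
    wint(48)
    writeBin(as.numeric(c(traj$box[f, 1], 0, traj$box[f, 2], 0, 0,
                          traj$box[f, 3])), con, size = 8, endian = "little")
    wint(48)
    for (d in 1:3) {
      wint(4L * natom)
      writeBin(as.numeric(traj$coords[, d, f]), con, size = 4,
               endian = "little")
      wint(4L * natom)
    }
  }
  invisible(path)
}

#' Read a trajectory (structure + DCD) into a \code{mem_trajectory}
#'
#' @param structure_path PDB or GRO file defining atoms and topology.
#' @param traj_path DCD file with matching atom count.
#' @param specs lipid-definition list.
#' @param stride keep every \code{stride}-th frame.
#' @param dt_ns frame spacing in ns used to synthesize times (DCD time
#'   handling is dialect-dependent; the default 0.01 ns matches a 10 ps
#'   write interval).  Coordinates are not unwrapped at read time.
#' @param replicate_id,condition labels.
#' @return A \code{\link{mem_trajectory}}.
#' @export
read_trajectory <- function(structure_path, traj_path,
                            specs = lipid_definitions(), stride = 1L,
                            dt_ns = 0.01, replicate_id = basename(traj_path),
                            condition = "other") {
  st <- read_structure(structure_path, specs)
  xyz <- bio3d::read.dcd(traj_path, verbose = FALSE)
  cell <- bio3d::read.dcd(traj_path, verbose = FALSE, cell = TRUE)
  ndcd <- ncol(xyz) / 3
  natom <- dim(st$coords)[1]
  if (ndcd != natom)
    stop("atom-count mismatch: structure has ", natom,
         " atoms but trajectory has ", ndcd)
  idx <- seq(1L, nrow(xyz), by = stride)
  coords <- array(NA_real_, c(natom, 3, length(idx)))
  for (k in seq_along(idx))
    coords[, , k] <- matrix(xyz[idx[k], ], ncol = 3, byrow = TRUE)
  mem_trajectory(st$topology, coords, cell[idx, 1:3, drop = FALSE],
                 times = (idx - 1L) * dt_ns, replicate_id = replicate_id,
                 condition = condition)
}
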