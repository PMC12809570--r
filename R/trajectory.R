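# The mem_trajectory container: annotated topology + coordinates over frames.
# Coordinates are Angstrom, times ns, boxes orthorhombic (Lx, Ly, Lz).

#' Construct a trajectory container
#'
#' @param topology a \code{\link{annotate_topology}} result.
#' @param coords numeric array \code{[n_atoms, 3, n_frames]}, Angstrom.
#' @param box numeric matrix \code{[n_frames, 3]} of box lengths, Angstrom.
#' @param times numeric vector of frame times in ns, strictly increasing.
#' @param replicate_id label for the replicate.
#' @param condition one of \code{"cis"}, \code{"trans"}, \code{"other"}.
#' @return Object of class \code{"mem_trajectory"}.
#' @export
mem_trajectory <- function(topology, coords, box, times,
                           replicate_id = "r1", condition = "other") {
  condition <- match.arg(condition, c("cis", "trans", "other"))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be an [n_atoms, 3, n_frames] array")
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  if (nrow(box) != nf) stop("box must have one row per frame")
  if (any(box <= 0)) stop("box lengths must be positive")
  if (length(times) != nf) stop("times must have one entry per frame")
  if (nf > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (dim(coords)[1] != nrow(topology$atoms))
    stop("coords has ", dim(coords)[1], " atoms but topology has ",
         nrow(topology$atoms))
  if (!all(is.finite(coords))) stop("positions must be finite")
  structure(list(topology = topology, coords = coords, box = box,
                 times = times, replicate_id = replicate_id,
                 condition = condition),
            class = "mem_trajectory")
}

#' @export
print.mem_trajectory <- function(x, ...) {
  cat(sprintf(
    "<mem_trajectory> %s (%s): %d atoms, %d frames, %.4g-%.4g ns, box %.1f x %.1f x %.1f A\n",
    x$replicate_id, x$condition, dim(x$coords)[1], n_frames(x),
    x$times[1], x$times[n_frames(x)], x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  print(x$topology)
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{mem_trajectory}.
#' @return integer.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame
#' @param traj a \code{mem_trajectory}.
#' @param i frame index.
#' @return list with \code{xyz} (n_atoms x 3 matrix), \code{box}, \code{time}.
#' @export
get_frame <- function(traj, i = 1L) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  list(xyz = traj$coords[, , i, drop = TRUE], box = traj$box[i, ],
       time = traj$times[i])
}

#' Keep a subset of frames
#' @param traj a \code{mem_trajectory}.
#' @param idx frame indices to keep (increasing).
#' @return a \code{mem_trajectory}.
#' @export
subset_frames <- function(traj, idx) {
  mem_trajectory(traj$topology, traj$coords[, , idx, drop = FALSE],
                 traj$box[idx, , drop = FALSE], traj$times[idx],
                 traj$replicate_id, traj$condition)
}

# Heavy-atom (non-hydrogen) centroid of each lipid residue, one frame.
# Returns matrix [n_lipid_residues, 3] with rownames = resid.
residue_centroids_frame <- function(xyz, topology) {
  a <- topology$atoms
  sel <- a$is_lipid & a$role != "H"
  g <- a$resid[sel]
  cx <- rowsum(xyz[sel, , drop = FALSE], g)
  cx / as.vector(table(g)[rownames(cx)])
}

# Centroid tracks over all frames: array [n_res, 3, n_frames].
residue_centroid_tracks <- function(traj) {
  a <- traj$topology$atoms
  sel <- which(a$is_lipid & a$role != "H")
  g <- a$resid[sel]
  counts <- as.vector(table(g))
  nf <- n_frames(traj)
  nres <- length(counts)
  out <- array(NA_real_, c(nres, 3, nf))
  for (f in seq_len(nf)) {
    cx <- rowsum(traj$coords[sel, , f], g)
    out[, , f] <- cx / counts
  }
  dimnames(out) <- list(sort(unique(g)), NULL, NULL)
  out
}

# resname per lipid resid, in resid order
residue_names <- function(topology) {
  a <- topology$atoms[topology$atoms$is_lipid, ]
  tab <- a[!duplicated(a$resid), c("resid", "resname")]
  tab[order(tab$resid), ]
}
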