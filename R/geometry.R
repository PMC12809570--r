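# Core geometry: torsions, cis/trans classification, the 180-degree
# isomerization operator, leaflet assignment, xy periodic wrapping/unwrapping.

#' Signed dihedral (torsion) angle
#'
#' Standard signed torsion about the p2-p3 axis, in degrees in (-180, 180].
#' The sign follows the right-hand rule looking from p2 toward p3.
#'
#' @param p1,p2,p3,p4 numeric length-3 positions (Angstrom).
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16)
    stop("degenerate dihedral: three consecutive points are collinear")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Vectorized torsions for a sites table against one frame's coordinates.
site_dihedrals <- function(xyz, sites) {
  if (nrow(sites) == 0L) return(numeric(0))
  p1 <- xyz[sites$a1, , drop = FALSE]; p2 <- xyz[sites$a2, , drop = FALSE]
  p3 <- xyz[sites$a3, , drop = FALSE]; p4 <- xyz[sites$a4, , drop = FALSE]
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- rowcross(b1, b2); n2 <- rowcross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- rowcross(n1, b2n)
  ang <- atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Classify double-bond sites as cis or trans
#'
#' A site is cis iff the absolute torsion over its four defining carbons is
#' below 90 degrees; 90 itself (the symmetry point) is classed trans.
#'
#' @param xyz n_atoms x 3 coordinate matrix (one frame).
#' @param sites an \code{unsaturation_sites} table (see
#'   \code{\link{annotate_topology}}).
#' @return character vector \code{"cis"}/\code{"trans"}, one per site.
#' @export
classify_sites <- function(xyz, sites) {
  d <- site_dihedrals(xyz, sites)
  ifelse(abs(d) < 90, "cis", "trans")
}

# Distal atom set for a site: delete the a2-a3 bond, take the connected
# component containing a3.  Error if the component reaches back to a2 (ring).
distal_set <- function(site, bonds, n_atoms) {
  a2 <- site$a2; a3 <- site$a3
  keep <- !((bonds[, 1] == a2 & bonds[, 2] == a3) |
              (bonds[, 1] == a3 & bonds[, 2] == a2))
  b <- bonds[keep, , drop = FALSE]
  adj <- split(c(b[, 2], b[, 1]), c(b[, 1], b[, 2]))
  seen <- logical(n_atoms)
  seen[a3] <- TRUE
  queue <- a3
  while (length(queue)) {
    nb <- unique(unlist(adj[as.character(queue)], use.names = FALSE))
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- nb
  }
  if (seen[a2])
    stop("distal set reaches back across the double bond (ring detected) ",
         "for residue ", site$resid)
  which(seen)
}

#' Rotate one double bond by 180 degrees (cis <-> trans)
#'
#' Applies a rigid 180-degree rotation about the axis through the two
#' double-bond carbons to every atom distal to the bond (toward the chain
#' terminus), leaving the glycerol-proximal part fixed.  The operation is an
#' exact involution and an isometry on the rotated set.
#'
#' @param xyz n_atoms x 3 coordinate matrix.
#' @param site one row of an \code{unsaturation_sites} table.
#' @param bonds 2-column global bond index matrix.
#' @return the modified coordinate matrix.
#' @export
isomerize_site <- function(xyz, site, bonds) {
  idx <- distal_set(site, bonds, nrow(xyz))
  o <- xyz[site$a2, ]
  u <- xyz[site$a3, ] - o
  nu <- sqrt(sum(u^2))
  if (nu < 1e-10) stop("double-bond carbons coincide")
  u <- u / nu
  # 180-degree rotation about u through o: p' = o + 2 u (u . (p-o)) - (p-o)
  p <- sweep(xyz[idx, , drop = FALSE], 2, o)
  proj <- drop(p %*% u)
  xyz[idx, ] <- sweep(2 * outer(proj, u) - p, 2, o, "+")
  xyz
}

#' Isomerize every (selected) site toward a target state
#'
#' @param xyz n_atoms x 3 coordinate matrix.
#' @param sites \code{unsaturation_sites} table.
#' @param bonds bond index matrix.
#' @param target \code{"cis"}, \code{"trans"}, or \code{"invert"}.
#' @return list with \code{xyz} (new coordinates) and \code{report}
#'   (data.frame: per site, state before/after and whether it was rotated).
#' @export
isomerize_all <- function(xyz, sites, bonds, target = c("invert", "cis",
                                                        "trans")) {
  target <- match.arg(target)
  before <- classify_sites(xyz, sites)
  rotate <- if (target == "invert") rep(TRUE, nrow(sites)) else
    before != target
  for (i in which(rotate)) {
    xyz <- isomerize_site(xyz, sites[i, ], bonds)
  }
  after <- classify_sites(xyz, sites)
  want <- if (target == "invert") ifelse(before == "cis", "trans", "cis") else
    rep(target, nrow(sites))
  bad <- which(after != want)
  if (length(bad))
    stop("isomerization failed for site(s) at residue ",
         paste(sites$resid[bad], collapse = ", "))
  list(xyz = xyz,
       report = data.frame(resid = sites$resid, tail = sites$tail,
                           position = sites$position, before = before,
                           after = after, rotated = rotate))
}

#' Assign each lipid residue to a leaflet
#'
#' A residue is "upper" when its phosphate-centroid z lies above the mean z of
#' all lipid phosphate atoms, "lower" otherwise.  Residues whose centroid is
#' within \code{eps} of the midplane are resolved by tail direction (terminal
#' carbons below the phosphates means upper) and flagged.
#'
#' @param xyz n_atoms x 3 coordinate matrix (one frame).
#' @param topology a \code{mem_topology}.
#' @param eps ambiguity band half-width around the midplane (Angstrom).
#' @return named character vector resid -> \code{"upper"}/\code{"lower"},
#'   with attribute \code{"ambiguous"} listing flagged residues.
#' @export
assign_leaflets <- function(xyz, topology, eps = 5) {
  a <- topology$atoms
  ph <- a$role %in% c("P", "OP")
  if (!any(ph)) stop("no phosphate atoms in topology")
  mid <- mean(xyz[ph, 3])
  cz <- rowsum(xyz[ph, 3], a$resid[ph])
  cz <- cz / as.vector(table(a$resid[ph])[rownames(cz)])
  dz <- cz[, 1] - mid
  leaf <- ifelse(dz > 0, "upper", "lower")
  ambiguous <- character(0)
  near <- which(abs(dz) < eps)
  if (length(near)) {
    term <- a$role == "C"
    tz <- rowsum(xyz[term, 3], a$resid[term])
    tz <- tz / as.vector(table(a$resid[term])[rownames(tz)])
    for (i in near) {
      rid <- names(dz)[i]
      # tails point toward the midplane: tail carbons below the phosphates
      # for an upper-leaflet lipid
      leaf[i] <- if (tz[rid, 1] < cz[rid, 1]) "upper" else "lower"
      ambiguous <- c(ambiguous, rid)
    }
  }
  if (length(unique(leaf)) < 2L && length(leaf) >= 2L)
    warning("all residues assigned to one leaflet")
  attr(leaf, "ambiguous") <- ambiguous
  leaf
}

#' Wrap xy coordinates into the box
#' @param xy n x 2 matrix.
#' @param box length-2 (or more) box lengths.
#' @return wrapped matrix with columns in [0, L).
#' @export
wrap_xy <- function(xy, box) {
  cbind(xy[, 1] - box[1] * floor(xy[, 1] / box[1]),
        xy[, 2] - box[2] * floor(xy[, 2] / box[2]))
}

#' Unwrap periodic xy tracks into continuous tracks
#'
#' Removes box jumps from per-residue centroid tracks by minimum-image
#' correction of consecutive displacements.  Assumes no true displacement
#' exceeds half the box between consecutive frames; a remaining jump of that
#' size after unwrapping triggers a warning (aliasing).
#'
#' @param tracks array \code{[n_res, 2, n_frames]} of wrapped xy positions.
#' @param box length-2 box (Lx, Ly), or matrix \code{[n_frames, 2+]}.
#' @return array of the same shape, continuous in time.
#' @export
unwrap_xy <- function(tracks, box) {
  nf <- dim(tracks)[3]
  if (is.null(dim(box))) box <- matrix(box[1:2], nf, 2, byrow = TRUE)
  out <- tracks
  for (f in 2:nf) {
    d <- matrix(tracks[, , f] - tracks[, , f - 1L], ncol = 2)
    d <- d - rep(box[f, 1:2], each = nrow(d)) * round(
      d / rep(box[f, 1:2], each = nrow(d)))
    if (any(abs(d) >= box[f, 1:2][col(d)] / 2))
      warning("displacement >= box/2 after unwrapping at frame ", f,
              "; track may be aliased")
    out[, , f] <- out[, , f - 1L] + d
  }
  out
}
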