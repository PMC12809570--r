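# Frame-wise structural metrics: thickness, volume, grid area per lipid,
# kink angle, double-bond depth distribution, surface-accessibility fraction.

leaflets_or_default <- function(traj, leaflets) {
  if (!is.null(leaflets)) return(leaflets)
  assign_leaflets(get_frame(traj, 1L)$xyz, traj$topology)
}

thickness_frame <- function(xyz, topology, leaflets) {
  a <- topology$atoms
  ph <- which(a$role %in% c("P", "OP"))
  lf <- leaflets[as.character(a$resid[ph])]
  if (!any(lf == "upper") || !any(lf == "lower"))
    stop("empty leaflet: cannot measure thickness")
  mean(xyz[ph[lf == "upper"], 3]) - mean(xyz[ph[lf == "lower"], 3])
}

#' Phosphate-to-phosphate membrane thickness
#'
#' Mean z of the upper leaflet's phosphate atoms minus mean z of the lower
#' leaflet's, per frame.
#'
#' @param traj a \code{\link{mem_trajectory}}.
#' @param leaflets optional residue -> leaflet map; computed from frame 1 by
#'   \code{\link{assign_leaflets}} when NULL.
#' @return A \code{\link{metric_series}} in Angstrom.
#' @export
thickness <- function(traj, leaflets = NULL) {
  leaflets <- leaflets_or_default(traj, leaflets)
  v <- vapply(seq_len(n_frames(traj)), function(f)
    thickness_frame(traj$coords[, , f], traj$topology, leaflets), numeric(1))
  metric_series("thickness", "A", traj$times, v, traj$replicate_id,
                traj$condition)
}

#' Membrane volume
#'
#' Box X times box Y times phosphate-to-phosphate thickness, per frame.
#'
#' @inheritParams thickness
#' @return A \code{\link{metric_series}} in Angstrom^3.
#' @export
membrane_volume <- function(traj, leaflets = NULL) {
  th <- thickness(traj, leaflets)
  metric_series("volume", "A^3", traj$times,
                traj$box[, 1] * traj$box[, 2] * th$values,
                traj$replicate_id, traj$condition)
}

#' Grid assignment for one area-per-lipid plane
#'
#' Lays a grid (spacing at most \code{grid_max_spacing}) over the membrane
#' plane at height \code{gz} and assigns every grid point to the nearest
#' lipid residue among \code{candidates}, using xy minimum-image distance
#' plus (by default) the z offset to the plane.
#'
#' @param xyz frame coordinates.
#' @param box box lengths.
#' @param gz absolute z of the grid plane.
#' @param candidates integer atom indices eligible for assignment.
#' @param resid residue id per atom (full-length vector).
#' @param grid_max_spacing maximum grid spacing, A.
#' @param use_z include the z term in the distance (set FALSE for xy-only).
#' @return integer matrix \code{[nx, ny]} of residue ids, with attributes
#'   \code{cell_area} and \code{spacing}.
#' @export
apl_assign <- function(xyz, box, gz, candidates, resid,
                       grid_max_spacing = 1, use_z = TRUE) {
  nx <- ceiling(box[1] / grid_max_spacing)
  ny <- ceiling(box[2] / grid_max_spacing)
  ax <- box[1] / nx; ay <- box[2] / ny
  gx <- (seq_len(nx) - 0.5) * ax
  gy <- (seq_len(ny) - 0.5) * ay
  grid <- cbind(rep(gx, times = ny), rep(gy, each = nx))
  assign <- grid_nearest(grid, gz, xyz[candidates, , drop = FALSE],
                         as.integer(resid[candidates]), box[1], box[2],
                         use_z)
  structure(matrix(assign, nx, ny), cell_area = ax * ay,
            spacing = c(ax, ay))
}

#' Area per lipid by nearest-residue grid partitioning
#'
#' Subdivides the membrane plane into a grid with at most
#' \code{grid_max_spacing} between points, lays it out at the two
#' \code{plane_offsets} from the phosphate midplane, and assigns each point
#' to the nearest lipid residue of that plane's leaflet (heavy atoms only).
#' The per-type area is assigned cells times cell area divided by the count
#' of that type in the leaflet; total area is conserved exactly since every
#' cell is assigned exactly once.
#'
#' @param traj a \code{\link{mem_trajectory}}.
#' @param frames frame indices to analyze (default: all).
#' @param grid_max_spacing maximum grid spacing in A (default 1).
#' @param plane_offsets grid heights relative to the phosphate midplane, A.
#' @param use_z nearest search in 3D (TRUE, default) or xy-only (FALSE).
#' @param leaflets optional leaflet map.
#' @return Object of class \code{"apl_result"}: data.frame with one row per
#'   (resname, plane) holding the time-mean area per lipid (A^2), plus
#'   attributes \code{conservation_error} (cells, should be 0) and
#'   \code{spacing}.
#' @export
area_per_lipid <- function(traj, frames = NULL, grid_max_spacing = 1,
                           plane_offsets = c(-18, 18), use_z = TRUE,
                           leaflets = NULL) {
  leaflets <- leaflets_or_default(traj, leaflets)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  a <- traj$topology$atoms
  rids <- residue_names(traj$topology)
  heavy <- a$is_lipid & a$role != "H"
  leaf_of_atom <- leaflets[as.character(a$resid)]
  acc <- list()
  cons_err <- 0
  for (f in frames) {
    xyz <- traj$coords[, , f]
    box <- traj$box[f, ]
    ph <- a$role %in% c("P", "OP")
    lf <- leaf_of_atom[ph]
    mid <- (mean(xyz[which(ph)[lf == "upper"], 3]) +
              mean(xyz[which(ph)[lf == "lower"], 3])) / 2
    for (off in plane_offsets) {
      side <- if (off > 0) "upper" else "lower"
      cand <- which(heavy & leaf_of_atom == side)
      if (!length(cand)) stop("no lipids in the ", side, " leaflet")
      am <- apl_assign(xyz, box, mid + off, cand, a$resid,
                       grid_max_spacing, use_z)
      cells <- table(factor(am, levels = rids$resid))
      cons_err <- max(cons_err, abs(sum(cells) - length(am)))
      key <- paste(side, off)
      tab <- rowsum(as.numeric(cells),
                    rids$resname)[, 1] * attr(am, "cell_area")
      acc[[key]] <- if (is.null(acc[[key]])) tab else acc[[key]] + tab
    }
  }
  out <- list()
  for (key in names(acc)) {
    side <- sub(" .*", "", key)
    off <- as.numeric(sub(".* ", "", key))
    res_leaf <- rids[leaflets[as.character(rids$resid)] == side, ]
    counts <- table(res_leaf$resname)
    area <- acc[[key]] / length(frames)
    for (rn in names(area)) {
      n_in_leaf <- if (rn %in% names(counts)) as.integer(counts[[rn]]) else 0L
      if (n_in_leaf == 0L) {
        if (area[[rn]] > 0) stop("cells assigned to a type absent from the ",
                                 side, " leaflet")
        next  # area reported absent, not zero
      }
      out[[length(out) + 1L]] <- data.frame(
        resname = rn, plane_offset = off, leaflet = side,
        n_lipids = n_in_leaf, total_area = area[[rn]],
        area_per_lipid = area[[rn]] / n_in_leaf, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  structure(out, conservation_error = cons_err,
            n_frames = length(frames), class = c("apl_result", "data.frame"))
}

#' @export
print.apl_result <- function(x, ...) {
  cat(sprintf("<apl_result> %d plane rows over %d frame(s); conservation error %g cells\n",
              nrow(x), attr(x, "n_frames"), attr(x, "conservation_error")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Kink angle at each unsaturation site
#'
#' Interior angle at the chain-proximal double-bond carbon between the
#' vectors to the tail's terminal carbon and carbonyl carbon, in degrees.
#' Saturated tails have no kink and no site.
#'
#' @param traj a \code{\link{mem_trajectory}}.
#' @param frames frame indices (default all).
#' @return data.frame with columns frame, time_ns, resid, resname, tail,
#'   angle_deg.
#' @export
kink_angles <- function(traj, frames = NULL) {
  s <- traj$topology$sites
  if (nrow(s) == 0L) stop("no unsaturation sites: saturated tails have no kink")
  # first site per (resid, tail): multi-unsaturated tails use the first kink
  first <- !duplicated(s[, c("resid", "tail")])
  s <- s[first, ]
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    xyz <- traj$coords[, , f]
    v1 <- xyz[s$carbonyl, , drop = FALSE] - xyz[s$a2, , drop = FALSE]
    v2 <- xyz[s$terminal, , drop = FALSE] - xyz[s$a2, , drop = FALSE]
    cosang <- rowSums(v1 * v2) /
      sqrt(rowSums(v1^2) * rowSums(v2^2))
    out[[k]] <- data.frame(frame = f, time_ns = traj$times[f],
                           resid = s$resid, resname = s$resname,
                           tail = s$tail,
                           angle_deg = acos(pmin(1, pmax(-1, cosang))) *
                             180 / pi)
  }
  do.call(rbind, out)
}

#' Signed double-bond (or phosphate) depths below the phosphate plane
#'
#' For each frame and leaflet the reference plane is the mean z of that
#' leaflet's phosphorus atoms.  The signed depth is plane minus atom z for
#' the upper leaflet and atom z minus plane for the lower, so d > 0 means
#' buried toward the midplane and d < 0 past the plane into water.
#'
#' @param traj a \code{\link{mem_trajectory}}.
#' @param what \code{"double_bond"} (carbons of C=C bonds) or
#'   \code{"phosphate"} (phosphorus plus phosphate oxygens).
#' @param frames frame indices (default all).
#' @param leaflets optional leaflet map.
#' @return numeric vector of depths (A), pooled over atoms, leaflets, frames.
#' @export
double_bond_depths <- function(traj, what = c("double_bond", "phosphate"),
                               frames = NULL, leaflets = NULL) {
  what <- match.arg(what)
  leaflets <- leaflets_or_default(traj, leaflets)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  a <- traj$topology$atoms
  sel <- if (what == "double_bond") which(a$db & a$role == "C") else
    which(a$role %in% c("P", "OP"))
  if (!length(sel)) stop("empty selection for ", what)
  pP <- which(a$role == "P")
  lf_sel <- leaflets[as.character(a$resid[sel])]
  lf_P <- leaflets[as.character(a$resid[pP])]
  up <- lf_sel == "upper"
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    z <- traj$coords[, 3, frames[k]]
    plane_up <- mean(z[pP[lf_P == "upper"]])
    plane_lo <- mean(z[pP[lf_P == "lower"]])
    d <- numeric(length(sel))
    d[up] <- plane_up - z[sel[up]]
    d[!up] <- z[sel[!up]] - plane_lo
    out[[k]] <- d
  }
  unlist(out)
}

#' Depth distribution of double-bond and phosphate atoms
#'
#' Histogram of signed depths relative to the per-leaflet phosphate plane,
#' normalized to relative probability (each class sums to 1).  Samples
#' outside the bin range are counted into the end bins.
#'
#' @param traj a \code{\link{mem_trajectory}}.
#' @param breaks strictly increasing bin edges, A.
#' @param frames frame indices (default all).
#' @param leaflets optional leaflet map.
#' @return Object of class \code{"zdistribution"}: list with \code{breaks},
#'   \code{mids} and a \code{density} matrix (bins x classes).
#' @export
double_bond_zdist <- function(traj, breaks = seq(-10, 30, by = 0.5),
                              frames = NULL, leaflets = NULL) {
  if (any(diff(breaks) <= 0)) stop("bin edges must be strictly increasing")
  classes <- c("double_bond", "phosphate")
  dens <- sapply(classes, function(cl) {
    d <- double_bond_depths(traj, cl, frames, leaflets)
    i <- findInterval(d, breaks, all.inside = TRUE)
    tab <- tabulate(i, nbins = length(breaks) - 1L)
    tab / sum(tab)
  })
  structure(list(breaks = breaks,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 density = dens),
            class = "zdistribution")
}

#' @export
print.zdistribution <- function(x, ...) {
  cat(sprintf("<zdistribution> %d bins over [%g, %g] A; classes: %s\n",
              length(x$mids), min(x$breaks), max(x$breaks),
              paste(colnames(x$density), collapse = ", ")))
  invisible(x)
}

#' @export
plot.zdistribution <- function(x, ...) {
  graphics::matplot(x$mids, x$density, type = "l", lty = 1,
                    xlab = "depth below phosphate plane (A)",
                    ylab = "relative probability", ...)
  graphics::legend("topright", colnames(x$density), lty = 1,
                   col = seq_len(ncol(x$density)))
  invisible(x)
}

#' Fraction of double-bond carbons near the membrane surface
#'
#' Fraction of depth samples with d <= cutoff, i.e. within \code{cutoff} of
#' the phosphate plane on the headgroup side or beyond it into water
#' (\code{side = "headgroup"}, default).  \code{side = "absolute"} instead
#' counts |d| <= cutoff.
#'
#' @param x a \code{\link{mem_trajectory}} or a numeric vector of signed
#'   depths from \code{\link{double_bond_depths}}.
#' @param cutoff distance cutoff, A.
#' @param side counting rule, see above.
#' @param ... passed to \code{double_bond_depths} when \code{x} is a
#'   trajectory.
#' @return fraction in [0, 1].
#' @export
surface_fraction <- function(x, cutoff = 5,
                             side = c("headgroup", "absolute"), ...) {
  side <- match.arg(side)
  d <- if (inherits(x, "mem_trajectory"))
    double_bond_depths(x, "double_bond", ...) else as.numeric(x)
  if (!length(d)) stop("zero depth samples")
  if (side == "headgroup") mean(d <= cutoff) else mean(abs(d) <= cutoff)
}
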