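# Lateral diffusion: MSD over chunked, drift-corrected, unwrapped residue
# centroid tracks, and the endpoint D = MSD / (2 n t) estimator.

#' Unwrapped xy centroid tracks of all lipid residues
#'
#' Heavy-atom residue centroids, unwrapped across the periodic xy boundary.
#'
#' @param traj a \code{\link{mem_trajectory}}.
#' @return array \code{[n_res, 2, n_frames]} with residue ids as rownames.
#' @export
centroid_tracks <- function(traj) {
  tr <- residue_centroid_tracks(traj)
  xy <- tr[, 1:2, , drop = FALSE]
  dimnames(xy) <- dimnames(tr)
  if (n_frames(traj) > 1L) xy <- unwrap_xy(xy, traj$box)
  xy
}

#' Remove per-leaflet collective drift from tracks
#'
#' Subtracts, per frame and leaflet, the mean position of that leaflet's
#' residue centroids, so collective leaflet translation does not inflate the
#' MSD.
#'
#' @param tracks array \code{[n_res, 2, n_frames]} (residue ids as rownames).
#' @param leaflets residue -> leaflet map.
#' @return drift-corrected array of the same shape.
#' @export
drift_correct <- function(tracks, leaflets) {
  lf <- leaflets[rownames(tracks)]
  for (side in unique(lf)) {
    i <- which(lf == side)
    for (d in 1:2) {
      m <- colMeans(tracks[i, d, , drop = FALSE])
      tracks[i, d, ] <- tracks[i, d, ] - rep(m, each = length(i))
    }
  }
  tracks
}

#' Mean squared lateral displacement per chunk
#'
#' Splits the trajectory into non-overlapping chunks, restarts the reference
#' position x0 at each chunk start, and returns MSD(t) = mean over residues
#' of |r_xy(t) - r_xy(t0)|^2 (single time origin per chunk; set
#' \code{origin = "multi"} to average over all origins within the chunk).
#'
#' @param x a \code{\link{mem_trajectory}}, or a track array
#'   \code{[n, 2, n_frames]} (then supply \code{times}).
#' @param lipid_type optional residue-name filter (trajectory input only).
#' @param n_chunks number of equal chunks (default 1 = whole trajectory).
#' @param origin \code{"single"} (one origin per chunk) or \code{"multi"}.
#' @param drift logical: apply \code{\link{drift_correct}} (trajectory input
#'   only).
#' @param times frame times in ns, for track-array input.
#' @param replicate_id label used for track-array input.
#' @return Object of class \code{"msd_curves"}: data.frame with columns
#'   lag_ns, msd, type, chunk, replicate, n_res.
#' @export
msd <- function(x, lipid_type = NULL, n_chunks = 1L,
                origin = c("single", "multi"), drift = TRUE, times = NULL,
                replicate_id = NULL) {
  origin <- match.arg(origin)
  if (inherits(x, "mem_trajectory")) {
    tracks <- centroid_tracks(x)
    if (drift) {
      lf <- leaflets_or_default(x, NULL)
      tracks <- drift_correct(tracks, lf)
    }
    rn <- residue_names(x$topology)
    type <- stats::setNames(rn$resname, rn$resid)[rownames(tracks)]
    if (!is.null(lipid_type)) {
      keep <- type %in% lipid_type
      tracks <- tracks[keep, , , drop = FALSE]
      type <- type[keep]
    }
    times <- x$times
    replicate_id <- x$replicate_id
  } else {
    tracks <- x
    if (is.null(times)) stop("track-array input requires frame times")
    type <- rep("all", dim(tracks)[1])
    if (is.null(replicate_id)) replicate_id <- "r1"
  }
  nf <- dim(tracks)[3]
  if (nf < 2L) stop("need at least 2 frames for an MSD")
  if (!length(type)) stop("no residues selected")
  bounds <- floor(seq(0, nf, length.out = n_chunks + 1L))
  out <- list()
  for (ck in seq_len(n_chunks)) {
    idx <- (bounds[ck] + 1L):bounds[ck + 1L]
    sub <- tracks[, , idx, drop = FALSE]
    lags <- times[idx] - times[idx[1]]
    for (tp in unique(type)) {
      w <- which(type == tp)
      if (origin == "single") {
        d1 <- matrix(sub[w, 1, , drop = FALSE] - c(sub[w, 1, 1]),
                     nrow = length(w))
        d2 <- matrix(sub[w, 2, , drop = FALSE] - c(sub[w, 2, 1]),
                     nrow = length(w))
        m <- colMeans(d1^2 + d2^2)
      } else {
        nt <- length(idx)
        m <- numeric(nt)
        for (lag in 0:(nt - 1L)) {
          o <- 1:(nt - lag)
          dd <- (sub[w, 1, o + lag, drop = FALSE] -
                   sub[w, 1, o, drop = FALSE])^2 +
            (sub[w, 2, o + lag, drop = FALSE] -
               sub[w, 2, o, drop = FALSE])^2
          m[lag + 1L] <- mean(dd)
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        lag_ns = lags, msd = m, type = tp, chunk = ck,
        replicate = replicate_id, n_res = length(w),
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out), class = c("msd_curves", "data.frame"))
}

#' Diffusion coefficient from MSD curves
#'
#' The default \code{"endpoint"} mode applies D = MSD(T) / (2 n T) literally
#' to each chunk's final MSD value (T = chunk duration, n = 2 in-plane
#' dimensions); \code{"fit"} instead uses a least-squares line through the
#' origin over the whole chunk.  The estimate per type is the mean over
#' chunk x replicate samples; SE = sd / sqrt(n_samples).
#'
#' @param curves an \code{msd_curves} table from \code{\link{msd}} (possibly
#'   rbind-ed over replicates).
#' @param n_dims number of diffusive dimensions (2 for lateral diffusion).
#' @param mode \code{"endpoint"} or \code{"fit"}.
#' @return Object of class \code{"diffusion_estimate"}: data.frame with
#'   columns type, D_A2ns, D_cm2s (1 A^2/ns = 1e-7 cm^2/s), se_A2ns,
#'   n_samples.
#' @export
diffusion_coefficient <- function(curves, n_dims = 2,
                                  mode = c("endpoint", "fit")) {
  mode <- match.arg(mode)
  key <- interaction(curves$type, curves$chunk, curves$replicate, drop = TRUE)
  ds <- vapply(levels(key), function(k) {
    cc <- curves[key == k, ]
    T <- max(cc$lag_ns)
    if (T <= 0) stop("zero chunk duration")
    if (mode == "endpoint") {
      cc$msd[which.max(cc$lag_ns)] / (2 * n_dims * T)
    } else {
      sum(cc$msd * cc$lag_ns) / sum(cc$lag_ns^2) / (2 * n_dims)
    }
  }, numeric(1))
  type <- vapply(levels(key), function(k) curves$type[key == k][1],
                 character(1))
  out <- do.call(rbind, lapply(unique(type), function(tp) {
    v <- ds[type == tp]
    data.frame(type = tp, D_A2ns = mean(v), D_cm2s = mean(v) * 1e-7,
               se_A2ns = if (length(v) > 1L)
                 stats::sd(v) / sqrt(length(v)) else 0,
               n_samples = length(v), stringsAsFactors = FALSE)
  }))
  structure(out, class = c("diffusion_estimate", "data.frame"))
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat("<diffusion_estimate> D = MSD/(2 n t), endpoint per chunk\n")
  df <- x
  if (!is.null(df$D_cm2s)) df$D_cm2s <- sprintf("%.3g", df$D_cm2s)
  print.data.frame(df, digits = 4)
  invisible(x)
}
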