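# Acyl-chain order parameter S_CH = <3 cos^2(theta) - 1>/2, theta between
# each C-H bond vector and the bilayer normal (+z), averaged over hydrogens,
# residues and frames.  Reported with sign (not |S_CD|).

#' Order-parameter profile per carbon
#'
#' @param traj a \code{\link{mem_trajectory}} with explicit hydrogens.
#' @param lipid_type optional residue name filter (default: all types).
#' @param tail optional tail index filter.
#' @param frames frame indices (default all).
#' @return Object of class \code{"order_profile"}: data.frame with columns
#'   resname, tail, carbon, sch, n (sample count).  Carbons without
#'   hydrogens are simply absent.
#' @export
sch <- function(traj, lipid_type = NULL, tail = NULL, frames = NULL) {
  a <- traj$topology$atoms
  h <- which(a$role == "H")
  if (!is.null(lipid_type)) h <- h[a$resname[h] %in% lipid_type]
  if (!is.null(tail)) h <- h[a$tail[h] %in% tail]
  if (!length(h)) stop("no C-H pairs selected")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  par <- a$parent[h]
  grp <- factor(paste(a$resname[h], a$tail[h], a$pos[h], sep = "\r"))
  ssum <- numeric(nlevels(grp)); n <- 0
  for (f in frames) {
    v <- traj$coords[h, , f] - traj$coords[par, , f]
    cost2 <- v[, 3]^2 / rowSums(v^2)
    ssum <- ssum + rowsum((3 * cost2 - 1) / 2, grp)[, 1]
    n <- n + 1
  }
  cnt <- as.integer(table(grp)) * length(frames)
  key <- do.call(rbind, strsplit(levels(grp), "\r", fixed = TRUE))
  out <- data.frame(resname = key[, 1], tail = as.integer(key[, 2]),
                    carbon = as.integer(key[, 3]),
                    sch = ssum / (as.integer(table(grp)) * length(frames)),
                    n = cnt, stringsAsFactors = FALSE)
  out <- out[order(out$resname, out$tail, out$carbon), ]
  rownames(out) <- NULL
  structure(out, class = c("order_profile", "data.frame"))
}

#' @export
print.order_profile <- function(x, ...) {
  cat(sprintf("<order_profile> %d carbons; tail-mean S_CH = %.4f\n",
              nrow(x), stats::weighted.mean(x$sch, x$n)))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Tail-averaged order parameter over time windows
#'
#' Windowed tail-mean S_CH versus time, exposing order drift such as a phase
#' change during the trajectory.
#'
#' @param traj a \code{\link{mem_trajectory}}.
#' @param window_frames frames per window (non-overlapping).
#' @param lipid_type,tail optional filters as in \code{\link{sch}}.
#' @return A \code{\link{metric_series}} (dimensionless), one value per
#'   window at the window's central time.
#' @export
order_timeseries <- function(traj, window_frames, lipid_type = NULL,
                             tail = NULL) {
  nf <- n_frames(traj)
  if (window_frames > nf)
    stop("window (", window_frames, " frames) longer than trajectory (",
         nf, ")")
  starts <- seq(1L, nf - window_frames + 1L, by = window_frames)
  vals <- vapply(starts, function(s) {
    p <- sch(traj, lipid_type, tail, frames = s:(s + window_frames - 1L))
    stats::weighted.mean(p$sch, p$n)
  }, numeric(1))
  mid <- traj$times[starts + (window_frames - 1L) %/% 2L]
  metric_series("order", "1", mid, vals, traj$replicate_id, traj$condition)
}
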