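# Seeded synthetic-bilayer generator with closed-form ground truth for every
# analysis metric.  Lipids are bead-resolution: balanced phosphate bead sets
# (so the per-residue phosphate centroid sits exactly at the leaflet plane),
# zig-zag acyl chains with an exactly constructed kink angle at the double
# bond, and explicit hydrogens resampled per frame from the tilt law.

.geom <- list(step = 1.25,     # axis advance per chain carbon, A
              w = 0.45,        # zig-zag half-width, A
              ch = 1.09,       # C-H bond length, A
              d_head = 2.0,    # carbonyl drop below the phosphate plane, A
              tilt = 8 * pi / 180)  # chain-axis tilt from the normal

#' Parameters of a synthetic bilayer trajectory
#'
#' The defaults emulate the all-atom P. putida patch at desk scale: the full
#' 100-lipid composition, a phosphate-to-phosphate thickness near 38-40 A,
#' lateral diffusion in the high-1e-8 cm2/s range with slower cardiolipin,
#' double-bond depths ~12 A below the phosphate plane with rare surface
#' excursions (stationary probability ~0.8% cis / 0.15% trans within 5 A of
#' the plane), and a kink angle 15 degrees smaller (more bent) for cis.
#'
#' @param condition \code{"cis"} or \code{"trans"}; selects condition presets
#'   for every parameter left \code{NULL}.
#' @param seed integer RNG seed (mandatory; all randomness flows from it).
#' @param composition a \code{\link{membrane_composition}} (per leaflet).
#' @param box box lengths (Lx, Ly, Lz) in Angstrom; NULL (default) selects
#'   the condition preset (57.0 cis / 55.6 trans in-plane, chosen with the
#'   thickness pair so the all-cis membrane is ~2.5 percent larger in
#'   volume).
#' @param thickness_mean,thickness_sd phosphate-to-phosphate thickness law, A.
#' @param diffusion named per-residue-type lateral diffusion coefficients in
#'   A^2/ns (unnamed scalar = all types).
#' @param tilt C-H tilt law: \code{list(type = "fixed", theta0_deg = x)} with
#'   \code{x} scalar or per-frame vector, or \code{list(type = "isotropic")}.
#' @param depth_mean,depth_sd bulk Gaussian law for double-bond depth below
#'   the phosphate plane, A.
#' @param surface_prob stationary probability of the surface-excursion state
#'   (site placed uniformly within \code{surface_band} of the plane).
#' @param surface_persistence Markov switching rate in (0, 1]; 1 = no
#'   persistence (i.i.d. states), smaller = stickier states.
#' @param surface_band depth interval (A) occupied during an excursion.
#' @param kink_angle_deg interior angle at the double bond between the
#'   vectors to the terminal and carbonyl carbons.
#' @param n_frames,dt_ns trajectory length and frame spacing.
#' @return Object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(condition = c("cis", "trans"), seed,
                           composition = default_composition(),
                           box = NULL,
                           thickness_mean = NULL, thickness_sd = 0.3,
                           diffusion = NULL,
                           tilt = NULL,
                           depth_mean = NULL, depth_sd = NULL,
                           surface_prob = NULL, surface_persistence = 0.2,
                           surface_band = c(0, 5),
                           kink_angle_deg = NULL,
                           n_frames = 501, dt_ns = 0.1) {
  condition <- match.arg(condition)
  if (missing(seed)) stop("a seed is mandatory for the synthetic generator")
  cis <- condition == "cis"
  # trans lipids pack tighter: smaller in-plane box (lower area per lipid)
  # but a thicker membrane.  The 57.0/55.6 x 39/40 pairing leaves the
  # all-cis membrane ~2.5% larger in volume, as in the study system.
  if (is.null(box)) box <- if (cis) c(57, 57, 80) else c(55.6, 55.6, 80)
  if (is.null(thickness_mean)) thickness_mean <- if (cis) 39 else 40
  if (is.null(diffusion)) {
    d0 <- if (cis) 0.65 else 0.52
    dcl <- if (cis) 0.30 else 0.24
    diffusion <- stats::setNames(
      ifelse(vapply(composition$specs, `[[`, character(1),
                    "headgroup_class") == "CL", dcl, d0),
      names(composition$specs))
  }
  if (is.null(names(diffusion)) && length(diffusion) == 1L)
    diffusion <- stats::setNames(rep(diffusion, length(composition$specs)),
                                 names(composition$specs))
  if (is.null(tilt))
    tilt <- list(type = "fixed", theta0_deg = if (cis) 48.8 else 45)
  if (is.null(depth_mean)) depth_mean <- if (cis) 12 else 13
  if (is.null(depth_sd)) depth_sd <- if (cis) 2 else 1.5
  if (is.null(surface_prob)) surface_prob <- if (cis) 0.0078 else 0.0015
  if (is.null(kink_angle_deg)) kink_angle_deg <- if (cis) 135 else 150
  stopifnot(surface_prob >= 0, surface_prob <= 1,
            surface_persistence > 0, surface_persistence <= 1,
            thickness_sd >= 0, depth_sd >= 0, all(diffusion >= 0),
            dt_ns > 0, n_frames >= 1)
  structure(list(condition = condition, seed = as.integer(seed),
                 composition = composition, box = box,
                 thickness_mean = thickness_mean, thickness_sd = thickness_sd,
                 diffusion = diffusion, tilt = tilt,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 surface_prob = surface_prob,
                 surface_persistence = surface_persistence,
                 surface_band = surface_band,
                 kink_angle_deg = kink_angle_deg,
                 n_frames = as.integer(n_frames), dt_ns = dt_ns),
            class = "synthetic_spec")
}

# Closed-form expectations implied by a synthetic_spec.
ground_truth <- function(spec, cutoff = 5) {
  th <- spec$tilt
  sch <- if (th$type == "isotropic") 0 else
    (3 * cos(th$theta0_deg * pi / 180)^2 - 1) / 2
  sf <- spec$surface_prob +
    (1 - spec$surface_prob) *
    stats::pnorm((cutoff - spec$depth_mean) / spec$depth_sd)
  list(condition = spec$condition, seed = spec$seed,
       thickness = spec$thickness_mean,
       sch = sch,
       diffusion = spec$diffusion,
       msd_slope = 4 * spec$diffusion,
       surface_fraction = sf, surface_cutoff = cutoff,
       kink_angle = spec$kink_angle_deg)
}

# Planar acyl chain from bond-direction angles (2D: u = in-plane, v = z).
# The chain is a zig-zag about a mean axis tilted .geom$tilt from the normal.
# At the double bond the C(p)-C(p+1) bond is laid exactly horizontal (both
# carbons share one z, which keeps the per-atom depth law exact), the next
# bond rises for cis / falls for trans (setting the torsion to exactly 0 /
# 180 since the chain is planar), and the second arm's mean axis is solved
# so the measured carbonyl-kink-terminal angle equals kink_deg exactly.
build_tail_2d <- function(n, p, condition, kink_deg) {
  bond <- 1.53
  half <- 34.25 * pi / 180            # zig-zag half-angle
  M1 <- -pi / 2 + .geom$tilt          # descending mean axis, slight +u
  beta <- function(j, M, phase) M + (-1)^(j + phase) * half
  if (is.null(p)) {                    # saturated: plain zig-zag
    b <- vapply(seq_len(n - 1L), beta, numeric(1), M = M1, phase = 0L)
    uv <- rbind(c(0, 0), cbind(cumsum(bond * cos(b)), cumsum(bond * sin(b))))
    return(uv)
  }
  if (p > n - 3L)
    stop("generator chains need at least three carbons past the double bond")
  # arm 1: carbonyl (j = 1) down to C(p); phase chosen so the bond into C(p)
  # is the shallow one, then the double bond itself runs horizontal
  b1 <- vapply(seq_len(p - 1L), function(j) beta(j, M1, phase = (p - 1L) %% 2L),
               numeric(1))
  uv <- rbind(c(0, 0), cbind(cumsum(bond * cos(b1)), cumsum(bond * sin(b1))))
  uv <- rbind(uv, uv[p, ] + c(bond, 0))           # C(p+1), horizontal bond
  up <- if (condition == "cis") 1 else -1          # cis: C(p+2) on the same
  b_first <- up * 60 * pi / 180                    # side as C(p-1) (above)
  arm2 <- function(M2) {
    b2 <- c(b_first,
            vapply((p + 2L):(n - 1L), function(j) beta(j, M2, phase = p %% 2L),
                   numeric(1)))
    sweep(cbind(cumsum(bond * cos(b2)), cumsum(bond * sin(b2))),
          2, uv[p + 1L, ], "+")
  }
  kink_of <- function(M2) {
    tail2 <- arm2(M2)
    v1 <- uv[1, ] - uv[p, ]
    v2 <- tail2[nrow(tail2), ] - uv[p, ]
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }
  sol <- stats::uniroot(function(M2) kink_of(M2) - kink_deg,
                        lower = -88 * pi / 180, upper = 45 * pi / 180,
                        tol = 1e-12)
  rbind(uv, arm2(sol$root))
}

# Build one lipid in a local frame: phosphate centroid exactly at the origin,
# tails descending toward -z.  Returns coords in template atom order plus the
# local depth of each double-bond carbon pair (both carbons share one z).
build_lipid_local <- function(lspec, condition, kink_deg) {
  tpl <- lipid_template(lspec)
  n <- nrow(tpl$atoms)
  xyz <- matrix(NA_real_, n, 3)
  g <- .geom
  # phosphate bead set, balanced in z so the centroid is exact
  ph <- which(tpl$atoms$role %in% c("P", "OP"))
  k <- 0L
  for (i in ph) {
    k <- k + 1L
    grp <- (k - 1L) %/% 5L   # 5 atoms per phosphate group (P + 4 O)
    j <- (k - 1L) %% 5L
    xyz[i, ] <- if (j == 0L) c(1.6 * grp, 0, 0) else
      c(1.6 * grp + 0.8 * cos(pi / 2 * j), 0.8 * sin(pi / 2 * j),
        0.6 * c(1, -1, 1, -1)[j])
  }
  site_depth <- numeric(0)
  ntail <- length(lspec$tails)
  for (ti in seq_len(ntail)) {
    tl <- lspec$tails[[ti]]
    if (length(tl$unsaturations) > 1L)
      stop("the generator supports at most one unsaturation per tail")
    p <- if (length(tl$unsaturations)) tl$unsaturations[[1]]$position else
      NULL
    uv <- build_tail_2d(tl$n_carbons, p, condition, kink_deg)
    phi <- 2 * pi * (ti - 1) / ntail + pi / 7
    e <- c(cos(phi), sin(phi), 0)
    c1 <- c(0.5 * e[1:2], -g$d_head)                 # carbonyl anchor
    cpos <- matrix(c1, tl$n_carbons, 3, byrow = TRUE) +
      outer(uv[, 1], e) + outer(uv[, 2], c(0, 0, 1))
    if (!is.null(p)) {
      dih <- dihedral_angle(cpos[p - 1L, ], cpos[p, ], cpos[p + 1L, ],
                            cpos[p + 2L, ])
      stopifnot((abs(dih) < 90) == (condition == "cis"))
      site_depth <- c(site_depth, -cpos[p, 3])
    }
    crow <- which(tpl$atoms$role == "C" & tpl$atoms$tail == ti)
    xyz[crow, ] <- cpos[tpl$atoms$pos[crow], ]
  }
  # hydrogens placed later (tilt law); park them on their parent carbon
  hrow <- which(tpl$atoms$role == "H")
  xyz[hrow, ] <- xyz[tpl$atoms$parent[hrow], ]
  list(xyz = xyz, site_depth = site_depth)
}

rotate_z <- function(xyz, alpha) {
  ca <- cos(alpha); sa <- sin(alpha)
  cbind(ca * xyz[, 1] - sa * xyz[, 2], sa * xyz[, 1] + ca * xyz[, 2],
        xyz[, 3])
}

#' Build a synthetic bilayer structure
#'
#' Places one lipid per jittered lattice site on each leaflet, phosphate
#' planes at +/- thickness/2, double-bond dihedrals set to the spec's
#' condition.  Deterministic for a given seed.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return A one-frame \code{\link{mem_trajectory}} with a
#'   \code{$ground_truth} list (closed-form expectations, leaflet labels,
#'   per-site built depths).
#' @export
build_membrane <- function(spec) {
  set.seed(spec$seed)
  comp <- spec$composition
  nlip <- sum(comp$counts)
  if (spec$box[1] * spec$box[2] / nlip < 55)
    stop("overfilled box: ", round(spec$box[1] * spec$box[2] / nlip, 1),
         " A^2 per lipid < 55")
  inst <- instantiate_composition(comp)
  topo <- annotate_topology(inst$raw, comp$specs)
  natoms <- nrow(topo$atoms)
  xyz <- matrix(NA_real_, natoms, 3)

  # one local template per (resname); kink set by condition
  local <- lapply(comp$specs, build_lipid_local,
                  condition = spec$condition, kink = spec$kink_angle_deg)

  ncell <- ceiling(sqrt(nlip))
  sx <- spec$box[1] / ncell; sy <- spec$box[2] / ncell
  zh <- spec$thickness_mean / 2
  rids <- residue_names(topo)
  site_depth <- numeric(0)
  for (lf in c("upper", "lower")) {
    sel_r <- which(inst$leaflet_by_resid == lf)
    cells <- sample(ncell^2, length(sel_r))
    for (k in seq_along(sel_r)) {
      rid <- sel_r[k]
      rn <- rids$resname[rid]
      loc <- local[[rn]]$xyz
      loc <- rotate_z(loc, stats::runif(1, 0, 2 * pi))
      if (lf == "lower") loc[, 3] <- -loc[, 3]
      cx <- ((cells[k] - 1) %% ncell + 0.5) * sx +
        stats::runif(1, -0.1, 0.1) * sx
      cy <- ((cells[k] - 1) %/% ncell + 0.5) * sy +
        stats::runif(1, -0.1, 0.1) * sy
      rows <- which(topo$atoms$resid == rid)
      xyz[rows, ] <- sweep(loc, 2, c(cx, cy, if (lf == "upper") zh else -zh),
                           "+")
      site_depth <- c(site_depth,
                      rep(local[[rn]]$site_depth,
                          1))  # one entry per site of this residue
    }
  }
  # hydrogens by tilt law (frame-1 draw)
  xyz <- place_hydrogens(xyz, topo, spec$tilt, frame = 1L)
  topo$atoms$leaflet <- inst$leaflet_by_resid[topo$atoms$resid]
  gt <- ground_truth(spec)
  gt$leaflets <- stats::setNames(inst$leaflet_by_resid, rids$resid)
  gt$site_depth_built <- site_depth
  traj <- mem_trajectory(topo, array(xyz, c(natoms, 3, 1)),
                         matrix(spec$box, 1), times = 0,
                         replicate_id = paste0("seed", spec$seed),
                         condition = spec$condition)
  traj$ground_truth <- gt
  traj
}

# Resample every tail hydrogen around its parent carbon per the tilt law.
place_hydrogens <- function(xyz, topo, tilt, frame) {
  hrow <- which(topo$atoms$role == "H")
  nh <- length(hrow)
  phi <- stats::runif(nh, 0, 2 * pi)
  if (tilt$type == "isotropic") {
    cost <- stats::runif(nh, -1, 1)
  } else {
    th0 <- tilt$theta0_deg
    th <- if (length(th0) > 1L) th0[min(frame, length(th0))] else th0
    cost <- rep(cos(th * pi / 180), nh)
  }
  sint <- sqrt(pmax(0, 1 - cost^2))
  u <- cbind(sint * cos(phi), sint * sin(phi), cost)
  xyz[hrow, ] <- xyz[topo$atoms$parent[hrow], ] + .geom$ch * u
  xyz
}

#' Simulate a synthetic bilayer trajectory
#'
#' Starting from \code{\link{build_membrane}}, every frame applies (i) a
#' lateral Brownian step per residue (rigid in-plane translation with the
#' residue type's D), wrapped into the box by residue, (ii) a per-frame
#' thickness fluctuation moving each leaflet rigidly, (iii) a double-bond
#' depth resampled from the bulk/surface two-state Markov mixture (rigid z
#' translation of the sub-chain from the proximal double-bond carbon to the
#' terminus), and (iv) C-H orientations resampled from the tilt law.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return A \code{\link{mem_trajectory}} with \code{$ground_truth}.
#' @export
simulate_trajectory <- function(spec) {
  bm <- build_membrane(spec)   # seeds the stream
  topo <- bm$topology
  a <- topo$atoms
  nf <- spec$n_frames
  natoms <- nrow(a)
  built <- bm$coords[, , 1]
  coords <- array(NA_real_, c(natoms, 3, nf))

  rids <- residue_names(topo)
  nres <- nrow(rids)
  Dres <- spec$diffusion[rids$resname]
  leaf <- bm$ground_truth$leaflets
  sgn <- ifelse(leaf == "upper", 1, -1)

  # cumulative Brownian displacement per residue
  sd_step <- sqrt(2 * Dres * spec$dt_ns)
  dispx <- cbind(0, matrix(stats::rnorm(nres * (nf - 1), 0, sd_step),
                           nres, max(nf - 1, 0)))
  dispy <- cbind(0, matrix(stats::rnorm(nres * (nf - 1), 0, sd_step),
                           nres, max(nf - 1, 0)))
  if (nf > 1L) {
    dispx <- t(apply(dispx, 1, cumsum))
    dispy <- t(apply(dispy, 1, cumsum))
  }

  # thickness fluctuation per frame (frame 1 kept at the built thickness so
  # build_membrane output is a prefix of the trajectory)
  dth <- c(0, stats::rnorm(nf - 1, 0, spec$thickness_sd))

  # two-state depth Markov chain per site
  sites <- topo$sites
  nsites <- nrow(sites)
  ps <- spec$surface_prob; rho <- spec$surface_persistence
  state <- matrix(FALSE, nsites, nf)   # TRUE = surface excursion
  if (nsites) {
    state[, 1] <- stats::runif(nsites) < ps
    if (nf > 1L) for (f in 2:nf) {
      r <- stats::runif(nsites)
      state[, f] <- ifelse(state[, f - 1L], r >= rho * (1 - ps), r < rho * ps)
    }
  }
  depth <- matrix(stats::rnorm(nsites * nf, spec$depth_mean, spec$depth_sd),
                  nsites, nf)
  nsurf <- sum(state)
  depth[state] <- stats::runif(nsurf, spec$surface_band[1],
                               spec$surface_band[2])

  # atoms moved by each site's depth offset: chain carbons from one before
  # the proximal double-bond carbon to the terminus, plus their hydrogens
  # (including C(p-1) keeps the site torsion exactly invariant under the
  # shift, so per-frame classification never drifts)
  shift_rows <- vector("list", nsites)
  site_sgn <- numeric(nsites)
  for (s in seq_len(nsites)) {
    rsel <- a$resid == sites$resid[s] & !is.na(a$tail) &
      a$tail == sites$tail[s] & a$pos >= sites$position[s] - 1L
    shift_rows[[s]] <- which(rsel)
    site_sgn[s] <- sgn[as.character(sites$resid[s])]
  }
  d_built <- bm$ground_truth$site_depth_built

  res_of_atom <- match(a$resid, rids$resid)
  for (f in seq_len(nf)) {
    xyz <- built
    # rigid per-residue xy translation, wrapped by residue
    dx <- dispx[res_of_atom, f]; dy <- dispy[res_of_atom, f]
    xyz[, 1] <- xyz[, 1] + dx
    xyz[, 2] <- xyz[, 2] + dy
    refx <- dispx[, f] + spec$box[1] / 2   # residue reference for wrapping
    refy <- dispy[, f] + spec$box[2] / 2
    kx <- floor(refx / spec$box[1]); ky <- floor(refy / spec$box[2])
    xyz[, 1] <- xyz[, 1] - spec$box[1] * kx[res_of_atom]
    xyz[, 2] <- xyz[, 2] - spec$box[2] * ky[res_of_atom]
    # leaflet breathing
    xyz[, 3] <- xyz[, 3] + sgn[res_of_atom] * dth[f] / 2
    # double-bond depth
    for (s in seq_len(nsites)) {
      rows <- shift_rows[[s]]
      xyz[rows, 3] <- xyz[rows, 3] +
        site_sgn[s] * (d_built[s] - depth[s, f])
    }
    xyz <- place_hydrogens(xyz, topo, spec$tilt, frame = f)
    coords[, , f] <- xyz
  }
  traj <- mem_trajectory(topo, coords,
                         matrix(spec$box, nf, 3, byrow = TRUE),
                         times = (seq_len(nf) - 1) * spec$dt_ns,
                         replicate_id = paste0("seed", spec$seed),
                         condition = spec$condition)
  traj$ground_truth <- bm$ground_truth
  traj
}

#' Simulate plain 2D Brownian tracks
#'
#' Minimal lateral-diffusion generator used for parameter-recovery testing of
#' the MSD/diffusion estimators: \code{n} independent walkers with diffusion
#' coefficient \code{D}, wrapped into a periodic box.
#'
#' @param n number of walkers.
#' @param D diffusion coefficient, A^2/ns.
#' @param n_frames,dt_ns frames and spacing.
#' @param box c(Lx, Ly) in A.
#' @param seed RNG seed.
#' @param wrap wrap tracks into the box (default TRUE).
#' @return array \code{[n, 2, n_frames]} of positions.
#' @export
simulate_brownian_tracks <- function(n, D, n_frames, dt_ns = 0.1,
                                     box = c(60, 60), seed, wrap = TRUE) {
  set.seed(seed)
  sd_step <- sqrt(2 * D * dt_ns)
  x <- apply(cbind(stats::runif(n, 0, box[1]),
                   matrix(stats::rnorm(n * (n_frames - 1), 0, sd_step), n)),
             1, cumsum)
  y <- apply(cbind(stats::runif(n, 0, box[2]),
                   matrix(stats::rnorm(n * (n_frames - 1), 0, sd_step), n)),
             1, cumsum)
  out <- array(NA_real_, c(n, 2, n_frames))
  out[, 1, ] <- t(x); out[, 2, ] <- t(y)
  if (wrap) for (f in seq_len(n_frames))
    out[, , f] <- wrap_xy(out[, , f, drop = TRUE], box)
  out
}

# Replicate seeds are spread across the seed space with an LCG step rather
# than taken consecutively: Mersenne-Twister streams started from adjacent
# seeds are not independent, which would correlate replicates and invalidate
# the standard errors.
derive_seed <- function(base, i) {
  as.integer((as.double(base) + (i - 1) * 1013904223) %% 2147483629)
}

#' Paired cis/trans replicate set
#'
#' Seeds \code{n_replicates} trajectories per condition from the two specs'
#' base seeds (replicate seeds are derived by spreading the base seed across
#' the seed space); all derived seeds must be unique.
#'
#' @param spec_cis,spec_trans \code{\link{synthetic_spec}} objects for the two
#'   conditions (their \code{seed} fields act as per-condition base seeds).
#' @param n_replicates replicates per condition.
#' @param simulate if TRUE (default), trajectories are generated now;
#'   otherwise only the seeded specs are returned and \code{simulate_trajectory}
#'   can be applied lazily (useful to bound memory).
#' @return Object of class \code{"condition_set"}: list with \code{specs},
#'   \code{condition}, \code{replicate} and (if simulated)
#'   \code{trajectories}.
#' @export
paired_condition_set <- function(spec_cis, spec_trans, n_replicates = 5,
                                 simulate = TRUE) {
  specs <- list(); cond <- character(0); repl <- integer(0)
  for (i in seq_len(n_replicates)) {
    s <- spec_cis; s$seed <- derive_seed(spec_cis$seed, i)
    specs[[length(specs) + 1L]] <- s; cond <- c(cond, "cis")
    repl <- c(repl, i)
    s <- spec_trans; s$seed <- derive_seed(spec_trans$seed, i)
    specs[[length(specs) + 1L]] <- s; cond <- c(cond, "trans")
    repl <- c(repl, i)
  }
  seeds <- vapply(specs, `[[`, integer(1), "seed")
  if (anyDuplicated(seeds))
    stop("duplicate seeds across replicates: ",
         paste(seeds[duplicated(seeds)], collapse = ", "),
         "; give the two specs different base seeds")
  out <- list(specs = specs, condition = cond, replicate = repl,
              seeds = seeds)
  if (simulate) out$trajectories <- lapply(specs, simulate_trajectory)
  class(out) <- "condition_set"
  out
}

#' @export
print.condition_set <- function(x, ...) {
  cat(sprintf("<condition_set> %d trajectories (%d cis, %d trans)%s\n",
              length(x$specs), sum(x$condition == "cis"),
              sum(x$condition == "trans"),
              if (is.null(x$trajectories)) " [specs only]" else ""))
  invisible(x)
}
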