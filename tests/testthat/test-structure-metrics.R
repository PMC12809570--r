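# Thickness, volume, area per lipid, kink angle, depth distribution and
# surface fraction.

test_that("thickness and volume follow their definitions and invariances", {
  bm <- build_membrane(small_spec("cis", seed = 21, n_frames = 1))
  lf <- assign_leaflets(bm$coords[, , 1], bm$topology)
  th <- memiso:::thickness_frame(bm$coords[, , 1], bm$topology, lf)
  expect_equal(th, 39)
  # rigid z translation leaves thickness unchanged
  sh <- bm
  sh$coords[, 3, ] <- sh$coords[, 3, ] + 7
  expect_equal(mean(thickness(sh)), 39)
  # volume = Lx Ly thickness; doubling Lx doubles it
  v <- membrane_volume(bm)
  expect_equal(v$values, 30 * 30 * 39)
  wide <- bm
  wide$box[, 1] <- wide$box[, 1] * 2
  expect_equal(mean(membrane_volume(wide)), 2 * mean(v$values))
  # constant box: time-mean volume = area x mean thickness
  tr <- simulate_trajectory(small_spec("cis", seed = 21, n_frames = 8))
  expect_equal(mean(membrane_volume(tr)),
               30 * 30 * mean(thickness(tr)))
})

test_that("one lipid alone in a leaflet claims the whole plane", {
  comp <- membrane_composition(lipid_definitions(), c(PYPE = 1L))
  sp <- synthetic_spec("cis", seed = 5, composition = comp,
                       box = c(12, 12, 60), n_frames = 1)
  bm <- build_membrane(sp)
  ap <- area_per_lipid(bm, grid_max_spacing = 1)
  expect_equal(nrow(ap), 2L)  # one row per plane
  expect_equal(ap$area_per_lipid, c(144, 144))
  expect_equal(attr(ap, "conservation_error"), 0)
})

test_that("two identical lipids split the plane symmetrically", {
  # hand-built frame: two PYPE in the upper leaflet at (1/4, 1/2) and
  # (3/4, 1/2) of the box, mirrored pair below
  raw <- one_lipid_raw()
  raw4 <- do.call(rbind, lapply(1:4, function(i) {
    r <- raw; r$resid <- i; r
  }))
  topo <- annotate_topology(raw4)
  tpl <- memiso:::lipid_template(lipid_definitions()$PYPE)
  n1 <- nrow(tpl$atoms)
  box <- c(40, 40, 80)
  base <- build_membrane(synthetic_spec("cis", seed = 1,
    composition = membrane_composition(lipid_definitions(), c(PYPE = 1L)),
    box = c(12, 12, 60), n_frames = 1))
  loc <- base$coords[seq_len(n1), , 1]
  ph <- (base$topology$atoms$role %in% c("P", "OP"))[seq_len(n1)]
  loc <- sweep(loc, 2, colMeans(loc[ph, , drop = FALSE]))
  place <- function(cx, cy, zsign) {
    l <- loc
    if (zsign < 0) l[, 3] <- -l[, 3]
    sweep(l, 2, c(cx, cy, zsign * 19), "+")
  }
  xyz <- rbind(place(10, 20, 1), place(30, 20, 1),
               place(10, 20, -1), place(30, 20, -1))
  tr <- mem_trajectory(topo, array(xyz, c(nrow(xyz), 3, 1)),
                       matrix(box, 1), 0)
  ap <- area_per_lipid(tr, grid_max_spacing = 1)
  # each lipid gets half the plane (two per leaflet, symmetric)
  expect_equal(ap$area_per_lipid, rep(800, nrow(ap)), tolerance = 0.05)
  expect_equal(sum(ap$total_area[ap$leaflet == "upper"]), 1600)
})

test_that("grid assignment equals the brute-force all-pairs oracle", {
  # random 20-lipid leaflets in a 30 x 30 box, point lipids
  for (seed in 1:4) {
    set.seed(seed)
    box <- c(30, 30, 60)
    n <- 20
    xyz <- cbind(runif(n, 0, 30), runif(n, 0, 30), rnorm(n, 15, 1))
    resid <- seq_len(n)
    got <- apl_assign(xyz, box, gz = 18, candidates = seq_len(n),
                      resid = resid, grid_max_spacing = 1)
    want <- apl_brute_force(xyz, box, gz = 18, candidates = seq_len(n),
                            resid = resid, spacing = 1)
    expect_identical(unclass(got)[, ], want)
    # exact conservation: every cell assigned exactly once
    expect_equal(sum(table(got)), 30 * 30)
    # 2D mode agrees with its oracle too
    got2 <- apl_assign(xyz, box, gz = 18, candidates = seq_len(n),
                       resid = resid, grid_max_spacing = 1, use_z = FALSE)
    want2 <- apl_brute_force(xyz, box, gz = 18, candidates = seq_len(n),
                             resid = resid, spacing = 1, use_z = FALSE)
    expect_identical(unclass(got2)[, ], want2)
  }
})

test_that("area accounting conserves the box area on a full membrane", {
  bm <- build_membrane(small_spec("cis", seed = 23, n_frames = 1))
  ap <- area_per_lipid(bm)
  expect_equal(attr(ap, "conservation_error"), 0)
  for (side in c("upper", "lower"))
    expect_equal(sum(ap$total_area[ap$leaflet == side]), 30 * 30)
})

test_that("kink angle recovers the construction angle exactly on build", {
  for (cond in c("cis", "trans")) {
    kd <- if (cond == "cis") 131 else 149
    bm <- build_membrane(small_spec(cond, seed = 24, n_frames = 1,
                                    kink_angle_deg = kd))
    ka <- kink_angles(bm)
    expect_equal(ka$angle_deg, rep(kd, nrow(ka)), tolerance = 1e-9)
  }
  # collinear carbonyl-kink-terminal measures 180, right angle measures 90
  bm <- build_membrane(small_spec("cis", seed = 24, n_frames = 1))
  s <- bm$topology$sites[1, ]
  xyz <- bm$coords[, , 1]
  xyz[s$carbonyl, ] <- xyz[s$a2, ] + c(0, 0, 5)
  xyz[s$terminal, ] <- xyz[s$a2, ] - c(0, 0, 7)
  tr <- bm; tr$coords[, , 1] <- xyz
  expect_equal(kink_angles(tr)$angle_deg[1], 180)
  xyz[s$terminal, ] <- xyz[s$a2, ] + c(3, 0, 0)
  tr$coords[, , 1] <- xyz
  expect_equal(kink_angles(tr)$angle_deg[1], 90)
  # saturated-only systems have no kink
  comp <- membrane_composition(lipid_definitions(), c(PYPE = 1L))
  one <- build_membrane(synthetic_spec("cis", seed = 1, composition = comp,
                                       box = c(12, 12, 60), n_frames = 1))
  no_sites <- one$topology
  no_sites$sites <- no_sites$sites[0, ]
  one$topology <- no_sites
  expect_error(kink_angles(one), "no unsaturation sites")
})

test_that("depth distribution matches construction and a Gaussian law", {
  bm <- build_membrane(small_spec("cis", seed = 25, n_frames = 1))
  # phosphate class against its own plane is centred at 0
  dp <- double_bond_depths(bm, "phosphate")
  expect_equal(mean(dp), 0, tolerance = 1e-9)
  # all double-bond carbons moved exactly to the plane -> delta at 0
  lf <- assign_leaflets(bm$coords[, , 1], bm$topology)
  a <- bm$topology$atoms
  pP <- which(a$role == "P")
  up_plane <- mean(bm$coords[pP[lf[as.character(a$resid[pP])] == "upper"],
                             3, 1])
  lo_plane <- mean(bm$coords[pP[lf[as.character(a$resid[pP])] == "lower"],
                             3, 1])
  dbc <- which(a$db & a$role == "C")
  z <- ifelse(lf[as.character(a$resid[dbc])] == "upper", up_plane, lo_plane)
  tr <- bm; tr$coords[dbc, 3, 1] <- z
  zd <- double_bond_zdist(tr, breaks = seq(-10, 30, 0.5))
  expect_equal(sum(zd$density[, "double_bond"]), 1)
  expect_equal(sum(zd$density[zd$mids > -0.5 & zd$mids < 0.5,
                              "double_bond"]), 1)
  # histogram of a Gaussian depth law matches the density at n = 1e4
  set.seed(7)
  d <- rnorm(1e4, 9, 3)
  i <- findInterval(d, seq(-10, 30, 0.5), all.inside = TRUE)
  emp <- tabulate(i, 80) / 1e4
  want <- diff(pnorm(seq(-10, 30, 0.5), 9, 3))
  expect_lt(max(abs(emp - want)), 4 * sqrt(max(want) / 1e4))
  # translation invariance of depths
  sh <- bm; sh$coords[, 3, ] <- sh$coords[, 3, ] + 13
  expect_equal(double_bond_depths(sh), double_bond_depths(bm),
               tolerance = 1e-9)
})

test_that("surface fraction matches the normal closed form and is monotone", {
  set.seed(31)
  d <- rnorm(1e4, 9, 3)
  want <- pnorm((5 - 9) / 3)               # Phi(-4/3) ~ 0.0912
  se <- sqrt(want * (1 - want) / 1e4)
  expect_lt(abs(surface_fraction(d, 5) - want), 3 * se)
  # boundary inclusion and the fully-buried case
  expect_equal(surface_fraction(rep(0, 10), 5), 1)
  expect_equal(surface_fraction(rep(20, 10), 5), 0)
  expect_error(surface_fraction(numeric(0)), "zero depth samples")
  # monotone non-decreasing in the cutoff
  fr <- vapply(seq(0, 20, by = 1), function(ct) surface_fraction(d, ct),
               numeric(1))
  expect_true(all(diff(fr) >= 0))
  # water side counts toward the surface under the default rule
  expect_equal(surface_fraction(c(-8, 2, 30), 5), 2 / 3)
  expect_equal(surface_fraction(c(-8, 2, 30), 5, side = "absolute"), 1 / 3)
})

test_that("generator excursion probability is recovered from trajectories", {
  sp <- small_spec("cis", seed = 26, n_frames = 150,
                   depth_mean = 15, depth_sd = 1,   # bulk fully buried
                   surface_prob = 0.03)
  tr <- simulate_trajectory(sp)
  d <- double_bond_depths(tr)
  frac <- surface_fraction(d, 5)
  n <- length(d)
  se <- sqrt(0.03 * 0.97 / n)
  # correlated frames (persistence) inflate the error over iid binomial
  expect_lt(abs(frac - tr$ground_truth$surface_fraction), 6 * se)
})
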