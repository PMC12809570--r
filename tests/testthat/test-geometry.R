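# Torsion measurement, cis/trans classification, the 180-degree
# isomerization operator, leaflet assignment and periodic unwrapping.

# planar zig-zag quads for the trivial torsion geometries
quad_cis <- list(p1 = c(0, 1, 0), p2 = c(1, 0, 0), p3 = c(2, 0, 0),
                 p4 = c(3, 1, 0))
quad_trans <- list(p1 = c(0, 1, 0), p2 = c(1, 0, 0), p3 = c(2, 0, 0),
                   p4 = c(3, -1, 0))

test_that("dihedral_angle gives signed torsions and flags degeneracy", {
  expect_equal(do.call(dihedral_angle, quad_cis), 0)
  expect_equal(abs(do.call(dihedral_angle, quad_trans)), 180)
  # rotate p4 by +90 degrees from the cis position about the p2-p3 (x) axis:
  # oracle by explicit rotation-matrix construction
  th <- 90 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  p4r <- drop(R %*% (quad_cis$p4 - quad_cis$p3)) + quad_cis$p3
  got <- dihedral_angle(quad_cis$p1, quad_cis$p2, quad_cis$p3, p4r)
  expect_equal(abs(got), 90, tolerance = 1e-10)
  # and sweeping a range of rotations recovers each construction angle
  for (deg in c(-150, -45, 30, 120)) {
    th <- deg * pi / 180
    R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
    p4r <- drop(R %*% (quad_cis$p4 - quad_cis$p3)) + quad_cis$p3
    expect_equal(abs(dihedral_angle(quad_cis$p1, quad_cis$p2, quad_cis$p3,
                                    p4r)),
                 abs(deg), tolerance = 1e-10)
  }
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "degenerate")
})

test_that("classification threshold is 90 degrees with trans at the boundary", {
  mk <- function(deg) {
    th <- deg * pi / 180
    R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
    xyz <- rbind(quad_cis$p1, quad_cis$p2, quad_cis$p3,
                 drop(R %*% (quad_cis$p4 - quad_cis$p3)) + quad_cis$p3)
    sites <- data.frame(resid = 1L, resname = "X", tail = 1L, position = 2L,
                        a1 = 1L, a2 = 2L, a3 = 3L, a4 = 4L)
    classify_sites(xyz, sites)
  }
  expect_equal(mk(3), "cis")
  expect_equal(mk(178), "trans")
  expect_equal(mk(90), "trans")   # boundary rule
  expect_equal(mk(-90), "trans")
  expect_equal(mk(-89.9), "cis")
})

test_that("isomerize_site is an involution and an isometry on the distal set", {
  bm <- build_membrane(small_spec("cis", seed = 11, n_frames = 1))
  xyz <- bm$coords[, , 1]
  topo <- bm$topology
  site <- topo$sites[3, ]
  distal <- memiso:::distal_set(site, topo$bonds, nrow(xyz))
  out <- isomerize_site(xyz, site, topo$bonds)
  # flips the classification
  expect_equal(classify_sites(xyz, site), "cis")
  expect_equal(classify_sites(out, site), "trans")
  # isometry on the distal set (rigid rotation): all pairwise distances kept
  i <- distal[seq(1, length(distal), by = 3)]
  expect_equal(as.vector(dist(out[i, ])), as.vector(dist(xyz[i, ])),
               tolerance = 1e-9)
  # cross-set distances change
  prox <- setdiff(which(topo$atoms$resid == site$resid), distal)
  expect_gt(max(abs(out[distal, ] - xyz[distal, ])), 0.1)
  expect_equal(out[prox, ], xyz[prox, ])
  # involution to 1e-6 A
  back <- isomerize_site(out, site, topo$bonds)
  expect_lt(max(abs(back - xyz)), 1e-6)
  # atoms of other residues untouched
  other <- which(topo$atoms$resid != site$resid)
  expect_equal(out[other, ], xyz[other, ])
})

test_that("isomerize_site agrees with an explicit rotation-matrix oracle", {
  bm <- build_membrane(small_spec("cis", seed = 12, n_frames = 1))
  xyz <- bm$coords[, , 1]
  topo <- bm$topology
  site <- topo$sites[1, ]
  distal <- memiso:::distal_set(site, topo$bonds, nrow(xyz))
  u <- xyz[site$a3, ] - xyz[site$a2, ]; u <- u / sqrt(sum(u^2))
  # Rodrigues at 180 degrees: R = 2 u u^T - I
  R <- 2 * outer(u, u) - diag(3)
  expected <- xyz
  expected[distal, ] <- sweep(
    sweep(xyz[distal, , drop = FALSE], 2, xyz[site$a2, ]) %*% t(R),
    2, xyz[site$a2, ], "+")
  got <- isomerize_site(xyz, site, topo$bonds)
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("isomerize_all flips every cis site and is idempotent toward a target", {
  bm <- build_membrane(small_spec("cis", seed = 13, n_frames = 1))
  xyz <- bm$coords[, , 1]
  topo <- bm$topology
  res <- isomerize_all(xyz, topo$sites, topo$bonds, target = "trans")
  expect_true(all(classify_sites(res$xyz, topo$sites) == "trans"))
  expect_true(all(res$report$rotated))
  # already-trans input with target trans: zero rotations
  res2 <- isomerize_all(res$xyz, topo$sites, topo$bonds, target = "trans")
  expect_false(any(res2$report$rotated))
  expect_equal(res2$xyz, res$xyz)
  # mixed membrane: only cis sites flipped
  mixed <- isomerize_site(res$xyz, topo$sites[2, ], topo$bonds)
  res3 <- isomerize_all(mixed, topo$sites, topo$bonds, target = "trans")
  expect_equal(sum(res3$report$rotated), 1L)
  expect_equal(which(res3$report$rotated), 2L)
})

test_that("leaflet assignment matches construction and is translation invariant", {
  bm <- build_membrane(small_spec("cis", seed = 14, n_frames = 1))
  xyz <- bm$coords[, , 1]
  lf <- assign_leaflets(xyz, bm$topology)
  expect_equal(unname(table(lf)[c("lower", "upper")]),
               structure(c(9L, 9L), class = "table"),
               ignore_attr = TRUE)
  # matches the generator ground truth
  expect_equal(lf[names(bm$ground_truth$leaflets)],
               bm$ground_truth$leaflets, ignore_attr = TRUE)
  # rigid translation leaves the assignment unchanged
  sh <- sweep(xyz, 2, c(11, -4, 7), "+")
  expect_equal(assign_leaflets(sh, bm$topology), lf, ignore_attr = TRUE)
})

test_that("unwrap_xy inverts wrapping of Brownian tracks", {
  set.seed(99)
  box <- c(25, 30)
  raw <- simulate_brownian_tracks(20, D = 2, n_frames = 200, dt_ns = 1,
                                  box = box, seed = 99, wrap = FALSE)
  wrapped <- raw
  for (f in 1:200) wrapped[, , f] <- wrap_xy(raw[, , f], box)
  un <- unwrap_xy(wrapped, box)
  # equal to the pre-wrap track up to a constant per-particle offset that is
  # a multiple of the box
  off <- un[, , 1] - raw[, , 1]
  expect_lt(max(abs(off %% box[1] %% box[2])), 1e-9)
  rel_un <- sweep(un, c(1, 2), un[, , 1])
  rel_raw <- sweep(raw, c(1, 2), raw[, , 1])
  expect_equal(rel_un, rel_raw, tolerance = 1e-9)
  # stationary particle unchanged
  still <- array(5, c(1, 2, 10))
  expect_equal(unwrap_xy(still, box), still)
  # single +x crossing stays continuous with net displacement > Lx/2
  tr <- array(0, c(1, 2, 4))
  tr[1, 1, ] <- c(20, 24, 3, 7)   # crosses the 25 A boundary once
  tr[1, 2, ] <- 1
  un1 <- unwrap_xy(tr, box)
  expect_equal(un1[1, 1, ], c(20, 24, 28, 32))
})
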