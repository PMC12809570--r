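# MSD and the endpoint D = MSD/(2 n t) estimator: closed forms, parameter
# recovery on simulated Brownian tracks, drift correction.

test_that("MSD obeys its closed forms", {
  # static system: MSD identically zero
  still <- array(3, c(5, 2, 10))
  cur <- msd(still, times = 0:9)
  expect_equal(cur$msd, rep(0, 10))
  expect_equal(cur$msd[cur$lag_ns == 0], 0)
  # ballistic track r(t) = (v t, 0): MSD = v^2 t^2 exactly
  v <- 1.7
  t <- seq(0, 9)
  tr <- array(0, c(1, 2, 10))
  tr[1, 1, ] <- v * t
  cur <- msd(tr, times = t)
  expect_equal(cur$msd, v^2 * t^2)
  expect_error(msd(array(0, c(2, 2, 1)), times = 0), "at least 2 frames")
})

test_that("endpoint estimator inverts MSD = 4 D T exactly", {
  # analytic MSD with D = 1 A^2/ns over T = 200 ns, n = 2
  lag <- seq(0, 200, by = 10)
  curves <- structure(data.frame(lag_ns = lag, msd = 4 * 1 * lag,
                                 type = "all", chunk = 1, replicate = "r1",
                                 n_res = 1),
                      class = c("msd_curves", "data.frame"))
  est <- diffusion_coefficient(curves, n_dims = 2)
  expect_equal(est$D_A2ns, 1)
  expect_equal(est$D_cm2s, 1e-7)
  # endpoint and fit-through-origin agree exactly on a linear MSD
  est_fit <- diffusion_coefficient(curves, n_dims = 2, mode = "fit")
  expect_equal(est_fit$D_A2ns, est$D_A2ns, tolerance = 1e-12)
  # five identical chunks give SE = 0
  five <- do.call(rbind, lapply(1:5, function(k) {
    cc <- curves; cc$chunk <- k; cc
  }))
  est5 <- diffusion_coefficient(structure(five,
                                          class = c("msd_curves",
                                                    "data.frame")))
  expect_equal(est5$se_A2ns, 0)
  expect_equal(est5$n_samples, 5L)
})

test_that("Brownian generator recovers D across the studied range", {
  # 5 replicates x 5 chunks = 25 endpoint samples per D
  for (D in c(0.1, 0.5, 0.65, 1.0)) {
    curves <- do.call(rbind, lapply(1:5, function(r) {
      tracks <- simulate_brownian_tracks(100, D, n_frames = 500, dt_ns = 0.1,
                                         box = c(60, 60),
                                         seed = 1000 * D + r)
      un <- unwrap_xy(tracks, c(60, 60))
      cc <- msd(un, times = seq(0, by = 0.1, length.out = 500), n_chunks = 5)
      cc$replicate <- paste0("r", r)
      cc
    }))
    est <- diffusion_coefficient(curves)
    expect_equal(est$n_samples, 25L)
    expect_lt(abs(est$D_A2ns - D), 2 * est$se_A2ns + 1e-12)
    # MSD slope close to 4D as well (fit mode)
    est_fit <- diffusion_coefficient(curves, mode = "fit")
    expect_lt(abs(est_fit$D_A2ns - D) / D, 0.10)
  }
})

test_that("drift correction cancels collective leaflet motion", {
  set.seed(77)
  n <- 30
  leaflets <- stats::setNames(rep(c("upper", "lower"), each = n / 2),
                              as.character(seq_len(n)))
  # pure uniform translation of one leaflet -> zero MSD after correction
  tr <- array(0, c(n, 2, 20))
  rownames(tr) <- names(leaflets)
  drift <- seq(0, 19) * 0.5
  for (f in 1:20) tr[1:(n / 2), 1, f] <- drift[f]
  cor <- drift_correct(tr, leaflets)
  cur <- msd(cor, times = 0:19)
  expect_equal(max(cur$msd), 0, tolerance = 1e-18)
  # without drift, tracks are unchanged up to a mean-zero per-frame offset
  tracks <- simulate_brownian_tracks(n, 0.5, n_frames = 50, dt_ns = 0.1,
                                     box = c(500, 500), seed = 5,
                                     wrap = FALSE)
  rownames(tracks) <- names(leaflets)
  cor2 <- drift_correct(tracks, leaflets)
  for (f in c(1, 25, 50))
    for (side in c("upper", "lower")) {
      i <- which(leaflets == side)
      expect_equal(colMeans(cor2[i, , f]), c(0, 0), tolerance = 1e-9)
    }
  # drifting Brownian tracks: recovered D equals the no-drift value
  drifted <- tracks
  for (f in 1:50) drifted[, 1, f] <- drifted[, 1, f] + 0.8 * (f - 1)
  t50 <- seq(0, by = 0.1, length.out = 50)
  d_plain <- diffusion_coefficient(msd(tracks, times = t50, n_chunks = 2))
  d_drift <- diffusion_coefficient(
    msd(drift_correct(drifted, leaflets), times = t50, n_chunks = 2))
  d_ref <- diffusion_coefficient(
    msd(drift_correct(tracks, leaflets), times = t50, n_chunks = 2))
  expect_equal(d_drift$D_A2ns, d_ref$D_A2ns, tolerance = 1e-9)
  expect_lt(abs(d_drift$D_A2ns - d_plain$D_A2ns),
            2 * (d_plain$se_A2ns + d_drift$se_A2ns) + 0.05)
})

test_that("full-trajectory diffusion recovers the generator's D", {
  # one synthetic replicate, uniform D across types for a tight check
  Dset <- c(PYPE = 0.6, POPE = 0.6, YOPE = 0.6, PYPG = 0.6, POPG = 0.6,
            PVCL2 = 0.6)
  tr <- simulate_trajectory(small_spec("cis", seed = 55, n_frames = 400,
                                       diffusion = Dset))
  cur <- msd(tr, n_chunks = 4)
  est <- diffusion_coefficient(cur)
  pooled <- stats::weighted.mean(est$D_A2ns, est$n_samples)
  # 18 residues only; generous but honest bound from the chunk spread
  se <- sqrt(sum(est$se_A2ns^2 * est$n_samples^2)) / sum(est$n_samples)
  expect_lt(abs(pooled - 0.6), 3 * se + 0.05)
})
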