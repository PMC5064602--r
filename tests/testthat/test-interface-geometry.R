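test_that("groupCOM matches symmetry, identity and the brute-force oracle", {
  m <- matrix(c(0, 0, 10, 0, 0, 30), 2, 3, byrow = TRUE)
  expect_equal(groupCOM(m, 1:2, c(1, 1))[3], 20)
  expect_equal(groupCOM(m, 2L, c(1, 5)), c(0, 0, 30))
  expect_error(groupCOM(m, integer(), c(1, 1)), "empty")

  # 50 random atoms, random masses, group compact (< box/2): equals
  # brute-force sum(m r) / sum(m) with no imaging
  set.seed(101)
  for (rep in 1:5) {
    r <- matrix(runif(150, 20, 35), 50, 3)
    w <- runif(50, 1, 40)
    brute <- colSums(r * w) / sum(w)
    expect_equal(groupCOM(r, 1:50, w, box = c(60, 60, 60)), brute,
                 tolerance = 1e-10)
  }

  # group straddling a periodic boundary is unwrapped about its first member
  r <- matrix(c(1, 5, 5, 59, 5, 5), 2, 3, byrow = TRUE)
  com <- groupCOM(r, 1:2, c(1, 1), box = c(60, 60, 60))
  expect_equal(com, c(0, 5, 5))
})

test_that("leaflet assignment splits a bilayer and is translation invariant", {
  sys <- flatSystem(nP = 64)
  lf <- assignLeaflets(sys$traj, sys$topo)
  expect_length(lf$upper, 64)
  expect_length(lf$lower, 64)

  gen <- genBilayerTrajectory(smallRecipe(seed = 21, duration = 0.5))
  lf2 <- assignLeaflets(gen$traj, gen$topo)
  expect_setequal(lf2$upper, gen$manifest$leaflet_truth$upper)
  expect_setequal(lf2$lower, gen$manifest$leaflet_truth$lower)

  shifted <- gen$traj
  shifted@coords[, 3, ] <- shifted@coords[, 3, ] + 5
  lf3 <- assignLeaflets(shifted, gen$topo)
  expect_identical(lf3, lf2)

  # degenerate: everything on one side
  bad <- gen$traj
  bad@coords[topoGroup(gen$topo, "phosphorus"), 3, ] <-
    abs(bad@coords[topoGroup(gen$topo, "phosphorus"), 3, ]) + 1
  expect_error(assignLeaflets(bad, gen$topo), "degenerate")
})

test_that("reference distances recover prescribed paths and obey symmetries", {
  # transporter COM exactly at the phosphorus plane -> zero distance
  sys <- flatSystem(z_dec = 19, z_N = 15, z_pC = 12)
  ser <- referenceDistanceSeries(sys$traj, sys$topo)
  expect_equal(ser$d_decalin, rep(0, 3), tolerance = 1e-9)
  expect_equal(ser$d_NH, rep(4, 3), tolerance = 1e-9)   # 4 A toward core
  expect_equal(ser$d_pC, rep(7, 3), tolerance = 1e-9)

  # generator prescription recovered within placement noise; the first
  # nanoseconds are excluded because near the midplane the closest leaflet
  # is genuinely ambiguous and the prescription is leaflet-relative
  gen <- genBilayerTrajectory(smallRecipe(seed = 22, duration = 5))
  ser2 <- referenceDistanceSeries(gen$traj, gen$topo)
  truth <- gen$manifest$reference_paths
  settled <- ser2$time_ns >= 2
  for (v in c("d_decalin", "d_NH", "d_pC", "d_tail")) {
    rms <- sqrt(mean((ser2[[v]][settled] - truth[[v]][settled])^2))
    expect_lt(rms, gen$manifest$placement_noise)
  }

  # mirror the whole system through the midplane: series unchanged
  mirrored <- gen$traj
  mirrored@coords[, 3, ] <- -mirrored@coords[, 3, ]
  ser3 <- referenceDistanceSeries(mirrored, gen$topo)
  for (v in c("d_decalin", "d_NH", "d_pC", "d_tail", "d_Cl")) {
    expect_equal(ser3[[v]], ser2[[v]], tolerance = 1e-9)
  }
  expect_true(all(ser3$leaflet != ser2$leaflet))
})

test_that("pooled averages equal the brute-force pooled mean and SEM", {
  const <- data.frame(time_ns = 0:10, d_decalin = 6, d_NH = 4, d_pC = 2,
                      d_Cl = 0, leaflet = "upper")
  avg <- averageReferencePositions(list(const), c(0, 10))
  expect_equal(unname(avg$mean[c("d_pC", "d_NH", "d_decalin")]), c(2, 4, 6))
  expect_equal(unname(avg$sem), rep(0, 3))

  set.seed(33)
  reps <- lapply(1:4, function(i) {
    data.frame(time_ns = seq(0, 10, 0.5), d_decalin = rnorm(21, 6),
               d_NH = rnorm(21, 4), d_pC = rnorm(21, 2))
  })
  avg4 <- averageReferencePositions(reps, c(5, 10))
  pooled <- unlist(lapply(reps, function(s) s$d_decalin[s$time_ns >= 5]))
  expect_equal(unname(avg4$mean["d_decalin"]), mean(pooled), tolerance = 1e-12)
  expect_equal(unname(avg4$sem["d_decalin"]), sd(pooled) / sqrt(length(pooled)),
               tolerance = 1e-12)

  # four identical replicates: same mean, half the SEM of one
  one <- averageReferencePositions(reps[1], c(5, 10))
  four <- averageReferencePositions(rep(reps[1], 4), c(5, 10))
  expect_equal(four$mean, one$mean)
  # pooled SEM shrinks ~ sqrt((n-1)/(4n-1)), just under a factor of 2
  expect_equal(unname(four$sem["d_NH"]),
               unname(one$sem["d_NH"]) / 2, tolerance = 0.05)
  expect_lt(four$sem["d_NH"], one$sem["d_NH"])

  expect_error(averageReferencePositions(reps, c(5, 20)), "window")
})

test_that("orientation classification follows the decalin - para-C margin", {
  mk <- function(ddec, dpc) list(mean = c(d_decalin = ddec, d_NH = (ddec + dpc) / 2,
                                          d_pC = dpc))
  expect_equal(classifyOrientation(mk(6, 3), 1)$label, "toward_interface")
  expect_equal(classifyOrientation(mk(3, 6), 1)$label, "away_from_interface")
  expect_equal(classifyOrientation(mk(5, 5), 1)$label, "none")
  expect_equal(classifyOrientation(mk(6, 3), 1)$margin, 3)
})

test_that("chloride release detection honours cutoff and dwell", {
  # bound throughout (restrained setup): no event
  gen <- genBilayerTrajectory(smallRecipe(seed = 24, duration = 5,
                                          release_time = NA))
  ev <- detectRelease(gen$traj, gen$topo)
  expect_true(is.na(ev$release_time))

  # injected release recovered within 2 frames
  gen2 <- genBilayerTrajectory(smallRecipe(seed = 25, duration = 12,
                                           release_time = 8))
  ev2 <- detectRelease(gen2$traj, gen2$topo)
  expect_lt(abs(ev2$release_time - 8), 2 * gen2$manifest$recipe$frame_dt + 1e-9)

  # degenerate cutoff: release at the first frame
  ev3 <- detectRelease(gen$traj, gen$topo, cutoff = 0, dwell = 1)
  expect_equal(ev3$release_time, 0)

  expect_error(detectRelease(gen$traj, gen$topo, dwell = 100), "dwell")
})

test_that("flip detection counts injected inversions, with hysteresis", {
  gen <- genBilayerTrajectory(smallRecipe(seed = 26, duration = 20, margin = 5,
                                          flip_times = c(6, 13)))
  ev <- detectFlips(gen$traj, gen$topo)
  expect_length(ev$flip_times, 2)
  expect_lt(abs(ev$flip_times[1] - 6), 2 + 1e-9)
  expect_lt(abs(ev$flip_times[2] - 13), 2 + 1e-9)

  # constant orientation: zero flips
  gen0 <- genBilayerTrajectory(smallRecipe(seed = 27, duration = 10, margin = 5))
  expect_length(detectFlips(gen0$traj, gen0$topo)$flip_times, 0)

  # oscillation inside the hysteresis band never registers
  sys <- flatSystem(nFrames = 50)
  # wiggle the N group so theta oscillates ~85-95 deg about the normal
  nidx <- topoGroup(sys$topo, "thiourea_N")
  didx <- topoGroup(sys$topo, "decalin_C")
  for (f in 1:50) {
    dz <- 4 * cos((85 + 10 * (f %% 2)) * pi / 180)
    dx <- 4 * sin((85 + 10 * (f %% 2)) * pi / 180)
    dec <- colMeans(sys$traj@coords[didx, , f])
    sys$traj@coords[nidx, , f] <-
      matrix(rep(dec + c(dx, 0, -dz), each = 4), 4, 3) +
      cbind(c(-.1, .1, -.1, .1), 0, c(-.1, -.1, .1, .1))
  }
  sys$traj@times <- seq(0, 4.9, 0.1)
  expect_length(detectFlips(sys$traj, sys$topo)$flip_times, 0)

  expect_error(detectFlips(gen$traj, gen$topo, enter_angle = 120,
                           exit_angle = 60), "enter_angle")
})

test_that("flip counts are monotonically non-increasing in dwell", {
  gen <- genBilayerTrajectory(smallRecipe(seed = 28, duration = 30, margin = 5,
                                          flip_times = c(5, 12, 20)))
  counts <- vapply(c(0.5, 1, 2, 4, 8),
                   function(dw) length(detectFlips(gen$traj, gen$topo,
                                                   dwell = dw)$flip_times),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[3], 3)   # default dwell recovers all three
})
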