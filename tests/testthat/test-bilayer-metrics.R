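test_that("area per lipid matches the closed form and the brute-force mean", {
  tr <- Trajectory(list(matrix(runif(12), 4, 3)), c(62, 62, 70), 0)
  apl <- areaPerLipid(tr, 128)
  expect_equal(apl$mean, 62 * 62 / 64)   # 60.0625
  expect_equal(apl$sem, 0)

  set.seed(51)
  boxes <- cbind(runif(20, 60, 64), runif(20, 60, 64), 70)
  trf <- Trajectory(array(runif(4 * 3 * 20), c(4, 3, 20)), boxes, 0:19)
  apl2 <- areaPerLipid(trf, 64)
  brute <- mean(boxes[, 1] * boxes[, 2] / 32)
  expect_equal(apl2$mean, brute, tolerance = 1e-12)

  expect_error(areaPerLipid(tr, 127), "even")
})

test_that("P-to-P thickness is recovered and is translation invariant", {
  sys <- flatSystem(zP = 19)
  th <- bilayerThickness(sys$traj, sys$topo)
  expect_equal(th$mean, 38)
  expect_equal(th$sem, 0)

  gen <- genBilayerTrajectory(smallRecipe(seed = 52, duration = 10,
                                          z_P = 19.25, z_noise = 0.8))
  th2 <- bilayerThickness(gen$traj, gen$topo)
  expect_lt(abs(th2$mean - gen$manifest$thickness_truth),
            max(2 * th2$sem, 0.2))

  shifted <- gen$traj
  shifted@coords[, 3, ] <- shifted@coords[, 3, ] + 7.5
  th3 <- bilayerThickness(shifted, gen$topo)
  expect_equal(th3$per_frame, th2$per_frame, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("electron density profile conserves total electrons", {
  # all electrons at the midplane fall into one occupied bin
  sys <- flatSystem(nP = 2)
  topo <- sys$topo
  topo@electrons <- rep(0, nAtoms(topo))
  topo@electrons[topoGroup(topo, "decalin_C")] <- 10
  tr <- sys$traj
  # put the decalin exactly at the phosphorus midplane (z = 0)
  tr@coords[topoGroup(topo, "decalin_C"), 3, ] <- 0
  edp <- electronDensityProfile(tr, topo, bin_width = 1)
  occupied <- edp$density > 0
  expect_lte(sum(occupied), 2)   # zero-sum jitter keeps them within 2 bins
  total <- sum(edp$density) * 1 * attr(edp, "area")
  expect_equal(total, 100, tolerance = 0.01 * 100)

  # conservation holds on a full synthetic bilayer with waters and ions
  rc <- trajectoryRecipe(n_lipids = 32, n_waters = 200, n_ion_pairs = 4,
                         duration = 1, n_chain_carbons = 2, release_time = NA,
                         seed = 53)
  gen <- genBilayerTrajectory(rc)
  edp2 <- electronDensityProfile(gen$traj, gen$topo, bin_width = 0.5)
  total2 <- sum(edp2$density) * 0.5 * attr(edp2, "area")
  expect_equal(total2, sum(gen$topo@electrons), tolerance = 0.01)

  # two-Gaussian phosphorus distribution peaks near +/- z_P
  topoP <- gen$topo
  keepP <- topoGroup(topoP, "phosphorus")
  topoP@electrons[setdiff(seq_len(nAtoms(topoP)), keepP)] <- 0
  edp3 <- electronDensityProfile(gen$traj, topoP, bin_width = 1)
  up <- edp3[edp3$z_center > 0, ]
  lo <- edp3[edp3$z_center < 0, ]
  expect_lt(abs(up$z_center[which.max(up$density)] - 19), 1.5)
  expect_lt(abs(lo$z_center[which.max(lo$density)] + 19), 1.5)

  expect_error(electronDensityProfile(sys$traj, sys$topo), "electron")
})

test_that("order parameters hit the parallel, in-plane and isotropic limits", {
  mkchain <- function(hvecs) {
    nH <- nrow(hvecs)
    coords <- rbind(c(10, 10, 10), sweep(hvecs, 2, c(10, 10, 10), `+`),
                    c(5, 5, 19), c(5, 5, -19))   # carbon, H..., two P
    nA <- nH + 3L
    traj <- Trajectory(list(coords), c(40, 40, 60), 0)
    topo <- TopologyMap(nA, list(phosphorus = c(nH + 2L, nH + 3L),
                                 decalin_C = 1L, thiourea_N = 1L, para_C = 1L,
                                 tail_term_C = integer(), chloride = 1L),
                        chains = list(list(carbon = 1L, hydrogens = 2:(nH + 1L),
                                           position = 1)))
    list(traj = traj, topo = topo)
  }
  # all C-H parallel to the normal: S_CD = 1, reported -S_CD = -1
  par <- mkchain(matrix(c(0, 0, 1.09), 1, 3))
  expect_equal(orderParameters(par$traj, par$topo)$minus_SCD, -1)
  # all C-H in the membrane plane: S_CD = -0.5, reported 0.5
  inpl <- mkchain(matrix(c(1.09, 0, 0, 0, 1.09, 0), 2, 3, byrow = TRUE))
  expect_equal(orderParameters(inpl$traj, inpl$topo)$minus_SCD, 0.5)
  # isotropic orientations: S_CD = 0 +/- 0.01 (Monte-Carlo oracle, 1e5 draws)
  set.seed(54)
  v <- matrix(rnorm(3e5), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  iso <- mkchain(1.09 * v)
  expect_lt(abs(orderParameters(iso$traj, iso$topo)$minus_SCD), 0.01)
  # a carbon with no hydrogens is skipped with a warning
  bad <- par$topo
  bad@chains <- c(bad@chains, list(list(carbon = 1L, hydrogens = integer(),
                                        position = 2)))
  expect_warning(orderParameters(par$traj, bad), "skipped")
})

test_that("bilayer metrics are insensitive to the embedded transporter", {
  # two independent bilayers from the same recipe family, one untailed,
  # differ by less than ~2 pooled SEM in area and thickness
  g1 <- genBilayerTrajectory(smallRecipe(seed = 55, duration = 10))
  g2 <- genBilayerTrajectory(smallRecipe(seed = 56, duration = 10,
                                         tailed = FALSE, orientation = "away"))
  t1 <- bilayerThickness(g1$traj, g1$topo)
  t2 <- bilayerThickness(g2$traj, g2$topo)
  pooled_sem <- sqrt(t1$sem^2 + t2$sem^2)
  expect_lt(abs(t1$mean - t2$mean), 2 * pooled_sem + 0.05)
  a1 <- areaPerLipid(g1$traj, 32); a2 <- areaPerLipid(g2$traj, 32)
  expect_equal(a1$mean, a2$mean, tolerance = 1e-9)   # boxes identical by recipe
})
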