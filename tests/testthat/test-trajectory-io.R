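test_that("write-read round trip is identity within format precision", {
  gen <- genBilayerTrajectory(smallRecipe(seed = 11, duration = 0.2))
  tr <- gen$traj
  tol <- c(gro = 0.006, pdb = 0.0006, xyz = 0.0006)  # GRO written in nm at 0.001
  for (fmt in c("gro", "pdb", "xyz")) {
    p <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeTrajectory(tr, p)
    tr2 <- readTrajectory(p)
    expect_equal(nFrames(tr2), nFrames(tr))
    expect_equal(nAtoms(tr2), nAtoms(tr))
    expect_lt(max(abs(tr2@coords - tr@coords)), tol[[fmt]])
    expect_equal(frameTimes(tr2), frameTimes(tr), tolerance = 1e-6)
    expect_equal(tr2@box, tr@box, ignore_attr = TRUE, tolerance = 1e-3)
    # atom order preserved: atom-wise displacement tiny for every atom
    expect_lt(max(abs(frameCoords(tr2, 1) - frameCoords(tr, 1))), tol[[fmt]])
  }
})

test_that("single-frame PDB with 10 atoms parses to 1 frame x 10 atoms", {
  tr <- Trajectory(list(matrix(runif(30, 0, 50), 10, 3)), c(60, 60, 70), 0)
  p <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(tr, p)
  tr2 <- readTrajectory(p)
  expect_equal(nFrames(tr2), 1L)
  expect_equal(nAtoms(tr2), 10L)
})

test_that("synthetic trajectory frame count and timestamps match the manifest", {
  gen <- genBilayerTrajectory(smallRecipe(seed = 12, duration = 1.5))
  expect_equal(nFrames(gen$traj), gen$manifest$n_frames)
  expect_equal(frameTimes(gen$traj), gen$manifest$times)
  expect_equal(nAtoms(gen$traj), gen$manifest$n_atoms)
  p <- withr::local_tempfile(fileext = ".gro")
  writeTrajectory(gen$traj, p)
  tr2 <- readTrajectory(p)
  expect_equal(nFrames(tr2), gen$manifest$n_frames)
  expect_equal(nAtoms(tr2), gen$manifest$n_atoms)
  expect_equal(frameTimes(tr2), gen$manifest$times, tolerance = 1e-6)
})

test_that("invalid trajectories and malformed files are rejected with context", {
  expect_error(Trajectory(array(1, c(0, 3, 1)), c(1, 1, 1), 0), "atom")
  expect_error(Trajectory(array(1, c(2, 3, 2)), c(10, 10, 10), c(1, 1)),
               "increasing")
  expect_error(Trajectory(array(1, c(2, 3, 1)), c(-1, 10, 10), 0), "positive")
  # truncated GRO names the frame
  gen <- genBilayerTrajectory(smallRecipe(seed = 13, duration = 0.2, n_lipids = 8))
  p <- withr::local_tempfile(fileext = ".gro")
  writeTrajectory(gen$traj, p)
  lines <- readLines(p)
  writeLines(lines[1:(length(lines) - 2)], p)    # drop tail of last frame
  expect_error(readTrajectory(p), "frame 3")
  # inconsistent atom counts across XYZ frames
  p2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "time=0 box=10,10,10", "C 1 1 1", "C 2 2 2",
               "1", "time=1 box=10,10,10", "C 1 1 1"), p2)
  expect_error(readTrajectory(p2), "inconsistent atom count")
  # XYZ without box token needs a fixed box
  p3 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "time=0", "C 1 1 1"), p3)
  expect_error(readTrajectory(p3), "box")
  expect_equal(nAtoms(readTrajectory(p3, box = c(10, 10, 10))), 1L)
})

test_that("topology sidecar round-trips and validates its required groups", {
  gen <- genBilayerTrajectory(smallRecipe(seed = 14, duration = 0.2,
                                          n_chain_carbons = 1))
  p <- withr::local_tempfile(fileext = ".json")
  writeTopoMap(gen$topo, p)
  topo2 <- readTopoMap(p)
  expect_equal(topo2@groups, gen$topo@groups)
  expect_equal(topo2@masses, gen$topo@masses)
  expect_equal(topo2@electrons, gen$topo@electrons)
  expect_equal(length(topo2@chains), length(gen$topo@chains))
  # sidecar groups match generator ground truth
  expect_equal(topo2@groups$phosphorus,
               sort(c(gen$manifest$leaflet_truth$upper,
                      gen$manifest$leaflet_truth$lower)))

  # missing chloride -> validation error naming the group
  j <- jsonlite::fromJSON(p, simplifyDataFrame = FALSE)
  j$groups$chloride <- NULL
  jsonlite::write_json(j, p, auto_unbox = TRUE)
  expect_error(readTopoMap(p), "chloride")

  # untailed transporter: empty tail_term_C accepted
  gen7a <- genBilayerTrajectory(smallRecipe(seed = 15, duration = 0.2,
                                            tailed = FALSE))
  p2 <- withr::local_tempfile(fileext = ".json")
  writeTopoMap(gen7a$topo, p2)
  topo7a <- readTopoMap(p2)
  expect_length(topoGroup(topo7a, "tail_term_C"), 0)
})
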