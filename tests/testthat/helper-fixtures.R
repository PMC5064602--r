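# small, fast recipes used across the suite
smallRecipe <- function(seed, duration = 10, orientation = "toward", margin = 3,
                        release_time = NA, flip_times = numeric(),
                        n_lipids = 32, n_chain_carbons = 0, ...) {
  trajectoryRecipe(n_lipids = n_lipids, n_waters = 0, n_ion_pairs = 0,
                   duration = duration, orientation = orientation,
                   margin = margin, release_time = release_time,
                   flip_times = flip_times, n_chain_carbons = n_chain_carbons,
                   seed = seed, ...)
}

# hand-built flat bilayer: nP phosphorus per leaflet at exactly +/- zP, plus a
# transporter whose group COMs sit at prescribed z values (no noise)
flatSystem <- function(zP = 19, nP = 4, z_dec = 10, z_N = 12, z_pC = 14,
                       z_cl = 12, nFrames = 3, box = c(60, 60, 70)) {
  nA <- 2 * nP + 10 + 4 + 2 + 1
  xy <- cbind(rep(seq_len(2 * nP) * 5, length.out = 2 * nP),
              rep(10, 2 * nP))
  frames <- lapply(seq_len(nFrames), function(f) {
    m <- matrix(0, nA, 3)
    m[1:(2 * nP), 1:2] <- xy
    m[1:nP, 3] <- zP
    m[(nP + 1):(2 * nP), 3] <- -zP
    grp <- function(idx, z, n) {
      # symmetric offsets, zero-sum, so COM z is exact
      off <- rep(c(-0.5, 0.5), length.out = n)
      off <- off - mean(off)
      cbind(30 + seq_len(n) * 0.1, 30, z + off)
    }
    m[2 * nP + 1:10, ] <- grp(NULL, z_dec, 10)
    m[2 * nP + 11:14, ] <- grp(NULL, z_N, 4)
    m[2 * nP + 15:16, ] <- grp(NULL, z_pC, 2)
    m[2 * nP + 17, ] <- c(30, 30, z_cl)
    m
  })
  traj <- Trajectory(frames, box, seq_len(nFrames) - 1)
  topo <- TopologyMap(nA, list(
    phosphorus = 1:(2 * nP), decalin_C = 2 * nP + 1:10,
    thiourea_N = 2 * nP + 11:14, para_C = 2 * nP + 15:16,
    tail_term_C = integer(), chloride = 2 * nP + 17L))
  list(traj = traj, topo = topo)
}
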