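# run expr with a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Recipe for a synthetic bilayer trajectory
#'
#' Describes the geometric emulation of a solvated POPC bilayer carrying one
#' anion transporter and its chloride. Defaults emulate the simulated study
#' system: 128 lipids, a 6500-molecule water slab represented as inert
#' electron-density filler, 18 Na+ / 18 Cl- bystander ions, leaflet
#' phosphorus planes near +/-19 Angstrom, 150 ns at 0.1 ns/frame, and a
#' chloride released within the first 15 ns. Trajectories are geometric
#' emulations with prescribed reference-point paths, not physical
#' simulations.
#'
#' @param n_lipids total lipid count (even), default 128.
#' @param n_waters inert water-equivalent filler points, default 6500.
#' @param n_ion_pairs bystander Na/Cl pairs in the water phase, default 18.
#' @param box box lengths (Angstrom), default `c(62, 62, 70)`.
#' @param z_P mean |z| of the leaflet phosphorus planes (Angstrom), default 19.
#' @param z_noise per-frame phosphorus z jitter sd (Angstrom), default 0.8.
#' @param duration trajectory length (ns), default 150.
#' @param frame_dt frame spacing (ns), default 0.1.
#' @param orientation transporter orientation label: `"toward"`, `"none"` or
#'   `"away"` (aromatics toward / no preference / away from the interface).
#' @param margin prescribed equilibrium `d_decalin - d_pC` magnitude
#'   (Angstrom), default 3.
#' @param placement_noise per-atom placement jitter sd about each prescribed
#'   reference COM (Angstrom), default 1.
#' @param d_eq equilibrium decalin-COM depth below the interface (Angstrom),
#'   default 6.
#' @param tau relaxation time of the core-to-interface approach (ns), default 10.
#' @param release_time chloride release time (ns); `NULL` (default) draws one
#'   uniformly from (0, 15]; `NA` keeps the chloride bound throughout (the
#'   restrained setup).
#' @param flip_times times (ns) of prescribed 180-degree orientation
#'   inversions, default none.
#' @param n_chain_carbons acyl-chain carbons per lipid (each with two
#'   hydrogens, for order parameters), default 4; 0 omits chains.
#' @param tailed logical: does the transporter carry alkyl tails (terminal
#'   tail carbons present), default TRUE.
#' @param seed RNG seed (mandatory).
#' @return a validated `trajectoryRecipe` list.
#' @export
trajectoryRecipe <- function(n_lipids = 128, n_waters = 6500, n_ion_pairs = 18,
                             box = c(62, 62, 70), z_P = 19, z_noise = 0.8,
                             duration = 150, frame_dt = 0.1,
                             orientation = c("toward", "none", "away"),
                             margin = 3, placement_noise = 1.0,
                             d_eq = 6, tau = 10,
                             release_time = NULL, flip_times = numeric(),
                             n_chain_carbons = 4, tailed = TRUE, seed) {
  orientation <- match.arg(orientation)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (n_lipids <= 0 || n_lipids %% 2 != 0) {
    stop("n_lipids must be positive and even", call. = FALSE)
  }
  if (duration <= 0 || frame_dt <= 0) stop("duration and frame_dt must be positive", call. = FALSE)
  if (!is.null(release_time) && !is.na(release_time) && release_time >= duration) {
    stop("release_time must fall inside the trajectory", call. = FALSE)
  }
  if (is.unsorted(flip_times)) stop("flip_times must be sorted", call. = FALSE)
  if (length(flip_times) && (any(flip_times <= 0) || any(flip_times >= duration))) {
    stop("flip_times must fall inside the trajectory", call. = FALSE)
  }
  if (margin < 0 || margin > 6.5) stop("margin must be in [0, 6.5] Angstrom", call. = FALSE)
  structure(list(n_lipids = n_lipids, n_waters = n_waters,
                 n_ion_pairs = n_ion_pairs, box = box, z_P = z_P,
                 z_noise = z_noise, duration = duration, frame_dt = frame_dt,
                 orientation = orientation, margin = margin,
                 placement_noise = placement_noise, d_eq = d_eq, tau = tau,
                 release_time = release_time, flip_times = flip_times,
                 n_chain_carbons = n_chain_carbons, tailed = tailed,
                 seed = as.integer(seed)),
            class = "trajectoryRecipe")
}

# distances (Angstrom) from the decalin COM to the other reference COMs
# along the binding-site axis
.AX_N <- 4      # thiourea-N COM
.AX_P <- 7      # para-phenylene-C COM
.AX_TAIL <- -4  # tail terminal carbons sit behind the decalin

#' Generate a synthetic bilayer trajectory with ground truth
#'
#' Builds a geometric emulation of the study system from a
#' [trajectoryRecipe()]: two Gaussian phosphorus leaflets about +/- `z_P`,
#' a transporter whose reference-point COMs follow a prescribed smooth path
#' from the bilayer core to an interface-proximal equilibrium with the
#' prescribed orientation, a chloride that co-moves with the binding site
#' until its release time and then departs to the water side, optional
#' 180-degree orientation inversions, bystander ions and an inert
#' water-equivalent slab. Every prescribed quantity is recorded in the
#' returned manifest so each detector can be scored against truth.
#'
#' @param recipe a [trajectoryRecipe()].
#' @return list with `traj` ([Trajectory-class]), `topo`
#'   ([TopologyMap-class]) and `manifest` (recipe, realised prescribed paths,
#'   orientation-angle series, leaflet truth and event times).
#' @export
genBilayerTrajectory <- function(recipe) {
  stopifnot(inherits(recipe, "trajectoryRecipe"))
  .with_seed(recipe$seed, .gen_bilayer(recipe))
}

.gen_bilayer <- function(rc) {
  times <- seq(0, rc$duration, by = rc$frame_dt)
  nF <- length(times)
  box <- rc$box
  nL <- rc$n_lipids
  half <- nL / 2L

  # release time: NULL -> sample from (0, 15]; NA -> never released
  t_rel <- if (is.null(rc$release_time)) stats::runif(1, 0, min(15, rc$duration * 0.9))
           else rc$release_time

  # ---- atom bookkeeping -------------------------------------------------
  nCC <- rc$n_chain_carbons
  atoms_per_lipid <- 1L + nCC * 3L          # P + (C + 2 H) per chain carbon
  n_lipid_atoms <- nL * atoms_per_lipid
  n_dec <- 10L; n_N <- 4L; n_pC <- 2L
  n_tail <- if (rc$tailed) 4L else 0L
  n_trans <- n_dec + n_N + n_pC + n_tail
  n_ions <- 2L * rc$n_ion_pairs
  nA <- n_lipid_atoms + n_trans + 1L + n_ions + rc$n_waters

  idx_P <- seq_len(nL) ; off <- nL
  idx_chain_C <- if (nCC > 0) off + seq_len(nL * nCC) else integer()
  off <- off + nL * nCC
  idx_chain_H <- if (nCC > 0) off + seq_len(nL * nCC * 2L) else integer()
  off <- nL * atoms_per_lipid
  idx_dec <- off + seq_len(n_dec); off <- off + n_dec
  idx_N <- off + seq_len(n_N); off <- off + n_N
  idx_pC <- off + seq_len(n_pC); off <- off + n_pC
  idx_tail <- if (n_tail) off + seq_len(n_tail) else integer(); off <- off + n_tail
  idx_Cl <- off + 1L; off <- off + 1L
  idx_ions <- if (n_ions) off + seq_len(n_ions) else integer(); off <- off + n_ions
  idx_wat <- if (rc$n_waters) off + seq_len(rc$n_waters) else integer()

  masses <- numeric(nA)
  electrons <- numeric(nA)
  masses[idx_P] <- 30.97; electrons[idx_P] <- 15
  masses[idx_chain_C] <- 12.01; electrons[idx_chain_C] <- 6
  masses[idx_chain_H] <- 1.008; electrons[idx_chain_H] <- 1
  masses[c(idx_dec, idx_pC, idx_tail)] <- 12.01
  electrons[c(idx_dec, idx_pC, idx_tail)] <- 6
  masses[idx_N] <- 14.01; electrons[idx_N] <- 7
  masses[idx_Cl] <- 35.45; electrons[idx_Cl] <- 18
  if (n_ions) {
    na_half <- idx_ions[seq_len(rc$n_ion_pairs)]
    cl_half <- setdiff(idx_ions, na_half)
    masses[na_half] <- 22.99; electrons[na_half] <- 10
    masses[cl_half] <- 35.45; electrons[cl_half] <- 18
  }
  masses[idx_wat] <- 18.02; electrons[idx_wat] <- 10

  # ---- static lipid layout ---------------------------------------------
  grid_n <- ceiling(sqrt(half))
  gx <- (rep(seq_len(grid_n), grid_n)[seq_len(half)] - 0.5) * box[1] / grid_n
  gy <- (rep(seq_len(grid_n), each = grid_n)[seq_len(half)] - 0.5) * box[2] / grid_n
  leaflet_sign <- rep(c(1, -1), each = half)    # first half upper, second lower
  px <- c(gx, gx); py <- c(gy, gy)
  # static per-lipid z offsets, centred per leaflet so each phosphorus plane
  # averages exactly +/- z_P (keeps the realised thickness unbiased)
  off_up <- stats::rnorm(half, 0, rc$z_noise / 2); off_up <- off_up - mean(off_up)
  off_lo <- stats::rnorm(half, 0, rc$z_noise / 2); off_lo <- off_lo - mean(off_lo)
  pz0 <- leaflet_sign * rc$z_P + c(off_up, off_lo)

  # transporter orientation: axis z-component from the prescribed margin
  uz0 <- switch(rc$orientation,
                toward = rc$margin / .AX_P,
                none = 0,
                away = -rc$margin / .AX_P)
  theta0 <- acos(uz0)                 # radians, angle to outward normal (+z)
  # prescribed theta(t) with smooth logistic inversions at flip_times
  theta_t <- rep(theta0, nF)
  for (ft in rc$flip_times) {
    s <- stats::plogis((times - ft) / 0.1)     # ~0.5 ns wide inversion
    # each inversion reflects the orientation angle about 90 degrees
    theta_t <- (1 - s) * theta_t + s * (pi - theta_t)
  }
  uz_t <- cos(theta_t)
  ur_t <- sin(theta_t)               # in-plane component magnitude

  # prescribed decalin depth below the interface (positive toward core)
  d_dec <- rc$z_P + (rc$d_eq - rc$z_P) * (1 - exp(-times / rc$tau))

  # fixed in-group offsets (zero-sum) so atoms spread around each COM
  offsets <- function(n, spread = 1.2) {
    o <- matrix(stats::rnorm(n * 3, 0, spread), ncol = 3)
    sweep(o, 2, colMeans(o))
  }
  off_dec <- offsets(n_dec); off_N <- offsets(n_N, 0.8)
  off_pC <- offsets(n_pC, 0.8); off_tail <- if (n_tail) offsets(n_tail) else NULL
  azim <- stats::runif(1, 0, 2 * pi)

  coords <- array(NA_real_, dim = c(nA, 3L, nF))
  d_truth <- data.frame(time_ns = times, d_decalin = NA_real_, d_NH = NA_real_,
                        d_pC = NA_real_, d_Cl = NA_real_)
  if (n_tail) d_truth$d_tail <- NA_real_
  cx <- box[1] / 2; cy <- box[2] / 2

  for (f in seq_len(nF)) {
    xyz <- matrix(0, nA, 3L)
    # lipids: phosphorus planes with per-frame jitter
    pz <- pz0 + stats::rnorm(nL, 0, rc$z_noise)
    xyz[idx_P, ] <- cbind(px + stats::rnorm(nL, 0, 0.3),
                          py + stats::rnorm(nL, 0, 0.3), pz)
    if (nCC > 0) {
      # chain carbons descend from each P toward the core, mostly ordered
      for (j in seq_len(nCC)) {
        ci <- idx_chain_C[(j - 1L) * nL + seq_len(nL)]
        cz <- pz - leaflet_sign * (2.5 * j) + stats::rnorm(nL, 0, 0.5)
        cxy <- cbind(px + stats::rnorm(nL, 0, 0.8), py + stats::rnorm(nL, 0, 0.8))
        xyz[ci, ] <- cbind(cxy, cz)
        # two H per carbon, roughly perpendicular to the chain (in-plane)
        phi <- stats::runif(nL, 0, 2 * pi)
        for (h in 1:2) {
          hi <- idx_chain_H[((j - 1L) * 2L + (h - 1L)) * nL + seq_len(nL)]
          ang <- phi + (h - 1) * pi + stats::rnorm(nL, 0, 0.4)
          xyz[hi, ] <- xyz[ci, ] + cbind(1.09 * cos(ang), 1.09 * sin(ang),
                                         stats::rnorm(nL, 0, 0.25))
        }
      }
    }
    # realised upper-leaflet interface (transporter binds the upper leaflet)
    pint_up <- mean(pz[leaflet_sign > 0])
    z_dec <- pint_up - d_dec[f]
    u <- c(ur_t[f] * cos(azim), ur_t[f] * sin(azim), uz_t[f])
    com_dec <- c(cx, cy, z_dec)
    com_N <- com_dec + .AX_N * u
    com_pC <- com_dec + .AX_P * u
    place <- function(idx, com, offs) {
      xyz[idx, ] <<- sweep(offs + matrix(stats::rnorm(length(idx) * 3, 0,
                                                      rc$placement_noise),
                                         ncol = 3), 2, com, `+`)
    }
    place(idx_dec, com_dec, off_dec)
    place(idx_N, com_N, off_N)
    place(idx_pC, com_pC, off_pC)
    if (n_tail) place(idx_tail, com_dec + .AX_TAIL * u, off_tail)
    # chloride: bound 2 Angstrom beyond the N COM until release, then to water
    released <- !is.na(t_rel) && times[f] >= t_rel
    sep <- if (released) 2 + pmin(28, 60 * (times[f] - t_rel)) else 2
    dir_w <- if (released) c(0, 0, 1) else u   # water side of the upper leaflet
    com_cl <- com_N + sep * dir_w
    xyz[idx_Cl, ] <- com_cl + stats::rnorm(3, 0, rc$placement_noise / 2)
    # bystander ions and water filler in the aqueous slabs (|z| > z_P + 2)
    n_aq <- n_ions + rc$n_waters
    if (n_aq) {
      zr <- stats::runif(n_aq, rc$z_P + 2, box[3] / 2) *
        sample(c(-1, 1), n_aq, replace = TRUE)
      xyz[c(idx_ions, idx_wat), ] <- cbind(stats::runif(n_aq, 0, box[1]),
                                           stats::runif(n_aq, 0, box[2]), zr)
    }
    coords[, , f] <- xyz
    # prescribed truth relative to the realised upper interface
    d_truth$d_decalin[f] <- d_dec[f]
    d_truth$d_NH[f] <- d_dec[f] - .AX_N * uz_t[f]
    d_truth$d_pC[f] <- d_dec[f] - .AX_P * uz_t[f]
    if (n_tail) d_truth$d_tail[f] <- d_dec[f] - .AX_TAIL * uz_t[f]
    d_truth$d_Cl[f] <- pint_up - com_cl[3]
  }

  groups <- list(phosphorus = idx_P, decalin_C = idx_dec, thiourea_N = idx_N,
                 para_C = idx_pC, tail_term_C = idx_tail, chloride = idx_Cl)
  chains <- if (nCC > 0) {
    unlist(lapply(seq_len(nCC), function(j) {
      lapply(seq_len(nL), function(l) {
        list(carbon = idx_chain_C[(j - 1L) * nL + l],
             hydrogens = c(idx_chain_H[((j - 1L) * 2L) * nL + l],
                           idx_chain_H[((j - 1L) * 2L + 1L) * nL + l]),
             position = j)
      })
    }), recursive = FALSE)
  } else list()
  topo <- TopologyMap(nA, groups, masses = masses, electrons = electrons,
                      chains = chains)
  elements <- rep("O", nA)
  elements[idx_P] <- "P"; elements[c(idx_chain_C, idx_dec, idx_pC, idx_tail)] <- "C"
  elements[idx_chain_H] <- "H"; elements[idx_N] <- "N"
  elements[idx_Cl] <- "Cl"
  traj <- Trajectory(coords, box, times,
                     metadata = list(elements = elements, setup = "synthetic"))
  manifest <- list(recipe = unclass(rc),
                   n_atoms = nA, n_frames = nF, times = times,
                   leaflet_truth = list(upper = idx_P[leaflet_sign > 0],
                                        lower = idx_P[leaflet_sign <= 0]),
                   reference_paths = d_truth,
                   theta_deg = theta_t * 180 / pi,
                   orientation = rc$orientation, margin = rc$margin,
                   release_time = t_rel, flip_times = rc$flip_times,
                   placement_noise = rc$placement_noise,
                   z_P = rc$z_P, thickness_truth = 2 * rc$z_P)
  list(traj = traj, topo = topo, manifest = manifest)
}

#' Generate a synthetic lucigenin fluorescence trace
#'
#' The noiseless normalised signal is the double-exponential growth
#' `y(t) = 1 + A1 (1 - exp(-k1 t)) + A2 (1 - exp(-k2 t))`; the recorded
#' fluorescence is `F = F0 / y` plus additive Gaussian noise with sd
#' `noise_sd * F0`.
#'
#' @param A1,k1,A2,k2 amplitudes (dimensionless) and rate constants (1/s).
#' @param F0 baseline fluorescence (a.u.), default 100.
#' @param noise_sd fractional noise scale on F, default 0.005.
#' @param duration trace length (s), default 600.
#' @param dt sampling interval (s), default 1.
#' @param ratio transporter/lipid mole ratio recorded on the trace.
#' @param label transporter identifier.
#' @param seed RNG seed (mandatory).
#' @return list with `trace` ([fluorescenceTrace()]) and `truth` (parameters
#'   and the closed-form initial rate `A1 k1 + A2 k2`).
#' @export
genFluorescenceTrace <- function(A1, k1, A2, k2, F0 = 100, noise_sd = 0.005,
                                 duration = 600, dt = 1, ratio = 1 / 1000,
                                 label = NA_character_, seed) {
  stopifnot(A1 >= 0, k1 >= 0, A2 >= 0, k2 >= 0, F0 > 0)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  .with_seed(seed, {
    t <- seq(0, duration, by = dt)
    y <- .dexp_model(t, A1, k1, A2, k2)
    Fv <- F0 / y + stats::rnorm(length(t), 0, noise_sd * F0)
    Fv <- pmax(Fv, F0 * 1e-3)
    list(trace = fluorescenceTrace(t, Fv, F0, ratio = ratio, label = label),
         truth = list(A1 = A1, k1 = k1, A2 = A2, k2 = k2, F0 = F0,
                      noise_sd = noise_sd,
                      initial_rate = A1 * k1 + A2 * k2,
                      y_noiseless = y))
  })
}

#' Generate a synthetic NMR titration
#'
#' Observed shifts follow the exact 1:1 isotherm plus Gaussian noise. The
#' default 12-point schedule runs to 10 guest equivalents, which takes a
#' host at 2 mM past 90 percent saturation for association constants near
#' 7e2 1/M.
#'
#' @param Ka association constant (1/M).
#' @param delta_free,delta_bound free and limiting shifts (ppm), defaults
#'   9.8 and 11.8.
#' @param H0 host concentration (M), scalar or per point, default 2e-3.
#' @param equivalents guest equivalents schedule, default 12 points to 10.
#' @param noise_sd shift noise sd (ppm), default 0.002.
#' @param seed RNG seed (mandatory).
#' @return list with `data` ([titrationData()]) and `truth`.
#' @export
genTitration <- function(Ka, delta_free = 9.8, delta_bound = 11.8, H0 = 2e-3,
                         equivalents = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4,
                                         6, 8, 10),
                         noise_sd = 0.002, seed) {
  stopifnot(Ka > 0)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  .with_seed(seed, {
    if (length(H0) == 1L) H0 <- rep(H0, length(equivalents))
    G0 <- equivalents * H0
    f <- isotherm1to1(H0, pmax(G0, 0), Ka)
    f[G0 == 0] <- 0
    delta <- delta_free + (delta_bound - delta_free) * f +
      stats::rnorm(length(G0), 0, noise_sd)
    list(data = titrationData(G0, delta, H0),
         truth = list(Ka = Ka, delta_free = delta_free,
                      delta_bound = delta_bound, bound_fraction = f,
                      saturation_max = max(f)))
  })
}
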