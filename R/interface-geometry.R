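#' Mass-weighted centre of mass of an atom group
#'
#' The group is unwrapped by the minimum-image convention about its first
#' member before averaging, so groups that straddle a periodic boundary get a
#' physically meaningful COM (valid while the group spans less than half the
#' box in every dimension). Orthorhombic boxes only.
#'
#' @param coords `nAtoms x 3` coordinate matrix (Angstrom).
#' @param indices 1-based atom indices of the group.
#' @param masses per-atom masses for the whole system (amu).
#' @param box length-3 box vector (Angstrom); `NULL` disables imaging.
#' @return length-3 COM (Angstrom).
#' @export
groupCOM <- function(coords, indices, masses, box = NULL) {
  if (length(indices) == 0L) stop("empty atom group", call. = FALSE)
  r <- coords[indices, , drop = FALSE]
  m <- masses[indices]
  ref <- r[1, ]
  d <- sweep(r, 2, ref)
  if (!is.null(box)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  ref + colSums(d * m) / sum(m)
}

#' Assign leaflet membership of the phosphorus atoms
#'
#' Each phosphorus is assigned to the upper or lower leaflet by the sign of
#' its z coordinate relative to the bilayer midplane (the mean phosphorus z)
#' in the first frame. The assignment is held fixed across frames: lipid
#' flip-flop is not expected on the hundred-nanosecond timescales these
#' trajectories cover.
#'
#' @param traj a [Trajectory-class].
#' @param topo a [TopologyMap-class] with a non-empty `phosphorus` group.
#' @return list with integer vectors `upper` and `lower` (atom indices).
#' @export
assignLeaflets <- function(traj, topo) {
  p <- topoGroup(topo, "phosphorus")
  z <- frameCoords(traj, 1L)[p, 3]
  mid <- mean(z)
  upper <- p[z > mid]
  lower <- p[z <= mid]
  if (length(upper) == 0L || length(lower) == 0L ||
      mean(z[z > mid]) - mean(z[z <= mid]) < 6) {
    stop("degenerate bilayer: phosphorus atoms do not form two separated leaflets",
         call. = FALSE)
  }
  list(upper = upper, lower = lower)
}

# P_int z of both leaflets for one frame
.pint_z <- function(xyz, leaflets, masses, box) {
  c(upper = groupCOM(xyz, leaflets$upper, masses, box)[3],
    lower = groupCOM(xyz, leaflets$lower, masses, box)[3])
}

# Signed distance of a z position to the interface of one leaflet.
# Convention: 0 at the phosphorus plane, positive toward the bilayer core,
# negative on the water side.
.signed_d <- function(z, pz, leaflet) {
  if (leaflet == "upper") pz - z else z - pz
}

#' Interface-relative distance series for the five reference points
#'
#' For every frame, the interface is the phosphorus-plane centre of mass
#' (P_int) of the leaflet closest to the transporter's decalin COM; the
#' chloride is referenced to the same interface, which avoids discontinuities
#' when the complex crosses the midplane. Signed distances follow the
#' convention: 0 at the interface, positive toward the bilayer core, negative
#' on the water side.
#'
#' @param traj a [Trajectory-class].
#' @param topo a [TopologyMap-class]; `tail_term_C` may be empty, in which
#'   case the tail series is omitted.
#' @return a `referenceSeries` data.frame with columns `time_ns`, `d_decalin`,
#'   `d_NH`, `d_pC`, `d_tail` (if tails exist), `d_Cl` and `leaflet`.
#' @export
referenceDistanceSeries <- function(traj, topo) {
  leaflets <- assignLeaflets(traj, topo)
  m <- topoMasses(topo)
  has_tail <- length(topoGroup(topo, "tail_term_C")) > 0L
  nF <- nFrames(traj)
  out <- data.frame(time_ns = frameTimes(traj),
                    d_decalin = NA_real_, d_NH = NA_real_, d_pC = NA_real_,
                    d_Cl = NA_real_, leaflet = NA_character_,
                    stringsAsFactors = FALSE)
  if (has_tail) out$d_tail <- NA_real_
  for (f in seq_len(nF)) {
    xyz <- frameCoords(traj, f)
    bx <- frameBox(traj, f)
    pz <- .pint_z(xyz, leaflets, m, bx)
    zdec <- groupCOM(xyz, topoGroup(topo, "decalin_C"), m, bx)[3]
    lf <- if (abs(zdec - pz["upper"]) <= abs(zdec - pz["lower"])) "upper" else "lower"
    p <- pz[[lf]]
    out$d_decalin[f] <- .signed_d(zdec, p, lf)
    out$d_NH[f] <- .signed_d(groupCOM(xyz, topoGroup(topo, "thiourea_N"), m, bx)[3], p, lf)
    out$d_pC[f] <- .signed_d(groupCOM(xyz, topoGroup(topo, "para_C"), m, bx)[3], p, lf)
    if (has_tail) {
      out$d_tail[f] <- .signed_d(groupCOM(xyz, topoGroup(topo, "tail_term_C"), m, bx)[3], p, lf)
    }
    out$d_Cl[f] <- .signed_d(xyz[topoGroup(topo, "chloride")[1], 3], p, lf)
    out$leaflet[f] <- lf
  }
  class(out) <- c("referenceSeries", "data.frame")
  out
}

#' Pooled average reference positions over a time window
#'
#' Pools all frames with `start <= t <= end` across the supplied replicate
#' series and returns the mean and standard error of each reference-point
#' distance, mirroring the common practice of averaging the equilibrated tail
#' of several independent replicates.
#'
#' @param seriesList list of `referenceSeries` data.frames (replicates).
#' @param window numeric length-2, `c(start, end)` in ns.
#' @return an `averagePositions` list with `mean`, `sem` (named vectors),
#'   `window` and `n_frames_pooled`.
#' @export
averageReferencePositions <- function(seriesList, window) {
  if (inherits(seriesList, "data.frame")) seriesList <- list(seriesList)
  stopifnot(length(window) == 2L, window[1] < window[2])
  for (s in seriesList) {
    if (window[1] < min(s$time_ns) - 1e-9 || window[2] > max(s$time_ns) + 1e-9) {
      stop("averaging window [", window[1], ", ", window[2],
           "] ns lies outside a replicate's time span", call. = FALSE)
    }
  }
  vars <- c("d_decalin", "d_NH", "d_pC", "d_tail")
  pooled <- lapply(vars, function(v) {
    unlist(lapply(seriesList, function(s) {
      if (!v %in% names(s)) return(numeric())
      s[[v]][s$time_ns >= window[1] & s$time_ns <= window[2]]
    }))
  })
  names(pooled) <- vars
  pooled <- pooled[vapply(pooled, length, integer(1)) > 0L]
  n <- length(pooled[[1]])
  if (n == 0L) stop("no frames fall inside the averaging window", call. = FALSE)
  res <- list(
    mean = vapply(pooled, mean, numeric(1)),
    sem = vapply(pooled, function(x) stats::sd(x) / sqrt(length(x)), numeric(1)),
    window = window,
    n_frames_pooled = n
  )
  class(res) <- "averagePositions"
  res
}

#' @export
print.averagePositions <- function(x, ...) {
  cat("Average reference positions over [", x$window[1], ",", x$window[2],
      "] ns (", x$n_frames_pooled, " frames pooled)\n", sep = "")
  for (v in names(x$mean)) {
    cat(sprintf("  %-10s %7.2f +/- %.3f Angstrom\n", v, x$mean[[v]], x$sem[[v]]))
  }
  invisible(x)
}

#' Classify transporter orientation at the interface
#'
#' The orientation margin is `d_decalin - d_pC` (Angstrom): positive when the
#' para-phenylene carbons sit closer to the interface than the decalin core
#' (binding site angled toward the water), negative when the aromatics are
#' angled away into the membrane interior, and near zero when the transporter
#' shows no preferential orientation.
#'
#' @param avg an `averagePositions` result (or any list with `mean` holding
#'   `d_decalin` and `d_pC`).
#' @param threshold Angstrom margin below which the orientation is called
#'   `"none"` (default 1.5).
#' @return an `orientationClass` list with `label` (one of
#'   `"toward_interface"`, `"none"`, `"away_from_interface"`), `margin` and
#'   `threshold`.
#' @export
classifyOrientation <- function(avg, threshold = 1.5) {
  m <- avg$mean
  if (is.null(m[["d_decalin"]]) || is.null(m[["d_pC"]])) {
    stop("average positions must include d_decalin and d_pC", call. = FALSE)
  }
  margin <- unname(m[["d_decalin"]] - m[["d_pC"]])
  label <- if (margin > threshold) "toward_interface"
           else if (margin < -threshold) "away_from_interface"
           else "none"
  structure(list(label = label, margin = margin, threshold = threshold),
            class = "orientationClass")
}

#' @export
print.orientationClass <- function(x, ...) {
  cat("Orientation:", x$label,
      sprintf("(margin %.2f Angstrom, threshold %.2f)\n", x$margin, x$threshold))
  invisible(x)
}

#' Detect chloride release from the thiourea binding site
#'
#' Release is declared at the first time the chloride--thiourea-N-COM
#' distance exceeds `cutoff` continuously for at least `dwell` ns. Distances
#' use the minimum-image convention.
#'
#' @param traj a [Trajectory-class].
#' @param topo a [TopologyMap-class] whose `chloride` group has exactly one atom.
#' @param cutoff separation threshold in Angstrom (default 6).
#' @param dwell required persistence in ns (default 1).
#' @return a `releaseEvent` list with `release_time` (ns, or `NA` if the
#'   chloride never leaves), `criterion`, and the full `distance_series`.
#' @export
detectRelease <- function(traj, topo, cutoff = 6.0, dwell = 1.0) {
  cl <- topoGroup(topo, "chloride")
  if (length(cl) != 1L) stop("chloride group must contain exactly one atom", call. = FALSE)
  times <- frameTimes(traj)
  if (dwell > diff(range(times))) {
    stop("dwell (", dwell, " ns) exceeds the trajectory span", call. = FALSE)
  }
  m <- topoMasses(topo)
  nF <- nFrames(traj)
  dist <- numeric(nF)
  for (f in seq_len(nF)) {
    xyz <- frameCoords(traj, f)
    bx <- frameBox(traj, f)
    ncom <- groupCOM(xyz, topoGroup(topo, "thiourea_N"), m, bx)
    v <- xyz[cl, ] - ncom
    v <- v - bx * round(v / bx)
    dist[f] <- sqrt(sum(v^2))
  }
  beyond <- dist > cutoff
  release <- NA_real_
  r <- rle(beyond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    span <- times[ends[i]] - times[starts[i]]
    if (span >= dwell) { release <- times[starts[i]]; break }
  }
  structure(list(release_time = release,
                 criterion = c(cutoff = cutoff, dwell = dwell),
                 distance_series = data.frame(time_ns = times, dist_Cl_N = dist)),
            class = "releaseEvent")
}

#' @export
print.releaseEvent <- function(x, ...) {
  if (is.na(x$release_time)) {
    cat("No chloride release detected (cutoff", x$criterion["cutoff"],
        "Angstrom, dwell", x$criterion["dwell"], "ns)\n")
  } else {
    cat(sprintf("Chloride release at %.2f ns (cutoff %.1f Angstrom, dwell %.1f ns)\n",
                x$release_time, x$criterion["cutoff"], x$criterion["dwell"]))
  }
  invisible(x)
}

#' Orientation angle of the binding-site axis
#'
#' Angle (degrees) between the axis running from the decalin COM to the
#' thiourea-N COM and the outward normal of the closest leaflet (+z for the
#' upper leaflet, -z for the lower). 0 deg points the binding site at the
#' water phase; 180 deg points it at the opposite leaflet.
#'
#' @inheritParams referenceDistanceSeries
#' @return data.frame with `time_ns` and `theta_deg`.
#' @export
orientationAngleSeries <- function(traj, topo) {
  leaflets <- assignLeaflets(traj, topo)
  m <- topoMasses(topo)
  nF <- nFrames(traj)
  theta <- numeric(nF)
  for (f in seq_len(nF)) {
    xyz <- frameCoords(traj, f)
    bx <- frameBox(traj, f)
    dec <- groupCOM(xyz, topoGroup(topo, "decalin_C"), m, bx)
    ncom <- groupCOM(xyz, topoGroup(topo, "thiourea_N"), m, bx)
    pz <- .pint_z(xyz, leaflets, m, bx)
    lf <- if (abs(dec[3] - pz["upper"]) <= abs(dec[3] - pz["lower"])) "upper" else "lower"
    normal <- if (lf == "upper") c(0, 0, 1) else c(0, 0, -1)
    ax <- ncom - dec
    ax <- ax - bx * round(ax / bx)
    ct <- sum(ax * normal) / sqrt(sum(ax^2))
    theta[f] <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  }
  data.frame(time_ns = frameTimes(traj), theta_deg = theta)
}

#' Detect 180-degree orientation flips
#'
#' A flip is a transition of the binding-site axis between the "outward"
#' state (orientation angle below `enter_angle`) and the "inward" state
#' (angle above `exit_angle`) that persists for at least `dwell` ns. The
#' hysteresis band between the two angles prevents double counting of
#' crossings that rattle about a single threshold.
#'
#' @inheritParams referenceDistanceSeries
#' @param enter_angle lower hysteresis angle in degrees (default 60).
#' @param exit_angle upper hysteresis angle in degrees (default 120).
#' @param dwell persistence requirement in ns (default 2).
#' @return a `flipEvent` list with `flip_times` (ns, possibly empty) and the
#'   `orientation_angle_series` data.frame.
#' @export
detectFlips <- function(traj, topo, enter_angle = 60, exit_angle = 120, dwell = 2.0) {
  if (enter_angle >= exit_angle) {
    stop("enter_angle must be smaller than exit_angle", call. = FALSE)
  }
  ser <- orientationAngleSeries(traj, topo)
  times <- ser$time_ns
  state <- ifelse(ser$theta_deg < enter_angle, "out",
                  ifelse(ser$theta_deg > exit_angle, "in", NA_character_))
  defined <- which(!is.na(state))
  flips <- numeric()
  if (length(defined)) {
    # runs of identical defined state; a run is an established orientation
    # when it spans >= dwell ns (transients inside the hysteresis band or
    # shorter than dwell never register)
    r <- rle(state[defined])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    span <- times[defined[ends]] - times[defined[starts]]
    keep <- span >= dwell
    est_state <- r$values[keep]
    est_start <- times[defined[starts[keep]]]
    if (length(est_state) > 1L) {
      tr <- which(est_state[-1] != est_state[-length(est_state)]) + 1L
      flips <- est_start[tr]
    }
  }
  structure(list(flip_times = flips,
                 criterion = c(enter_angle = enter_angle, exit_angle = exit_angle,
                               dwell = dwell),
                 orientation_angle_series = ser),
            class = "flipEvent")
}

#' @export
print.flipEvent <- function(x, ...) {
  cat(length(x$flip_times), "flip(s) detected")
  if (length(x$flip_times)) {
    cat(" at", paste(sprintf("%.2f", x$flip_times), collapse = ", "), "ns")
  }
  cat("\n")
  invisible(x)
}

#' Write a reference-distance series as tidy CSV
#'
#' @param series a `referenceSeries` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeReferenceSeriesCSV <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
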