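#' Area per lipid
#'
#' Per-frame lateral box area divided by the number of lipids per leaflet,
#' `Lx * Ly / (n_lipids / 2)`, averaged over frames.
#'
#' @param traj a [Trajectory-class].
#' @param n_lipids total lipid count (both leaflets); must be even.
#' @return list with `mean`, `sem` (Angstrom^2) and `per_frame`.
#' @export
areaPerLipid <- function(traj, n_lipids) {
  if (n_lipids <= 0 || n_lipids %% 2 != 0) {
    stop("n_lipids must be a positive even number", call. = FALSE)
  }
  a <- traj@box[, 1] * traj@box[, 2] / (n_lipids / 2)
  list(mean = mean(a),
       sem = if (length(a) > 1L) stats::sd(a) / sqrt(length(a)) else 0,
       per_frame = a)
}

#' Bilayer thickness (phosphate plane to phosphate plane)
#'
#' Per-frame separation of the two leaflet phosphorus centres of mass along
#' z, averaged over frames. Thickness is defined P-to-P; other conventions
#' (e.g. Luzzati) would need composition information the trajectory does not
#' carry.
#'
#' @param traj a [Trajectory-class].
#' @param topo a [TopologyMap-class].
#' @return list with `mean`, `sem` (Angstrom) and `per_frame`.
#' @export
bilayerThickness <- function(traj, topo) {
  leaflets <- assignLeaflets(traj, topo)
  m <- topoMasses(topo)
  th <- vapply(seq_len(nFrames(traj)), function(f) {
    pz <- .pint_z(frameCoords(traj, f), leaflets, m, frameBox(traj, f))
    abs(pz["upper"] - pz["lower"])
  }, numeric(1))
  list(mean = mean(th),
       sem = if (length(th) > 1L) stats::sd(th) / sqrt(length(th)) else 0,
       per_frame = th)
}

#' Electron-density profile along the bilayer normal
#'
#' Histograms per-atom electron counts along z relative to the instantaneous
#' bilayer midplane (mean phosphorus z of the frame, which removes bilayer
#' drift), normalised by bin volume and frame count so the profile is in
#' electrons per cubic Angstrom. The integral of the profile times the
#' lateral box area recovers the total electron count.
#'
#' @param traj a [Trajectory-class].
#' @param topo a [TopologyMap-class] with per-atom `electrons` populated.
#' @param bin_width histogram bin width in Angstrom (default 1).
#' @return data.frame with `z_center` (Angstrom from midplane) and `density`
#'   (e/Angstrom^3); attribute `"area"` holds the mean lateral box area.
#' @export
electronDensityProfile <- function(traj, topo, bin_width = 1.0) {
  if (!length(topo@electrons)) {
    stop("topology map carries no per-atom electron counts", call. = FALSE)
  }
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  p <- topoGroup(topo, "phosphorus")
  nF <- nFrames(traj)
  zrel <- vector("list", nF)
  for (f in seq_len(nF)) {
    z <- frameCoords(traj, f)[, 3]
    zrel[[f]] <- z - mean(z[p])
  }
  zrel <- unlist(zrel)
  rng <- range(zrel)
  breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                ceiling(rng[2] / bin_width) * bin_width + bin_width,
                by = bin_width)
  w <- rep(topo@electrons, nF)
  idx <- findInterval(zrel, breaks, rightmost.closed = TRUE)
  counts <- vapply(seq_len(length(breaks) - 1L),
                   function(b) sum(w[idx == b]), numeric(1))
  area <- mean(traj@box[, 1] * traj@box[, 2])
  dens <- counts / (area * bin_width * nF)
  out <- data.frame(z_center = breaks[-length(breaks)] + bin_width / 2,
                    density = dens)
  attr(out, "area") <- area
  out
}

#' Acyl-chain deuterium order parameters
#'
#' Computes `S_CD = <(3 cos^2 theta - 1) / 2>` for every chain carbon
#' position, where theta is the angle between each C--H vector and the
#' bilayer normal (z axis), averaged over attached hydrogens, lipids sharing
#' the carbon position, and frames. The conventional `-S_CD` is reported.
#' Chain carbons without attached hydrogens are skipped with a warning.
#'
#' @param traj a [Trajectory-class].
#' @param topo a [TopologyMap-class] with `chains` populated; each entry is
#'   `list(carbon = i, hydrogens = c(...), position = p)` where the optional
#'   `position` groups equivalent carbons across lipids (defaults to the
#'   entry's order within the list).
#' @return data.frame with `position` and `minus_SCD`.
#' @export
orderParameters <- function(traj, topo) {
  if (!length(topo@chains)) stop("topology map carries no chain definitions", call. = FALSE)
  nF <- nFrames(traj)
  acc <- list()   # per position: running sum and count of (3cos^2-1)/2
  for (ci in seq_along(topo@chains)) {
    ch <- topo@chains[[ci]]
    if (length(ch$hydrogens) == 0L) {
      warning("chain carbon ", ch$carbon, " has no attached hydrogens; skipped")
      next
    }
    pos <- as.character(ch$position %||% ci)
    s <- 0; n <- 0L
    for (f in seq_len(nF)) {
      xyz <- frameCoords(traj, f)
      bx <- frameBox(traj, f)
      v <- sweep(xyz[ch$hydrogens, , drop = FALSE], 2, xyz[ch$carbon, ])
      for (k in 1:3) v[, k] <- v[, k] - bx[k] * round(v[, k] / bx[k])
      ct2 <- v[, 3]^2 / rowSums(v^2)
      s <- s + sum((3 * ct2 - 1) / 2)
      n <- n + nrow(v)
    }
    if (is.null(acc[[pos]])) acc[[pos]] <- c(0, 0)
    acc[[pos]] <- acc[[pos]] + c(s, n)
  }
  if (!length(acc)) stop("no usable chain carbons", call. = FALSE)
  data.frame(position = names(acc),
             minus_SCD = -vapply(acc, function(a) a[1] / a[2], numeric(1)),
             row.names = NULL)
}

#' All four bilayer structural health checks in one call
#'
#' @inheritParams electronDensityProfile
#' @param n_lipids total lipid count.
#' @param bin_width EDP bin width in Angstrom.
#' @return list with `area_per_lipid`, `thickness`, `edp` and (when chains
#'   are defined) `scd`.
#' @export
bilayerMetrics <- function(traj, topo, n_lipids, bin_width = 1.0) {
  out <- list(
    area_per_lipid = areaPerLipid(traj, n_lipids),
    thickness = bilayerThickness(traj, topo),
    edp = if (length(topo@electrons)) electronDensityProfile(traj, topo, bin_width)
  )
  if (length(topo@chains)) out$scd <- orderParameters(traj, topo)
  out
}
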