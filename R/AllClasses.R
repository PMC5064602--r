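#' @import methods
NULL

#' Trajectory: a multi-frame coordinate trajectory
#'
#' Holds ordered frames of atom coordinates for a bilayer system, together
#' with per-frame orthorhombic box dimensions and timestamps. Coordinates are
#' stored in Angstrom and times in nanoseconds throughout the package; GRO
#' files (which use nm) are converted on read/write.
#'
#' @slot coords numeric array of dimension `c(nAtoms, 3, nFrames)` (Angstrom).
#' @slot box numeric matrix `nFrames x 3` of box lengths Lx, Ly, Lz (Angstrom).
#' @slot times numeric vector of frame times (ns), strictly increasing.
#' @slot metadata free-form list of labels (e.g. setup tag, replicate index).
#'
#' @seealso [readTrajectory()], [writeTrajectory()], [genBilayerTrajectory()]
#' @export
setClass("Trajectory",
  representation(
    coords = "array",
    box = "matrix",
    times = "numeric",
    metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("Trajectory", function(object) {
  msgs <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L) {
    msgs <- c(msgs, "coords must be an nAtoms x 3 x nFrames array")
  } else {
    if (d[3] < 1L) msgs <- c(msgs, "trajectory must contain at least one frame")
    if (d[1] < 1L) msgs <- c(msgs, "trajectory must contain at least one atom")
    if (nrow(object@box) != d[3] || ncol(object@box) != 3L) {
      msgs <- c(msgs, "box must be an nFrames x 3 matrix")
    }
    if (length(object@times) != d[3]) {
      msgs <- c(msgs, "times must have one entry per frame")
    }
  }
  if (any(object@box <= 0)) msgs <- c(msgs, "box lengths must be positive")
  if (length(object@times) > 1L && any(diff(object@times) <= 0)) {
    msgs <- c(msgs, "frame times must be strictly increasing")
  }
  if (any(!is.finite(object@coords))) msgs <- c(msgs, "coordinates must be finite")
  if (length(msgs)) msgs else TRUE
})

#' TopologyMap: named atom groups and per-atom attributes
#'
#' The sidecar that identifies the atom groups every geometric analysis uses.
#' Required group names are `phosphorus`, `decalin_C`, `thiourea_N`, `para_C`,
#' `tail_term_C` and `chloride`; `tail_term_C` may be empty (the unsubstituted
#' transporter carries no alkyl tails). Optional per-atom electron counts
#' drive electron-density profiles, masses drive centres of mass, and `chains`
#' (lists with `$carbon` and `$hydrogens` indices) drive order parameters.
#'
#' @slot nAtoms integer, the atom count the indices are validated against.
#' @slot groups named list of integer index vectors (1-based).
#' @slot masses numeric per-atom masses (amu); defaults to 1 for all atoms.
#' @slot electrons numeric per-atom electron counts (may be empty).
#' @slot chains list of acyl-chain positions, each
#'   `list(carbon = i, hydrogens = c(...))` (may be empty).
#'
#' @seealso [readTopoMap()], [writeTopoMap()]
#' @export
setClass("TopologyMap",
  representation(
    nAtoms = "integer",
    groups = "list",
    masses = "numeric",
    electrons = "numeric",
    chains = "list"
  ),
  prototype(electrons = numeric(), chains = list())
)

.REQUIRED_GROUPS <- c("phosphorus", "decalin_C", "thiourea_N", "para_C",
                      "tail_term_C", "chloride")

setValidity("TopologyMap", function(object) {
  msgs <- character()
  missing <- setdiff(.REQUIRED_GROUPS, names(object@groups))
  if (length(missing)) {
    msgs <- c(msgs, paste0("missing required groups: ",
                           paste(missing, collapse = ", ")))
  }
  idx <- unlist(object@groups, use.names = FALSE)
  if (length(idx) && (any(idx < 1L) || any(idx > object@nAtoms))) {
    msgs <- c(msgs, "group indices must lie in [1, nAtoms]")
  }
  # phosphorus is needed by every analysis; transporter groups may be empty
  # (tail_term_C for the untailed transporter, all of them for a pure membrane)
  if ("phosphorus" %in% names(object@groups) &&
      length(object@groups$phosphorus) == 0L) {
    msgs <- c(msgs, "group 'phosphorus' must be non-empty")
  }
  # chloride must not sit in any lipid group
  if (all(c("chloride", "phosphorus") %in% names(object@groups))) {
    if (length(intersect(object@groups$chloride, object@groups$phosphorus))) {
      msgs <- c(msgs, "chloride indices overlap the phosphorus group")
    }
  }
  if (length(object@masses) && length(object@masses) != object@nAtoms) {
    msgs <- c(msgs, "masses must have one entry per atom")
  }
  if (length(object@electrons) && length(object@electrons) != object@nAtoms) {
    msgs <- c(msgs, "electrons must have one entry per atom")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Trajectory
#'
#' @param coords numeric array `nAtoms x 3 x nFrames` (Angstrom), or a list of
#'   `nAtoms x 3` matrices, one per frame.
#' @param box `nFrames x 3` matrix of box lengths (Angstrom), or a length-3
#'   vector recycled to all frames.
#' @param times frame times in ns.
#' @param metadata optional list of labels.
#' @return a validated [Trajectory-class] object.
#' @export
Trajectory <- function(coords, box, times, metadata = list()) {
  if (is.list(coords)) {
    nA <- nrow(coords[[1]])
    coords <- array(unlist(coords, use.names = FALSE), dim = c(nA, 3L, length(coords)))
  }
  nF <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nrow = nF, ncol = 3L, byrow = TRUE)
  new("Trajectory", coords = coords, box = box, times = as.numeric(times),
      metadata = metadata)
}

#' Construct a TopologyMap
#'
#' @param nAtoms atom count the map describes.
#' @param groups named list of 1-based integer index vectors; must include the
#'   six required group names (see [TopologyMap-class]).
#' @param masses optional per-atom masses (amu); defaults to 1.
#' @param electrons optional per-atom electron counts.
#' @param chains optional list of `list(carbon =, hydrogens =)` entries.
#' @return a validated [TopologyMap-class] object.
#' @export
TopologyMap <- function(nAtoms, groups, masses = NULL, electrons = NULL,
                        chains = list()) {
  if (is.null(masses)) masses <- rep(1, nAtoms)
  if (is.null(electrons)) electrons <- numeric()
  groups <- lapply(groups, as.integer)
  new("TopologyMap", nAtoms = as.integer(nAtoms), groups = groups,
      masses = as.numeric(masses), electrons = as.numeric(electrons),
      chains = chains)
}

#' @describeIn Trajectory-class number of frames
#' @param x a Trajectory
#' @export
nFrames <- function(x) dim(x@coords)[3]

#' @describeIn Trajectory-class number of atoms
#' @export
nAtoms <- function(x) {
  if (is(x, "TopologyMap")) return(x@nAtoms)
  dim(x@coords)[1]
}

#' @describeIn Trajectory-class frame timestamps (ns)
#' @export
frameTimes <- function(x) x@times

#' @describeIn Trajectory-class coordinates of one frame (`nAtoms x 3`, Angstrom)
#' @param i frame index
#' @export
frameCoords <- function(x, i) x@coords[, , i, drop = FALSE][, , 1]

#' @describeIn Trajectory-class box lengths of one frame (Angstrom)
#' @export
frameBox <- function(x, i) x@box[i, ]

#' Atom indices of a named group
#' @param topo a [TopologyMap-class]
#' @param name group name
#' @return integer vector of 1-based atom indices
#' @export
topoGroup <- function(topo, name) {
  if (!name %in% names(topo@groups)) {
    stop("no group named '", name, "' in topology map", call. = FALSE)
  }
  topo@groups[[name]]
}

#' Per-atom masses of a topology map
#' @param topo a [TopologyMap-class]
#' @export
topoMasses <- function(topo) topo@masses

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", dim(object@coords)[1], "atoms,", nFrames(object), "frames\n")
  cat("  time span:", format(object@times[1]), "-",
      format(object@times[nFrames(object)]), "ns\n")
  cat("  mean box:", paste(sprintf("%.1f", colMeans(object@box)), collapse = " x "),
      "Angstrom\n")
  if (length(object@metadata)) {
    vals <- vapply(object@metadata, function(v) {
      if (length(v) == 1L) format(v) else paste0("<", length(v), " values>")
    }, character(1))
    cat("  metadata:", paste(names(vals), vals, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "TopologyMap", function(object) {
  cat("TopologyMap for", object@nAtoms, "atoms\n")
  sizes <- vapply(object@groups, length, integer(1))
  cat("  groups:", paste(names(sizes), sizes, sep = ":", collapse = ", "), "\n")
  cat("  electrons:", if (length(object@electrons)) "present" else "absent",
      "| chains:", length(object@chains), "\n")
})
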