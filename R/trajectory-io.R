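#' Read a multi-frame coordinate trajectory
#'
#' Supported formats: GRO (GROMACS coordinate format, concatenated frames,
#' coordinates in nm converted to Angstrom on read, time taken from a
#' `t= <ns>` token on the title line), PDB (multi-MODEL, box from CRYST1,
#' time from an optional `REMARK   6 TIME= <ns>` record), and multi-frame XYZ
#' (dialect: the comment line carries `time=<ns> box=<Lx,Ly,Lz>` in Angstrom;
#' if the box token is absent a fixed `box` must be supplied).
#'
#' Atom order in the file is preserved: atom i in the file is atom i in every
#' frame. Frames missing a timestamp are numbered 0, 1, 2, ... ns.
#'
#' @param path file to read.
#' @param fmt one of `"gro"`, `"pdb"`, `"xyz"`, or `"auto"` (from extension).
#' @param box optional length-3 box (Angstrom) for XYZ files without a box token.
#' @return a [Trajectory-class]; element symbols, when the format carries them,
#'   are stored in `metadata$elements`.
#' @export
readTrajectory <- function(path, fmt = c("auto", "gro", "pdb", "xyz"), box = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (fmt == "auto") {
    fmt <- tolower(tools::file_ext(path))
    if (!fmt %in% c("gro", "pdb", "xyz")) {
      stop("cannot infer trajectory format from extension '", fmt, "'",
           call. = FALSE)
    }
  }
  lines <- readLines(path)
  switch(fmt,
    gro = .read_gro(lines),
    pdb = .read_pdb(lines),
    xyz = .read_xyz(lines, box = box)
  )
}

.num <- function(x, frame, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) {
    stop("malformed ", what, " in frame ", frame, call. = FALSE)
  }
  v
}

.assemble <- function(frames, boxes, times, elements = NULL) {
  nA <- nrow(frames[[1]])
  counts <- vapply(frames, nrow, integer(1))
  if (any(counts != nA)) {
    bad <- which(counts != nA)[1]
    stop("inconsistent atom count in frame ", bad, " (", counts[bad],
         " vs ", nA, ")", call. = FALSE)
  }
  if (all(is.na(times))) times <- seq_along(frames) - 1
  if (any(is.na(times))) {
    stop("timestamps present for some frames but not all", call. = FALSE)
  }
  md <- list()
  if (!is.null(elements)) md$elements <- elements
  Trajectory(frames, do.call(rbind, boxes), times, metadata = md)
}

.read_gro <- function(lines) {
  frames <- list(); boxes <- list(); times <- numeric(); pos <- 1L; f <- 0L
  elements <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    f <- f + 1L
    title <- lines[pos]
    nat <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(nat) || nat < 1L) stop("malformed atom count in frame ", f, call. = FALSE)
    if (pos + 1L + nat + 1L > length(lines)) {
      stop("truncated frame ", f, call. = FALSE)
    }
    at <- lines[(pos + 2L):(pos + 1L + nat)]
    x <- .num(substr(at, 21, 28), f, "x coordinate")
    y <- .num(substr(at, 29, 36), f, "y coordinate")
    z <- .num(substr(at, 37, 44), f, "z coordinate")
    if (is.null(elements)) {
      elements <- gsub("[0-9 ]", "", substr(at, 11, 15))
      elements[!nzchar(elements)] <- "C"
    }
    bx <- .num(strsplit(trimws(lines[pos + 2L + nat]), "[[:space:]]+")[[1]][1:3],
               f, "box line")
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times <- c(times, if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_)
    frames[[f]] <- cbind(x, y, z) * 10      # nm -> Angstrom
    boxes[[f]] <- bx * 10
    pos <- pos + nat + 3L
  }
  if (!length(frames)) stop("no frames found in GRO file", call. = FALSE)
  .assemble(frames, boxes, times, elements)
}

.read_pdb <- function(lines) {
  cryst <- grep("^CRYST1", lines, value = TRUE)
  box <- if (length(cryst)) {
    .num(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
           substr(cryst[1], 25, 33)), 1, "CRYST1 record")
  } else NULL
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  single <- FALSE
  if (!length(starts)) { starts <- 1L; ends <- length(lines); single <- TRUE }
  if (length(starts) != length(ends)) stop("unbalanced MODEL/ENDMDL records", call. = FALSE)
  frames <- list(); boxes <- list(); times <- numeric(); elements <- NULL
  for (f in seq_along(starts)) {
    blk <- lines[starts[f]:ends[f]]
    at <- grep("^(ATOM  |HETATM)", blk, value = TRUE)
    if (!length(at)) stop("no atom records in frame ", f, call. = FALSE)
    x <- .num(substr(at, 31, 38), f, "x coordinate")
    y <- .num(substr(at, 39, 46), f, "y coordinate")
    z <- .num(substr(at, 47, 54), f, "z coordinate")
    if (is.null(elements)) {
      elements <- trimws(substr(at, 77, 78))
      fallback <- gsub("[0-9 ]", "", substr(at, 13, 16))
      elements[!nzchar(elements)] <- substr(fallback[!nzchar(elements)], 1, 1)
      elements[!nzchar(elements)] <- "C"
    }
    tline <- grep("^REMARK +6 +TIME=", blk, value = TRUE)
    times <- c(times, if (length(tline)) {
      .num(sub("^REMARK +6 +TIME=", "", tline[1]), f, "TIME remark")
    } else NA_real_)
    if (is.null(box)) stop("PDB file has no CRYST1 record; box unknown", call. = FALSE)
    frames[[f]] <- cbind(x, y, z)
    boxes[[f]] <- box
  }
  .assemble(frames, boxes, times, elements)
}

.read_xyz <- function(lines, box = NULL) {
  frames <- list(); boxes <- list(); times <- numeric(); pos <- 1L; f <- 0L
  elements <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    f <- f + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1L) stop("malformed atom count in frame ", f, call. = FALSE)
    if (pos + 1L + nat > length(lines)) stop("truncated frame ", f, call. = FALSE)
    comment <- lines[pos + 1L]
    tm <- regmatches(comment, regexpr("time=\\s*[-0-9.eE+]+", comment))
    bm <- regmatches(comment, regexpr("box=\\s*[-0-9.eE+]+,[-0-9.eE+]+,[-0-9.eE+]+", comment))
    bx <- if (length(bm)) {
      .num(strsplit(sub("box=\\s*", "", bm), ",")[[1]], f, "box token")
    } else if (!is.null(box)) {
      box
    } else {
      stop("frame ", f, " has no box token and no fixed box was supplied",
           call. = FALSE)
    }
    at <- strsplit(trimws(lines[(pos + 2L):(pos + 1L + nat)]), "[[:space:]]+")
    if (any(vapply(at, length, integer(1)) < 4L)) {
      stop("malformed atom line in frame ", f, call. = FALSE)
    }
    m <- do.call(rbind, lapply(at, function(v) v[1:4]))
    if (is.null(elements)) elements <- m[, 1]
    frames[[f]] <- matrix(.num(m[, 2:4], f, "coordinates"), ncol = 3L)
    boxes[[f]] <- bx
    times <- c(times, if (length(tm)) as.numeric(sub("time=\\s*", "", tm)) else NA_real_)
    pos <- pos + nat + 2L
  }
  if (!length(frames)) stop("no frames found in XYZ file", call. = FALSE)
  .assemble(frames, boxes, times, elements)
}

#' Write a trajectory to GRO, PDB or XYZ
#'
#' Round-trips through [readTrajectory()]: GRO is written in nm at 0.001 nm
#' precision (0.01 Angstrom), PDB and XYZ in Angstrom at 0.001 precision.
#' Element symbols are taken from `metadata$elements` when present ("C"
#' otherwise).
#'
#' @param traj a valid [Trajectory-class].
#' @param path output file.
#' @param fmt `"gro"`, `"pdb"`, `"xyz"` or `"auto"` (from extension).
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path, fmt = c("auto", "gro", "pdb", "xyz")) {
  fmt <- match.arg(fmt)
  validObject(traj)
  if (fmt == "auto") {
    fmt <- tolower(tools::file_ext(path))
    if (!fmt %in% c("gro", "pdb", "xyz")) {
      stop("cannot infer trajectory format from extension '", fmt, "'", call. = FALSE)
    }
  }
  nA <- nAtoms(traj)
  el <- traj@metadata$elements
  if (is.null(el)) el <- rep("C", nA)
  out <- character()
  for (f in seq_len(nFrames(traj))) {
    xyz <- frameCoords(traj, f)
    bx <- frameBox(traj, f)
    tm <- traj@times[f]
    if (fmt == "gro") {
      out <- c(out,
        sprintf("bilayer system t= %.6f", tm),
        sprintf("%5d", nA),
        sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                1L, "SYS", substr(el, 1, 5), seq_len(nA) %% 100000L,
                xyz[, 1] / 10, xyz[, 2] / 10, xyz[, 3] / 10),
        sprintf("%10.5f%10.5f%10.5f", bx[1] / 10, bx[2] / 10, bx[3] / 10))
    } else if (fmt == "pdb") {
      if (f == 1L) {
        out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                              bx[1], bx[2], bx[3], 90, 90, 90))
      }
      out <- c(out,
        sprintf("MODEL     %4d", f),
        sprintf("REMARK   6 TIME= %.6f", tm),
        sprintf("ATOM  %5d %-4s%-4s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                seq_len(nA) %% 100000L, substr(el, 1, 4), "SYS",
                1L, xyz[, 1], xyz[, 2], xyz[, 3], substr(el, 1, 2)),
        "ENDMDL")
    } else {
      out <- c(out,
        sprintf("%d", nA),
        sprintf("time=%.6f box=%.4f,%.4f,%.4f", tm, bx[1], bx[2], bx[3]),
        sprintf("%-3s %12.3f %12.3f %12.3f", el, xyz[, 1], xyz[, 2], xyz[, 3]))
    }
  }
  if (fmt == "pdb") out <- c(out, "END")
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read a topology-map sidecar (JSON)
#'
#' The sidecar is a JSON object with fields `n_atoms`, `groups` (an object
#' mapping the six required group names to 1-based index arrays), and the
#' optional `masses`, `electrons` and `chains`
#' (`[{"carbon": i, "hydrogens": [...]}, ...]`) fields.
#'
#' @param path JSON file.
#' @return a validated [TopologyMap-class].
#' @export
readTopoMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(j$n_atoms)) stop("topology map lacks 'n_atoms'", call. = FALSE)
  if (is.null(j$groups)) stop("topology map lacks 'groups'", call. = FALSE)
  missing <- setdiff(.REQUIRED_GROUPS, names(j$groups))
  if (length(missing)) {
    stop("topology map missing required groups: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  groups <- lapply(j$groups, function(g) as.integer(unlist(g)))
  chains <- lapply(j$chains %||% list(), function(ch) {
    out <- list(carbon = as.integer(ch$carbon),
                hydrogens = as.integer(unlist(ch$hydrogens)))
    if (!is.null(ch$position)) out$position <- ch$position
    out
  })
  TopologyMap(nAtoms = j$n_atoms, groups = groups,
              masses = if (length(j$masses)) as.numeric(j$masses) else NULL,
              electrons = if (length(j$electrons)) as.numeric(j$electrons) else numeric(),
              chains = chains)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a topology-map sidecar (JSON)
#'
#' @param topo a [TopologyMap-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTopoMap <- function(topo, path) {
  validObject(topo)
  obj <- list(n_atoms = topo@nAtoms, groups = topo@groups)
  if (length(topo@masses)) obj$masses <- topo@masses
  if (length(topo@electrons)) obj$electrons <- topo@electrons
  if (length(topo@chains)) obj$chains <- topo@chains
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
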