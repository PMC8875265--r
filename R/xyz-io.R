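# Multi-frame (extended-)XYZ I/O. Frames are concatenated blocks:
#   <natoms>
#   <comment, optionally extended-XYZ key=value pairs incl. Lattice="...">
#   <symbol> <x> <y> <z>   (natoms lines)
# Coordinates are in angstrom throughout.

#' Build a trajectory object in memory
#'
#' @param symbols Character vector of element symbols (shared by all
#'   frames).
#' @param coords List of numeric `n_atoms x 3` matrices, one per frame,
#'   angstrom.
#' @param dt Time step between stored frames, fs.
#' @param cell Optional `3 x 3` matrix of lattice vectors (rows), angstrom.
#' @return Object of class `trajectory` with fields `symbols`, `coords`,
#'   `dt` (fs), `cell`.
#' @export
trajectory <- function(symbols, coords, dt, cell = NULL) {
  if (!is.list(coords) || length(coords) < 1L) {
    stop("coords must be a non-empty list of n x 3 matrices", call. = FALSE)
  }
  n <- length(symbols)
  for (f in seq_along(coords)) {
    m <- coords[[f]]
    if (!is.matrix(m) || ncol(m) != 3L || nrow(m) != n) {
      stop("frame ", f, ": expected a ", n, " x 3 coordinate matrix",
           call. = FALSE)
    }
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a positive time step in fs", call. = FALSE)
  }
  if (!is.null(cell)) {
    cell <- as.matrix(cell)
    if (!all(dim(cell) == c(3L, 3L)) || abs(det(cell)) < 1e-10) {
      stop("cell must be 3 linearly independent lattice vectors",
           call. = FALSE)
    }
  }
  structure(list(symbols = as.character(symbols), coords = coords,
                 dt = dt, cell = cell),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("MD trajectory: ", n_frames(x), " frames, ", length(x$symbols),
      " atoms, dt = ", x$dt, " fs (", format(duration_ps(x)),
      " ps)\n", sep = "")
  if (!is.null(x$cell)) cat("  periodic cell present\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$coords)

#' Duration of a trajectory in ps
#'
#' `(n_frames - 1) * dt`, i.e. the time spanned from the first to the last
#' stored frame.
#'
#' @param traj A [trajectory()].
#' @return Duration in ps.
#' @export
duration_ps <- function(traj) (n_frames(traj) - 1L) * traj$dt / 1000

#' Frame times in ps
#' @param traj A [trajectory()].
#' @return Numeric vector, one time per frame, starting at 0.
#' @export
frame_times_ps <- function(traj) {
  (seq_len(n_frames(traj)) - 1L) * traj$dt / 1000
}

# Extract Lattice="ax ay az bx by bz cx cy cz" from an extended-XYZ
# comment line; NULL when absent.
.parse_lattice <- function(comment) {
  m <- regmatches(comment,
                  regexpr('Lattice="[^"]*"', comment, ignore.case = TRUE))
  if (length(m) == 0L) return(NULL)
  nums <- as.numeric(strsplit(trimws(sub('^[^"]*"', "",
                                         sub('"$', "", m))), "\\s+")[[1]])
  if (length(nums) != 9L || anyNA(nums)) {
    stop("malformed Lattice header: ", m, call. = FALSE)
  }
  matrix(nums, nrow = 3, byrow = TRUE)
}

#' Read a multi-frame (extended-)XYZ trajectory
#'
#' Accepts plain XYZ and the extended-XYZ dialect; a `Lattice="..."`
#' key in the comment line populates the periodic cell (the first frame's
#' lattice is used for the whole trajectory).
#'
#' @param path Path to the XYZ file.
#' @param dt Time step between stored frames, fs.
#' @return A [trajectory()].
#' @export
read_xyz_trajectory <- function(path, dt) {
  lines <- readLines(path)
  # drop trailing blank lines only
  while (length(lines) > 0L && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) stop("empty XYZ file: ", path, call. = FALSE)

  coords <- list()
  symbols <- NULL
  cell <- NULL
  pos <- 1L
  frame <- 0L
  while (pos <= length(lines)) {
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1L) {
      stop("frame ", frame, ": malformed atom-count header at line ", pos,
           call. = FALSE)
    }
    if (pos + 1L + nat > length(lines) + 0L) {
      stop("frame ", frame, ": truncated (expected ", nat, " atom lines)",
           call. = FALSE)
    }
    comment <- lines[pos + 1L]
    if (frame == 1L) cell <- .parse_lattice(comment)
    block <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(block), "\\s+")
    sym <- vapply(toks, `[`, character(1), 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (anyNA(xyz)) {
      stop("frame ", frame, ": non-numeric coordinates", call. = FALSE)
    }
    if (is.null(symbols)) {
      symbols <- sym
    } else if (length(sym) != length(symbols) || any(sym != symbols)) {
      stop("frame ", frame, ": atom count or symbol order differs from ",
           "frame 1", call. = FALSE)
    }
    coords[[frame]] <- xyz
    pos <- pos + 2L + nat
  }
  trajectory(symbols, coords, dt = dt, cell = cell)
}

#' Write a trajectory as extended XYZ
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param digits Coordinate precision (decimal places).
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, digits = 8) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$symbols)
  lat <- if (!is.null(traj$cell)) {
    sprintf('Lattice="%s" ', paste(sprintf("%.8f", t(traj$cell)),
                                   collapse = " "))
  } else ""
  props <- "Properties=species:S:1:pos:R:3"
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%-3s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(as.character(n),
                 paste0(lat, props, sprintf(" Time=%.4f",
                                            (f - 1L) * traj$dt)),
                 sprintf(fmt, traj$symbols, traj$coords[[f]][, 1],
                         traj$coords[[f]][, 2], traj$coords[[f]][, 3])),
               con)
  }
  invisible(path)
}
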