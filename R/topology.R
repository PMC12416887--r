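#' Transmembrane helix definitions for the human BK Core-MT construct
#'
#' Residue ranges (author numbering, human BK convention) of the six
#' transmembrane helices used throughout the package: S1 T109-S135,
#' S2 F148-A170, S3 V181-L199, S4 G205-N225, S5 S230-S259 and S6 A313-E324
#' (the segment below the glycine hinge).
#'
#' @return Named list of length-2 integer vectors `c(first, last)`.
#' @export
bk_helix_definitions <- function() {
  list(
    S1 = c(109L, 135L),
    S2 = c(148L, 170L),
    S3 = c(181L, 199L),
    S4 = c(205L, 225L),
    S5 = c(230L, 259L),
    S6 = c(313L, 324L)
  )
}

#' Representative charged-group atom for a residue type
#'
#' Charged-group positions follow the guanidinium CZ atom for arginine and
#' the side-chain carboxyl carbon for aspartate (CG) and glutamate (CD).
#' Lysine maps to the terminal NZ nitrogen.
#'
#' @param resname 3-letter residue code(s).
#' @return Character vector of atom names; `NA` for residues without a
#'   standard charged group.
#' @export
charged_group_atom <- function(resname) {
  map <- c(ARG = "CZ", ASP = "CG", GLU = "CD", LYS = "NZ")
  unname(map[toupper(resname)])
}

#' Construct a topology
#'
#' A topology holds the per-atom table (identifiers, residue assignment,
#' partial charge and van der Waals radius) plus helix definitions and the
#' charged-group convention. Atom identity `(resid, chain, name)` must be
#' unique.
#'
#' @param atoms Data frame with columns `atom_id`, `name`, `resid`,
#'   `resname`, `chain`, `element`, and optionally `charge` (e) and
#'   `radius` (A).
#' @param helices Named list of residue ranges; defaults to
#'   [bk_helix_definitions()].
#' @return An object of class `topology`.
#' @export
new_topology <- function(atoms, helices = bk_helix_definitions()) {
  atoms <- as_tibble(atoms)
  need <- c("atom_id", "name", "resid", "resname", "chain", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    abort(paste0("atoms is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  if (!"radius" %in% names(atoms)) atoms$radius <- NA_real_
  key <- paste(atoms$resid, atoms$chain, atoms$name)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(paste0("duplicate atom key (resid chain name): ", dup))
  }
  if (any(!is.na(atoms$radius) & atoms$radius <= 0)) {
    abort("van der Waals radii must be positive")
  }
  structure(list(atoms = atoms, helices = helices), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain)), " chain(s), ",
      length(x$helices), " helix definition(s)\n", sep = "")
  invisible(x)
}

n_atoms <- function(topology) nrow(topology$atoms)

#' Construct a trajectory
#'
#' Frames of Cartesian coordinates (A) with per-frame orthorhombic box
#' lengths. The z axis is the membrane normal with the extracellular side at
#' positive z and z = 0 at the membrane centre.
#'
#' @param coords Numeric array `[n_atoms, 3, n_frames]` (a single
#'   `[n_atoms, 3]` matrix is promoted to one frame).
#' @param box Numeric length-3 vector, or `[n_frames, 3]` matrix of box
#'   lengths (A).
#' @param time_step Time per frame, ns.
#' @return Object of class `trajectory`.
#' @export
new_trajectory <- function(coords, box, time_step = 1) {
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  if (nrow(box) == 1 && nf > 1) box <- box[rep(1, nf), , drop = FALSE]
  if (nrow(box) != nf) abort("box must have one row per frame")
  if (any(box <= 0)) abort("box lengths must be positive")
  structure(list(coords = coords, box = box, time_step = time_step),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", dim(x$coords)[1], " atoms x ", n_frames(x),
      " frame(s), dt = ", x$time_step, " ns\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Coordinates of one frame
#' @param trajectory A `trajectory`.
#' @param frame Frame index (1-based).
#' @return `[n_atoms, 3]` numeric matrix.
#' @export
frame_coords <- function(trajectory, frame) {
  if (frame < 1 || frame > n_frames(trajectory)) {
    abort(paste0("frame ", frame, " outside 1..", n_frames(trajectory)))
  }
  m <- trajectory$coords[, , frame]
  if (!is.matrix(m)) m <- matrix(m, ncol = 3)
  m
}

frame_times <- function(trajectory) {
  (seq_len(n_frames(trajectory)) - 1) * trajectory$time_step
}
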