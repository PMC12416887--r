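# Structure and trajectory I/O: PDB v3 coordinate records, multi-model PDB
# trajectories, and the CSV parameter table carrying partial charges and
# van der Waals radii. Reading goes through bio3d; the multi-model writer is
# local because bio3d does not emit MODEL blocks.

parse_cryst1 <- function(lines) {
  i <- grep("^CRYST1", lines)
  if (!length(i)) return(NULL)
  ln <- lines[i[1]]
  a <- as.numeric(substr(ln, 7, 15))
  b <- as.numeric(substr(ln, 16, 24))
  c_ <- as.numeric(substr(ln, 25, 33))
  ang <- c(as.numeric(substr(ln, 34, 40)),
           as.numeric(substr(ln, 41, 47)),
           as.numeric(substr(ln, 48, 54)))
  if (any(abs(ang - 90) > 1e-3)) {
    abort("triclinic boxes are not supported (CRYST1 angles differ from 90)")
  }
  c(a, b, c_)
}

validate_pdb_records <- function(lines) {
  rec <- grep("^(ATOM  |HETATM)", lines)
  for (i in rec) {
    ln <- lines[i]
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz)) {
      abort(paste0("malformed coordinate record at line ", i, ": ",
                   trimws(substr(ln, 1, 54))))
    }
  }
  invisible(TRUE)
}

#' Read a PDB structure
#'
#' Parses PDB v3 coordinate records into a [new_topology()] plus a
#' single-frame [new_trajectory()]. Author residue numbering is preserved
#' verbatim (no renumbering); coordinates are in angstroms. Only
#' orthorhombic boxes are supported.
#'
#' @param path Path to a PDB file.
#' @param box Optional length-3 box (A) used when the file has no CRYST1.
#' @return List with elements `topology` and `trajectory`.
#' @export
read_structure <- function(path, box = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  validate_pdb_records(lines)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  el <- trimws(a$elesy)
  el[is.na(el) | el == ""] <- substr(trimws(a$elety)[is.na(el) | el == ""], 1, 1)
  atoms <- tibble(
    atom_id = seq_len(nrow(a)),
    name = trimws(a$elety),
    resid = as.integer(a$resno),
    resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    element = el
  )
  topo <- new_topology(atoms)
  b <- parse_cryst1(lines)
  if (is.null(b)) b <- box
  if (is.null(b)) {
    xyz <- cbind(a$x, a$y, a$z)
    b <- apply(xyz, 2, function(v) diff(range(v))) + 20
  }
  traj <- new_trajectory(cbind(a$x, a$y, a$z), b)
  list(topology = topo, trajectory = traj)
}

format_pdb_atom <- function(i, name, resname, chain, resid, x, y, z,
                            element) {
  nm <- ifelse(nchar(name) < 4, paste0(" ", name), name)
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i %% 100000, nm, substr(resname, 1, 3), substr(chain, 1, 1),
          resid %% 10000, x, y, z, 1.0, 0.0, substr(element, 1, 2))
}

#' Write a structure or trajectory as (multi-model) PDB
#'
#' Writes one MODEL block per frame, with a CRYST1 record carrying the box
#' of the first frame. Coordinates are written at the PDB's native 3-decimal
#' precision.
#'
#' @param trajectory A [new_trajectory()] (single- or multi-frame).
#' @param topology The matching [new_topology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(trajectory, topology, path) {
  at <- topology$atoms
  if (nrow(at) != dim(trajectory$coords)[1]) {
    abort(paste0("atom count mismatch: topology has ", nrow(at),
                 ", trajectory has ", dim(trajectory$coords)[1]))
  }
  nf <- n_frames(trajectory)
  b <- trajectory$box[1, ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    b[1], b[2], b[3], 90, 90, 90), con)
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- trajectory$coords[, , f]
    writeLines(format_pdb_atom(at$atom_id, at$name, at$resname, at$chain,
                               at$resid, xyz[, 1], xyz[, 2], xyz[, 3],
                               at$element), con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a trajectory from a multi-model PDB
#'
#' Frames are returned in file order. The box is read from CRYST1 when
#' present, otherwise taken from `box`.
#'
#' @param path Multi-model PDB path.
#' @param topology Topology the frames must match (atom count checked).
#' @param box Optional length-3 box (A) when the file carries none.
#' @param time_step ns per frame.
#' @return A [new_trajectory()].
#' @export
read_trajectory <- function(path, topology, box = NULL, time_step = 1) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  validate_pdb_records(lines)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  nat <- ncol(xyz) / 3
  if (nat != n_atoms(topology)) {
    abort(paste0("atom count mismatch: file has ", nat,
                 " atoms, topology has ", n_atoms(topology)))
  }
  nf <- nrow(xyz)
  coords <- array(0, c(nat, 3, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  b <- parse_cryst1(lines)
  if (is.null(b)) b <- box
  if (is.null(b)) abort("file has no CRYST1 record; supply box= explicitly")
  new_trajectory(coords, b, time_step = time_step)
}

#' Read a charge/radius parameter table
#'
#' CSV with header `residue,atom,charge_e,radius_A`. A `residue` value of
#' `*` acts as a wildcard matched after all specific rows.
#'
#' @param path CSV path.
#' @return Tibble with columns `residue`, `atom`, `charge_e`, `radius_A`.
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tab <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("residue", "atom", "charge_e", "radius_A")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(paste0("parameter table missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  tab
}

#' Assign partial charges and radii onto a topology
#'
#' Atoms are matched by `(residue_name, atom_name)`; rows with residue `*`
#' match any residue and are consulted after specific rows
#' (first-match-wins). Duplicate keys in the table trigger a warning naming
#' the shadowed rows; atoms with no matching row are an error.
#'
#' @param topology A [new_topology()].
#' @param parameters Table from [read_parameter_table()] (or equivalent
#'   data frame).
#' @return The topology with `charge` and `radius` filled in.
#' @export
assign_parameters <- function(topology, parameters) {
  tab <- as_tibble(parameters)
  key <- paste(tab$residue, tab$atom)
  if (anyDuplicated(key)) {
    warn(paste0("shadowed parameter row(s) ignored: ",
                paste(unique(key[duplicated(key)]), collapse = "; ")))
    tab <- tab[!duplicated(key), ]
  }
  at <- topology$atoms
  k_specific <- paste(at$resname, at$name)
  k_wild <- paste("*", at$name)
  tk <- paste(tab$residue, tab$atom)
  idx <- match(k_specific, tk)
  idx[is.na(idx)] <- match(k_wild, tk)[is.na(idx)]
  if (anyNA(idx)) {
    bad <- unique(k_specific[is.na(idx)])
    abort(paste0("no parameters for atom(s): ", paste(bad, collapse = "; ")))
  }
  at$charge <- tab$charge_e[idx]
  at$radius <- tab$radius_A[idx]
  topology$atoms <- at
  topology
}
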